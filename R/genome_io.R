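#' @importFrom stats setNames median cor cutree hclust as.dist dist lm coef
#'   pt pnorm p.adjust rnbinom rpois runif rnorm sample.int quantile var
#'   predict ecdf ks.test glm binomial rbinom aggregate complete.cases sd
#' @importFrom utils head tail write.table read.table
NULL

# ---- GenomeAnnotation -------------------------------------------------------
# Internal coordinates are 0-based half-open everywhere; conversion to the
# 1-based inclusive GTF convention happens only in read_gtf()/write_gtf().

#' Construct a genome annotation
#'
#' A `genome_annotation` bundles chromosome lengths, a transcript table and an
#' exon table. All coordinates are 0-based half-open. Exons are stored sorted
#' by transcript and start; each transcript lies on one chromosome and one
#' strand and has at least one exon.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`+`/`-`), `biotype` (`coding`/`noncoding`).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_lengths, transcripts, exons) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need_tx <- c("transcript_id", "gene_id", "chrom", "strand", "biotype")
  if (!all(need_tx %in% names(transcripts)))
    stop("transcripts must have columns: ", paste(need_tx, collapse = ", "))
  if (!all(c("transcript_id", "start", "end") %in% names(exons)))
    stop("exons must have columns transcript_id, start, end")
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript ids")
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  rownames(transcripts) <- NULL
  ann <- structure(list(chrom_lengths = chrom_lengths,
                        transcripts = transcripts,
                        exons = exons),
                   class = "genome_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  tx <- ann$transcripts
  ex <- ann$exons
  if (!all(tx$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(tx$chrom %in% names(ann$chrom_lengths)))
    stop("transcript on unknown chromosome: ",
         paste(unique(setdiff(tx$chrom, names(ann$chrom_lengths))), collapse = ","))
  if (!all(tx$transcript_id %in% ex$transcript_id))
    stop("every transcript must have >= 1 exon")
  if (!all(ex$transcript_id %in% tx$transcript_id))
    stop("exon with unknown transcript_id")
  if (any(ex$start >= ex$end)) stop("exon with start >= end")
  if (any(ex$start < 0)) stop("negative exon start")
  chrom_of <- setNames(tx$chrom, tx$transcript_id)
  lim <- ann$chrom_lengths[chrom_of[ex$transcript_id]]
  if (any(ex$end > lim)) stop("exon beyond chromosome end")
  # sortedness / non-overlap within transcript (exons are pre-sorted)
  by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- ex$start[idx]; e <- ex$end[idx]
      if (any(s[-1] < e[-length(e)]))
        stop("overlapping exons within transcript ", ex$transcript_id[idx[1]])
    }
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_lengths), "chromosomes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Per-transcript genomic spans and spliced lengths
#'
#' @param ann a `genome_annotation`.
#' @return data.frame with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`, `start`, `end` (locus span, 0-based
#'   half-open) and `spliced_length` (sum of exon lengths, nt).
#' @export
tx_spans <- function(ann) {
  ex <- ann$exons
  sp_start <- tapply(ex$start, ex$transcript_id, min)
  sp_end <- tapply(ex$end, ex$transcript_id, max)
  sp_len <- tapply(ex$end - ex$start, ex$transcript_id, sum)
  tx <- ann$transcripts
  tx$start <- as.integer(sp_start[tx$transcript_id])
  tx$end <- as.integer(sp_end[tx$transcript_id])
  tx$spliced_length <- as.integer(sp_len[tx$transcript_id])
  tx
}

# ---- FASTA ------------------------------------------------------------------

#' Read a multi-record FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequence contains characters outside {A,C,G,T,N}")
  setNames(seqs, nm)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---- GTF / GFF3 -------------------------------------------------------------

#' Read a GTF (or GFF3) annotation
#'
#' Exon features are grouped into transcripts; 1-based inclusive file
#' coordinates become internal 0-based half-open. For GFF3 the `Parent`
#' attribute maps to the transcript and transcript features' `Parent` to the
#' gene; GTF (`transcript_id` / `gene_id` attributes) is the canonical
#' dialect.
#'
#' @param path GTF/GFF3 file.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent, each chromosome length is taken as the maximum annotated end.
#' @param format `"auto"` (by extension), `"gtf"` or `"gff3"`.
#' @return a [genome_annotation()].
#' @export
read_gtf <- function(path, chrom_lengths = NULL, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = format)
  meta <- S4Vectors::mcols(gr)
  is_exon <- !is.na(meta$type) & meta$type == "exon"
  ex <- gr[is_exon]
  if (length(ex) == 0L) {
    cl <- if (is.null(chrom_lengths)) integer(0) else chrom_lengths
    return(genome_annotation(cl,
      data.frame(transcript_id = character(0), gene_id = character(0),
                 chrom = character(0), strand = character(0),
                 biotype = character(0)),
      data.frame(transcript_id = character(0), start = integer(0),
                 end = integer(0))))
  }
  m <- S4Vectors::mcols(ex)
  if (format == "gff3") {
    txid <- as.character(S4Vectors::unstrsplit(m$Parent, ","))
    txid[txid == ""] <- NA_character_
    # gene of each transcript from the transcript-level features
    trf <- gr[!is.na(meta$type) & meta$type %in%
                c("transcript", "mRNA", "ncRNA", "lnc_RNA")]
    tm <- S4Vectors::mcols(trf)
    gene_of <- setNames(as.character(S4Vectors::unstrsplit(tm$Parent, ",")),
                        as.character(tm$ID))
    gid <- unname(gene_of[txid])
    gid[is.na(gid)] <- txid[is.na(gid)]
    bty <- rep(NA_character_, length(ex))
  } else {
    txid <- if ("transcript_id" %in% names(m)) as.character(m$transcript_id)
            else rep(NA_character_, length(ex))
    gid <- if ("gene_id" %in% names(m)) as.character(m$gene_id)
           else rep(NA_character_, length(ex))
    bty <- if ("transcript_biotype" %in% names(m))
      as.character(m$transcript_biotype) else rep(NA_character_, length(ex))
  }
  if (any(is.na(txid) | txid == ""))
    stop("exon feature lacking transcript_id in ", path)
  if (any(GenomicRanges::start(ex) > GenomicRanges::end(ex)))
    stop("exon with start > end")
  exons <- data.frame(transcript_id = txid,
                      start = GenomicRanges::start(ex) - 1L,
                      end = GenomicRanges::end(ex),
                      stringsAsFactors = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(ex))
  strand <- as.character(GenomicRanges::strand(ex))
  first <- !duplicated(txid)
  tx <- data.frame(transcript_id = txid[first],
                   gene_id = ifelse(is.na(gid[first]), txid[first], gid[first]),
                   chrom = chrom[first], strand = strand[first],
                   biotype = ifelse(is.na(bty[first]), "coding", bty[first]),
                   stringsAsFactors = FALSE)
  # one chromosome / strand per transcript
  if (any(tapply(chrom, txid, function(z) length(unique(z))) > 1L))
    stop("transcript with exons on multiple chromosomes")
  if (any(tapply(strand, txid, function(z) length(unique(z))) > 1L))
    stop("transcript with exons on multiple strands")
  if (any(tx$strand == "*")) stop("exon without strand")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(exons$end, chrom[match(exons$transcript_id, txid)], max)
    chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  genome_annotation(chrom_lengths, tx, exons)
}

#' Write a genome annotation as GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id` and
#' `transcript_biotype` attributes. Internal 0-based half-open coordinates
#' become 1-based inclusive, so `read_gtf(write_gtf(a))` reproduces `a`.
#'
#' @param ann a [genome_annotation()].
#' @param path output path.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(ann, path, source = "lncrnakit") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gtf produced by lncrnakit", con)
  tx <- ann$transcripts
  ex <- ann$exons
  if (nrow(ex) > 0L) {
    i <- match(ex$transcript_id, tx$transcript_id)
    lines <- sprintf(
      "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; transcript_biotype \"%s\";",
      tx$chrom[i], source, ex$start + 1L, ex$end, tx$strand[i],
      tx$gene_id[i], ex$transcript_id, tx$biotype[i])
    writeLines(lines, con)
  }
  invisible(path)
}

# ---- BED6 -------------------------------------------------------------------

#' Read a BED6 file of small-RNA read alignments
#'
#' @param path BED6 file (0-based half-open; strand in column 6).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "character"))
  if (!all(bed$strand %in% c("+", "-"))) stop("BED strand must be +/-")
  bed
}

#' Write small-RNA reads as BED6
#' @param reads data.frame as returned by [read_bed()].
#' @param path output path.
#' @export
write_bed <- function(reads, path) {
  write.table(reads[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- stranded interval index ------------------------------------------------

#' Build a stranded interval index over an annotation
#'
#' The index answers overlap queries at the transcript level on either the
#' genomic (unspliced) span or on exonic bases, with a same/opposite/both
#' strand filter. Results match a brute-force scan over all transcripts.
#'
#' @param ann a [genome_annotation()].
#' @return an object of class `interval_index`.
#' @export
build_interval_index <- function(ann) {
  sp <- tx_spans(ann)
  to_gr <- function(chrom, start, end, strand) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end),
                           strand = strand)
  }
  span_gr <- to_gr(sp$chrom, sp$start, sp$end, sp$strand)
  i <- match(ann$exons$transcript_id, sp$transcript_id)
  exon_gr <- to_gr(sp$chrom[i], ann$exons$start, ann$exons$end, sp$strand[i])
  structure(list(spans = sp, span_gr = span_gr, exon_gr = exon_gr,
                 exon_tx = ann$exons$transcript_id),
            class = "interval_index")
}

#' Query a stranded interval index
#'
#' @param index an `interval_index` from [build_interval_index()].
#' @param chrom chromosome name (unknown chromosome gives an empty result).
#' @param start,end query interval, 0-based half-open; a zero-length interval
#'   overlaps nothing.
#' @param query_strand strand of the query feature (`+`/`-`).
#' @param strand strand filter relative to `query_strand`.
#' @param level `"span"` for genomic-locus overlap, `"exon"` for exonic
#'   overlap (>= 1 bp either way).
#' @return character vector of transcript ids, in annotation order.
#' @export
query_index <- function(index, chrom, start, end, query_strand = "+",
                        strand = c("both", "same", "opposite"),
                        level = c("span", "exon")) {
  strand <- match.arg(strand)
  level <- match.arg(level)
  if (end <= start) return(character(0))
  if (!chrom %in% unique(index$spans$chrom)) return(character(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (level == "span") {
    hit <- GenomicRanges::findOverlaps(q, index$span_gr, ignore.strand = TRUE)
    ids <- index$spans$transcript_id[S4Vectors::subjectHits(hit)]
    strands <- index$spans$strand[S4Vectors::subjectHits(hit)]
  } else {
    hit <- GenomicRanges::findOverlaps(q, index$exon_gr, ignore.strand = TRUE)
    ids <- index$exon_tx[S4Vectors::subjectHits(hit)]
    strands <- as.character(GenomicRanges::strand(index$exon_gr))[S4Vectors::subjectHits(hit)]
    keep0 <- !duplicated(ids)
    ids <- ids[keep0]; strands <- strands[keep0]
  }
  keep <- switch(strand,
                 both = rep(TRUE, length(ids)),
                 same = strands == query_strand,
                 opposite = strands != query_strand)
  unique_ids <- ids[keep]
  unique_ids[order(match(unique_ids, index$spans$transcript_id))]
}

# exonic overlap in bp between two exon sets (data.frames with start/end),
# 0-based half-open
exonic_overlap_bp <- function(ex_a, ex_b) {
  if (nrow(ex_a) == 0L || nrow(ex_b) == 0L) return(0L)
  total <- 0L
  for (i in seq_len(nrow(ex_a))) {
    o <- pmin(ex_a$end[i], ex_b$end) - pmax(ex_a$start[i], ex_b$start)
    total <- total + sum(pmax(o, 0L))
  }
  as.integer(total)
}

#' Extract the spliced sequence of a transcript
#'
#' Exon sequences are concatenated 5' to 3' (reverse-complemented for minus
#' strand transcripts).
#'
#' @param ann a [genome_annotation()].
#' @param genome named character vector of chromosome sequences.
#' @param tx_id transcript id.
#' @return character scalar, the spliced transcript sequence.
#' @export
transcript_seq <- function(ann, genome, tx_id) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == tx_id, ]
  if (nrow(tx) == 0L) stop("unknown transcript: ", tx_id)
  ex <- ann$exons[ann$exons$transcript_id == tx_id, , drop = FALSE]
  chrom_seq <- genome[[tx$chrom]]
  pieces <- substring(chrom_seq, ex$start + 1L, ex$end)
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
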