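# Small-RNA cluster calling from 17-27 nt 5'-U reads: coverage islands with
# gap merging, ranking, and per-cluster genomic feature fractions.

#' Filter small-RNA reads to 17-27 nt 5'-U reads
#'
#' Keeps reads of length 17 to 27 nt whose 5' base is U: a plus-strand read
#' must start on a reference `T`, a minus-strand read must end on a
#' reference `A` (so that the read itself, reverse-complemented, starts
#' with U).
#'
#' @param reads data.frame as from [read_bed()] (0-based half-open).
#' @param genome named character vector of chromosome sequences.
#' @param min_len,max_len inclusive read-length bounds (defaults 17, 27).
#' @return the retained reads with added `length` and `first_base` columns
#'   (`first_base` is the base at the read's 5' end, in read space).
#' @export
filter_srna_reads <- function(reads, genome, min_len = 17L, max_len = 27L) {
  if (!all(reads$chrom %in% names(genome)))
    stop("read on unknown chromosome")
  lens <- nchar(genome)[reads$chrom]
  if (any(reads$start < 0L) || any(reads$end > lens))
    stop("read off chromosome end")
  len <- reads$end - reads$start
  keep_len <- len >= min_len & len <= max_len
  plus <- reads$strand == "+"
  base5 <- character(nrow(reads))
  base5[plus] <- substring(genome[reads$chrom[plus]],
                           reads$start[plus] + 1L, reads$start[plus] + 1L)
  base5[!plus] <- substring(genome[reads$chrom[!plus]],
                            reads$end[!plus], reads$end[!plus])
  is_u <- (plus & base5 == "T") | (!plus & base5 == "A")
  out <- reads[keep_len & is_u, , drop = FALSE]
  out$length <- len[keep_len & is_u]
  out$first_base <- rep("T", nrow(out))
  rownames(out) <- NULL
  out
}

#' Call small-RNA clusters from filtered reads
#'
#' Strand-agnostic per-base read depth is computed; maximal runs of bases
#' with depth >= `mincov` become islands, and islands separated by at most
#' `pad` bp are merged into one cluster. The cluster interval is the merged
#' span; `read_count` is the number of reads overlapping it.
#'
#' @param reads filtered reads ([filter_srna_reads()]).
#' @param pad maximum merged gap (bp, default 22).
#' @param mincov minimum per-base depth (default 20).
#' @param total_reads denominator for cluster CPM (default: number of input
#'   reads).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `read_count`, `cpm`, sorted by position.
#' @export
call_clusters <- function(reads, pad = 22L, mincov = 20L,
                          total_reads = nrow(reads)) {
  if (pad < 0L) stop("pad must be >= 0")
  if (mincov < 1L) stop("mincov must be >= 1")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), read_count = integer(0),
                      cpm = numeric(0))
  if (nrow(reads) == 0L) return(empty)
  out <- list()
  for (chr in sort(unique(reads$chrom))) {
    r <- reads[reads$chrom == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    cov <- IRanges::coverage(ir)
    isl <- IRanges::slice(cov, lower = mincov, rangesOnly = TRUE)
    if (length(isl) == 0L) next
    merged <- IRanges::reduce(isl, min.gapwidth = pad + 1L)
    cnt <- IRanges::countOverlaps(merged, ir)
    out[[chr]] <- data.frame(chrom = chr,
                             start = IRanges::start(merged) - 1L,
                             end = IRanges::end(merged),
                             read_count = as.integer(cnt),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  cl <- do.call(rbind, out)
  rownames(cl) <- NULL
  cl$cpm <- cl$read_count / total_reads * 1e6
  cl
}

#' Rank clusters by read count
#'
#' @param clusters data.frame from [call_clusters()].
#' @param top_n number of top clusters to keep (default 80).
#' @param total_reads denominator for the coverage share (default: total
#'   reads over all clusters).
#' @return list with `top` (the top clusters with a `rank` column;
#'   descending read count, ties broken by genomic position) and `share`
#'   (fraction of `total_reads` falling in the top clusters).
#' @export
rank_clusters <- function(clusters, top_n = 80L,
                          total_reads = sum(clusters$read_count)) {
  if (top_n <= 0L) stop("top_n must be positive")
  ord <- order(-clusters$read_count, clusters$chrom, clusters$start)
  top <- clusters[head(ord, top_n), , drop = FALSE]
  top$rank <- seq_len(nrow(top))
  rownames(top) <- NULL
  list(top = top,
       share = if (total_reads > 0) sum(top$read_count) / total_reads else 0)
}

# per-position feature category lookup over gene loci (locus-level overlap;
# sRNA may derive from unspliced precursors)
.position_category <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom & genes$start <= pos & genes$end > pos, ,
             drop = FALSE]
  if (nrow(g) == 0L) return("intergenic")
  if (all(c("+", "-") %in% g$strand)) return("overlapped")
  if (any(g$coding)) return("coding")
  "noncoding"
}

#' Partition a cluster's reads among genomic feature categories
#'
#' Each read is assigned by the position of its 5' end: `overlapped` when a
#' gene locus is annotated on both strands there, else `coding` /
#' `noncoding` by the gene locus it falls in, else `intergenic`. Fractions
#' are category counts over the cluster's read count and sum to one.
#'
#' @param cluster one row of [call_clusters()] output.
#' @param reads filtered reads.
#' @param annotation [genome_annotation()] carrying coding and noncoding
#'   transcripts.
#' @return named numeric vector of fractions over
#'   `c(intergenic, coding, overlapped, noncoding)`.
#' @export
partition_cluster_reads <- function(cluster, reads, annotation) {
  r <- reads[reads$chrom == cluster$chrom & reads$start < cluster$end &
               reads$end > cluster$start, , drop = FALSE]
  if (nrow(r) == 0L) stop("cluster with zero reads")
  genes <- gene_loci(annotation)
  pos5 <- ifelse(r$strand == "+", r$start, r$end - 1L)
  cats <- vapply(pos5, .position_category, character(1),
                 chrom = cluster$chrom, genes = genes)
  lev <- c("intergenic", "coding", "overlapped", "noncoding")
  cnt <- table(factor(cats, levels = lev))
  setNames(as.numeric(cnt) / nrow(r), lev)
}

#' Closest coding gene to a cluster center
#'
#' The cluster center is the midpoint of its interval; distance to a gene
#' locus is 0 when the center lies inside it and the distance to the nearer
#' locus edge otherwise. Ties go to the leftmost gene.
#'
#' @param cluster one row of [call_clusters()] output.
#' @param annotation [genome_annotation()]; must contain a coding gene.
#' @return list with `gene_id` and `distance` (bp).
#' @export
nearest_coding_gene <- function(cluster, annotation) {
  genes <- gene_loci(annotation)
  genes <- genes[genes$coding & genes$chrom == cluster$chrom, , drop = FALSE]
  if (nrow(genes) == 0L) {
    genes_all <- gene_loci(annotation)
    if (!any(genes_all$coding)) stop("annotation has no coding gene")
    stop("no coding gene on chromosome ", cluster$chrom)
  }
  center <- (cluster$start + cluster$end) %/% 2L
  d <- ifelse(center < genes$start, genes$start - center,
              ifelse(center >= genes$end, center - (genes$end - 1L), 0L))
  ord <- order(d, genes$start)
  list(gene_id = genes$gene_id[ord[1]], distance = as.integer(d[ord[1]]))
}
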