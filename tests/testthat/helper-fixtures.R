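# Shared fixtures and independent brute-force oracles. Oracles are written
# as literal rule transcriptions, independent of the package's code paths.

rand_dna <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# small hand-built annotation: tx is a list of lists with fields
# id, gene, chrom, strand, exons (matrix/data.frame of start,end), biotype
tiny_ann <- function(tx, chrom_lengths = c(chr1 = 100000L, chr2 = 100000L)) {
  txdf <- do.call(rbind, lapply(tx, function(t)
    data.frame(transcript_id = t$id, gene_id = t$gene, chrom = t$chrom,
               strand = t$strand,
               biotype = if (is.null(t$biotype)) "coding" else t$biotype,
               stringsAsFactors = FALSE)))
  exdf <- do.call(rbind, lapply(tx, function(t)
    data.frame(transcript_id = t$id, start = t$exons[, 1], end = t$exons[, 2])))
  genome_annotation(chrom_lengths, txdf, exdf)
}

ex1 <- function(s, e) cbind(s, e)

# ---- independent oracles ----------------------------------------------------

# longest ORF by per-ATG forward scan to the first in-frame stop
oracle_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  if (n < 6L) return(best)
  for (f in 0:2) {
    i <- f + 1L
    while (i + 2L <= n) {
      if (substr(s, i, i + 2L) == "ATG") {
        j <- i
        while (j + 2L <= n) {
          cod <- substr(s, j, j + 2L)
          if (cod %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, j + 3L - i)
            break
          }
          j <- j + 3L
        }
      }
      i <- i + 3L
    }
  }
  best
}

# class code by literal rule transcription over all (query, reference) pairs
oracle_class_code <- function(q_exons, q_strand, q_chrom, reference,
                              window = 2000L) {
  sp <- tx_spans(reference)
  q_start <- min(q_exons[, 1]); q_end <- max(q_exons[, 2])
  chain_eq <- junction_shared <- antisense_exonic <- sense_exonic <- FALSE
  tandem <- FALSE
  q_j <- if (nrow(q_exons) > 1L)
    paste(q_exons[-nrow(q_exons), 2], q_exons[-1, 1]) else character(0)
  for (k in seq_len(nrow(sp))) {
    if (sp$chrom[k] != q_chrom) next
    rex <- reference$exons[reference$exons$transcript_id == sp$transcript_id[k], ]
    ov <- 0L
    for (a in seq_len(nrow(q_exons))) for (b in seq_len(nrow(rex)))
      ov <- ov + max(0L, min(q_exons[a, 2], rex$end[b]) -
                       max(q_exons[a, 1], rex$start[b]))
    if (sp$strand[k] == q_strand) {
      same_chain <- nrow(rex) == nrow(q_exons) &&
        all(rex$start == q_exons[, 1]) && all(rex$end == q_exons[, 2])
      if (same_chain) chain_eq <- TRUE
      r_j <- if (nrow(rex) > 1L)
        paste(rex$end[-nrow(rex)], rex$start[-1]) else character(0)
      if (!same_chain && length(intersect(q_j, r_j)) > 0L)
        junction_shared <- TRUE
      if (ov > 0L) sense_exonic <- TRUE
      d <- if (q_strand == "+") q_start - sp$end[k] else sp$start[k] - q_end
      if (d >= 0L && d <= window) tandem <- TRUE
    } else if (ov > 0L) {
      antisense_exonic <- TRUE
    }
  }
  genes <- gene_loci(reference)
  locus_ov <- any(genes$chrom == q_chrom & genes$start < q_end &
                    genes$end > q_start)
  if (chain_eq) return("=")
  if (junction_shared) return("J")
  if (antisense_exonic) return("X")
  if (!sense_exonic && tandem) return("P")
  if (!locus_ov) return("U")
  "other"
}

# slow, literal re-implementation of the TESTCODE tables for cross-checking
fickett_oracle <- function(seq) {
  pos_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
  pos_prob <- list(A = c(.51, .55, .57, .52, .48, .58, .57, .54, .50, .36),
                   C = c(.29, .44, .55, .49, .52, .60, .60, .56, .51, .33),
                   G = c(.62, .67, .74, .65, .61, .62, .52, .41, .31, .17),
                   T = c(.51, .60, .69, .64, .53, .54, .44, .31, .23, .14))
  pos_w <- c(A = .062, C = .093, G = .205, T = .154)
  con_para <- c(.33, .31, .29, .27, .25, .23, .21, .19, .17, 0)
  con_prob <- list(A = c(.40, .55, .58, .58, .52, .48, .45, .45, .38, .19),
                   C = c(.50, .63, .59, .50, .41, .30, .33, .29, .29, .36),
                   G = c(.21, .40, .47, .50, .52, .60, .57, .52, .42, .30),
                   T = c(.30, .49, .56, .75, .55, .40, .39, .24, .28, .24))
  con_w <- c(A = .084, C = .076, G = .081, T = .055)
  ch <- strsplit(toupper(seq), "")[[1]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- c(0, 0, 0)
    for (i in seq_along(ch)) if (ch[i] == b)
      cnt[(i - 1) %% 3 + 1] <- cnt[(i - 1) %% 3 + 1] + 1
    pv <- max(cnt) / (min(cnt) + 1)
    cv <- sum(cnt) / sum(ch %in% c("A", "C", "G", "T"))
    total <- total +
      pos_prob[[b]][which(pv >= pos_para)[1]] * pos_w[[b]] +
      con_prob[[b]][which(cv >= con_para)[1]] * con_w[[b]]
  }
  total
}

# KS statistic as an explicit sup over the pooled sample points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# a default synthetic dataset shared across test files (built once)
.fixture_env <- new.env(parent = emptyenv())
default_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- simulate_dataset(seed = 101L)
  .fixture_env$ds
}
default_discovery <- function() {
  if (is.null(.fixture_env$disc)) {
    ds <- default_dataset()
    .fixture_env$disc <- suppressWarnings(suppressMessages(run_discovery(list(
      genome = ds$genome, reference = ds$reference, assembled = ds$assembled,
      counts = ds$counts, samples = ds$samples, seed = 101L))))
  }
  .fixture_env$disc
}
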