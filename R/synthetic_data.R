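# Synthetic genomes, annotations, assembled transcripts, stage-wise count
# matrices, small-RNA reads and two-genotype experiments with planted ground
# truth, so that every downstream caller is testable without external data.
#
# All generators are seed-deterministic: they take an explicit seed and use
# only R's own RNG.

.BASES <- c("A", "C", "G", "T")

random_seq <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# rejection-sample a sequence whose sense-strand longest ORF stays short
.orf_poor_seq <- function(n, at = 0.55, max_orf = 150L, n_try = 500L) {
  for (i in seq_len(n_try)) {
    s <- random_seq(n, at)
    if (find_longest_orf(s)$length <= max_orf) return(s)
  }
  stop("could not sample an ORF-poor sequence of length ", n)
}

.NONSTOP_CODONS <- local({
  g <- expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE)[, 3:1]
  all3 <- do.call(paste0, g)
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

.random_cds <- function(n_codons, gc_bias = 0.35) {
  gc <- vapply(strsplit(.NONSTOP_CODONS, ""), function(ch)
    sum(ch %in% c("G", "C")), numeric(1))
  w <- exp(gc_bias * gc)
  body <- paste(sample(.NONSTOP_CODONS, n_codons, replace = TRUE,
                       prob = w / sum(w)), collapse = "")
  paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
}

# split a spliced sequence into exon/intron structure; returns the genomic
# (plus-orientation) sequence and exon offsets within it
.splice_structure <- function(spliced, max_exons = 5L) {
  len <- nchar(spliced)
  n_ex <- sample.int(min(max_exons, max(1L, len %/% 80L)), 1L)
  if (n_ex == 1L) {
    return(list(genomic = spliced,
                exons = data.frame(start = 0L, end = len)))
  }
  cuts <- sort(sample(seq.int(40L, len - 40L), n_ex - 1L))
  ex_start <- c(0L, cuts)
  ex_end <- c(cuts, len)
  introns <- vapply(seq_len(n_ex - 1L),
                    function(i) random_seq(sample(50:200, 1L), at = 0.55),
                    character(1))
  pieces <- character(0)
  offs <- integer(n_ex)
  pos <- 0L
  for (i in seq_len(n_ex)) {
    exon_seq <- substr(spliced, ex_start[i] + 1L, ex_end[i])
    offs[i] <- pos
    pieces <- c(pieces, exon_seq)
    pos <- pos + nchar(exon_seq)
    if (i < n_ex) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  list(genomic = paste(pieces, collapse = ""),
       exons = data.frame(start = offs, end = offs + (ex_end - ex_start)))
}

#' Simulate a compact multi-chromosome genome with stranded gene models
#'
#' Emulates a gene-dense fungal genome: genes with 1-5 exons on both
#' strands, coding transcripts carrying a planted ORF of at least 300 nt,
#' and intergenic gaps drawn from a short-gap distribution (median about
#' 1 kb). Noncoding reference genes are rejection-sampled so their
#' sense-strand ORF stays at or below 150 nt.
#'
#' @param seed RNG seed.
#' @param n_chrom number of chromosomes (default 4).
#' @param chrom_len chromosome length (bp, default 3e5).
#' @param n_genes total gene count (default 120).
#' @param noncoding_frac fraction of reference genes that are noncoding
#'   (default 0.08).
#' @return list with `genome` (named character), `annotation`
#'   ([genome_annotation()]; one transcript per gene) and `truth`
#'   (data.frame with per-transcript coding flag and planted ORF
#'   coordinates in spliced space).
#' @export
simulate_genome_and_annotation <- function(seed, n_chrom = 4L,
                                           chrom_len = 300000L,
                                           n_genes = 120L,
                                           noncoding_frac = 0.08) {
  set.seed(seed)
  per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1L)))
  genome <- character(n_chrom)
  names(genome) <- paste0("chr", seq_len(n_chrom))
  tx_rows <- list(); ex_rows <- list(); truth_rows <- list()
  gi <- 0L
  for (ci in seq_len(n_chrom)) {
    chrom <- names(genome)[ci]
    pieces <- character(0)
    pos <- 0L
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      gap_len <- max(200L, as.integer(round(stats::rlnorm(1, log(1000), 0.9))))
      coding <- stats::runif(1) > noncoding_frac
      if (coding) {
        n_cod <- sample(100:320, 1L)
        cds <- .random_cds(n_cod)
        utr5 <- random_seq(sample(20:120, 1L), at = 0.55)
        utr3 <- random_seq(sample(20:150, 1L), at = 0.55)
        spliced <- paste0(utr5, cds, utr3)
        orf_start <- nchar(utr5)
        orf_len <- nchar(cds)
      } else {
        spliced <- .orf_poor_seq(sample(300:900, 1L), at = 0.55)
        orf_start <- NA_integer_
        orf_len <- NA_integer_
      }
      st <- .splice_structure(spliced)
      glen <- nchar(st$genomic)
      if (pos + gap_len + glen > chrom_len - 200L)
        stop("infeasible packing: reduce n_genes or increase chrom_len")
      strand <- sample(c("+", "-"), 1L)
      seg <- if (strand == "+") st$genomic else revcomp(st$genomic)
      ex <- st$exons
      if (strand == "-") {
        ex <- data.frame(start = glen - rev(ex$end), end = glen - rev(ex$start))
      }
      gene_start <- pos + gap_len
      gid <- sprintf("g%04d", gi)
      tid <- sprintf("t%04d", gi)
      tx_rows[[gi]] <- data.frame(transcript_id = tid, gene_id = gid,
                                  chrom = chrom, strand = strand,
                                  biotype = if (coding) "coding" else "noncoding",
                                  stringsAsFactors = FALSE)
      ex_rows[[gi]] <- data.frame(transcript_id = tid,
                                  start = gene_start + ex$start,
                                  end = gene_start + ex$end)
      truth_rows[[gi]] <- data.frame(transcript_id = tid, gene_id = gid,
                                     coding = coding, orf_start = orf_start,
                                     orf_len = orf_len,
                                     spliced_length = nchar(spliced),
                                     stringsAsFactors = FALSE)
      pieces <- c(pieces, random_seq(gap_len, at = 0.60), seg)
      pos <- gene_start + glen
    }
    tail_len <- chrom_len - pos
    pieces <- c(pieces, random_seq(tail_len, at = 0.60))
    genome[ci] <- paste(pieces, collapse = "")
  }
  empty_tx <- data.frame(transcript_id = character(0), gene_id = character(0),
                         chrom = character(0), strand = character(0),
                         biotype = character(0))
  empty_ex <- data.frame(transcript_id = character(0), start = integer(0),
                         end = integer(0))
  ann <- genome_annotation(
    setNames(rep(chrom_len, n_chrom), names(genome)),
    if (length(tx_rows) > 0L) do.call(rbind, tx_rows) else empty_tx,
    if (length(ex_rows) > 0L) do.call(rbind, ex_rows) else empty_ex)
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               coding = logical(0), orf_start = integer(0),
               orf_len = integer(0), spliced_length = integer(0))
  list(genome = genome, annotation = ann, truth = truth)
}

.free_position <- function(genes, chrom_len, chrom, len, tandem_window,
                           margin = 25L, n_try = 4000L) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  for (i in seq_len(n_try)) {
    s <- sample.int(chrom_len - len - 1L, 1L)
    e <- s + len
    if (any(g$start - margin < e & g$end + margin > s)) next
    strand <- sample(c("+", "-"), 1L)
    # avoid the tandem window downstream of any same-strand gene (would be P)
    gs <- g[g$strand == strand, , drop = FALSE]
    d <- if (strand == "+") s - gs$end else gs$start - e
    if (any(d >= 0L & d <= tandem_window)) next
    return(list(start = s, end = e, strand = strand))
  }
  NULL
}

#' Simulate assembled transcripts of known novelty class
#'
#' Constructs transcripts per requested class against a reference from
#' [simulate_genome_and_annotation()]: `=` exact copies; `J` splice variants
#' sharing a junction; `P` same-strand transcripts within the tandem window
#' downstream of a gene; `U` transcripts in gene-free space; `X` transcripts
#' with exonic antisense overlap (> 100 bp) of a coding gene. Transcripts of
#' classes P, U and X are noncoding by construction (no ORF above 150 nt on
#' the transcript strand); a few short (< 200 nt) U transcripts exercise the
#' lncRNA length floor.
#'
#' @param sim output of [simulate_genome_and_annotation()].
#' @param seed RNG seed.
#' @param n_per_class named vector with names among `=, J, P, U, X`.
#' @param n_short_u number of additional sub-200-nt U transcripts.
#' @param tandem_window run-on window used both to plant P and to keep U
#'   clear of it (default 2000).
#' @return list with `annotation` (the assembled transcripts) and `truth`
#'   (data.frame: class, coding flag, `is_lnc` = novel noncoding > 200 nt).
#' @export
simulate_assembled_transcripts <- function(sim, seed,
                                           n_per_class = c("=" = 8L, J = 8L,
                                                           P = 6L, U = 16L,
                                                           X = 10L),
                                           n_short_u = 3L,
                                           tandem_window = 2000L) {
  set.seed(seed)
  ref <- sim$annotation
  genome <- sim$genome
  sp <- tx_spans(ref)
  genes <- gene_loci(ref)
  chrom_len <- ref$chrom_lengths
  tx_rows <- list(); ex_rows <- list(); truth_rows <- list()
  ai <- 0L
  add_tx <- function(chrom, strand, exons, class, coding, is_lnc) {
    ai <<- ai + 1L
    tid <- sprintf("a%04d", ai)
    tx_rows[[ai]] <<- data.frame(transcript_id = tid, gene_id = paste0("loc_", tid),
                                 chrom = chrom, strand = strand,
                                 biotype = "unknown", stringsAsFactors = FALSE)
    ex_rows[[ai]] <<- data.frame(transcript_id = tid, start = exons$start,
                                 end = exons$end)
    truth_rows[[ai]] <<- data.frame(transcript_id = tid, class = class,
                                    coding = coding, is_lnc = is_lnc,
                                    spliced_length = sum(exons$end - exons$start),
                                    stringsAsFactors = FALSE)
    tid
  }
  get <- function(nm) if (nm %in% names(n_per_class)) n_per_class[[nm]] else 0L

  coding_multi <- sp$transcript_id[sp$biotype == "coding" &
    sp$transcript_id %in% names(which(table(ref$exons$transcript_id) >= 2L))]
  # "=": exact copies of reference transcripts
  if (get("=") > 0L) {
    picks <- sample(sp$transcript_id, get("="))
    for (id in picks) {
      i <- match(id, sp$transcript_id)
      add_tx(sp$chrom[i], sp$strand[i], .tx_exons(ref, id), "=",
             sp$biotype[i] == "coding", FALSE)
    }
  }
  # J: keep the chain but extend the terminal exon by 60 bp
  if (get("J") > 0L) {
    if (length(coding_multi) < get("J"))
      stop("class counts infeasible: too few multi-exon coding references")
    picks <- sample(coding_multi, get("J"))
    for (id in picks) {
      i <- match(id, sp$transcript_id)
      ex <- .tx_exons(ref, id)
      if (sp$strand[i] == "+") {
        ex$end[nrow(ex)] <- min(ex$end[nrow(ex)] + 60L, chrom_len[[sp$chrom[i]]])
      } else {
        ex$start[1] <- max(ex$start[1] - 60L, 0L)
      }
      add_tx(sp$chrom[i], sp$strand[i], ex, "J", TRUE, FALSE)
    }
  }
  # P: mono-exon, same strand, within the tandem window downstream
  n_p <- get("P")
  placed <- 0L; tries <- 0L
  while (placed < n_p && tries < 5000L) {
    tries <- tries + 1L
    i <- sample(nrow(sp), 1L)
    len <- sample(250:700, 1L)
    d <- sample(50:1200, 1L)
    if (sp$strand[i] == "+") {
      s <- sp$end[i] + d; e <- s + len
    } else {
      e <- sp$start[i] - d; s <- e - len
    }
    if (s < 0L || e > chrom_len[[sp$chrom[i]]]) next
    g <- genes[genes$chrom == sp$chrom[i], , drop = FALSE]
    if (any(g$start - 25L < e & g$end + 25L > s)) next
    seqp <- substr(genome[[sp$chrom[i]]], s + 1L, e)
    if (sp$strand[i] == "-") seqp <- revcomp(seqp)
    if (find_longest_orf(seqp)$length > 150L) next
    add_tx(sp$chrom[i], sp$strand[i], data.frame(start = s, end = e),
           "P", FALSE, TRUE)
    placed <- placed + 1L
  }
  if (placed < n_p) stop("class counts infeasible: could not place P transcripts")
  # U: gene-free space, outside every tandem window, noncoding sequence
  n_u <- get("U") + n_short_u
  for (k in seq_len(n_u)) {
    len <- if (k <= get("U")) sample(300:1100, 1L) else sample(130:190, 1L)
    fp <- NULL
    for (tr in 1:200) {
      chrom <- sample(names(chrom_len), 1L)
      fp <- .free_position(genes, chrom_len[[chrom]], chrom, len, tandem_window)
      if (is.null(fp)) next
      sequ <- substr(genome[[chrom]], fp$start + 1L, fp$end)
      if (fp$strand == "-") sequ <- revcomp(sequ)
      if (find_longest_orf(sequ)$length <= 150L) break
      fp <- NULL
    }
    if (is.null(fp)) stop("class counts infeasible: could not place U transcripts")
    add_tx(chrom, fp$strand, data.frame(start = fp$start, end = fp$end),
           "U", FALSE, len > 200L)
  }
  # X: mono-exon antisense to a coding exon, overlap > 100 bp, noncoding
  n_x <- get("X")
  placed <- 0L; tries <- 0L
  coding_ids <- sp$transcript_id[sp$biotype == "coding"]
  while (placed < n_x && tries < 5000L) {
    tries <- tries + 1L
    id <- sample(coding_ids, 1L)
    i <- match(id, sp$transcript_id)
    ex <- .tx_exons(ref, id)
    j <- sample(nrow(ex), 1L)
    if (ex$end[j] - ex$start[j] < 160L) next
    ov <- sample(150:min(400L, ex$end[j] - ex$start[j]), 1L)
    len <- sample(max(300L, ov):700L, 1L)
    anchor <- sample(ex$start[j]:(ex$end[j] - ov), 1L)
    s <- anchor; e <- min(s + len, chrom_len[[sp$chrom[i]]])
    if (e - s < 200L) next
    strand <- if (sp$strand[i] == "+") "-" else "+"
    tmp_ann <- genome_annotation(chrom_len,
      data.frame(transcript_id = "tmp", gene_id = "tmp", chrom = sp$chrom[i],
                 strand = strand, biotype = "unknown"),
      data.frame(transcript_id = "tmp", start = s, end = e))
    seqx <- transcript_seq(tmp_ann, genome, "tmp")
    if (find_longest_orf(seqx)$length > 150L) next
    # must not equal a reference chain nor share a junction (mono-exon: safe)
    add_tx(sp$chrom[i], strand, data.frame(start = s, end = e), "X",
           FALSE, TRUE)
    placed <- placed + 1L
  }
  if (placed < n_x) stop("class counts infeasible: could not place X transcripts")
  ann <- genome_annotation(chrom_len, do.call(rbind, tx_rows),
                           do.call(rbind, ex_rows))
  list(annotation = ann, truth = do.call(rbind, truth_rows))
}

#' Merge two annotations (union with identical-chain collapse)
#'
#' @param a,b [genome_annotation()] objects over the same chromosomes.
#' @return merged annotation; transcripts of `b` whose exon chain duplicates
#'   one in `a` (same chromosome and strand) are dropped.
#' @export
merge_annotations <- function(a, b) {
  chain <- function(ann) {
    sp <- tx_spans(ann)
    vapply(sp$transcript_id, function(id) {
      ex <- .tx_exons(ann, id)
      paste(sp$chrom[match(id, sp$transcript_id)],
            sp$strand[match(id, sp$transcript_id)],
            paste(ex$start, ex$end, sep = ":", collapse = ";"))
    }, character(1))
  }
  ca <- chain(a); cb <- chain(b)
  keep <- !(cb %in% ca)
  tx_b <- b$transcripts[keep, , drop = FALSE]
  ex_b <- b$exons[b$exons$transcript_id %in% tx_b$transcript_id, , drop = FALSE]
  lens <- a$chrom_lengths
  for (nm in names(b$chrom_lengths))
    lens[nm] <- max(lens[nm], b$chrom_lengths[nm], na.rm = TRUE)
  genome_annotation(lens, rbind(a$transcripts, tx_b), rbind(a$exons, ex_b))
}

.ARCHETYPES <- c("peak_S0", "peak_S1", "peak_S2", "peak_S3", "peak_S4",
                 "peak_S5", "late_induction")

.profile_of <- function(archetype, fold, n_stage = 6L) {
  if (archetype == "late_induction") {
    half <- n_stage %/% 2L
    return(c(rep(1, half), rep(fold / 2, n_stage - half - 1L), fold))
  }
  prof <- rep(1, n_stage)
  prof[as.integer(sub("peak_S", "", archetype)) + 1L] <- fold
  prof
}

#' Simulate stage-wise counts with planted expression archetypes
#'
#' Negative-binomial counts across developmental stages x replicates. Each
#' planted lncRNA follows one of 7 stage-profile archetypes (peaks at each
#' of the 6 stages plus a monotone ramp); a configurable fraction (default
#' 0.40) peaks at the meiotic stage S4. Reference/coding transcripts are
#' mostly flat with a minority of mildly stage-biased profiles.
#'
#' @param annotation merged [genome_annotation()] whose transcripts are the
#'   count rows.
#' @param lnc_ids transcript ids planted as lncRNAs (stage-specific).
#' @param seed RNG seed.
#' @param stages stage labels (default S0..S5).
#' @param reps replicates per stage (default 3).
#' @param dispersion NB dispersion (size = 1/dispersion; default 0.1;
#'   values below 1e-8 give Poisson counts).
#' @param lib_factors per-sample library-size factors (default: mild
#'   lognormal variation).
#' @param s4_frac fraction of lncRNAs peaking at S4 (default 0.40).
#' @param lnc_fold peak fold of the planted lncRNA archetypes (default 8).
#' @return list with `counts` (integer matrix), `samples` (data.frame:
#'   sample, stage, replicate) and `profiles` (per-transcript archetype,
#'   fold and expected peak stage).
#' @export
simulate_stage_counts <- function(annotation, lnc_ids, seed,
                                  stages = paste0("S", 0:5), reps = 3L,
                                  dispersion = 0.1, lib_factors = NULL,
                                  s4_frac = 0.40, lnc_fold = 8) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  set.seed(seed)
  sp <- tx_spans(annotation)
  n_tx <- nrow(sp)
  n_stage <- length(stages)
  n_smp <- n_stage * reps
  samples <- data.frame(
    sample = paste0(rep(stages, each = reps), "_r", rep(seq_len(reps), n_stage)),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), n_stage), stringsAsFactors = FALSE)
  if (is.null(lib_factors)) lib_factors <- exp(stats::rnorm(n_smp, 0, 0.15))
  is_lnc <- sp$transcript_id %in% lnc_ids
  arch <- character(n_tx)
  fold <- numeric(n_tx)
  n_lnc <- sum(is_lnc)
  lnc_arch <- character(n_lnc)
  n_s4 <- round(s4_frac * n_lnc)
  lnc_arch[seq_len(n_s4)] <- "peak_S4"
  others <- setdiff(.ARCHETYPES, "peak_S4")
  if (n_lnc > n_s4)
    lnc_arch[(n_s4 + 1L):n_lnc] <- sample(others, n_lnc - n_s4, replace = TRUE)
  arch[is_lnc] <- sample(lnc_arch)   # shuffle assignment across lncRNAs
  fold[is_lnc] <- lnc_fold
  mrna_de <- stats::runif(n_tx) < 0.35 & !is_lnc
  arch[!is_lnc & !mrna_de] <- "flat"
  arch[mrna_de] <- sample(.ARCHETYPES, sum(mrna_de), replace = TRUE)
  fold[mrna_de] <- stats::runif(sum(mrna_de), 1.5, 4)
  base <- ifelse(is_lnc, pmax(stats::rlnorm(n_tx, log(90), 0.4), 60),
                 stats::rlnorm(n_tx, log(220), 0.7))
  mu <- matrix(0, n_tx, n_smp,
               dimnames = list(sp$transcript_id, samples$sample))
  for (t in seq_len(n_tx)) {
    prof <- if (arch[t] == "flat") rep(1, n_stage)
            else .profile_of(arch[t], fold[t], n_stage)
    mu[t, ] <- base[t] * (sp$spliced_length[t] / 1000) *
      prof[match(samples$stage, stages)] * lib_factors
  }
  counts <- if (dispersion < 1e-8) {
    matrix(rpois(length(mu), lambda = mu), nrow = n_tx)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow = n_tx)
  }
  dimnames(counts) <- dimnames(mu)
  peak <- vapply(seq_len(n_tx), function(t) {
    if (arch[t] == "flat") NA_character_
    else stages[which.max(.profile_of(arch[t], fold[t], n_stage))]
  }, character(1))
  list(counts = counts, samples = samples,
       profiles = data.frame(transcript_id = sp$transcript_id,
                             archetype = arch, fold = fold,
                             peak_stage = peak, stringsAsFactors = FALSE))
}

#' Simulate small-RNA read alignments with planted clusters
#'
#' Plants dense piles of 17-27 nt reads in cluster windows (post-filter
#' per-base depth at least three times the default `mincov` of 20) with a
#' stated fraction of 5'-U reads, plus Poisson-scattered background reads
#' (including some out-of-range lengths) that stay below the calling
#' threshold.
#'
#' @param sim output of [simulate_genome_and_annotation()].
#' @param seed RNG seed.
#' @param n_clusters planted clusters (default 12).
#' @param background_rate background reads per bp (default 2e-5).
#' @param u_frac planted fraction of 5'-U reads (default 0.76, the midpoint
#'   of the 70-82% range typical of fungal small RNAs).
#' @param cluster_width planted window width (bp, default 250).
#' @param reads_per_cluster reads per planted window (default 1500).
#' @return list with `reads` (BED6-style data.frame) and `planted`
#'   (data.frame of planted cluster intervals).
#' @export
simulate_srna_reads <- function(sim, seed, n_clusters = 12L,
                                background_rate = 2e-5, u_frac = 0.76,
                                cluster_width = 250L,
                                reads_per_cluster = 1500L) {
  set.seed(seed)
  genome <- sim$genome
  chrom_len <- nchar(genome)
  chroms <- names(genome)
  # non-overlapping windows, at least 2 kb apart
  planted <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
  tries <- 0L
  while (nrow(planted) < n_clusters && tries < 5000L) {
    tries <- tries + 1L
    chr <- sample(chroms, 1L)
    s <- sample.int(chrom_len[[chr]] - cluster_width - 100L, 1L)
    near <- planted$chrom == chr & abs(planted$start - s) < cluster_width + 2000L
    if (any(near)) next
    planted <- rbind(planted, data.frame(chrom = chr, start = s,
                                         end = s + cluster_width))
  }
  if (nrow(planted) < n_clusters) stop("could not place sRNA clusters")
  planted <- planted[order(planted$chrom, planted$start), ]
  rownames(planted) <- NULL
  rows <- list(); ri <- 0L
  emit <- function(chr, s, e, strand) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(chrom = chr, start = s, end = e,
                              name = sprintf("r%06d", ri), score = "0",
                              strand = strand, stringsAsFactors = FALSE)
  }
  reads_per_cluster <- as.integer(reads_per_cluster)
  for (w in seq_len(nrow(planted))) {
    chr <- planted$chrom[w]
    ws <- planted$start[w]; we <- planted$end[w]
    seqw <- substr(genome[[chr]], ws + 1L, we)
    chw <- strsplit(seqw, "", fixed = TRUE)[[1]]
    for (j in seq_len(reads_per_cluster)) {
      len <- sample(17:27, 1L)
      strand <- sample(c("+", "-"), 1L)
      lim <- cluster_width - len
      cand <- seq_len(lim)            # offsets 0..lim-1 (1-based index)
      if (strand == "+") {
        uposs <- cand[chw[cand] == "T"]
      } else {
        uposs <- cand[chw[cand + len - 1L] == "A"]
      }
      want_u <- stats::runif(1) < u_frac
      pool <- if (want_u) uposs else setdiff(cand, uposs)
      if (length(pool) == 0L) pool <- cand
      off <- pool[sample.int(length(pool), 1L)] - 1L
      emit(chr, ws + off, ws + off + len, strand)
    }
  }
  n_bg <- rpois(1, sum(chrom_len) * background_rate)
  for (j in seq_len(n_bg)) {
    chr <- sample(chroms, 1L, prob = chrom_len / sum(chrom_len))
    len <- if (stats::runif(1) < 0.8) sample(17:27, 1L)
           else sample(c(14:16, 28:31), 1L)
    s <- sample.int(chrom_len[[chr]] - len, 1L)
    emit(chr, s, s + len, sample(c("+", "-"), 1L))
  }
  reads <- do.call(rbind, rows)
  rownames(reads) <- NULL
  list(reads = reads, planted = planted)
}

#' Simulate a WT versus exonuclease-deletion (xrn1) experiment
#'
#' Two-genotype count matrices at two stages with planted Xrn1-sensitive
#' unstable transcripts (XUTs). Only XUTs change in true abundance (by their
#' planted fold); the confounding global scale shift (`rp_shift`) is planted
#' in the reported mapped-library sizes of the mutant samples, so that every
#' non-XUT transcript -- including the ribosomal-protein housekeeping set
#' that absorbs the shift during normalization -- shows a naive
#' RPKM fold of about `rp_shift`, while XUTs show `rp_shift` times their
#' planted fold. Decoy transcripts with XUT-like folds but mutant abundance
#' below the 3.0 RPKM floor are also planted.
#'
#' @param seed RNG seed.
#' @param n_transcripts total transcripts (default 1500).
#' @param n_xut planted XUTs (default 100).
#' @param n_rp ribosomal-protein housekeeping genes (default 124).
#' @param n_decoy low-abundance decoys (default 10).
#' @param fold_range planted XUT fold range (default c(4, 8); a lower bound
#'   below 3 warns that planted XUTs may be undetectable by design).
#' @param rp_shift global mutant scale shift, scalar or one value per stage
#'   (default 2).
#' @param dispersion NB dispersion (default 0.1).
#' @param rp_dispersion NB dispersion of the RP housekeeping genes (default
#'   0.02): their low biological variance is the property that qualifies
#'   them as normalization anchors.
#' @param reps replicates per genotype and stage (default 3).
#' @param stages stage labels (default S0, S4).
#' @param lib_size target library size (default 3e6).
#' @param depth expected counts per expression unit per kb (default 4).
#' @param unmapped_factor reported library sizes exceed the in-annotation
#'   read total by this factor (default 1.25).
#' @return list with `wt_counts`, `mut_counts`, `wt_lib_sizes`,
#'   `mut_lib_sizes`, `col_stages`, `lengths`, `rp_ids`, `truth` (id,
#'   is_xut, fold, is_decoy) and the applied `rp_shift` (one value per
#'   stage).
#' @export
simulate_xrn1_experiment <- function(seed, n_transcripts = 1500L,
                                     n_xut = 100L, n_rp = 124L,
                                     n_decoy = 10L, fold_range = c(4, 8),
                                     rp_shift = 2, dispersion = 0.1,
                                     rp_dispersion = 0.02, reps = 3L,
                                     stages = c("S0", "S4"),
                                     depth = 4, unmapped_factor = 1.25) {
  if (fold_range[1] < 3)
    warning("fold_range lower bound < 3: planted XUTs may be undetectable")
  set.seed(seed)
  ids <- sprintf("x%04d", seq_len(n_transcripts))
  lens <- sample(400:3000, n_transcripts, replace = TRUE)
  roles <- rep("bg", n_transcripts)
  pick <- sample.int(n_transcripts, n_rp + n_xut + n_decoy)
  roles[pick[seq_len(n_rp)]] <- "rp"
  roles[pick[n_rp + seq_len(n_xut)]] <- "xut"
  roles[pick[n_rp + n_xut + seq_len(n_decoy)]] <- "decoy"
  shift <- rep_len(rp_shift, length(stages))
  base <- stats::rlnorm(n_transcripts, log(30), 1)
  base[roles == "rp"] <- stats::rlnorm(n_rp, log(80), 0.3)
  base[roles == "xut"] <- pmax(stats::rlnorm(n_xut, log(2.5), 0.4), 1)
  base[roles == "decoy"] <- stats::runif(n_decoy, 0.01, 0.035)
  fold <- rep(1, n_transcripts)
  fold[roles == "xut"] <- stats::runif(n_xut, fold_range[1], fold_range[2])
  fold[roles == "decoy"] <- stats::runif(n_decoy, 4, 6)
  stage_mod <- matrix(stats::rlnorm(n_transcripts * length(stages), 0, 0.2),
                      n_transcripts)
  cols <- paste0(rep(stages, each = reps), "_r",
                 rep(seq_len(reps), length(stages)))
  draw <- function(expr_mat, lib_shift) {
    out <- matrix(0L, n_transcripts, length(cols), dimnames = list(ids, cols))
    libs <- numeric(length(cols))
    disp <- ifelse(roles == "rp", rp_dispersion, dispersion)
    for (si in seq_along(stages)) for (r in seq_len(reps)) {
      mu <- expr_mat[, si] * lens / 1000 * depth * exp(stats::rnorm(1, 0, 0.08))
      cnt <- ifelse(disp < 1e-8, rpois(n_transcripts, mu),
                    rnbinom(n_transcripts, mu = mu,
                            size = 1 / pmax(disp, 1e-8)))
      j <- (si - 1L) * reps + r
      out[, j] <- cnt
      # the reported mapped-library size carries the global shift: mutant
      # libraries are under-reported by the per-stage shift, so every
      # unchanged transcript appears rp_shift-fold up in naive RPKM
      libs[j] <- sum(cnt) * unmapped_factor / lib_shift[si]
    }
    list(counts = out, libs = setNames(libs, cols))
  }
  wt_expr <- base * stage_mod
  mut_expr <- wt_expr * fold
  wt <- draw(wt_expr, rep(1, length(stages)))
  mut <- draw(mut_expr, shift)
  list(wt_counts = wt$counts, mut_counts = mut$counts,
       wt_lib_sizes = wt$libs, mut_lib_sizes = mut$libs,
       col_stages = rep(stages, each = reps),
       lengths = setNames(lens, ids),
       rp_ids = ids[roles == "rp"],
       truth = data.frame(transcript_id = ids, is_xut = roles == "xut",
                          fold = fold, is_decoy = roles == "decoy",
                          stringsAsFactors = FALSE),
       rp_shift = setNames(shift, stages))
}

#' Generate and write a full synthetic dataset
#'
#' Drives every generator from one configuration (a YAML file path or a
#' list) and writes FASTA/GTF/BED/TSV files plus truth sidecars, all
#' byte-deterministic for a given seed.
#'
#' @param config list (or YAML path) overriding generator defaults; honored
#'   keys: `n_chrom`, `chrom_len`, `n_genes`, `n_per_class`, `dispersion`,
#'   `s4_frac`, `lnc_fold`, `n_clusters`, `u_frac`.
#' @param outdir output directory (created); `NULL` skips writing.
#' @param seed RNG seed.
#' @return list with all simulated objects (and `paths` when written).
#' @export
simulate_dataset <- function(config = list(), outdir = NULL, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(n_chrom = 4L, chrom_len = 300000L, n_genes = 120L,
                         n_per_class = c("=" = 8L, J = 8L, P = 6L, U = 16L,
                                         X = 10L),
                         dispersion = 0.1, s4_frac = 0.40, lnc_fold = 8,
                         n_clusters = 12L, u_frac = 0.76), config)
  sim <- simulate_genome_and_annotation(seed, cfg$n_chrom, cfg$chrom_len,
                                        cfg$n_genes)
  asm <- simulate_assembled_transcripts(sim, seed + 1L,
                                        n_per_class = cfg$n_per_class)
  merged <- merge_annotations(sim$annotation, asm$annotation)
  lnc_ids <- asm$truth$transcript_id[asm$truth$is_lnc]
  cnt <- simulate_stage_counts(merged, lnc_ids, seed + 2L,
                               dispersion = cfg$dispersion,
                               s4_frac = cfg$s4_frac,
                               lnc_fold = cfg$lnc_fold)
  srna <- simulate_srna_reads(sim, seed + 3L, n_clusters = cfg$n_clusters,
                              u_frac = cfg$u_frac)
  res <- list(genome = sim$genome, reference = sim$annotation,
              reference_truth = sim$truth, assembled = asm$annotation,
              assembled_truth = asm$truth, merged = merged,
              counts = cnt$counts, samples = cnt$samples,
              profiles = cnt$profiles, srna_reads = srna$reads,
              srna_planted = srna$planted)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_fasta(sim$genome, p("genome.fa"))
    write_gtf(sim$annotation, p("reference.gtf"))
    write_gtf(asm$annotation, p("assembled.gtf"))
    wt <- function(x, f) write.table(x, p(f), sep = "\t", quote = FALSE,
                                     row.names = FALSE)
    write.table(data.frame(transcript_id = rownames(cnt$counts),
                           cnt$counts, check.names = FALSE),
                p("counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(cnt$samples, "samples.tsv")
    write_bed(srna$reads, p("srna_reads.bed"))
    wt(asm$truth, "truth_assembled.tsv")
    wt(sim$truth, "truth_reference.tsv")
    wt(cnt$profiles, "truth_profiles.tsv")
    wt(srna$planted, "truth_srna_clusters.tsv")
    res$paths <- vapply(c("genome.fa", "reference.gtf", "assembled.gtf",
                          "counts.tsv", "samples.tsv", "srna_reads.bed"),
                        p, character(1))
  }
  res
}
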