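# End-to-end orchestration: the discovery funnel (novel -> noncoding -> DE
# -> lncRNA typing) and the characterization reports.

.load_maybe <- function(x, loader) if (is.character(x) && length(x) == 1L) loader(x) else x

.read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

# sample intergenic fragments (gene-free on both strands) from the genome
.intergenic_fragments <- function(genome, annotation, n, frag_len = 500L) {
  genes <- gene_loci(annotation)
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < n * 50L) {
    tries <- tries + 1L
    chr <- sample(names(genome), 1L)
    lim <- nchar(genome[[chr]]) - frag_len
    if (lim < 1L) next
    s <- sample.int(lim, 1L)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (any(g$start < s + frag_len & g$end > s)) next
    out <- c(out, substr(genome[[chr]], s + 1L, s + frag_len))
  }
  out
}

#' Train a coding-potential model from a reference annotation
#'
#' The coding corpus is the spliced sequence of every coding reference
#' transcript; the noncoding corpus combines first-order Markov
#' (dinucleotide-preserving) resamples of those sequences with intergenic
#' fragments. The decision threshold follows the two-graph ROC on the
#' training scores, reproducing the protocol that set the original
#' species-specific cutoff.
#'
#' @param genome named character vector of chromosome sequences.
#' @param reference reference [genome_annotation()].
#' @param seed RNG seed (corpus sampling).
#' @return a `coding_potential_model`.
#' @export
train_reference_model <- function(genome, reference, seed = 1L) {
  set.seed(seed)
  sp <- tx_spans(reference)
  cod_ids <- sp$transcript_id[sp$biotype == "coding"]
  coding_seqs <- vapply(cod_ids, function(id)
    transcript_seq(reference, genome, id), character(1))
  shuffled <- vapply(coding_seqs, markov_resample, character(1))
  n_inter <- max(10L, length(coding_seqs) %/% 2L)
  inter <- .intergenic_fragments(genome, reference, n_inter)
  fit_coding_model(coding_seqs, c(shuffled, inter), calibrate = "training")
}

#' Run the lncRNA discovery funnel
#'
#' Executes, in order: class-code assignment, restriction to the novel
#' classes J/P/U/X, the >200 nt length floor, the coding-potential filter
#' (score <= threshold is noncoding), optional Pfam/Rfam hit removal
#' (E < 1e-10), the expression filter (CPM > 1 in >= 3 samples),
#' differential expression in at least one successive-stage comparison, and
#' ancRNA/lincRNA typing. Deterministic given config and seed.
#'
#' @param config list (or YAML path) with elements `genome`, `reference`,
#'   `assembled`, `counts`, `samples` (objects or file paths),
#'   optional `pfam_hits`, optional `model` (a pre-trained
#'   `coding_potential_model`), and parameter overrides `tandem_window`
#'   (2000), `min_len` (200), `threshold` (NULL = trained), `cpm_min` (1),
#'   `min_samples` (3), `de_fdr` (0.05), `de_fc` (1), `evalue_max` (1e-10),
#'   `seed` (1), `outdir` (NULL).
#' @return object of class `funnel_report`: the per-class funnel counts,
#'   the final lncRNA table (type, peak stage), the class codes, the model
#'   and the DE table.
#' @export
run_discovery <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(tandem_window = 2000L, min_len = 200L, threshold = NULL,
                   cpm_min = 1, min_samples = 3L, de_fdr = 0.05, de_fc = 1,
                   evalue_max = 1e-10, seed = 1L, outdir = NULL,
                   pfam_hits = NULL, model = NULL)
  cfg <- modifyList(defaults, config)
  for (f in c("genome", "reference", "assembled", "counts", "samples"))
    if (is.null(cfg[[f]])) stop("config is missing the required field: ", f)
  genome <- .load_maybe(cfg$genome, read_fasta)
  reference <- .load_maybe(cfg$reference, read_gtf)
  assembled <- .load_maybe(cfg$assembled, read_gtf)
  counts <- if (is.character(cfg$counts)) .read_counts_tsv(cfg$counts) else cfg$counts
  samples <- .load_maybe(cfg$samples, function(p)
    read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  pfam <- .load_maybe(cfg$pfam_hits, function(p)
    read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE))

  log <- list()
  note <- function(step, n) {
    log[[length(log) + 1L]] <<- data.frame(step = step, n = n)
    message(sprintf("[funnel] %-28s %d", step, n))
  }
  codes <- assign_class_codes(assembled, reference, cfg$tandem_window)
  sp_a <- tx_spans(assembled)
  note("assembled transcripts", length(codes))
  novel <- names(codes)[codes %in% c("J", "P", "U", "X")]
  note("novel (J/P/U/X)", length(novel))
  lens <- setNames(sp_a$spliced_length, sp_a$transcript_id)
  long <- novel[lens[novel] > cfg$min_len]
  note(sprintf("length > %d nt", cfg$min_len), length(long))

  model <- cfg$model
  if (is.null(model)) model <- train_reference_model(genome, reference, cfg$seed)
  thr <- if (!is.null(cfg$threshold)) cfg$threshold else model$threshold
  scores <- if (length(long) > 0L)
    coding_probability(vapply(long, function(id)
      transcript_seq(assembled, genome, id), character(1)), model)
  else numeric(0)
  names(scores) <- long
  noncod <- long[scores <= thr]
  note(sprintf("coding score <= %.3f", thr), length(noncod))
  noncod <- filter_domain_hits(noncod, pfam, cfg$evalue_max)
  note("no Pfam/Rfam hit", length(noncod))

  factors <- tmm_factors(counts)
  expressed_all <- filter_expressed(counts, factors, cfg$cpm_min, cfg$min_samples)
  expressed <- intersect(noncod, expressed_all)
  note(sprintf("CPM > %g in >= %d samples", cfg$cpm_min, cfg$min_samples),
       length(expressed))

  stages <- unique(samples$stage)
  de_tabs <- list()
  for (i in seq_len(length(stages) - 1L)) {
    a <- which(samples$stage == stages[i])
    b <- which(samples$stage == stages[i + 1L])
    de_tabs[[i]] <- de_test(counts, a, b, fc_threshold = cfg$de_fc,
                            fdr = cfg$de_fdr, factors = factors,
                            comparison = paste0(stages[i], "-vs-", stages[i + 1L]))
  }
  de_all <- do.call(rbind, de_tabs)
  de_ids <- unique(de_all$transcript_id[de_all$de])
  final <- intersect(expressed, de_ids)
  note(sprintf("DE in >= 1 stage (FDR %g)", cfg$de_fdr), length(final))

  type <- if (length(final) > 0L)
    classify_lncrna_type(final, assembled, reference) else
    setNames(character(0), character(0))
  rpkm <- rpkm_matrix(counts, lens[rownames(counts)], factors)
  sm <- stage_means(rpkm, samples$stage)
  peak <- if (length(final) > 0L) peak_stage(sm[final, , drop = FALSE])
          else character(0)
  lncrnas <- data.frame(transcript_id = final,
                        class = unname(codes[final]),
                        type = unname(type),
                        coding_probability = unname(scores[final]),
                        spliced_length = unname(lens[final]),
                        peak_stage = peak, stringsAsFactors = FALSE)

  classes <- c("J", "P", "U", "X")
  funnel <- data.frame(
    class = classes,
    n_novel = vapply(classes, function(k) sum(codes[long] == k), integer(1)),
    n_noncoding = vapply(classes, function(k) sum(codes[noncod] == k), integer(1)),
    n_de = vapply(classes, function(k) sum(codes[final] == k), integer(1)),
    stringsAsFactors = FALSE)
  funnel <- rbind(funnel,
                  data.frame(class = "total", n_novel = sum(funnel$n_novel),
                             n_noncoding = sum(funnel$n_noncoding),
                             n_de = sum(funnel$n_de)))
  res <- structure(list(funnel = funnel, lncrnas = lncrnas,
                        class_codes = codes, scores = scores,
                        model = model, threshold = thr, de = de_all,
                        tmm_factors = factors,
                        log = do.call(rbind, log)),
                   class = "funnel_report")
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(funnel, file.path(cfg$outdir, "funnel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(lncrnas, file.path(cfg$outdir, "lncrnas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(lncrnas) > 0L) {
      keep_tx <- assembled$transcripts$transcript_id %in% lncrnas$transcript_id
      lnc_ann <- genome_annotation(
        assembled$chrom_lengths,
        assembled$transcripts[keep_tx, , drop = FALSE],
        assembled$exons[assembled$exons$transcript_id %in%
                          lncrnas$transcript_id, , drop = FALSE])
      write_gtf(lnc_ann, file.path(cfg$outdir, "lncrnas.gtf"))
    }
  }
  res
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("lncRNA discovery funnel\n")
  print(x$funnel, row.names = FALSE)
  cat("final lncRNAs:", nrow(x$lncrnas),
      sprintf("(%d ancRNA, %d lincRNA)\n",
              sum(x$lncrnas$type == "ancRNA"),
              sum(x$lncrnas$type == "lincRNA")))
  invisible(x)
}

#' Characterize a discovered lncRNA set
#'
#' Computes the descriptive reports around a discovery run: peak-stage
#' distribution of lncRNAs versus DE mRNAs, stage-specificity (max/mean)
#' ratios with a KS comparison, A/U content by feature class, coexpression
#' modules of the lncRNAs, sense-antisense pair correlations and
#' neighbor-context correlation summaries.
#'
#' @param discovery a `funnel_report` from [run_discovery()].
#' @param genome,reference,assembled the inputs used for discovery.
#' @param counts,samples the expression inputs used for discovery.
#' @param treecut module cut height (default 0.18).
#' @param power soft-threshold power for modules; `NULL` picks the lowest
#'   power reaching a 0.80 scale-free fit.
#' @param outdir optional output directory for TSV reports.
#' @return list of report tables.
#' @export
run_characterization <- function(discovery, genome, reference, assembled,
                                 counts, samples, treecut = 0.18,
                                 power = NULL, outdir = NULL) {
  lnc <- discovery$lncrnas
  sp_a <- tx_spans(assembled)
  lens_all <- c(setNames(sp_a$spliced_length, sp_a$transcript_id),
                with(tx_spans(reference),
                     setNames(spliced_length, transcript_id)))
  rpkm <- rpkm_matrix(counts, lens_all[rownames(counts)],
                      discovery$tmm_factors)
  sm <- stage_means(rpkm, samples$stage)
  # DE mRNAs: reference coding transcripts DE in >= 1 successive comparison
  ref_cod <- tx_spans(reference)
  ref_cod <- ref_cod$transcript_id[ref_cod$biotype == "coding"]
  de_ids <- unique(discovery$de$transcript_id[discovery$de$de])
  de_mrna <- intersect(ref_cod, de_ids)

  reports <- list()
  if (nrow(lnc) > 0L) {
    reports$peak_stage <- data.frame(
      stage = colnames(sm),
      lncRNA = as.integer(table(factor(lnc$peak_stage, colnames(sm)))),
      mRNA = as.integer(table(factor(peak_stage(sm[de_mrna, , drop = FALSE]),
                                     colnames(sm)))))
    mmr <- function(ids) {
      v <- apply(sm[ids, , drop = FALSE], 1L, max_mean_ratio)
      v[is.finite(v)]
    }
    r_l <- mmr(lnc$transcript_id); r_m <- mmr(de_mrna)
    ks <- if (length(r_l) > 0L && length(r_m) > 0L) ks_compare(r_l, r_m)
          else list(D = NA_real_, p = NA_real_)
    reports$stage_specificity <- list(lncRNA_ratios = r_l, mRNA_ratios = r_m,
                                      ks = ks)
    # A/U content by feature class
    au_of <- function(seqs) vapply(seqs, au_content, numeric(1))
    cds_seqs <- utr5_seqs <- utr3_seqs <- character(0)
    for (id in ref_cod) {
      s <- transcript_seq(reference, genome, id)
      orf <- find_longest_orf(s)
      if (orf$length >= 300L) {
        cds_seqs <- c(cds_seqs, substr(s, orf$start + 1L, orf$end))
        if (orf$start >= 30L) utr5_seqs <- c(utr5_seqs, substr(s, 1L, orf$start))
        if (nchar(s) - orf$end >= 30L)
          utr3_seqs <- c(utr3_seqs, substr(s, orf$end + 1L, nchar(s)))
      }
    }
    inter <- .intergenic_fragments(genome, reference, 50L)
    lnc_seq <- vapply(lnc$transcript_id, function(id)
      transcript_seq(assembled, genome, id), character(1))
    reports$au_content <- list(
      CDS = au_of(cds_seqs), UTR5 = au_of(utr5_seqs), UTR3 = au_of(utr3_seqs),
      intergenic = au_of(inter),
      lincRNA = au_of(lnc_seq[lnc$type == "lincRNA"]),
      ancRNA = au_of(lnc_seq[lnc$type == "ancRNA"]))
    # coexpression modules of the lncRNAs
    if (nrow(lnc) >= 3L) {
      expr <- sm[lnc$transcript_id, , drop = FALSE]
      if (is.null(power)) {
        power <- tryCatch(
          suppressWarnings(pick_soft_threshold(expr)$power), error = function(e) 1L)
      }
      reports$modules <- cluster_coexpression(expr, power = power,
                                              treecut = treecut)
      reports$modules$power <- power
    }
    # sense-antisense pairs and their expression correlation
    anc <- lnc$transcript_id[lnc$type == "ancRNA"]
    pairs <- pair_sense_antisense(anc, assembled, reference)
    if (nrow(pairs) > 0L) {
      cor_rows <- lapply(seq_len(nrow(pairs)), function(i) {
        a <- rpkm[pairs$mrna_id[i], ]; b <- rpkm[pairs$ancrna_id[i], ]
        pp <- tryCatch(pearson_with_p(a, b),
                       error = function(e) list(r = NA, p = NA, correlated = FALSE))
        data.frame(r = pp$r, p = pp$p, correlated = pp$correlated)
      })
      pairs <- cbind(pairs, do.call(rbind, cor_rows))
    }
    reports$pairs <- pairs
    # neighbor context correlations
    ctx <- do.call(rbind, lapply(lnc$transcript_id, neighbor_context,
                                 assembled = assembled, reference = reference))
    if (!is.null(ctx) && nrow(ctx) > 0L) {
      ref_sp <- tx_spans(reference)
      g2t <- setNames(ref_sp$transcript_id, ref_sp$gene_id)
      ctx$r <- vapply(seq_len(nrow(ctx)), function(i) {
        tid <- g2t[[ctx$gene_id[i]]]
        if (is.null(tid) || !(tid %in% rownames(rpkm))) return(NA_real_)
        tryCatch(pearson_with_p(rpkm[ctx$lnc_id[i], ], rpkm[tid, ])$r,
                 error = function(e) NA_real_)
      }, numeric(1))
    }
    reports$neighbor_context <- ctx
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("peak_stage", "pairs", "neighbor_context")) {
      if (!is.null(reports[[nm]]) && is.data.frame(reports[[nm]]))
        write.table(reports[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  reports
}
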