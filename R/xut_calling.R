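# Xrn1-sensitive unstable transcript (XUT) calling: housekeeping
# (ribosomal-protein) normalization, fold/FDR/abundance gates, reference
# assignment and coding classification.

#' Ribosomal-protein normalization factor
#'
#' The factor by which WT expression values are multiplied so that the
#' housekeeping ribosomal-protein (RP) genes are expressed at the same level
#' in both genotypes: the median over RP genes of mutant/WT mean RPKM,
#' computed per stage. RP genes with zero WT expression are excluded.
#'
#' @param wt_rpkm,mut_rpkm per-transcript mean RPKM vectors (named) for one
#'   stage.
#' @param rp_ids ids of the RP gene set.
#' @return scalar normalization factor.
#' @export
rp_normalization_factor <- function(wt_rpkm, mut_rpkm, rp_ids) {
  if (length(rp_ids) == 0L) stop("rp_ids must be non-empty")
  rp <- intersect(rp_ids, names(wt_rpkm))
  w <- wt_rpkm[rp]; m <- mut_rpkm[rp]
  ok <- w > 0
  if (!any(ok)) stop("all RP genes have zero WT expression")
  median(m[ok] / w[ok])
}

#' Call Xrn1-sensitive unstable transcripts
#'
#' Per stage, WT RPKM is multiplied by the RP normalization factor, a
#' moderated test on log2(RPKM + 0.5) compares mutant and normalized WT
#' replicates, and transcripts are kept when the mutant-over-WT normalized
#' fold exceeds `fold_min` (one-directional), the BH-adjusted q is below
#' `fdr` and mutant mean RPKM is at least `rpkm_floor`. The result is the
#' union over stages with per-stage provenance.
#'
#' @param wt_counts,mut_counts count matrices (transcripts x samples),
#'   columns grouped by stage.
#' @param col_stages stage label per column (same layout for both
#'   genotypes); >= 2 replicates per genotype and stage.
#' @param lengths transcript lengths (nt), named.
#' @param rp_ids housekeeping gene ids.
#' @param fold_min minimum mutant/WT fold, strict (default 3).
#' @param fdr BH q cutoff (default 0.05).
#' @param rpkm_floor minimum mutant mean RPKM (default 3.0).
#' @param factors optional named per-stage normalization factors overriding
#'   the RP-derived estimate (e.g. `c(S0 = 1)` to disable normalization).
#' @param wt_lib_sizes,mut_lib_sizes optional per-sample mapped-library
#'   sizes for the RPKM views (column sums when absent).
#' @return list with `xuts` (data.frame: transcript_id, stage, fold, q,
#'   mut_rpkm, one row per transcript and calling stage) and `factors`
#'   (per-stage RP factors used).
#' @export
call_xuts <- function(wt_counts, mut_counts, col_stages, lengths, rp_ids,
                      fold_min = 3, fdr = 0.05, rpkm_floor = 3.0,
                      factors = NULL, wt_lib_sizes = NULL,
                      mut_lib_sizes = NULL) {
  stages <- unique(col_stages)
  wt_rpkm <- rpkm_matrix(wt_counts, lengths, lib_sizes = wt_lib_sizes)
  mut_rpkm <- rpkm_matrix(mut_counts, lengths, lib_sizes = mut_lib_sizes)
  out <- list()
  used <- numeric(0)
  for (s in stages) {
    cols <- which(col_stages == s)
    if (length(cols) < 2L) {
      warning("stage ", s, " has < 2 replicates; skipped")
      next
    }
    wms <- rowMeans(wt_rpkm[, cols, drop = FALSE])
    mms <- rowMeans(mut_rpkm[, cols, drop = FALSE])
    f <- if (!is.null(factors) && s %in% names(factors)) factors[[s]]
         else rp_normalization_factor(setNames(wms, rownames(wt_rpkm)),
                                      setNames(mms, rownames(mut_rpkm)),
                                      rp_ids)
    used[s] <- f
    lmat <- cbind(log2(wt_rpkm[, cols, drop = FALSE] * f + 0.5),
                  log2(mut_rpkm[, cols, drop = FALSE] + 0.5))
    mt <- moderated_t_test(lmat, seq_along(cols),
                           length(cols) + seq_along(cols))
    q <- p.adjust(mt$p, method = "BH")
    fold <- mms / (wms * f)
    keep <- is.finite(fold) & fold > fold_min & q < fdr & mms >= rpkm_floor
    if (any(keep)) {
      out[[s]] <- data.frame(transcript_id = rownames(wt_counts)[keep],
                             stage = s, fold = fold[keep], q = q[keep],
                             mut_rpkm = mms[keep], stringsAsFactors = FALSE,
                             row.names = NULL)
    }
  }
  xuts <- if (length(out) > 0L) do.call(rbind, out)
          else data.frame(transcript_id = character(0), stage = character(0),
                          fold = numeric(0), q = numeric(0),
                          mut_rpkm = numeric(0))
  rownames(xuts) <- NULL
  list(xuts = xuts, factors = used)
}

#' Assign a XUT to its same-strand reference transcript
#'
#' The reference transcript whose exonic same-strand overlap covers strictly
#' more than half of the XUT's exonic length; ties resolved by larger
#' overlap, then leftmost reference.
#'
#' @param xut_id transcript id in `annotation`.
#' @param annotation [genome_annotation()] containing the XUT.
#' @param reference reference [genome_annotation()].
#' @param min_frac required covered fraction of the XUT's exonic length,
#'   strict (default 0.5).
#' @return list with `transcript_id` and `gene_id` of the assignment (both
#'   `NA` when no reference transcript qualifies).
#' @export
assign_xut_to_reference <- function(xut_id, annotation, reference,
                                    min_frac = 0.5) {
  sp <- tx_spans(annotation)
  qi <- sp[sp$transcript_id == xut_id, ]
  ex_q <- .tx_exons(annotation, xut_id)
  qlen <- sum(ex_q$end - ex_q$start)
  ref_sp <- tx_spans(reference)
  cand <- which(ref_sp$chrom == qi$chrom & ref_sp$strand == qi$strand &
                  ref_sp$start < qi$end & ref_sp$end > qi$start)
  if (length(cand) == 0L)
    return(list(transcript_id = NA_character_, gene_id = NA_character_))
  ov <- vapply(cand, function(r)
    exonic_overlap_bp(ex_q, .tx_exons(reference, ref_sp$transcript_id[r])),
    integer(1))
  ok <- ov > min_frac * qlen
  if (!any(ok))
    return(list(transcript_id = NA_character_, gene_id = NA_character_))
  cand <- cand[ok]; ov <- ov[ok]
  best <- order(-ov, ref_sp$start[cand])[1]
  list(transcript_id = ref_sp$transcript_id[cand[best]],
       gene_id = ref_sp$gene_id[cand[best]])
}

#' Classify a XUT as coding or noncoding, and flag lncRNA identity
#'
#' @param xut_seq spliced sequence of the XUT.
#' @param model a fitted `coding_potential_model`.
#' @param xut_id,annotation,lnc_ann optional: when given, the lncRNA flag is
#'   set iff the XUT matches a transcript of `lnc_ann` on the same strand
#'   with exonic overlap exceeding half the shorter transcript.
#' @return list with `coding_probability`, `is_noncoding` (probability <=
#'   model threshold) and `is_lncRNA`.
#' @export
classify_xut_coding <- function(xut_seq, model, xut_id = NULL,
                                annotation = NULL, lnc_ann = NULL) {
  p <- coding_probability(xut_seq, model)
  is_lnc <- FALSE
  if (!is.null(xut_id) && !is.null(lnc_ann) && !is.null(annotation) &&
      nrow(lnc_ann$transcripts) > 0L) {
    sp <- tx_spans(annotation)
    qi <- sp[sp$transcript_id == xut_id, ]
    ex_q <- .tx_exons(annotation, xut_id)
    qlen <- sum(ex_q$end - ex_q$start)
    lsp <- tx_spans(lnc_ann)
    cand <- which(lsp$chrom == qi$chrom & lsp$strand == qi$strand &
                    lsp$start < qi$end & lsp$end > qi$start)
    for (r in cand) {
      ex_l <- .tx_exons(lnc_ann, lsp$transcript_id[r])
      ov <- exonic_overlap_bp(ex_q, ex_l)
      shorter <- min(qlen, sum(ex_l$end - ex_l$start))
      if (ov > 0.5 * shorter) { is_lnc <- TRUE; break }
    }
  }
  list(coding_probability = p, is_noncoding = p <= model$threshold,
       is_lncRNA = is_lnc)
}
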