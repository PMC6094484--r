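# Normalization (TMM effective library sizes, CPM/RPKM), moderated
# differential expression, stage-specificity statistics, correlation
# screening and coexpression modules with soft thresholding.

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization (30% two-sided trim
#' on M, 5% on A; genes with a zero in either sample excluded; factors
#' rescaled to geometric mean 1). The reference sample defaults to the one
#' whose upper quartile is closest to the mean upper quartile. Computed by
#' edgeR's TMM implementation.
#'
#' @param counts non-negative integer matrix (transcripts x samples).
#' @param reference_sample optional column index or name of the reference.
#' @return numeric vector of factors, one per sample (geometric mean 1).
#' @export
tmm_factors <- function(counts, reference_sample = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  if (is.character(reference_sample))
    reference_sample <- match(reference_sample, colnames(counts))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              refColumn = reference_sample)
  setNames(as.numeric(f), colnames(counts))
}

#' Counts per million on effective library sizes
#'
#' @param counts counts matrix.
#' @param factors TMM factors (default 1); effective library size is the raw
#'   library size times the factor.
#' @param lib_sizes optional per-sample mapped-library sizes overriding the
#'   column sums (e.g. total mapped reads including unannotated regions).
#' @return CPM matrix.
#' @export
cpm_matrix <- function(counts, factors = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  eff <- lib_sizes * factors
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Reads per kilobase per million on effective library sizes
#'
#' @param counts counts matrix.
#' @param lengths transcript lengths (nt), recycled along rows by name when
#'   named.
#' @param factors TMM factors (default 1).
#' @param lib_sizes optional explicit mapped-library sizes.
#' @return RPKM matrix.
#' @export
rpkm_matrix <- function(counts, lengths, factors = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  cpm_matrix(counts, factors, lib_sizes) / (as.numeric(lengths) / 1000)
}

#' Expression filter: CPM > 1 in at least `min_samples` samples
#'
#' @param counts counts matrix.
#' @param factors optional TMM factors used for the CPM view.
#' @param cpm_min CPM threshold, strict (default 1).
#' @param min_samples minimum number of samples above the threshold
#'   (default 3).
#' @return character vector of retained row names.
#' @export
filter_expressed <- function(counts, factors = NULL, cpm_min = 1,
                             min_samples = 3L) {
  cpm <- cpm_matrix(counts, factors)
  keep <- rowSums(cpm > cpm_min) >= min_samples
  rownames(counts)[keep]
}

# ---- moderated t ------------------------------------------------------------

.trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Empirical-Bayes variance shrinkage: fit a scaled inverse-chi-square prior
# to the per-gene sample variances (df residual degrees of freedom) by
# moment matching on the log scale, and return posterior variances and the
# prior df.
squeeze_variances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(var_post = s2, df_prior = 0, var_prior = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df_prior * s02 + df * s2) / (df_prior + df)
  } else {
    df_prior <- Inf
    s02 <- exp(mean(e))
    var_post <- rep(s02, length(s2))
  }
  list(var_post = var_post, df_prior = df_prior, var_prior = s02)
}

#' Row-wise moderated two-sample t-test
#'
#' Ordinary per-row two-sample t statistics on a matrix of (log-scale)
#' values, with the per-row pooled variances shrunk toward a common prior
#' fitted across rows (scaled inverse-chi-square, moment-matched), after
#' Smyth's empirical-Bayes scheme.
#'
#' @param mat numeric matrix (features x samples).
#' @param cols_a,cols_b column indices (or names) of the two groups, each of
#'   size >= 2.
#' @return data.frame with `diff` (mean B - mean A), `t`, `df`, `p`.
#' @export
moderated_t_test <- function(mat, cols_a, cols_b) {
  a <- mat[, cols_a, drop = FALSE]
  b <- mat[, cols_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 replicates")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2); vb <- rowSums((b - mb)^2)
  df <- na + nb - 2L
  s2 <- (va + vb) / df
  sq <- squeeze_variances(s2, df)
  df_total <- df + sq$df_prior
  se <- sqrt(sq$var_post * (1 / na + 1 / nb))
  tt <- (mb - ma) / se
  p <- 2 * pt(-abs(tt), df = df_total)
  data.frame(diff = mb - ma, t = tt, df = df_total, p = p,
             row.names = rownames(mat))
}

#' Differential expression between two sample groups
#'
#' Moderated two-sample test on log2(CPM + 0.5) (effective library sizes via
#' TMM factors), Benjamini-Hochberg adjustment across transcripts, and a
#' conjunctive call: DE iff q < `fdr` and |log2FC| > log2(`fc_threshold`).
#'
#' @param counts counts matrix over all samples used for normalization.
#' @param cols_a,cols_b columns of the two groups (>= 2 replicates each).
#' @param fc_threshold fold-change gate (default 4; use 1 to disable).
#' @param fdr BH-adjusted q-value cutoff (default 0.05).
#' @param factors optional TMM factors (computed from `counts` when NULL).
#' @param comparison label stored in the result.
#' @return data.frame with `transcript_id`, `log2fc`, `p`, `q`, `de`,
#'   `comparison`.
#' @export
de_test <- function(counts, cols_a, cols_b, fc_threshold = 4, fdr = 0.05,
                    factors = NULL, comparison = "A-vs-B") {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  lcpm <- log2(cpm_matrix(counts, factors) + 0.5)
  mt <- moderated_t_test(lcpm, cols_a, cols_b)
  q <- p.adjust(mt$p, method = "BH")
  de <- q < fdr & abs(mt$diff) > log2(fc_threshold)
  data.frame(transcript_id = rownames(counts), log2fc = mt$diff, p = mt$p,
             q = q, de = de, comparison = comparison,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stage-specificity ratio: max over mean of the remaining stages
#'
#' @param stage_means numeric vector of 6 non-negative stage means.
#' @return max / mean(other five); `Inf` when the other five are all zero
#'   and the max is positive; `NA` (excluded) for an all-zero profile.
#' @export
max_mean_ratio <- function(stage_means) {
  if (length(stage_means) != 6L) stop("expected 6 stage means")
  if (any(stage_means < 0)) stop("negative stage mean")
  if (all(stage_means == 0)) return(NA_real_)
  i <- which.max(stage_means)
  rest <- mean(stage_means[-i])
  if (rest == 0) return(Inf)
  stage_means[i] / rest
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param values_a,values_b numeric samples (non-empty).
#' @return list with `D` (sup |ECDF difference|) and asymptotic `p`.
#' @export
ks_compare <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) stop("empty input")
  kt <- suppressWarnings(ks.test(values_a, values_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Pearson correlation with Fisher z-transformation p-value
#'
#' @param x,y numeric vectors (length >= 3, non-constant).
#' @param r_threshold,p_threshold a pair is flagged `correlated` iff
#'   |r| > `r_threshold` (default 0.7) and p < `p_threshold` (default 0.05).
#' @return list with `r`, `p`, `correlated`.
#' @export
pearson_with_p <- function(x, y, r_threshold = 0.7, p_threshold = 0.05) {
  n <- length(x)
  if (n < 3L || n != length(y)) stop("need two equal-length vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  r <- cor(x, y)
  if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    p <- 2 * pnorm(-abs(z) * sqrt(n - 3))
  } else {
    p <- if (abs(r) >= 1) 0 else 1
  }
  list(r = r, p = p, correlated = abs(r) > r_threshold && p < p_threshold)
}

# signed scale-free topology fit index of a connectivity vector
scale_free_fit <- function(k, nbreaks = 10L) {
  k <- k[is.finite(k)]
  if (length(k) < 2L || max(k) == min(k)) return(NA_real_)
  cuts <- cut(k, breaks = nbreaks)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = nbreaks) / length(k)
  ok <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(ok) < 2L) return(NA_real_)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Choose the soft-thresholding power for a coexpression network
#'
#' For each candidate power the unsigned adjacency |cor|^power is formed,
#' per-node connectivity computed, and the scale-free topology fit index
#' (sign-corrected R^2 of log10 p(k) on log10 k over connectivity bins)
#' evaluated; the lowest power whose fit reaches `target_fit` is returned.
#' When no power reaches the target, the power with maximal fit is returned
#' with a warning.
#'
#' @param expr numeric matrix (transcripts x conditions) of expression
#'   values; correlations are computed between transcript rows.
#' @param powers ascending candidate powers (default 1:30).
#' @param target_fit fit index target (default 0.80).
#' @param nbreaks connectivity bins (default 10).
#' @return list with `power`, `fit` (per-power fit indices) and
#'   `connectivity` (mean connectivity per power).
#' @export
pick_soft_threshold <- function(expr, powers = 1:30, target_fit = 0.80,
                                nbreaks = 10L) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("need >= 2 transcripts")
  cc <- abs(cor(t(expr)))
  diag(cc) <- 0
  fits <- numeric(length(powers))
  kbar <- numeric(length(powers))
  for (i in seq_along(powers)) {
    a <- cc^powers[i]
    k <- rowSums(a)
    fits[i] <- scale_free_fit(k, nbreaks)
    kbar[i] <- mean(k)
  }
  ok <- which(!is.na(fits) & fits >= target_fit)
  if (length(ok) > 0L) {
    power <- powers[ok[1]]
  } else {
    warning("no candidate power reaches the target fit index; ",
            "returning the power with maximal fit")
    power <- powers[which.max(ifelse(is.na(fits), -Inf, fits))]
  }
  list(power = power, fit = setNames(fits, powers),
       connectivity = setNames(kbar, powers))
}

#' Detect coexpression modules by average-linkage clustering
#'
#' Transcripts are clustered on the dissimilarity 1 - |cor|^power by
#' average-linkage hierarchical clustering; the dendrogram is cut at the
#' static height `treecut`. Singleton clusters are labeled 0 (unassigned).
#'
#' @param expr numeric matrix (transcripts x conditions).
#' @param power soft-thresholding power (from [pick_soft_threshold()] or
#'   user-set).
#' @param treecut static cut height on the dissimilarity scale
#'   (default 0.18).
#' @return list with `modules` (named integer vector; 0 = unassigned),
#'   `n_modules`, and `profiles` (Z-score normalized mean expression of each
#'   module across the columns of `expr`).
#' @export
cluster_coexpression <- function(expr, power = 1, treecut = 0.18) {
  expr <- as.matrix(expr)
  n <- nrow(expr)
  if (n < 3L) stop("need >= 3 transcripts")
  d <- 1 - abs(cor(t(expr)))^power
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, h = treecut)
  sizes <- table(cl)
  singleton <- as.integer(names(sizes)[sizes == 1L])
  modules <- ifelse(cl %in% singleton, 0L, cl)
  # relabel non-singleton modules 1..m by decreasing size
  keep <- sort(unique(modules[modules != 0L]))
  if (length(keep) > 0L) {
    ord <- keep[order(-as.integer(table(factor(modules, levels = keep))))]
    modules <- ifelse(modules == 0L, 0L, match(modules, ord))
  }
  modules <- setNames(as.integer(modules), rownames(expr))
  profiles <- NULL
  if (any(modules != 0L)) {
    prof <- t(vapply(sort(unique(modules[modules != 0L])), function(m)
      colMeans(expr[modules == m, , drop = FALSE]), numeric(ncol(expr))))
    profiles <- t(apply(prof, 1L, function(z)
      if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0))
    rownames(profiles) <- paste0("module_", sort(unique(modules[modules != 0L])))
    colnames(profiles) <- colnames(expr)
  }
  list(modules = modules, n_modules = length(unique(modules[modules != 0L])),
       profiles = profiles)
}

#' Per-stage mean expression
#'
#' @param values matrix (transcripts x samples).
#' @param stages factor/character of stage labels, one per column.
#' @return matrix transcripts x stages of arithmetic means over replicates.
#' @export
stage_means <- function(values, stages) {
  stages <- as.character(stages)
  lev <- unique(stages)
  out <- vapply(lev, function(s)
    rowMeans(values[, stages == s, drop = FALSE]), numeric(nrow(values)))
  colnames(out) <- lev
  out
}

#' Stage of peak expression per transcript
#'
#' @param sm stage-means matrix from [stage_means()].
#' @return character vector of peak stage labels (ties -> earliest stage).
#' @export
peak_stage <- function(sm) {
  colnames(sm)[apply(sm, 1L, which.max)]
}
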