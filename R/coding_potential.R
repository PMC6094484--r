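# Coding-potential model: longest ORF + Fickett TESTCODE + hexamer usage bias
# combined by logistic regression, with a two-graph ROC decision threshold.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame on the sense strand
#'
#' Scans all three forward frames for ATG..stop spans (stop codon included);
#' the reverse strand is not searched because transcripts are strand-resolved
#' by stranded RNA-seq.
#'
#' @param seq nucleotide sequence over \{A,C,G,T,N\} (case-insensitive).
#' @return list with `length` (nt, 0 if no ORF), `start` (0-based), `end`
#'   (0-based exclusive, includes the stop codon) and `frame` (0..2).
#' @export
find_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- list(length = 0L, start = NA_integer_, end = NA_integer_,
               frame = NA_integer_)
  if (n < 6L) return(best)
  for (f in 0:2) {
    starts <- seq.int(f + 1L, by = 3L, length.out = (n - f) %/% 3L)
    if (length(starts) < 2L) next
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% .STOP_CODONS)
    if (length(atg) == 0L || length(stp) == 0L) next
    nxt <- findInterval(atg, stp) + 1L     # first stop strictly after each ATG
    ok <- nxt <= length(stp)
    if (!any(ok)) next
    len <- (stp[nxt[ok]] - atg[ok] + 1L) * 3L
    i <- which.max(len)
    if (len[i] > best$length) {
      a <- atg[ok][i]; e <- stp[nxt[ok][i]]
      best <- list(length = len[i], start = starts[a] - 1L,
                   end = starts[e] + 2L, frame = f)
    }
  }
  best
}

# Fickett (1982) TESTCODE lookup tables as used by coding-potential scoring:
# position/content parameters are converted to probabilities through the
# published intervals and combined with the published weights.
.FICKETT_POS_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
.FICKETT_POS_PROB <- list(
  A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
  C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.33),
  G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.52, 0.41, 0.31, 0.17),
  T = c(0.51, 0.60, 0.69, 0.64, 0.53, 0.54, 0.44, 0.31, 0.23, 0.14))
.FICKETT_POS_WEIGHT <- c(A = 0.062, C = 0.093, G = 0.205, T = 0.154)
.FICKETT_CONT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
.FICKETT_CONT_PROB <- list(
  A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
  C = c(0.50, 0.63, 0.59, 0.50, 0.41, 0.30, 0.33, 0.29, 0.29, 0.36),
  G = c(0.21, 0.40, 0.47, 0.50, 0.52, 0.60, 0.57, 0.52, 0.42, 0.30),
  T = c(0.30, 0.49, 0.56, 0.75, 0.55, 0.40, 0.39, 0.24, 0.28, 0.24))
.FICKETT_CONT_WEIGHT <- c(A = 0.084, C = 0.076, G = 0.081, T = 0.055)

.fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1]]
}

#' Fickett TESTCODE statistic
#'
#' For each base the position parameter is the maximum count over the three
#' codon phases divided by (minimum count + 1) and the content parameter is
#' the base frequency; both are mapped through the published lookup tables
#' and combined with the published weights. Deterministic; higher values are
#' more coding-like (range approximately 0.26 to 1.62).
#'
#' @param seq nucleotide sequence, length >= 6 nt.
#' @return numeric scalar.
#' @export
fickett_score <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 6L) stop("fickett_score requires >= 6 nt")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  phase <- (seq_len(n) - 1L) %% 3L
  score <- 0
  total <- sum(ch %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(phase[ch == b] + 1L, nbins = 3L)
    posval <- max(cnt) / (min(cnt) + 1)
    contval <- if (total > 0) sum(cnt) / total else 0
    score <- score +
      .fickett_lookup(posval, .FICKETT_POS_PARA, .FICKETT_POS_PROB[[b]]) *
        .FICKETT_POS_WEIGHT[[b]] +
      .fickett_lookup(contval, .FICKETT_CONT_PARA, .FICKETT_CONT_PROB[[b]]) *
        .FICKETT_CONT_WEIGHT[[b]]
  }
  unname(score)
}

.ALL_HEXAMERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
})

.count_hexamers <- function(seqs, step) {
  counts <- setNames(numeric(4096L), .ALL_HEXAMERS)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, n - 5L, by = step)
    hx <- substring(s, starts, starts + 5L)
    hx <- hx[!grepl("N", hx, fixed = TRUE)]
    if (length(hx) == 0L) next
    tb <- table(hx)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  counts
}

#' Build a hexamer log-ratio table
#'
#' Step-3 hexamer frequencies from a coding CDS corpus (in frame, since CDS
#' start frame 0) against step-3 frequencies from a noncoding corpus (whose
#' frame is arbitrary). Both corpora are counted identically, so identical
#' corpora give an all-zero table. Counts are pseudocount-smoothed before
#' normalization, so every entry is finite.
#'
#' @param coding_seqs character vector of coding (CDS) sequences.
#' @param noncoding_seqs character vector of noncoding sequences.
#' @param pseudocount added to every hexamer count before normalization.
#' @return named numeric vector of 4096 values
#'   `log(F_coding(h) / F_noncoding(h))`.
#' @export
build_hexamer_table <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L)
    stop("both corpora must be non-empty")
  cc <- .count_hexamers(coding_seqs, step = 3L) + pseudocount
  nc <- .count_hexamers(noncoding_seqs, step = 3L) + pseudocount
  log((cc / sum(cc)) / (nc / sum(nc)))
}

#' Hexamer usage-bias score of a sequence
#'
#' Mean hexamer log-ratio over the in-frame (step 3) hexamers of the longest
#' ORF; when the sequence has no ORF, frame 0 of the full sequence is used.
#'
#' @param seq nucleotide sequence, length >= 6 nt.
#' @param table hexamer table from [build_hexamer_table()].
#' @return numeric scalar (0 when no hexamer is scorable).
#' @export
hexamer_score <- function(seq, table) {
  s <- toupper(seq)
  if (nchar(s) < 6L) stop("hexamer_score requires >= 6 nt")
  orf <- find_longest_orf(s)
  region <- if (orf$length > 0L) substr(s, orf$start + 1L, orf$end) else s
  n <- nchar(region)
  if (n < 6L) region <- s
  n <- nchar(region)
  starts <- seq.int(1L, n - 5L, by = 3L)
  hx <- substring(region, starts, starts + 5L)
  hx <- hx[!grepl("N", hx, fixed = TRUE)]
  if (length(hx) == 0L) return(0)
  mean(table[hx])
}

#' A/U content of a sequence
#'
#' @param seq nucleotide sequence (non-empty). `N` bases are excluded from
#'   the denominator.
#' @return fraction of A+T among A/C/G/T bases.
#' @export
au_content <- function(seq) {
  s <- toupper(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  denom <- sum(ch %in% c("A", "C", "G", "T"))
  if (denom == 0L) stop("sequence has no A/C/G/T base")
  sum(ch %in% c("A", "T")) / denom
}

.base_features <- function(seqs) {
  orf_len <- vapply(seqs, function(s) find_longest_orf(s)$length, integer(1))
  fick <- vapply(seqs, fickett_score, numeric(1))
  cbind(orf = log10(orf_len + 1), fickett = unname(fick))
}

.coding_features <- function(seqs, hexamer_table, base = NULL) {
  if (is.null(base)) base <- .base_features(seqs)
  hex <- vapply(seqs, hexamer_score, numeric(1), table = hexamer_table)
  cbind(base, hexamer = unname(hex))
}

.orf_region <- function(s) {
  orf <- find_longest_orf(s)
  if (orf$length > 0L) substr(toupper(s), orf$start + 1L, orf$end)
  else toupper(s)
}

# table + logistic fit without the corpus-size precondition (used both for
# the final model and for the cross-fitting folds)
.fit_core <- function(coding_seqs, noncoding_seqs, pseudocount, base = NULL) {
  cds <- vapply(coding_seqs, .orf_region, character(1))
  tab <- build_hexamer_table(cds, noncoding_seqs, pseudocount)
  seqs <- c(coding_seqs, noncoding_seqs)
  y <- rep(c(1L, 0L), c(length(coding_seqs), length(noncoding_seqs)))
  x <- .coding_features(seqs, tab, base)
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  separated <- !fit$converged || any(!is.finite(beta)) ||
    max(abs(beta[-1]), na.rm = TRUE) > 50
  if (separated) {
    warning("perfect separation detected; using ridge-penalized fit")
    rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = TRUE)
    beta <- c(as.numeric(rf$a0), as.numeric(rf$beta))
  }
  beta <- setNames(as.numeric(beta), c("b0", "b_orf", "b_fickett", "b_hexamer"))
  list(beta = beta, table = tab,
       scores = as.numeric(stats::plogis(beta[1] + x %*% beta[-1])))
}

#' Fit a coding-potential model
#'
#' Logistic regression of the coding label on three sequence features:
#' log10(longest ORF length + 1), Fickett TESTCODE score and hexamer
#' usage-bias score. The hexamer table is built from the longest-ORF regions
#' of the coding corpus (in frame) against the noncoding corpus. The
#' decision threshold is selected by the two-graph ROC rule
#' ([select_threshold()]); by default it is calibrated on cross-fitted
#' (out-of-fold) scores, because in-sample scores of the coding corpus are
#' inflated by the hexamer table having been counted from those very
#' sequences. The fit is deterministic; under perfect separation a
#' ridge-penalized fit is used with a warning.
#'
#' @param coding_seqs,noncoding_seqs training corpora (>= 50 sequences each).
#' @param pseudocount hexamer pseudocount.
#' @param calibrate `"cv"` (default) selects the threshold on out-of-fold
#'   scores; `"training"` uses in-sample scores.
#' @param folds cross-fitting folds (default 4; assigned round-robin, so the
#'   fit is deterministic).
#' @return object of class `coding_potential_model` with elements
#'   `coefficients` (b0..b3), `hexamer_table`, `threshold` and
#'   `training_scores`.
#' @export
fit_coding_model <- function(coding_seqs, noncoding_seqs, pseudocount = 1,
                             calibrate = c("cv", "training"), folds = 4L) {
  calibrate <- match.arg(calibrate)
  if (length(coding_seqs) < 50L || length(noncoding_seqs) < 50L)
    stop("need >= 50 sequences per class")
  base_c <- .base_features(coding_seqs)
  base_n <- .base_features(noncoding_seqs)
  core <- .fit_core(coding_seqs, noncoding_seqs, pseudocount,
                    base = rbind(base_c, base_n))
  y <- rep(c(TRUE, FALSE), c(length(coding_seqs), length(noncoding_seqs)))
  if (calibrate == "cv") {
    fc <- (seq_along(coding_seqs) - 1L) %% folds + 1L
    fn <- (seq_along(noncoding_seqs) - 1L) %% folds + 1L
    oof_c <- numeric(length(coding_seqs))
    oof_n <- numeric(length(noncoding_seqs))
    for (k in seq_len(folds)) {
      fold_core <- .fit_core(coding_seqs[fc != k], noncoding_seqs[fn != k],
                             pseudocount,
                             base = rbind(base_c[fc != k, , drop = FALSE],
                                          base_n[fn != k, , drop = FALSE]))
      score_of <- function(seqs, base) {
        x <- .coding_features(seqs, fold_core$table, base)
        b <- fold_core$beta
        as.numeric(stats::plogis(b[1] + x %*% b[-1]))
      }
      oof_c[fc == k] <- score_of(coding_seqs[fc == k],
                                 base_c[fc == k, , drop = FALSE])
      oof_n[fn == k] <- score_of(noncoding_seqs[fn == k],
                                 base_n[fn == k, , drop = FALSE])
    }
    thr <- select_threshold(c(oof_c, oof_n), y)
  } else {
    thr <- select_threshold(core$scores, y)
  }
  structure(list(coefficients = core$beta, hexamer_table = core$table,
                 threshold = thr,
                 training_scores = data.frame(score = core$scores, coding = y)),
            class = "coding_potential_model")
}

#' Coding probability of sequences under a fitted model
#'
#' @param seq character vector of nucleotide sequences.
#' @param model a `coding_potential_model`.
#' @return numeric vector of probabilities in \[0, 1\]; a sequence is called
#'   noncoding iff its probability is <= `model$threshold`.
#' @export
coding_probability <- function(seq, model) {
  x <- .coding_features(toupper(seq), model$hexamer_table)
  b <- model$coefficients
  unname(as.numeric(stats::plogis(b[1] + x %*% b[-1])))
}

#' @export
predict.coding_potential_model <- function(object, newdata,
                                           type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- coding_probability(newdata, object)
  if (type == "prob") p
  else ifelse(p <= object$threshold, "noncoding", "coding")
}

#' @export
coef.coding_potential_model <- function(object, ...) object$coefficients

#' @export
print.coding_potential_model <- function(x, ...) {
  cat("coding_potential_model\n")
  cat("  logit(p) =", sprintf("%.4g", x$coefficients[1]), "+",
      sprintf("%.4g*log10(ORF+1)", x$coefficients[2]), "+",
      sprintf("%.4g*Fickett", x$coefficients[3]), "+",
      sprintf("%.4g*Hexamer", x$coefficients[4]), "\n")
  cat("  noncoding decision: p <=", sprintf("%.3f", x$threshold), "\n")
  invisible(x)
}

#' @export
summary.coding_potential_model <- function(object, ...) {
  ts <- object$training_scores
  pred_nc <- ts$score <= object$threshold
  cat("coding_potential_model trained on", sum(ts$coding), "coding /",
      sum(!ts$coding), "noncoding sequences\n")
  cat("  threshold:", sprintf("%.3f", object$threshold), "\n")
  cat("  training sensitivity (coding):",
      sprintf("%.3f", mean(!pred_nc[ts$coding])), "\n")
  cat("  training specificity (noncoding):",
      sprintf("%.3f", mean(pred_nc[!ts$coding])), "\n")
  invisible(object)
}

#' Two-graph ROC threshold selection
#'
#' Chooses the cutoff where the sensitivity and specificity curves intersect:
#' the grid cutoff minimizing |sensitivity - specificity|, ties broken by
#' maximal sensitivity + specificity, then by the lower cutoff. A sequence
#' scoring less than or equal to the cutoff is called negative (noncoding).
#'
#' @param scores numeric scores (higher = more coding-like).
#' @param labels logical, `TRUE` for the positive (coding) class.
#' @return the selected cutoff.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  grid <- sort(unique(scores))
  sens <- vapply(grid, function(c) mean(scores[labels] > c), numeric(1))
  spec <- vapply(grid, function(c) mean(scores[!labels] <= c), numeric(1))
  d <- abs(sens - spec)
  cand <- which(d == min(d))
  if (length(cand) > 1L) {
    tot <- sens[cand] + spec[cand]
    cand <- cand[tot == max(tot)]
  }
  grid[cand[1]]
}

#' Remove transcripts with significant Pfam/Rfam hits
#'
#' Pure filter over a precomputed hit table (no HMM search is run): any
#' transcript with a hit at E-value strictly below `evalue_max` is removed.
#'
#' @param ids transcript ids to filter.
#' @param hits data.frame with columns `transcript_id` and `evalue` (optional
#'   `accession`); `NULL` skips the filter.
#' @param evalue_max E-value cutoff (default 1e-10).
#' @return ids with hit-bearing transcripts removed.
#' @export
filter_domain_hits <- function(ids, hits, evalue_max = 1e-10) {
  if (is.null(hits) || nrow(hits) == 0L) return(ids)
  bad <- unique(hits$transcript_id[hits$evalue < evalue_max])
  setdiff(ids, bad)
}

#' Serialize / load a coding-potential model (JSON)
#'
#' @param model a `coding_potential_model`.
#' @param path file path.
#' @return `read_coding_model` returns the model; `write_coding_model` the
#'   path, invisibly.
#' @export
write_coding_model <- function(model, path) {
  jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                            threshold = model$threshold,
                            hexamer_table = as.list(model$hexamer_table)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coding_model
#' @export
read_coding_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(o$coefficients),
                 hexamer_table = unlist(o$hexamer_table),
                 threshold = o$threshold,
                 training_scores = NULL),
            class = "coding_potential_model")
}

# first-order Markov resampling preserving dinucleotide composition;
# uses the caller's RNG state
markov_resample <- function(seq) {
  s <- toupper(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  n <- length(ch)
  if (n < 2L) return(s)
  b <- c("A", "C", "G", "T")
  tr <- matrix(1e-9, 4, 4, dimnames = list(b, b))
  from <- ch[-n]; to <- ch[-1]
  for (i in 1:4) {
    sel <- from == b[i]
    if (any(sel)) tr[i, ] <- tr[i, ] + tabulate(match(to[sel], b), nbins = 4)
  }
  tr <- tr / rowSums(tr)
  out <- character(n)
  out[1] <- sample(b, 1L, prob = tabulate(match(ch, b), nbins = 4))
  for (i in 2:n) out[i] <- sample(b, 1L, prob = tr[out[i - 1L], ])
  paste(out, collapse = "")
}
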