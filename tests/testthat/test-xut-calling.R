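test_that("RP normalization factor is the median mutant/WT ratio over RP genes", {
  wt <- c(a = 10, b = 20, c = 30, d = 5)
  expect_equal(rp_normalization_factor(wt, wt, c("a", "b", "c")), 1)
  expect_equal(rp_normalization_factor(wt, wt / 2, c("a", "b", "c")), 0.5)
  # zero-WT RP genes are excluded
  wt0 <- c(a = 0, b = 20, c = 30)
  mut <- c(a = 5, b = 40, c = 60)
  expect_equal(rp_normalization_factor(wt0, mut, c("a", "b", "c")), 2)
  expect_error(rp_normalization_factor(c(a = 0), c(a = 1), "a"), "zero WT")
  expect_error(rp_normalization_factor(wt, wt, character(0)), "non-empty")
})

# deterministic two-stage fixture: replicate triples (x-1, x, x+1) keep group
# means exact and variances positive
xut_fixture <- function(rpkm_wt, rpkm_mut, lens = 1000L) {
  ids <- names(rpkm_wt)
  lib <- 1e6
  tri <- function(x) x * c(0.9, 1, 1.1)   # exact mean, positive variance
  mk <- function(rpkm) {
    m <- t(sapply(rpkm, function(x) c(tri(x), tri(x))))
    colnames(m) <- paste0(rep(c("S0", "S4"), each = 3), "_r", 1:3)
    rownames(m) <- ids
    m
  }
  # counts = RPKM when lib = 1e6 and length = 1000
  list(wt = mk(rpkm_wt), mut = mk(rpkm_mut),
       stages = rep(c("S0", "S4"), each = 3),
       lens = setNames(rep(lens, length(ids)), ids),
       libs = setNames(rep(lib, 6), paste0(rep(c("S0", "S4"), each = 3),
                                           "_r", 1:3)))
}

test_that("XUT gates: strict fold, FDR and the 3.0 RPKM floor", {
  wt <- c(strong = 20, floor_fail = 0.5, fold_fail = 50, at_floor = 0.7,
          down = 60, anchor1 = 40, anchor2 = 80, anchor3 = 120)
  mut <- c(strong = 100, floor_fail = 2.0, fold_fail = 145,
           at_floor = 3, down = 12, anchor1 = 40, anchor2 = 80, anchor3 = 120)
  fx <- xut_fixture(wt, mut)
  res <- call_xuts(fx$wt, fx$mut, fx$stages, fx$lens,
                   rp_ids = c("anchor1", "anchor2", "anchor3"),
                   wt_lib_sizes = fx$libs, mut_lib_sizes = fx$libs)
  called <- unique(res$xuts$transcript_id)
  expect_equal(unname(res$factors), c(1, 1))
  expect_true("strong" %in% called)              # fold 5, abundant
  expect_false("floor_fail" %in% called)         # fold 4 but 2.0 RPKM < 3.0
  expect_true("at_floor" %in% called)            # mutant RPKM exactly 3.0 kept
  expect_false("fold_fail" %in% called)          # fold 2.9 below the gate
  expect_false("down" %in% called)               # decreased: one-directional
})

test_that("a fold of exactly the threshold is rejected (strict >)", {
  wt <- c(x = 20, a1 = 40, a2 = 80, a3 = 120)
  mut <- c(x = 60, a1 = 40, a2 = 80, a3 = 120)   # fold exactly 3
  fx <- xut_fixture(wt, mut)
  res <- call_xuts(fx$wt, fx$mut, fx$stages, fx$lens, c("a1", "a2", "a3"),
                   wt_lib_sizes = fx$libs, mut_lib_sizes = fx$libs)
  expect_false("x" %in% res$xuts$transcript_id)
  # nudge above the threshold
  mut["x"] <- 60.8
  fx2 <- xut_fixture(wt, mut)
  res2 <- call_xuts(fx2$wt, fx2$mut, fx2$stages, fx2$lens, c("a1", "a2", "a3"),
                    wt_lib_sizes = fx2$libs, mut_lib_sizes = fx2$libs)
  expect_true("x" %in% res2$xuts$transcript_id)
})

test_that("the XUT set is invariant to uniform rescaling of both genotypes", {
  set.seed(71)
  xx <- simulate_xrn1_experiment(71, n_transcripts = 400L, n_xut = 30L,
                                 n_rp = 60L)
  r1 <- call_xuts(xx$wt_counts, xx$mut_counts, xx$col_stages, xx$lengths,
                  xx$rp_ids, wt_lib_sizes = xx$wt_lib_sizes,
                  mut_lib_sizes = xx$mut_lib_sizes)
  r2 <- call_xuts(xx$wt_counts * 2L, xx$mut_counts * 2L, xx$col_stages,
                  xx$lengths, xx$rp_ids,
                  wt_lib_sizes = xx$wt_lib_sizes * 2,
                  mut_lib_sizes = xx$mut_lib_sizes * 2)
  expect_identical(r1$xuts$transcript_id, r2$xuts$transcript_id)
  expect_equal(r1$factors, r2$factors)
  # one-directional gating: called transcripts all increased
  expect_true(all(r1$xuts$fold > 3))
})

test_that("forcing unit factors reproduces the unnormalized pipeline", {
  set.seed(72)
  xx <- simulate_xrn1_experiment(72, n_transcripts = 400L, n_xut = 30L,
                                 n_rp = 60L, rp_shift = 1)
  forced <- call_xuts(xx$wt_counts, xx$mut_counts, xx$col_stages, xx$lengths,
                      xx$rp_ids, factors = c(S0 = 1, S4 = 1),
                      wt_lib_sizes = xx$wt_lib_sizes,
                      mut_lib_sizes = xx$mut_lib_sizes)
  estimated <- call_xuts(xx$wt_counts, xx$mut_counts, xx$col_stages,
                         xx$lengths, xx$rp_ids,
                         wt_lib_sizes = xx$wt_lib_sizes,
                         mut_lib_sizes = xx$mut_lib_sizes)
  expect_equal(unname(forced$factors), c(1, 1))
  # with rp_shift = 1 the estimated factors are ~1 and the sets agree
  expect_equal(unname(estimated$factors), c(1, 1), tolerance = 0.05)
  expect_gt(length(intersect(forced$xuts$transcript_id,
                             estimated$xuts$transcript_id)) /
              length(union(forced$xuts$transcript_id,
                           estimated$xuts$transcript_id)), 0.9)
})

test_that("planted XUT experiments are recovered: factor, sensitivity, FDR", {
  xx <- simulate_xrn1_experiment(73, n_transcripts = 800L, n_xut = 60L)
  res <- call_xuts(xx$wt_counts, xx$mut_counts, xx$col_stages, xx$lengths,
                   xx$rp_ids, wt_lib_sizes = xx$wt_lib_sizes,
                   mut_lib_sizes = xx$mut_lib_sizes)
  expect_lt(abs(mean(res$factors) - 2) / 2, 0.05)
  called <- unique(res$xuts$transcript_id)
  truth <- xx$truth$transcript_id[xx$truth$is_xut]
  expect_gte(mean(truth %in% called), 0.9)
  expect_lte(mean(!(called %in% truth)), 0.10)
  # decoys below the abundance floor are never called
  expect_false(any(xx$truth$transcript_id[xx$truth$is_decoy] %in% called))
})

test_that("fold_range below 3 warns that planted XUTs may be undetectable", {
  expect_warning(simulate_xrn1_experiment(74, n_transcripts = 200L,
                                          n_xut = 10L, n_rp = 30L,
                                          fold_range = c(2, 4)),
                 "undetectable")
})

test_that("reference assignment requires > 50% same-strand exonic coverage", {
  ref <- tiny_ann(list(
    list(id = "rA", gene = "gA", chrom = "chr1", strand = "+",
         exons = ex1(0, 2000)),
    list(id = "rB", gene = "gB", chrom = "chr1", strand = "-",
         exons = ex1(3000, 5000))))
  mk_xut <- function(s, e, strand) tiny_ann(list(
    list(id = "x", gene = "q", chrom = "chr1", strand = strand,
         exons = ex1(s, e))))
  # nested -> assigned
  got <- assign_xut_to_reference("x", mk_xut(100, 600, "+"), ref)
  expect_equal(got$transcript_id, "rA")
  expect_equal(got$gene_id, "gA")
  # exactly 50% -> none (strict >)
  half <- assign_xut_to_reference("x", mk_xut(1500, 2500, "+"), ref)
  expect_true(is.na(half$transcript_id))
  # 50% + 1 bp -> assigned
  over <- assign_xut_to_reference("x", mk_xut(1499, 2499, "+"), ref)
  expect_equal(over$transcript_id, "rA")
  # antisense-only overlap -> none
  anti <- assign_xut_to_reference("x", mk_xut(3100, 3500, "+"), ref)
  expect_true(is.na(anti$transcript_id))
})

test_that("XUT coding classification applies the threshold and lncRNA matching", {
  m <- structure(list(coefficients = c(b0 = 0, b_orf = 0, b_fickett = 0,
                                       b_hexamer = 0),
                      hexamer_table = setNames(rep(0, 4096),
                                               lncrnakit:::.ALL_HEXAMERS),
                      threshold = 0.540),
                 class = "coding_potential_model")
  # all-zero model scores 0.5 <= 0.540 -> noncoding
  out <- classify_xut_coding("ACGTACGTACGT", m)
  expect_true(out$is_noncoding)
  ann <- tiny_ann(list(list(id = "x", gene = "q", chrom = "chr1",
                            strand = "+", exons = ex1(100, 600))))
  lnc <- tiny_ann(list(list(id = "L", gene = "l", chrom = "chr1",
                            strand = "+", biotype = "noncoding",
                            exons = ex1(100, 600))))
  out2 <- classify_xut_coding("ACGTACGTACGT", m, xut_id = "x",
                              annotation = ann, lnc_ann = lnc)
  expect_true(out2$is_lncRNA)
  # opposite strand lncRNA does not match
  lnc_m <- tiny_ann(list(list(id = "L", gene = "l", chrom = "chr1",
                              strand = "-", biotype = "noncoding",
                              exons = ex1(100, 600))))
  out3 <- classify_xut_coding("ACGTACGTACGT", m, xut_id = "x",
                              annotation = ann, lnc_ann = lnc_m)
  expect_false(out3$is_lncRNA)
})
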