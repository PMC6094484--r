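ref_basic <- tiny_ann(list(
  list(id = "r1", gene = "gA", chrom = "chr1", strand = "+",
       exons = rbind(c(100, 200), c(300, 400))),
  list(id = "r2", gene = "gB", chrom = "chr1", strand = "-",
       exons = ex1(5000, 6000)),
  list(id = "r3", gene = "gC", chrom = "chr2", strand = "+",
       exons = ex1(1000, 2000))))

test_that("class codes follow the = > J > X > P > U precedence rules", {
  q <- tiny_ann(list(
    list(id = "eq",  gene = "q", chrom = "chr1", strand = "+",
         exons = rbind(c(100, 200), c(300, 400))),
    list(id = "jx",  gene = "q", chrom = "chr1", strand = "+",
         exons = rbind(c(100, 200), c(300, 450))),
    list(id = "anti", gene = "q", chrom = "chr1", strand = "-",
         exons = ex1(120, 180)),
    list(id = "tand", gene = "q", chrom = "chr1", strand = "+",
         exons = ex1(900, 1300)),
    list(id = "inter", gene = "q", chrom = "chr1", strand = "+",
         exons = ex1(20000, 20500))))
  codes <- assign_class_codes(q, ref_basic)
  expect_identical(unname(codes[c("eq", "jx", "anti", "tand", "inter")]),
                   c("=", "J", "X", "P", "U"))
})

test_that("the tandem window boundary for P is inclusive and strand-aware", {
  # plus-strand reference r1 ends at 400; window 2000 reaches starts <= 2400
  at <- function(s, strand = "+") tiny_ann(list(
    list(id = "q", gene = "q", chrom = "chr1", strand = strand,
         exons = ex1(s, s + 300))))
  expect_identical(unname(assign_class_codes(at(2400), ref_basic)["q"]), "P")
  expect_identical(unname(assign_class_codes(at(2401), ref_basic)["q"]), "U")
  # minus-strand reference r2 starts at 5000: downstream means leftward
  qm <- tiny_ann(list(list(id = "q", gene = "q", chrom = "chr1", strand = "-",
                           exons = ex1(4400, 4700))))
  expect_identical(unname(assign_class_codes(qm, ref_basic)["q"]), "P")
})

test_that("transcripts on unknown chromosomes are rejected", {
  q <- tiny_ann(list(list(id = "q", gene = "q", chrom = "chr2", strand = "+",
                          exons = ex1(10, 300))),
                chrom_lengths = c(chr2 = 100000L))
  ref <- tiny_ann(list(list(id = "r", gene = "g", chrom = "chr1",
                            strand = "+", exons = ex1(10, 300))),
                  chrom_lengths = c(chr1 = 100000L))
  expect_error(assign_class_codes(q, ref), "unknown")
})

test_that("class codes equal the exhaustive rule oracle on fuzzed annotations", {
  set.seed(31)
  n_checked <- 0L
  for (rep in 1:30) {
    # small random reference
    n_ref <- sample(3:6, 1)
    ref_tx <- list()
    pos <- 100L
    for (k in seq_len(n_ref)) {
      n_ex <- sample(1:3, 1)
      exs <- NULL
      p <- pos
      for (e in seq_len(n_ex)) {
        w <- sample(80:300, 1)
        exs <- rbind(exs, c(p, p + w))
        p <- p + w + sample(50:150, 1)
      }
      ref_tx[[k]] <- list(id = paste0("r", k), gene = paste0("g", k),
                          chrom = "chr1", strand = sample(c("+", "-"), 1),
                          exons = exs)
      pos <- p + sample(200:2500, 1)
    }
    ref <- tiny_ann(ref_tx)
    # random queries: perturbed copies and random placements
    for (qq in 1:20) {
      if (runif(1) < 0.5) {
        base <- ref_tx[[sample(n_ref, 1)]]
        exs <- base$exons
        if (runif(1) < 0.5) exs[nrow(exs), 2] <- exs[nrow(exs), 2] + sample(0:80, 1)
        if (runif(1) < 0.3) exs[1, 1] <- max(0, exs[1, 1] - sample(0:80, 1))
        strand <- if (runif(1) < 0.7) base$strand else setdiff(c("+", "-"), base$strand)
      } else {
        s <- sample.int(30000L, 1)
        exs <- ex1(s, s + sample(100:800, 1))
        strand <- sample(c("+", "-"), 1)
      }
      q <- tiny_ann(list(list(id = "q", gene = "q", chrom = "chr1",
                              strand = strand, exons = exs)))
      got <- unname(assign_class_codes(q, ref)["q"])
      want <- oracle_class_code(exs, strand, "chr1", ref)
      expect_identical(got, want)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 500L)
})

test_that("planted class codes are recovered exactly on synthetic data", {
  ds <- default_dataset()
  codes <- assign_class_codes(ds$assembled, ds$reference)
  expect_identical(unname(codes[ds$assembled_truth$transcript_id]),
                   ds$assembled_truth$class)
})

test_that("ancRNA typing uses a strict 100 bp exonic antisense threshold", {
  mk <- function(ov) tiny_ann(list(
    list(id = "lnc", gene = "q", chrom = "chr1", strand = "-",
         exons = ex1(200L - ov, 500L))))
  ref <- tiny_ann(list(list(id = "m", gene = "gm", chrom = "chr1",
                            strand = "+", exons = ex1(0, 200))))
  expect_identical(unname(classify_lncrna_type("lnc", mk(150L), ref)), "ancRNA")
  expect_identical(unname(classify_lncrna_type("lnc", mk(100L), ref)), "lincRNA")
  far <- tiny_ann(list(list(id = "lnc", gene = "q", chrom = "chr1",
                            strand = "-", exons = ex1(10000, 10500))))
  expect_identical(unname(classify_lncrna_type("lnc", far, ref)), "lincRNA")
})

test_that("sense-antisense pairs carry per-strand orientation", {
  ref <- tiny_ann(list(
    list(id = "m1", gene = "g1", chrom = "chr1", strand = "+",
         exons = ex1(0, 1000)),
    list(id = "m2", gene = "g2", chrom = "chr1", strand = "+",
         exons = ex1(1300, 2000))))
  # nested ancRNA -> full overlap
  nested <- tiny_ann(list(list(id = "a", gene = "q", chrom = "chr1",
                               strand = "-", exons = ex1(300, 700))))
  p <- pair_sense_antisense("a", nested, ref)
  expect_equal(p$orientation, "full_overlap")
  expect_equal(p$overlap_bp, 400L)
  # 3' ends in the shared region -> tail overlap
  tail_a <- tiny_ann(list(list(id = "a", gene = "q", chrom = "chr1",
                               strand = "-", exons = ex1(800, 1500))))
  pt <- pair_sense_antisense("a", tail_a, ref)
  expect_equal(pt$orientation[pt$mrna_id == "m1"], "tail_overlap")
  # 5' ends in the shared region -> head overlap
  head_a <- tiny_ann(list(list(id = "a", gene = "q", chrom = "chr2",
                               strand = "-", exons = ex1(0, 400))))
  ref2 <- tiny_ann(list(list(id = "m", gene = "g", chrom = "chr2",
                             strand = "+", exons = ex1(150, 900))))
  expect_equal(pair_sense_antisense("a", head_a, ref2)$orientation,
               "head_overlap")
  # one ancRNA across two mRNAs -> two pairs
  two <- tiny_ann(list(list(id = "a", gene = "q", chrom = "chr1",
                            strand = "-", exons = ex1(700, 1500))))
  p2 <- pair_sense_antisense("a", two, ref)
  expect_equal(nrow(p2), 2L)
  expect_setequal(p2$mrna_id, c("m1", "m2"))
})

test_that("exonic overlap is symmetric", {
  set.seed(5)
  for (i in 1:20) {
    a <- data.frame(start = s1 <- sample.int(1000, 3),
                    end = s1 + sample(50:200, 3))
    b <- data.frame(start = s2 <- sample.int(1000, 2),
                    end = s2 + sample(50:200, 2))
    expect_identical(lncrnakit:::exonic_overlap_bp(a, b),
                     lncrnakit:::exonic_overlap_bp(b, a))
  }
})

test_that("neighbor context classifies divergent, convergent and tandem geometry", {
  ref <- tiny_ann(list(
    list(id = "d", gene = "gd", chrom = "chr1", strand = "-",
         exons = ex1(3000, 4800)),
    list(id = "u", gene = "gu", chrom = "chr2", strand = "+",
         exons = ex1(4000, 4700)),
    list(id = "c", gene = "gc", chrom = "chr1", strand = "-",
         exons = ex1(6200, 7000))))
  lnc <- tiny_ann(list(
    list(id = "L1", gene = "q", chrom = "chr1", strand = "+",
         exons = ex1(5000, 6000)),
    list(id = "L2", gene = "q2", chrom = "chr2", strand = "+",
         exons = ex1(5000, 6000))))
  ctx <- neighbor_context("L1", lnc, ref)
  expect_setequal(ctx$gene_id, c("gd", "gc"))
  expect_equal(ctx$relation[ctx$gene_id == "gd"], "divergent")
  expect_equal(ctx$gap_bp[ctx$gene_id == "gd"], 200L)
  expect_equal(ctx$relation[ctx$gene_id == "gc"], "convergent")
  ctx2 <- neighbor_context("L2", lnc, ref)
  expect_equal(ctx2$relation, "tandem_upstream")
  expect_equal(ctx2$gap_bp, 300L)
  # nothing within max_gap
  expect_equal(nrow(neighbor_context("L1", lnc, ref, max_gap = 100L)), 0L)
})

test_that("every ancRNA pairs with an mRNA and no lincRNA does", {
  ds <- default_dataset()
  disc <- default_discovery()
  lnc <- disc$lncrnas
  anc <- lnc$transcript_id[lnc$type == "ancRNA"]
  linc <- lnc$transcript_id[lnc$type == "lincRNA"]
  pairs <- pair_sense_antisense(c(anc, linc), ds$assembled, ds$reference)
  expect_true(all(anc %in% pairs$ancrna_id))
  expect_false(any(linc %in% pairs$ancrna_id))
})
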