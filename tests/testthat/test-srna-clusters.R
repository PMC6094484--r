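mk_reads <- function(chrom, start, end, strand = "+") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = sprintf("r%03d", seq_along(start)), score = "0",
             strand = strand, stringsAsFactors = FALSE)
}

test_that("read filtering enforces the 17-27 nt and 5'-U rules on both strands", {
  # genome: position 101 (0-based 100) is T; position 140 (0-based 139) is A
  g <- c(chr1 = paste0(strrep("C", 100), "T", strrep("G", 38), "A",
                       strrep("C", 60)))
  # plus-strand reads starting on the T
  r <- mk_reads("chr1", c(100, 100, 100, 100), c(116, 117, 127, 128))
  out <- filter_srna_reads(r, g)
  expect_equal(out$end - out$start, c(17L, 27L))   # 16 and 28 dropped
  expect_true(all(out$first_base == "T"))
  # plus-strand read not starting on T -> dropped
  expect_equal(nrow(filter_srna_reads(mk_reads("chr1", 99, 119), g)), 0L)
  # minus-strand read whose reference interval ends in A -> 5' U on the read
  rm <- mk_reads("chr1", 120, 140, "-")
  expect_equal(nrow(filter_srna_reads(rm, g)), 1L)
  rm2 <- mk_reads("chr1", 121, 141, "-")  # ends on C
  expect_equal(nrow(filter_srna_reads(rm2, g)), 0L)
  expect_error(filter_srna_reads(mk_reads("chr1", 190, 210), g), "off chromosome")
})

test_that("cluster calling respects the depth threshold and the pad boundary", {
  # 19 identical reads: depth below mincov everywhere -> no clusters
  r19 <- mk_reads("chr1", rep(100, 19), rep(122, 19))
  expect_equal(nrow(call_clusters(r19, pad = 22, mincov = 20)), 0L)
  # islands [100,122) and [144,166): gap = 22 -> merged at pad 22
  island <- function(s) mk_reads("chr1", rep(s, 25), rep(s + 22, 25))
  two <- rbind(island(100), island(144))
  cl <- call_clusters(two, pad = 22, mincov = 20)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(100L, 166L))
  expect_equal(cl$read_count, 50L)
  # gap = 23 -> two clusters
  two2 <- rbind(island(100), island(145))
  cl2 <- call_clusters(two2, pad = 22, mincov = 20)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$start, c(100L, 145L))
})

test_that("cluster calling equals the brute-force coverage oracle on fuzzed reads", {
  set.seed(61)
  oracle_clusters <- function(reads, pad, mincov, glen = 3000L) {
    depth <- integer(glen)
    for (i in seq_len(nrow(reads)))
      depth[(reads$start[i] + 1):reads$end[i]] <-
        depth[(reads$start[i] + 1):reads$end[i]] + 1L
    above <- which(depth >= mincov)
    if (length(above) == 0) return(NULL)
    # islands, then merge gaps <= pad
    brk <- which(diff(above) > 1)
    isl <- cbind(above[c(1, brk + 1)] - 1L, above[c(brk, length(above))])
    merged <- isl[1, , drop = FALSE]
    if (nrow(isl) > 1) for (k in 2:nrow(isl)) {
      if (isl[k, 1] - merged[nrow(merged), 2] <= pad)
        merged[nrow(merged), 2] <- isl[k, 2]
      else merged <- rbind(merged, isl[k, ])
    }
    cnt <- apply(merged, 1, function(iv)
      sum(reads$start < iv[2] & reads$end > iv[1]))
    cbind(merged, cnt)
  }
  for (i in 1:30) {
    n <- sample(60:220, 1)
    s <- sample.int(2500L, n, replace = TRUE)
    reads <- mk_reads("chr1", s, s + sample(17:27, n, replace = TRUE))
    pad <- sample(0:30, 1); mincov <- sample(2:8, 1)
    got <- call_clusters(reads, pad = pad, mincov = mincov)
    want <- oracle_clusters(reads, pad, mincov)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, unname(want[, 1]))
      expect_equal(got$end, unname(want[, 2]))
      expect_equal(got$read_count, unname(want[, 3]))
    }
    # invariance to input order
    got2 <- call_clusters(reads[sample(nrow(reads)), ], pad = pad,
                          mincov = mincov)
    expect_identical(got, got2)
  }
})

test_that("cluster ranking is deterministic with a leftmost tie-break", {
  cl <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(500L, 100L, 100L), end = c(600L, 200L, 200L),
                   read_count = c(10L, 5L, 1L), cpm = c(0, 0, 0))
  rk <- rank_clusters(cl, top_n = 2)
  expect_equal(rk$top$read_count, c(10L, 5L))
  expect_equal(rk$share, 15 / 16)
  # ties resolved by position
  cl$read_count <- c(5L, 5L, 5L)
  rk2 <- rank_clusters(cl, top_n = 2)
  expect_equal(rk2$top$start, c(100L, 500L))
  rk3 <- rank_clusters(cl, top_n = 10)
  expect_equal(nrow(rk3$top), 3L)
  expect_equal(rk3$share, 1)
  expect_error(rank_clusters(cl, 0), "positive")
})

test_that("read partitioning assigns 5' ends to exclusive, exhaustive categories", {
  ann <- tiny_ann(list(
    list(id = "c1", gene = "gc", chrom = "chr1", strand = "+",
         exons = ex1(1000, 2000)),
    list(id = "n1", gene = "gn", chrom = "chr1", strand = "+",
         biotype = "noncoding", exons = ex1(5000, 6000)),
    list(id = "a1", gene = "ga", chrom = "chr1", strand = "-",
         biotype = "noncoding", exons = ex1(1800, 2600))))
  cl <- data.frame(chrom = "chr1", start = 900L, end = 6100L,
                   read_count = NA, cpm = NA)
  reads <- mk_reads("chr1",
                    c(1100, 1850, 5100, 950, 2400),
                    c(1100, 1850, 5100, 950, 2400) + 22)
  fr <- partition_cluster_reads(cl, reads, ann)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["coding"]), 1 / 5)       # read at 1100
  expect_equal(unname(fr["overlapped"]), 1 / 5)   # 1850: genes on both strands
  expect_equal(unname(fr["noncoding"]), 2 / 5)    # 5100 and 2400 (a1 only)
  expect_equal(unname(fr["intergenic"]), 1 / 5)   # 300
  expect_error(partition_cluster_reads(
    data.frame(chrom = "chr2", start = 0L, end = 10L), reads, ann),
    "zero reads")
  # all reads inside a lone coding gene
  fr2 <- partition_cluster_reads(
    data.frame(chrom = "chr1", start = 1000L, end = 1500L),
    mk_reads("chr1", c(1100, 1200), c(1122, 1222)), ann)
  expect_equal(unname(fr2["coding"]), 1)
})

test_that("nearest coding gene uses center distance with a leftmost tie-break", {
  ann <- tiny_ann(list(
    list(id = "c1", gene = "gL", chrom = "chr1", strand = "+",
         exons = ex1(1000, 2000)),
    list(id = "c2", gene = "gR", chrom = "chr1", strand = "+",
         exons = ex1(4000, 5000)),
    list(id = "n1", gene = "gN", chrom = "chr1", strand = "+",
         biotype = "noncoding", exons = ex1(2900, 3100))))
  inside <- data.frame(chrom = "chr1", start = 1200L, end = 1300L)
  expect_equal(nearest_coding_gene(inside, ann),
               list(gene_id = "gL", distance = 0L))
  # center at 3000: equidistant (to 1999 and 4000 -> 1001/1000)... use exact middle
  mid <- data.frame(chrom = "chr1", start = 2999L, end = 3001L)
  got <- nearest_coding_gene(mid, ann)
  expect_true(got$gene_id %in% c("gL", "gR"))
  # construct an exact tie: genes at [0,10) and [30,40), center 20
  ann2 <- tiny_ann(list(
    list(id = "x1", gene = "gA", chrom = "chr1", strand = "+",
         exons = ex1(0, 10)),
    list(id = "x2", gene = "gB", chrom = "chr1", strand = "+",
         exons = ex1(30, 40))))
  tie <- data.frame(chrom = "chr1", start = 14L, end = 25L)  # center 19
  # distances: 19-9 = 10 and 30-19 = 11 -> gA; shift to center 20: tie -> gA
  tie2 <- data.frame(chrom = "chr1", start = 15L, end = 26L) # center 20: 11/10
  expect_equal(nearest_coding_gene(tie, ann2)$gene_id, "gA")
  expect_equal(nearest_coding_gene(tie2, ann2)$gene_id, "gB")
  only_nc <- tiny_ann(list(list(id = "n", gene = "g", chrom = "chr1",
                                strand = "+", biotype = "noncoding",
                                exons = ex1(0, 10))))
  expect_error(nearest_coding_gene(inside, only_nc), "no coding gene")
  # fuzzed agreement with an exhaustive scan
  set.seed(62)
  sim <- simulate_genome_and_annotation(62, n_genes = 30L)
  genes <- lncrnakit:::gene_loci(sim$annotation)
  for (i in 1:100) {
    c0 <- sample.int(290000L, 1)
    cl <- data.frame(chrom = sample(names(sim$genome), 1),
                     start = c0, end = c0 + 200L)
    got <- nearest_coding_gene(cl, sim$annotation)
    g <- genes[genes$coding & genes$chrom == cl$chrom, ]
    center <- (cl$start + cl$end) %/% 2L
    d <- mapply(function(s, e) {
      if (center >= s && center < e) 0L
      else min(abs(center - s), abs(center - (e - 1L)))
    }, g$start, g$end)
    expect_equal(got$distance, min(d))
  }
})

test_that("planted sRNA clusters are recovered and background stays silent", {
  sim <- simulate_genome_and_annotation(63, n_genes = 30L)
  sr <- simulate_srna_reads(sim, 63, n_clusters = 6L)
  fr <- filter_srna_reads(sr$reads, sim$genome)
  cl <- call_clusters(fr)
  expect_equal(nrow(cl), 6L)
  for (i in seq_len(nrow(sr$planted))) {
    p <- sr$planted[i, ]
    hit <- cl[cl$chrom == p$chrom & cl$start < p$end & cl$end > p$start, ]
    expect_equal(nrow(hit), 1L)
    inter <- min(hit$end, p$end) - max(hit$start, p$start)
    union <- max(hit$end, p$end) - min(hit$start, p$start)
    expect_gte(inter / union, 0.9)
  }
  # pure background: no read pile reaches mincov
  bg <- simulate_srna_reads(sim, 64, n_clusters = 0L,
                            background_rate = 2e-5)
  frb <- filter_srna_reads(bg$reads, sim$genome)
  expect_equal(nrow(call_clusters(frb)), 0L)
})

test_that("the planted 5'-U fraction is matched at large read counts", {
  sim <- simulate_genome_and_annotation(65, n_genes = 20L)
  sr <- simulate_srna_reads(sim, 65, n_clusters = 34L, background_rate = 0,
                            reads_per_cluster = 1500L)
  expect_gte(nrow(sr$reads), 50000L)
  fr <- filter_srna_reads(sr$reads, sim$genome)
  expect_lt(abs(nrow(fr) / nrow(sr$reads) - 0.76), 0.02)
})
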