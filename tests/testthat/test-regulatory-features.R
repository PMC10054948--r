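test_that("BED parsing validates coordinates and handles empty files", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_equal(nrow(read_bed(f)), 0)

  writeLines("chr1 100 200", f)
  b <- read_bed(f)
  expect_equal(b[, c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 100, end = 200))

  writeLines(c("chr1\t100\t200\tpk1", "chr1\t300\t250"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("loop and annotation readers enforce their schemas", {
  f <- withr::local_tempfile()
  writeLines(c("chrom1\tstart1\tend1\tchrom2\tstart2\tend2\treads\tfdr",
               "chr1\t0\t100\tchr1\t500\t600\t5\t0.01"), f)
  lp <- read_loops(f)
  expect_equal(lp$reads, 5)
  writeLines(c("chrom1\tstart1\tend1", "chr1\t0\t100"), f)
  expect_error(read_loops(f), "missing columns")

  writeLines(c("gene_id\tchrom\ttss\tstrand\tlength",
               "g1\tchr1\t1000\t+\t5000",
               "g1\tchr1\t2000\t-\t4000"), f)
  expect_error(read_annotation(f), "one row")
})

test_that("loop filter keeps reads >= 3 AND fdr < 0.05, boundaries included", {
  lp <- data.frame(chrom1 = "c", start1 = 0, end1 = 10, chrom2 = "c",
                   start2 = 20, end2 = 30,
                   reads = c(3, 2, 10, 3), fdr = c(0.049, 0.01, 0.05, 0.05))
  kept <- filter_loops(lp)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$reads, 3)
  expect_equal(kept$fdr, 0.049)
})

test_that("promoters are width bp centered on the TSS, clipped at zero", {
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                  tss = c(1000, 100, 1000))
  p <- define_promoters(g[1:2, ])
  expect_equal(p$start, c(750, 0))
  expect_equal(p$end, c(1250, 350))
  expect_equal(define_promoters(g[3, ], width = 1000)$start, 500)
  expect_equal(define_promoters(g[3, ], width = 1000)$end, 1500)
})

test_that("enhancer assignment follows loop anchors with set semantics", {
  prom <- region("chr1", 750, 1250, name = "gA")
  peaks <- region("chr1", c(5000, 5300, 9000, 800),
                  c(5100, 5400, 9100, 900),
                  name = c("p1", "p2", "p3", "pSelf"))
  loops <- data.frame(chrom1 = "chr1", start1 = 700, end1 = 1300,
                      chrom2 = "chr1", start2 = 4900, end2 = 5500,
                      reads = 5, fdr = 0.01)

  # no loops touching the promoter -> empty
  far <- loops; far$start1 <- 10000; far$end1 <- 10100
  expect_equal(nrow(assign_enhancers(prom, far, peaks)$gA$enhancers), 0)

  # two disjoint peaks in the partner anchor
  reg <- assign_enhancers(prom, loops, peaks)
  expect_equal(sort(reg$gA$enhancers$name), c("p1", "p2"))

  # same peak reachable via two loops is counted once; anchors can appear
  # in either column
  two <- rbind(loops, data.frame(chrom1 = "chr1", start1 = 4900, end1 = 5500,
                                 chrom2 = "chr1", start2 = 700, end2 = 1300,
                                 reads = 8, fdr = 0.001))
  reg2 <- assign_enhancers(prom, two, peaks)
  expect_equal(sort(reg2$gA$enhancers$name), c("p1", "p2"))

  # a peak overlapping the gene's own promoter is never its enhancer
  own <- data.frame(chrom1 = "chr1", start1 = 700, end1 = 1300,
                    chrom2 = "chr1", start2 = 700, end2 = 1300,
                    reads = 5, fdr = 0.01)
  reg3 <- assign_enhancers(prom, own, peaks)
  expect_false("pSelf" %in% reg3$gA$enhancers$name)
})

test_that("overlap machinery agrees with a quadratic brute-force intersector", {
  set.seed(99)
  for (rep in 1:5) {
    q <- region(sample(c("c1", "c2"), 40, TRUE),
                s <- sample(0:500, 40, TRUE), s + sample(1:50, 40, TRUE))
    s2 <- sample(0:500, 30, TRUE)
    su <- region(sample(c("c1", "c2"), 30, TRUE), s2, s2 + sample(1:50, 30, TRUE))
    got <- estrodyn:::overlap_pairs(q, su)
    want <- brute_overlap(q, su)
    expect_identical(got[order(got$query, got$subject), ],
                     want[order(want$query, want$subject), ],
                     ignore_attr = TRUE)
  }
})

test_that("zscore standardizes with sample sd and rejects constants", {
  tab <- data.frame(A = c(1, 2, 3), B = c(5, 5, 5))
  rownames(tab) <- c("r1", "r2", "r3")
  expect_equal(as.numeric(zscore(tab, "A")), c(-1, 0, 1))
  expect_error(zscore(tab, "B"), "B")
  set.seed(1)
  tab$C <- rnorm(3)
  z <- zscore(tab, "C")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("enhancer score: empty set, exact sums, clamp, monotone, additive", {
  expect_identical(enhancer_score(numeric(0)), 0)
  expect_equal(enhancer_score(c(1, 3)), 3)
  expect_equal(enhancer_score(-2), log2(0.01))

  # independent brute-force oracle over random inputs
  set.seed(42)
  for (i in 1:50) {
    z <- rnorm(sample(0:8, 1), sd = 2)
    manual <- 0
    for (v in z) manual <- manual + log2(max(v, -0.99) + 1)
    expect_equal(enhancer_score(z), manual, tolerance = 1e-12)
  }

  # monotone in each component, additive over disjoint subsets
  z <- c(-0.5, 0.4, 2)
  expect_gt(enhancer_score(z + c(0.1, 0, 0)), enhancer_score(z))
  expect_equal(enhancer_score(z), enhancer_score(z[1:2]) + enhancer_score(z[3]))
})

test_that("ERBS counting is an overlap-bounded subset of enhancers", {
  sim <- small_sim(seed = 61)
  prom <- define_promoters(sim$genes)
  reg <- assign_enhancers(prom, filter_loops(sim$arch$loops),
                          sim$arch$h3k27ac, er_peaks = sim$arch$er_peaks)
  erbs <- count_erbs(reg)
  n_enh <- vapply(reg, function(g) nrow(g$enhancers), 1L)
  expect_true(all(erbs <= n_enh))
  expect_identical(erbs, count_erbs(reg, sim$arch$er_peaks))
  none <- count_erbs(reg, er_peaks = sim$arch$er_peaks[0, ])
  expect_true(all(none == 0))
})

test_that("feature table matches an independent per-gene recomputation", {
  sim <- small_sim(seed = 71, n_genes = 20)
  prom <- define_promoters(sim$genes)
  reg <- assign_enhancers(prom, filter_loops(sim$arch$loops),
                          sim$arch$h3k27ac, er_peaks = sim$arch$er_peaks)
  sig <- sim$arch$signal
  ft <- build_feature_table(reg, sig, sim$genes, "ctxA")
  expect_false(anyNA(ft))

  is_prom <- startsWith(rownames(sig), "prom:")
  for (gi in sample(seq_len(20), 10)) {
    g <- sim$genes$gene_id[gi]
    for (a in c("H3K27ac", "ER")) {
      x <- sig[[a]][is_prom]
      expect_equal(ft[[paste0(a, "_promoter")]][gi],
                   (sig[paste0("prom:", g), a] - mean(x)) / sd(x),
                   tolerance = 1e-12)
      xe <- sig[[a]][!is_prom]
      zs <- (sig[reg[[g]]$enhancers$name, a] - mean(xe)) / sd(xe)
      expect_equal(ft[[paste0(a, "_enh_score")]][gi],
                   sum(log2(pmax(zs, -0.99) + 1)), tolerance = 1e-12)
    }
    expect_equal(ft$n_enhancers[gi], nrow(reg[[g]]$enhancers))
    expect_equal(ft$gene_length[gi], sim$genes$length[gi])
  }

  # rebuilding is bitwise identical; pooling contexts concatenates rows
  expect_identical(ft, build_feature_table(reg, sig, sim$genes, "ctxA"))
  ftB <- build_feature_table(reg, sig, sim$genes, "ctxB")
  expect_equal(nrow(rbind(ft, ftB)), 2 * nrow(ft))

  bad <- sim$genes
  bad$gene_id[1] <- "ghost"
  expect_error(build_feature_table(reg, sig, bad, "x"), "ghost")
})

test_that("recovered architecture ranks EarlyUp above Null on ERBS count", {
  sim <- small_sim(seed = 81, n_genes = 600, coupling_strength = 1)
  prom <- define_promoters(sim$genes)
  reg <- assign_enhancers(prom, filter_loops(sim$arch$loops),
                          sim$arch$h3k27ac, er_peaks = sim$arch$er_peaks)
  ft <- build_feature_table(reg, sim$arch$signal, sim$genes, "x")
  tr <- sim$arch$truth
  expect_gt(mean(ft$n_ERBS[tr$true_trajectory == "EarlyUp"]),
            mean(ft$n_ERBS[tr$true_trajectory == "Null"]))
})

test_that("axis aggregation equals a brute-force double mean", {
  set.seed(5)
  ft <- data.frame(gene_id = paste0("g", 1:40), context = "x",
                   A_promoter = rnorm(40), B_promoter = rnorm(40),
                   A_enh_score = rnorm(40), n_enhancers = rpois(40, 2),
                   n_ERBS = rpois(40, 1), gene_length = 1000)
  labels <- rep(c("Low", "High"), each = 20)
  conf <- c("A_promoter", "B_promoter", "A_enh_score", "n_enhancers",
            "gene_length")
  ax <- aggregate_axes(ft, conf, labels)

  # counts and length excluded; promoter axis = mean over genes of the
  # per-gene mean across confirmed promoter features
  want <- mean(rowMeans(ft[labels == "Low", c("A_promoter", "B_promoter")]))
  got <- ax$mean[ax$class == "Low" & ax$axis == "promoter"]
  expect_equal(got, want, tolerance = 1e-12)

  # single confirmed feature per axis reduces to that feature's class mean
  ax1 <- aggregate_axes(ft, c("A_promoter", "A_enh_score"), labels)
  expect_equal(ax1$mean[ax1$class == "High" & ax1$axis == "enhancer"],
               mean(ft$A_enh_score[labels == "High"]), tolerance = 1e-12)

  expect_error(aggregate_axes(ft, conf, c("solo", labels[-1])), "2 genes")
  expect_error(aggregate_axes(ft, c("A_promoter"), labels), "enhancer")
})
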