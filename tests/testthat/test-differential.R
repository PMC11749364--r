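test_that("site interrogation recounts qualified support per sample", {
  sites <- EditingSites("chr1", c(10L, 20L), "A", "G", "+", TRUE,
                        "intergenic", "", c(2L, 3L), c(10L, 10L))
  obs <- list(
    s1 = mkObs(c(rep(10L, 10), rep(20L, 4)),
               c(rep("G", 3), rep("A", 7), rep("A", 4))),
    s2 = mkObs(rep(10L, 10), rep("A", 10)))
  ee <- interrogateSites(sites, obs)
  expect_s4_class(ee, "EditingExperiment")
  expect_equal(SummarizedExperiment::assay(ee, "edited")[, "s1"], c(3L, 0L),
               ignore_attr = TRUE)
  expect_equal(SummarizedExperiment::assay(ee, "total")[, "s1"], c(10L, 4L),
               ignore_attr = TRUE)
  # a site with 4 reads is unqualified there
  expect_equal(SummarizedExperiment::assay(ee, "qualified")[, "s1"],
               c(TRUE, FALSE), ignore_attr = TRUE)
  expect_true(is.na(SummarizedExperiment::assay(ee, "level")[2, "s1"]))
  # 0 of 10 edited is level 0, not NA
  expect_equal(unname(SummarizedExperiment::assay(ee, "level")[1, "s2"]), 0)

  # random fixture: levels equal a brute-force recount
  set.seed(19)
  pos <- sort(sample.int(300, 30))
  sites2 <- EditingSites("chr1", pos, "A", "G", "+", TRUE, "intergenic",
                         "", 1L, 10L)
  robs <- mkObs(rep(pos, each = 15),
                sample(c("A", "G"), 15 * 30, replace = TRUE),
                baq = sample(c(20L, 30L), 450, replace = TRUE),
                mapq = sample(c(10L, 40L), 450, replace = TRUE))
  ee2 <- interrogateSites(sites2, list(sx = robs))
  dfobs <- as.data.frame(robs)
  for (i in seq_along(pos)) {
    rows <- dfobs[dfobs$pos == pos[i] & dfobs$baq >= 25 &
                  dfobs$mapq >= 20, ]
    expect_equal(unname(SummarizedExperiment::assay(ee2, "total")[i, 1]),
                 nrow(rows))
    expect_equal(unname(SummarizedExperiment::assay(ee2, "edited")[i, 1]),
                 sum(rows$base == "G"))
  }
})

test_that("replicate concordance matches hypergeometric enumeration", {
  # identical proportions: p = 1
  r <- replicateConcordance(5, 10, 5, 10)
  expect_equal(r$p, 1)
  expect_true(r$pass)

  # 3/10 vs 9/10 fails at alpha 0.05; oracle confirms p ~ 0.0198
  oracle <- fisherEnumOracle(3, 10, 9, 10)
  r2 <- replicateConcordance(3, 10, 9, 10)
  expect_equal(r2$p, oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.0198, tolerance = 0.01)
  expect_false(r2$pass)

  # zero-depth replicate is ineligible
  expect_true(is.na(replicateConcordance(0, 0, 3, 10)$pass))

  # 50 random tables against the enumeration oracle
  set.seed(23)
  for (i in 1:50) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(replicateConcordance(k1, n1, k2, n2)$p,
                 fisherEnumOracle(k1, n1, k2, n2), tolerance = 1e-12)
  }
})

test_that("the exact conditional rate test enumerates the binomial null", {
  expect_equal(poissonRateTest(0, 100, 0, 100), 1)
  # printed enumeration case: K = 12, equal exposures
  expect_equal(poissonRateTest(10, 100, 2, 100), 158 / 4096,
               tolerance = 1e-12)
  # symmetry under group swap
  set.seed(29)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    k1 <- rbinom(1, n1, 0.2); k2 <- rbinom(1, n2, 0.2)
    expect_equal(poissonRateTest(k1, n1, k2, n2),
                 poissonRateTest(k2, n2, k1, n1), tolerance = 1e-12)
  }
  # equals both the direct enumeration oracle and the stock binomial test
  for (i in 1:50) {
    n1 <- sample(20:400, 1); n2 <- sample(20:400, 1)
    k1 <- rbinom(1, n1, runif(1, 0, 0.5)); k2 <- rbinom(1, n2, runif(1, 0, 0.5))
    if (k1 + k2 == 0) next
    p <- poissonRateTest(k1, n1, k2, n2)
    expect_equal(p, binomEnumOracle(k1, n1, k2, n2), tolerance = 1e-12)
    expect_equal(p, binom.test(k1, k1 + k2, n1 / (n1 + n2))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("DES calling gates on concordance, adjusted p and fold change", {
  mkee <- function(edited, total) {
    n <- nrow(edited)
    rr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(seq_len(n), width = 1L),
                                 strand = "+")
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
      ref = "A", var = "G", subst_type = "A>G", in_alu = TRUE,
      region_class = "intergenic", gene_ids = "", edited_reads = 0L,
      total_reads = 0L, level = NA_real_)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(edited = edited, total = total,
                    level = edited / total, qualified = total >= 5L),
      rowRanges = rr)
    new("EditingExperiment", se)
  }
  ed <- rbind(c(15, 15, 5, 5),    # 0.30 vs 0.10: fold 3, strong counts
              c(10, 10, 10, 10),  # identical: fold 1
              c(2, 2, 1, 1))      # qualified but tiny counts
  tot <- matrix(50L, 3, 4)
  colnames(ed) <- colnames(tot) <- c("a1", "a2", "b1", "b2")
  des <- callDES(mkee(ed, tot), c("a1", "a2"), c("b1", "b2"))
  expect_equal(des$fold_change[1], 3)
  expect_equal(des$status[1], "DES")
  expect_equal(des$direction[1], "down")
  expect_equal(des$fold_change[2], 1)
  expect_equal(des$status[2], "not-DES")

  # swapping group labels flips direction but keeps status
  des2 <- callDES(mkee(ed, tot), c("b1", "b2"), c("a1", "a2"))
  expect_equal(des2$status, des$status)
  expect_equal(des2$direction[1], "up")
  expect_equal(des2$p, des$p, tolerance = 1e-12)

  # an unqualified replicate makes the site ineligible
  tot2 <- tot; tot2[1, "b2"] <- 4L
  ed2b <- ed; ed2b[1, "b2"] <- 2
  des3 <- callDES(mkee(ed2b, tot2), c("a1", "a2"), c("b1", "b2"))
  expect_equal(des3$status[1], "ineligible")

  # discordant replicates are screened out before the rate test
  ed4 <- rbind(c(25, 0, 5, 5))
  tot4 <- matrix(50L, 1, 4)
  colnames(ed4) <- colnames(tot4) <- c("a1", "a2", "b1", "b2")
  des4 <- callDES(mkee(ed4, tot4), c("a1", "a2"), c("b1", "b2"))
  expect_equal(des4$status[1], "ineligible")
  expect_lt(des4$concordance_p_a[1], 0.05)
})

test_that("large-set confirmation recovers planted shifts and matches BH", {
  # note on sample sizes: with 6 vs 3 samples the smallest achievable
  # rank-sum p is 2/84 ~ 0.024, which can never clear a BH threshold of
  # 0.05 * 50/500; recovery of a 50-of-500 planting therefore needs groups
  # large enough that complete separation is individually significant
  set.seed(37)
  n <- 500; shift_idx <- 1:50
  mat <- matrix(runif(n * 18, 0.2, 0.6), n, 18)
  colnames(mat) <- paste0("s", 1:18)
  groups <- rep(c("A", "B"), c(12, 6))
  mat[shift_idx, groups == "B"] <- mat[shift_idx, groups == "B"] + 0.3
  res <- confirmDESLargeSet(mat, groups)
  found <- which(res$significant)
  tp <- length(intersect(found, shift_idx))
  prec <- tp / max(length(found), 1); rec <- tp / 50
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.8)
  # BH equals the sorted-formula oracle
  expect_equal(res$p_adjusted, bhOracle(res$p), tolerance = 1e-12)
  # identical groups: nothing significant
  mat0 <- matrix(rep(runif(50, 0.2, 0.6), 18), 50, 18)
  expect_false(any(confirmDESLargeSet(mat0, groups)$significant))
  expect_error(confirmDESLargeSet(mat, rep("A", 18)), "two groups")
})

test_that("median level comparison is a paired-universe rank-sum test", {
  r <- medianLevelComparison(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4))
  expect_equal(r$median_a, r$median_b)
  expect_equal(r$p, 1)
  set.seed(41)
  a <- runif(500, 0.1, 0.9); b <- pmax(a - 0.05, 0.01)
  r2 <- medianLevelComparison(a, b)
  expect_equal(r2$difference, median(b) - median(a))
  expect_lt(r2$p, 0.01)
  # exact enumeration at small n
  for (i in 1:5) {
    v <- sample(1:100, 12) / 100
    x <- v[1:6]; y <- v[7:12]
    expect_equal(medianLevelComparison(x, y)$p, ranksumEnumOracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("DES type-I error on null data stays at or below alpha", {
  # identical true rates in both groups: with raw p-values the rejection
  # rate must not exceed alpha (the exact conditional test is
  # conservative); with BH it collapses further
  set.seed(43)
  n <- 2000
  lv <- runif(n, 0.1, 0.5)
  ed <- matrix(rbinom(n * 4, 50, rep(lv, 4)), n, 4)
  tot <- matrix(50L, n, 4)
  colnames(ed) <- colnames(tot) <- c("a1", "a2", "b1", "b2")
  rr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq_len(n), width = 1L),
                               strand = "+")
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    ref = "A", var = "G", subst_type = "A>G", in_alu = TRUE,
    region_class = "intergenic", gene_ids = "", edited_reads = 0L,
    total_reads = 0L, level = NA_real_)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(edited = ed, total = tot, level = ed / tot,
                  qualified = tot >= 5L), rowRanges = rr)
  ee <- new("EditingExperiment", se)
  raw <- callDES(ee, c("a1", "a2"), c("b1", "b2"), adjust = FALSE)
  eligible <- raw$status != "ineligible"
  fpr <- mean(raw$p_adjusted[eligible] < 0.05 &
              raw$fold_change[eligible] >= 2)
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / sum(eligible)))
  adj <- callDES(ee, c("a1", "a2"), c("b1", "b2"))
  expect_lte(mean(adj$status == "DES"), 0.05)
})
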