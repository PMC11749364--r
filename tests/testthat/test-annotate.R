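test_that("substitution spectrum tallies and reclassifies correctly", {
  # 10 A>G sites: fraction 1
  s <- EditingSites("chr1", 1:10, "A", "G", "+", TRUE, "intergenic", "",
                    3L, 10L)
  sp <- substitutionSpectrum(s)
  expect_equal(sp$frac_genomic[sp$subst_type == "A>G"], 1)
  expect_equal(sum(sp$frac_genomic), 1)

  # 8 genomic A>G plus 2 genomic T>C on minus-strand genes: stranded
  # spectrum is pure A>G
  refv <- c(rep("A", 8), rep("T", 2))
  s2 <- EditingSites("chr1", 1:10, refv, ifelse(refv == "A", "G", "C"),
                     c(rep("+", 8), rep("-", 2)), TRUE, "intergenic", "",
                     3L, 10L)
  sp2 <- substitutionSpectrum(s2)
  expect_equal(sp2$frac_stranded[sp2$subst_type == "A>G"], 1)
  expect_equal(sp2$frac_genomic[sp2$subst_type == "A>G"], 0.8)
  expect_equal(sp2$frac_genomic[sp2$subst_type == "T>C"], 0.2)

  # random mixed input equals a hand tally
  set.seed(21)
  refv <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  varv <- vapply(refv, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  s3 <- EditingSites("chr1", 1:60, refv, varv, "+", TRUE, "intergenic", "",
                     3L, 10L)
  sp3 <- substitutionSpectrum(s3)
  tal <- table(factor(paste0(refv, ">", varv), levels = sp3$subst_type))
  expect_equal(sp3$n_genomic, as.integer(tal))
})

test_that("region annotation respects precedence and matches brute force", {
  gm <- readGeneModels(twoGeneBed12())
  mk <- function(pos) EditingSites("chr1", pos, "A", "G", "*", FALSE,
                                   "intergenic", "", 3L, 10L)
  cls <- function(pos)
    S4Vectors::mcols(annotateRegion(mk(pos), gm))$region_class
  expect_equal(cls(680), "UTR3")      # + gene 3'UTR (651..700)
  expect_equal(cls(120), "UTR5")      # + gene 5'UTR (101..150)
  expect_equal(cls(200), "CDS")
  expect_equal(cls(400), "intronic")
  expect_equal(cls(10), "intergenic")
  expect_equal(cls(1020), "UTR3")     # - gene 3'UTR (1001..1050)
  out <- annotateRegion(mk(10), gm)
  expect_identical(S4Vectors::mcols(out)$gene_ids, "")

  # brute-force per-base annotator over random sites
  set.seed(31)
  pos <- sample.int(2000, 300, replace = FALSE)
  got <- S4Vectors::mcols(annotateRegion(mk(sort(pos)), gm))$region_class
  oracle <- vapply(sort(pos), function(p) {
    inr <- function(gr) any(BiocGenerics::start(gr) <= p &
                            BiocGenerics::end(gr) >= p)
    if (inr(gm@cds)) "CDS"
    else if (inr(gm@utr3)) "UTR3"
    else if (inr(gm@utr5)) "UTR5"
    else if (inr(genes(gm))) "intronic"
    else "intergenic"
  }, "")
  expect_equal(got, oracle)
})

test_that("ncRNA sites classify as exonic or intronic ncRNA", {
  f <- tempfile(fileext = ".bed")
  # noncoding: thickStart == thickEnd
  writeLines("chr1\t100\t700\tnc1\t0\t+\t100\t100\t0\t2\t200,200\t0,400", f)
  gm <- readGeneModels(f)
  expect_equal(S4Vectors::mcols(genes(gm))$biotype, "ncRNA")
  mk <- function(pos) EditingSites("chr1", pos, "A", "G", "*", FALSE,
                                   "intergenic", "", 3L, 10L)
  cls <- function(pos)
    S4Vectors::mcols(annotateRegion(mk(pos), gm))$region_class
  expect_equal(cls(200), "ncRNA_exonic")
  expect_equal(cls(400), "ncRNA_intronic")
})

test_that("category enrichment is an exact 2x2 test with BH across classes", {
  # all edited sites forced into UTR3: largest odds ratio and smallest p
  s <- EditingSites("chr1", 1:40, "A", "G", "+", FALSE,
                    c(rep("UTR3", 30), rep("intronic", 10)), "g", 3L, 10L)
  bg <- c(CDS = 500L, UTR3 = 500L, UTR5 = 500L, ncRNA_exonic = 0L,
          intronic = 2000L, ncRNA_intronic = 0L, intergenic = 2000L)
  expect_warning(res <- categoryEnrichment(s, bg), "zero background")
  expect_equal(res$category[which.min(res$p)], "UTR3")
  expect_gt(res$odds_ratio[res$category == "UTR3"], 1)
  expect_true(all(res$p_adjusted >= res$p - 1e-12))

  # the exact p equals hypergeometric enumeration on random tables
  set.seed(8)
  for (i in 1:20) {
    cls <- c("UTR3", "intronic", "intergenic")
    edited <- setNames(sample(0:30, 3, replace = TRUE), cls)
    bgc <- setNames(edited + sample(20:200, 3, replace = TRUE), cls)
    s2 <- EditingSites("chr1", seq_len(sum(edited)), "A", "G", "+", FALSE,
                       rep(cls, edited), "", 3L, 10L)
    res2 <- categoryEnrichment(s2, bgc)
    for (r in seq_len(nrow(res2))) {
      # oracle: hypergeometric two-sided via fixed margins
      k1 <- res2$edited_in[r]; k2 <- res2$edited_out[r]
      n1 <- res2$background_in[r]; n2 <- res2$background_out[r]
      expect_equal(res2$p[r],
                   fisherEnumOracle(k1, n1, k2, n2), tolerance = 1e-12)
    }
  }
})

test_that("null enrichment draws rarely reach significance", {
  # edited sites drawn uniformly from the background: the family of exact
  # tests should essentially never reject after BH
  set.seed(77)
  bg <- c(UTR3 = 300L, intronic = 1200L, intergenic = 1500L)
  hits <- 0L
  for (i in 1:60) {
    draw <- table(factor(sample(rep(names(bg), bg), 120),
                         levels = names(bg)))
    s <- EditingSites("chr1", seq_len(sum(draw)), "A", "G", "+", FALSE,
                      rep(names(draw), draw), "", 3L, 10L)
    res <- categoryEnrichment(s, bg)
    if (any(res$p_adjusted < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits / 60, 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("per-gene counts group and average like a split-apply oracle", {
  s <- EditingSites("chr1", 1:33, "A", "G", "+", FALSE, "UTR3", "CYP20-like",
                    3L, 10L)
  pg <- perGeneCounts(s)
  expect_equal(pg$counts$n_sites, 33L)
  expect_equal(pg$mean_per_gene, 33)

  expect_equal(nrow(perGeneCounts(EditingSites())$counts), 0L)

  set.seed(12)
  gids <- sample(c("", "g1", "g2", "g1,g3"), 80, replace = TRUE)
  s2 <- EditingSites("chr1", 1:80, "A", "G", "+", FALSE,
                     ifelse(gids == "", "intergenic", "UTR3"), gids, 3L, 10L)
  pg2 <- perGeneCounts(s2)
  oracle <- table(unlist(strsplit(gids[gids != ""], ",")))
  expect_equal(sort(setNames(pg2$counts$n_sites, pg2$counts$gene_id)),
               sort(unclass(oracle))[order(names(oracle))][
                 order(sort(names(oracle)))], ignore_attr = TRUE)
  expect_equal(pg2$mean_per_gene, mean(oracle))
})

test_that("level-distribution comparison is a textbook chi-square", {
  # identical distributions: statistic 0, p = 1
  lv <- rep(c(0.15, 0.45, 0.85), c(30, 30, 30))
  r <- compareLevelDistributions(lv, lv)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # clear separation gives a small p
  a <- runif(200, 0.9, 1); b <- runif(200)
  expect_lt(compareLevelDistributions(a, b)$p, 1e-10)

  # statistic equals the textbook formula on the merged table
  set.seed(4)
  a <- rbeta(150, 2, 5); b <- rbeta(120, 5, 2)
  r <- compareLevelDistributions(a, b)
  tb <- r$table
  expc <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  expect_equal(r$statistic, sum((tb - expc)^2 / expc), tolerance = 1e-12)
  expect_equal(r$p, stats::pchisq(r$statistic, r$df, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("gene-set over-representation equals hypergeometric enumeration", {
  universe <- paste0("g", 1:30)
  sets <- list(A = paste0("g", 1:8), B = paste0("g", 9:20),
               C = paste0("g", c(1, 9, 21:25)))
  # the whole of set A as input: A is the top hit
  res <- genesetOverrepresentation(sets$A, sets, universe)
  expect_equal(res$set[1], "A")

  # enumeration oracle on small cases: P(X >= k) by summing the
  # hypergeometric mass directly
  set.seed(6)
  for (i in 1:25) {
    gl <- sample(universe, sample(3:12, 1))
    res <- genesetOverrepresentation(gl, sets, universe)
    for (r in seq_len(nrow(res))) {
      K <- res$set_size[r]; k <- res$overlap[r]; n <- res$list_size[r]
      pr <- sum(vapply(k:min(K, n), function(x)
        choose(K, x) * choose(30 - K, n - x) / choose(30, n), 1))
      expect_equal(res$p[r], pr, tolerance = 1e-12)
    }
  }
  expect_warning(genesetOverrepresentation(c("g1", "zz"), sets, universe),
                 "outside the universe")
})

test_that("depth comparison reports medians and an exact rank-sum p", {
  r <- depthComparison(c(14, 15, 13, 16), c(7, 8, 6, 9))
  expect_equal(r$median_shared, 14.5)
  expect_equal(r$median_specific, 7.5)
  # exact enumeration oracle at small n
  set.seed(13)
  for (i in 1:10) {
    nx <- sample(4:8, 1); ny <- sample(4:8, 1)
    v <- sample(1:100, nx + ny)   # distinct values: exact test, no ties
    x <- v[seq_len(nx)]; y <- v[nx + seq_len(ny)]
    expect_equal(depthComparison(x, y)$p, ranksumEnumOracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(depthComparison(numeric(), 1:3), "non-empty")
})
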