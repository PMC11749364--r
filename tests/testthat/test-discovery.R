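test_that("candidate calling applies depth, variant and quality thresholds", {
  # 5 qualified reads, all reference: no candidate
  expect_equal(nrow(callCandidates(mkObs(rep(10L, 5), "A"))), 0L)

  # 5 qualified reads including 2 variant reads: candidate at level 0.4
  # is 2/5 of the qualified depth
  obs <- mkObs(rep(10L, 5), c("A", "A", "A", "G", "G"))
  cands <- callCandidates(obs)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$var, "G")
  expect_equal(cands$edited_reads, 2L)
  expect_equal(cands$total_reads, 5L)
  expect_equal(cands$level, 0.4)

  # low-quality variant reads do not count
  obs$baq[4] <- 20L
  expect_equal(nrow(callCandidates(obs)), 0L)
  obs$baq[4] <- 30L; obs$mapq[5] <- 10L
  expect_equal(nrow(callCandidates(obs)), 0L)

  # unsorted observations are refused
  expect_error(callCandidates(mkObs(c(11L, 10L), "A")), "sorted")
})

test_that("candidate calling matches a brute-force recount on random data", {
  set.seed(101)
  p <- CallerParams()
  pos <- rep(sort(sample.int(500, 200)), each = 12)
  obs <- mkObs(pos, sample(c("A", "A", "A", "G", "C", "N"), length(pos),
                           replace = TRUE),
               baq = sample(c(20L, 30L), length(pos), replace = TRUE),
               mapq = sample(c(10L, 40L), length(pos), replace = TRUE),
               read_pos = sample.int(100, length(pos), replace = TRUE))
  cands <- callCandidates(obs, p)

  # independent per-position recount over the raw rows
  oracle <- list()
  for (q in unique(obs$pos)) {
    rows <- obs[obs$pos == q & obs$base != "N" & obs$baq >= 25 &
                obs$mapq >= 20 & obs$read_pos > 6]
    if (nrow(rows) < 5) next
    vars <- rows[rows$base != rows$ref]
    if (!nrow(vars)) next
    tab <- sort(table(vars$base), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      bq <- tapply(vars$baq, vars$base, sum)[names(tab)[1:2]]
      if (bq[1] == bq[2]) next  # dropped tie
    }
    if (tab[1] < 2) next
    oracle[[as.character(q)]] <- list(pos = q, var = names(tab)[1],
                                      n = unname(tab[1]), depth = nrow(rows))
  }
  expect_equal(cands$pos, as.integer(names(oracle)))
  expect_equal(cands$edited_reads,
               vapply(oracle, function(x) as.integer(x$n), 1L),
               ignore_attr = TRUE)
  expect_equal(cands$total_reads,
               vapply(oracle, function(x) x$depth, 1L), ignore_attr = TRUE)
})

test_that("hexamer-prefix exclusion removes read-start support", {
  # variant support only at read positions 1-6 evaporates
  obs <- mkObs(rep(10L, 9), c(rep("A", 5), rep("G", 4)),
               read_pos = c(rep(50L, 5), 1L, 3L, 5L, 6L))
  expect_equal(nrow(callCandidates(obs)), 0L)
  # position 7 is the first retained read position
  obs$read_pos[6:9] <- 7L
  expect_equal(nrow(callCandidates(obs)), 1L)
  # exclusion is exactly a set difference on read_pos <= 6
  set.seed(1)
  r <- mkObs(rep(1L, 200), "A", read_pos = sample.int(101, 200,
                                                      replace = TRUE))
  expect_equal(filterHexamerPrefix(r), r[r$read_pos > 6])
})

test_that("genomic evidence decisions follow the depth/variant truth table", {
  p <- CallerParams()
  mkcand <- function() callCandidates(
    mkObs(rep(10L, 10), c(rep("A", 6), rep("G", 4))))
  for (dna_depth in c(0L, 3L, 5L, 10L)) {
    for (dna_var in 0:2) {
      if (dna_var > dna_depth) next
      dna <- if (dna_depth > 0)
        mkObs(rep(10L, dna_depth),
              c(rep("G", dna_var), rep("A", dna_depth - dna_var)))
      else mkObs(integer(), character())
      out <- filterGenomicEvidence(mkcand(), dna, p)
      expected <- dna_depth >= 5L && dna_var <= 0L
      expect_identical(out$pass_genomic, expected,
                       info = paste(dna_depth, dna_var))
    }
  }
})

test_that("known-variant exclusion equals a set-difference oracle", {
  set.seed(5)
  obs_pos <- rep(sort(sample.int(2000, 300)), each = 8)
  obs <- mkObs(obs_pos, sample(c("A", "G", "G"), length(obs_pos),
                               replace = TRUE))
  cands <- callCandidates(obs)
  snp_pos <- sample.int(2000, 400)
  snps <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(snp_pos, width = 1L))
  out <- filterKnownVariants(cands, snps)
  expect_identical(out$pass_snp, !(out$pos %in% snp_pos))
  # empty set is the identity
  out0 <- filterKnownVariants(cands, GenomicRanges::GRanges())
  expect_true(all(out0$pass_snp))
})

test_that("non-Alu filters: frequency, splice, homopolymer, similarity", {
  p <- CallerParams()
  gm <- readGeneModels(twoGeneBed12())
  # reference: A everywhere except a 5-run of A is everywhere... build
  # a controlled sequence: C background, AAAAA at 2001..2005, AAAA at
  # 2101..2104
  seqc <- rep("C", 3000)
  seqc[2001:2005] <- "A"; seqc[2101:2104] <- "A"
  ref <- mkRef(paste(seqc, collapse = ""))
  alu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500, 2600))
  simmask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2700, 2800))

  mkcands <- function(pos, nvar, ntot = 30L) {
    obs <- mkObs(rep(pos, ntot),
                 c(rep("G", nvar), rep("C", ntot - nvar)), ref = "C")
    callCandidates(obs, p)
  }
  run <- function(cands) applyNonAluFilters(cands, alu, gm, ref, simmask, p)

  # frequency: level 2/30 < 0.1 fails outside Alu, exempt inside
  low_out <- run(mkcands(2900L, 2L))
  expect_false(low_out$pass_freq)
  low_in <- run(mkcands(2550L, 2L))
  expect_true(low_in$pass_freq)
  expect_true(low_in$in_alu)

  # splice distance: gene gp intron is 301..500; 3 bp in fails, 5 bp passes,
  # 4 bp is the failing boundary
  spl <- function(pos) run(mkcands(pos, 10L))$pass_splice
  expect_false(spl(303L))  # 3 bases into the intron
  expect_false(spl(304L))  # exactly 4
  expect_true(spl(305L))   # 5 bases in
  expect_true(spl(499L) == FALSE)  # 2 bases from the downstream junction

  # homopolymer: run of 5 covering the site fails, run of 4 passes
  hp5 <- mkcands(2003L, 10L); hp5$ref <- "A"  # site inside AAAAA
  obs5 <- mkObs(rep(2003L, 30), c(rep("G", 10), rep("A", 20)), ref = "A")
  expect_false(run(callCandidates(obs5, p))$pass_homopolymer)
  obs4 <- mkObs(rep(2102L, 30), c(rep("G", 10), rep("A", 20)), ref = "A")
  expect_true(run(callCandidates(obs4, p))$pass_homopolymer)

  # similarity mask
  expect_false(run(mkcands(2750L, 10L))$pass_similarity)
  expect_true(run(mkcands(2900L, 10L))$pass_similarity)

  # Alu exemption covers all four rules
  inalu <- run(mkcands(2550L, 2L))
  expect_true(all(unlist(
    inalu[, c("pass_freq", "pass_splice", "pass_homopolymer",
              "pass_similarity")])))
})

test_that("the cascade is idempotent and order-independent where claimed", {
  set.seed(17)
  p <- CallerParams()
  gm <- readGeneModels(twoGeneBed12())
  seqc <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  ref <- mkRef(paste(seqc, collapse = ""))
  alu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1200, 1600))
  simmask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2200))
  poss <- sort(sample.int(2900, 80))
  obs <- data.table::rbindlist(lapply(poss, function(q) {
    nv <- sample(0:6, 1)
    mkObs(rep(q, 20), c(rep("G", nv), rep(seqc[q], 20 - nv)),
          ref = seqc[q])
  }))
  obs <- obs[obs$ref != "G"]
  data.table::setorder(obs, chrom, pos)
  obs$read_id <- paste0("r", seq_len(nrow(obs)))
  dna <- data.table::copy(obs); dna$base <- dna$ref
  snps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample(poss, 10), width = 1L))

  cands <- callCandidates(obs, p)
  f1 <- applyNonAluFilters(
    filterKnownVariants(filterGenomicEvidence(cands, dna, p), snps),
    alu, gm, ref, simmask, p)
  # applying the whole battery twice changes nothing
  f2 <- applyNonAluFilters(
    filterKnownVariants(filterGenomicEvidence(f1, dna, p), snps),
    alu, gm, ref, simmask, p)
  expect_equal(f1[, sort(names(f1)), with = FALSE],
               f2[, sort(names(f2)), with = FALSE])
  # site-identity filters commute
  g1 <- filterGenomicEvidence(filterKnownVariants(cands, snps), dna, p)
  expect_equal(sort(names(g1)), sort(names(f1[, names(g1), with = FALSE])))
  expect_equal(retainedCandidates(
    applyNonAluFilters(g1, alu, gm, ref, simmask, p)),
    retainedCandidates(f1))
})

test_that("strand assignment follows gene models and conserves pair totals", {
  gm <- readGeneModels(twoGeneBed12())
  # T>C inside the - gene reports as A>G on strand -
  s <- EditingSites("chr1", 1100, "T", "C", "*", FALSE, "intergenic", "",
                    3L, 10L)
  out <- assignStrand(s, gm)
  expect_equal(as.character(BiocGenerics::strand(out)), "-")
  expect_equal(S4Vectors::mcols(out)$subst_type, "A>G")

  # a site under genes on both strands stays unknown and genomic
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t700\tgp\t0\t+\t150\t650\t0\t1\t600\t0",
               "chr1\t100\t700\tgq\t0\t-\t150\t650\t0\t1\t600\t0"), f)
  gm2 <- readGeneModels(f)
  out2 <- assignStrand(EditingSites("chr1", 400, "T", "C", "*", FALSE,
                                    "intergenic", "", 3L, 10L), gm2)
  expect_equal(as.character(BiocGenerics::strand(out2)), "*")
  expect_equal(S4Vectors::mcols(out2)$subst_type, "T>C")

  # conservation: count(A>G) + count(T>C) is invariant under assignment
  set.seed(3)
  n <- 40
  refv <- sample(c("A", "T"), n, replace = TRUE)
  sites <- EditingSites("chr1", sample.int(2000, n), refv,
                        ifelse(refv == "A", "G", "C"), "*", FALSE,
                        "intergenic", "", 3L, 10L)
  before <- S4Vectors::mcols(sites)$subst_type
  after <- S4Vectors::mcols(assignStrand(sites, gm))$subst_type
  expect_equal(sum(before %in% c("A>G", "T>C")),
               sum(after %in% c("A>G", "T>C")))
})

test_that("replicate intersection behaves like a hash join", {
  mk <- function(pos, var = "G") {
    refv <- ifelse(var == "G", "A", "T")
    EditingSites("chr1", pos, refv, var, "*", FALSE, "intergenic", "",
                 3L, 10L)
  }
  # disjoint inputs
  r <- intersectReplicates(mk(1:5), mk(11:15))
  expect_length(r$shared, 0)
  expect_length(r$rep1_specific, 5)
  # identical inputs
  r <- intersectReplicates(mk(1:5), mk(1:5))
  expect_length(r$shared, 5)
  expect_length(r$rep2_specific, 0)
  # random inputs vs a hash-join oracle
  set.seed(9)
  p1 <- sample.int(500, 200); p2 <- sample.int(500, 200)
  r <- intersectReplicates(mk(sort(p1)), mk(sort(p2)))
  expect_setequal(BiocGenerics::start(r$shared), intersect(p1, p2))
  expect_setequal(BiocGenerics::start(r$rep1_specific), setdiff(p1, p2))
  expect_setequal(BiocGenerics::start(r$rep2_specific), setdiff(p2, p1))
  # per-replicate support is carried
  expect_true(all(c("edited_reads2", "total_reads2") %in%
                  colnames(S4Vectors::mcols(r$shared))))
})
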