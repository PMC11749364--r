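# Shared fixtures and independent oracles, built in code.

# observation table builder -------------------------------------------------
mkObs <- function(pos, base, ref = "A", baq = 30L, mapq = 40L,
                  read_pos = 50L, sample_id = "s1", chrom = "chr1") {
  n <- length(pos)
  data.table::data.table(
    sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
    pos = as.integer(pos), ref = rep_len(ref, n), base = rep_len(base, n),
    baq = as.integer(rep_len(baq, n)), mapq = as.integer(rep_len(mapq, n)),
    read_pos = as.integer(rep_len(read_pos, n)),
    read_id = paste0("r", seq_len(n)))
}

# a two-gene annotation (one per strand) written as BED12 --------------------
# gene gp: +, span 101..700, exons 101..300 and 501..700, CDS 151..650
#   (UTR5 101..150, UTR3 651..700)
# gene gm: -, span 1001..1600, exons 1001..1200 and 1401..1600,
#   CDS 1051..1550 (UTR3 1001..1050, UTR5 1551..1600)
twoGeneBed12 <- function() {
  f <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t700\tgp\t0\t+\t150\t650\t0\t2\t200,200\t0,400",
    "chr1\t1000\t1600\tgm\t0\t-\t1050\t1550\t0\t2\t200,200\t0,400"),
    f)
  f
}

twoGeneGtf <- function() {
  f <- tempfile(fileext = ".gtf")
  a <- function(id) sprintf("gene_id \"%s\";", id)
  writeLines(c(
    paste("chr1", "t", "gene", 101, 700, ".", "+", ".", a("gp"), sep = "\t"),
    paste("chr1", "t", "exon", 101, 300, ".", "+", ".", a("gp"), sep = "\t"),
    paste("chr1", "t", "exon", 501, 700, ".", "+", ".", a("gp"), sep = "\t"),
    paste("chr1", "t", "CDS", 151, 300, ".", "+", ".", a("gp"), sep = "\t"),
    paste("chr1", "t", "CDS", 501, 650, ".", "+", ".", a("gp"), sep = "\t"),
    paste("chr1", "t", "gene", 1001, 1600, ".", "-", ".", a("gm"),
          sep = "\t"),
    paste("chr1", "t", "exon", 1001, 1200, ".", "-", ".", a("gm"),
          sep = "\t"),
    paste("chr1", "t", "exon", 1401, 1600, ".", "-", ".", a("gm"),
          sep = "\t"),
    paste("chr1", "t", "CDS", 1051, 1200, ".", "-", ".", a("gm"),
          sep = "\t"),
    paste("chr1", "t", "CDS", 1401, 1550, ".", "-", ".", a("gm"),
          sep = "\t")), f)
  f
}

grFields <- function(gr) {
  list(chrom = as.character(GenomicRanges::seqnames(gr)),
       start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
       strand = as.character(BiocGenerics::strand(gr)),
       gene_id = S4Vectors::mcols(gr)$gene_id)
}

# independent statistical oracles -------------------------------------------

# two-sided Fisher exact p by hypergeometric enumeration over the fixed
# margins of [[k1, n1-k1], [k2, n2-k2]]
fisherEnumOracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  lo <- max(0L, K - n2); hi <- min(n1, K)
  a <- lo:hi
  pr <- dhyper(a, n1, n2, K)
  sum(pr[pr <= dhyper(k1, n1, n2, K) * (1 + 1e-07)])
}

# two-sided exact conditional rate test by direct binomial enumeration
binomEnumOracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  if (K == 0) return(1)
  p0 <- n1 / (n1 + n2)
  pr <- dbinom(0:K, K, p0)
  min(1, sum(pr[pr <= pr[k1 + 1] * (1 + 1e-07)]))
}

# exact two-sided rank-sum p by enumeration of all assignments (n <= 8)
ranksumEnumOracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  wobs <- sum(r[seq_len(n)])
  combs <- utils::combn(N, n)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (N + 1) / 2
  mean(abs(ws - mu) >= abs(wobs - mu) - 1e-09)
}

# BH adjustment by the sorted formula
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# brute-force TOM (triple loop)
tomOracle <- function(a) {
  n <- nrow(a)
  a0 <- a; diag(a0) <- 0
  k <- rowSums(a0)
  t <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a0[i, u] * a0[u, j]
    t[i, j] <- (s + a0[i, j]) / (min(k[i], k[j]) + 1 - a0[i, j])
  }
  t
}

# small reference with one chromosome from an explicit string
mkRef <- function(seqstr, chrom = "chr1") {
  Biostrings::DNAStringSet(setNames(seqstr, chrom))
}
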