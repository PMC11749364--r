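# Cross-sample interrogation of editing sites and the two-stage
# differentially-edited-site (DES) procedure: replicate concordance by
# Fisher's exact test, an exact conditional rate test on pooled counts with
# BH adjustment, and a fold-change gate; plus the large-sample rank-sum
# confirmation analysis.

#' Interrogate a set of query sites across samples
#'
#' For every (site, sample) pair, the qualified read support is recounted
#' from the sample's observations: qualified means base quality at least
#' \code{minBaq} and mapping quality at least \code{minMapq} (interrogation
#' uses quality thresholds only; the hexamer exclusion belongs to de novo
#' calling).  A site is qualified in a sample when its total qualified depth
#' reaches \code{minDepth}; the editing level is defined only there.
#' Samples lacking any observation at a site simply leave it unqualified.
#'
#' @param sites query \code{EditingSites} (typically the editome of the
#'   reference cell type).
#' @param obsList named list of observation data.tables, one per sample.
#' @param params a \code{\link{CallerParams}} object.
#' @param colData optional \code{DataFrame}/data.frame of sample metadata
#'   (row order matching \code{obsList}); a \code{cell_type} column is used
#'   by downstream group comparisons.
#' @return an \code{\link{EditingExperiment}} with assays \code{edited},
#'   \code{total}, \code{level} and \code{qualified}.
#' @export
interrogateSites <- function(sites, obsList, params = CallerParams(),
                             colData = NULL) {
  stopifnot(length(obsList) >= 1L, !is.null(names(obsList)))
  n <- length(sites); s <- names(obsList)
  edited <- matrix(0L, n, length(s), dimnames = list(NULL, s))
  total <- matrix(0L, n, length(s), dimnames = list(NULL, s))
  key <- paste(seqnames(sites), start(sites))
  for (j in seq_along(obsList)) {
    q <- .qualifyObs(as.data.table(obsList[[j]]), params, hexamer = FALSE)
    if (!nrow(q)) next
    kq <- paste(q$chrom, q$pos)
    q <- q[kq %in% key]
    if (!nrow(q)) next
    agg <- q[, list(total = .N), by = c("chrom", "pos")]
    i <- match(paste(agg$chrom, agg$pos), key)
    total[i, j] <- agg$total
    vb <- mcols(sites)$var[match(paste(q$chrom, q$pos), key)]
    qv <- q[q$base == vb]
    if (nrow(qv)) {
      aggv <- qv[, list(edited = .N), by = c("chrom", "pos")]
      iv <- match(paste(aggv$chrom, aggv$pos), key)
      edited[iv, j] <- aggv$edited
    }
  }
  qualified <- total >= params@minDepth
  level <- ifelse(total > 0L, edited / total, NA_real_)
  level[!qualified] <- NA_real_
  cd <- if (is.null(colData)) DataFrame(sample_id = s, row.names = s)
        else DataFrame(colData, row.names = s)
  if (!"sample_id" %in% colnames(cd)) cd$sample_id <- s
  se <- SummarizedExperiment(
    assays = list(edited = edited, total = total, level = level,
                  qualified = qualified),
    rowRanges = granges(sites, use.mcols = TRUE), colData = cd)
  new("EditingExperiment", se)
}

#' Replicate concordance by Fisher's exact test
#'
#' Within a cell type, a site is eligible for the differential analysis only
#' when its editing level does not differ significantly between replicates:
#' a two-sided Fisher's exact test on the 2x2 table of (edited, not-edited)
#' reads per replicate must give p >= alpha.
#'
#' @param k1,n1 edited and total qualified reads in replicate 1.
#' @param k2,n2 same for replicate 2.
#' @param alpha concordance level; default 0.05.
#' @return list with \code{p} and logical \code{pass}.
#' @export
replicateConcordance <- function(k1, n1, k2, n2, alpha = 0.05) {
  if (n1 == 0L || n2 == 0L)
    return(list(p = NA_real_, pass = NA))
  p <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2))$p.value
  list(p = p, pass = p >= alpha)
}

#' Exact conditional test of two editing rates ("Poisson test")
#'
#' Tests equality of the editing rates of two groups given pooled counts,
#' normalizing for read coverage: conditional on the total number of edited
#' reads K = k1 + k2, k1 is Binomial(K, n1/(n1+n2)) under the null of equal
#' rates.  The two-sided p-value sums the probabilities of all outcomes no
#' more likely than the observed one (the standard exact two-sided rule).
#'
#' @param k1,n1 pooled edited and total reads in group 1.
#' @param k2,n2 same for group 2.
#' @return the two-sided p-value (1 when K = 0).
#' @export
poissonRateTest <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  if (K == 0L) return(1)
  if (n1 + n2 == 0L) return(1)
  p0 <- n1 / (n1 + n2)
  d <- dbinom(0:K, K, p0)
  # tolerance guard against ties lost to floating-point noise
  min(1, sum(d[d <= d[k1 + 1L] * (1 + 1e-07)]))
}

#' Call differentially edited sites between two groups
#'
#' Per site: (1) every replicate of both groups must be qualified, else the
#' site is ineligible; (2) replicate concordance must pass within each
#' group (all pairwise Fisher tests at \code{concordanceAlpha}); (3)
#' replicates are pooled per group and the exact conditional rate test is
#' applied, BH-adjusted across the sites reaching stage 3; (4) the fold
#' change is the ratio of pooled levels max/min, and a DES requires
#' adjusted p below \code{alpha} and fold change at least \code{minFold}.
#' Direction is the sign of (group B level - group A level).
#'
#' @param ee an \code{\link{EditingExperiment}}.
#' @param groupA,groupB character vectors of sample names (column names of
#'   \code{ee}) forming the two groups.
#' @param alpha significance level on the (adjusted) rate-test p.
#' @param minFold minimum pooled-level fold change; default 2.
#' @param concordanceAlpha replicate-concordance level; default 0.05.
#' @param adjust BH-adjust the rate-test p-values (set \code{FALSE} for raw
#'   p behaviour).
#' @return data.frame with one row per site: pooled counts and levels,
#'   concordance p per group, \code{p}, \code{p_adjusted},
#'   \code{fold_change}, \code{direction} and \code{status} (\code{DES},
#'   \code{not-DES} or \code{ineligible}).
#' @export
callDES <- function(ee, groupA, groupB, alpha = 0.05, minFold = 2,
                    concordanceAlpha = 0.05, adjust = TRUE) {
  stopifnot(all(c(groupA, groupB) %in% colnames(ee)))
  ed <- assay(ee, "edited"); tot <- assay(ee, "total")
  qual <- assay(ee, "qualified")
  n <- nrow(ee)
  concA <- concB <- p <- rep(NA_real_, n)
  kA <- nA <- kB <- nB <- rep(NA_integer_, n)
  eligible <- rep(FALSE, n)
  groupConc <- function(i, grp) {
    if (length(grp) < 2L) return(list(p = NA_real_, pass = TRUE))
    pmin_ <- 1
    for (a in seq_along(grp))
      for (b in seq_along(grp))
        if (a < b) {
          r <- replicateConcordance(ed[i, grp[a]], tot[i, grp[a]],
                                    ed[i, grp[b]], tot[i, grp[b]],
                                    concordanceAlpha)
          pmin_ <- min(pmin_, r$p)
        }
    list(p = pmin_, pass = pmin_ >= concordanceAlpha)
  }
  if (length(groupA) < 2L || length(groupB) < 2L)
    warning("a group has a single replicate; concordance skipped there")
  for (i in seq_len(n)) {
    if (!all(qual[i, c(groupA, groupB)])) next
    ca <- groupConc(i, groupA); cb <- groupConc(i, groupB)
    concA[i] <- ca$p; concB[i] <- cb$p
    if (!isTRUE(ca$pass) || !isTRUE(cb$pass)) next
    eligible[i] <- TRUE
    kA[i] <- sum(ed[i, groupA]); nA[i] <- sum(tot[i, groupA])
    kB[i] <- sum(ed[i, groupB]); nB[i] <- sum(tot[i, groupB])
    p[i] <- poissonRateTest(kA[i], nA[i], kB[i], nB[i])
  }
  p_adj <- rep(NA_real_, n)
  p_adj[eligible] <- if (adjust) p.adjust(p[eligible], "BH") else p[eligible]
  levelA <- kA / nA; levelB <- kB / nB
  fold <- ifelse(pmin(levelA, levelB) > 0,
                 pmax(levelA, levelB) / pmin(levelA, levelB),
                 ifelse(pmax(levelA, levelB) > 0, Inf, 1))
  status <- ifelse(!eligible, "ineligible",
                   ifelse(p_adj < alpha & fold >= minFold, "DES", "not-DES"))
  rr <- rowRanges(ee)
  data.frame(
    chrom = as.character(seqnames(rr)), pos = start(rr),
    edited_a = kA, total_a = nA, edited_b = kB, total_b = nB,
    level_a = levelA, level_b = levelB,
    concordance_p_a = concA, concordance_p_b = concB,
    p = p, p_adjusted = p_adj, fold_change = fold,
    direction = ifelse(eligible,
                       ifelse(levelB > levelA, "up",
                              ifelse(levelB < levelA, "down", "none")),
                       NA_character_),
    status = status, stringsAsFactors = FALSE)
}

#' Rank-sum confirmation of differential editing on a larger sample set
#'
#' For a complete editing-level matrix (sites qualified in every sample),
#' tests each site with a two-sided Wilcoxon rank-sum test between the two
#' groups and BH-adjusts across sites.
#'
#' @param mat numeric matrix, sites x samples, of editing levels with no
#'   missing values.
#' @param groups character/factor of group labels per column (exactly two
#'   levels, each with at least 2 samples).
#' @param alpha significance level on the adjusted p; default 0.05.
#' @return data.frame with per-site \code{p}, \code{p_adjusted} and logical
#'   \code{significant}, in the row order of \code{mat}.
#' @export
confirmDESLargeSet <- function(mat, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups required")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  p <- vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ia]; y <- mat[i, ib]
    if (length(unique(c(x, y))) == 1L) return(1)  # no evidence either way
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  }, 1)
  p_adj <- p.adjust(p, "BH")
  data.frame(site = if (is.null(rownames(mat))) seq_len(nrow(mat))
                    else rownames(mat),
             p = p, p_adjusted = p_adj,
             significant = p_adj < alpha, stringsAsFactors = FALSE)
}

#' Compare median editing levels of two cell types over a common site set
#'
#' @param levels_a,levels_b per-site editing levels over the same
#'   (qualified) site universe.
#' @return list with the two medians, their difference and the two-sided
#'   rank-sum \code{p}.
#' @export
medianLevelComparison <- function(levels_a, levels_b) {
  levels_a <- levels_a[!is.na(levels_a)]
  levels_b <- levels_b[!is.na(levels_b)]
  if (!length(levels_a) || !length(levels_b))
    stop("empty level vectors")
  exact <- length(levels_a) <= 50 && length(levels_b) <= 50
  wt <- suppressWarnings(wilcox.test(levels_a, levels_b, exact = exact))
  list(median_a = median(levels_a), median_b = median(levels_b),
       difference = median(levels_b) - median(levels_a), p = wt$p.value)
}
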