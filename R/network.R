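# Weighted co-editing network: unsigned soft-threshold adjacency,
# topological overlap, average-linkage module detection with a simplified
# hybrid cut (static cut + size floor + eigen-based reassignment of small
# branches), module eigen-profiles, membership and hubs.

#' Build a complete editing-level matrix across samples
#'
#' With \code{requireAll} (the construction used for the co-editing
#' network), only sites qualified in every sample are retained, giving a
#' complete matrix with no missingness.
#'
#' @param ee an \code{\link{EditingExperiment}}.
#' @param requireAll keep only sites qualified in all samples.
#' @return numeric matrix (sites x samples) of editing levels; row names
#'   are \code{chrom:pos} site keys.
#' @export
buildMatrix <- function(ee, requireAll = TRUE) {
  if (ncol(ee) < 3L)
    stop("at least 3 samples are required")
  lv <- assay(ee, "level")
  rr <- rowRanges(ee)
  rownames(lv) <- paste0(seqnames(rr), ":", start(rr))
  if (requireAll) {
    keep <- rowSums(assay(ee, "qualified")) == ncol(ee)
    lv <- lv[keep, , drop = FALSE]
  }
  lv
}

#' Unsigned soft-threshold adjacency
#'
#' \code{a_ij = |cor(x_i, x_j)|^power} with Pearson correlation across
#' samples; the diagonal is 1 by convention and excluded from connectivity
#' sums.  Rows with zero variance are dropped with a warning (their
#' correlations are undefined).
#'
#' @param mat sites x samples level matrix (complete).
#' @param params a \code{\link{NetworkParams}} object.
#' @return symmetric adjacency matrix with entries in [0, 1].
#' @export
adjacencyMatrix <- function(mat, params = NetworkParams()) {
  if (ncol(mat) < 3L) stop("at least 3 samples are required")
  v <- apply(mat, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance site(s) dropped")
    mat <- mat[v > 0, , drop = FALSE]
  }
  a <- abs(cor(t(mat)))^params@power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' for i != j, with connectivity \code{k_i = sum_{u != i} a_iu};
#' \code{TOM_ii = 1}.  The dissimilarity used for clustering is
#' \code{1 - TOM}.
#'
#' @param a symmetric adjacency with entries in [0, 1].
#' @return list with \code{tom} and \code{diss} (= 1 - tom) matrices.
#' @export
tomMatrix <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  a0 <- a; diag(a0) <- 0
  num <- a0 %*% a0 + a0
  k <- rowSums(a0)
  den <- outer(k, k, pmin) + 1 - a0
  tom <- num / den
  diag(tom) <- 1
  list(tom = tom, diss = 1 - tom)
}

.standardizeRows <- function(mat) {
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, sd)
  sdv[sdv == 0] <- 1
  (mat - mu) / sdv
}

.eigenOfBlock <- function(block) {
  # unit-norm first right-singular vector of the standardized block,
  # sign-oriented so the mean correlation with member profiles is positive
  z <- .standardizeRows(block)
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- e / sqrt(sum(e^2))
  mm <- cor(t(block), e)
  if (mean(mm, na.rm = TRUE) < 0) e <- -e
  e
}

#' Module eigen-profiles
#'
#' The eigen-profile of a module is the unit-norm first principal component
#' (first right-singular vector) of the standardized member submatrix,
#' sign-oriented so the mean correlation with member profiles is positive.
#' A singleton module's eigen-profile is its standardized, normalized
#' profile.
#'
#' @param mat sites x samples level matrix.
#' @param labels integer module labels per row (0 = unassigned).
#' @return matrix, modules x samples.
#' @export
moduleEigen <- function(mat, labels) {
  k <- max(labels, 0L)
  if (k == 0L) return(matrix(numeric(), 0, ncol(mat)))
  e <- matrix(NA_real_, k, ncol(mat),
              dimnames = list(paste0("module", seq_len(k)), colnames(mat)))
  for (q in seq_len(k)) {
    block <- mat[labels == q, , drop = FALSE]
    if (!nrow(block)) stop("module ", q, " has no members")
    e[q, ] <- .eigenOfBlock(block)
  }
  e
}

#' Module membership and hub sites
#'
#' MM of site i for module q is the Pearson correlation of the site's level
#' profile with the module's eigen-profile.  Hubs of a module are its own
#' members with MM above \code{hubMmMin}.  Zero-variance profiles have
#' undefined MM and are excluded (NA).
#'
#' @param mat sites x samples level matrix.
#' @param eigens modules x samples eigen-profile matrix.
#' @param labels integer module labels per row of \code{mat}.
#' @param params a \code{\link{NetworkParams}} object.
#' @return list with \code{membership} (sites x modules) and \code{hubs}
#'   (list of site keys per module).
#' @export
moduleMembership <- function(mat, eigens, labels,
                             params = NetworkParams()) {
  k <- nrow(eigens)
  mm <- matrix(NA_real_, nrow(mat), k,
               dimnames = list(rownames(mat), rownames(eigens)))
  v <- apply(mat, 1, sd)
  ok <- v > 0
  if (k > 0 && any(ok))
    mm[ok, ] <- cor(t(mat[ok, , drop = FALSE]), t(eigens))
  hubs <- vector("list", k)
  names(hubs) <- rownames(eigens)
  for (q in seq_len(k)) {
    own <- which(labels == q & ok)
    hubs[[q]] <- rownames(mat)[own][mm[own, q] > params@hubMmMin]
  }
  list(membership = mm, hubs = hubs)
}

#' Detect modules on a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of \code{1 - TOM}, cut at the
#' static height \code{cutHeight}; branches of at least
#' \code{minModuleSize} sites become modules.  Sites in smaller branches
#' are adopted by the module whose eigen-profile they correlate with most,
#' provided the absolute correlation reaches \code{reassignMinCor}; the
#' rest stay unassigned (label 0).  This is a deliberately simplified form
#' of the dynamic hybrid tree cut; planted-structure recovery, not parity
#' with the reference implementation, is the design goal.  Module labels
#' are deterministic: ordered by decreasing size, ties by smallest member
#' key.
#'
#' @param diss square dissimilarity matrix (1 - TOM).
#' @param mat the sites x samples level matrix (used for reassignment).
#' @param params a \code{\link{NetworkParams}} object.
#' @return integer vector of labels (0 = unassigned) named by site key.
#' @export
clusterModules <- function(diss, mat, params = NetworkParams()) {
  n <- nrow(diss)
  keys <- rownames(mat)
  if (is.null(keys)) keys <- as.character(seq_len(n))
  if (n < params@minModuleSize) {
    warning("fewer sites than minModuleSize; all unassigned")
    return(setNames(integer(n), keys))
  }
  hc <- hclust(as.dist(diss), method = "average")
  # a branch counts as a module candidate only when it is both large
  # enough and internally tight (median member-member TOM dissimilarity
  # at or below 0.99) — loose size-floor clusters of chained background
  # are not modules
  .qualityBranches <- function(ct) {
    sz <- table(ct)
    big <- as.integer(names(sz)[sz >= params@minModuleSize])
    keep <- vapply(big, function(b) {
      memb <- which(ct == b)
      dd <- diss[memb, memb][upper.tri(diag(length(memb)))]
      median(dd) <= 0.99
    }, TRUE)
    big[keep]
  }
  h <- params@cutHeight
  if (is.na(h)) {
    # adaptive height: the number of tight size-floor branches is
    # maximized; ties go to the lowest height (least chained background)
    grid <- seq(0.90, 0.999, by = 0.0025)
    nbig <- vapply(grid, function(g) {
      length(.qualityBranches(cutree(hc, h = g)))
    }, 1L)
    h <- grid[which.max(nbig)]
  }
  raw <- cutree(hc, h = h)
  big <- .qualityBranches(raw)
  labels <- integer(n)
  for (j in seq_along(big)) labels[raw == big[j]] <- j
  labels <- .relabelBySize(labels, keys)
  # membership pruning: average linkage lets weakly connected sites chain
  # into a branch, so members are released when their mean topological
  # overlap dissimilarity to co-members is an outlier (median + pruneTomMad
  # MADs, branch-adaptive) or their correlation with the module
  # eigen-profile falls below the floor; a module shrunk below half the
  # size floor dissolves
  for (pass in 1:2) {
    if (max(labels) == 0L) break
    changed <- FALSE
    for (q in seq_len(max(labels))) {
      memb <- which(labels == q)
      if (length(memb) < 3L) next
      dm <- vapply(memb, function(i) mean(diss[i, setdiff(memb, i)]), 1)
      thr <- median(dm) + params@pruneTomMad * stats::mad(dm)
      eig <- .eigenOfBlock(mat[memb, , drop = FALSE])
      mm <- abs(cor(t(mat[memb, , drop = FALSE]), eig))
      weak <- memb[dm > thr | mm < params@pruneMinCor]
      if (length(weak)) { labels[weak] <- 0L; changed <- TRUE }
      if (sum(labels == q) < params@minModuleSize / 2) {
        labels[labels == q] <- 0L; changed <- TRUE
      }
    }
    labels <- .relabelBySize(labels, keys)
    if (!changed) break
  }
  if (max(labels) > 0L && any(labels == 0L)) {
    eig <- moduleEigen(mat, labels)
    loose <- which(labels == 0L)
    cc <- cor(t(mat[loose, , drop = FALSE]), t(eig))
    best <- max.col(abs(cc), ties.method = "first")
    bestcor <- abs(cc)[cbind(seq_along(loose), best)]
    adopt <- bestcor >= params@reassignMinCor
    labels[loose[adopt]] <- best[adopt]
    labels <- .relabelBySize(labels, keys)
  }
  setNames(labels, keys)
}

.relabelBySize <- function(labels, keys) {
  k <- max(labels, 0L)
  if (k == 0L) return(labels)
  info <- lapply(seq_len(k), function(q) {
    members <- keys[labels == q]
    list(q = q, size = length(members), first = min(members))
  })
  ord <- order(-vapply(info, `[[`, 1L, "size"),
               vapply(info, `[[`, "", "first"))
  remap <- integer(k)
  remap[vapply(info, `[[`, 1L, "q")[ord]] <- seq_len(k)
  out <- labels
  out[labels > 0L] <- remap[labels[labels > 0L]]
  out
}

#' Merge modules with highly correlated eigen-profiles
#'
#' Average-linkage clustering of modules on \code{1 - cor(eigen_p,
#' eigen_q)}; clusters joining below \code{mergeCutHeight} are merged and
#' eigen-profiles recomputed.  Merging is idempotent: a second pass changes
#' nothing.
#'
#' @param mat sites x samples level matrix.
#' @param labels integer module labels.
#' @param params a \code{\link{NetworkParams}} object.
#' @return list with updated \code{labels} and \code{eigens}.
#' @export
mergeModules <- function(mat, labels, params = NetworkParams()) {
  keys <- names(labels)
  if (is.null(keys)) keys <- rownames(mat)
  repeat {
    k <- max(labels, 0L)
    eig <- moduleEigen(mat, labels)
    if (k <= 1L) return(list(labels = setNames(labels, keys), eigens = eig))
    d <- 1 - cor(t(eig))
    hc <- hclust(as.dist(d), method = "average")
    grp <- cutree(hc, h = params@mergeCutHeight)
    if (max(grp) == k)
      return(list(labels = setNames(labels, keys), eigens = eig))
    newlab <- labels
    newlab[labels > 0L] <- grp[labels[labels > 0L]]
    labels <- .relabelBySize(newlab, keys)
  }
}

#' Run the complete co-editing network analysis
#'
#' Adjacency, TOM, module detection, merging, eigen-profiles, membership
#' and hubs in one call.
#'
#' @param mat complete sites x samples editing-level matrix (see
#'   \code{\link{buildMatrix}}).
#' @param params a \code{\link{NetworkParams}} object.
#' @return a \code{\link{CoEditingModules}} object.
#' @export
coEditingNetwork <- function(mat, params = NetworkParams()) {
  if (is.null(rownames(mat)))
    rownames(mat) <- as.character(seq_len(nrow(mat)))
  v <- apply(mat, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance site(s) left unassigned")
  }
  use <- v > 0
  a <- adjacencyMatrix(mat[use, , drop = FALSE], params)
  t <- tomMatrix(a)
  lab_use <- clusterModules(t$diss, mat[use, , drop = FALSE], params)
  merged <- mergeModules(mat[use, , drop = FALSE], lab_use, params)
  labels <- setNames(integer(nrow(mat)), rownames(mat))
  labels[names(merged$labels)] <- merged$labels
  mmres <- moduleMembership(mat[use, , drop = FALSE], merged$eigens,
                            merged$labels, params)
  membership <- matrix(NA_real_, nrow(mat), nrow(merged$eigens),
                       dimnames = list(rownames(mat),
                                       rownames(merged$eigens)))
  if (nrow(merged$eigens))
    membership[rownames(mmres$membership), ] <- mmres$membership
  new("CoEditingModules", labels = labels, eigens = merged$eigens,
      membership = membership, hubs = mmres$hubs, params = params)
}
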