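# Planted miRNA target gain/loss fixtures.  For a gain event, a miRNA is
# designed whose complement matches the edited (G) allele of a 3'UTR
# editing site across the site position with a perfect seed, while the
# reference (A) allele breaks the seed pair; enough non-seed mismatches
# are introduced that the broken-seed alignment drops below the score
# threshold.  Loss events are the mirror design against the reference
# allele (the edited allele then carries a G:U wobble at the seed, worth
# less than a Watson-Crick pair but more than a mismatch, hence the larger
# mismatch budget).  Every designed event is verified with the scanner at
# default thresholds before being accepted.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.mismatchBase <- function(q) {
  # a base that neither Watson-Crick- nor wobble-pairs the query base
  bad <- .COMPLEMENT[[q]]
  if (q == "G") bad <- c(bad, "T")
  if (q == "T") bad <- c(bad, "G")
  sample(setdiff(c("A", "C", "G", "T"), bad), 1L)
}

.designMirna <- function(query, site_pos1, n_mismatch, mm_start, b = 13L) {
  # miRNA position j (1-based from its 5' end) pairs query position
  # b + (23 - j); the editing site must land on a seed position
  j_site <- 23L - (site_pos1 - b)
  if (j_site < 2L || j_site > 8L) return(NULL)
  qc <- strsplit(query, "")[[1]]
  m <- character(22L)
  for (j in 1:22) m[j] <- .COMPLEMENT[[qc[b + 23L - j]]]
  mm <- mm_start + seq_len(n_mismatch) - 1L
  if (any(mm <= 8L | mm > 20L)) return(NULL)
  for (j in mm) m[j] <- .mismatchBase(qc[b + 23L - j])
  paste(m, collapse = "")
}

.utr3TruthSites <- function(sim) {
  tr <- sim$truth$sites[sim$truth$sites$class == "utr3"]
  if (!nrow(tr)) return(EditingSites())
  EditingSites(tr$chrom, tr$pos, tr$ref, tr$var,
               ifelse(tr$ref == "A", "+", "-"),
               tr$in_alu, "UTR3", "", 0L, 0L, level = tr$level)
}

#' Simulate a miRNA fixture with planted target gain/loss events
#'
#' Uses the 3'UTR editing sites planted by \code{\link{simulateReference}}.
#' Each gain (loss) event designs a miRNA that passes the default score and
#' energy thresholds on the edited (reference) allele with a hit covering
#' the site, and fails on the other allele; neutral miRNAs are random
#' sequences hitting neither allele.  Designs are verified with
#' \code{\link{scanTargets}} and retried with different binding offsets and mismatch layouts; a
#' design that cannot be realized raises an error.
#'
#' @param sim result of \code{\link{simulateReference}}.
#' @param config the \code{\link{simulationConfig}}.
#' @param params scanner thresholds the fixture must respect.
#' @param outDir if given, writes \code{mirnas.fa} there.
#' @return list with \code{mirnas} (named character, RNA alphabet),
#'   \code{sites} (the 3'UTR \code{EditingSites}) and \code{truth}
#'   (data.table: \code{site_key, mirna_id, class}).
#' @export
simulateMirnaFixture <- function(sim, config, params = ScanParams(),
                                 outDir = NULL) {
  set.seed(config$seed + 23L)
  sites <- .utr3TruthSites(sim)
  n_ev <- config$n_gain_events + config$n_loss_events
  if (length(sites) < n_ev)
    stop("not enough planted 3'UTR sites for the requested events")
  classes <- c(rep("gain", config$n_gain_events),
               rep("loss", config$n_loss_events))
  mirnas <- character(); truth <- list()
  for (k in seq_len(n_ev)) {
    site <- sites[k]
    pair <- buildAlleleQueries(site, sim$ref)
    target_allele <- if (classes[k] == "gain") "edit" else "ref"
    qry <- if (target_allele == "edit") pair$edit_query else pair$ref_query
    n_mm <- if (classes[k] == "gain") 5L else 7L
    ok <- FALSE
    for (try in seq_len(120L)) {
      mm_start <- sample(9:(21L - n_mm), 1L)
      b <- sample(10:16, 1L)   # binding offset: site lands on a seed pos
      m <- .designMirna(qry, pair$site_offset + 1L, n_mm, mm_start, b = b)
      if (is.null(m)) next
      id <- sprintf("mir-%s%02d", classes[k], k)
      h <- scanTargets(pair, setNames(m, id), params)
      cov <- h[h$covers_site, , drop = FALSE]
      on_edit <- "edit" %in% cov$allele
      on_ref <- "ref" %in% cov$allele
      want <- if (classes[k] == "gain") on_edit && !on_ref
              else on_ref && !on_edit
      if (want) {
        mirnas[id] <- chartr("T", "U", m)
        truth[[length(truth) + 1L]] <- data.table(
          site_key = pair$site_key, mirna_id = id, class = classes[k])
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not realize a ", classes[k], " event at ", pair$site_key,
           " after 120 attempts")
  }
  # neutral miRNAs: random sequences with no covering hit on any allele of
  # any fixture site
  for (k in seq_len(config$n_neutral_mirnas)) {
    id <- sprintf("mir-neutral%02d", k)
    for (try in seq_len(40L)) {
      m <- paste(sample(c("A", "C", "G", "T"), 22L, replace = TRUE),
                 collapse = "")
      clean <- TRUE
      for (i in seq_len(min(length(sites), n_ev))) {
        pair <- buildAlleleQueries(sites[i], sim$ref)
        h <- scanTargets(pair, setNames(m, id), params)
        if (nrow(h)) { clean <- FALSE; break }
      }
      if (clean) { mirnas[id] <- chartr("T", "U", m); break }
    }
    if (!id %in% names(mirnas))
      stop("could not generate a neutral miRNA")
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeLines(as.vector(rbind(paste0(">", names(mirnas)),
                               unname(mirnas))),
               file.path(outDir, "mirnas.fa"))
  }
  list(mirnas = mirnas, sites = sites,
       truth = data.table::rbindlist(truth))
}
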