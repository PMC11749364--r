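# miRNA target rewiring at edited 3'UTR positions: dual-allele 61-nt query
# construction, a miRanda-style two-phase scanner (seed-weighted local
# complementarity alignment, then a nearest-neighbor duplex-energy gate)
# and per-miRNA gain/loss classification.  The scanner follows miRanda's
# architecture and default-like scoring table but does not promise parity
# with the miRanda binary.

.normalizeSeq <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x)
}

.BASE_PAIRS <- local({
  wc <- c(AT = TRUE, TA = TRUE, CG = TRUE, GC = TRUE)
  wob <- c(GT = TRUE, TG = TRUE)
  list(wc = names(wc), wobble = names(wob))
})

.pairType <- function(q, m) {
  # q: query (mRNA sense) base, m: miRNA base, both DNA alphabet
  key <- paste0(q, m)
  ifelse(key %in% .BASE_PAIRS$wc, "match",
         ifelse(key %in% .BASE_PAIRS$wobble, "wobble", "mismatch"))
}

#' Build reference/edited allele queries around an editing site
#'
#' Extracts \code{flank} bases either side of the editing position on the
#' transcript strand (reverse-complemented for minus-strand sites), giving
#' a 61-nt query by default.  The reference query carries A at the site
#' offset and the edited query G (transcript sense).  Sites closer than
#' \code{flank} to a contig end yield truncated queries with the offset
#' adjusted and \code{truncated = TRUE}.
#'
#' @param site a single-site \code{EditingSites} (strand must be + or -).
#' @param refseq reference \code{DNAStringSet}.
#' @param flank bases of context either side; default 30.
#' @return list with \code{site_key}, \code{ref_query}, \code{edit_query},
#'   \code{site_offset} (0-based index of the edited base within the
#'   query) and \code{truncated}.
#' @export
buildAlleleQueries <- function(site, refseq, flank = 30L) {
  stopifnot(length(site) == 1L)
  str <- as.character(strand(site))
  if (!str %in% c("+", "-"))
    stop("site strand must be known (+/-) to build transcript-sense queries")
  chrom <- as.character(seqnames(site)); pos <- start(site)
  if (!chrom %in% names(refseq))
    stop("reference sequence missing for chromosome ", chrom)
  L <- Biostrings::nchar(refseq[[chrom]])
  lo <- max(1L, pos - flank); hi <- min(L, pos + flank)
  truncated <- (lo != pos - flank) || (hi != pos + flank)
  s <- subseq(refseq[[chrom]], lo, hi)
  if (str == "-") {
    s <- reverseComplement(s)
    offset <- hi - pos
  } else {
    offset <- pos - lo
  }
  refq <- as.character(s)
  base <- substr(refq, offset + 1L, offset + 1L)
  if (base != "A")
    stop("transcript-sense reference base at the site is ", base,
         ", expected A")
  editq <- refq
  substr(editq, offset + 1L, offset + 1L) <- "G"
  list(site_key = paste0(chrom, ":", pos), ref_query = refq,
       edit_query = editq, site_offset = as.integer(offset),
       truncated = truncated)
}

#' Seed-weighted local alignment of a miRNA against a query
#'
#' Gotoh local alignment of the miRNA (3'->5') against the query (5'->3'),
#' scoring Watson-Crick pairs, G:U wobbles, mismatches and affine gaps;
#' substitution scores at miRNA seed positions (\code{seedStart}..
#' \code{seedEnd} from the miRNA 5' end) are multiplied by
#' \code{seedScale}.  Deterministic: ties are broken by leftmost query
#' start, then shortest span.
#'
#' @param query query sequence, 5'->3' (DNA or RNA alphabet).
#' @param mirna mature miRNA sequence, 5'->3'.
#' @param params a \code{\link{ScanParams}} object.
#' @return list with \code{score}, 1-based query span \code{q_start},
#'   \code{q_end}, and \code{pairs}: a data.frame of aligned columns with
#'   \code{q_pos}, \code{m_pos} (1-based from the miRNA 5' end; NA at
#'   gaps), bases and pair \code{type}.
#' @export
alignMirna <- function(query, mirna, params = ScanParams()) {
  q <- strsplit(.normalizeSeq(query), "")[[1]]
  m5 <- strsplit(.normalizeSeq(mirna), "")[[1]]
  if (!all(q %in% c("A", "C", "G", "T")) ||
      !all(m5 %in% c("A", "C", "G", "T")))
    stop("non-nucleotide character in input sequence")
  nm <- length(m5)
  m <- rev(m5)                       # aligned 3'->5'
  mpos <- nm:1                       # miRNA 5'-based position per column
  seedcol <- mpos >= params@seedStart & mpos <= params@seedEnd
  nq <- length(q)
  sub <- matrix(0, nq, nm)
  for (j in seq_len(nm)) {
    ty <- .pairType(q, m[j])
    sc <- ifelse(ty == "match", params@matchScore,
                 ifelse(ty == "wobble", params@wobbleScore,
                        params@mismatchScore))
    if (seedcol[j]) sc <- sc * params@seedScale
    sub[, j] <- sc
  }
  NEG <- -1e9
  H <- matrix(0, nq + 1L, nm + 1L)
  E <- matrix(NEG, nq + 1L, nm + 1L)  # gap in miRNA (consume query)
  F <- matrix(NEG, nq + 1L, nm + 1L)  # gap in query (consume miRNA)
  ptr <- matrix(0L, nq + 1L, nm + 1L) # 1 diag, 2 up (E), 3 left (F)
  for (i in seq_len(nq) + 1L) {
    for (j in seq_len(nm) + 1L) {
      E[i, j] <- max(H[i - 1L, j] + params@gapOpen,
                     E[i - 1L, j] + params@gapExtend)
      F[i, j] <- max(H[i, j - 1L] + params@gapOpen,
                     F[i, j - 1L] + params@gapExtend)
      d <- H[i - 1L, j - 1L] + sub[i - 1L, j - 1L]
      best <- max(0, d, E[i, j], F[i, j])
      H[i, j] <- best
      ptr[i, j] <- if (best == 0) 0L else if (best == d) 1L
                   else if (best == E[i, j]) 2L else 3L
    }
  }
  smax <- max(H)
  if (smax <= 0)
    return(list(score = 0, q_start = NA_integer_, q_end = NA_integer_,
                pairs = NULL))
  ends <- which(H == smax, arr.ind = TRUE)
  cand <- lapply(seq_len(nrow(ends)), function(r) {
    .tracebackAlign(ends[r, 1], ends[r, 2], H, E, F, ptr, q, m, mpos,
                    params)
  })
  starts <- vapply(cand, function(x) x$q_start, 1L)
  spans <- vapply(cand, function(x) x$q_end - x$q_start, 1L)
  ord <- order(starts, spans)
  out <- cand[[ord[1]]]
  out$score <- smax
  out
}

.tracebackAlign <- function(i, j, H, E, F, ptr, q, m, mpos, params) {
  cols <- list()
  state <- "H"
  while (i > 1L || j > 1L) {
    if (state == "H") {
      pt <- ptr[i, j]
      if (pt == 0L) break
      if (pt == 1L) {
        ty <- .pairType(q[i - 1L], m[j - 1L])
        cols[[length(cols) + 1L]] <- list(q_pos = i - 1L,
                                          m_pos = mpos[j - 1L],
                                          q_base = q[i - 1L],
                                          m_base = m[j - 1L], type = ty)
        i <- i - 1L; j <- j - 1L
      } else if (pt == 2L) state <- "E" else state <- "F"
    } else if (state == "E") {
      cols[[length(cols) + 1L]] <- list(q_pos = i - 1L, m_pos = NA_integer_,
                                        q_base = q[i - 1L], m_base = "-",
                                        type = "gap")
      from_open <- (E[i, j] == H[i - 1L, j] + params@gapOpen)
      i <- i - 1L
      if (from_open) state <- "H"
    } else {
      cols[[length(cols) + 1L]] <- list(q_pos = NA_integer_,
                                        m_pos = mpos[j - 1L], q_base = "-",
                                        m_base = m[j - 1L], type = "gap")
      from_open <- (F[i, j] == H[i, j - 1L] + params@gapOpen)
      j <- j - 1L
      if (from_open) state <- "H"
    }
  }
  pairs <- do.call(rbind, lapply(rev(cols), as.data.frame))
  qpos <- pairs$q_pos[!is.na(pairs$q_pos)]
  list(q_start = min(qpos), q_end = max(qpos), pairs = pairs)
}

# ---------------------------------------------------------------------------
# Duplex energy
# ---------------------------------------------------------------------------

# Nearest-neighbor stacking free energies (kcal/mol, 37 degrees C) for the
# ten Watson-Crick RNA stacks of the standard parameter set.  Keys read
# 5'-XY-3' on the mRNA strand over its paired miRNA dinucleotide; the same
# stack read from the other strand is looked up by symmetry.  Stacks
# containing a G:U wobble are approximated by a single constant; internal
# loops and bulges incur a fixed penalty per event.  More extensive pairing
# therefore always lowers (improves) the energy.
.NN_STACK <- c(
  "AA/UU" = -0.93, "AU/AU" = -1.10, "UA/UA" = -1.33,
  "CU/AG" = -2.08, "CA/UG" = -2.11, "GU/AC" = -2.24,
  "GA/UC" = -2.35, "CG/CG" = -2.36, "GG/CC" = -3.26, "GC/GC" = -3.42)
.NN_WOBBLE <- -1.0
.LOOP_PENALTY <- 3.0

.stackKey <- function(q1, q2, m1, m2) {
  # 5'-q1 q2-3' paired with 3'-m1 m2-5'; canonical table keys are written
  # "top/bottom" with the bottom strand reported 5'->3' (i.e. m2 m1)
  paste0(q1, q2, "/", m2, m1)
}

.toRNA <- function(x) chartr("T", "U", x)

#' Duplex energy of an aligned miRNA-target pair
#'
#' Nearest-neighbor stacking sum over consecutive paired alignment columns
#' (Watson-Crick stacks from the standard 37 degree parameter set; stacks
#' containing a G:U wobble use a constant approximation), plus a fixed
#' penalty per internal loop or bulge separating helices.  An alignment
#' with no paired columns has energy 0.
#'
#' @param alignment result of \code{\link{alignMirna}} (uses
#'   \code{$pairs}).
#' @return estimated free energy in kcal/mol (more negative = more stable).
#' @export
duplexEnergy <- function(alignment) {
  pairs <- alignment$pairs
  if (is.null(pairs) || !nrow(pairs)) return(0)
  paired <- pairs$type %in% c("match", "wobble")
  if (!any(paired)) return(0)
  e <- 0
  helix_open <- FALSE
  prev <- NULL
  for (r in seq_len(nrow(pairs))) {
    if (!paired[r]) {
      helix_open <- FALSE
      next
    }
    if (!is.null(prev) && helix_open) {
      q1 <- .toRNA(pairs$q_base[prev]); q2 <- .toRNA(pairs$q_base[r])
      m1 <- .toRNA(pairs$m_base[prev]); m2 <- .toRNA(pairs$m_base[r])
      key <- .stackKey(q1, q2, m1, m2)
      val <- .NN_STACK[key]
      if (is.na(val)) {
        # same stack read from the complementary strand
        key2 <- .stackKey(m2, m1, q2, q1)
        val <- .NN_STACK[key2]
      }
      if (is.na(val)) val <- .NN_WOBBLE
      e <- e + unname(val)
    }
    helix_open <- TRUE
    prev <- r
  }
  # one penalty per internal loop/bulge, i.e. per interruption with pairing
  # resuming afterwards
  resumed <- which(paired)
  n_loops <- 0L
  if (length(resumed) > 1L) {
    gaps_between <- vapply(seq_len(length(resumed) - 1L), function(k) {
      resumed[k + 1L] - resumed[k] > 1L
    }, TRUE)
    n_loops <- sum(gaps_between)
  }
  e + .LOOP_PENALTY * n_loops
}

#' Scan both allele queries for miRNA target hits
#'
#' A hit is a miRNA whose best alignment on a query reaches the score
#' threshold and whose duplex energy passes the energy gate;
#' \code{covers_site} records whether the alignment span contains the
#' editing position.
#'
#' @param pair allele query pair from \code{\link{buildAlleleQueries}}.
#' @param mirnas named character vector or \code{DNAStringSet}/RNAStringSet
#'   of mature miRNA sequences.
#' @param params a \code{\link{ScanParams}} object.
#' @return data.frame of hits: \code{mirna_id, allele, span_start,
#'   span_end} (0-based half-open on the query), \code{score, energy,
#'   covers_site}.
#' @export
scanTargets <- function(pair, mirnas, params = ScanParams()) {
  seqs <- vapply(as.list(mirnas), function(x) .normalizeSeq(x), "")
  hits <- list()
  for (allele in c("ref", "edit")) {
    qry <- if (allele == "ref") pair$ref_query else pair$edit_query
    for (id in names(seqs)) {
      al <- alignMirna(qry, seqs[[id]], params)
      if (al$score < params@scoreMin) next
      en <- duplexEnergy(al)
      if (en > params@energyMax) next
      hits[[length(hits) + 1L]] <- data.frame(
        mirna_id = id, allele = allele,
        span_start = al$q_start - 1L, span_end = al$q_end,
        score = al$score, energy = en,
        covers_site = pair$site_offset >= al$q_start - 1L &
          pair$site_offset < al$q_end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(mirna_id = character(), allele = character(),
                      span_start = integer(), span_end = integer(),
                      score = numeric(), energy = numeric(),
                      covers_site = logical()))
  do.call(rbind, hits)
}

#' Classify per-miRNA target change between the two alleles
#'
#' Only hits covering the editing position count.  A miRNA gains a target
#' when it has a covering hit on the edited allele only, loses one when on
#' the reference allele only; otherwise \code{present_both} or
#' \code{absent_both}.
#'
#' @param hits data.frame from \code{\link{scanTargets}} (both alleles).
#' @param mirna_ids the full set of scanned miRNA ids (needed to report
#'   \code{absent_both}).
#' @return data.frame with \code{mirna_id} and \code{class}.
#' @export
classifyTargetChange <- function(hits, mirna_ids) {
  cov <- hits[hits$covers_site, , drop = FALSE]
  on_ref <- mirna_ids %in% cov$mirna_id[cov$allele == "ref"]
  on_edit <- mirna_ids %in% cov$mirna_id[cov$allele == "edit"]
  cls <- ifelse(on_ref & on_edit, "present_both",
                ifelse(on_edit, "gain",
                       ifelse(on_ref, "loss", "absent_both")))
  data.frame(mirna_id = mirna_ids, class = cls, stringsAsFactors = FALSE)
}

#' Scan a set of 3'UTR editing sites for target rewiring
#'
#' Convenience wrapper: builds allele queries for every site, scans all
#' miRNAs on both alleles and classifies the per-miRNA change.
#'
#' @param sites \code{EditingSites} with known strand.
#' @param refseq reference \code{DNAStringSet}.
#' @param mirnas named miRNA sequences.
#' @param params a \code{\link{ScanParams}} object.
#' @return list with \code{hits} and \code{changes} data.frames (both
#'   keyed by \code{site_key}).
#' @export
scanRetargeting <- function(sites, refseq, mirnas, params = ScanParams()) {
  ids <- names(mirnas)
  all_hits <- list(); all_changes <- list()
  for (i in seq_along(sites)) {
    pair <- buildAlleleQueries(sites[i], refseq)
    h <- scanTargets(pair, mirnas, params)
    ch <- classifyTargetChange(h, ids)
    if (nrow(h)) h$site_key <- pair$site_key
    ch$site_key <- pair$site_key
    all_hits[[i]] <- h
    all_changes[[i]] <- ch
  }
  list(hits = do.call(rbind, all_hits[vapply(all_hits, nrow, 1L) > 0]),
       changes = do.call(rbind, all_changes))
}
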