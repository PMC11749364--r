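# Candidate variant calling from read-base observations and the filter
# cascade producing an editome.  Candidates travel as a data.table with one
# audit column per filter (pass_*); a candidate is retained iff every audit
# flag is TRUE.  All filters are subtractive: they only set flags, so the
# cascade is idempotent and (apart from the hexamer exclusion, which acts on
# observations before counting) order-independent.

.qualifyObs <- function(obs, params, hexamer = TRUE) {
  keep <- obs$base != "N" & obs$baq >= params@minBaq &
    obs$mapq >= params@minMapq
  if (hexamer) keep <- keep & obs$read_pos > params@hexamerPrefixLen
  obs[keep]
}

#' Exclude observations from the read-start hexamer prefix
#'
#' Random-hexamer priming can introduce false mismatches at the first bases
#' of a read, so observations with \code{read_pos} at or below
#' \code{prefixLen} are dropped before any counting.  This is applied to RNA
#' observations only; it is an artifact of the RNA library preparation.
#'
#' @param obs observation data.table (see \code{\link{readObservations}}).
#' @param prefixLen prefix length; default 6.
#' @return the observations with prefix rows removed.
#' @export
filterHexamerPrefix <- function(obs, prefixLen = 6L) {
  obs[obs$read_pos > prefixLen]
}

#' Call candidate RNA variants from one sample's observations
#'
#' An observation is qualified iff its base quality is at least
#' \code{minBaq}, its mapping quality at least \code{minMapq} and its
#' position within the read beyond the hexamer prefix.  A candidate is
#' emitted at every position where the qualified depth reaches
#' \code{minDepth} and the most frequent non-reference base has at least
#' \code{minVariantReads} qualified supports; the editing level is the
#' variant fraction of the qualified depth.  A tie between two variant
#' bases is broken by the higher summed base quality; a persistent tie drops
#' the column (recorded in \code{attr(,"dropped_ties")}).
#'
#' @param obs observation data.table for a single sample, sorted by
#'   \code{(chrom, pos)}.
#' @param params a \code{\link{CallerParams}} object.
#' @return a data.table of candidates with columns \code{chrom, pos, ref,
#'   var, edited_reads, total_reads, level} and (initially empty) audit
#'   flags.
#' @export
callCandidates <- function(obs, params = CallerParams()) {
  obs <- as.data.table(obs)
  if (length(unique(obs$sample_id)) > 1L)
    stop("callCandidates expects observations from a single sample")
  if (nrow(obs) > 1L) {
    ok <- all(diff(obs$pos)[obs$chrom[-1L] == obs$chrom[-nrow(obs)]] >= 0L)
    if (!ok) stop("observations must be sorted by (chrom, pos)")
  }
  qual <- .qualifyObs(obs, params, hexamer = TRUE)
  empty <- data.table(chrom = character(), pos = integer(),
                      ref = character(), var = character(),
                      edited_reads = integer(), total_reads = integer(),
                      level = numeric())
  if (!nrow(qual)) return(empty)
  counts <- qual[, list(n = .N, bq = sum(baq)),
                 by = c("chrom", "pos", "ref", "base")]
  depth <- counts[, list(total_reads = sum(n)), by = c("chrom", "pos", "ref")]
  vr <- counts[counts$base != counts$ref]
  if (!nrow(vr)) return(empty)
  setorder(vr, chrom, pos, -n, -bq, base)
  top <- vr[, head(.SD, 2L), by = c("chrom", "pos", "ref")]
  first <- top[, head(.SD, 1L), by = c("chrom", "pos", "ref")]
  second <- top[, if (.N > 1L) .SD[2L], by = c("chrom", "pos", "ref")]
  tied <- merge(first, second, by = c("chrom", "pos", "ref"),
                suffixes = c("", ".2"))
  tied <- tied[tied$n == tied$n.2 & tied$bq == tied$bq.2]
  cands <- merge(first, depth, by = c("chrom", "pos", "ref"))
  if (nrow(tied)) {
    key <- paste(cands$chrom, cands$pos)
    cands <- cands[!key %in% paste(tied$chrom, tied$pos)]
  }
  cands <- cands[cands$total_reads >= params@minDepth &
                 cands$n >= params@minVariantReads]
  out <- cands[, list(chrom = chrom, pos = pos, ref = ref, var = base,
                      edited_reads = n, total_reads = total_reads,
                      level = n / total_reads)]
  setorder(out, chrom, pos)
  attr(out, "dropped_ties") <- nrow(tied)
  out[]
}

.candGR <- function(cands) {
  GRanges(cands$chrom, IRanges(cands$pos, width = 1L), strand = "*")
}

#' Remove candidates contradicted (or unsupported) by genomic reads
#'
#' A candidate passes only when the DNA evidence is both sufficient and
#' clean: qualified DNA depth at least \code{minDnaDepth} and at most
#' \code{maxDnaVariantReads} DNA reads carrying the candidate's variant
#' base.  Candidates with insufficient DNA coverage are removed as
#' unassessable.  DNA observations are qualified on base and mapping
#' quality only (the hexamer exclusion is an RNA library artifact).
#'
#' @param cands candidate data.table from \code{\link{callCandidates}}.
#' @param dna_obs DNA observation data.table.
#' @param params a \code{\link{CallerParams}} object.
#' @return \code{cands} with an added logical \code{pass_genomic} column.
#' @export
filterGenomicEvidence <- function(cands, dna_obs, params = CallerParams()) {
  dq <- .qualifyObs(as.data.table(dna_obs), params, hexamer = FALSE)
  dd <- dq[, list(dna_depth = .N), by = c("chrom", "pos")]
  cands <- merge(cands, dd, by = c("chrom", "pos"), all.x = TRUE)
  cands$dna_depth[is.na(cands$dna_depth)] <- 0L
  dv <- dq[, list(dna_var = .N), by = c("chrom", "pos", "base")]
  cands <- merge(cands, dv,
                 by.x = c("chrom", "pos", "var"),
                 by.y = c("chrom", "pos", "base"), all.x = TRUE)
  cands$dna_var[is.na(cands$dna_var)] <- 0L
  cands$pass_genomic <- cands$dna_depth >= params@minDnaDepth &
    cands$dna_var <= params@maxDnaVariantReads
  cands$dna_depth <- cands$dna_var <- NULL
  setorder(cands, chrom, pos)
  cands[]
}

#' Remove candidates at known variant positions
#'
#' Exclusion is by position only (any alternate allele at the position
#' disqualifies the candidate), across any number of variant sets (for
#' example dbSNP, 1000 Genomes and an exome-project call set).
#'
#' @param cands candidate data.table.
#' @param variantSets a \code{GRanges} (from
#'   \code{\link{readVariantPositions}}) or a list of them.
#' @return \code{cands} with an added logical \code{pass_snp} column.
#' @export
filterKnownVariants <- function(cands, variantSets) {
  if (is(variantSets, "GRanges")) variantSets <- list(variantSets)
  hit <- rep(FALSE, nrow(cands))
  if (nrow(cands)) {
    gr <- .candGR(cands)
    for (vs in variantSets)
      if (length(vs)) hit <- hit | overlapsAny(gr, vs, ignore.strand = TRUE)
  }
  cands$pass_snp <- !hit
  cands[]
}

.homopolymerCovers <- function(refseq, chrom, pos, run) {
  # TRUE iff a run of >= `run` identical reference bases includes pos
  if (!chrom %in% names(refseq))
    stop("reference sequence missing for chromosome ", chrom)
  L <- Biostrings::nchar(refseq[[chrom]])
  lo <- max(1L, pos - (run - 1L)); hi <- min(L, pos + (run - 1L))
  win <- strsplit(as.character(subseq(refseq[[chrom]], lo, hi)), "")[[1]]
  r <- rle(win)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  p <- pos - lo + 1L
  any(r$lengths >= run & starts <= p & ends >= p)
}

.spliceDistance <- function(cands, genes) {
  # distance (in bases, 1 = adjacent) from each candidate to the nearest
  # exon-intron boundary, for candidates lying inside an intron; Inf
  # otherwise.  Introns are gene spans minus exons, computed per gene.
  out <- rep(Inf, nrow(cands))
  if (!nrow(cands)) return(out)
  gr <- .candGR(cands)
  g <- genes(genes); ex <- geneExons(genes)
  introns <- GRanges()
  for (i in seq_along(g)) {
    gid <- mcols(g)$gene_id[i]
    exg <- ex[mcols(ex)$gene_id == gid]
    if (!length(exg)) next
    intr <- GenomicRanges::setdiff(granges(g[i]), granges(exg),
                                   ignore.strand = TRUE)
    if (length(intr)) introns <- c(introns, intr)
  }
  if (!length(introns)) return(out)
  ov <- findOverlaps(gr, introns, ignore.strand = TRUE)
  if (length(ov)) {
    p <- start(gr)[S4Vectors::queryHits(ov)]
    s <- start(introns)[S4Vectors::subjectHits(ov)]
    e <- end(introns)[S4Vectors::subjectHits(ov)]
    d <- pmin(p - s + 1L, e - p + 1L)
    agg <- tapply(d, S4Vectors::queryHits(ov), min)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Apply the non-Alu filter battery
#'
#' Candidates inside the Alu mask are exempt; the remaining candidates fail
#' if their level is below \code{nonAluMinFreq}, if they are intronic within
#' \code{spliceFlankBp} bases of an exon-intron boundary, if the reference
#' context contains a homopolymer run of \code{homopolymerMinRun} or more
#' identical bases covering the site, or if they fall in the
#' genome-similarity mask.  Each rule gets its own audit flag
#' (\code{pass_freq}, \code{pass_splice}, \code{pass_homopolymer},
#' \code{pass_similarity}); \code{in_alu} is recorded as a column.
#'
#' @param cands candidate data.table.
#' @param alu Alu mask \code{GRanges} (see \code{\link{readIntervalMask}}).
#' @param genes a \code{\link{GeneModels}} object.
#' @param refseq reference \code{DNAStringSet}.
#' @param similarity genome-similarity mask \code{GRanges}.
#' @param params a \code{\link{CallerParams}} object.
#' @return \code{cands} with \code{in_alu} and the four audit flags added.
#' @export
applyNonAluFilters <- function(cands, alu, genes, refseq, similarity,
                               params = CallerParams()) {
  n <- nrow(cands)
  gr <- .candGR(cands)
  in_alu <- if (n) overlapsAny(gr, alu, ignore.strand = TRUE) else logical()
  cands$in_alu <- in_alu
  cands$pass_freq <- in_alu | cands$level >= params@nonAluMinFreq
  d <- .spliceDistance(cands, genes)
  cands$pass_splice <- in_alu | d > params@spliceFlankBp
  homo <- logical(n)
  idx <- which(!in_alu)
  for (i in idx)
    homo[i] <- .homopolymerCovers(refseq, cands$chrom[i], cands$pos[i],
                                  params@homopolymerMinRun)
  cands$pass_homopolymer <- in_alu | !homo
  insim <- if (n) overlapsAny(gr, similarity, ignore.strand = TRUE)
           else logical()
  cands$pass_similarity <- in_alu | !insim
  cands[]
}

#' Which candidates survive every filter so far
#'
#' @param cands candidate data.table with any number of \code{pass_*}
#'   audit columns.
#' @return logical vector.
#' @export
retainedCandidates <- function(cands) {
  flags <- grep("^pass_", names(cands), value = TRUE)
  if (!length(flags)) return(rep(TRUE, nrow(cands)))
  Reduce(`&`, lapply(flags, function(f) cands[[f]]))
}

#' Convert retained candidates into an EditingSites object
#'
#' Strand is unknown (\code{*}) and the region class \code{intergenic}
#' until \code{\link{assignStrand}} and \code{\link{annotateRegion}} are
#' applied.
#'
#' @param cands candidate data.table.
#' @param onlyRetained drop candidates with a failed audit flag first.
#' @return an \code{EditingSites} object.
#' @export
candidatesToSites <- function(cands, onlyRetained = TRUE) {
  if (onlyRetained) cands <- cands[retainedCandidates(cands)]
  in_alu <- if ("in_alu" %in% names(cands)) cands$in_alu
            else rep(NA, nrow(cands))
  EditingSites(cands$chrom, cands$pos, cands$ref, cands$var, "*",
               in_alu, "intergenic", "", cands$edited_reads,
               cands$total_reads, cands$level)
}

#' Assign transcriptional strand from gene models
#'
#' A site gets a strand only when all overlapping gene models agree; if no
#' gene overlaps, or overlapping genes lie on both strands, the strand stays
#' unknown and the substitution type stays genomic.  On minus-strand
#' assignment the substitution is re-expressed on the transcribed strand
#' (a genomic T>C becomes A>G).
#'
#' @param sites an \code{EditingSites} object.
#' @param genes a \code{\link{GeneModels}} object.
#' @return the sites with strand and \code{subst_type} updated.
#' @export
assignStrand <- function(sites, genes) {
  if (!length(sites)) return(sites)
  g <- genes(genes)
  ov <- findOverlaps(granges(sites), g, ignore.strand = TRUE)
  str <- rep("*", length(sites))
  if (length(ov)) {
    sh <- split(as.character(strand(g))[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    uni <- vapply(sh, function(x) {
      u <- unique(x); if (length(u) == 1L) u else "*"
    }, "")
    str[as.integer(names(uni))] <- uni
  }
  m <- mcols(sites)
  strand(sites) <- str
  ref_s <- ifelse(str == "-", .complementBase(m$ref), m$ref)
  var_s <- ifelse(str == "-", .complementBase(m$var), m$var)
  mcols(sites)$subst_type <- paste0(ref_s, ">", var_s)
  validObject(sites)
  sites
}

#' Intersect the editomes of two replicates
#'
#' A site is shared iff the same (chrom, pos, variant base) was called in
#' both replicates.  Shared sites keep both replicates' read support
#' (columns \code{edited_reads2}, \code{total_reads2}, \code{level2} from
#' replicate 2); replicate-specific sites are returned for the depth
#' comparison.
#'
#' @param rep1,rep2 \code{EditingSites} from the two replicates.
#' @return a list with elements \code{shared}, \code{rep1_specific} and
#'   \code{rep2_specific}.
#' @export
intersectReplicates <- function(rep1, rep2) {
  key <- function(s) paste(seqnames(s), start(s), mcols(s)$var)
  k1 <- key(rep1); k2 <- key(rep2)
  shared <- rep1[k1 %in% k2]
  if (length(shared)) {
    i2 <- match(key(shared), k2)
    mcols(shared)$edited_reads2 <- mcols(rep2)$edited_reads[i2]
    mcols(shared)$total_reads2 <- mcols(rep2)$total_reads[i2]
    mcols(shared)$level2 <- mcols(rep2)$level[i2]
  }
  list(shared = shared,
       rep1_specific = rep1[!k1 %in% k2],
       rep2_specific = rep2[!k2 %in% k1])
}

#' Run the full site-discovery cascade for every sample of a sample sheet
#'
#' For each sample: qualify observations (quality thresholds plus hexamer
#' exclusion), call candidates, filter on genomic evidence, known variants
#' and the non-Alu battery, assign strand and annotate regions.  Cell types
#' with exactly two replicates additionally get a replicate-intersection
#' table.  Per-filter attrition counts are recorded, and all outputs are
#' deterministic given the inputs.
#'
#' @param sampleSheet data.table from \code{\link{readSampleSheet}}.
#' @param params a \code{\link{CallerParams}} object.
#' @param resources a list with elements \code{ref} (DNAStringSet),
#'   \code{genes} (GeneModels), \code{alu}, \code{similarity} (GRanges
#'   masks), \code{snps} (GRanges or list of GRanges; may be empty) and
#'   \code{dnaObs} (DNA observation data.table).
#' @param outDir if given, site tables, shared-site tables and the
#'   attrition audit TSV are written there.
#' @return a list with \code{sites} (named list of \code{EditingSites} per
#'   sample), \code{shared} (named list per cell type with two replicates),
#'   and \code{attrition} (data.table of per-filter survivor counts).
#' @export
runSiteDiscovery <- function(sampleSheet, params = CallerParams(),
                             resources, outDir = NULL) {
  stopifnot(all(c("ref", "genes", "alu", "similarity", "dnaObs")
                %in% names(resources)))
  snps <- resources$snps
  if (is.null(snps)) snps <- GRanges()
  persample <- list(); attr_rows <- list()
  for (i in seq_len(nrow(sampleSheet))) {
    sid <- sampleSheet$sample_id[i]
    obs <- readObservations(sampleSheet$path[i], sample_id = sid)
    cands <- callCandidates(obs, params)
    n0 <- nrow(cands)
    cands <- filterGenomicEvidence(cands, resources$dnaObs, params)
    cands <- filterKnownVariants(cands, snps)
    cands <- applyNonAluFilters(cands, resources$alu, resources$genes,
                                resources$ref, resources$similarity, params)
    surv <- function(flags) {
      keep <- rep(TRUE, nrow(cands))
      for (f in flags) keep <- keep & cands[[f]]
      sum(keep)
    }
    cascade <- c("pass_genomic", "pass_snp", "pass_freq", "pass_splice",
                 "pass_homopolymer", "pass_similarity")
    counts <- integer(length(cascade) + 1L)
    counts[1] <- n0
    for (k in seq_along(cascade)) counts[k + 1L] <- surv(cascade[seq_len(k)])
    attr_rows[[sid]] <- data.table(
      sample_id = sid, stage = c("candidates", cascade),
      survivors = counts,
      removed = c(0L, -diff(counts)))
    sites <- candidatesToSites(cands)
    sites <- assignStrand(sites, resources$genes)
    sites <- annotateRegion(sites, resources$genes)
    persample[[sid]] <- sites
  }
  shared <- list()
  for (ct in unique(sampleSheet$cell_type)) {
    ids <- sampleSheet$sample_id[sampleSheet$cell_type == ct]
    if (length(ids) == 2L)
      shared[[ct]] <- intersectReplicates(persample[[ids[1]]],
                                          persample[[ids[2]]])
  }
  attrition <- data.table::rbindlist(attr_rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(persample))
      writeSiteTable(persample[[sid]],
                     file.path(outDir, paste0(sid, ".sites.tsv")))
    for (ct in names(shared))
      writeSiteTable(shared[[ct]]$shared,
                     file.path(outDir, paste0(ct, ".shared.tsv")))
    fwrite(attrition, file.path(outDir, "attrition.tsv"), sep = "\t")
  }
  list(sites = persample, shared = shared, attrition = attrition)
}

#' @importFrom data.table as.data.table
NULL
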