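#' @import methods
#' @importFrom stats cor dbinom dpois fisher.test median p.adjust phyper
#'   prcomp quantile rbeta rbinom rnorm rpois runif sd setNames var wilcox.test
#'   chisq.test as.dist cutree hclust
#' @importFrom utils head read.table tail write.table packageVersion
#' @importFrom data.table data.table fread fwrite setkey setorder := .N .SD
#' @importFrom BiocGenerics sort start end width strand
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame Rle
#' @importFrom IRanges IRanges reduce findOverlaps overlapsAny
#' @importFrom GenomicRanges GRanges seqnames strand<- granges GRangesList
#' @importFrom GenomeInfoDb seqlevels seqlengths seqinfo
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq DNAString
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData assayNames
NULL

.REGION_CLASSES <- c("CDS", "UTR3", "UTR5", "ncRNA_exonic", "intronic",
                     "ncRNA_intronic", "intergenic")

.SUBST_TYPES <- {
  b <- c("A", "C", "G", "T")
  p <- expand.grid(ref = b, var = b, stringsAsFactors = FALSE)
  p <- p[p$ref != p$var, ]
  sort(paste0(p$ref, ">", p$var))
}

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Parameters of the editing-site caller and filter cascade
#'
#' Holds every threshold used during candidate calling and filtering.  The
#' defaults are the values of the published pipeline this package models: a
#' candidate needs at least five qualified RNA reads including two variant
#' reads, base (BAQ) quality >= 25 and mapping quality >= 20; observations in
#' the first six bases of a read are excluded (random-hexamer priming
#' artifacts); non-Alu candidates additionally require editing level >= 0.1,
#' must not be intronic within 4 bp of a splice junction, must not sit in a
#' homopolymer run of >= 5 bp and must not fall in the genome-similarity
#' mask.  Genomic (DNA) evidence requires at least \code{minDnaDepth}
#' qualified DNA reads with at most \code{maxDnaVariantReads} variant reads.
#'
#' @slot minDepth minimum qualified RNA depth at a candidate site.
#' @slot minVariantReads minimum qualified reads carrying the variant base.
#' @slot minBaq minimum (BAQ-adjusted) base quality for a read base to count.
#' @slot minMapq minimum mapping quality.
#' @slot hexamerPrefixLen read-start prefix length whose observations are
#'   excluded before counting.
#' @slot nonAluMinFreq minimum editing level for non-Alu candidates.
#' @slot spliceFlankBp intronic distance to a splice junction at or below
#'   which a non-Alu candidate is removed.
#' @slot homopolymerMinRun homopolymer run length at or above which a
#'   non-Alu candidate is removed.
#' @slot minDnaDepth minimum qualified DNA depth for genomic evidence.
#' @slot maxDnaVariantReads maximum DNA reads carrying the variant base.
#' @export
setClass("CallerParams", representation(
  minDepth = "integer", minVariantReads = "integer",
  minBaq = "integer", minMapq = "integer",
  hexamerPrefixLen = "integer", nonAluMinFreq = "numeric",
  spliceFlankBp = "integer", homopolymerMinRun = "integer",
  minDnaDepth = "integer", maxDnaVariantReads = "integer"))

setValidity("CallerParams", function(object) {
  v <- c(minDepth = object@minDepth, minVariantReads = object@minVariantReads,
         minBaq = object@minBaq, minMapq = object@minMapq,
         hexamerPrefixLen = object@hexamerPrefixLen,
         spliceFlankBp = object@spliceFlankBp,
         homopolymerMinRun = object@homopolymerMinRun,
         minDnaDepth = object@minDnaDepth,
         maxDnaVariantReads = object@maxDnaVariantReads)
  if (any(is.na(v)) || any(v < 0))
    return("all thresholds must be non-negative")
  if (is.na(object@nonAluMinFreq) || object@nonAluMinFreq < 0 ||
      object@nonAluMinFreq > 1)
    return("nonAluMinFreq must lie in [0, 1]")
  TRUE
})

#' @param minDepth,minVariantReads,minBaq,minMapq,hexamerPrefixLen integers,
#'   see slots.
#' @param nonAluMinFreq,spliceFlankBp,homopolymerMinRun,minDnaDepth,maxDnaVariantReads
#'   see slots.
#' @return a \code{CallerParams} object.
#' @examples
#' CallerParams()
#' CallerParams(minDepth = 10)
#' @rdname CallerParams-class
#' @export
CallerParams <- function(minDepth = 5L, minVariantReads = 2L, minBaq = 25L,
                         minMapq = 20L, hexamerPrefixLen = 6L,
                         nonAluMinFreq = 0.1, spliceFlankBp = 4L,
                         homopolymerMinRun = 5L, minDnaDepth = 5L,
                         maxDnaVariantReads = 0L) {
  new("CallerParams", minDepth = as.integer(minDepth),
      minVariantReads = as.integer(minVariantReads),
      minBaq = as.integer(minBaq), minMapq = as.integer(minMapq),
      hexamerPrefixLen = as.integer(hexamerPrefixLen),
      nonAluMinFreq = as.numeric(nonAluMinFreq),
      spliceFlankBp = as.integer(spliceFlankBp),
      homopolymerMinRun = as.integer(homopolymerMinRun),
      minDnaDepth = as.integer(minDnaDepth),
      maxDnaVariantReads = as.integer(maxDnaVariantReads))
}

#' Parameters of the miRNA target scanner
#'
#' Two-phase scanner settings: a complementarity alignment score gate
#' followed by a duplex-energy gate.  Defaults follow the published analysis
#' (score >= 155, energy <= -20 kcal/mol) with a miRanda-style scoring table
#' (match +5, G:U wobble +2, mismatch -3, gap open -9, gap extend -4, and a
#' 4x scale on miRNA seed positions 2-8 counted from the miRNA 5' end).
#'
#' @slot scoreMin minimum alignment score for a hit.
#' @slot energyMax maximum (most positive) duplex energy in kcal/mol.
#' @slot matchScore,wobbleScore,mismatchScore substitution scores.
#' @slot gapOpen,gapExtend affine gap penalties (negative).
#' @slot seedScale multiplier applied to substitution scores at seed
#'   positions.
#' @slot seedStart,seedEnd seed window on the miRNA, 1-based from its 5' end.
#' @export
setClass("ScanParams", representation(
  scoreMin = "numeric", energyMax = "numeric",
  matchScore = "numeric", wobbleScore = "numeric", mismatchScore = "numeric",
  gapOpen = "numeric", gapExtend = "numeric",
  seedScale = "numeric", seedStart = "integer", seedEnd = "integer"))

setValidity("ScanParams", function(object) {
  if (object@scoreMin <= 0) return("scoreMin must be positive")
  if (object@energyMax >= 0) return("energyMax must be negative")
  if (object@seedStart < 1L || object@seedEnd < object@seedStart)
    return("invalid seed window")
  TRUE
})

#' @param scoreMin,energyMax,matchScore,wobbleScore,mismatchScore see slots.
#' @param gapOpen,gapExtend,seedScale,seedStart,seedEnd see slots.
#' @return a \code{ScanParams} object.
#' @examples
#' ScanParams()
#' @rdname ScanParams-class
#' @export
ScanParams <- function(scoreMin = 155, energyMax = -20, matchScore = 5,
                       wobbleScore = 2, mismatchScore = -3, gapOpen = -9,
                       gapExtend = -4, seedScale = 4, seedStart = 2L,
                       seedEnd = 8L) {
  new("ScanParams", scoreMin = scoreMin, energyMax = energyMax,
      matchScore = matchScore, wobbleScore = wobbleScore,
      mismatchScore = mismatchScore, gapOpen = gapOpen, gapExtend = gapExtend,
      seedScale = seedScale, seedStart = as.integer(seedStart),
      seedEnd = as.integer(seedEnd))
}

#' Parameters of the co-editing network analysis
#'
#' @slot power soft-threshold exponent beta of the unsigned adjacency
#'   \code{|cor|^beta}.
#' @slot minModuleSize smallest branch size retained as a module.
#' @slot mergeCutHeight modules whose eigen-profiles cluster below this
#'   height on \code{1 - cor} are merged.
#' @slot hubMmMin module-membership threshold above which an own-module site
#'   is called a hub.
#' @slot cutHeight height at which the average-linkage tree of
#'   \code{1 - TOM} is cut; \code{NA} (the default) chooses the height
#'   adaptively by maximizing the number of branches reaching the size
#'   floor (ties resolved toward the lowest height).
#' @slot reassignMinCor minimum absolute correlation with a module
#'   eigen-profile for a small-branch site to be adopted by that module.
#' @slot pruneMinCor members whose absolute correlation with their own
#'   module eigen-profile falls below this are released to the unassigned
#'   pool.
#' @slot pruneTomMad members whose mean TOM dissimilarity to co-members
#'   exceeds the branch median by more than this many MADs are released
#'   (branch-adaptive outlier rule).
#' @export
setClass("NetworkParams", representation(
  power = "numeric", minModuleSize = "integer", mergeCutHeight = "numeric",
  hubMmMin = "numeric", cutHeight = "numeric", reassignMinCor = "numeric",
  pruneMinCor = "numeric", pruneTomMad = "numeric"))

setValidity("NetworkParams", function(object) {
  if (object@power < 1) return("power must be >= 1")
  if (object@mergeCutHeight <= 0 || object@mergeCutHeight >= 1)
    return("mergeCutHeight must lie in (0, 1)")
  if (object@hubMmMin <= 0 || object@hubMmMin >= 1)
    return("hubMmMin must lie in (0, 1)")
  TRUE
})

#' @param power,minModuleSize,mergeCutHeight,hubMmMin,cutHeight,reassignMinCor
#'   see slots.
#' @param pruneMinCor,pruneTomMad see slots.
#' @return a \code{NetworkParams} object.
#' @examples
#' NetworkParams()
#' @rdname NetworkParams-class
#' @export
NetworkParams <- function(power = 12, minModuleSize = 30L,
                          mergeCutHeight = 0.25, hubMmMin = 0.9,
                          cutHeight = NA_real_, reassignMinCor = 0.75,
                          pruneMinCor = 0.5, pruneTomMad = 1.5) {
  new("NetworkParams", power = power,
      minModuleSize = as.integer(minModuleSize),
      mergeCutHeight = mergeCutHeight, hubMmMin = hubMmMin,
      cutHeight = cutHeight, reassignMinCor = reassignMinCor,
      pruneMinCor = pruneMinCor, pruneTomMad = pruneTomMad)
}

# ---------------------------------------------------------------------------
# EditingSites
# ---------------------------------------------------------------------------

#' A set of called RNA editing sites
#'
#' \code{EditingSites} extends \code{GRanges}; every range is a single
#' genomic position (width 1, 1-based) carrying the metadata columns
#' \code{ref}, \code{var} (genomic-strand bases), \code{subst_type}
#' (substitution re-expressed on the assigned strand, e.g. a genomic T>C in
#' a minus-strand gene is reported as \code{"A>G"}), \code{in_alu},
#' \code{region_class}, \code{gene_ids} (comma-joined, empty for
#' intergenic), \code{edited_reads}, \code{total_reads} and \code{level}.
#' Strand is the assigned transcriptional strand, \code{*} when unknown.
#'
#' @export
setClass("EditingSites", contains = "GRanges")

setValidity("EditingSites", function(object) {
  need <- c("ref", "var", "subst_type", "in_alu", "region_class", "gene_ids",
            "edited_reads", "total_reads", "level")
  miss <- setdiff(need, colnames(mcols(object)))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  m <- mcols(object)
  if (any(GenomicRanges::width(object) != 1L))
    return("all sites must have width 1")
  if (!all(m$ref %in% c("A", "C", "G", "T")) ||
      !all(m$var %in% c("A", "C", "G", "T")))
    return("ref and var must be A/C/G/T")
  if (any(m$ref == m$var)) return("ref and var must differ")
  if (!all(m$subst_type %in% .SUBST_TYPES))
    return("invalid subst_type")
  if (!all(m$region_class %in% .REGION_CLASSES))
    return("invalid region_class")
  if (any(m$edited_reads > m$total_reads))
    return("edited_reads must not exceed total_reads")
  if (any(m$level < 0 | m$level > 1, na.rm = TRUE))
    return("level must lie in [0, 1]")
  # subst_type must agree with (ref, var) on the reported strand
  s <- as.character(strand(object))
  ref_s <- ifelse(s == "-", .complementBase(m$ref), m$ref)
  var_s <- ifelse(s == "-", .complementBase(m$var), m$var)
  if (!all(m$subst_type == paste0(ref_s, ">", var_s)))
    return("subst_type inconsistent with ref/var on the reported strand")
  TRUE
})

.complementBase <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

#' Construct an EditingSites object
#'
#' @param chrom character chromosome names.
#' @param pos 1-based genomic positions.
#' @param ref,var genomic-strand reference and variant bases.
#' @param strand assigned strand (\code{+}, \code{-} or \code{*}).
#' @param in_alu logical, inside the Alu mask.
#' @param region_class one of \code{CDS, UTR3, UTR5, ncRNA_exonic, intronic,
#'   ncRNA_intronic, intergenic}.
#' @param gene_ids comma-joined overlapping gene ids (\code{""} if none).
#' @param edited_reads,total_reads qualified read counts.
#' @param level editing level; defaults to \code{edited_reads/total_reads}.
#' @return an \code{EditingSites} object.
#' @examples
#' EditingSites("chr1", 100, "A", "G", "+", TRUE, "UTR3", "g1", 4, 10)
#' @export
EditingSites <- function(chrom = character(), pos = integer(),
                         ref = character(), var = character(),
                         strand = "*", in_alu = logical(),
                         region_class = "intergenic", gene_ids = "",
                         edited_reads = integer(), total_reads = integer(),
                         level = NULL) {
  n <- length(pos)
  if (is.null(level)) {
    level <- if (n) rep_len(as.numeric(edited_reads), n) /
                    rep_len(as.numeric(total_reads), n)
             else numeric()
  }
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  ref <- rep_len(as.character(ref), n); var <- rep_len(as.character(var), n)
  ref_s <- ifelse(strand == "-", .complementBase(ref), ref)
  var_s <- ifelse(strand == "-", .complementBase(var), var)
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L), strand = strand)
  mcols(gr) <- DataFrame(
    ref = ref, var = var,
    subst_type = if (n) paste0(ref_s, ">", var_s) else character(),
    in_alu = rep_len(as.logical(in_alu), n),
    region_class = rep_len(as.character(region_class), n),
    gene_ids = rep_len(as.character(gene_ids), n),
    edited_reads = rep_len(as.integer(edited_reads), n),
    total_reads = rep_len(as.integer(total_reads), n),
    level = rep_len(as.numeric(level), n))
  new("EditingSites", gr)
}

setMethod("show", "EditingSites", function(object) {
  cat("EditingSites with", length(object), "sites\n")
  if (length(object)) {
    tab <- table(mcols(object)$subst_type)
    cat("  substitution types:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    cat("  in Alu:", sum(mcols(object)$in_alu), "/", length(object), "\n")
  }
  invisible(object)
})

# ---------------------------------------------------------------------------
# EditingExperiment
# ---------------------------------------------------------------------------

#' Editing levels across samples
#'
#' A \code{SummarizedExperiment} with assays \code{edited}, \code{total} and
#' \code{level} (sites x samples), a \code{qualified} assay flagging sites
#' covered by at least \code{minDepth} qualified reads in a sample, and the
#' interrogated sites as \code{rowRanges}.  \code{colData} carries at least
#' \code{sample_id} and \code{cell_type}.
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @export
setClass("EditingExperiment", contains = "RangedSummarizedExperiment")

setValidity("EditingExperiment", function(object) {
  need <- c("edited", "total", "level", "qualified")
  miss <- setdiff(need, assayNames(object))
  if (length(miss))
    return(paste("missing assays:", paste(miss, collapse = ", ")))
  ed <- assay(object, "edited"); tot <- assay(object, "total")
  if (any(ed > tot, na.rm = TRUE))
    return("edited must not exceed total")
  TRUE
})

# ---------------------------------------------------------------------------
# CoEditingModules
# ---------------------------------------------------------------------------

#' Co-editing modules
#'
#' Result container of the co-editing network analysis: an integer module
#' label per site (0 = unassigned), module eigen-profiles (unit-norm first
#' principal components of the standardized member levels, modules x
#' samples), the site x module membership matrix (correlation of each site's
#' profile with each eigen-profile) and the hub sites of every module
#' (own-module membership above the hub threshold).
#'
#' @slot labels named integer vector of module labels (0 = unassigned);
#'   names are site keys.
#' @slot eigens numeric matrix, modules x samples.
#' @slot membership numeric matrix, sites x modules.
#' @slot hubs named list of character vectors, hub site keys per module.
#' @slot params the \code{NetworkParams} used.
#' @export
setClass("CoEditingModules", representation(
  labels = "integer", eigens = "matrix", membership = "matrix",
  hubs = "list", params = "NetworkParams"))

setValidity("CoEditingModules", function(object) {
  if (is.null(names(object@labels))) return("labels must be named")
  if (any(object@labels < 0L)) return("labels must be >= 0")
  k <- max(object@labels, 0L)
  if (k > 0L && nrow(object@eigens) != k)
    return("one eigen-profile per module required")
  if (length(object@membership) &&
      any(abs(object@membership) > 1 + 1e-8, na.rm = TRUE))
    return("membership must lie in [-1, 1]")
  TRUE
})

setMethod("show", "CoEditingModules", function(object) {
  k <- max(object@labels, 0L)
  cat("CoEditingModules:", k, "modules over", length(object@labels),
      "sites (", sum(object@labels == 0L), "unassigned )\n")
  if (k > 0L) {
    sz <- tabulate(object@labels, k)
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
    cat("  hubs per module:",
        paste(vapply(object@hubs, length, 1L), collapse = ", "), "\n")
  }
  invisible(object)
})

#' @rdname CoEditingModules-class
#' @param object a \code{CoEditingModules} object.
#' @export
moduleLabels <- function(object) object@labels

#' @rdname CoEditingModules-class
#' @export
moduleEigens <- function(object) object@eigens

#' @rdname CoEditingModules-class
#' @export
moduleMembershipMatrix <- function(object) object@membership

#' @rdname CoEditingModules-class
#' @export
moduleHubs <- function(object) object@hubs
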