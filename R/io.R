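# Readers and writers for every on-disk format the pipeline touches.
# Conventions: all on-disk genomic positions are 1-based (BED being 0-based
# half-open is converted on import); all in-memory positions follow the
# GRanges convention (1-based, width-1 ranges for single positions).
# Coordinate conversion happens only in this file.

.OBS_COLS <- c("sample_id", "chrom", "pos", "ref", "base", "baq", "mapq",
               "read_pos", "read_id")

#' Read a read-base observation table
#'
#' The canonical read-level input is a long-format TSV with one row per
#' aligned read base: columns \code{sample_id, chrom, pos} (1-based),
#' \code{ref, base, baq, mapq, read_pos} (1-based position of the base
#' within its read, counted from the read's 5' end) and \code{read_id}.
#' Base qualities are taken as already BAQ-recalculated upstream.  Rows must
#' be sorted by \code{(chrom, pos)}; malformed rows are rejected with an
#' error naming the offending line.
#'
#' @param path path to the TSV file.
#' @param sample_id if given, overrides the \code{sample_id} column.
#' @return a \code{data.table} with the columns above.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' obs <- data.frame(sample_id = "s1", chrom = "chr1", pos = c(10L, 11L),
#'                   ref = "A", base = c("A", "G"), baq = 30L, mapq = 40L,
#'                   read_pos = c(12L, 50L), read_id = c("r1", "r2"))
#' writeObservations(obs, f)
#' readObservations(f)
#' @export
readObservations <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  obs <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("sample_id", "chrom", "ref", "base", "read_id")),
    showProgress = FALSE)
  miss <- setdiff(.OBS_COLS, names(obs))
  if (length(miss))
    stop("observation file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  .lineno <- function(i) i + 1L  # header occupies line 1
  for (col in c("pos", "baq", "mapq", "read_pos")) {
    v <- obs[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop("non-numeric ", col, " in ", path, " at line ",
           .lineno(if (is.na(bad)) 1L else bad))
    }
    obs[[col]] <- as.integer(v)
  }
  bad <- which(obs$pos < 1L | obs$read_pos < 1L | obs$baq < 0L |
               obs$mapq < 0L)
  if (length(bad))
    stop("invalid coordinate or quality in ", path, " at line ",
         .lineno(bad[1]))
  bad <- which(!(obs$ref %in% c("A", "C", "G", "T")))
  if (length(bad))
    stop("invalid ref base in ", path, " at line ", .lineno(bad[1]))
  bad <- which(!(obs$base %in% c("A", "C", "G", "T", "N")))
  if (length(bad))
    stop("invalid observed base in ", path, " at line ", .lineno(bad[1]))
  # sortedness within the file: chromosome blocks with non-decreasing pos
  if (nrow(obs) > 1L) {
    newchrom <- obs$chrom[-1L] != obs$chrom[-nrow(obs)]
    if (anyDuplicated(rle(obs$chrom)$values))
      stop("unsorted input in ", path, ": chromosome blocks interleaved")
    bad <- which(!newchrom & diff(obs$pos) < 0L)
    if (length(bad))
      stop("unsorted input in ", path, " at line ", .lineno(bad[1] + 1L))
  }
  if (!is.null(sample_id)) obs$sample_id <- as.character(sample_id)
  obs[]
}

#' @rdname readObservations
#' @param obs a data.frame/data.table of observations.
#' @export
writeObservations <- function(obs, path) {
  obs <- as.data.frame(obs)[, .OBS_COLS]
  fwrite(obs, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Stranded gene models used for annotation and strand assignment
#'
#' Slots hold genomic intervals (GRanges, 1-based) for gene spans, exons,
#' CDS and the two UTRs, each carrying a \code{gene_id} metadata column.
#' Genes without CDS are noncoding (\code{biotype = "ncRNA"} on
#' \code{genes}).
#'
#' @export
setClass("GeneModels", representation(
  genes = "GRanges", exons = "GRanges", cds = "GRanges",
  utr5 = "GRanges", utr3 = "GRanges"))

setValidity("GeneModels", function(object) {
  if (!"gene_id" %in% colnames(mcols(object@genes)))
    return("genes must carry gene_id")
  if (anyDuplicated(mcols(object@genes)$gene_id))
    return("duplicate gene_id")
  for (nm in c("exons", "cds", "utr5", "utr3")) {
    gr <- slot(object, nm)
    if (length(gr) && !"gene_id" %in% colnames(mcols(gr)))
      return(paste(nm, "must carry gene_id"))
  }
  TRUE
})

setMethod("show", "GeneModels", function(object) {
  bt <- table(mcols(object@genes)$biotype)
  cat("GeneModels with", length(object@genes), "genes (",
      paste(names(bt), bt, sep = ":", collapse = ", "), ")\n")
  invisible(object)
})

#' @rdname GeneModels-class
#' @param object a GeneModels object.
#' @export
genes <- function(object) object@genes

#' @rdname GeneModels-class
#' @export
geneExons <- function(object) object@exons

.sortGR <- function(gr) GenomicRanges::sort(gr, ignore.strand = TRUE)

.assembleGeneModels <- function(genes, exons, cds) {
  # derive UTRs: exon portions outside the CDS span, 5'/3' by strand
  utr5 <- GRanges(); utr3 <- GRanges()
  mcols(utr5)$gene_id <- character(); mcols(utr3)$gene_id <- character()
  for (g in seq_along(genes)) {
    gid <- mcols(genes)$gene_id[g]
    ex <- exons[mcols(exons)$gene_id == gid]
    cd <- cds[mcols(cds)$gene_id == gid]
    if (!length(cd)) next
    cdsl <- min(start(cd)); cdsr <- max(end(cd))
    left <- GenomicRanges::intersect(
      GRanges(seqnames(genes)[g],
              IRanges(start(genes)[g], cdsl - 1L),
              strand = strand(genes)[g]),
      ex, ignore.strand = TRUE)
    right <- GenomicRanges::intersect(
      GRanges(seqnames(genes)[g],
              IRanges(cdsr + 1L, end(genes)[g]),
              strand = strand(genes)[g]),
      ex, ignore.strand = TRUE)
    strand(left) <- strand(genes)[g]; strand(right) <- strand(genes)[g]
    if (as.character(strand(genes)[g]) == "+") {
      u5 <- left; u3 <- right
    } else {
      u5 <- right; u3 <- left
    }
    if (length(u5)) { mcols(u5)$gene_id <- gid; utr5 <- c(utr5, u5) }
    if (length(u3)) { mcols(u3)$gene_id <- gid; utr3 <- c(utr3, u3) }
  }
  mcols(genes)$biotype <- ifelse(
    mcols(genes)$gene_id %in% mcols(cds)$gene_id, "coding", "ncRNA")
  new("GeneModels", genes = .sortGR(genes), exons = .sortGR(exons),
      cds = .sortGR(cds), utr5 = .sortGR(utr5), utr3 = .sortGR(utr3))
}

#' Read gene models from BED12 or minimal GTF
#'
#' BED12 blocks become exons and the thick range becomes the CDS span (a
#' record with an empty thick range is noncoding); UTRs are derived from the
#' record strand.  The minimal GTF dialect uses feature types \code{gene},
#' \code{exon} and \code{CDS} with a \code{gene_id} attribute.  A BED12 and
#' a GTF encoding of the same gene yield identical models.
#'
#' @param path path to a \code{.bed} (BED12) or \code{.gtf} file; format is
#'   chosen by extension.
#' @return a \code{GeneModels} object.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff")) .readGeneModelsGtf(path)
  else .readGeneModelsBed12(path)
}

.readGeneModelsBed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!all(c("name", "thick", "blocks") %in% colnames(mcols(gr))))
    stop("not a BED12 file (name/thick/blocks required): ", path)
  bl <- rtracklayer::blocks(gr)  # absolute exon coordinates per record
  genes <- GRanges(); exons <- GRanges(); cds <- GRanges()
  mcols(cds)$gene_id <- character()
  for (i in seq_along(gr)) {
    gid <- mcols(gr)$name[i]
    ex <- bl[[i]]
    if (length(ex) > 1L) {
      o <- order(start(ex))
      ex <- ex[o]
      if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
        stop("overlapping blocks in BED12 record ", gid)
    }
    th <- mcols(gr)$thick[i]
    g <- granges(gr[i]); mcols(g)$gene_id <- gid
    genes <- c(genes, g)
    mcols(ex) <- NULL; mcols(ex)$gene_id <- gid
    exons <- c(exons, ex)
    if (IRanges::width(th) > 0L) {
      if (IRanges::start(th) < start(gr[i]) || IRanges::end(th) > end(gr[i]))
        stop("thick range outside record in BED12 record ", gid)
      cd <- GenomicRanges::intersect(
        GRanges(seqnames(gr[i]), th, strand = strand(gr[i])), ex,
        ignore.strand = TRUE)
      strand(cd) <- strand(gr[i])
      mcols(cd)$gene_id <- gid
      cds <- c(cds, cd)
    }
  }
  .assembleGeneModels(genes, exons, cds)
}

.readGeneModelsGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% colnames(mcols(gr)))
    stop("GTF lacks gene_id attributes: ", path)
  typ <- as.character(mcols(gr)$type)
  genes <- gr[typ == "gene"]
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  keep <- function(x) {
    gid <- mcols(x)$gene_id
    x <- granges(x); mcols(x)$gene_id <- gid; x
  }
  genes <- keep(genes); exons <- keep(exons); cds <- keep(cds)
  if (!length(genes)) {           # derive spans from exons if absent
    sp <- split(exons, mcols(exons)$gene_id)
    genes <- unlist(GenomicRanges::reduce(sp, min.gapwidth = 1e9))
    mcols(genes)$gene_id <- names(genes); names(genes) <- NULL
  }
  .assembleGeneModels(genes, exons, cds)
}

# ---------------------------------------------------------------------------
# Interval masks and variant positions
# ---------------------------------------------------------------------------

#' Read a BED interval mask (Alu, genome-similarity, ...)
#'
#' Input intervals are converted from BED's 0-based half-open convention,
#' merged when overlapping and returned sorted.
#'
#' @param path path to a BED3+ file.
#' @param label mask label stored in \code{metadata(..)$label}.
#' @return a reduced, sorted \code{GRanges}.
#' @export
readIntervalMask <- function(path, label = "mask") {
  if (!file.exists(path)) stop("mask file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    gr <- GRanges()
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (any(IRanges::width(gr) < 1L))
      stop("format error in ", path, ": interval with start >= end")
    gr <- reduce(.sortGR(granges(gr)), ignore.strand = TRUE)
  }
  metadata(gr)$label <- label
  gr
}

#' Read known-variant positions from a VCF
#'
#' Only CHROM, POS, REF and ALT are consumed; multi-allelic records are
#' expanded to one entry per alternate allele.  Exclusion downstream is by
#' position only.
#'
#' @param path path to a VCF 4.x file.
#' @return a width-1 \code{GRanges} with metadata columns \code{ref} and
#'   \code{alt}, one row per (position, alt allele).
#' @export
readVariantPositions <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("format error reading VCF ", path, ": ",
                             conditionMessage(e)))
  rr <- rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n <- elementNROWS(alt)
  idx <- rep(seq_along(rr), n)
  out <- granges(rr)[idx]
  GenomicRanges::width(out) <- 1L  # SNV positions; indel REFs collapse to pos
  mcols(out) <- DataFrame(ref = as.character(VariantAnnotation::ref(vcf))[idx],
                          alt = as.character(unlist(alt)))
  strand(out) <- "*"
  names(out) <- NULL
  out
}

#' @importFrom S4Vectors elementNROWS
NULL

# ---------------------------------------------------------------------------
# Site tables
# ---------------------------------------------------------------------------

.SITE_COLS <- c("chrom", "pos", "ref", "var", "strand", "subst_type",
                "in_alu", "region_class", "gene_ids", "edited_reads",
                "total_reads", "level")

#' Write / read an editing-site table
#'
#' The on-disk format is a TSV with columns \code{chrom, pos} (1-based),
#' \code{ref, var, strand, subst_type, in_alu, region_class, gene_ids}
#' (comma-joined), \code{edited_reads, total_reads, level}.  Levels are
#' written with six decimal places; the round trip is otherwise lossless.
#' Reading re-validates every site, so a hand-edited file violating an
#' invariant (for example \code{level > 1} or an unknown region class) is
#' rejected.
#'
#' @param sites an \code{EditingSites} object.
#' @param path output (or input) TSV path.
#' @return \code{readSiteTable} returns an \code{EditingSites} object.
#' @examples
#' s <- EditingSites("chr1", 5, "A", "G", "+", TRUE, "UTR3", "g1", 3, 10)
#' f <- tempfile(fileext = ".tsv")
#' writeSiteTable(s, f)
#' readSiteTable(f)
#' @export
writeSiteTable <- function(sites, path) {
  stopifnot(is(sites, "EditingSites"))
  m <- mcols(sites)
  df <- data.frame(
    chrom = as.character(seqnames(sites)), pos = start(sites),
    ref = m$ref, var = m$var, strand = as.character(strand(sites)),
    subst_type = m$subst_type, in_alu = m$in_alu,
    region_class = m$region_class, gene_ids = m$gene_ids,
    edited_reads = m$edited_reads, total_reads = m$total_reads,
    level = sprintf("%.6f", m$level), stringsAsFactors = FALSE)
  fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("chrom", "ref", "var", "strand", "subst_type",
                  "gene_ids", "region_class")), showProgress = FALSE)
  miss <- setdiff(.SITE_COLS, names(df))
  if (length(miss))
    stop("site table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!(df$region_class %in% .REGION_CLASSES))
  if (length(bad))
    stop("format error in ", path, " at line ", bad[1] + 1L,
         ": unknown region_class '", df$region_class[bad[1]], "'")
  sites <- EditingSites(df$chrom, df$pos, df$ref, df$var, df$strand,
                        as.logical(df$in_alu), df$region_class,
                        ifelse(is.na(df$gene_ids), "", df$gene_ids),
                        df$edited_reads, df$total_reads,
                        as.numeric(df$level))
  validObject(sites)
  sites
}

# ---------------------------------------------------------------------------
# Sample sheets and reference sequence
# ---------------------------------------------------------------------------

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id, cell_type, replicate_id, path}
#' (observation TSV per sample).  Relative paths are resolved against the
#' sheet's directory; every path must exist and sample ids must be unique.
#'
#' @param path path to the sample sheet TSV.
#' @return a \code{data.table}.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
                 showProgress = FALSE)
  need <- c("sample_id", "cell_type", "replicate_id", "path")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^/", sheet$path), sheet$path,
                file.path(base, sheet$path))
  ok <- file.exists(abs)
  if (!all(ok))
    stop("sample sheet path does not exist: ", sheet$path[!ok][1])
  sheet$path <- abs
  sheet[]
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA path; sequence names are truncated at the first
#'   whitespace.
#' @return a \code{DNAStringSet}.
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  ref <- readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
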