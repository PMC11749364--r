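# Editome annotation and summary statistics: region classes, substitution
# spectrum, level distributions, coverage-normalized region enrichment,
# per-gene counts and gene-set over-representation.

#' Annotate sites with a region class and overlapping genes
#'
#' Every site gets exactly one class by precedence \code{CDS > UTR3 > UTR5 >
#' ncRNA_exonic > intronic > ncRNA_intronic > intergenic} across all
#' overlapping gene models; \code{gene_ids} collects every overlapping gene
#' (comma-joined), and is empty exactly for intergenic sites.  UTR3 is
#' ranked above UTR5 so that a position in both UTRs of overlapping genes is
#' reported in the 3'UTR class.
#'
#' @param sites an \code{EditingSites} object (or any width-1 GRanges-like
#'   \code{EditingSites}).
#' @param genes a \code{\link{GeneModels}} object.
#' @return the sites with \code{region_class} and \code{gene_ids} updated.
#' @export
annotateRegion <- function(sites, genes) {
  if (!length(sites)) return(sites)
  gr <- granges(sites)
  g <- genes(genes)
  coding <- mcols(g)$biotype == "coding"
  gid <- mcols(g)$gene_id
  inAny <- function(target, ids = NULL) {
    if (!length(target)) return(rep(FALSE, length(gr)))
    if (!is.null(ids)) target <- target[mcols(target)$gene_id %in% ids]
    if (!length(target)) return(rep(FALSE, length(gr)))
    overlapsAny(gr, target, ignore.strand = TRUE)
  }
  in_cds <- inAny(genes@cds)
  in_u3 <- inAny(genes@utr3)
  in_u5 <- inAny(genes@utr5)
  in_nc_ex <- inAny(genes@exons, gid[!coding])
  in_coding_gene <- inAny(g[coding])
  in_nc_gene <- inAny(g[!coding])
  cls <- rep("intergenic", length(gr))
  cls[in_nc_gene] <- "ncRNA_intronic"
  cls[in_coding_gene] <- "intronic"
  cls[in_nc_ex] <- "ncRNA_exonic"
  cls[in_u5] <- "UTR5"
  cls[in_u3] <- "UTR3"
  cls[in_cds] <- "CDS"
  ids <- rep("", length(gr))
  ov <- findOverlaps(gr, g, ignore.strand = TRUE)
  if (length(ov)) {
    sp <- split(gid[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
    joined <- vapply(sp, function(x) paste(sort(unique(x)), collapse = ","),
                     "")
    ids[as.integer(names(joined))] <- joined
  }
  mcols(sites)$region_class <- cls
  mcols(sites)$gene_ids <- ids
  validObject(sites)
  sites
}

#' Substitution spectrum over the 12 substitution types
#'
#' Counts and fractions of every substitution type, both on the genomic
#' strand (from \code{ref}/\code{var}) and after strand reclassification
#' (from \code{subst_type}, where e.g. a genomic T>C inside a minus-strand
#' gene is counted as A>G).  Fractions sum to 1 on non-empty input.
#'
#' @param sites an \code{EditingSites} object.
#' @return a data.frame with columns \code{subst_type, n_genomic,
#'   frac_genomic, n_stranded, frac_stranded}.
#' @export
substitutionSpectrum <- function(sites) {
  m <- mcols(sites)
  genomic <- if (length(sites)) paste0(m$ref, ">", m$var) else character()
  stranded <- m$subst_type
  tab <- function(x) {
    n <- as.integer(table(factor(x, levels = .SUBST_TYPES)))
    f <- if (sum(n)) n / sum(n) else rep(NA_real_, length(n))
    list(n = n, f = f)
  }
  tg <- tab(genomic); ts <- tab(stranded)
  data.frame(subst_type = .SUBST_TYPES,
             n_genomic = tg$n, frac_genomic = tg$f,
             n_stranded = ts$n, frac_stranded = ts$f)
}

#' Count covered adenosines per region class
#'
#' Builds the background for the region-enrichment test: positions whose
#' qualified RNA coverage reaches \code{minDepth} and whose reference base
#' is adenosine on the annotated strand (genomic A, or genomic T inside a
#' minus-strand gene; unannotated positions count genomic A only).
#'
#' @param obs observation data.table.
#' @param genes a \code{\link{GeneModels}} object.
#' @param params a \code{\link{CallerParams}} object.
#' @return named integer vector of per-class counts of covered adenosines.
#' @export
coveredAdenosineBackground <- function(obs, genes, params = CallerParams()) {
  qual <- .qualifyObs(as.data.table(obs), params, hexamer = TRUE)
  depth <- qual[, list(depth = .N, ref = ref[1]), by = c("chrom", "pos")]
  depth <- depth[depth$depth >= params@minDepth]
  if (!nrow(depth))
    return(setNames(integer(length(.REGION_CLASSES)), .REGION_CLASSES))
  dummy <- EditingSites(depth$chrom, depth$pos, depth$ref,
                        ifelse(depth$ref == "G", "A", "G"),
                        "*", FALSE, "intergenic", "",
                        0L, depth$depth)
  dummy <- assignStrand(dummy, genes)
  dummy <- annotateRegion(dummy, genes)
  s <- as.character(strand(dummy))
  base_stranded <- ifelse(s == "-", .complementBase(depth$ref), depth$ref)
  keep <- base_stranded == "A"
  cls <- factor(mcols(dummy)$region_class[keep], levels = .REGION_CLASSES)
  setNames(as.integer(table(cls)), .REGION_CLASSES)
}

#' Coverage-normalized region enrichment of editing sites
#'
#' For each region class, a two-sided Fisher's exact test on the 2x2 table
#' \{edited, covered-not-edited\} x \{in class, in other classes\}, where
#' the background is the per-class count of adenosines with qualified
#' coverage.  P-values are Benjamini-Hochberg adjusted across classes;
#' classes with zero background are excluded with a warning.
#'
#' @param sites annotated \code{EditingSites}.
#' @param background named per-class counts of covered adenosines (see
#'   \code{\link{coveredAdenosineBackground}}).
#' @return data.frame with per-class counts, odds ratio, \code{p} and
#'   \code{p_adjusted}.
#' @export
categoryEnrichment <- function(sites, background) {
  cls <- names(background)
  edited <- as.integer(table(factor(mcols(sites)$region_class,
                                    levels = cls)))
  keep <- background > 0
  if (any(!keep))
    warning("excluding classes with zero background: ",
            paste(cls[!keep], collapse = ", "))
  cls <- cls[keep]; edited <- edited[keep]
  bg <- as.integer(background[keep])
  not_edited <- pmax(bg - edited, 0L)
  res <- lapply(seq_along(cls), function(i) {
    tb <- matrix(c(edited[i], sum(edited[-i]),
                   not_edited[i], sum(not_edited[-i])), 2, 2)
    ft <- fisher.test(tb)
    data.frame(category = cls[i], edited_in = edited[i],
               edited_out = sum(edited[-i]), background_in = bg[i],
               background_out = sum(bg[-i]),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out
}

#' Per-gene editing-site counts
#'
#' Genes with no sites are omitted; the mean is taken over genes carrying
#' at least one site.  Sites overlapping several genes count once per gene.
#'
#' @param sites annotated \code{EditingSites}.
#' @return a list with \code{counts} (data.frame gene_id, n_sites, sorted
#'   by decreasing count) and \code{mean_per_gene}.
#' @export
perGeneCounts <- function(sites) {
  ids <- mcols(sites)$gene_ids
  ids <- ids[!is.na(ids) & ids != ""]
  if (!length(ids))
    return(list(counts = data.frame(gene_id = character(),
                                    n_sites = integer()),
                mean_per_gene = NaN))
  gene <- unlist(strsplit(ids, ",", fixed = TRUE))
  tab <- sort(table(gene), decreasing = TRUE)
  counts <- data.frame(gene_id = names(tab), n_sites = as.integer(tab),
                       row.names = NULL)
  list(counts = counts, mean_per_gene = mean(counts$n_sites))
}

#' Histogram of editing levels
#'
#' @param sites an \code{EditingSites} object (or a numeric vector of
#'   levels).
#' @param bin_edges increasing bin edges spanning [0, 1]; bins are
#'   left-open, right-closed except the first, which includes its left
#'   edge.
#' @return integer vector of bin counts, named by bin.
#' @export
levelHistogram <- function(sites, bin_edges = seq(0, 1, by = 0.1)) {
  lv <- if (is.numeric(sites)) sites else mcols(sites)$level
  ct <- table(cut(lv, bin_edges, include.lowest = TRUE))
  setNames(as.integer(ct), names(ct))
}

#' Chi-square comparison of two editing-level distributions
#'
#' The two site classes are binned on common edges and compared with a
#' Pearson chi-square test on the 2 x k contingency table (no continuity
#' correction).  Bins whose expected count falls below \code{min_expected}
#' are merged rightward (the merged bin absorbs its right neighbour) until
#' the expectation rule holds.
#'
#' @param a,b \code{EditingSites} objects or numeric level vectors.
#' @param bin_edges common bin edges.
#' @param min_expected minimum expected count per cell; default 5.
#' @return list with \code{statistic}, \code{df}, \code{p} and the merged
#'   \code{table}.
#' @export
compareLevelDistributions <- function(a, b, bin_edges = seq(0, 1, by = 0.1),
                                      min_expected = 5) {
  ca <- levelHistogram(a, bin_edges)
  cb <- levelHistogram(b, bin_edges)
  tb <- rbind(a = ca, b = cb)
  repeat {
    if (ncol(tb) <= 1L) break
    exp_ <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    bad <- which(apply(exp_, 2, min) < min_expected)
    if (!length(bad)) break
    j <- bad[1]
    k <- if (j < ncol(tb)) j + 1L else j - 1L  # merge rightward, last leftward
    lo <- min(j, k); hi <- max(j, k)
    nm <- colnames(tb)
    newnm <- c(nm[seq_len(lo - 1L)], paste(nm[lo], nm[hi], sep = "+"),
               if (hi < ncol(tb)) nm[(hi + 1L):ncol(tb)])
    tb <- cbind(tb[, seq_len(lo - 1L), drop = FALSE],
                tb[, lo] + tb[, hi],
                tb[, seq_len(ncol(tb)) > hi, drop = FALSE])
    colnames(tb) <- newnm
  }
  ct <- suppressWarnings(chisq.test(tb, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tb)
}

#' Gene-set over-representation (one-sided hypergeometric)
#'
#' Standard ORA: for each set, the probability of drawing at least the
#' observed overlap when sampling \code{length(gene_list)} genes from the
#' universe without replacement.  Genes outside the universe are dropped
#' with a warning; BH adjustment across sets.
#'
#' @param gene_list character vector of genes of interest.
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all assayable genes.
#' @return data.frame with per-set overlap, set size, \code{p} and
#'   \code{p_adjusted}, sorted by \code{p}.
#' @export
genesetOverrepresentation <- function(gene_list, gene_sets, universe) {
  gene_list <- unique(gene_list)
  out_of_universe <- setdiff(gene_list, universe)
  if (length(out_of_universe)) {
    warning(length(out_of_universe), " gene(s) outside the universe dropped")
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe); n <- length(gene_list)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set); k <- length(intersect(gene_list, set))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               universe_size = N, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Read depth of shared vs replicate-specific sites
#'
#' Two-sided Wilcoxon rank-sum test on total qualified read depth; the
#' published pipeline observed that sites found in both replicates carry
#' roughly double the median depth of replicate-specific sites.
#'
#' @param shared,specific \code{EditingSites} objects (or numeric depth
#'   vectors).
#' @return list with the two medians and the rank-sum \code{p}.
#' @export
depthComparison <- function(shared, specific) {
  d1 <- if (is.numeric(shared)) shared else mcols(shared)$total_reads
  d2 <- if (is.numeric(specific)) specific else mcols(specific)$total_reads
  if (!length(d1) || !length(d2))
    stop("both groups must be non-empty")
  wt <- wilcox.test(d1, d2, exact = (length(d1) <= 50 && length(d2) <= 50))
  list(median_shared = median(d1), median_specific = median(d2),
       p = wt$p.value)
}
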