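# Synthetic-data generator with planted ground truth.  Every input the
# pipeline consumes (reference FASTA, gene models, Alu and similarity
# masks, a SNP VCF, read-base observation tables, editing-level matrices
# and miRNA fixtures) can be generated with known truth, so each stage is
# testable without external downloads.  Planted site classes (editing,
# SNP, hexamer artifact, homopolymer artifact) are disjoint by
# construction, making per-filter attribution unambiguous.  All outputs
# are deterministic given (config, seed).

#' Build a simulation configuration
#'
#' Defaults define the reference study conditions: a 100 kb single-contig
#' genome with ~30% Alu content, 300 planted A-to-G editing sites with
#' Beta(2, 5)-distributed editing levels truncated at 0.1, 50 germline
#' SNPs, 30 random-hexamer artifact positions, 20 homopolymer artifact
#' sites, Poisson(30) read coverage of 101-nt reads at a 0.001 per-base
#' error rate, editing-level matrices with one-factor correlated modules
#' (within-correlation 0.8) over 9 samples, and differential sites shifted
#' 2.5-fold at a base level of 0.27 with read depth 50.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param ... named overrides of any default listed above (see the source
#'   for the complete field list).
#' @return a \code{SimulationConfig} (validated named list).
#' @export
simulationConfig <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chroms = 1L, chrom_length = 100000L,
    alu_fraction = 0.3, alu_length = 300L,
    n_genes = 12L, exons_per_gene = 3L, exon_length = 400L,
    intron_length = 400L, utr5_length = 100L, utr3_length = 300L,
    n_similarity = 5L, similarity_length = 500L,
    n_homopolymer_runs = 25L, homopolymer_run_length = 6L,
    # planted site classes
    n_editing_sites = 300L, alu_site_fraction = 0.97,
    level_shape1 = 2, level_shape2 = 5, level_min = 0.1,
    n_utr3_sites = 8L, n_snps = 50L,
    n_hexamer_artifacts = 30L, n_homopolymer_sites = 20L,
    artifact_level = 0.3, snp_het_fraction = 0.5,
    # reads
    coverage = 30, dna_coverage = 30, read_length = 101L,
    error_rate = 0.001, frac_low_baq = 0.05, frac_low_mapq = 0.02,
    baq_high = 37L, baq_low = 15L, mapq_high = 40L, mapq_low = 10L,
    # observation-level differential editing (demo): fraction of planted
    # sites down-shifted in the second cell type
    obs_des_fraction = 0.1, obs_des_fold = 2.5,
    # editing-level matrix
    module_sizes = c(60L, 40L, 30L), module_cor = 0.8,
    hubs_per_module = 2L, hub_weight = 0.995,
    n_background = 200L, n_samples_a = 6L, n_samples_b = 3L,
    matrix_depth = 50L, level_mean_range = c(0.2, 0.6), level_sd = 0.08,
    n_des_sites = 0L, des_fold = 2.5, des_level = 0.27, des_direction = "up",
    # miRNA fixture
    n_gain_events = 4L, n_loss_events = 3L, n_neutral_mirnas = 5L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  fr <- c("alu_fraction", "alu_site_fraction", "level_min", "error_rate",
          "frac_low_baq", "frac_low_mapq", "snp_het_fraction",
          "obs_des_fraction")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  if (is.na(cfg$seed)) stop("seed is mandatory")
  class(cfg) <- "SimulationConfig"
  cfg
}

.placeIntervals <- function(L, n, len, occupied = NULL, max_tries = 20000L) {
  # non-overlapping placement of n intervals of length len on [1, L],
  # avoiding `occupied` (IRanges); deterministic under the current RNG
  placed <- IRanges()
  tries <- 0L
  while (length(placed) < n && tries < max_tries) {
    tries <- tries + 1L
    s <- sample.int(L - len, 1L)
    cand <- IRanges(s, width = len)
    if (!is.null(occupied) && length(occupied) &&
        length(findOverlaps(cand, occupied))) next
    if (length(placed) && length(findOverlaps(cand, placed))) next
    placed <- c(placed, cand)
  }
  if (length(placed) < n)
    stop("infeasible packing: could not place ", n, " intervals of length ",
         len)
  sort(placed)
}

#' Simulate a reference genome with planted structure
#'
#' Generates a random genome with Alu-labelled intervals, stranded genes
#' (exon/CDS/UTR structure on both strands), a genome-similarity mask in
#' intergenic space, homopolymer runs at recorded positions, germline SNPs
#' and planted A-to-G editing sites: an \code{alu_site_fraction} of them in
#' Alu intervals, the rest in intergenic non-Alu space, plus
#' \code{n_utr3_sites} sites in gene 3'UTRs (transcript-sense adenosines).
#' Editing levels are Beta(\code{level_shape1}, \code{level_shape2})
#' truncated below at \code{level_min}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param outDir if given, writes \code{ref.fa}, \code{genes.bed},
#'   \code{alu.bed}, \code{similarity.bed} and \code{snps.vcf} there.
#' @return list with \code{ref} (DNAStringSet), \code{genes}
#'   (\code{GeneModels}), \code{alu}, \code{similarity} (GRanges),
#'   \code{snps} (GRanges) and \code{truth} (list of data.tables:
#'   \code{sites}, \code{snps}, \code{hexamer}, \code{homopolymer_sites},
#'   \code{homopolymer_runs}).
#' @export
simulateReference <- function(config, outDir = NULL) {
  set.seed(config$seed + 1L)
  L <- config$chrom_length
  chrom <- "chrS1"
  seqc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  # Alu intervals
  n_alu <- ceiling(config$alu_fraction * L / config$alu_length)
  alu_ir <- .placeIntervals(L, n_alu, config$alu_length)

  # genes, non-overlapping with each other (may overlap Alu, as in real
  # genomes); structure: exons_per_gene exons separated by introns
  ex_n <- config$exons_per_gene
  gene_len <- ex_n * config$exon_length + (ex_n - 1L) * config$intron_length
  gene_ir <- .placeIntervals(L, config$n_genes, gene_len)
  gene_strand <- rep(c("+", "-"), length.out = config$n_genes)
  gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
  bed <- list(); exons_l <- list()
  for (g in seq_len(config$n_genes)) {
    gs <- start(gene_ir)[g]
    ex_starts <- gs + (seq_len(ex_n) - 1L) *
      (config$exon_length + config$intron_length)
    ex_ends <- ex_starts + config$exon_length - 1L
    ge <- ex_ends[ex_n]
    if (gene_strand[g] == "+") {
      thick <- c(gs + config$utr5_length, ge - config$utr3_length)
    } else {
      thick <- c(gs + config$utr3_length, ge - config$utr5_length)
    }
    bed[[g]] <- sprintf(
      "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
      chrom, gs - 1L, ge, gene_ids[g], gene_strand[g],
      thick[1] - 1L, thick[2], ex_n,
      paste(rep(config$exon_length, ex_n), collapse = ","),
      paste(ex_starts - gs, collapse = ","))
    exons_l[[g]] <- IRanges(ex_starts, ex_ends)
  }
  gene_occupied <- gene_ir

  # similarity mask: intergenic, non-Alu
  sim_ir <- .placeIntervals(L, config$n_similarity, config$similarity_length,
                            occupied = c(gene_occupied, alu_ir))

  # homopolymer runs: intergenic, non-Alu, away from the similarity mask
  run_len <- config$homopolymer_run_length
  run_ir <- .placeIntervals(L, config$n_homopolymer_runs, run_len,
                            occupied = c(gene_occupied, alu_ir, sim_ir))
  run_base <- sample(c("A", "C", "G", "T"), length(run_ir), replace = TRUE)
  for (r in seq_along(run_ir))
    seqc[start(run_ir)[r]:end(run_ir)[r]] <- run_base[r]

  occupied_all <- c(gene_occupied, sim_ir, run_ir)

  .pickPositions <- function(n, inside = NULL, avoid = IRanges()) {
    # sample distinct positions inside `inside` (IRanges; NULL = anywhere)
    # avoiding `avoid` and previously planted positions
    pool <- if (is.null(inside)) seq_len(L)
            else unlist(lapply(seq_along(inside), function(i)
              start(inside)[i]:end(inside)[i]))
    if (length(avoid))
      pool <- pool[!overlapsAny(IRanges(pool, width = 1L), avoid)]
    if (length(pool) < n) stop("not enough positions to plant sites")
    sort(sample(pool, n))
  }

  planted <- IRanges()
  .reserve <- function(pos) {
    planted <<- c(planted, IRanges(pos, width = 1L))
  }

  # A-to-G editing sites (genomic A forced at the position)
  n_in_alu <- round(config$n_editing_sites * config$alu_site_fraction)
  n_out <- config$n_editing_sites - n_in_alu
  pos_alu <- .pickPositions(n_in_alu, alu_ir, planted)
  .reserve(pos_alu)
  pos_out <- if (n_out > 0)
    .pickPositions(n_out, avoid = c(occupied_all, alu_ir, planted))
  else integer()
  .reserve(pos_out)
  site_pos <- c(pos_alu, pos_out)
  # editing is A-to-I on the transcript: sites inside minus-strand genes
  # are planted as genomic T>C (transcript-sense A>G); everywhere else the
  # genomic strand carries the A
  site_gr <- IRanges(site_pos, width = 1L)
  on_minus <- overlapsAny(site_gr, gene_ir[gene_strand == "-"])
  on_plus <- overlapsAny(site_gr, gene_ir[gene_strand == "+"])
  minus_only <- on_minus & !on_plus
  site_ref <- ifelse(minus_only, "T", "A")
  site_var <- ifelse(minus_only, "C", "G")
  seqc[site_pos] <- site_ref
  rlev <- function(n) {
    lv <- rbeta(n, config$level_shape1, config$level_shape2)
    while (any(lv < config$level_min))
      lv[lv < config$level_min] <-
        rbeta(sum(lv < config$level_min), config$level_shape1,
              config$level_shape2)
    lv
  }
  sites <- data.table(
    chrom = chrom, pos = site_pos, ref = site_ref, var = site_var,
    level = rlev(length(site_pos)),
    in_alu = c(rep(TRUE, n_in_alu), rep(FALSE, n_out)),
    class = "editing")

  # 3'UTR editing sites: transcript-sense A inside a gene's 3'UTR, away
  # from homopolymer contexts
  utr3_rows <- list()
  if (config$n_utr3_sites > 0L) {
    per_gene <- ceiling(config$n_utr3_sites / config$n_genes)
    got <- 0L
    for (g in seq_len(config$n_genes)) {
      if (got >= config$n_utr3_sites) break
      gs <- start(gene_ir)[g]; ge <- end(gene_ir)[g]
      utr3_geno <- if (gene_strand[g] == "+")
        IRanges(ge - config$utr3_length + 1L, ge)
      else IRanges(gs, gs + config$utr3_length - 1L)
      # keep 35 bp off the UTR edges so 61-nt queries stay inside
      cand <- (start(utr3_geno) + 35L):(end(utr3_geno) - 35L)
      cand <- cand[!overlapsAny(IRanges(cand, width = 1L), planted)]
      cand <- sample(cand)
      for (p in cand) {
        if (got >= config$n_utr3_sites) break
        base_needed <- if (gene_strand[g] == "+") "A" else "T"
        old <- seqc[p]
        seqc[p] <- base_needed
        win <- seqc[max(1L, p - 5L):min(L, p + 5L)]
        if (max(rle(win)$lengths) >= 5L) { seqc[p] <- old; next }
        .reserve(p)
        utr3_rows[[length(utr3_rows) + 1L]] <- data.table(
          chrom = chrom, pos = p,
          ref = base_needed,
          var = if (base_needed == "A") "G" else "C",
          level = rlev(1L), in_alu = FALSE, class = "utr3")
        got <- got + 1L
        if (got %% per_gene == 0L) break
      }
    }
    if (length(utr3_rows))
      sites <- data.table::rbindlist(list(sites,
                                          data.table::rbindlist(utr3_rows)))
  }

  # germline SNPs: anywhere except planted positions
  snp_pos <- .pickPositions(config$n_snps, avoid = planted)
  .reserve(snp_pos)
  snp_ref <- seqc[snp_pos]
  snp_alt <- vapply(snp_ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  snps <- data.table(chrom = chrom, pos = snp_pos, ref = snp_ref,
                     alt = unname(snp_alt),
                     het = runif(length(snp_pos)) < config$snp_het_fraction)

  # hexamer artifacts: intergenic non-Alu, variant support only at read
  # starts
  hex_pos <- .pickPositions(config$n_hexamer_artifacts,
                            avoid = c(occupied_all, alu_ir, planted))
  .reserve(hex_pos)
  hex_ref <- seqc[hex_pos]
  hexamer <- data.table(
    chrom = chrom, pos = hex_pos, ref = hex_ref,
    var = vapply(hex_ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""))

  # homopolymer artifact sites: center of a planted run
  stopifnot(config$n_homopolymer_sites <= length(run_ir))
  run_idx <- sample(seq_along(run_ir), config$n_homopolymer_sites)
  hp_pos <- start(run_ir)[run_idx] + run_len %/% 2L
  hp_ref <- run_base[run_idx]
  homop <- data.table(
    chrom = chrom, pos = hp_pos, ref = hp_ref,
    var = vapply(hp_ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""),
    level = config$artifact_level)

  ref <- DNAStringSet(setNames(paste(seqc, collapse = ""), chrom))

  alu <- GRanges(chrom, alu_ir)
  metadata(alu)$label <- "Alu"
  similarity <- GRanges(chrom, sim_ir)
  metadata(similarity)$label <- "similarity_mask"
  snp_gr <- GRanges(chrom, IRanges(snps$pos, width = 1L))
  mcols(snp_gr) <- DataFrame(ref = snps$ref, alt = snps$alt)

  bed_lines <- unlist(bed)
  genes_gm <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeXStringSet(ref, file.path(outDir, "ref.fa"))
    writeLines(bed_lines, file.path(outDir, "genes.bed"))
    rtracklayer::export(alu, file.path(outDir, "alu.bed"), format = "bed")
    rtracklayer::export(similarity, file.path(outDir, "similarity.bed"),
                        format = "bed")
    .writeMinimalVcf(snps, file.path(outDir, "snps.vcf"))
    genes_gm <- readGeneModels(file.path(outDir, "genes.bed"))
  } else {
    tmp <- tempfile(fileext = ".bed")
    writeLines(bed_lines, tmp)
    genes_gm <- readGeneModels(tmp)
    unlink(tmp)
  }

  list(ref = ref, genes = genes_gm, alu = alu, similarity = similarity,
       snps = snp_gr,
       truth = list(sites = sites, snps = snps, hexamer = hexamer,
                    homopolymer_sites = homop,
                    homopolymer_runs = data.table(
                      chrom = chrom, start = start(run_ir),
                      end = end(run_ir), base = run_base)))
}

.writeMinimalVcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=editomics-simulator",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  snps$chrom, snps$pos, snps$ref, snps$alt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.simQuals <- function(n, config) {
  list(baq = ifelse(runif(n) < config$frac_low_baq, config$baq_low,
                    config$baq_high),
       mapq = ifelse(runif(n) < config$frac_low_mapq, config$mapq_low,
                     config$mapq_high))
}

.columnReads <- function(pos, ref, var, p_var, config, read_pos_var = NULL) {
  # expand one set of columns (vectorized over positions) into read rows
  ref <- rep_len(ref, length(pos)); var <- rep_len(var, length(pos))
  p_var <- rep_len(p_var, length(pos))
  depth <- rpois(length(pos), config$coverage)
  keep <- depth > 0L
  pos <- pos[keep]; ref <- ref[keep]; var <- var[keep]
  p_var <- p_var[keep]; depth <- depth[keep]
  idx <- rep(seq_along(pos), depth)
  n <- length(idx)
  is_var <- runif(n) < p_var[idx]
  base <- ifelse(is_var, var[idx], ref[idx])
  if (is.null(read_pos_var)) {
    rp <- sample.int(config$read_length, n, replace = TRUE)
  } else {
    # artifact columns: variant reads only at read starts, reference reads
    # strictly after the prefix
    rp <- integer(n)
    rp[is_var] <- sample.int(read_pos_var, sum(is_var), replace = TRUE)
    rp[!is_var] <- sample(seq.int(read_pos_var + 1L, config$read_length),
                          sum(!is_var), replace = TRUE)
  }
  q <- .simQuals(n, config)
  data.table(chrom = "chrS1", pos = pos[idx], ref = ref[idx], base = base,
             baq = as.integer(q$baq), mapq = as.integer(q$mapq),
             read_pos = as.integer(rp),
             read_id = paste0("r", pos[idx], "_", sequence(depth)))
}

#' Simulate read-base observation tables
#'
#' Emits a sparse pileup: read columns at every planted-truth position plus
#' columns hit by random sequencing errors (a column with no variant read
#' can never produce a candidate, so reference-only columns elsewhere are
#' not materialized).  Coverage per column is Poisson(\code{coverage});
#' edited-read counts are Binomial(depth, level); SNPs are variant in both
#' RNA and DNA (heterozygous at level 0.5, homozygous at 1); hexamer
#' artifact columns carry variant reads only at \code{read_pos <=} the
#' hexamer prefix; qualities are drawn with a configured fraction below the
#' caller thresholds.  A fraction \code{obs_des_fraction} of planted
#' editing sites is down-shifted by \code{obs_des_fold} in every cell type
#' except the first (differential-editing truth for the demo).
#'
#' @param sim result of \code{\link{simulateReference}}.
#' @param config the \code{\link{simulationConfig}}.
#' @param samples data.frame with columns \code{sample_id} and
#'   \code{cell_type}; default two replicates of one cell type.
#' @param outDir if given, per-sample \code{<id>.obs.tsv} and
#'   \code{dna.obs.tsv} are written there.
#' @return list with \code{obs} (named list of per-sample observation
#'   data.tables), \code{dna} (DNA observation data.table) and
#'   \code{des_truth} (data.table of down-shifted sites, possibly empty).
#' @export
simulateObservations <- function(sim, config,
                                 samples = data.frame(
                                   sample_id = c("s1", "s2"),
                                   cell_type = c("A", "A")),
                                 outDir = NULL) {
  truth <- sim$truth
  ct_levels <- unique(samples$cell_type)
  n_des <- if (length(ct_levels) > 1L)
    round(nrow(truth$sites) * config$obs_des_fraction) else 0L
  set.seed(config$seed + 50L)
  # differential sites are planted among well-edited sites so the shifted
  # level still clears the detection floor
  eligible <- which(truth$sites$level >= 0.25)
  des_idx <- if (n_des > 0L && length(eligible))
    sort(sample(eligible, min(n_des, length(eligible)))) else integer()
  des_truth <- truth$sites[des_idx]
  obs <- list()
  for (s in seq_len(nrow(samples))) {
    set.seed(config$seed + 100L + s)
    lev <- truth$sites$level
    if (samples$cell_type[s] != ct_levels[1] && length(des_idx))
      lev[des_idx] <- lev[des_idx] / config$obs_des_fold
    parts <- list(
      .columnReads(truth$sites$pos, truth$sites$ref, truth$sites$var,
                   lev, config),
      .columnReads(truth$snps$pos, truth$snps$ref, truth$snps$alt,
                   ifelse(truth$snps$het, 0.5, 1), config),
      .columnReads(truth$hexamer$pos, truth$hexamer$ref, truth$hexamer$var,
                   config$artifact_level, config,
                   read_pos_var = 6L),
      .columnReads(truth$homopolymer_sites$pos, truth$homopolymer_sites$ref,
                   truth$homopolymer_sites$var,
                   truth$homopolymer_sites$level, config))
    # sequencing-error columns
    n_err <- rpois(1, config$chrom_length * config$coverage *
                     config$error_rate)
    if (n_err > 0L) {
      ep <- unique(sample.int(config$chrom_length, n_err, replace = TRUE))
      ep <- ep[!ep %in% c(truth$sites$pos, truth$snps$pos,
                          truth$hexamer$pos, truth$homopolymer_sites$pos)]
      if (length(ep)) {
        eref <- substring(as.character(sim$ref[[1]]), ep, ep)
        evar <- vapply(eref, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        # roughly one error read per affected column
        parts[[length(parts) + 1L]] <-
          .columnReads(ep, eref, unname(evar),
                       rep(1.5 / config$coverage, length(ep)), config)
      }
    }
    tab <- data.table::rbindlist(parts)
    tab$sample_id <- samples$sample_id[s]
    setorder(tab, chrom, pos, read_id)
    obs[[samples$sample_id[s]]] <-
      tab[, c("sample_id", "chrom", "pos", "ref", "base", "baq", "mapq",
              "read_pos", "read_id"), with = FALSE]
  }
  # DNA track: clean reference at all planted RNA positions, variant at
  # SNPs according to zygosity
  set.seed(config$seed + 99L)
  all_pos <- sort(unique(c(truth$sites$pos, truth$snps$pos,
                           truth$hexamer$pos,
                           truth$homopolymer_sites$pos)))
  refc <- substring(as.character(sim$ref[[1]]), all_pos, all_pos)
  pvar <- rep(0, length(all_pos))
  varb <- refc
  i <- match(truth$snps$pos, all_pos)
  pvar[i] <- ifelse(truth$snps$het, 0.5, 1)
  varb[i] <- truth$snps$alt
  cfg_dna <- config; cfg_dna$coverage <- config$dna_coverage
  dna <- .columnReads(all_pos, refc, varb, pvar, cfg_dna)
  dna$sample_id <- "dna"
  setorder(dna, chrom, pos, read_id)
  dna <- dna[, c("sample_id", "chrom", "pos", "ref", "base", "baq", "mapq",
                 "read_pos", "read_id"), with = FALSE]
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(obs))
      writeObservations(obs[[sid]], file.path(outDir,
                                              paste0(sid, ".obs.tsv")))
    writeObservations(dna, file.path(outDir, "dna.obs.tsv"))
  }
  list(obs = obs, dna = dna, des_truth = des_truth)
}

#' Simulate an editing-level matrix with planted modules and DESs
#'
#' Module sites follow a one-factor model per module, x = w f + sqrt(1 -
#' w^2) e, with weights set to reach the target within-module correlation
#' (w = sqrt(\code{module_cor})); \code{hubs_per_module} sites per module
#' get weight \code{hub_weight} and are the planted hubs.  Background
#' sites are independent.  Latent profiles are mapped to editing levels by
#' level = clip(mu + \code{level_sd} x, 0.01, 0.99) with per-site mu drawn
#' uniformly from \code{level_mean_range}.  \code{n_des_sites} background
#' sites get a group shift: group A at \code{des_level} and group B at
#' \code{des_level * des_fold} (direction \code{"up"}) or divided by the
#' fold (\code{"down"}), clipped; the realized fold is recorded.  Counts
#' are Binomial(\code{matrix_depth}, level).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{levels}, \code{edited}, \code{total} matrices
#'   (sites x samples), \code{groups} (per-column labels) and \code{truth}
#'   (list: \code{modules} integer labels with 0 = background, \code{hubs}
#'   site keys, \code{des} data.table).
#' @export
simulateEditingMatrix <- function(config) {
  set.seed(config$seed + 7L)
  sizes <- as.integer(config$module_sizes)
  n_mod_sites <- sum(sizes)
  n <- n_mod_sites + config$n_background
  S <- config$n_samples_a + config$n_samples_b
  if (S < 3L) stop("need at least 3 samples")
  groups <- c(rep("A", config$n_samples_a), rep("B", config$n_samples_b))
  labels <- integer(n)
  w <- numeric(n)
  x <- matrix(rnorm(n * S), n, S)
  off <- 0L
  hubs <- character()
  keys <- sprintf("site%04d", seq_len(n))
  for (m in seq_along(sizes)) {
    idx <- off + seq_len(sizes[m])
    labels[idx] <- m
    f <- rnorm(S)
    wm <- rep(sqrt(config$module_cor), sizes[m])
    nh <- min(config$hubs_per_module, sizes[m])
    wm[seq_len(nh)] <- config$hub_weight
    x[idx, ] <- wm %o% f + sqrt(1 - wm^2) * x[idx, , drop = FALSE]
    w[idx] <- wm
    hubs <- c(hubs, keys[idx[seq_len(nh)]])
    off <- off + sizes[m]
  }
  mu <- runif(n, config$level_mean_range[1], config$level_mean_range[2])
  lv <- mu + config$level_sd * x
  # planted DES sites: background sites with a group mean shift
  des_idx <- integer()
  if (config$n_des_sites > 0L) {
    bg <- which(labels == 0L)
    if (config$n_des_sites > length(bg))
      stop("n_des_sites exceeds background size")
    des_idx <- bg[seq_len(config$n_des_sites)]
    la <- config$des_level
    lb <- if (config$des_direction == "up") la * config$des_fold
          else la / config$des_fold
    lv[des_idx, groups == "A"] <- la +
      config$level_sd * x[des_idx, groups == "A", drop = FALSE]
    lv[des_idx, groups == "B"] <- lb +
      config$level_sd * x[des_idx, groups == "B", drop = FALSE]
  }
  lv <- pmin(pmax(lv, 0.01), 0.99)
  total <- matrix(as.integer(config$matrix_depth), n, S)
  edited <- matrix(rbinom(n * S, as.vector(total), as.vector(lv)), n, S)
  dimnames(lv) <- dimnames(total) <- dimnames(edited) <-
    list(keys, paste0(tolower(groups), "_", seq_len(S)))
  des <- data.table(site = keys[des_idx])
  if (length(des_idx)) {
    des$level_a <- rowMeans(lv[des_idx, groups == "A", drop = FALSE])
    des$level_b <- rowMeans(lv[des_idx, groups == "B", drop = FALSE])
    des$realized_fold <- pmax(des$level_a, des$level_b) /
      pmin(des$level_a, des$level_b)
    if (any(des$realized_fold < config$des_fold * 0.9))
      warning("clipping reduced some realized folds below the target")
  }
  list(levels = lv, edited = edited, total = total, groups = groups,
       truth = list(modules = setNames(labels, keys), hubs = hubs,
                    weights = setNames(w, keys), des = des))
}

#' Wrap a simulated matrix as an EditingExperiment
#'
#' @param msim result of \code{\link{simulateEditingMatrix}}.
#' @return an \code{\link{EditingExperiment}} on a synthetic contig.
#' @export
matrixToExperiment <- function(msim) {
  n <- nrow(msim$levels)
  rr <- GRanges("chrM1", IRanges(seq_len(n), width = 1L), strand = "+")
  mcols(rr) <- DataFrame(ref = "A", var = "G", subst_type = "A>G",
                         in_alu = TRUE, region_class = "intergenic",
                         gene_ids = "", edited_reads = 0L, total_reads = 0L,
                         level = NA_real_)
  se <- SummarizedExperiment(
    assays = list(edited = msim$edited, total = msim$total,
                  level = msim$levels,
                  qualified = matrix(TRUE, n, ncol(msim$levels),
                                     dimnames = dimnames(msim$levels))),
    rowRanges = rr,
    colData = DataFrame(sample_id = colnames(msim$levels),
                        cell_type = msim$groups,
                        row.names = colnames(msim$levels)))
  new("EditingExperiment", se)
}
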