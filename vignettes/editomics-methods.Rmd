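---
title: "Methods: RNA editome discovery, differential editing and co-editing networks"
author: "editomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA editome discovery, differential editing and co-editing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomics)
```

# The problem

A-to-I RNA editing — deamination of adenosine by the ADAR enzymes — is read
out by sequencers as an A>G mismatch between RNA reads and the genome.
Calling editing sites from RNA-seq is therefore a variant-calling problem
with an unusual error model: germline SNPs, sequencing and alignment
errors, random-hexamer priming artifacts at read starts, homopolymer
contexts and multi-mapping regions all masquerade as candidate edits.
Because the bulk of human editing sits in *Alu* repeats (whose inverted
copies form the double-stranded RNA that ADAR requires), practical
pipelines treat Alu and non-Alu candidates differently: the prior odds of a
true edit in Alu are high enough that only the core read-support thresholds
are applied there, while non-Alu candidates face a stricter battery.

`editomics` implements that filter cascade, the downstream annotation and
enrichment summaries, a two-stage differential-editing test between cell
types, a miRNA target gain/loss classifier for edited 3'UTR positions, and
weighted co-editing network analysis — together with a synthetic-data
generator that plants every signal and artifact class with known truth, so
the whole pipeline is testable without any external data.

# Site discovery

The unit of input is a *read-base observation*: one aligned read base at
one genomic position, with its (BAQ-recalibrated) base quality, mapping
quality and position within the read.  Alignment, duplicate marking and
BAQ recalibration are upstream tools' work; this package consumes their
output as a long-format TSV (`readObservations()`).

An observation is **qualified** if base quality \(\ge\) 25, mapping
quality \(\ge\) 20 and its read position is beyond the first six bases
(random-hexamer priming can introduce mismatches at read starts; the
exclusion is applied to observations *before* counting, not to sites after
the fact, so a site with mixed support keeps its genuine reads).  A
**candidate** is any position with qualified depth \(\ge\) 5 whose most
frequent non-reference base has \(\ge\) 2 qualified supporting reads; its
editing level is the variant fraction of qualified depth.  Ties between
two variant bases are broken by summed base quality, and a persistent tie
drops the column — deterministic and conservative.

Candidates then pass through subtractive, idempotent filters, each
recording its own audit flag:

* **Genomic evidence** — a candidate survives only if DNA reads cover the
  position with qualified depth \(\ge\) 5 *and* carry zero variant reads.
  Sites without sufficient DNA coverage are removed as unassessable: the
  requirement that a variant be absent from genomic reads can only be
  established where genomic reads exist.
* **Known variants** — position-level exclusion against any number of
  variant sets (dbSNP-style VCFs).  Allele-level matching is deliberately
  not used; a polymorphic position is suspect regardless of allele.
* **Non-Alu battery** (candidates inside the Alu mask are exempt):
  editing level \(\ge\) 0.1; intronic candidates within 4 bp of an
  exon–intron boundary removed; candidates covered by a reference
  homopolymer run of \(\ge\) 5 identical bases removed (the window
  examined is \(\pm(\mathrm{run}-1)\) around the site); candidates in a
  precomputed genome-similarity mask removed.  Computing mappability is
  out of scope — the similarity mask is consumed as a BED file.

Strand is assigned only when all overlapping gene models agree; a genomic
T>C inside a minus-strand gene is then reported as A>G on the transcribed
strand.  Region classes are assigned with precedence
CDS > UTR3 > UTR5 > ncRNA_exonic > intronic > ncRNA_intronic > intergenic;
UTR3 outranks UTR5 so that positions in overlapping UTRs land in the class
of primary biological interest here.  Replicate editomes are intersected
on (chromosome, position, variant base), and shared vs replicate-specific
sites feed the depth comparison (`depthComparison()`, rank-sum).

Region enrichment (`categoryEnrichment()`) normalizes for coverage: the
background is the per-class count of adenosines (on the annotated strand)
with qualified coverage at the caller's depth floor, and each class gets a
two-sided Fisher's exact test on {edited, covered-not-edited} x {in class,
elsewhere} with Benjamini–Hochberg adjustment across classes.  BH is used
everywhere a family of tests is run.

# Differential editing

Editing levels are re-estimated across samples by interrogating the query
sites against each sample's observations (quality thresholds only — the
hexamer exclusion belongs to de novo calling); a site is qualified in a
sample at \(\ge\) 5 qualified reads.  The two-stage DES procedure is:

1. **Replicate concordance.** Within each cell type, a two-sided Fisher's
   exact test between replicates' (edited, not-edited) counts must give
   \(p \ge 0.05\) (configurable); discordant sites are ineligible, not
   "not differential".  Sites unqualified in any required sample are
   likewise ineligible — absence of evidence is kept explicit.
2. **Rate test with a fold gate.** Replicates are pooled per group and an
   exact conditional test of two rates is applied: conditional on the
   total edited count \(K = k_1 + k_2\), \(k_1 \sim
   \mathrm{Bin}(K,\, n_1/(n_1+n_2))\) under the null of equal editing
   rates, with the two-sided p summing all outcomes no more likely than
   the observed one.  This is the standard exact construction for
   comparing Poisson rates with exposures equal to the qualified depths —
   i.e. "normalized against read coverage".  P-values are BH-adjusted
   across eligible sites (raw-p behaviour via `adjust = FALSE`), and a DES
   additionally requires a pooled-level fold change \(\ge\) 2.  The fold
   is a ratio of pooled rates, not raw counts.

The large-sample confirmation (`confirmDESLargeSet()`) applies a two-sided
Wilcoxon rank-sum test per site on a complete level matrix with BH across
sites.  One attainability caveat is worth stating: with \(n_A = 6\) and
\(n_B = 3\) samples the smallest achievable rank-sum p is \(2/\binom{9}{3}
\approx 0.024\), so a BH threshold of \(0.05\,k/m\) can only be cleared
when the tested family is small or a large fraction of it is truly
shifted.  The package's recovery tests therefore use group sizes at which
a planted shift is individually significant; users comparing few samples
should test a focused site set, exactly as a confirmation analysis (which
re-tests previously identified DESs) naturally does.

# miRNA target rewiring

For each edited 3'UTR position, two 61-nt transcript-sense queries are
built — 30 bases either side, with A (reference) or G (edited) at the
center — and scanned against mature miRNA sequences with a two-phase,
miRanda-style scanner:

1. **Complementarity score.** Gotoh local alignment of the miRNA (3'→5')
   against the query (5'→3'), scoring Watson–Crick pairs +5, G:U wobbles
   +2, mismatches −3, affine gaps −9/−4, with substitution scores at
   miRNA seed positions 2–8 multiplied by 4.  Hits require score
   \(\ge\) 155.  Ties are resolved to the leftmost, shortest alignment.
2. **Duplex energy.** Nearest-neighbor stacking over consecutive paired
   columns using the standard Watson–Crick 37 °C parameter set, a constant
   approximation (−1.0 kcal/mol) for stacks containing a wobble, and a
   fixed +3 kcal/mol penalty per internal loop or bulge.  Hits require
   \(\le\) −20 kcal/mol.  The model is monotone — more pairing never
   raises the energy — which is the property the threshold exploits; it
   is an approximation, not a secondary-structure prediction, and parity
   with the miRanda binary is explicitly not claimed.

A predicted target counts only if its alignment covers the editing
position.  Per miRNA, the change class is *gain* (covering hit on the
edited allele only), *loss* (reference only), *present_both* or
*absent_both*; swapping alleles maps gain to loss exactly.

# Co-editing networks

The network is built from sites qualified in **every** sample (a complete
matrix, no missingness) with unsigned soft-threshold adjacency
\(a_{ij} = |\mathrm{cor}(x_i, x_j)|^{12}\) and the topological overlap
\[
\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
                        {\min(k_i, k_j) + 1 - a_{ij}},
\]
clustered by average linkage on \(1 - \mathrm{TOM}\).  The published
dynamic hybrid tree cut is replaced by a documented simplification whose
design surface is planted-structure recovery, not parity with the
reference implementation:

* **Adaptive static cut.** The tree is cut at the height (grid
  0.90–0.999) that maximizes the number of *tight* branches — branches
  with at least `minModuleSize` (30) members whose median intra-branch TOM
  dissimilarity is \(\le\) 0.99; ties resolve to the lowest height.  The
  tightness condition stops loose clusters of chained background from
  counting as modules, and the adaptive height matters because latent
  module factors can correlate by chance when samples are few, delaying
  branch separation to dataset-specific heights.
* **Membership pruning.** Average linkage lets weakly connected sites
  chain into branches, so members are released when their mean TOM
  dissimilarity to co-members is a branch-adaptive outlier (median +
  1.5 MAD) or their correlation with the module eigen-profile falls below
  0.5; a module shrunk below half the size floor dissolves.  Two passes.
* **Reassignment.** Unassigned sites are adopted by the module whose
  eigen-profile they correlate with at \(|r| \ge 0.75\).

These three constants were fixed by calibration on the generator's
planted-module simulations (module sizes 60/40/30, within-correlation
0.8, 9 samples, 200 background sites) before the acceptance assertions
were frozen, and are exposed in `NetworkParams`.  Module eigen-profiles
are unit-norm first right-singular vectors of the row-standardized member
submatrix, sign-oriented so the mean member correlation is positive;
modules whose eigen-profiles cluster below 0.25 on \(1 - r\) are merged
(idempotent); module membership (MM) is the correlation of a site's
profile with an eigen-profile, and hubs are own-module sites with
MM > 0.9.  Labels are deterministic (ordered by size, ties by smallest
member key).  With only nine samples the sampling error of a correlation
is large (\(\mathrm{sd}(z) \approx 0.41\)); perfect background/module
separation is information-theoretically out of reach, which is why the
recovery target is an adjusted Rand index of about 0.8, not 1.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions; every draw is seeded and
byte-reproducible.  The generator emulates:

* a 100 kb genome with ~30% Alu content, stranded multi-exon genes with
  CDS/UTR structure, a similarity mask, and homopolymer runs at recorded
  positions;
* planted A-to-G sites (genomic T>C inside minus-strand genes, so the
  transcript-sense event is always A-to-G) with Beta(2, 5) editing levels
  truncated at 0.1 — right-skewed with a median near the published
  medians of 0.2–0.3 — concentrated in Alu; germline SNPs (variant in
  both RNA and DNA, and listed in the VCF); hexamer artifacts whose
  variant reads sit only in the first six read positions; homopolymer
  artifact sites centered in planted runs;
* sparse pileups: read columns are emitted at truth positions and at
  error-struck positions (a column with no variant read can never become
  a candidate, so all-reference columns elsewhere carry no information
  for the caller); coverage Poisson(30), read length 101, error rate
  10^-3, 5% of bases below the BAQ threshold and 2% below the MAPQ
  threshold;
* editing-level matrices from a one-factor model per module
  (\(x_i = w_i f + \sqrt{1-w_i^2}\,\varepsilon\), \(w = \sqrt{0.8}\);
  two hub sites per module at \(w = 0.995\), i.e. near-perfect factor
  representatives), mapped to levels by \(\mu_i + 0.08\,x\) clipped to
  [0.01, 0.99] with \(\mu_i \sim U(0.2, 0.6)\), plus binomial counts at
  depth 50; differential sites use a base level of 0.27 — the published
  median editing level of the pluripotent state — shifted 2.5-fold, and
  null simulations set the biological noise to zero so that "no
  difference" genuinely means equal rates;
* miRNA fixtures: for each gain event a miRNA is designed whose
  complement matches the edited allele across the site with a perfect
  seed and enough non-seed mismatches that the reference allele's
  broken-seed alignment falls below the score threshold; loss events
  mirror this against the reference allele (the edited allele then
  carries a seed G:U wobble, hence a larger mismatch budget); every
  design is verified with the package's own scanner before acceptance.

What the generator does **not** emulate — quality-by-cycle error
profiles, splice-aware reads, fragment-level read pairs, overdispersed
editing levels, batch structure — bounds what passing tests show: they
demonstrate correctness of the implemented rules and the statistical
behaviour of the tests under the stated models, not performance on real
libraries.

# Numerical and degenerate-input choices

Fisher, rank-sum and chi-square tests are delegated to R's `stats`
(exact where applicable; the level-distribution chi-square merges bins
rightward until expected counts reach 5); the exact conditional rate test
is enumerated directly from `dbinom` with the conventional
\(1 + 10^{-7}\) tie guard, and the unit tests hold it to the independent
enumeration oracle at \(10^{-12}\).  Zero-variance profiles are dropped
from adjacency with a warning and excluded from MM; a constant row in the
rank-sum confirmation gets \(p = 1\); empty site lists propagate as empty
results, not errors.  All on-disk positions are 1-based (BED converted on
import); in memory, positions live in `GRanges`.

# Problem sizes

The test-suite and acceptance simulations use a 100 kb genome at coverage
30 (300 planted sites), 2 000 null and 200 shifted sites at depth 50 for
the DES operating characteristics, ten 330 x 9 matrices for module
recovery, and a handful of 61-nt x 22-nt scans — sizes at which every
stochastic assertion has comfortable Monte-Carlo margin while the whole
suite stays fast.

# Known limitations

Single-nucleotide substitutions only (no indels, no multi-allelic sites,
no hyper-editing clusters); annotation is gene-level, not
isoform-resolved; the energy model is a stacking approximation; the
module detector is a simplification of the published dynamic hybrid cut;
BAM ingestion is not provided — observations arrive as TSV produced by an
upstream pileup step.
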