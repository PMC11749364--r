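# editomics

Comparative RNA-editome analysis from read-level evidence: discovery of
A-to-I (read as A-to-G) editing sites through a quality- and
artifact-aware filter cascade with distinct handling of *Alu* and
non-*Alu* regions, editome annotation and enrichment, differential
editing between cell types, classification of microRNA target gain/loss
at edited 3ʹUTR positions, and weighted co-editing network analysis with
module eigen-profiles and hub sites. A seeded synthetic-data generator
plants every signal and artifact class with known truth, so the entire
pipeline runs and validates end to end without external data.

The package is aimed at transcriptomics groups profiling editing in stem
cell differentiation or similar designs: bulk RNA-seq with replicates,
matched genomic DNA for the reference cell type, and standard annotation
files (BED12/GTF gene models, BED masks, VCF variant sets, FASTA).

## The statistics at the core

* **Calling**: a candidate needs ≥ 5 qualified reads (BAQ ≥ 25,
  MAPQ ≥ 20, read position beyond the first 6 bases) including ≥ 2
  variant reads; level = variant / qualified depth. Non-Alu candidates
  additionally require level ≥ 0.1, no splice junction within 4 bp
  (intronic), no homopolymer run ≥ 5 covering the site, and absence from
  a genome-similarity mask; all candidates must be clean and covered
  (≥ 5 reads, 0 variant) in genomic DNA and absent from known-variant
  sets.
* **Differential editing**: replicate concordance by two-sided Fisher's
  exact test (p ≥ 0.05 required within each group), then an exact
  conditional rate test on pooled counts — given K = k₁ + k₂ edited
  reads, k₁ ~ Bin(K, n₁/(n₁+n₂)) under equal rates — with BH adjustment
  and a ≥ 2-fold pooled-level change; a rank-sum + BH confirmation for
  larger sample sets.
* **Retargeting**: 61-nt reference/edited transcript-sense queries,
  seed-weighted local complementarity alignment (score ≥ 155) and a
  nearest-neighbor duplex-energy gate (≤ −20 kcal/mol); gain/loss from
  hits covering the edited position.
* **Networks**: unsigned adjacency |cor|¹², topological overlap,
  average-linkage modules (adaptive cut + pruning), eigen-profiles as
  first principal components, module membership MM = cor(site, eigen),
  hubs at MM > 0.9, module merging at eigen-correlation 0.75.

## Worked example

Simulate a study, run discovery, and compare with the planted truth:

```r
library(editomics)

cfg  <- simulationConfig(seed = 1)
sim  <- simulateReference(cfg)          # genome, genes, masks, SNPs, truth
so   <- simulateObservations(sim, cfg)  # read-base tables (RNA + DNA)

p     <- CallerParams()
cands <- callCandidates(so$obs$s1, p)
cands <- filterGenomicEvidence(cands, so$dna, p)
cands <- filterKnownVariants(cands, sim$snps)
cands <- applyNonAluFilters(cands, sim$alu, sim$genes, sim$ref,
                            sim$similarity, p)
sites <- annotateRegion(assignStrand(candidatesToSites(cands),
                                     sim$genes), sim$genes)
show(sites)
#> EditingSites with 298 sites
#>   substitution types: A>G:298
#>   in Alu: 284 / 298
```

All 298 retained sites are A>G after strand reclassification (254 were
genomic A>G; 44 sat in minus-strand genes as genomic T>C and are
re-expressed on the transcribed strand), 284 fall in the Alu mask, and
none of the planted SNPs or read-start/homopolymer artifacts survive the
cascade. Against the planted truth this run recovers 96.8% of the 308
planted sites — the misses are low-level sites whose edited reads fell
below the two-read floor by binomial sampling. The exact conditional
rate test behind DES calling is fully enumerable; for example 10 edited
of 100 reads vs 2 of 100 gives

```r
poissonRateTest(10, 100, 2, 100)
#> [1] 0.03857422   # = 158/4096
```

`runEditomeDemo(outDir, seed)` chains simulate → call → differential →
retarget → network and writes a truth-comparison report; rerunning with
the same seed reproduces every output byte for byte.

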