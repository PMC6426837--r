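---
title: "Detecting ghost genomes and testing resurrection hypotheses in hemi-clonal complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ghost genomes and testing resurrection hypotheses in hemi-clonal complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological model

A hybridogenetic (hemi-clonal) lineage arises from hybridization between two
sexual species. One haploid parental genome is thereafter transmitted
clonally — identical in every individual of the lineage, in every
generation — while the other is discarded at gametogenesis and re-acquired
each generation by mating with a sexual "host" species. The host is a
genetic parent of every offspring but never a grandparent. When the species
that donated the clonal genome is no longer found anywhere, it persists only
as a *ghost* inside its hemi-clonal descendants.

This structure has three diagnostic genetic consequences, each of which the
package turns into a statistic:

1. **Fixed heterozygosity.** At any locus where the two parental species are
   fixed for different alleles (a *diagnostic locus*), every hybridogen is
   heterozygous, carrying one allele from each side. Sexual species, by
   contrast, are mostly homozygous at such loci. Hence observed
   heterozygosity (H_O, the mean over loci of the within-taxon heterozygote
   fraction) is an order of magnitude higher in hybridogens, and the
   fraction of diagnostic-panel loci at which an individual is
   A-side/B-side heterozygous (`f_het`, from `hybridogen_score()`) is near 1
   for hybridogens and near 0 for sexual individuals.

2. **No fixed differences against the host.** Because every hybridogen
   carries a fresh host gamete, a lineage and its host taxon share an allele
   at essentially every locus: the count of *absolute fixed differences*
   (loci at which two taxa share no observed alleles, `tloc = 0`) is zero.

3. **The resurrection test.** A putative "pure" population of the ghost
   species could in principle be a natural de-extinction: offspring of a
   cross between two hemi-clonal lineages that both carry the ghost genome.
   But such offspring are, locus by locus, one clonal haplotype from each
   founding lineage — so they must share an allele with each founder at
   *every* locus sampled. Any absolute fixed difference between the
   population and a founder lineage (beyond an error allowance `tau`)
   falsifies the resurrection origin; `resurrection_test()` reports
   per-founder counts, locus lists and a verdict.

## Statistics and their conventions

* **Fixed differences** (`fixed_difference_count()`): a locus is compared
  only when both taxa have at least `min_n` non-missing calls there
  (default `min_n = 1`, because real remnant populations can be as small as
  a handful of individuals; the value used is recorded in the result so it
  can be tightened). With `tloc = 0` the criterion is strict set
  disjointness; with `tloc > 0` an allele shared between the taxa is
  tolerated if its frequency is at most `tloc` in at least one of them.
  Loci with data in only one taxon are excluded from the comparison and
  from `n_loci_compared` — this is why comparisons against a taxon with
  heavy locus dropout run over fewer loci.

* **Euclidean genetic distance** (`euclidean_distance()`): root sum of
  squared differences in the per-locus reference-allele frequency over
  shared-data loci, unscaled by default so that magnitudes grow with panel
  size (typical values over thousands of SNPs are in the tens); a
  `normalize` option divides by the square root of the locus count.

* **Nei (1972) standard distance** (`nei_distance()`): the per-locus
  homozygosity and identity sums are averaged across loci *before* the
  logarithm (Nei's original convention, not a per-locus log average).
  Fully disjoint profiles give an infinite distance, which is returned as
  `Inf` rather than an error.

* **PCoA** (`pcoa()`): Gower double-centering of `-D^2/2` followed by a
  symmetric eigendecomposition; axes with non-positive eigenvalues are
  dropped, with a warning recording the largest negative magnitude when it
  exceeds `1e-8` of the leading eigenvalue. Individual distances
  (`genotype_distance_matrix()`) are Euclidean on reference-allele dosage
  (0/1/2), with multi-allelic (allozyme) loci expanded to one dosage column
  per allele. Missing data are handled by pairwise-complete rescaling:
  squared differences are averaged over mutually non-missing columns and
  multiplied by the total column count. This keeps expected distances
  comparable between fully genotyped pairs and pairs with heavy random
  dropout, unlike mean imputation, which shrinks them toward the centroid.
  Coordinates are defined up to rotation and sign; all internal comparisons
  use Procrustes alignment.

* **Intermediacy** (`intermediacy()`): with taxon centroids `h`, `a`, `b` in
  the first `k` axes (default `k = 2`, the plane one inspects on a
  scatterplot), the projection fraction
  `t = ((h - a) . (b - a)) / ||b - a||^2` is 0.5 for a perfect F1 and the
  midpoint displacement `D_mid = ||h - (a+b)/2|| / ||a - b||` is 0.
  Coincident parent centroids are an error (undefined geometry).

## The filter chain

`filter_snp_chain()` applies, in order: reproducibility (`rep_avg >=
0.99`), call rate (`>= 0.95`, i.e. removing loci with *more than* 5%
missing calls — threshold comparisons are inclusive), secondaries (exactly
one randomly chosen SNP per sequenced tag, under a recorded seed), and
monomorphic-locus removal. The order matters and is recorded, with per-step
locus counts and removed-IDs, in a report that reconciles exactly
(`loci_out = loci_in - loci_removed` at every step). Monomorphic removal is
not applied automatically after `subset_dataset()`; it is a cheap explicit
call (`drop_monomorphic()`) whenever a subset is analysed on its own.
Individual-level filtering is deliberately absent: the chain filters loci
only.

## Classification

`classify_individuals()` builds a diagnostic panel for every pair of sexual
reference taxa and computes each individual's `f_het` against each panel.
An individual is called a hybridogen of the best-scoring pair when
`f_het >= theta` over at least `min_loci` usable panel loci; otherwise it is
assigned to the sexual reference with which it shares the highest
proportion of alleles. Defaults: `theta = 0.9` — "mostly fixed"
heterozygosity, leaving room for genotyping error and for panel loci where
a lineage's single founding clone happens to carry an off-side allele — and
`min_loci = 10`, below which a call is not attempted. Both are exposed
because the minimal sufficient panel size depends on marker type (an
allozyme study may have ~13 diagnostic loci; a SNP panel, hundreds).
Resurrected individuals (homozygous ghost-genome carriers) classify as
sexual members of the ghost cluster, exactly as a field worker would score
them — distinguishing them from a true remnant is the job of
`resurrection_test()`, not of the classifier.

For `tau` the default is 0: the resurrection argument is a by-definition
one ("must share alleles at all loci"), and the test conditions only on
allele sharing, never on frequencies. Positive `tau` is available because
genotyping error in small samples can manufacture a handful of spurious
fixed differences.

## What the simulator emulates — and what it does not

`sim_scenario()`/`simulate_dataset()` generate a sexual/unisexual complex
with a per-individual truth table:

* **Species divergence.** Ancestral frequencies are Uniform(0.05, 0.95);
  each species' frequencies are Balding–Nichols draws
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`. The default `Fst = 0.85` was chosen so
  the synthetic complex reproduces the structure reduced-representation SNP
  panels show for long-diverged congeners: within-species frequencies
  mostly near 0 or 1, sexual H_O of a few percent versus 0.2–0.4 for
  hybridogens, and hundreds of absolute fixed differences per sexual
  species pair. On top of this, `n_diagnostic = 40` loci per species pair
  are forced to (1, 0) frequencies, guaranteeing a diagnostic panel even in
  small scenarios.

* **Hemi-clonal inheritance.** A lineage's clonal haplotype is drawn once
  at founding (`n_founder_clones = 1` by default; several founding clones
  can be requested, since the true number in any real lineage is unknown)
  and is bit-identical across generations and individuals; each individual
  adds a fresh host gamete. Resurrection offspring are the two founders'
  clonal haplotypes combined, hence genetically identical. Remnant
  populations drift from the founding ghost frequencies by a second
  Balding–Nichols step (`F_drift = 0.05` by default — modest divergence, on
  the scale suggested by within-species phylogeographic contrasts of a few
  fixed differences and Nei D ≈ 0.1 in comparable datasets).

* **Missingness.** Two layers: per-taxon locus dropout (`dropout = c(HX =
  0.30)` by default, emulating restriction-site mutations that silence a
  locus across an entire diverged taxon — the signature that makes remnant
  populations missing-heavy) and random per-call missingness
  (`call_missing = 0.01`), so the remnant taxon sits near 31% missing data
  while everything else sits near 1%. Genotyping error (symmetric
  single-copy allele flip, `error_rate = 0` by default) is available for
  robustness experiments.

Not simulated: linkage and recombination maps, mutation during clonal
transmission, gynogenesis, sequence-level mtDNA (maternal clades are
categorical labels only), and any morphological signal. Passing tests on
this generator therefore demonstrate the *inferential logic* — the
statistics recover known truth under realistic divergence, missingness and
error regimes — not robustness to linkage disequilibrium between panel
loci, reference bias, or non-random missingness within a taxon.

A single-clone subtlety worth knowing: because a lineage's clonal haplotype
is one random draw from the donor species' gene pool, a finite sample of
the donor species can miss an allele the clone carries, producing a
handful of "fixed differences" between a lineage and the species whose
genome it transmits. The lineage-versus-*host* count, by contrast, is zero
by construction. The same sampling logic is why `tau > 0` exists for the
resurrection test.

## Numerical and degenerate-input choices

* Unordered-pair genotype storage; phase is never used. Half-missing calls
  (e.g. `./0` in VCF) are treated as fully missing.
* Integer allele codes are per-locus in first-seen order; all statistics
  are invariant to relabeling and to individual order (tested).
* A taxon with all calls missing yields `NA` heterozygosity with a warning,
  never a silent zero; taxa sharing no genotyped loci are an error naming
  the pair.
* The secondaries draw and every simulation are reproducible under recorded
  seeds; the RNG state of the caller is always restored.
* PCoA negative eigenvalues below `1e-8` of the leading eigenvalue are
  treated as numerical noise; larger ones (possible under pairwise-complete
  rescaling, which is not guaranteed Euclidean) are dropped with a warning.

## Validation problem sizes

The test suite validates each statistic against independent brute-force
oracles on ~1,000 random small datasets (up to 10 individuals x 50 loci),
checks the zero-fixed-difference law on 100 simulated scenarios, calibrates
the resurrection test on 200 replicates per verdict class at the remnant
study conditions (4,000 loci, 7 individuals, `F_drift = 0.05`), recovers the
six-taxon default scenario (120 individuals, 4,000 loci) at >= 98%
individual-level accuracy, and verifies F1 intermediacy (`t` within
[0.45, 0.55]) in >= 95% of 100 ordination replicates. A small synthetic
DArT-style fixture ships in `inst/extdata` with statistics frozen from the
oracles, pinning the full file-to-verdict path.

## Known limitations

* The resurrection test's `tau = 0` logic is exact only under error-free
  genotyping; with error, calibrate `tau` via the simulator's
  `error_rate`.
* `classify_individuals()` assumes the sexual references are correctly
  identified and non-overlapping; it does not discover reference taxa.
* Euclidean distances between profiles use one reference allele per locus,
  which halves the information at multi-allelic allozyme loci relative to a
  full per-allele expansion (the individual-level distance matrix does use
  the full expansion).
* Reported missingness is a single number per dataset; datasets assembled
  from different individual subsets will legitimately differ in the second
  decimal.
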