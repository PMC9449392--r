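---
title: "Selection-signature scans with sweepscan: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A composite breed is formed by crossing two diverged source populations and
then breeding the cross closed. Loci that were targets of selection during
breed formation leave local signatures: loss of diversity (low pooled
heterozygosity `Hp`, low nucleotide diversity `θπ`), allele-frequency
differentiation from the source breeds (high `FST`), and unusually long,
homogeneous haplotypes (high `XP-EHH`). Because each statistic has its own
blind spots and error modes, the scan combines them: windows flagged by at
least two statistics form the candidate set, and genes within ±50 kb of a
candidate window are the candidate genes.

## Statistics and their estimators

All statistics are computed in windows (default 100 kb, sliding by half a
window) over biallelic SNPs that survive the site filters (call rate
strictly above 0.9, QUAL strictly above 30, removal of *both* members of
any SNP pair closer than 5 bp — the conservative reading of the adjacency
rule; a keep-first mode is available).

* **Pooled heterozygosity.** `Hp = 2·ΣnMAJ·ΣnMIN/(ΣnMAJ+ΣnMIN)²` over the
  summed major/minor allele counts of a window's SNPs. Counts come from
  called genotypes (the data are individual genomes, not read pools).
* **FST.** The Weir–Cockerham (1984) two-population variance-components
  estimator without inbreeding term, computed per SNP and averaged
  arithmetically over the window (average-of-ratios; a ratio-of-sums
  variant is available, as is Hudson's estimator). Sites monomorphic in
  both populations, or with fewer than two non-missing alleles in either,
  are excluded. Estimates can be slightly negative; that is a property of
  the estimator, not an error.
* **Nucleotide diversity and its ratio.** Per-site unbiased heterozygosity
  `2p̂(1−p̂)·n/(n−1)` summed over a window and divided by window length in
  bp; the two-population track is `log2(θπ,focal/θπ,ref)`. Windows with a
  zero denominator are missing, never ±Inf (a pseudocount option exists
  for tiny simulated windows).
* **EHH / iHH / XP-EHH.** `EHH(x)` is the probability that two random
  haplotypes are identical from the core SNP out to distance `x`, computed
  over *all* haplotypes (so `EHH(0)` is the core-site homozygosity); this
  matches the cross-population use where a core need not be polymorphic in
  both populations. Per-core-allele curves are available for diagnostics.
  Curves stop below `EHH = 0.05` or at gaps > 200 kb (both configurable);
  `iHH` is the trapezoidal integral over both directions; `XP-EHH` is the
  *unstandardised* `ln(iHH_A/iHH_B)`, positive when haplotypes are longer
  in the first (focal) population. The published 0.7 cut-off is far below
  the |2| typical of normalised XP-EHH, so the unstandardised ratio is the
  primary output; a genome-wide mean/sd normalisation can be applied
  downstream with `z_transform()`.
* **Z-transformation.** Genome-wide, population (divide-by-N) standard
  deviation over all non-missing windows jointly; per-chromosome
  standardisation is deliberately not used, matching genome-wide Manhattan
  thresholds. A zero-spread track is an error naming the track.

### Thresholds and combination

Fixed mode uses the printed conventions: `Z(Hp) < −4`, `Z(FST) > 4`,
`XP-EHH > 0.7`, `log2 θπ-ratio > 2`, all strict. With the θπ ratio written
focal/reference, the `> 2` rule flags windows of *high* focal diversity;
for sweep detection in the focal population the opposite tail is the
relevant one. Because the intended direction is ambiguous in the
literature this package never flips it silently: `ratio_tail = "upper"`
(default, the printed rule) or `"lower"` (sweep-in-focal logic) is an
explicit argument.

Quantile mode replaces each fixed cut-off with the empirical 1st or 99th
percentile of the statistic's own genome-wide distribution — appropriate
for small (simulated) genomes where ±4 SD outliers need not exist. The
quantile is taken over the pooled values of all comparisons of one
statistic, giving one cut-off per method; per-comparison quantiles would
flag ~2 windows per method and force spurious ≥2-method coincidences on
small window universes.

Evidence is combined at window identity (contig, start): a window enters
the combined set when at least `min_methods = 2` distinct statistics
flagged it (1 = union, number of methods = intersection). Gene mapping
extends candidate windows by ±50 kb (flank applied to windows, strand
ignored, half-open overlap of ≥1 bp); window-level combination before gene
mapping is the default, gene-level combination is available via
`per_method_gene_counts()`.

## Windows

Windows start at 0, step, 2·step, …; trailing windows are truncated at the
contig end and emitted (flagged `partial`) rather than dropped, so the
windows exactly tile `[0, contig length)`. Windows with fewer than
`min_snps = 10` usable SNPs are set missing *before* Z-transformation to
keep small-sample outliers out of the tails. Internal coordinates are
0-based half-open (BED convention); VCF/GFF3 input is converted on
ingestion and user-facing reports are 1-based where the format demands it.

## Structure layer

Distances are `1 − IBS` over shared non-missing sites (the matrix can be
exported in PHYLIP format for external cross-checks). Neighbour joining is
the Saitou–Nei algorithm with the standard Q-criterion; ties take the
lowest index pair, and a negative branch length is clamped to zero with
the deficit moved to its sister so path lengths are preserved — on
additive matrices the tree reproduces the input distances exactly. PCA
uses the EIGENSOFT normalisation (centre by `2p̂`, scale by
`√(p̂(1−p̂))`, missing dosages mean-imputed per SNP); coordinates are
eigenvectors scaled by the square root of their eigenvalues. Tracy–Widom
testing is out of scope. LD decay follows the PopLDdecay conventions
(MAF strictly > 0.05, per-SNP heterozygote fraction ≤ 0.9, missing
fraction ≤ 0.1, pairs within 1 Mb, 1-kb distance bins); `r²` comes from
haplotype frequencies when the input is phased, else from squared dosage
correlation — the two agree exactly when all genotypes are homozygous.

## The simulator and its study conditions

`wf_simulate()` is a forward Wright–Fisher simulation chosen over a
coalescent because selection and admixture are then exact by construction:
an ancestral population burns in from a monomorphic state, splits into two
parents that drift independently, and an admixed hybrid is founded by
drawing each founder haplotype from parent A with probability
`admix_prop`, then mating internally. Infinite sites with collision
re-draw; crossovers `Poisson(rho·L)` at uniform positions; one contig per
dataset (concatenate independent runs for more).

The defaults are desk-scale study conditions chosen once, with reasons:

* `N = 100` diploids per population and `L = 2 Mb` keep a full replicate
  in a few seconds.
* `mu = 1e-7` is ~10× a mammalian per-generation rate, the standard
  compensation for scaled-down `N`; it yields ≈ 2,000 segregating sites
  on 2 Mb, i.e. realistic SNP density for the window sizes used.
* `rho = 5e-8` (scaled ~5×; `rho/mu = 0.5`) keeps both neutral haplotype
  blocks and sweep footprints on the 100-kb window scale.
* `split_gens = 600` (= 3·2N) makes the parents deeply diverged breeds.
  This matters for the science: a sweep in the hybrid locally erases
  *between-parent* diversity, whereas neutral drift blocks bottom out at
  *within-parent* diversity — parental divergence is what separates the
  two signals.
* `admix_gens = 20` is the scaled age of a recently formed composite
  breed.
* The optional sweep is a **standing variant of single ancestral origin**:
  `init_copies` founder haplotypes (default 20% of the pool) carry the
  allele on tracts of one origin haplotype, exponentially distributed
  around the site with mean `1/(rho·origin_age)` per side
  (`origin_age = 150` generations, the expected age of a neutral variant
  at 20% frequency when 2N = 200, giving ≈130-kb tracts). Selection
  (`s = 0.1`, `h = 0.5`, fitnesses 1, 1+hs, 1+s) then drives it past
  `target_freq = 0.95`; trajectories that lose the allele (or exceed
  `max_gens`) are restarted and the restart count is recorded in the
  truth. A sweep from a brand-new single copy (`init_copies = 1`) is
  available but, at `2N = 200`, takes of the order of `2N` generations,
  during which coalescent turnover regenerates diversity and erases most
  of the footprint — the standing-variant default exists precisely so
  that simulated sweeps have footprints on the scale the windowed scan
  targets.

The simulator's truth records the swept tract
(`position ± 1/(rho·origin_age)`), and `sweep_detected()` counts a sweep
as recovered when a combined candidate window overlaps that tract.

### What passing simulation tests do and do not show

The generator emulates the *structure* the analysis assumes — two diverged
parents, an admixed hybrid, realistic SNP density and LD decay, a hard
sweep with known truth — but not genotyping error, missing data patterns,
variable recombination or mutation-rate heterogeneity along real
chromosomes, or realistic sheep demography. Statistical power measured on
it is the power *at these scaled conditions*, and they are hard ones: with
`2N = 200` and 39 half-step windows, a sweep reaching frequency 0.95
floors the core window at roughly 0.3× baseline diversity (the ≈10% of
haplotype pairs involving a non-carrier or recombination escapee carry
full diversity), while neutral coalescence at this population size
produces drift blocks of comparable depth. Consequently the combined
≥2-method rule at 1st/99th-percentile thresholds recovers the swept tract
in roughly half to two thirds of replicates, and neutral replicates yield
an empty combined set in roughly 60–90% — both measured honestly by
`scripts/acceptance.R` and the test suite. On real-scale data (thousands
of windows, `2N` in the thousands, sweeps many standard deviations deep)
the same machinery has far more resolution; the desk-scale numbers are a
property of the problem size, not of the estimators, which all match
independent brute-force oracles to 1e-9.

## Numerical choices and degenerate inputs

* Empty windows give `NA`, never 0; `NA` propagates through
  Z-transformation and is never selected as a candidate.
* `Hp` of an all-fixed window is 0; of an empty window `NA`.
* FST with both populations monomorphic is undefined (`NA`), as is a site
  with fewer than two non-missing alleles in a population.
* θπ-ratio with a zero denominator is `NA` (no pseudocount by default).
* NJ Q-matrix ties break to the lowest index pair; negative branch
  lengths are clamped with the deficit moved to the sister branch.
* The EHH engine renumbers group ids each step and drops haplotypes whose
  group has become a singleton (they can never again contribute to the
  homozygosity numerator); this and the compiled inner loop are what make
  whole-matrix XP-EHH scans feasible, and the fast path is tested for
  exact equality against an O(n²·L) pairwise-identity oracle.
* All randomness flows from a single integer seed; identical seeds give
  byte-identical VCFs and statistic TSVs.

## Problem sizes used by the checks

The test suite and acceptance script use 12–20 replicates at the default
conditions for the power/specificity measurements, 100 random additive
trees for NJ consistency, and 1,000 random haplotype fixtures for the
EHH/XP-EHH property checks; oracle-equivalence fixtures are ≤ 20 samples ×
≤ 50 SNPs. These sizes were chosen so that a full run completes in minutes
on one CPU while keeping the statistical assertions within three standard
errors of their expectations.

The structure-recapitulation replicates use multi-contig datasets (8
independent 200-kb contigs, `N = 30`, `rho = 5e-6`, `admix_gens = 60`).
Two of those choices deserve explanation. First, a single low-recombination
contig cannot reproduce a whole-genome tree or PCA: with few independent
ancestry draws per individual, "hybrid" individuals range from nearly pure
parent A to nearly pure parent B, and the NJ tree interleaves them with
the parents. Many independent contigs plus a high per-contig recombination
rate stand in for the genome-wide shuffling that dozens of chromosomes
provide. Second, a freshly admixed population is *geometrically incapable*
of forming its own clade on a distance tree — its individuals sit on the
path between the parental clusters (a negative stem length, resolved by NJ
as a paraphyletic grade). What places a real composite breed in its own
clade is the drift it accrues during closed breeding; with ~60 generations
of closed breeding the simulated hybrid separates cleanly, and the PCA
places it between the parents throughout.

## Known limitations

Statistical phasing is not implemented: XP-EHH requires phased input (the
simulator emits phased VCFs; real data must be phased upstream). Windows
are fixed-size in bp, not SNP-count-based. GO/KEGG enrichment of candidate
genes and sweep-age/strength estimation are out of scope.
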