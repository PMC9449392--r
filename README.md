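# sweepscan

Window-based detection of selective sweeps in diploid genomes, with the
population-structure analyses that usually accompany such a scan, and a
forward-in-time Wright–Fisher simulator that makes the whole pipeline
testable end to end without any external data.

The package is aimed at the classic livestock / population-genomics setting:
two diverged source breeds, a composite (hybrid) breed formed by crossing
them, and the question *which genomic regions were under selection during
the breed's formation?*

## The statistics

Four complementary signals are computed in 100-kb windows sliding by half a
window along each contig, and candidate windows are those flagged by at
least two of them:

- **Pooled heterozygosity** `Hp = 2·ΣnMAJ·ΣnMIN / (ΣnMAJ + ΣnMIN)²`, where
  `ΣnMAJ` and `ΣnMIN` sum the major and minor allele counts of all SNPs in
  a window. Sweeps drive `Hp` towards 0; windows are flagged at
  `Z(Hp) < −4`.
- **FST** per SNP between two populations, using the Weir–Cockerham (1984)
  variance-components estimator `θ̂ = a/(a+b+c)`, averaged across each
  window; flagged at `Z(FST) > 4`.
- **Nucleotide-diversity ratio** `log2(θπ,A / θπ,B)` per window, with
  `θπ = Σ 2p̂(1−p̂)·n/(n−1) / window length`; flagged at `|log2 ratio| > 2`
  (direction configurable — see the vignette).
- **XP-EHH** `ln(iHH_A / iHH_B)` per core SNP, where `iHH` is the
  trapezoidal integral of the extended haplotype homozygosity
  `EHH(x) = Σ_h C(c_h,2)/C(n,2)` against physical distance; averaged per
  window and flagged at `XP-EHH > 0.7` (positive = longer haplotypes in
  population A).

Fixed thresholds can be replaced by empirical 1st/99th-percentile
cut-offs (`threshold_mode = "quantile"`), which is appropriate for small
simulated genomes. Candidate windows are mapped to genes with a ±50-kb
flank.

The structure layer provides 1−IBS allele-sharing distances, a
Saitou–Nei neighbour-joining tree (Newick export), Patterson-normalised
PCA (EIGENSOFT-style genotype scaling), and LD-decay curves (`r²` vs
distance, with MAF/heterozygosity/missingness filters).

## Worked example

Simulate two parental populations plus an admixed hybrid carrying a hard
sweep, then scan the hybrid against both parents:

```r
library(sweepscan)

cfg <- sim_config(seed = 13,
                  sweep = sweep_spec("HYB", position = 1e6, s = 0.1))
sim <- wf_simulate(cfg)
sim
#> wf_sim: 3 populations x 200 haplotypes, 1394 segregating sites on 2e+06 bp
#>   sweep in HYB at bp 1000000 (s=0.1), final freq 0.960, 0 restart(s)

conv <- as_variant_matrix(sim)
scan <- selection_scan(conv$vm, conv$popmap, focal = "HYB",
                       refs = c("P1", "P2"),
                       threshold_mode = "quantile", ratio_tail = "lower",
                       contig_length = cfg$L)
scan
#> selection_scan: focal HYB vs P1, P2; 40 windows of 100 kb (step 50 kb)
#>   thresholds: quantile mode; min_methods = 2
#>   Hp          1 candidate window(s)
#>   Fst         1 candidate window(s)
#>   pi_ratio    1 candidate window(s)
#>   XPEHH       1 candidate window(s)
#>   combined (>=2 methods): 1 window(s)

scan$combined
#>   contig   start     end     methods n_methods
#> 1   sim1 1000000 1100000 Hp,pi_ratio         2

sweep_detected(scan, sim$truth)
#> [1] TRUE
```

The combined candidate window `[1000000, 1100000)` contains the true
sweep locus at 1 Mb: that window is simultaneously the genome-wide
extreme of pooled heterozygosity and of the diversity ratio. (At this
deliberately small simulated scale — 39 windows, 100 diploids per
population — roughly half of sweep replicates are recovered this way;
see the methods vignette for the power analysis.) `plot(scan)` draws
the four Manhattan panels; `write_scan_outputs(scan, "out/")` writes one
TSV per track, a BED of candidate windows, and a JSON run manifest.
`generate_dataset(sim, "data/")` writes the phased VCF, population map,
contig-length file and ground-truth JSON used above, and
`read_vcf()` / `filter_variants()` bring real VCFs into the same pipeline
(biallelic SNPs, call rate > 90%, QUAL > 30, < 5 bp adjacency rule).

A thin command-line front end with `simulate`, `filter`, `scan`,
`structure` and `annotate` subcommands is installed at
`inst/cli/sweepscan.R`.

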