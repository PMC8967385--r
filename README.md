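# retromethylmap

Copy-resolved DNA methylation analysis of retrotransposons (SVA, LINE-1,
LTR12) in germ-cell whole-genome bisulfite sequencing (WGBS) data.

Human primordial germ cells erase DNA methylation almost genome-wide,
yet individual copies of young retroelement families resist erasure, and
during spermatogenesis copies re-acquire methylation to degrees that
differ between donors. Asking *which* copies resist, and *why*, needs
statistics at the level of the individual repeat instance. This package
provides that workflow for epigenomics researchers:

* **Copy catalog** — select nearly full-length copies (length ≥ 90% of
  the subtype consensus; solo LTRs against the LTR consensus) from
  RepeatMasker or BED annotation, and classify genomic context
  (genic-antisense / genic-sense / non-genic).
* **Per-copy methylation** — from Bismark coverage files: site level
  `m/t` at depth ≥ 5, copy level as the unweighted mean over ≥ 10
  analyzable CpGs, three classes (low < 20% ≤ medium < 60% ≤ high) and
  two-donor concordance classes (`common_high`, `common_low`,
  `high_and_low`, `other`).
* **Association** — class-wise KRAB-ZFP peak-overlap fractions with
  chi-square / two-proportion tests, FIMO-style PWM scanning with exact
  p-values (integer-scaled log-odds, dynamic-programming null), greedy
  non-overlapping motif counts, VNTR unit counting by consensus tiling,
  length-normalized metaprofiles, per-cell-type RPM expression, Tukey
  HSD and Dunnett comparisons.
* **Mappability** — fraction of 100 bp windows of a copy occurring
  exactly once in the genome (both strands, exact search, optional
  Hamming tolerance).
* **DMRs** — sliding-window candidates refined by the two-sample
  filter: ≥ 10 successive CpGs analyzable in both donors and ≥ 40
  percentage-point difference of candidate means; SVA-overlap census
  per direction.
* **Synthetic truth** — a seeded generator producing genome, repeats,
  two-donor binomial methylomes, motif-coupled peaks, context-coupled
  expression and implanted DMRs, so every stage is validated against
  known truth.

## Worked example

Simulate a study-like dataset with known truth and run the
demethylation-resistance analysis:

```r
library(retromethylmap)
cfg  <- synth_config(seed = 42)
sim  <- generate_genome(cfg)          # ~0.5 Mb genome, 200 repeat copies
meth <- generate_methylomes(sim, cfg) # two donors, Poisson(20) depth
res  <- run_resistance_analysis(meth$donor1, sim$repeats,
                                sim$consensus_lengths,
                                peaks  = generate_peaks(sim, cfg),
                                pwms   = list(znf = sim$motif_pwm),
                                genome = sim$genome)
#> catalog: 200 copies in, 178 full-length
#> methylome: 178 of 178 copies analyzable

res$family_summary
#>   subtype  n median_level frac_low frac_medium frac_high below_floor
#> 1   L1PA4 36        0.372    0.333       0.389     0.278       FALSE
#> 2  LTR12C 35        0.499    0.257       0.257     0.486       FALSE
#> 3   SVA_A 54        0.340    0.444       0.185     0.370       FALSE
#> 4   SVA_B 53        0.481    0.208       0.340     0.453       FALSE
```

Each subtype row gives the analyzable copy count, the median per-copy
methylation level and the class fractions (`below_floor` flags subtypes
under the 30-copy reporting floor). Peak overlap rises with the
methylation class, and the chi-square test picks up the implanted
coupling between motif count and class:

```r
res$peak_overlap$peaks$table   # fraction of copies with a peak, per class
#>    class n_copies n_overlapping fraction
#> 2    low       56             2   0.0357
#> 3 medium       51            13   0.2549
#> 1   high       71            38   0.5352
res$peak_overlap$peaks$test[c("statistic", "df", "p_value")]
#> $statistic [1] 38      $df [1] 2      $p_value [1] 5.65e-09

aggregate(znf ~ class, res$motif_counts, mean)  # motifs per copy
#>    class  znf
#> 1   high 6.55
#> 2    low 1.82
#> 3 medium 3.55
```

Highly methylated copies carry ~6.5 motif hits on average versus ~1.8
for lowly methylated copies — the generator's coupling, recovered from
sequence by the scanner. The two-donor stage
(`run_sperm_analysis()`) adds concordance typing, context fractions,
host-gene expression comparison and the refined DMR census.

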