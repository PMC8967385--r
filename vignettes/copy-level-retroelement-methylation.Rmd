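---
title: "Copy-level retroelement methylation analysis: models, filters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-level retroelement methylation analysis: models, filters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromethylmap)
```

## The problem

Most of the mammalian genome is transposable-element derived, and the
germ line keeps these elements silenced largely through DNA methylation.
Human primordial germ cells (hPGCs) erase almost all DNA methylation
genome-wide, yet individual copies of young retroelement families —
SVA, L1PA and LTR12 — retain high methylation ("demethylation
resistance"), and during spermatogenesis many copies re-acquire
methylation to degrees that differ between individuals. Studying this
requires *copy-resolved* statistics: each repeat instance gets its own
methylation level, class label, KRAB-ZFP binding status, motif content,
VNTR length, mappability score and genomic context, and copies are then
compared across classes and across donors.

This package implements that workflow end to end for whole-genome
bisulfite sequencing (WGBS) inputs, together with a seeded synthetic
generator that produces genomes, methylomes, peaks and expression with
known truth, so that every stage can be validated against what was
implanted.

## Per-copy methylation model and filters

For CpG site $i$ with $m_i$ methylated and $t_i$ total reads, the site
level is $m_i / t_i$, defined only when $t_i \ge 5$ (sites below the
depth floor are *filtered*, not zeroed). The methylation level of a
repeat copy is the **unweighted mean of the analyzable site levels**
inside its genomic span — not a read-weighted pooled ratio — and a copy
is analyzable only when it contains at least 10 analyzable CpGs. Copies
enter the analysis only when nearly full length: copy length at least
90% of the subtype's consensus length (solo LTRs are measured against
the LTR consensus). All three constants live in one object:

```{r}
meth_thresholds()
```

Class boundaries are closed exactly as conventionally printed:
*low* $< 20\% \le$ *medium* $< 60\% \le$ *high*. Two-donor concordance
classes reuse the same boundaries: `common_high` (both donors high),
`common_low` (both low), `high_and_low` (donor 1 high *and* donor 2
low — deliberately directional, with a `mirrored` switch to symmetrize),
and `other` for everything else. Where the conventional wording mixes
"$>60\%$" and "$\ge 60\%$", we use $\ge$ everywhere, and the inclusive
reading of the 90% full-length rule for both ordinary and solo-LTR
copies; these choices only affect values landing exactly on a boundary.

Whether CpGs inside an SVA's VNTR should contribute to the copy mean is
genuinely open; the default uses every CpG in the copy span. To restrict
to a sub-region (e.g. the VNTR only), pass a sub-interval of the copy to
`copy_methylation()` — the operation is purely interval-driven.

## Association statistics

Peak overlap per class uses half-open 0-based intervals and a $\ge 1$ bp
intersection rule. Class-versus-overlap association uses the Pearson
chi-square test without continuity correction for three or more classes
and the two-proportion test (`prop.test`, correction off by default and
config-exposed) for two; tables with an expected cell below 1 are
flagged degenerate rather than silently tested. Multi-group level
comparisons use Tukey's HSD (`all_pairs`) or Dunnett many-to-one
contrasts via the multivariate-$t$ distribution (`vs_control`,
`multcomp`); the method used is recorded on the result.

### Motif scanning

`scan_motifs()` scores every window on both strands with the log-odds
$\sum_i \log_2 \left( p_i(b) / q(b) \right)$ of a position weight matrix
against its background $q$ (`N` bases contribute 0). Significance is an
**exact p-value**: scores are discretized to integer units of $10^{-3}$
bits and the full null distribution of the window score under the
i.i.d. background is built by dynamic programming (lattice
convolution), exactly the construction FIMO uses. The only
approximation is the discretization itself, and the test suite holds
the scanner to *exact* agreement with an oracle that enumerates all
$4^w$ words. We threshold on the exact p-value rather than a q-value,
because q-values depend on the scanned universe; `motif_hits_bh()`
applies the Benjamini–Hochberg conversion over a declared universe when
FIMO-style q-values are wanted. Motif *counts* per copy resolve
overlapping windows greedily left to right (best score wins at equal
offset), so tandem motifs are counted once per occupied site.

### VNTR units and mappability

No standard tool defines "VNTR unit number" operationally, so the
package fixes a deterministic definition: greedy left-to-right tiling
of the unit consensus, counting a unit whenever the window identity is
at least 0.8 (config-exposed) and jumping a full unit, otherwise
sliding 1 bp. Unit-length indels therefore register as reduced
identity — acceptable for the simulator's substitution-only divergence
and transparent on real data.

Mappability of a copy is the fraction of `read_length` (default 100 bp)
windows fully contained in the copy that occur **exactly once** in the
whole genome, counting plus-strand occurrences of the read and of its
reverse complement (a self-reverse-complementary read is counted once
per locus). Exact search is a deliberately stricter stand-in for a
`-m 1`-style unique-alignment criterion; a Hamming-tolerant mode
(`max_mismatch`) is exposed for sensitivity checks, and a `step`
argument thins the tiling for large runs. Occurrence counting is
required to be observationally equivalent to a full window census, and
is tested against one.

## DMR calling

The normative component is the *refinement filter*: for each candidate
region, a CpG is analyzable when covered by $\ge 5$ reads in **both**
samples; the candidate is kept when it contains $\ge 10$ *successive*
analyzable CpGs and the two candidate-level means (each averaged over
analyzable CpGs) differ by $\ge 40$ percentage points. "Successive" is
read strictly — a run of consecutive CpG positions, over the union of
both samples' observed CpGs, uninterrupted by any non-analyzable
position; `successive = "total"` relaxes this to a simple count.

The candidate stage is declared plumbing: a sliding window of 10 shared
analyzable CpGs seeds a candidate when the mean per-site
$|{\Delta}|$ reaches 0.25; overlapping windows merge, and the merged
span is trimmed to the outermost CpG whose per-site and 3-site-smoothed
differences both reach the seed threshold. The smoothing term exists
because isolated binomial-noise sites at span edges otherwise drag flat
flanking CpGs into the candidate and dilute its means; requiring both
conditions leaves clean block edges intact. Any external candidate BED
can be substituted for this stage. Refinement is anti-monotone in both
of its thresholds (raising either never adds DMRs), which the suite
checks.

## The synthetic generator

`synth_config()` fixes the reference simulation; `generate_genome()`,
`generate_methylomes()`, `generate_peaks()` and `generate_expression()`
are pure functions of the configuration (each stage re-seeds from
`seed` plus a fixed stage offset, so artifacts are reproducible
independently).

What it emulates, and the defaults:

* **Repeat catalog** — four subtypes (two SVA-like with an internal
  VNTR, an L1-like and an LTR12-like body), 200 copies, 2% per-base
  substitution divergence, random strand, 15% of copies truncated to
  50–85% of consensus to exercise the full-length filter. Subtype
  consensus sizes are scaled down (≈1–3 kb) so that a whole simulated
  chromosome stays near 0.5 Mb; the VNTR sits mid-element with
  class-dependent unit count (low 2–4, medium 5–8, high 9–12 units of a
  fixed 40 bp unit whose first 12 bp are the implanted binding motif),
  mirroring the observation that methylation-retaining copies carry
  more VNTR units and hence more KRAB-ZFP motifs.
* **Methylomes** — per copy and donor a latent class (mixture
  0.3/0.3/0.4 low/medium/high; donor 2 shares donor 1's class with
  probability 0.6) and a true level drawn uniformly inside
  class-specific bands (0.02–0.12, 0.30–0.50, 0.70–0.95) chosen to
  represent clearly low/medium/high copies rather than boundary cases;
  background (non-repeat) CpGs sit at 0.75 in both donors, sperm-like.
  Per CpG, depth is Poisson (default mean 20) and methylated reads
  binomial at the local true level — the simplest model that exercises
  every depth/count filter. No within-copy autocorrelation, indels,
  bisulfite-conversion error or strand asymmetry is modeled, so passing
  recovery tests demonstrates correctness of the estimators and
  filters, not robustness to those real-data features.
* **Peaks** — one peak per copy with probability
  $\mathrm{logit}^{-1}(-4 + 0.6 \cdot \text{motif count})$, covering
  the VNTR span; slope 0 gives the calibration null.
* **Expression** — genes are placed so that 40%/10%/50% of copies are
  genic-antisense/genic-sense/non-genic; genes hosting an antisense
  `common_high` copy are shifted up by `expression_coupling` (default
  2) log2 units, `high_and_low` hosts by half that, counts negative
  binomial (size 10) over 30 cells of one type.
* **DMRs** — optional blocks of 15–20 consecutive background CpGs with
  true levels 0.85 vs 0.15, implanted at least 100 bp away from any
  copy; flat-background runs set `identical_donors = TRUE` so donors
  share exact latent levels and any call is a false positive.

Problem sizes used by the test and acceptance runs — 200 copies at
depth 20 for class recovery, depth 50 for discordant-copy recovery, 5
implanted DMRs × 10 seeds, and 200 reduced-size generator seeds
(single subtype, 150 copies) for the null calibration of the
class–peak chi-square — were chosen as the smallest sets at which the
binomial tail bounds make the recovery targets statistically safe
margins rather than coin flips.

```{r, eval = FALSE}
cfg <- synth_config(seed = 42)
sim <- generate_genome(cfg)
meth <- generate_methylomes(sim, cfg)
res <- run_resistance_analysis(meth$donor1, sim$repeats,
                               sim$consensus_lengths,
                               peaks = generate_peaks(sim, cfg),
                               genome = sim$genome)
```

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open everywhere; Bismark coverage
  (1-based) and RepeatMasker `.out` (1-based inclusive, strand `C`)
  are converted on read, and abutting intervals never overlap.
* Bismark percent columns are ignored; counts are authoritative.
* Integer score scale for motif p-values: $10^3$ per bit; PWM
  pseudocount 0.001 mixed uniformly so log-odds stay finite.
* Context classification: largest gene overlap wins, ties to the
  smaller gene start; a strandless copy overlapping a gene is an error
  because antisense orientation would be undefined.
* Filtering is a value (`NA`), not an error: under-covered sites and
  under-CpG'd copies flow through as non-analyzable and are excluded
  from class fractions and concordance typing.
* Empty inputs return empty, schema-stable tables; empty classes
  produce `NA` fractions and are flagged rather than dropped silently.

## Limitations

Bisulfite alignment, peak calling, de novo motif discovery and
phylogenetics are out of scope — the package starts from coverage
tables, interval files and PWMs. The exact-match mappability is
stricter than a mismatch-tolerant aligner, so absolute mappability
values are conservative (the Hamming mode bounds the effect). The VNTR
tiling definition has no indel handling. The generator's binomial
model cannot probe smoothing- or autocorrelation-dependent behavior,
and desk-scale simulations cannot reproduce genome-scale headline
fractions that depend on the full human repeat complement; the
arithmetic worked examples and recovery suites are the appropriate
desk-scale checks.
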