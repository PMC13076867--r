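---
title: "Methods: termination, readthrough and replication-conflict metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: termination, readthrough and replication-conflict metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polterm)
```

## Scope and model

`polterm` quantifies RNA polymerase II termination behaviour from
strand-specific binned nascent coverage. The underlying picture: engaged
polymerase produces a promoter-proximal pause peak, a roughly uniform
gene-body plateau, and — when termination works — a rapid signal decay past
the transcript end site (TES). Termination failure converts that decay into
an extended downstream plateau ("readthrough") which can invade downstream
intergenic elements, including DNA replication-initiation (RI) zones.
Everything in the package is a function of that coverage plus gene models;
no alignment, peak calling or transcript quantification happens here.

Coordinates are 0-based, half-open throughout; BED and bedGraph are native,
GTF is converted on read. Coverage is stored per (chromosome, strand) on a
fixed bin grid with bedGraph per-bp value semantics, so the signal mass of
a bin is `value * bin_extent`. Rasterization of intervals onto the grid
uses length-weighted means: mass is conserved exactly, and region sums are
invariant to bin-width refinement on piecewise-constant tracks. Antisense
signal is never mixed into sense-strand metrics; only the strandless RI
zone quantification sums both strands, since replication initiation has no
strand.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `dog_length` | 2500 | bp | downstream-of-gene window for the termination index |
| `min_separation` | 2500 | bp | flank clearance for the non-overlapping gene set |
| `min_density` | 50 | norm. counts/bp | strict coverage floor, both conditions |
| `pause_window` | 300 | bp | promoter-proximal window of the pausing index |
| `pa_cutoff_log2` | log2(1.25) | log2 ratio | P-A vs P-NA zone boundary (strict) |
| `wave_min_length` | 60000 | bp | minimum gene length for wave calling |
| `wave_min_reduction` | 0.70 | fraction | proximal (TSS+1–20 kb) signal drop filter |
| `min_input` | 5 | counts | BrdU input floor per valid 1-kb bin |
| `smoothing_m` | 10 | bins | moving-average half-width (2m+1 window) |
| `background_band` | 10 | track units | excluded band on the replication delta |

The pausing-index window is not standardized in the field; 300 bp (pause
site at 20–60 nt plus margin) is the package default and is recorded in
the output so results are auditable. The NDT/NIT `delta_threshold`
deliberately has **no default**: the boundary depends on the expected
effect size, and `classify_ndt_nit()` refuses to guess. For simulated data
`expected_delta_ti()` supplies the closed-form expected shift and the
pipeline uses half of it — far enough from both the null (0) and the full
effect to be insensitive to counting noise at the default depths.

## The synthetic-data generator

`sim_scenario()` fixes every generative parameter plus a seed; each
generator is a pure function of (scenario, condition), so identical
scenarios give byte-identical output and planted ground truth is exact.

Default study conditions: 20 genes of 100 kb on one chromosome,
alternating strands, intergenic gaps of 32–45 kb; body density 0.5
reads/bp with a 10-fold, 250-bp pause boxcar; post-TES decay exponential
with 500-bp scale, truncated at 3 kb; readthrough plateau at 0.5x body
density over 10 kb planted in half the genes in the perturbed condition;
uniform 0.005 reads/bp both-strand background; spike-in read share 0.1;
inhibition waves at 2 kb/min suppressing to a 10% residual; junction reads
spliced with probability 0.7; BrdU domains alternating early/late every
100 kb at 3-fold early enrichment, mean counts 50/bin, with perturbed
replication attenuated 0.4x in 20-kb windows downstream of planted genes
and boosted 1.5x in late domains. Noise is Poisson per bin (`noise_model =
"none"` gives exact expectations for closed-form tests).

Gene starts are snapped to the coverage bin grid so noise-free profiles
are exactly piecewise-constant per bin; the pause boxcar may still
straddle a bin boundary, where its mass (not its shape) is preserved.

Zone placement is the one deliberately engineered part: consecutive TESs
on alternating strands face shared (convergent) intergenic gaps, so a
"beyond reach" zone must clear the readthrough plateau plus decay cutoff
of *both* flanking genes. Zones are therefore drawn either fully inside
the would-be plateau (500–2000 bp gaps) or clear of every plateau, making
the `planted_invaded` tag exact ground truth rather than a probabilistic
label. The decay shape itself is a modeling convenience — real post-PAS
profiles are not characterized here — so recovery results speak to the
metrics' arithmetic and discrimination, not to the empirical shape of
termination in any cell line.

What the generator does **not** emulate: mappability and GC structure,
fragment-length effects, antisense and convergent transcription,
replication-timing gradients finer than two-state domains, overdispersion
beyond Poisson, and multi-isoform annotation ambiguity. Passing recovery
tests therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to every artefact of real libraries.

## Numerical choices

- **Zero densities.** No pseudocounts anywhere. A zero body density makes
  TI undefined (`NA`, flagged); a zero DoG density gives the `-Inf`
  sentinel, flagged and excluded from summaries. The analysis universe is
  expected to be pre-filtered to well-covered genes (strict `> 50`
  counts/bp in both conditions), which makes zeros out-of-universe rather
  than data.
- **Strict boundaries.** Every published-style threshold here is strict
  (`>`): coverage 50, zone cutoff log2(1.25), RI score 10, fold change 2,
  wave length 60 kb, reduction 70%, and the NDT threshold. A zone ratio of
  exactly 1.25 is P-NA; a delta of exactly +10 on the replication
  subtraction is background.
- **Changepoint calling.** The transition caller fits a two-segment
  piecewise-constant model by exhaustive scan over all breakpoints using
  cumulative sums (O(n)); near-ties are re-scored with the direct residual
  formula so exact ties (common on integer counts) resolve to the smallest
  breakpoint, identically to a brute-force scan — this equivalence is a
  tested invariant. Flat tracks (no residual improvement) and optima at
  either extreme candidate are flagged uncalled rather than reported.
- **Replicate agreement.** The reproducibility tolerance between replicate
  transition calls is not standardized; the default is 2 kb (two calling
  bins) and configurable.
- **Smoothing edges.** The 2m+1 moving average shrinks to the available
  valid bins at track edges and across masked bins; no padding, so no
  signal is fabricated at chromosome ends. Masked-only windows stay `NA`.
- **BrdU normalization order.** `NB` and `NI` are normalized by grand
  totals over all bins *before* the input-minimum mask; the mask applies
  only to the enrichment ratio. On the delta track the package works in
  enrichment-percent units (100x EB) so the +/-10 noise band retains its
  conventional magnitude; the band is configurable because the original
  unit convention at that step is ambiguous.
- **Subtraction sign.** Condition subtraction takes an explicit ordered
  pair; swapping the order swaps plus and minus zones exactly (tested), so
  either sign convention is a label swap, not a different analysis.
- **ChIP spike factors.** The reference condition is fixed at 1 and the
  other factor is density(ref)/density(other) — the orientation in which
  multiplying the non-reference track by its factor equalizes spike
  densities. The per-peak densities are averaged unweighted after per-peak
  length normalization.
- **Gene separation filter.** "Separated by at least 2.5 kb" is applied
  against genes on either strand on both flanks (the filter exists to keep
  neighbor signal out of the TI windows, and bleed-through does not care
  about strand); it is symmetric, so two close genes both fail.
- **Splicing units.** Spliced reads are those whose alignment carries a
  gap; efficiency is spliced/total among strand-matched overlapping reads
  of a unit. Units can be genes, junction windows or exons — the contract
  is per-interval, covering all three conventions.

## Problem sizes

The shipped tests and the acceptance script use the default scenario (20
genes of 100 kb; ~2.7-Mb chromosome at 100-bp bins) and a 100-gene variant
for the noisy termination-recovery check; the changepoint oracle runs on
1,000 random tracks of up to 200 bins, and the rank test's size is checked
over 2,000 null replicates at n = 30 per group. These sizes give stable
verdicts for every tested property while keeping the whole suite fast on a
single CPU.

## Known limitations

- The elongation-rate model assumes a single clean wavefront per gene;
  internal pause sites, premature termination, or intronic RNA instability
  would bias front calls on real data.
- TI conflates readthrough with downstream antisense or overlapping
  transcription unless the gene universe is filtered as intended.
- The Brunner–Munzel test is asymptotic; for very small groups the
  implementation refuses degenerate cases rather than switching to an
  exact permutation version automatically.
- P-A/P-NA classification depends on a baseline signal in the zone; zones
  silent in the baseline are reported `unscored`, not forced into a class.
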