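# polterm

Quantitative analysis of RNA polymerase II transcription **termination
failure** and its collision course with **DNA replication initiation**, from
strand-specific nascent-transcription coverage (POINT-seq / TT-seq / PRO-seq
style data).

When termination factors are lost, Pol II fails to stop at the transcript
end site (TES) and reads through into downstream intergenic space — including
zones where DNA replication initiates. `polterm` implements the coverage
metrics used to quantify this, a changepoint-based elongation-rate estimator,
a BrdU-IP replication-enrichment pipeline, and a seeded synthetic-data
generator that plants known readthrough, wavefront, splicing and replication
structure so that every metric can be validated against ground truth.

## Who is this for

Computational biologists analysing nascent transcription around gene 3'
ends: termination/readthrough phenotypes after degron or inhibitor
perturbations, spike-in-normalized condition comparisons, elongation-rate
estimation from CDK9-inhibition time courses, and transcription–replication
conflict quantification.

## The statistics at the core

**Termination index.** For a gene with body `[TSS, TES)` and a
downstream-of-gene (DoG) window of length `L = 2500` bp past the TES,

```
TI = log2( (DoG counts / L) / (body counts / (TES − TSS)) )
```

computed strand-specifically on normalized coverage (any global
normalization factor cancels). A termination defect raises the DoG density,
hence TI; genes are classified termination-dependent (NDT) vs independent
(NIT) by the shift `ΔTI = TI_perturbed − TI_control` against a strict
threshold.

**Spike-in normalization.** With spike-in (e.g., SIRV) read tallies,
`factor = spike / (endogenous + spike)`; tracks are multiplied by
`1/factor` so equal-spike conditions land on a common absolute scale.

**Replication-zone invasion.** Replication-initiation (RI) zones, scored
intervals consumed as BED5, are quantified as mean both-strand nascent
signal per bp; a zone is Pol II-affected (P-A) when
`log2(signal_treated / signal_baseline) > log2(1.25)`, otherwise P-NA.

**Elongation rate.** A CDK9 inhibitor stops pause release; the cleared
"inhibition wave" front sits `v·t` past the TSS after `t` minutes. The front
is located by an exhaustive two-segment piecewise-constant least-squares
fit over binned treated coverage, and `v = front / t` (kb/min).

**Replication enrichment.** BrdU-IP and input reads are binned (1 kb, read
midpoints), bins with input count `< 5` masked, `NB = CB/ΣCB`,
`NI = CI/ΣCI`, enrichment `EB = NB/NI`, smoothed by a 2m+1 moving average
(`m = 10`). Condition differences outside a ±10 noise band define
replication-gained (plus) and replication-lost (minus) zones; readthrough
signal stratified by zone sign is compared with the Brunner–Munzel rank
test.

## Worked example

```r
library(polterm)

sc    <- sim_scenario(seed = 1)            # 20 genes of 100 kb, half with a
genome <- simulate_genome(sc)              # planted readthrough defect
ctrl  <- simulate_point_coverage(genome, sc, "control")
pert  <- simulate_point_coverage(genome, sc, "perturbed")

nf <- spike_factor(ctrl$spike_reads, ctrl$endogenous_reads)
nf
#> spike normalization: factor 0.100188 (scale 9.98121) from 117771 spike / 1057726 endogenous reads

cc <- apply_spike_scaling(ctrl$coverage, nf)
pc <- apply_spike_scaling(pert$coverage,
                          spike_factor(pert$spike_reads, pert$endogenous_reads))

ti_c <- termination_index(cc, genome$genes)
ti_p <- termination_index(pc, genome$genes)
cls  <- classify_ndt_nit(ti_c, ti_p,
                         0.5 * expected_delta_ti(sc)$delta_ti)
head(cls, 3)
#>   gene_id ti_control ti_perturbed delta_ti class
#> 1    g001  -2.241806   -0.9437625 1.298044   NDT
#> 2    g002  -2.253653   -0.8972822 1.356371   NDT
#> 3    g003  -2.364154   -1.0173889 1.346765   NDT
table(cls$class)
#> NDT NIT
#>  10  10
```

Control genes terminate (TI ≈ −2.3: DoG density ~20% of body); perturbed
planted genes read through (TI rises by ~1.3, matching the planted
amplitude of 0.5 relative to the decaying control tail), and exactly the
10 planted genes are called NDT. Zone classification on the same tracks:

```r
z <- quantify_zone_signal(genome$zones, list(control = cc, perturbed = pc))
z <- classify_pa_pna(z, "perturbed", "control")
table(z$label)
#> P-A P-NA
#>  11    9
```

The full pipeline (simulate → normalize → metrics → zones → rate → brdu),
writing TSV/BED outputs plus a manifest:

```r
run_pipeline(run_config(seed = 1, outdir = "out"))
```

or from a shell: `Rscript inst/cli/polterm.R run --seed 1 --outdir out`.

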