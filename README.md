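# duplexmrd

Analysis stack for sequencing assays that **selectively enrich rare variant
molecules** before sequencing — hybridization-capture panels whose probes
release variant-bound molecules far more efficiently than wild-type ones —
used to track tumour-informed variant panels in cell-free DNA and call
minimal residual disease (MRD) at tumour fractions down to parts per
million.

It is written for assay developers and computational biologists who have
(or want to simulate) per-probe molecule counts from UMI-tagged duplex
sequencing and need the downstream statistics: enrichment quantification,
background error modelling, per-variant limits of detection, input-VAF
inference and sample-level MRD calls.

## What it computes

**Molecule counting.** Aligned reads are grouped into read bundles
(identical fragment breakpoints, UMIs within Levenshtein distance ≤ 2,
greedy transitive clustering). Per-strand ≥ 2/3-majority consensus classes
each bundle as a *duplex* molecule (both strands concordant) or
*single-strand* molecule of the alternate or wild-type allele.

**Selectivity.** For `m` recovered alternate and `w` wild-type molecules at
input VAF `f`,

    S = (1 − f)·m / (f·w)

(`S = 1` ⇒ non-selective). The panel-wide value `S_g` (counts aggregated
over probes; equivalently the m-weighted harmonic mean of per-probe S)
implies an enrichment factor `EF = S_g / (1 − f + f·S_g)` and a relative
sequencing amount `c_r = 1/EF` — e.g. `S_g = 44.5` at 1% VAF cuts the
required sequencing depth by 96.8%.

**Background errors.** Per-site error rates from blank samples feed two
Gamma priors, fitted separately for duplex and single-strand counts: a
moment-matched substitution-type prior (`α = μ²/σ²`, `β = μ/σ²`) and the
conjugate site-specific posterior (`α = 0.1 + Σx`, `β = 1 + N`).

**Detection.** Per-variant calling thresholds meet an FPR budget of
`1/(samples × variants)` under the Gamma-marginalised (negative-binomial)
background; LoD95 is solved by bisection; the input VAF gets a grid
posterior with exact Poisson⊗negative-binomial channel likelihoods.

**MRD.** Duplex and single-strand counts of all usable SNV probes are
integrated over an MRD-level grid with an explicit θ = 0 atom (prior mass
0.5), score-linked per-probe signal rates and control-probe sample
scaling, yielding P(MRD) and a level estimate with a 95% credible
interval.

**Probe design & simulation.** Candidate enumeration, nearest-neighbour
melting temperatures, design features, a pluggable (bundled random-forest)
scorer, seeded panel sampling — plus a synthetic-data generator that
emulates the whole dilution-series study design (probe performance spread,
type-specific background, sample scaling, control probes, dropouts,
phased-SNP contamination).

## Worked example

```r
library(duplexmrd)

cfg <- sim_config(n_probes = 200, seed = 7,
                  vaf_levels = c(0.1, 0.01, 0.001, 0),
                  replicates_per_level = 3)
sim <- simulate_panel(cfg)              # panel + generative truth
run <- simulate_counts(sim, config = cfg)

qc  <- qc_report(run)                   # 1 of 12 samples drops out
good    <- qc$sample_id[!qc$failed]
counts  <- run$counts [run$counts$sample_id  %in% good, ]
samples <- run$samples[run$samples$sample_id %in% good, ]

g <- global_selectivity(counts, samples)
round(g$S_g, 1)                                            # 12.4
round(relative_sequencing(g$S_g, 0.01)$reduction_percent)  # 91

blanks <- samples$sample_id[samples$vaf == 0]
bg <- fit_background_model(counts[counts$sample_id %in% blanks, ], sim$panel)
mrd <- mrd_call_cohort(run, sim$panel, bg$site, cfg,
                       setNames(sim$controls$reference_count,
                                sim$controls$control_id))
head(mrd[, c("sample_id", "probability_mrd", "level_estimate",
             "called", "qc_status")], 8)
```

```
  sample_id probability_mrd level_estimate called qc_status   (true VAF)
1      S001               1       0.096647   TRUE      pass        0.100
2      S002              NA             NA  FALSE    failed        0.100
3      S003               1       0.103938   TRUE      pass        0.100
4      S004               1       0.010141   TRUE      pass        0.010
5      S005               1       0.010141   TRUE      pass        0.010
6      S006               1       0.010517   TRUE      pass        0.010
7      S007               1       0.000989   TRUE      pass        0.001
8      S008               1       0.000989   TRUE      pass        0.001
```

The panel of 200 simulated probes shows a global selectivity of 12.4 —
a 91% reduction in required depth at 1% VAF — and the MRD caller recovers
the 10%, 1% and 0.1% dilution levels on every QC-passing sample (the
failed sample is excluded automatically, not mis-called).

A thin command-line wrapper over the same functions ships in
`inst/cli/duplexmrd.R` (subcommands `simulate`, `count`, `qc`,
`selectivity`, `errors`, `lod`, `vaf`, `mrd`, `design`, `theory`), and
`run_pipeline()` executes the whole chain with a manifest. See the
vignette `vignettes/assay-model.Rmd` for the models, parameter meanings
and numerical choices.

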