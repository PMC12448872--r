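---
title: "Models and methods: duplex molecule counting, selectivity and Bayesian MRD calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: duplex molecule counting, selectivity and Bayesian MRD calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmrd)
```

# The assay this package models

`duplexmrd` analyses hybridization-capture sequencing assays that
*selectively enrich* rare somatic variant molecules over wild-type molecules
before sequencing — for example capture chemistries in which a probe is
digested (and its target released for amplification) only when perfectly
base-paired to the variant allele. Such assays track a tumour-informed panel
of SNVs and short InDels in cell-free DNA and aim to detect minimal residual
disease (MRD) at tumour fractions of parts per million, while sequencing a
small fraction of the reads a non-selective assay would need.

The package implements the full desk-side analysis stack:

1. **Molecule counting** — UMI read-bundle grouping and duplex consensus.
2. **Selectivity calculus** — per-probe and panel-wide enrichment metrics.
3. **Background error models** — Gamma priors on per-site error rates.
4. **Per-variant detection** — FPR-budgeted thresholds, LoD95 and posterior
   input-VAF inference.
5. **Sample-level MRD calling** — a Bayesian integration of duplex and
   single-strand evidence across all probes.
6. **Probe design** — feature computation, melting-temperature filtering,
   pluggable scoring and panel sampling.
7. **A synthetic-data generator** that emulates the dilution-series study
   design, so every stage is testable without sequencing data.

# Molecule counting

Aligned reads are grouped into *read bundles*: reads sharing identical
fragment breakpoints whose UMIs lie within Levenshtein distance ≤ 2 of each
other (the threshold is the `max_edit_distance` argument). Within a
breakpoint group we cluster UMIs greedily: unique UMIs are ordered by
descending read support, and each unassigned seed absorbs — transitively —
every UMI reachable through edges of distance ≤ 2. Because absorption is
transitive, the partition equals the connected components of the adjacency
graph, which is what the test-suite's brute-force oracle (all-pairs
enumeration plus union–find) checks against. Distances use true edit
(Levenshtein) distance via `utils::adist`, not Hamming distance, so
length-changing sequencing errors in the UMI are tolerated.

Each bundle yields a per-strand consensus allele: the majority allele among
that strand's reads, requiring at least a 2/3 majority; ties and
sub-threshold majorities are "ambiguous". The 2/3 threshold is a design
choice — consensus conventions vary between pipelines — and is exposed as
the `majority` argument. A bundle with concordant non-ambiguous consensus on
*both* strands counts as a **duplex** molecule of that allele; consensus on
exactly one strand counts as a **single-strand** molecule. Conflicting
strands are dropped (and tallied), and bundles outside the target list are
tallied off-target rather than raising errors, so that
`duplex + single-strand + ambiguous + off-target` always equals the number
of bundles.

# Selectivity

For a probe observed with `m` recovered alternate molecules, `w` recovered
wild-type molecules, at input VAF `f`, the selectivity is

$$S = \frac{(1-f)\,m}{f\,w},$$

the ratio of the fraction of input alternate molecules recovered to the
fraction of input wild-type molecules recovered. `S = 1` for a non-selective
assay, and `S` is invariant to the input VAF under proportional recovery, so
values from different dilution levels can be averaged. Per-probe values
average the per-sample `S` over samples with `f ≥ 0.1%` (below that, `m` is
dominated by a handful of molecules and the ratio is unstable); samples with
`w = 0` leave `S` undefined and are excluded rather than mapped to infinity,
otherwise the arithmetic mean would be undefined. The panel-wide value
`S_g` applies the formula to counts summed over probes within each sample
and then averages across qualifying samples; within a sample the aggregate
value is *exactly* the `m`-weighted harmonic mean of per-probe
selectivities (an algebraic identity the tests verify). The interval
classification — nonselective `(0,1]`, weakly selective `(1,10]`, selective
`(10,50]`, strongly selective `>50` — follows the standard reporting bands.

A global selectivity implies an enrichment factor at input VAF $f_i$,
$EF = S_g / (1 - f_i + f_i S_g)$, i.e. the output/input VAF ratio, and a
relative sequencing amount $c_r = 1/EF$ — the fraction of a conventional
assay's depth needed for equivalent data. `theoretical_lod()` and
`theoretical_depth()` implement the standard panel-size calculators
($\mathrm{LoD} = \ln 20 / (\text{copies} \times n)$ from requiring ≥ 1
tumour molecule in 95% of samples, and
$n \times 10^5 \times 300 / 10^9$ Gb, optionally divided by the
enrichment factor).

# Background error model

Blank (expected-negative) samples define the error model, separately for
duplex and single-strand counts throughout — duplex consensus corrects most
errors, so single-strand rates are substantially higher and the two
channels must not be pooled. Two Gamma priors on the per-site rate
$\lambda_e$ are available:

* **Substitution-type prior**: per-site rates $\hat\lambda_{e,p}$ (the mean
  count across blanks) are moment-matched across all probes of one type:
  $\alpha = \mu^2/\sigma^2$, $\beta = \mu/\sigma^2$. The variance uses the
  population ($1/N$) convention by default (configurable); with small
  probe counts the two conventions differ noticeably and the population
  form pairs naturally with the population mean. Microsatellite/homopolymer
  probes are excluded by default — polymerase slippage makes their rates
  unrepresentative of their substitution type.
* **Site-specific prior**: the conjugate posterior of
  $\Gamma(\alpha = 0.1, \beta = 1)$ under Poisson counts,
  $\alpha = 0.1 + \sum_i x_i$, $\beta = 1 + N$. The conjugacy is verified
  against a brute-force grid posterior (KL < 10⁻⁶).

With a Gamma prior the marginal count distribution is negative binomial,
which the detection and MRD models use *exactly* rather than plugging in a
point estimate: the whole point of the site prior is to propagate the
uncertainty of a rate estimated from a few dozen blanks.

# Per-variant detection

The per-variant false-positive budget is
`fpr = 1 / (n_samples × n_variants)` — less than one expected false variant
call across the cohort (with 160 samples and 2199 variants this is
2.84 × 10⁻⁶). `call_threshold()` returns the smallest count whose
upper-tail probability under the negative-binomial background marginal is
within budget.

Probe performance is calibrated on high-VAF samples as the
exposure-normalised Poisson MLE
$\hat r = \max\!\big(0, (\sum x - N\,\bar\lambda_{bg}) / \sum s_i C f_i\big)$
with $C$ the haploid input copies ($C =$ input mass / 3.158 pg per haploid
genome; 20 ng gives ≈ 6333 copies, hence ≈ 633 alternate input molecules
at 10% VAF). LoD95 is then the smallest VAF at which 95% of samples reach
the threshold, solved by bisection (absolute tolerance 10⁻⁶) on the mean
scale at the median sample scaling; sample-to-sample variability enters the
LoD only through the calibrated exposure, a deliberate simplification that
the simulation-based self-consistency test validates.

The input VAF of a sample is inferred on a log-spaced grid
(10⁻⁷ … 1, 500 points) with equal prior mass per grid point — a
scale-invariant prior appropriate for a quantity spanning five decades.
Duplex and single-strand counts enter as independent Poisson likelihood
factors sharing one VAF, with channel rates $r d$ and $r(1-d)$ ($d$ = duplex
probability) and their own background priors marginalised exactly (a
Poisson ⊗ negative-binomial convolution). When the calibrated rate is
passed with its Gamma posterior (`calibrate_probe_performance(...,
posterior = TRUE)`), the signal term is likewise marginalised, propagating
calibration noise into the interval. Credible bounds are rounded *outward*
on the discrete grid (the lower bound steps one grid point down) so that
grid discretisation cannot clip the interval. Two residual approximations
remain: the two channels treat the rate posterior independently rather than
jointly, and the scale-invariant prior pulls very low-count posteriors
slightly downward; the interval-coverage acceptance test measures their
combined effect directly on cohorts spanning 0.5–10% VAF and finds coverage
inside the 93–97% band. A grid posterior was chosen over MCMC because the
parameter is one-dimensional — the posterior is deterministic,
exhaustively evaluated and fast.

# MRD calling

A sample-level MRD call integrates all usable SNV probes (InDels are
excluded by default — their slippage-driven error rates at homopolymers
cost more than their evidence adds — as are microsatellite- and
SNP-overlap-flagged probes). The model places prior mass 0.5 on an explicit
θ = 0 atom ("no MRD") and spreads the rest uniformly over a log-spaced grid
of MRD levels (10⁻⁷ … 0.2, 400 points). For each θ the log-likelihood sums
over probes, for the duplex channel,

$$\log P\!\big(x_{d,p} \mid \theta\, \rho_p\, d\, G_i\, C + \lambda_{d,p}\big),$$

with the probe's Gamma background prior marginalised exactly, and the
analogous single-strand term weighted by `ss_weight` (default 1; 0 disables
the noisier channel — the relative weight of non-duplex evidence is a free
parameter of the model, not something the data pin down at desk scale).
Here $\rho_p$ is the probe's signal rate from the design-score link,
$G_i$ the sample scaling estimated as the geometric mean of control-probe
count ratios against a reference panel (times library/capture input-mass
ratios), and $C$ the haploid copies. The posterior yields the probability
of MRD (mass on θ > 0) and, given θ > 0, the median level with a central
95% interval. A sample is called at posterior probability ≥ 0.99; on 200
simulated blank samples this produces no false calls (the acceptance suite
re-measures this), consistent with the Bayes-factor bound that limits how
often a null sample can reach such odds. The total alternate duplex
molecule count is also reported as a descriptive blank diagnostic (blank
cohorts sit below ~8 molecules panel-wide) but is never used for calling.

The score → rate link is a logistic in the design score scaled by the
library efficiency, anchored so a probe scoring 200 has enrichment-step
efficiency 0.47 — equivalently ≈ 19% overall recovery on a 40%-efficient
library, i.e. ≈ 120 of 633 input molecules. The anchor and the 40%
library efficiency are the two operating points the assay's
characterisation fixes; the logistic scale (75 score units) is a smooth
interpolation choice between them.

# Quality control

A sample fails when any control probe returns fewer than 100 molecules
(exactly 100 passes); failed samples are excluded from all downstream
statistics. Cross-contamination in blanks is detected from phased SNPs:
contaminating genomes contribute molecules carrying both the tracked
variant and a nearby germline SNP on the same haplotype, so the ratio of
double-positive molecules to variant molecules covering the second site
approximates the contaminated fraction of the apparent signal. A blank is
flagged only when *both* its aggregate alternate duplex count exceeds 8
molecules *and* the ratio exceeds 0.5 — elevated background alone is noted
but not attributed to contamination. Both thresholds are configurable; the
defaults take the observed blank background ceiling as the elevation bound
and require contaminant-derived molecules to dominate the apparent signal.

# Probe design

Candidate probes enumerate all (upstream, downstream) flank-length pairs
around the variant, so the variant sits `downstream` bases from the 3′ end
(typically a handful of bases — 3′-proximal variants discriminate best).
Melting temperatures use the unified nearest-neighbour parameter set with
terminal initiation terms, an entropic salt correction
$0.368\,(N-1)\ln[\mathrm{Na^+}]$ and defaults of 50 mM Na⁺ / 250 nM excess
single strand; the implementation is cross-checked against an independent
published calculator to within 0.5 °C. Designs below 65 °C are rejected
(the minimum is configurable — some protocol variants require 68 °C).
Features further include GC content (with a low-GC flag below 0.35 — AT-rich
probes underperform), flank lengths, a flag for known SNPs within 25 bp of
the 3′ end, and a microsatellite/homopolymer flag (run ≥ 6 or ≥ 3 tandem
copies of a 2–6-mer near the variant; the field has no canonical
definition, so this one is stated and configurable).

Scoring is pluggable: any function of the feature frame, or the bundled
random-forest scorer trained on simulator-generated (features → observed
score) data, where the latent quality surface encodes the known feature
effects (GC rising to a plateau, Tm and length optima, 3′-offset optimum,
SNP and repeat penalties) plus observation noise chosen to leave a held-out
r² around 0.7 — the regime in which such scorers realistically operate.
Since the score scale of any retrained scorer is its own, panel sampling in
"pool-2 mode" interprets the published per-type thresholds as
median-or-threshold semantics on the active scorer's scale.
`select_best()` takes the top-scoring design above the Tm filter, breaking
ties toward shorter, lexicographically earlier sequences so selection is
deterministic.

# The synthetic-data generator

`sim_config()` defaults describe the dilution-series study the analysis
stack is built for: 20 000 pg input at 3.158 pg per haploid genome
(≈ 6333 copies), a VAF ladder 10%, 1%, 0.1%, 100 ppm, 10 ppm, 1 ppm and
blanks, four replicates per level, 40% library efficiency, a 1800-probe
panel split 90/10 between SNVs and InDels (InDels equally over
SDEL/SINS/MDEL/MINS, lengths ≤ 40). Counts follow the same generative
family the analysis assumes: alternate molecules
$\mathrm{Pois}(s_i\,\varepsilon_p\,C f)$ (the Poisson approximation to
$\mathrm{Binom}(C, f)$ — negligible error at $f \le 0.1$ and conjugate
with the analysis model), wild-type molecules
$\mathrm{Pois}(s_i\,(\varepsilon_p/S_p)\,C(1-f))$, a duplex probability of
0.5 per recovered molecule (the true duplex fraction is assay-dependent
and not pinned down; it is a free parameter), and background errors drawn
once per probe from substitution-type Gamma priors with single-strand
rates 10× duplex rates. Default background priors put per-probe duplex
means at ~1–3 × 10⁻³ errors per sample (C>T elevated), so a ~1600-probe
SNV panel accumulates a few duplex background molecules per blank —
matching the "below 8 panel-wide" blank regime. Per-probe recovery runs
through the same score link as the analysis with log-normal jitter
(sd 0.2 on the log scale), which reproduces the observed strength of the
score–yield correlation (~0.7–0.8); true selectivities are log-normal with
median 35 and mean ≈ 90, matching reported panel-scale spreads. Sample
scaling is log-normal with median 1 (sd 0.15 — positivity and
multiplicative error are the minimal assumptions "sample-to-sample
variability" supports); 12.5% of samples drop out (a control probe forced
under 100 molecules), the observed failure rate; contamination, when
enabled, adds phased-SNP-carrying molecules to chosen blanks. All
randomness derives from one seed through named sub-streams (panel, counts,
reads), so stages regenerate independently.

What the generator does **not** emulate: sequence-level artefacts (no read
sequences, base qualities or alignment errors), PCR jackpotting /
over-dispersion beyond the Gamma-Poisson family, batch effects between
runs, and fragment-length biology. Passing tests therefore demonstrate
that the analysis is correct *under its own generative assumptions* and
robust to the parameter ranges above — not that those assumptions hold on
any particular instrument.

Read-level records (`simulate_reads()`) expand each molecule into a bundle
with shared breakpoints, an 8-nt UMI (one per fragment), two reads per
strand, and both strands iff the molecule is a duplex. Within a breakpoint
group UMIs are kept at pairwise distance ≥ 5 so that error-free records
round-trip *exactly* through the counter; optional per-read UMI errors of
up to 2 substitutions exercise the collapsing logic.

# Problem sizes and numerical choices

The test and acceptance suites size their simulations for a single CPU:
the MRD dilution-series check uses the full 1800-probe panel (1620 SNV
probes) over 10⁻⁵–10⁻¹ with 4 replicates per level, 32 training blanks and
200 evaluation blanks; interval coverage uses two 40-probe cohorts of 24
samples (≥ 1000 intervals); threshold validation draws 2 × 10⁶ blank
counts per configuration; LoD95 self-consistency uses 10⁴ draws. Degenerate
inputs are handled explicitly: `w = 0` selectivities are `NA` and excluded;
zero-variance type priors raise an error directing to the site prior; dead
probes (`rate = 0`) report `LoD95 = Inf` ("> 100%"); all-zero control
probes fail the sample rather than producing a scaling of 0; `alpha = 0`
background priors encode exactly-zero error rates. Ties in UMI seeding are
broken lexicographically and in design selection toward shorter sequences,
so every pipeline output is reproducible bit-for-bit under a fixed seed.

# Known limitations

* The MRD model assumes probe independence; overlapping probes or clonal
  structure would violate it.
* Sample scaling is treated as known once estimated from controls; its
  (small) uncertainty is not propagated.
* The VAF posterior treats the duplex/single-strand calibration posterior
  independently per channel (slightly conservative).
* InDel-specific performance is not modelled separately (no
  length-dependent recovery), and trinucleotide error contexts beyond the
  ten substitution classes are out of scope.
* The bundled scorer is trained on synthetic data; on real assays it is a
  placeholder for a scorer trained on measured probe recoveries.
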