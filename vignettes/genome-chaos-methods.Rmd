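---
title: "Models and methods: genome chaos, ergodicity and clonal selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genome chaos, ergodicity and clonal selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomechaos)
```

This vignette documents the scientific models implemented in
`genomechaos`, the assumptions behind them, the parameters that matter,
and the numerical and design choices made where more than one convention
was defensible.

## The biological picture

Chromothripsis is a catastrophic single event in which a chromosome
shatters into fragments that are rejoined in quasi-random order. Cells
that have undergone it mutate orders of magnitude faster than other
cancer cells, and their visible marker is the micronucleus: the fraction
of cells in a clone showing micronuclei (FCM, in percent) tracks the
prevalence of chromothripsis. A clone population at equilibrium keeps a
stationary FCM distribution across generations — its time averages equal
its ensemble averages, the definition of ergodic behaviour. Artificial
selection for ever-higher FCM drives the population away from that
equilibrium; beyond roughly 10% FCM clones stop proliferating and
undergo apoptosis, plausibly because the per-division mutation load on
anti-apoptotic housekeeping genes (BCL2 being the canonical example)
becomes overwhelming.

## Mutation Monte Carlo

`mutate_gene()` applies one division's worth of substitutions: each of
the `L` positions mutates independently with probability $\mu$, and a
mutated base is drawn uniformly from the three alternatives. The model
is substitution-only — no indels — so sequences keep their length, all
comparisons (`hamming_distance()`, `percent_identity()`) are ungapped,
and the number of mutation records always equals the Hamming distance
between input and output. This matches the worked single-SNP example the
package reproduces (one substitution in a 720-nt coding sequence gives
Hamming distance 1 and protein identity $100 \times 238/239 = 99.58\%$
on the 239-residue product).

The waiting time to a first mutation is geometric with per-division
success probability $p = 1 - (1-\mu)^L$, mean $1/p$.
`divisions_until_first_mutation()` simulates the divisions directly
(blocked binomial draws), and the closed form serves as the independent
oracle in the tests. At $L = 720$ and $\mu = 10^{-5}$ the mean is
$\approx 139.4$ divisions. A figure of about 86 divisions is sometimes
quoted for this configuration; it is inconsistent with the closed form
(it would require an effective length of roughly 1165 nt or a different
per-division probability), so this package treats the geometric law as
authoritative and does not reproduce that number. The waiting-time cap
(`max_divisions`, default $10^7$) raises an explicit error rather than
silently truncating, so a tiny rate cannot produce a biased mean.

Positions are reported 1-based throughout, the native R convention, and
codon indices in translation errors are 1-based as well.
`translate_gene()` uses the standard genetic code, drops a single
terminal stop, and treats an internal stop as an error naming the codon.

## The chromothripsis mixture model

With a fraction $f_c$ of cells carrying chromothripsis, the effective
population mutation rate is the linear mixture

$$\mu = f_c\,\mu_c + (1 - f_c)\,\mu_{can},$$

affine and increasing in $f_c$ and bounded by the component rates. Two
parameterisations ship as named presets because the source material uses
both without reconciling their units:

- **text** (`mu_c = 1e-4`, `mu_can = 1e-7`): the narrative example —
  $f_c = 0.1$ gives $\mu = 1.009\times10^{-5}$ per nucleotide per
  division.
- **table** (`mu_c = 1e-1`, `mu_can = 1e-4`): the parameterisation that
  reproduces, cell for cell, the published per-stage "effective mutation
  rate ×10⁻⁴" column when $f_c$ is the stage's average FCM divided by
  100. All five cells (6.99, 8.99, 17.98, 16.98, 47.95) were verified by
  direct arithmetic before being wired into the pipeline; the test suite
  keeps that brute-force check.

The two presets differ by a factor of 1000 in both components. Rather
than silently preferring one, `analyze_stage_table()` takes the preset
explicitly (default `"table"`, since that is what the per-stage column
tracks) and likewise makes the $f_c$ source column explicit (`"average"`
by default; the narrative example uses a maximum-FCM-like 10%).

Reported "×10⁻⁴" values use `round()`, i.e. round-half-even to two
decimals, which reproduces all five printed cells.

`cumulative_mutation_probability()` gives
$p = 1 - (1-\mu)^{L G}$ for $G$ divisions, computed via `expm1`/`log1p`
for accuracy at small rates. At $\mu \approx 10^{-5}$ and $G = 86$ the
720-nt probability is $\approx 0.46$; at the stage-4 table-preset rate
($\approx 4.8\times10^{-3}$) it is numerically 1, the package's
quantitative version of the claim that mutation of an anti-apoptotic
gene becomes near-certain at high chromothripsis fractions.

## Entropy and the stability criterion

`rearrangement_count()` returns the exact $N!$ — as a double while
exactly representable ($N \le 18$) and as an arbitrary-precision decimal
string beyond (schoolbook base-$10^7$ arithmetic; no external
big-integer dependency). `rearrangement_entropy()` offers two labelled
conventions: the default **permutation** mode $\ln(N!)$, the Shannon
entropy in nats of a uniform distribution over rearrangements (a proper
non-negative mixing entropy, zero iff $N \le 1$), and the **printed**
mode $-N\ln N$, a closed form sometimes quoted for this quantity that is
negative for $N > 1$ and is kept only for fidelity to that convention.
Pipelines use permutation mode.

The Gibbs-type criterion scores genome stability under a dimensionless
mutagenicity parameter $\theta$:
$\Delta G = \Delta h - \theta \Delta S$, stable while $\Delta G > 0$,
with the critical mutagenicity $\theta_0 = \Delta h/\Delta S$ and the
barrier height estimated as $\Delta h = 1/\mu_0 \approx 7\times10^9$ at
the spontaneous somatic rate $\mu_0 = 1.4\times10^{-10}$. No functional
form $\mu(\theta)$ is implemented: none is established, and the
criterion is an analogy for locating the transition, not a fit. The
stability flag uses the strict inequality, so $\theta = \theta_0$ is
classified as not stable; the boundary consistency is property-tested
with randomised $(\Delta h, \Delta S)$ pairs.

## The ergodicity defect

The deviation of a clone population from its equilibrium is measured by
an integrated squared difference between distributions. With no basis
functions, measure, or proportionality constant established for the
continuous form, the package discretises on a shared binning and fixes
the constant at 1:

$$D = \sum_i \left(m^{cur}_i - m^{ref}_i\right)^2,$$

where the $m_i$ are probability masses from `fcm_histogram()` —
half-open bins $[e_i, e_{i+1})$, default integer edges 0–20%, covering
the observed 0.5–17% range. $D$ is symmetric, zero iff the histograms
coincide, and bounded by 2 (disjoint point masses). The reference
defaults to the stage-0 (pre-selection) distribution, which is assumed
to be the equilibrium distribution.

A consequence of this choice, stated prominently: the published
per-stage defect values (0, 0.03, 0.74, 0.48, 7.96) **cannot** be
recomputed from the published min/avg/max summaries — they required
clone-level data, and a value of 7.96 is in any case outside the $[0,2]$
range of a squared-difference of probability masses, so the original
constant and basis must have differed. The package therefore treats that
column as non-reproducible, computes defects only when clone-level data
are supplied (`analyze_stage_table(clone_data = ...)`, omitted as `NA`
otherwise), and validates the statistic through its properties instead:
zero at stage 0, bounds, symmetry, and strict growth under mean shift of
a unimodal histogram.

For stationarity checks the tests compare an observed between-stage $D$
with the 99.7% quantile of its pooled-bootstrap null distribution rather
than a $\pm3$SE band around zero: $D$ is a positively biased sum of
squares, so its sampling noise is one-sided and the null quantile is the
meaningful "3-sigma" analogue.

## The clonal selection simulator

`run_selection_experiment()` emulates the artificial-selection protocol:
score a population of clones for FCM, seed the next stage from the
highest-FCM clones, repeat, and stop when the population can no longer
be propagated. Heredity is phenomenological — only stage summaries of
the real experiment are available, so the simulator targets their
statistical shape, not cell biology:

- **Stage 0** draws `n_clones` = 48 FCM values from a zero-floored
  normal with mean 0.6% and SD 0.5%, matching the observed pre-selection
  equilibrium (min 0, mean 0.6, max 2.0%). The floor is a clamp at 0,
  which keeps the sample mean near 0.6 (a fully truncated normal would
  shift it to ~0.71).
- **Selection** ranks clones by FCM (ties broken by clone id) and takes
  the top `selection_fraction` = 0.1 as parents — five of ~50 clones, a
  strong but realistic truncation intensity for a deliberate selection
  experiment.
- **Heredity**: offspring are redrawn around the blended mean
  $(1-r)\,\bar{x}_{pop} + r\,\bar{x}_{parents}$ with response $r = 1$ by
  default. FCM is a clone-level phenotype scored on hundreds of cells,
  so the clonal heritability of its mean is high; $r = 1$ together with
  the top-10% truncation reproduces the observed rise from 0.6% to
  ~5–8% mean FCM over four selection steps (the breeder's-equation
  increment is $r\, i\, \sigma_k$ with selection intensity
  $i \approx 1.75$).
- **Dispersal**: the redraw SD is `init_sd * dispersal^stage` with
  `dispersal` = 1.5, so the maximum FCM grows faster than the mean, as
  observed (stage-4 max ≈ 15% at mean ≈ 4.7%). This is a modelling
  device, not biology.
- **Apoptosis**: clones with FCM at or above `apoptosis_threshold` = 10%
  (inclusive, clone-level) are flagged apoptotic. The observed arrest
  happened around mean 4.7% / max ~15%, "on the order of 10%", hence the
  default with a config override.
- **Selection uses the full scored population, apoptotic clones
  included.** In the protocol each clone is cut in half and one half
  seeds the next stage before the other half's smear is scored, so
  clones destined for apoptosis cannot be excluded at selection time.
  This also makes the apoptosis termination reachable: breeding only
  from survivors can never push the offspring target mean past the
  threshold, so a population bred that way can never collapse. The run
  terminates, with cause `"apoptosis"`, when fewer than two clones
  survive the filter; otherwise it completes `n_stages` = 5 stages
  (indices 0–4) with cause `"selection-complete"`.

Per-stage summaries include all scored clones (apoptotic ones were
still measured). Each experiment also records its selection arithmetic
(population mean, parent mean, realised next-stage mean), from which
`estimate_selection_response()` recovers the configured response as the
through-origin regression slope of increments on selection
differentials; at 200 seeded experiments the estimate lands within
about ±0.02 of the configured value, comfortably inside the ±0.15
design band.

What the simulator does **not** emulate: karyotypes or chromosome-level
events (FCM is a scalar phenotype), within-clone cell counts and their
sampling error, measurement error of the smear counts, between-
experiment heterogeneity of the real selection lines, and any immune or
microenvironment dynamics. Passing tests therefore show that the
pipeline's statistics behave correctly on populations with the published
stage-level shape — not that the generator is a faithful model of
rhabdomyosarcoma biology. One observable consequence: the simulator's
stage-4 spread (SD ≈ 2.5%) is a little narrower than the real
experiment's 0.5–17% range implies, so the qualitative benchmark
">25% of clones above 9% FCM by stage 3–4" holds in a majority of seeds
but not an overwhelming one.

## Numerical conventions and degenerate inputs

- Entropies are in nats throughout (natural logarithm).
- Histogram bins are half-open, right-exclusive; an observation equal to
  the last edge is a range error, not silently clipped.
- Probability masses must sum to 1 within $10^{-9}$.
- `mu_x1e4` reports use round-half-even (R's `round()`) to two decimals.
- Rates are validated to $(0,1]$ with the ordering
  $\mu_0 \le \mu_{can} \le \mu_c$; fractions to $[0,1]$.
- Degenerate simulator inputs are defined, not errors: `init_sd = 0`
  gives a point-mass population, `response = 0` a stationary control,
  `selection_fraction = 1` a zero selection differential.
- All stochastic paths run off R's global RNG; the simulator seeds it
  from `config$seed`, and two runs with the same config are
  bit-identical.

## Problem sizes in the test suite

The property and calibration tests use $10^4$ Monte Carlo replicates for
waiting-time and cumulative-probability checks (3 SE agreement bands),
100 seeded experiments for trajectory and qualitative-shape properties,
and 200 for response recovery — sizes at which the checked quantities'
standard errors are several times smaller than the asserted bands while
the whole suite stays quick to run.

## Known limitations

- The defect statistic depends on the binning; comparisons are only
  meaningful on a shared grid, and the published defect column is not
  reproducible (see above).
- The mixture model is static per stage; it does not couple stages or
  model the feedback between mutation load and FCM.
- No functional form links the mutagenicity parameter $\theta$ to the
  mutation rate; the Gibbs criterion locates a threshold, nothing more.
- The similarity-score and absolute protein-stability numbers quoted
  alongside the sequence example derive from external structure-based
  tooling and are out of scope; `score_difference()` only subtracts
  supplied scores.
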