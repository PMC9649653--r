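---
title: "Profiling EGFR exon 19 variants: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling EGFR exon 19 variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfr19)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters, what the synthetic
generators emulate (and what they do not), and the numerical choices made
where the underlying procedure was open.

## The classification rule

Exon 19 of *EGFR* encodes the loop that connects strand β3 of the kinase
domain to the regulatory αC helix. In-frame deletions and indels in this
loop activate the kinase, but they split into two behavioural classes
determined by how much shorter the loop becomes:

* **Profile 1** — net shortening of ≤ 3 residues. The ATP site remains
  ordered and wild-type-like, *K*~M,ATP~ stays low (tens of µM), and
  because erlotinib and osimertinib must compete with ATP, these variants
  show primary resistance to both.
* **Profile 2** — net shortening of ≥ 4 residues. The longer deletion
  forces a structural rearrangement of αC that propagates disorder to the
  ATP pocket, raising *K*~M,ATP~ (roughly 90–240 µM) and thereby
  sensitising the kinase to ATP-competitive inhibitors.

Net shortening is counted at face value: residues deleted minus residues
inserted, regardless of what is inserted. A substitution nets zero. This
bookkeeping reproduces every published profile assignment, including the
instructive boundary pair `ΔL747-A750InsP` (4 − 1 = 3, profile 1) versus
`ΔL747-T751InsP` (5 − 1 = 4, profile 2), which differ by a single deleted
residue and sit on opposite sides of the clinical divide.

Shortening the loop is not the only way to activate the kinase: a proline
introduced in the loop (insertion or substitution, as in `L747P`)
restricts the loop conformation enough to activate on its own.
`classify_profile()` therefore carries a separate `proline_introduced`
flag and predicts activation for any profile 2 variant or any
proline-introducing variant. The 3-residue deletion `ΔL747-E749` is the
counter-example that motivates the distinction: profile 1 by length, not
activated, and structurally nearly wild type.

Choices worth recording:

* **Loop window.** No exact β3/αC loop boundary is published; the default
  window E746–I759 covers every deletion reported in the lung-cancer
  cohorts used here and is configurable via `egfr_reference()`. Deletions
  extending past the window edge (e.g. `ΔT751-I759InsN`, which ends on
  I759) are classified with a warning as long as one deleted residue lies
  inside.
* **Net insertions** (inserted > deleted) are outside the rule's domain —
  they resemble exon 20 insertions, which behave differently — and raise
  an error rather than a guess.
* **Numbering.** All coordinates are precursor (signal-peptide-inclusive)
  numbering; `convert_numbering()` maps to mature-protein numbering
  (precursor − 24).

## The kinetics estimator chain

The package reconstructs steady-state parameters in the order an assay
produces them.

**Calibration.** Fluorescence counts are converted to µM phosphopeptide by
an ordinary least-squares line through fully phosphorylated standards
(`calibrate_fluorescence()`, inverse `counts_to_uM()`).

**Initial velocities.** The published procedure selects the steady-state
phase by inspection. The automatic policy in
`estimate_initial_velocity()` makes that reproducible: the longest prefix
window (≥ 4 points) with linear-fit r² ≥ 0.99, capped where product
exceeds 10% of the peptide concentration so depletion cannot flatten the
slope. Blank (no-kinase) curves have no detectable trend, so a window
whose slope is within two standard errors of zero is accepted as v₀ ≈ 0.
A manual window override is available.

**Michaelis–Menten.** `fit_michaelis_menten()` fits
v = *V*~max~[S]/(*K*~M~+[S]) by Levenberg–Marquardt with positivity
bounds, starting from *K*~M~ = median([S]) and *V*~max~ = max(v). The
apparent *k*~cat~ is *V*~max~/[TKD] (nM → µM reconciled). A fitted *K*~M~
more than 10× outside the tested range warns rather than fails.

**IC50.** Dose–response rates are normalised to 100% at zero inhibitor and
fitted to the one-parameter hyperbola Rate = 100/(1+[TKI]/IC₅₀) — top,
bottom and Hill slope fixed at 100/0/1, deliberately not a four-parameter
logistic, matching how the published values were obtained. Assays whose
top dose inhibits less than 50% yield a censored bound (e.g. ">40000"),
not a point estimate, and censored values are excluded from fold-change
tests.

**Cheng–Prusoff.** For a reversible ATP-competitive inhibitor,
IC₅₀ = *K*~I~(1+[ATP]/*K*~M,ATP~). With a known *K*~M,ATP~ the single free
parameter *K*~I~ has a closed-form least-squares solution; otherwise a
linear regression of IC₅₀ on [ATP] gives *K*~I~ as intercept and
*K*~I~/*K*~M,ATP~ as slope. A series whose IC₅₀ does not rise with [ATP]
(slope ≤ 0 or p > 0.05) is flagged `noncompetitive` — several long-deletion
variants show exactly this behaviour, so no *K*~I~ is reported for them.
One published inconsistency is left visible rather than reconciled: for
`L747P`, the forward prediction from *K*~I~ = 6.2 nM and
*K*~M,ATP~ = 21 µM at 1 mM ATP is ≈ 301 nM, while the measured IC₅₀ is
141 ± 17 nM. The package surfaces both numbers and forces no agreement.

**Active-site correction.** Afatinib is potent enough that its IC₅₀ often
titrates the active enzyme rather than reporting affinity. Taking the
afatinib IC₅₀ as 50% of the active TKD concentration,

corrected *k*~cat~ = apparent *k*~cat~ × [TKD] / (2 × IC₅₀^afatinib^).

All published corrected values reproduce only when [TKD] is the
concentration of the *IC₅₀ assay* (100 nM for every variant except
`ΔL747-E749`, assayed at 1 µM with its reported IC₅₀ scaled down ×10 for
presentation); the source leaves this ambiguous, and the package adopts
that convention, storing assay concentrations and the presentation
divisor explicitly in `egfr_kinetic_table()`. Arithmetic always uses
assay-scale concentrations. An active fraction above 1 warns but still
reports.

**Fold changes.** `fold_change_table()` uses the delta method for the SD
of a ratio and Welch's two-sided t-test from summary statistics; the
published analysis states only "unpaired two-sided Student's t-tests", so
the Welch form is a package choice (robust to unequal variances,
testable).

## HDX-MS analysis

Percent exchange of a peptic peptide is
%Ex = (m~t~ − m~0~)/(m~f~ − m~0~) × 100 from centroid masses, with the
fully-deuterated reference m~f~ taken from measurement. When no such
reference exists, `theoretical_mf()` offers the standard convention
m~f~ = m~0~ + 0.95 × (exchangeable amides), with exchangeable amides =
length − 1 − (prolines after position 1). That is a community convention,
not a substitute for a measured reference, and is labelled as such.

**Residue mapping.** Peptide-level values are assigned to residues by the
shortest covering peptide; among equally short peptides the one whose
C-terminus extends furthest right is used ("retains the overlapping
region at its C-terminus"), with any remaining tie broken by the leftmost
start purely for determinism. The C-terminal tie rule is an
interpretation of an ambiguous prose rule; it is pinned by tests so any
future change is visible. Uncovered residues are flagged, never
interpolated.

**Envelope deconvolution and exchange regimes.** In the EX2 limit,
transient local unfolding produces a single envelope whose centroid
drifts upward. In the EX1 limit, long-lived unfolding produces two
co-existing envelopes — folded (low-mass) and unfolded (high-mass) — with
fixed positions and time-shifting areas. `fit_envelope()` fits one- and
two-component Gaussians (Levenberg–Marquardt, bounded widths, three
starting strategies including a residual-peak start and a local-maxima
start) and selects between them by AICc with a 2-point margin favouring
the simpler model. Numerical guards that matter:

* component widths are capped at a third of the m/z range, so a "wide
  baseline Gaussian" cannot masquerade as a population;
* a two-component solution whose mean separation is below **1× pooled
  width**, or with a component under 1% of the area, collapses to the
  unimodal model — least squares will otherwise happily split a single
  skewed envelope in two;
* separations between 1× and **1.5× pooled width** are called
  *fused-bimodal*: two populations present but unresolved (threshold
  configurable). Fully resolved bimodal envelopes require ≥ 1.5×.

`classify_exchange_regime()` then calls EX1 when bimodal envelopes
persist across timepoints with component means stable to within 0.5×
width, EX2 for drifting unimodal series, and fused-bimodal when
unresolved two-component envelopes dominate. Simulation shows exact
regime recovery whenever component separation is at least twice the
width; closer separations are genuinely ambiguous and the fused call is
the honest answer.

`ligand_occupancy()` solves the exact two-state binding quadratic; under
HDX labelling conditions (0.39 µM TKD, 0.78 µM erlotinib after 20-fold
dilution, *K*~d~ ≈ 5 nM) it confirms > 90% occupancy — about 98.7% — so
exchange differences with inhibitor reflect the bound state.

## Survival comparison

`km_estimate()`, `median_survival()` and `logrank_test()` wrap the
product-limit estimator and Mantel–Cox test from the `survival` package
behind this package's interfaces; the test suite checks them against an
independent brute-force product-limit oracle (exhaustive censoring
patterns at n ≤ 8) and a hand-computed contingency-table log-rank. Ties
between events and censorings at the same time follow the standard
convention (events first). The median is the smallest time with
S(t) ≤ 0.5, undefined when never reached. Cox proportional-hazards
adjustment is deliberately out of scope; `compare_profiles()` returns the
stratified data in a layout directly consumable by `survival::coxph()`.

## What the synthetic generators emulate

Each generator is a pure function of (scenario, seed) and feeds the exact
CSV dialects the analysis stages read.

* `gen_progress_curves()` integrates
  dP/dt = *k*~cat~·E~act~ · [ATP]/(*K*~M,ATP~(1+[I]/*K*~I~)+[ATP]) ·
  (S₀−P)/(*K*~M,pept~+S₀−P) by small-step explicit integration (ATP in
  excess, peptide depleting), then applies multiplicative Gaussian noise
  to the fluorescence signal. Default scenario parameters follow the
  published `ΔL747-A750InsP` values.
* `gen_dose_response()` draws from the same one-parameter hyperbola the
  fitter assumes, with multiplicative noise.
* `gen_hdx_series()` produces binomial per-amide incorporation (EX2) or a
  two-population mixture with folded fraction exp(−k~open~t) (EX1), as
  Gaussian-smoothed isotope combs at 1.00628/z spacing; generator truth
  (regime, fractions, noise-free centroids) is recorded for round-trip
  tests.
* `gen_cohort()` draws exponential event times (rate ln2/median per
  profile), independent uniform censoring calibrated to the requested
  censored fraction in expectation, and descriptors sampled from the
  published cohort composition tables.

The noise models (multiplicative Gaussian on fluorescence, additive on
envelope intensities) are simplicity-and-testability choices; no noise
model is published. What passing these tests shows is that the
*estimators* are correct and well-behaved under the assumed statistical
structure. What they do not show: robustness to real-instrument
pathologies — baseline drift, inner-filter effects, covalent-inhibitor
time dependence, peptide carry-over, back-exchange gradients, informative
censoring — none of which the generators attempt to model.

## Problem sizes and defaults

The simulation studies use sizes chosen to make Monte-Carlo error small
relative to the tolerances they check: 200 replicates for parameter
recovery (median |error| < 10% for *K*~M~/*V*~max~/*K*~I~, < 15% for
IC₅₀ at 4% noise), 500 seeded cohorts for log-rank power at the published
cohort sizes (6 profile 1 vs 70 profile 2, medians 2.3 vs 8.5 months, 20%
censoring — the test rejects at α = 0.05 in roughly three quarters of
runs, and the median p is well below 0.05), and 2×20,000 patients for
median recovery (within 2% of truth). ATP titrations span 0.98 µM–3 mM in
two-fold steps and inhibitor doses 0–40 µM, matching the published assay
designs. HDX timepoints default to 10/60/180/600 s.

## Known limitations

* The profile rule's domain is loop-shortening exon 19 variants only; it
  says nothing about exon 20 insertions, T790M-class gatekeeper mutations
  (the `L858R/T790M` row is carried as a control, not classified), or
  compound variants outside the β3/αC window.
* `activation_predicted` is a heuristic (profile 2 or proline): it
  correctly leaves `ΔL747-E749` unpredicted-active, but has only the
  published variant set as validation.
* Covalent inhibitors (afatinib, osimertinib) are summarised by IC₅₀ at a
  fixed pre-incubation; no k~inact~/*K*~I~ time-dependent modelling is
  attempted, so cross-inhibitor comparisons remain qualitative.
* Envelope deconvolution assumes at most two populations and Gaussian
  component shapes on the m/z axis; strongly skewed or three-state
  envelopes will be reported as fused.
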