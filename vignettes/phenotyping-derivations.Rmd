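---
title: "From raw traces to photosynthetic phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw traces to photosynthetic phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photopheno)
```

`photopheno` turns raw spectroscopy time series into the quantities a
photosynthesis phenotyping study reports: quenching light curves,
per-photosystem photochemical rates, photosystem stoichiometry, the
partition of chlorophyll between PSI and PSII, plastoquinone reoxidation
kinetics, functional antenna sizes, pigment contents, and grana
morphometry statistics. This vignette explains the models behind each
derivation, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## Data model

A `trace()` is a strictly increasing time base (always seconds
internally; readers convert declared ms/µs/ps units) with one signal
channel: PAM fluorescence (a.u.), ECS −ΔI/I at 520 or 546 nm, or TCSPC
photon counts. A `protocol()` annotates a trace with ordered light
phases — dark, actinic, far-red, saturating pulse, laser flash — each
with an intensity in µmol photons m⁻² s⁻¹. Phase membership is half-open
`[start, end)`, so a sample on a boundary belongs to the later phase;
this makes segmentation deterministic. `validate_protocol()` is a pure
diagnostic: it returns human-readable findings and never throws, so a
pipeline can report annotation faults without dying.

## PAM quenching analysis

The saturating-pulse method closes all PSII centers for ~0.5 s, so the
fluorescence during a pulse reads the maximal level Fm (dark-adapted) or
Fm′ (light-acclimated). The derived parameters are the standard ones:

* NPQ = (Fm − Fm′)/Fm′,
* ΦPSII = (Fm′ − Fs)/Fm′,
* 1 − qL = 1 − [(Fm′ − Fs)/(Fm′ − F0′)]·(F0′/Fs),
* qT = (Fm,St1 − Fm,St2)/Fm,St1.

`extract_landmarks()` reads them from an annotated trace with these
conventions:

* **Fs** is the mean of the last 5 % of the actinic phase preceding each
  pulse — the fluorescence "just before" the pulse, made robust to
  pulse-edge jitter by averaging a short steady window.
* **Fm, Fm′** are the *median* of the pulse-plateau samples. On a
  noiseless plateau the median equals the maximum; under noise the
  maximum of *k* plateau samples is biased upward by roughly 1.5 standard
  deviations, which at realistic noise and strong quenching (Fm′ ≈ Fm/3)
  propagates to an NPQ error of order 0.1. The median is unbiased on a
  flat plateau, which is why it is the estimator here.
* **F0** is the median of the pre-pulse dark window; **F0′** is the
  minimum within the 2 s far-red window after each step, because the
  far-red transient decays toward the oxidized minimal level.
* No smoothing is applied before extraction; determinism and
  testability take precedence, and any filtering should be explicit in
  the caller.

An Fm′ exceeding Fm by more than a noise tolerance produces a warning
finding rather than an exception, and ΦPSII or 1 − qL outside [0, 1] are
reported as findings, never silently clamped.

Two definitions of qT circulate: normalizing the Fm drop by the State 1
value (used here) or by the State 2 value. They differ by a factor
Fm,St1/Fm,St2; with qT ≈ 0.05 the difference is below 0.003. The
State-1-normalized form is implemented in `compute_qt()`.

NPQ induction/relaxation kinetics are decomposed operationally, not by
curve fitting: `decompose_npq_kinetics()` reads the NPQ at the last
pulse before light-off and at the pulse nearest a stated relaxation time
(5 min is typical), calling the difference qE (the rapidly reversible,
energy-dependent component) and the remainder the residual
(zeaxanthin-dependent and photoinhibitory quenching). A fitted
multi-component relaxation model would be statistically stronger but
also protocol-dependent; the two-point form matches how such numbers are
usually reported.

## The PAM generative model

`simulate_pam_protocol()` produces the trace such a protocol would
record, given a `simulation_ground_truth()`:

* Total NPQ is the sum of a fast component relaxing first-order toward
  the steady-state light response
  NPQ_ss(I) = npq_max·I^h/(I50^h + I^h) (τ = 60 s in light, 90 s in
  dark) and a slowly reversible component (amplitude 0.3, τ = 300 s in
  light, 5× slower in dark) that produces the residual quenching seen
  after dark relaxation.
* Fm′(t) = Fm/(1 + NPQ(t)); F0′ follows the Oxborough–Baker relation
  F0′ = F0/(Fv/Fm + F0/Fm′). The analysis path never assumes this
  relation — F0′ is read from the simulated far-red window, exactly as
  an instrument would.
* The closed-center fraction follows a lake model:
  C = σ_PSII·I/(σ_PSII·I + σ_PSI·I/r + k_d), i.e. PSII excitation
  against reoxidation of the PQ pool by PSI pull, plus a small
  constitutive acceptor capacity k_d = 5 (in σ·I units) so that closure
  vanishes in darkness. Steady-state fluorescence is then generated so
  that the open fraction equals qL:
  Fs = Fm′·F0′/(F0′ + (1 − C)(Fm′ − F0′)). With this choice the
  extracted 1 − qL equals C identically, which is what makes the
  closed-center fraction a recoverable ground-truth quantity.
* Saturating pulses are treated as non-actinic probes: they read Fm′
  without advancing the quenching state. Over a 0.5 s pulse the state
  would move by well under 1 %, and freezing it makes the pulse plateau
  exactly flat, so the emitted ground-truth landmarks are exact rather
  than approximate.

Gaussian noise is added pointwise; every simulator takes a seed, uses a
local RNG stream, and restores the caller's RNG state.

Default parameters describe a healthy Arabidopsis leaf: Fv/Fm = 0.8
(Fm = 3, F0 = 0.6 a.u.), npq_max = 2.2, I50 = 250 µmol photons m⁻² s⁻¹,
Hill slope 1.5, PSII/PSI center ratio 1.37, and a PSI cross-section
turning over twice as fast as PSII per center at the same limiting
light. The mutant-like set used by `run_study()` reduces the PSII
cross-section by 25 %, raises the center ratio by 25 %, lowers npq_max
by 30 %, nearly abolishes state transitions, and speeds far-red PQ
reoxidation — the canonical signature of losing the major trimeric
PSII antenna.

## ECS analysis

The carotenoid electrochromic bandshift at 520 nm reports the
transmembrane electric potential linearly. The 546 nm channel carries
the non-electrochromic nuisance (scattering drifts), so
`deconvolve_ecs()` subtracts it pointwise; mismatched time bases are an
error unless resampling is explicitly requested, because silent
interpolation hides acquisition faults.

A saturating single-turnover laser flash fires every reaction center
once; the ECS amplitude read 140 µs after the flash (linear
interpolation, baseline = mean of the preceding 1 ms) therefore
calibrates "one charge separation per photosystem". Two flashes — one
with all centers active, one with PSII inhibited by
DCMU/hydroxylamine — give the stoichiometry
r = (amp_total − amp_PSI)/amp_PSI.

Rates come from initial slopes: at light-off the reaction centers stop
instantly while ATP synthase keeps consuming the potential, so the
initial decay slope equals the steady charge-separation rate; at
light-on the initial rise slope equals the absorption-limited maximal
rate of the open photosystems. `photochemical_rate()` divides |slope| by
the single-charge amplitude to get e⁻ s⁻¹ PS⁻¹. The slope window
defaults to 5 ms with at least 10 samples: it must stay well below the
ATPase time constant (~0.15 s here) for the initial-slope approximation;
at 5 ms the curvature bias is under 1 %. Far-red excitation drives PSI
only, so the far-red off-decay slope reads the cyclic electron flow,
and `cef_fraction()` expresses it as a percentage of the total.

The simulator models flashes as instantaneous steps decaying with the
ATPase time constant, light transitions as saturating
exponentials whose initial slope encodes the generative rates, and the
546 nm nuisance as a slow linear drift added to both channels — so
deconvolution is exactly testable. The steady-state ECS level is set at
ten single-charge amplitudes, keeping the decay time constant long
against the slope window.

## Chlorophyll repartition and antenna size

Under the same limiting light, a photosystem's photochemical rate per
center is proportional to its absorption cross-section, i.e. to the
chlorophyll pool feeding it. With r PSII centers per PSI center, the
PSI share of total chlorophyll is

> PSI/(PSI + PSII) = rate_PSI / (rate_PSI + rate_PSII · r)

(`chl_fraction_from_rates()`). With the wild-type inputs
(39.98, 20.25, 1.37) this gives 0.59; with the mutant inputs
(46.14, 14.95, 1.71), 0.64.

The independent FLIM route fits a TCSPC decay with three exponentials at
fixed lifetimes — 0.1 ns (PSI-dominated), 0.9 ns (open PSII), 2.0 ns
(closed PSII/free antenna) — reducing the fit to non-negative least
squares on the (optionally Gaussian-IRF-convolved) basis. Fixing the
lifetimes mirrors standard practice and makes the problem linear and
well-conditioned; free-lifetime fitting is deliberately out of scope.
Amplitudes are normalized to sum to one and a reduced χ² is reported
under Poisson weights 1/max(count, 1). The PSI chlorophyll share is
then c·a1/(1 − a1 + c·a1) with c a setup-specific correction factor
(default 0.49) relating the detection efficiencies of the two pools; c
is not derivable from the data and must be supplied. Amplitude recovery
degrades with photon count roughly as expected from multinomial
statistics: at 10⁶ photons the fast amplitude is within ±0.02 in ≥95 %
of runs; at 10⁴ photons the spread is ~10× larger.

With DCMU blocking QA→QB transfer, each PSII performs a single stable
charge separation and the fluorescence rise F(t) tracks cumulative
closure: V(t) = (F − F0)/(Fm − F0) = 1 − exp(−kt) for a homogeneous
antenna, with k proportional to the functional PSII cross-section. The
complementary area ∫(1 − V)dt = 1/k is integrated trapezoidally;
because a finite trace truncates the area, the last 10 % of samples are
fitted to a single exponential and the tail integrated analytically to
infinity. A trace not reaching 99 % of Fm is a coverage error with a
partial-area diagnostic.

## Vj and plastoquinone reoxidation

Vj is the relative variable fluorescence 3 ms into a saturating
fast-induction pulse: (F(3 ms) − F0)/(Fm − F0), with F0 read 50 µs
after pulse onset (the first reliable point of this instrument class)
and Fm the pulse maximum. The variable-fluorescence normalization is
the JIP-test convention; a plain F(3 ms)/Fm variant is available behind
a flag. Vj is invariant to scaling and offset of the raw trace, and
both invariances are asserted as tests.

Trains of pulses separated by growing dark or far-red intervals probe
PQ-pool reoxidation: Vj(Δ) = V∞ + (V0 − V∞)exp(−Δ/τ). Because the
intervals span more than two decades (0.05–24 s dark, 0.05–1.6 s
far-red), the trend is summarized as the OLS slope of Vj against
log10(Δ); a lowess curve (span 0.75) is returned for display only. The
default reoxidation time constants (6 s dark, 0.8 s far-red wild-type,
0.5 s mutant) sit on the rising side of the grid's slope response, so a
faster τ always prints as a steeper negative trend on these interval
grids. Far-red reoxidation is faster than dark whenever PSI pull
exceeds the constitutive oxidation capacity, as in both default
parameter sets.

## Pigments

Chlorophylls are quantified from buffered 80 %-acetone extract
absorbances by the two-wavelength linear system
chl_a = 12.25·A663.6 − 2.55·A646.6,
chl_b = 20.31·A646.6 − 4.91·A663.6 (µg/ml, 1 cm path), after A750
turbidity subtraction and dilution scaling. The coefficient matrix is
exposed as an argument so other solvent systems can be swapped in. The
map is a linear bijection; `simulate_pigment_extract()` is its exact
inverse, and round trips are identity to 10⁻⁹. Results within
−0.01 µg/ml of zero are clamped (blank-extract noise); anything more
negative raises a spectra-inconsistency error.

## Morphometry statistics

`compare_groups()` reproduces the conventional gated workflow: a
Shapiro–Wilk test on the residuals decides between one-way ANOVA
(p ≥ α) and Kruskal–Wallis (p < α); a significant omnibus test is
followed by all pairwise Student's (pooled-variance) t-tests, reported
unadjusted by default with Holm/Bonferroni available. The branch choice
is a deterministic function of the Shapiro p-value and α, and the
empirical type-I error of the whole procedure stays within [0.03, 0.07]
at α = 0.05 in the package's null simulations.

Grana stack counts are modeled by a Poisson GLM with log link
(`n_layers ~ genotype`, or `genotype * covariate` for the
analysis-of-covariance form), fitted by IRLS to a deviance tolerance of
10⁻⁸ with Wald z statistics; widths by OLS. The synthetic generator
draws counts as 1 + Poisson(mean − 1), because a granum has at least one
layer, while the GLM still treats counts as plain Poisson — a
deliberate, mild misspecification that keeps the standard model family
and makes the GLM slightly conservative (the shifted counts are
underdispersed). The genotype coefficient of the Poisson GLM is exactly
the log ratio of group means, so a 4.57 vs 3.75 layers-per-stack
contrast is recovered as ≈ log(0.821) = −0.198.

## The synthetic study

`run_study()` chains everything for named parameter sets: simulate each
modality, analyze it with the same functions a user would call on real
data, and tabulate the contrasts. Default problem sizes are chosen to
keep a full run under a second while leaving each estimator comfortably
inside its validated precision: 1-minute actinic steps sampled at 50 Hz,
10⁶ TCSPC photons, 200 grana per genotype. Any stage error is recorded
per stage and the remaining stages still run. Given the configuration
(which fixes all seeds), reports are byte-identical across runs.

## What the simulations do and do not show

The generators reproduce the *statistical structure* each analysis
assumes: first-order quenching kinetics, exponential ECS relaxations,
multinomial photon statistics, shifted-Poisson counts, Gaussian widths.
They do not emulate instrument artifacts (detector nonlinearity,
baseline drift during PAM runs, IRF tails, stray actinic light in
far-red windows), biological heterogeneity between leaves, or the
O-J-I-P fine structure of fast induction (the Vj generator produces the
summary statistic directly, not the full transient). Passing the
recovery tests therefore validates the derivation chains — formulas,
landmark conventions, slope and area estimators, model fits — not the
generative adequacy of these models for any particular instrument.

## Known limitations

* NPQ decomposition is two-point, not kinetic; qI/qZ are not separated.
* No ECS b-phase/c-phase decomposition or proton-motive-force
  partitioning.
* FLIM analysis is aggregate-decay only; no per-pixel lifetime maps or
  target analysis.
* The statistics module consumes tabulated morphometry; image
  segmentation is out of scope.
* Binary instrument formats are not parsed; traces arrive as delimited
  text with a structured-text protocol sidecar.
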