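---
title: "Models and methods behind loomlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loomlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomlab)
```

loomlab quantifies closed-loop looming-escape behaviour in mice together
with the cellular measurements that accompany such studies: laminar visual
responses in the superior colliculus (SC), whole-cell physiology of
periaqueductal grey (PAG) neurons including the dendrotoxin-sensitive
potassium current, and label-free proteomics of the underlying tissue.
Because the raw recordings behind such experiments are rarely
redistributable, every analysis stage is paired with a seeded synthetic
generator that produces the same data modality with known ground truth.
The generators are first-class, tested code: the package's strongest
correctness argument is parameter recovery — each stage must recover what
its generator put in.

This vignette explains the models, the defaults and why they were chosen,
the numerical decisions, and what the recovery tests do and do not show
about real data.

## The behavioural assay and its simulator

In the assay a mouse explores a 32 cm square arena with a 9 cm shelter
against one wall. Whenever the animal crosses a threat-zone boundary 10 cm
from the shelter centre, a closed loop triggers an overhead stimulus — five
consecutive dark discs, each expanding at 80 deg/s for 500 ms to a final
diameter of 40 deg and held for 250 ms — with a minimum inter-stimulus
interval of 30 s. Escape is classified from the tracked centroid: a trial
is an escape if the animal returns to the shelter within 7 s of stimulus
onset and its speed (an 83 ms moving mean, 5 frames at 60 Hz) reaches at
least 20 cm/s; the reaction time is the time from onset to the speed
maximum before shelter entry, and the loom presentation containing that
peak gives the looms-to-escape category. The immediate response is
summarised by `s_at` (mean speed within ±50 ms of onset) and `s_im` (mean
speed 300–800 ms after onset); trials are labelled increase / decrease /
no-change against one standard deviation of the pooled genotype `s_at`.

The simulator (`gen_ler_session`) is a four-state semi-Markov agent:

* **shelter** — small positional jitter at the shelter centre;
* **explore** — an Ornstein–Uhlenbeck speed process (mean 7.5 cm/s,
  relaxation 1 s, noise 3 cm s^-1^ s^-1/2^) with a diffusing heading;
  walls mirror the step and the agent slides along the dilated shelter
  boundary rather than entering it, so each exploration bout is one
  well-defined shelter exit;
* **arrest** — a transient stop (1.2–3 s) shortly after an unanswered
  stimulus;
* **escape** — a straight run to the shelter whose speed follows a
  raised-cosine bump peaking at the drawn peak speed.

The escape run covers the full distance to the shelter centre, so the
speed peak falls clearly before shelter entry and the bump decays smoothly
inside the shelter; the true reaction time (hazard delay plus half the
bump width) is therefore known exactly and the reaction-time estimator can
be scored against it. Two genotype presets set the study conditions:
*wildtype* (latency median 0.3 s, per-loom escape hazard 0.9, peak speed
63 ± 8 cm/s, arrest probability 0.05) and *mutant* (1.5 s, 0.3,
50 ± 8 cm/s, 0.5). The latency medians are the contrast the recovery suite
is required to resolve; peak speeds and the exploration speed are anchored
to the per-animal averages printed for the two genotypes in the source
experiments. Tracking noise defaults to 0.02 cm, the scale of marker
jitter in video tracking at this resolution.

What the simulator does **not** model: sprint-like exploration bursts
(real animals reach 40 cm/s outside of escapes; our OU exploration stays
below ~16 cm/s), thigmotaxis, posture, and any visual computation — the
stimulus acts only through the hazard. Recovery results therefore show
that the estimators are unbiased and well-calibrated on data obeying the
stated escape definition, not that they are robust to every tracking
artefact of real video.

## Laminar alignment and visual-response metrics

The current source density (CSD) is the negative second spatial difference
of the flash-locked, trial-averaged LFP, with Vaknin-style edge padding
(first and last channels duplicated). The inflection depth (ID) is the
source-to-sink sign transition of the CSD profile averaged over an early
post-flash window (default 0–100 ms; the window is a configuration
parameter because published methods leave it open). Sign transitions are
searched on interior channels only — the padded edge estimates are
extrapolations and can carry spurious flips. Layers follow from the ID:
superficial SC spans ID − 300 µm to ID + 100 µm, intermediate/deep SC lies
below. The synthetic LFP is built by double-integrating a template CSD, so
the noiseless estimator recovers the template exactly; this is an identity
check of the discretisation, not evidence about real volume conduction.

Responsiveness uses a ZETA-style temporal-deviation statistic: the maximal
absolute deviation of the event-locked spike-time empirical CDF from the
uniform CDF, scaled by √n, with a circular-shift resampling null and a
permutation p-value. We chose the permutation form (rather than an
extreme-value tail fit) because exact calibration under the null is what
the acceptance suite verifies; with 100 resamples the smallest attainable
p is ~0.01, well below the 0.05 responsiveness threshold.

Spike-triggered averages are computed over a peri-spike lag window
(default 0–250 ms, configurable for the same reason as the CSD window).
The receptive-field centre is the pixel with maximal variance across lags;
SNR is `10·log10(max_power/noise_power)` with the noise power taken from a
5-pixel border of the cropped map; polarity is the sign of the
centre-pixel mean; the radius is the half-peak width of the spatial
profile. Units are flagged visually responsive relative to the 80th
percentile of their (superficial SC) population — a relative criterion, so
the synthetic recovery test checks centre and polarity absolutely but the
flag only against a simulated population. Direction selectivity is
`(D_p − D_np)/(D_p + D_np)` on baseline-normalised mean responses
(response/baseline ratio; the alternative baseline-subtraction convention
changes DSI values but not the ordering that the 80th-percentile DS flag
uses). K-means cluster counts are chosen from the Calinski–Harabasz index;
"elbow" is operationalised as the smallest k within 10% of the CH maximum
over k = 2…10, since no published rule exists. Time-to-peak ties break to
the earliest bin; pupil diameter is the major axis of a direct
least-squares ellipse fit (a tiny ridge keeps the scatter matrix
invertible when points lie exactly on a conic, and collinear frames are
flagged rather than fitted).

## The patch-clamp model

The synthetic cell is an exponential integrate-and-fire membrane with one
non-inactivating, Boltzmann-gated K^+^ conductance representing the
dendrotoxin-sensitive (Kv1-type) current:

C dV/dt = −g~L~(V − E~L~) + g~L~Δ~T~ exp((V − V~T~)/Δ~T~) −
g~Kv~ n (V − E~K~) + I,  with  τ~n~ dn/dt = n~∞~(V) − n,
n~∞~(V) = 1/(1 + exp(−(V − V~h~)/k)).

Defaults: C = 50 pF, g~L~ = 1 nS (R~in~ = 1 GΩ, τ = 50 ms), E~L~ = −70 mV,
V~T~ = −45 mV, Δ~T~ = 2 mV, g~Kv~ = 5 nS, V~h~ = −22 mV, k = 3.5 mV,
E~K~ = −90 mV, τ~n~ = 8 ms — passive values in the range reported for dPAG
neurons. Three numerical choices matter:

* the exponential spike-initiation drive is capped (default 15 nA) so the
  upstroke has a finite peak dV/dt that the K^+^ conductance can visibly
  reduce — in a raw EIF the upstroke diverges and the phase-plane peak
  would be a sampling artefact;
* spikes are stylised: after reaching +30 mV the trace descends linearly
  to an after-hyperpolarisation level over 0.5 ms, giving waveforms with
  measurable width, AHP and rise time without a multi-conductance model;
* integration uses forward Euler at 0.05 ms (the generator rejects steps
  above 0.1 ms) in compiled code.

Because V~h~ sits above threshold with a steep slope, the conductance is
silent at rest and near rheobase but activates during every spike and
decays over τ~n~ afterwards; its braking charge per interspike interval
grows with firing rate. The model consequently reproduces the qualitative
physiology: identical passive properties and rheobase, firing suppressed
at strong injections, and a lower phase-plane peak with larger g~Kv~. The
brake scales close to linearly with rate, so in cohort simulations the
genotype contrast is statistically invisible near rheobase (30 pA probe)
and clear at 120 pA; at intermediate currents (around 50 pA) significance
is marginal and seed-dependent, which is why the property test probes
30 vs 120 pA.

Voltage-clamp sweeps return the clamped ionic current with first-order
activation kinetics (no capacitive transient by default), and the
DTX-sensitive current is baseline minus post-drug averages with the
maximal signed deflection per 1 s step taken after a 50 ms settling window
so activation has reached steady state; dividing by C~m~ gives the current
density. Spontaneous EPSCs are Poisson events with bi-exponential shape
(rise 1.5 ms, decay 10 ms, 20 pA — the scale of the reported sEPSC
statistics); the detector matched-filters the baseline-subtracted trace
(running-median baseline over 200 ms), picks local maxima of the filter
output above 4 noise SDs with a minimum separation of one decay constant,
and additionally requires the estimated amplitude to exceed 3 baseline
noise SDs. At a 2 pA noise floor this keeps the false-positive rate below
0.1 Hz while recovering 2 Hz event trains within Poisson error.

## Proteomics reprocessing

The pipeline follows the reprocessing route from a peptidoform-level
intensity table to protein-group differential calls:

1. **Levenberg–Marquardt renormalisation** — one additive offset per
   sample in log space, fitted by damped least squares against the row
   medians (the row anchor is a design choice; the published description
   names only the optimiser), offsets constrained to sum to zero. The
   procedure is idempotent and recovers injected loading offsets; note
   that with many regulated features a global normaliser necessarily
   absorbs a share of the true effect (about 10% when 10% of rows carry
   the effect), a property of all global normalisation, not of the
   optimiser.
2. **Batch correction** — empirical-Bayes location/scale adjustment via
   ComBat with the biological group protected. Rows containing missing
   values cannot enter ComBat and receive per-batch location-only
   centring, flagged with a warning; missing values are never imputed.
3. **Best-flyer protein-group quantification** — a relative step (mean of
   mean-centred member peptidoform profiles) anchored by the mean
   intensity of the group's most intense peptidoform. Groups with at
   least 3 unique peptidoforms use unique ones only; phosphopeptidoforms
   are excluded throughout.
4. **Moderated t** — limma's empirical-Bayes shrinkage per protein,
   Benjamini–Hochberg adjustment, and the regulation rule: significant
   AND |log2 FC| above the 95th percentile of |log2(control/mean
   control)| ratios. The published phrase "greater than 5% of
   control-to-average-control ratios" is ambiguous; we read it as this
   percentile rule and expose the quantile as a parameter. A fixed-volcano
   classification (P < 0.1, |FC| > 0.4) is reported alongside.

The generator builds log-normal intensities additively (protein base +
peptidoform offset + loading + batch + group effect + noise, defaults:
noise 0.1 log10, loading 0.15, batch 0.1, 6 samples/group in 2 batches)
with optional missing-at-random dropout. It does not model
intensity-dependent missingness or correlated peptidoform noise, so the
calibration results speak to the statistics, not to ionisation physics.

## The statistical layer

All stages route hypothesis tests through one layer. `route_test` applies
Shapiro–Wilk normality (on each group, or on paired differences) and
Levene's variance homogeneity at α = 0.05 and selects the paired/unpaired
t test (Welch when variances differ) or the Wilcoxon counterpart;
two-tailed throughout; fewer than 3 observations defaults to a rank test
with a warning; paired identical samples return p = 1 by convention.
`chi2_independence` is plain Pearson χ² without Yates correction (the
convention consistent with the published test statistics at these sample
sizes; the correction is switchable). `rm_anova_multcomp` fits the mixed
between × within ANOVA via `aov` with an `Error(subject/within)` stratum
for balanced designs, applies a Greenhouse–Geisser correction when
Mauchly's test rejects sphericity (ε computed from the within-cell
covariance matrix), and takes Tukey- or Bonferroni-adjusted pairwise
contrasts from `emmeans`; unbalanced designs fall back to a linear mixed
model, flagged. The type-I error of the routed two-sample test stays near
nominal under both normal and skewed nulls (verified by simulation in the
test suite).

## Problem sizes, determinism and file formats

Every generator is a pure function of its parameters and seed; the
recovery suites fix seeds and run at deliberately desk-scale sizes chosen
to estimate each quantity with comfortable margin: 20 sessions per
genotype preset for the behaviour round trip (label agreement ≥ 95%,
reaction-time RMSE within 2 frame periods), 50 checker units and 500 null
units for the receptive-field and calibration checks, 20 randomised cells
for the passive-property suite (each within 5%), and ~500-protein
matrices for the proteomics calibration. All on-disk formats are plain
text: tracked sessions and stimulus logs as CSV, sweep sets as a long CSV
container with a commented header, peptidoform tables as TSV, run
configuration as YAML. `run_pipeline` drives the simulate→analyse
behaviour path end to end and is byte-reproducible under a fixed seed.

## Known limitations

* The behaviour agent's escape is always shelter-directed; directedness
  values near 1 are built in, so that metric is exercised structurally,
  not validated against tortuous escapes.
* The ZETA-style test shares the deviation-statistic idea with the
  published test but not its extreme-value machinery; p-values below the
  permutation resolution are unreachable.
* The EIF + Kv model produces a near-linear rate brake; phenomena such as
  depolarisation block or spike-height rundown at strong drive are out of
  scope.
* Cohort-level reproduction of the published figures requires the study's
  deposited per-figure data files; the package ships the aggregation
  stage and a check that runs when those files are pointed to locally
  (option `loomlab.supplementary_dir`), and that check reports failure in
  their absence.
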