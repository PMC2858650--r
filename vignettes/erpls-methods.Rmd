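---
title: "Models and methods behind erpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(erpls)
```

`erpls` analyzes longitudinal auditory evoked potential (AEP) studies in
which the P2 component of the P1-N1-P2 complex grows with repeated
stimulus exposure across recording sessions. Because subject-level EEG from
such studies is rarely shareable, the package pairs every analysis stage
with a synthetic-study generator that plants a known session-dependent P2
enhancement, so each stage can be verified against ground truth. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the verification experiments do and do not establish.

## The synthetic study

### Signal model

Each evoked component (P1, N1, P2) is a Gaussian bump in time,

$$k(t) = a \exp\left(-\tfrac{1}{2}\left(\tfrac{t - \ell}{\sigma}\right)^2\right),
\qquad \sigma = \frac{w}{\sqrt{2\ln 2}},$$

with signed amplitude $a$ (µV), latency $\ell$ (ms) and half-width at half
maximum $w$ (ms), multiplied by a fixed scalp topography (a vertex-maximal
Gaussian falloff over the montage grid). Defaults: P1 (+1 µV, 60 ms,
$w=20$), N1 (−2 µV, 110 ms, $w=25$), P2 (+2 µV, 185 ms, $w=25$). Latencies
are measured from the *effective* sound onset; the stimuli carry an internal
pre-voicing silence (~50 ms for "mba", ~60 ms for "ba") that delays every
component by that amount, so the simulated P2 peaks near 235–245 ms
post-trigger. The P2 width is chosen so that the planted session effect
spans roughly 190–290 ms after the silence shift — the latency range in
which exposure-driven P2 enhancement is classically reported. A Gaussian is
a deliberate simplification: real AEP deflections are asymmetric and
overlap; the generator's job is peak- and decomposition-level
verifiability, not biophysical realism.

The *effect plan* adds session-dependent amplitude gains with the P2 kernel
shape at chosen electrodes. The default plan plants +0.5 µV (session 2) and
+1.0 µV (session 3) at the temporal-occipital electrodes TP9, IZ, TP10,
doubled for group 2 (the group that also performs the identification task),
with session 4 retaining 60% of the session-3 gain. Gains are monotone
non-decreasing over sessions 1–3.

### Variability and noise

Each trial is the subject's noiseless evoked response plus zero-mean
Gaussian noise with inter-electrode correlation $\rho^{d}$ at grid distance
$d$ ($\rho = 0.6$), white in time, with `noise_sd = 1` µV. Subject-level
variability has three parts, all applied to component amplitudes/latencies:

* between-subject amplitude sd 0.2 µV and latency sd 8 ms (stable traits);
* within-subject session-to-session variability, split into a global
  amplitude fluctuation (sd 0.2 µV, one draw per subject × session ×
  component) and a spatially heterogeneous per-electrode term (sd 0.3 µV
  per electrode and component), the kind of day-to-day change produced by
  cap repositioning and impedance drift.

The structure of this variability matters and was a genuine design
decision. Placing most variability *between* subjects creates large
group-mean differences under any random 10/10 split; those inflate the
restricted permutation null of the task-PLS (whole subjects are permuted
across groups) and are faithfully reproduced by subject-level bootstrap
resampling, drowning the planted session structure. Making the
session-to-session part purely *global* is equally degenerate in the other
direction: one shared draw per session paints a coherent whole-scalp
structure that, in tail realizations, becomes bootstrap-stable everywhere
at once. Spreading it across electrodes decorrelates those columns, so the
bootstrap sees many nearly independent small effects instead of one large
coherent one, while still supplying the resampling variance that keeps the
deterministic re-reference leakage of the planted gain below the stability
threshold. Real cohorts have *more* between-subject spread than this
default; the recovery experiments therefore characterize the procedure in
a favorable signal-to-heterogeneity regime — the regime the reference
class of exposure studies reports, with a single dominant latent variable
carrying half to three-quarters of the cross-block covariance — and do not
certify power for strongly heterogeneous cohorts.

Artifact trials occur independently with probability `artifact_rate`
(default 0.05) and carry a 120 µV blink transient on the four periocular
channels (25% pickup on frontal scalp rows), guaranteeing the ±70 µV screen
catches them. The ground-truth record marks artifact trials by applying the
±70 µV rule to the generated data itself, so the rejection log can be
checked for exact equality. The behavioral observer is the equal-variance
Gaussian model: on "mba" trials the decision variable is $N(d', 1)$, on
"ba" trials $N(0, 1)$, unbiased criterion $d'/2$ by default, 25 + 25 trials
per session.

What the generator does **not** emulate: overlapping-component latency
interactions, non-Gaussian or temporally correlated noise, drifting
electrode impedances, true ocular propagation, or stimulus-specific
adaptation. Passing recovery tests therefore demonstrates correctness of
the *analysis machinery*, not robustness to every property of real EEG.

## Preprocessing

The chain is fixed and recorded in each object's provenance:
epoch → baseline-correct (−100..0 ms mean per trial and electrode) →
reject (±70 µV on all channels, eye channels included — the screen exists
to catch blinks) → average → band-pass → common-average re-reference
(scalp electrodes only). All stages except rejection are linear.

The band-pass realizes the "analog simulation" recording-software filter as
a causal cascade: 4th-order Butterworth high-pass at 1 Hz (24 dB/octave)
and 2nd-order low-pass at 20 Hz (12 dB/octave), each −3 dB at its corner,
applied forward-only. A zero-phase `filtfilt` variant exists behind the
`zero_phase` flag but is off by default because forward-backward
application doubles the corner attenuation to −6 dB and the stated rolloffs.
Two consequences of the causal choice are worth knowing: a few-ms group
delay in the passband, and a genuine post-P2 undershoot (the 4 high-pass
zeros at DC force vanishing low-order moments), which places some
session-effect mass just after the P2 deflection. Both are properties of
the emulated recording chain, not bugs.

## Peak and ROI quantification

Peak amplitude is the signed extremum (maximum for P1/P2, minimum for N1)
relative to the zero-mean pre-stimulus baseline, within fixed search
windows chosen to accommodate the silence shift: P1 80–160 ms, N1
120–220 ms, P2 190–320 ms post-trigger (configurable; recorded in the peak
table's metadata). Ties break to the earliest latency, and an extremum at a
window edge is *flagged* (`boundary = TRUE`) rather than dropped — a
deterministic replacement for manual peak confirmation. Windowed P2
amplitude is the unweighted mean over 190–290 ms, averaged over ROI
electrodes when a ROI (vertex = CZ; anterior-central = FC1/FZ/FC2;
temporal-occipital = TP9/IZ/TP10) is given.

## Task-PLS

For one stimulus, the data matrix stacks subjects by condition (group ×
session; rows contiguous per condition) against 59 electrodes × 301 time
samples (0–300 ms, time-major columns). Mean-centering PLS subtracts the
unweighted grand mean of the condition means and takes the SVD of the
centered 6 × p matrix, computed through its 6 × 6 cross-product — features
are never materialized beyond one matrix. This yields six latent variables
(orthonormal design saliencies, electrode saliencies, singular values);
covariance fractions are $s_k^2 / \sum s^2$. The "orthogonal design matrix"
is the identity on condition cells, i.e. pure mean-centering task-PLS.
Non-rotated PLS projects the centered means onto a unit-normalized a-priori
contrast (default (−1, 0, 1) over sessions), yielding exactly one LV whose
electrode salience is $M^\top c$ and singular value its norm.

**Permutation test.** LV strength uses 500 permutations with the
convention $p = (b + 1)/(n + 1)$. The default scheme respects the design:
session labels are permuted within each subject and whole subjects are
permuted across groups. This is exchangeable under the joint null and
therefore calibrated for any amount of subject heterogeneity; unrestricted
row reordering (the permissive historical alternative) is available behind
`restricted = FALSE` but is anti-conservative for group structure when
subjects differ stably.

**Bootstrap ratios.** Stability uses 500 bootstrap samples drawn with
replacement over subjects within group, each subject's session rows kept
together (whole-subject resampling can never empty a condition cell; a
guard redraws and logs if it ever did). Each refit's LVs are sign-aligned
to the original by the sign of the salience dot product — a deliberate
simplification over full Procrustes alignment that is exact for the
single-contrast case and adequate for a dominant LV1, but not trustworthy
for higher LVs, which is a documented limitation. Saliencies enter on the
singular-value scale ($M^\top u$, the cross-block structure) for both the
original and the refits; BSR = original / bootstrap sd, and `|BSR| > 3`
marks stable columns. With zero resampling variance and nonzero salience
the ratio is reported as infinite; 0/0 is reported as 0.

One subtle, faithful behavior: common-average re-referencing redistributes
a gain planted at 3 of 59 electrodes as a −(Σgain)/59 deflection on every
other electrode. That leakage is deterministic, so with enough trials it
*is* a stable effect, and the recovery experiment's spatial-concentration
measure therefore sums the absolute LV1 *saliences* (the effect map) over
stable columns — the small-amplitude leakage columns then contribute
little, while summing |BSR| itself would weight them by precision.

## Repeated-measures ANOVA

The balanced-only engine computes every within-subject stratum through
orthonormalized contrasts (normalized Helmert per factor, Kronecker
products across factors): for stratum $S$ with contrast scores $T$,
$SS_S = N\,\lVert\bar t\rVert^2$, the group interaction uses group means of
$T$, and the error is the pooled within-group variation, giving the exact
classical F tests (verified against `aov()` error strata to 1e-8).
Greenhouse-Geisser $\varepsilon = \mathrm{tr}(\Sigma)^2 / (d\,\lVert
\Sigma\rVert_F^2)$ from the pooled contrast-score covariance, clamped to
$[1/d, 1]$ (flagged when clamped), applied only when the numerator df
exceeds 1; uncorrected df are reported with GG-adjusted p. Partial
$\eta^2 = SS_e/(SS_e + SS_{err})$. Requiring balance (and equal group
sizes) sidesteps sum-of-squares-type ambiguity entirely; unbalanced data
are an error, never imputed.

Post-hoc analysis refits the ANOVA inside each level of the moderator
(sliced — not pooled — error terms, a documented choice) and applies
Bonferroni to pairwise comparisons of marginal means (paired t within,
pooled-variance t between), multiplying raw p by the family size, capping
at 1, and leaving a single comparison unadjusted. Retention contrasts are
separate two-level Session ANOVAs (1 vs 4, 3 vs 4) at the
temporal-occipital ROI.

## Behavior

Identification logs are scored with hits = "mba" trials answered "mba" and
correct rejections = "ba" answered "ba"; $d' = z(H) - z(FA)$ with rates
clamped to $[1/(2N), 1 - 1/(2N)]$ (the standard correction keeping perfect
scores finite at $N = 25$, where $d'(H{=}1, FA{=}0) \approx 4.11$).
Session contrasts use paired t tests (one-tailed where the hypothesis is
directional), group contrasts pooled-variance two-sample t tests, and
brain-behavior association Pearson correlations between $d'$ and windowed
190–290 ms P2 amplitude at CZ and the temporal-occipital ROI, with
zero-variance inputs flagged as degenerate rather than propagating NaN.

## Verification experiments and problem sizes

The experiment helpers re-run the full pipeline at sizes chosen to finish
in minutes on one core; all sizes are recorded here and in the function
documentation:

* `recovery_experiment()`: 20 replicate studies, default effect plan,
  1 µV trial noise, 10 subjects/group, one stimulus, 40 trials/block
  (the analysis consumes trial *averages*, so beyond a few dozen trials
  extra trials only shrink an already-small evoked noise term), 500
  permutations and 500 bootstraps. Reports the LV1 rejection rate at
  α = .05 and the stable-mass concentration in the planted 190–290 ms ×
  {TP9, IZ, TP10} set.
* `null_calibration_pls()`: 200 zero-effect studies on a 12-electrode
  calibration montage, 4 trials/block, 199 permutations — calibration of a
  permutation scheme depends on exchangeability, not on spatial coverage.
* `null_calibration_anova()`: 200 balanced null tables (subject random
  intercept sd 0.5 + unit noise) in the 2 × 2 × 3 design; Session GG-p at
  α = .05.
* `dprime_recovery()`: 1000 replicate 50-trial logs at $d' = 1$.

`scripts/acceptance.R` runs exactly these and writes the resulting numbers
as JSON.

## Numerical choices and degenerate inputs

* SVD through the conditions × conditions cross-product; eigenvalues
  clamped at 0; singular vectors for numerically zero singular values are
  zero-filled and the fit flagged `degenerate` when all covariance
  vanishes.
* Permutation p can never be 0 by the $(b+1)/(n+1)$ convention.
* A trial sample exactly at ±70 µV is retained ("exceeding" is strict).
* Peak ties break to the earliest sample; boundary peaks are flagged.
* Zero-variance paired differences and zero-variance correlation inputs
  return explicit degenerate records instead of infinite statistics.
* All seeds derive deterministically from one master seed
  (`derive_seeds()`), stay below $2^{31}$, and are stamped into every
  output.

## Known limitations

Sign-flip (not Procrustes) bootstrap alignment beyond LV1; balanced
equal-n designs only; no ocular regression/ICA (threshold rejection only,
as in the emulated protocol); Gaussian component kernels; noise white in
time; the generator's variability regime is favorable, as discussed above.
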