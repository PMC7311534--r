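---
title: "Methods: dictionary matching for liver DCE-MRI perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary matching for liver DCE-MRI perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcedict)
```

## The model

The liver receives blood from the hepatic artery and the portal vein, so a
single-input kinetic model misattributes enhancement. `dcedict` uses the
dual-input single-compartment model: tissue contrast concentration
$C_L(t)$ obeys

$$\frac{dC_L}{dt} = k_{1a}\,C_A(t-\tau_a) + k_{1p}\,C_P(t-\tau_p) - k_2\,C_L(t),$$

with arterial and portal plasma input functions $C_A$, $C_P$, influx rates
$k_{1a}, k_{1p}$ (1/s), efflux rate $k_2$ (1/s) and fixed vascular delays
$\tau_a, \tau_p$ (s). The physiological reparameterisation is
$AF = k_{1a}/(k_{1a}+k_{1p})$ (arterial fraction, 0–1),
$DV = (k_{1a}+k_{1p})/k_2$ (distribution volume, 0–1) and $MTT = 1/k_2$
(mean transit time, s). Assumptions inherited from the model: a single
well-mixed extracellular compartment (gadolinium chelates do not enter
cells), fast water exchange, and input functions measured without partial
volume error.

Two properties of the solution

$$C_L(t) = \int_0^t \left[k_{1a} C_A(s-\tau_a) + k_{1p} C_P(s-\tau_p)\right]
 e^{-k_2 (t-s)}\,ds$$

carry the whole method: it is *linear in DV* at fixed (AF, MTT), and it
superposes over the two inputs. Linearity in DV is what allows the
dictionary to fix $DV = 1$ and recover it afterwards from a norm ratio;
superposition is what makes dictionary construction cheap (two base
responses per MTT, combined per AF).

## Numerical solution of the forward model

The solution method is an exact exponential-convolution integrator: the
sampled inputs are treated as piecewise linear, and on each frame interval
the ODE has a closed form (computed with `expm1` for small $k_2\,\Delta t$
accuracy). This is unconditionally stable, exact for piecewise-linear
inputs, and reduces to a first-order linear recursion that vectorises over
frames. The test suite checks it against an independent forward-Euler
integration at 1 ms steps on random parameter draws (relative error
below $10^{-4}$ at every frame, normalised by the curve maximum — early
frames are identically zero, so pointwise relative error is undefined
there).

Delays are applied by evaluating the interpolated inputs at $t - \tau$;
input functions are defined as zero before time zero (causal bolus), and a
delay that would require input values beyond the recorded curve raises a
domain error rather than extrapolating. Both delays default to 0 s: the
fixed literature values such a study would use are not recoverable here, so
zero is the neutral, configurable choice.

## Signal model

Concentration and scanner signal are linked by the standard spoiled
gradient echo (SPGR) steady-state equation

$$S = M_0 \sin\alpha \,\frac{1-E}{1-E\cos\alpha},\qquad
E = \exp\!\left[-TR\,(1/T_{10} + r_1 C)\right],$$

with TR 4.8 ms, flip angle $\alpha = 15^\circ$, relaxivity
$r_1 = 6.3\ \mathrm{s^{-1}mM^{-1}}$ and pre-contrast $T_{10}$ presets of
800 ms (healthy liver), 950 ms (cirrhotic liver) and 1800 ms (blood), all
3 T literature values. $T_2^*$ decay is neglected: at TE = 0.5 ms it is a
sub-percent effect. $M_0$ is estimated from the mean of the first five
pre-contrast frames. The inversion solves for $E$ per frame; a frame whose
fractional signal reaches the saturation asymptote $S \ge M_0\sin\alpha$
(no finite concentration can produce it — only possible under noise) is
flagged `NA` rather than clamped, and downstream stages treat any flagged
frame as invalidating that curve. Negative concentrations from noise are
allowed; they are information, not errors.

## The dictionary

* **Grid.** AF 0–1 in steps of 0.01 (101 values); MTT 0.0001 s plus the
  integers 1–100 s (101 values); $DV$ fixed to 1. The 0.0001 s point is
  kept verbatim even though it is physiologically degenerate — MTT = 0 is
  excluded by the model, and this is the conventional near-zero bound. The
  grid is 10,201 entries of 100 frames: small enough that the full matrix
  product is the fastest search.
* **Normalisation.** Each column is divided by its own L2 norm; the
  pre-normalisation norms are stored so DV can be recovered as
  $\lVert C_L\rVert_2 / \lVert C_{LD}\rVert_2$ against the *un-normalised*
  best entry. With that reading the recovery is exact (to floating point)
  for noiseless on-grid curves, which fixes the interpretation of the norm
  ratio's denominator.
* **Matching.** Probes are L2-normalised, scored by inner product against
  all columns, and the arg-max wins; exact ties break to the lowest column
  index (AF-major, MTT-minor order), a deterministic documented rule.
  Zero-norm probes (no enhancement) are *flagged*, not errors — one flat
  voxel must not abort a whole-volume map. Matching runs in probe batches
  bounded by a configurable element budget; results are independent of the
  batch size. Estimated DV may exceed 1 under noise; it is reported raw,
  with optional clipping and an optional inner-product validity threshold
  (default: keep everything).
* **Compression.** A seeded Gaussian-sketch randomized SVD provides a
  low-rank representation; the default rank is the smallest retaining
  99.999 % of singular-value energy. At full rank compressed matching
  reproduces the uncompressed arg-max exactly; the truncated default is
  checked in tests to agree on ≥ 99 % of random probes.

Quantization is the dictionary's characteristic error: a noiseless probe
whose true AF or MTT lies off the grid lands on a neighbouring grid value.
The step-size study (`run_stepsize_study()`) makes this visible by
matching one ideal curve (AF 0.3, MTT 15 s) against dictionaries with AF
steps {0.01, 0.02, 0.04, 0.1, 0.2, 0.5} and MTT steps {1, 2, 4, 11, 25,
50}. Note that quantization error is *not* monotone in step size whenever
the truth sits on a coarser grid but off a finer one (AF 0.3 is on the
0.1 grid but off the 0.04 grid), so "error grows with step size" holds
only as a trend, exactly as the implementation reports it.

## The curve-fitting baseline

`fit_curve()` minimises the residual sum of squares over (AF, DV, MTT)
within bounds 0–1, 0–1, 0.0001–100, from the fixed initial guess
(0.2, 0.2, 10). The backend is Levenberg–Marquardt with box bounds
(`minpack.lm::nls.lm`) with finite-difference Jacobians. The reference
configuration's trust-region tolerances do not map one-to-one onto any
other optimiser, so the closest semantic equivalents are used and
documented: step tolerance 1e-2 → `ptol` (relative parameter change),
function tolerance 1e-3 → `ftol` (relative cost reduction), gradient
tolerance 1e-1 → `gtol` (first-order optimality; the phrase "minimum
gradient change" is ambiguous and is read as an optimality tolerance).
Fitting the physiological triplet directly (rather than the rate
constants) keeps the bounds and the initial guess meaningful. Failure to
converge returns the best iterate with `converged = FALSE` rather than an
error.

## Synthetic input functions

The generator stands in for subject-measured, temporally smoothed input
curves, which are not distributable. It emulates their defining features:
a gamma-variate arterial first pass (default whole-blood peak 5 mM,
time-to-peak 8 s, bolus arrival 15 s — after the five baseline frames),
a dispersed recirculation shoulder and a slow washout tail; the portal
curve is the arterial curve passed through an exponential transit-time
dispersion kernel (mean 14 s) plus a 6 s delay, giving the
characteristically later, broader, lower portal peak. Curves are built on
a 0.25 s internal grid, resampled to the acquisition grid (default 100
frames at 2.4 s), smoothed with a centred 3-frame moving average (the
smoothing method applied to measured curves is not specified anywhere, so
a moving average is the simplest defensible choice), forced causal (zero
before arrival) and corrected to plasma concentration with hematocrit
0.4. The defaults are held fixed as the package's study conditions.

What the generator does **not** emulate: partial-volume and inflow
artefacts in vessel ROIs, breathing-induced baseline drift, bolus-shape
variability between subjects, and $T_2^*$ effects at the arterial peak.
Passing simulation tests therefore demonstrates estimator correctness
under the model, not robustness to every in vivo confounder — the same
caveat any self-consistent simulation study carries.

## Monte Carlo design

Noise is added in *signal* space: the noiseless tissue curve is converted
to SPGR signal, white Gaussian noise with power
$P_{noise} = P_{signal}\,10^{-SNR/10}$ (with
$P_{signal} = \tfrac1t\sum_n s(n)^2$) is added per frame, and the noisy
signal is converted back to concentration before estimation — so the
noise passes through the nonlinear conversion exactly as scanner noise
would. The noise is real Gaussian on the magnitude signal (the classical
`awgn` convention), a deliberate simplification of Rician MRI noise.

Sweeps vary one property (AF 0.2–0.7, DV 0.2–0.7, or MTT 11–71 s in
integer steps) from the healthy-liver base (0.30, 0.30, 30 s) across SNR
10–100 dB. Percent error is $|est - true|/true \times 100$, averaged over
realisations; realisations whose conversion produces a flagged frame (a
low-SNR phenomenon) are excluded and counted. The exact set of sweep
values behind the reference study's "252 permutations" is not stated
anywhere, so the defaults cover the stated ranges at the dictionary's own
resolution. One seed drives the whole pipeline; identical seeds give
bit-identical error tables. The packaged tests and the acceptance script
run 25 realisations per cell (the full study convention is 100, available
via `n_realizations`); with 61 MTT values × 5 SNR levels this keeps the
dictionary sweep around 7,600 matches and the fitting sweeps around 1,300
fits — sizes chosen so the whole validation runs in well under a minute
each.

## Voxel mapping, phantom and statistics

`map_volume()` converts each masked voxel's signal to concentration and
estimates per voxel, flagging rather than interpolating: non-positive
baselines, non-invertible frames, and curves with L2 norm below a minimal
enhancement threshold (1e-6 mM — a flat signal converts to numerical dust
at the 1e-16 level, which must not be matched) all yield `NA` map entries
and a `FALSE` validity mask. Output maps carry the input volume's geometry
attributes untouched, and batched matching is bit-identical to
voxel-at-a-time matching.

The digital phantom generates a labelled volume (parenchyma, a
hypervascular and a hypovascular lesion, arterial and portal vessel tubes
carrying the input curves directly) with ground-truth maps returned
alongside; tissue parameters sit on the default dictionary grid so
noiseless recovery is exact, and re-simulating from the returned truth
reproduces the noiseless volume bit-exactly. Default size 32 × 32 × 8
voxels (tests use 10 × 10 × 3), deliberately toy-sized geometry — it
validates plumbing and statistics, not anatomy.

`roi_compare()` reports per-ROI mean ± SD per method and a two-tailed
two-sample t-test per property. The reference analysis says only
"two-sample", so Student's equal-variance test is the default with Welch
as an option, and the methods' voxel sets are treated as independent
samples (whether the original comparison paired voxels is unknowable from
the text). Zero-variance degeneracies — e.g. identical uniform maps —
are resolved by convention: equal means give $t = 0, p = 1$, unequal
means with zero variance give $p = 0$.

## Known limitations

* Estimates are quantized to the dictionary grid; off-grid truth incurs up
  to half-step bias that noise averaging cannot remove.
* A dictionary entry from wrong parameters can be nearly collinear with
  the truth's curve; the inner product flags poor absolute fits but not
  plausible-but-wrong ones.
* The awgn noise model is Gaussian, not Rician; at very low SNR the
  magnitude-signal statistics diverge from real scanners.
* The same model generates and fits the simulated data, so simulation
  accuracy does not bound model misspecification error in vivo (vessels
  and metastatic lesions notoriously violate the single-compartment
  assumption).
* Image reconstruction and motion correction are upstream of this package
  and out of scope; inputs are assumed registered.
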