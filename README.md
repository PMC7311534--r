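# dcedict

Dictionary matching for liver perfusion quantification from DCE-MRI.

`dcedict` estimates the three perfusion properties of the dual-input
single-compartment liver model — arterial fraction (AF), distribution volume
(DV) and mean transit time (MTT) — from dynamic contrast-enhanced MRI
enhancement curves, for researchers doing voxel-wise pharmacokinetic mapping
of the liver. Its core estimator is an exhaustive dictionary search in the
style of MR fingerprinting; a bounded nonlinear least-squares curve-fitting
baseline, Monte Carlo noise studies, voxel-wise mapping and a digital
phantom round out the toolbox.

## The model and the estimator

Tissue contrast concentration follows the dual-input single-compartment
model

```
dC_L(t)/dt = k1a C_A(t - tau_a) + k1p C_P(t - tau_p) - k2 C_L(t)
```

where `C_A` and `C_P` are the arterial and portal-venous plasma input
functions (whole-blood curves divided by `1 - hematocrit`, default 0.4).
The rate constants are reparameterised as

```
AF = k1a / (k1a + k1p)    DV = (k1a + k1p) / k2    MTT = 1 / k2
```

**Dictionary matching.** Every (AF, MTT) pair on a grid (AF 0–1 in steps of
0.01; MTT 0.0001 plus the integers 1–100 s) is run through the model at
DV = 1; each curve is divided by its own L2 norm and stored as a column of
the `t x n` dictionary. A measured curve, also L2-normalised, is scored
against all columns by inner product; the arg-max column gives AF and MTT,
and because the model is exactly linear in DV,

```
DV = ||C_L||_2 / ||C_LD||_2
```

with `C_LD` the un-normalised best-match model curve. The search is
exhaustive — every entry is considered — so there is no initial guess and no
local-minimum problem, and the inner product (0–1 for enhancement curves)
is a per-voxel goodness-of-match score. A seeded randomized-SVD compression
of the dictionary is available for memory-constrained matching.

**Curve fitting baseline.** Bounded nonlinear least squares on (AF, DV,
MTT) with bounds 0–1, 0–1, 0.0001–100, initial estimates (0.2, 0.2, 10) and
step/function/gradient tolerances 1e-2 / 1e-3 / 1e-1.

Signal and concentration are interconverted through the spoiled gradient
echo equation with literature constants (3 T: liver T1 800 ms, blood
1800 ms, relaxivity 6.3 /s/mM, flip 15°), with the scanner scale estimated
from the pre-contrast baseline frames.

## Worked example

```r
library(dcedict)

inputs <- synthesize_inputs(default_time_grid())   # synthetic AIF / PVIF
dict   <- build_dictionary(inputs)                 # 100 x 10201 dictionary

truth  <- perfusion_params(af = 0.35, dv = 0.45, mtt = 25)
curve  <- forward_model(truth, inputs)
signal <- spgr_signal(curve, acquisition_params(), m0 = 1000)
noisy  <- add_awgn(signal, snr_db = 60, seed = 42)
meas   <- concentration_from_signal(noisy, acquisition_params())

match_dictionary(meas, dict)
#> # A tibble: 1 × 7
#>   id       af   mtt    dv inner_product column_index valid
#>   <chr> <dbl> <dbl> <dbl>         <dbl>        <int> <lgl>
#> 1 1      0.35    25 0.449         1.000         3561 TRUE

tidy(fit_curve(meas, inputs))
#> # A tibble: 3 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 af       0.351
#> 2 dv       0.449
#> 3 mtt     25.1
```

At 60 dB both estimators recover the truth: the dictionary returns the
exact grid values AF = 0.35 and MTT = 25 s with DV = 0.449 from the norm
ratio (truth 0.45), and the fit lands within a fraction of a percent. The
inner product of essentially 1 says the matched model curve explains the
measurement.

Voxel-wise workflow: `generate_phantom()` (or `read_volume()` on your own
NIfTI data) → `map_volume()` → `difference_map()` / `roi_compare()` /
`autoplot()`. A command-line wrapper over the same functions is installed
at `inst/cli/dcedict.R` with subcommands `build-dict`, `match`, `fit`,
`mc-study`, `stepsize-study`, `phantom`, `map` and `roi-compare`.

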