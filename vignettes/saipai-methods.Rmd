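---
title: "Methods: instantaneous autonomic indices from heartbeat point processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instantaneous autonomic indices from heartbeat point processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Heartbeats are treated as an inhomogeneous point process.  Given ordered
event times $u_1 < \dots < u_K$ and heart periods $HP_k = u_k - u_{k-1}$,
the waiting time from the last beat follows an inverse-Gaussian density

$$f(t \mid \mathcal H_t, \xi(t)) =
  \sqrt{\frac{\xi_0(t)}{2\pi (t-u_k)^3}}
  \exp\left\{ -\tfrac12\,
  \frac{\xi_0(t)\,[\,t-u_k-\mu_{HP}(t)\,]^2}{\mu_{HP}(t)^2\,(t-u_k)}
  \right\},$$

whose history-dependent mean is a linear combination of orthonormal
discrete Laguerre filter outputs of the past heart periods,

$$\mu_{HP}(t) = g_0(t) + \sum_{j=0}^{P_p} g_1(j,t)\, l_j(t), \qquad
  l_j(t) = \sum_{n \ge 0} \phi_j(n)\, HP_{\tilde N(t) - n},$$

with $\tilde N(t)$ the index of the last event strictly before $t$.  The
Laguerre basis ($\alpha = 0.2$, orders $0..9$) compresses long
autoregressive memory into ten coefficients; orders $0..P_s$ ($P_s = 2$)
form the sympathetic block, orders $P_s+1..P_p$ ($P_p = 9$) the
parasympathetic block.  The time-resolved parameter vector
$\xi(t) = \{g_0, g_1, \xi_0\}$ maximizes the local log-likelihood of the
intervals observed in a sliding window $[t-W, t]$ ($W = 70$ s), plus a
right-censoring term $\log(1-F)$ for the interval still open at $t$,
and is revised every 5 ms by damped Newton--Raphson ascent warm-started
from the previous grid point, with $\xi_0 > 0$ maintained through a log
reparameterization.

The sympathetic and parasympathetic activity indices are linear
"disentangling" combinations of the fitted coefficients,

$$SAI = \psi_{S0} + \sum_j \psi_{Sj}\, g_1(j) \quad (j \in \text{symp. block}),
\qquad
PAI = \psi_{P0} + \sum_j \psi_{Pj}\, g_1(j) \quad (j \in \text{parasymp. block}),$$

each divided by $\mu_{HP}^2$ and floored at zero, so both are
non-negative instantaneous series in arbitrary units.

## Numerical and design choices

**Laguerre lag convention.**  The printed closed form of the discrete
Laguerre function circulating in the literature is typographically
unstable (mixed symbols, an exponent that breaks orthonormality); we
implement the standard orthonormal form
$\phi_j(n) = \alpha^{(n-j)/2}(1-\alpha)^{1/2}
\sum_{i=0}^{j}(-1)^i\binom{n}{i}\binom{j}{i}\alpha^{j-i}(1-\alpha)^{i}$,
verified by its Gram matrix.  The filter assigns weight $\phi_j(0)$ to
the most recent *completed* interval.  This matters: if lags start at
$n = 1$, the basis restricted to the used lags has Gram
$I - vv^{\top}$ with $v_j = \phi_j(0)$ and $\|v\|^2 = 1-\alpha^{J+1}$,
an almost exact null direction (smallest design singular value
$\approx \alpha^{(J+1)/2} \approx 4\times10^{-4}$ at $\alpha=0.2$,
$J=9$) that makes $g_1$ structurally unidentifiable.  Starting at lag 0
over completed intervals preserves orthonormality and identifiability
while keeping the filter strictly causal.

**Censoring and the optimizer.**  The interval sum has analytic gradient
and Hessian; the censoring term contributes its value and gradient (the
latter by central differences in $(\mu_c, \log\xi_0)$, chained through
the design row) but is omitted from the Hessian.  Backtracking line
search preserves the ascent property regardless, and the stationary
point is unchanged.  Newton steps smaller than the floating-point
resolution of the objective are taken without a line search — near the
optimum a step's true gain ($\sim\!\|\nabla\ell\|^2/2\lambda_{max}$)
falls below the representable resolution of a log-likelihood of order
$10^3$ long before the gradient tolerance ($10^{-6}$) is met.

**Dispersion correction.**  The windowed maximum-likelihood estimate of
$\xi_0$ is biased upward by roughly $n/(n-p)$ ($n \approx 80$ beats per
window, $p = 11$ mean parameters), exactly as the ML residual variance
in linear regression; reported states carry the $(n-p)/n$-corrected
value, which also removes a systematic shift in the time-rescaling
goodness-of-fit statistic.

**Reducing the trajectory to one estimate.**  A 70-s window cannot by
itself separate the baseline $g_0$ from the DC response of the Laguerre
blocks (within a window, a slow level shift and the intercept are nearly
collinear), so the plain arithmetic mean of local states wanders along
that ridge.  `coef()` therefore returns the information-weighted time
average $\bar\theta = (\sum_t H_t)^{-1}\sum_t H_t\theta_t$ with $H_t$
the local observed information, which pools the overlapping windows into
(effectively) the full-recording likelihood solution.  Parameter
recovery in the test suite uses this estimator.

**Goodness of fit.**  The time-rescaling theorem maps each interval to
$z_k = \int_{u_{k-1}}^{u_k}\lambda(t)\,dt$; under a correct model the
$1-e^{-z_k}$ are i.i.d. uniform and their KS distance is compared with
the 95% band $1.36/\sqrt K$.  The integral is computed exactly for
piecewise-constant parameters (cumulative-hazard increments per
revision segment), not by quadrature on the hazard, which at coarse
revision steps otherwise inflates the statistic by $\sim 0.02$.

**$\psi$ weights.**  Numeric disentangling weights are not published in
a transcribable form and the public tool is unavailable offline, so the
shipped defaults are *synthetic surrogate weights* produced by
`calibrate_psi()`: the package fits its own model to simulated
recordings at baseline, with low-frequency (LF, 0.1 Hz) modulation
doubled, and with high-frequency (HF, 0.25 Hz) modulation halved, and
uses the displacement of the time-averaged block coefficients — the LF
displacement orthogonalized against the HF displacement for
$\psi_S$, and vice versa (negated) for $\psi_P$.  The orthogonalization
is what makes the indices *disentangling*: without it, doubling LF
drive moves the parasympathetic block enough to mask a concurrent vagal
withdrawal.  Offsets of 0.5 a.u. keep baseline indices away from the
zero floor.  The `provenance` field records the origin; users with
externally validated weights should supply them.

**From indices to fMRI.**  The index series is synchronized to the
volume grid (TR = 0.72 s, 1200 volumes by default) by linear
interpolation between the two bracketing 5-ms samples
(nearest-neighbour available); non-converged gaps shorter than 2 s are
bridged, longer ones become missing volumes dropped listwise from the
GLM.  The regressor is convolved with a canonical double-gamma
hemodynamic response (peak 6 s, undershoot 16 s, dispersions 1 s, ratio
1/6, 32-s support, peak-normalized; the gamma shapes are
$delay/dispersion + 1$ so each lobe's mode falls exactly at its stated
delay) and standardized to zero mean, unit variance, so first-level
effects are comparable across subjects.

**Three-level GLM.**  Level 1 is voxelwise OLS on
[intercept, linear drift, regressor] with a Gaussianized $t$; both
signed contrasts are available.  Level 2 combines a subject's two runs
by inverse-variance fixed effects.  Level 3 is a one-sample
mixed-effects combination with a DerSimonian--Laird moment estimate of
between-subject variance floored at zero (a simplified FLAME).  Cluster
inference thresholds the group $Z$ at 2.3 and compares 26-connected
cluster extents with a sign-flip permutation null of the maximal
extent — exact under a symmetric null and free of smoothness
estimation; parity with parametric Gaussian-random-field correction is
explicitly not a goal.  The GLM does not pre-whiten; with AR(1) noise
(coefficient 0.3 in the generator) run-level variances are mildly
understated, which the permutation-based group inference absorbs but
run-level $Z$ values inherit.  This is a known limitation.

## What the synthetic data do and do not emulate

Two generators are deliberately kept distinct so validation is not
circular.  `simulate_from_model()` samples the fitted model class
itself (each interval inverse-Gaussian around its Laguerre-expanded
mean, self-starting so every simulated interval follows exactly the
model the fitter scores) and backs the parameter-recovery and
time-rescaling checks.  `simulate_ipfm()` is an integral
pulse-frequency-modulation generator — events fire when the integral of
$(1+m(t))/T_0$ crosses unity, with $m(t)$ a sum of an LF (0.1 Hz) and an
HF (0.25 Hz) sinusoid, epoch-scalable, plus small interval jitter — a
standard surrogate for autonomically modulated heartbeats from outside
the model class.  Scenario presets put both to work: 900-s recordings at
$T_0 = 0.9$ s with amplitudes 0.1; `sympathetic_activation` doubles LF
in the 300–600 s epoch, `vagal_withdrawal` halves HF there, and
`arousal` does both, the classic sympatho-excitatory pattern, which
lets one planted BOLD signal appear as a positive SAI and a negative
PAI association simultaneously in the end-to-end test.

Synthetic BOLD volumes are a scaled, HRF-convolved epoch regressor on a
planted active region plus AR(1) noise on a $20\times20\times10$ toy
grid with the study's temporal structure (1200 volumes, TR 0.72 s).
The planted effect (0.35 noise-SD units per unit standardized
regressor) is chosen so that a six-subject, two-run cohort detects the
coupling comfortably; it is a preset of the synthetic study, not an
empirical claim.  None of this reproduces real PPG morphology,
respiration–cardiac coupling, motion artifacts, or the spatial
covariance of real BOLD, so passing tests demonstrate the correctness
and calibration of the estimator chain — not performance on Human
Connectome Project data, whose preprocessing (ICA-FIX etc.) is outside
this package's scope.

## Benchmark problem sizes

The validation studies use sizes chosen to pin each quantity with
adequate statistical margin: parameter recovery uses 20 000 beats (the
relative error of $\hat g_0$ scales as $\approx c/\sqrt{n}$, with the
constant set by the collinearity between the intercept and the Laguerre
DC gains under the benchmark dynamics); goodness of fit uses 20
replicates of 700 beats; index responsiveness uses ten 900-s scenario
pairs with a window-length guard band after each epoch transition
(the estimator carries $W = 70$ s of memory); null calibration uses
1000 white-noise voxels and 200 null group simulations with 199
sign-flip permutations; the end-to-end run uses six subjects, two runs
each, at full 1200-volume length.  The benchmark generative parameters
(mean HP 0.85 s, HP CV $\approx 3\%$, mixed slow and oscillatory
dynamics with zero net DC gain, $\xi_0 = 1000$) describe unremarkable
resting heart-rate variability while keeping every parameter direction
identifiable — with zero net DC gain the baseline equals the mean heart
period, the regime in which intercept and autoregressive mass are
least confounded.

## Known limitations

* $\psi$ defaults are simulator-calibrated surrogates; absolute SAI/PAI
  values are not physiologically calibrated (no MSNA or blockade
  anchoring), only their within-recording dynamics are meaningful.
* No pre-whitening at level 1 (see above).
* The local estimator needs $\ge J+1$ completed intervals of history
  and a full window before its first state; the first $W$ seconds of a
  recording yield no index samples.
* Cluster inference assumes a symmetric null across subjects
  (sign-flip exchangeability); strongly skewed subject effects would
  need a different null.
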