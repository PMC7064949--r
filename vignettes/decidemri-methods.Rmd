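---
title: "Methods: model-driven registration and Bayesian fitting of placental diffusion-relaxation MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-driven registration and Bayesian fitting of placental diffusion-relaxation MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decidemri)
```

## The signal model

Placental DW-MRI acquired at multiple diffusion weightings $b$ (s mm$^{-2}$)
and echo times $TE$ (ms) carries joint information on perfusion and tissue
relaxation.  The three-compartment model implemented here is

$$S(b, TE) = S_0\Big(f\,e^{-b d^* - TE\,r_{2fb}} +
  (1-f)\big[v\,e^{-b d - TE\,r_{2mb}} + (1-v)\,e^{-b d - TE\,r_{2t}}\big]\Big)$$

with five free parameters: the rapid-perfusing (fetal blood) volume fraction
$f$, tissue diffusivity $d$ (mm$^2$ s$^{-1}$), pseudo-diffusivity $d^*$
(mm$^2$ s$^{-1}$), fetal-blood relaxation $r_{2fb} = 1/T_{2fb}$ (ms$^{-1}$),
and the slow-perfusing (maternal blood) fraction $v$ of the non-$f$ space.
The maternal-blood and tissue rates are fixed at literature values
$r_{2mb} = (240\ \mathrm{ms})^{-1}$ and $r_{2t} = (46\ \mathrm{ms})^{-1}$
(overridable via `decide_constants()`).

Two printed variants of the model exist in the source literature: one
attenuates only the maternal-blood compartment by $e^{-bd}$, the other (the
amplitude-linearized form) attenuates both non-fetal compartments.  This
package follows the linearized form throughout, because only that form makes
the amplitude reparameterization
$\lambda_1 = S_0 f$, $\lambda_2 = S_0(1-f)v$, $\lambda_3 = S_0(1-f)(1-v)$
an exact algebraic identity.  For the same reason the inverse map uses
$S_0 = \lambda_1+\lambda_2+\lambda_3$ (the published reciprocal form is a
typographic slip; the implemented inverse is the unique one for which
`lambda_from_physio()` and `physio_from_lambda()` are exact inverses, which
the test suite asserts to machine precision).

Units are fixed package-wide: $b$ in s mm$^{-2}$, $TE$ and $T_2$ in ms,
diffusivities in mm$^2$ s$^{-1}$, rates in ms$^{-1}$.  The product $b d$ is
dimensionless with these conventions and no further scaling.

## The default protocol

`build_protocol("decide_default")` reproduces the clinical acquisition: ten
echo times (81–300 ms) at $b = 0$, seven $b$-values (0–600 s mm$^{-2}$) at
$TE = 96$ ms, and $b \in \{50, 200\}$ at seven echo times 81–240 ms.  The
subsets overlap in three pairs; `dedup = TRUE` yields the 28 unique pairs.
The clinical series has 41 volumes, which cannot be reconstructed from the
printed subsets alone; extra repeated volumes are therefore user-declared
(`repeats =`), since repeated acquisitions are real data that matter for
registration.

## Linearized fitting

With $d^*$ and $r_{2fb}$ fixed at 0.073 mm$^2$ s$^{-1}$ and
$(144.89\ \mathrm{ms})^{-1}$ (a printed "144.89 ms$^{-1}$" fails dimensional
analysis; it is implemented as a $T_2$ of 144.89 ms), the model is linear in
$(\lambda_1, \lambda_2, \lambda_3)$.  The published linearization leaves $d$
formally free; `lls_fit_volume()` resolves this with a 1-D
variable-projection grid search (default 15 log-spaced candidates on
$5\times10^{-4}$–$4\times10^{-3}$ mm$^2$ s$^{-1}$), keeping the candidate
with minimum residual.  Amplitudes are constrained nonnegative — at low SNR
unconstrained least squares produces negative $\lambda$, which breaks the
inversion to $(f, v)$.  With only three coefficients, nonnegative least
squares is solved *exactly* by enumerating the $2^3$ active sets (tests
verify the KKT conditions).  Degenerate voxels with
$\lambda_2 + \lambda_3 = 0$ get $v = 0.5$ and a QC flag rather than NaN.

## Constrained nonlinear fitting

`nls_fit_voxel()` minimizes the sum of squared residuals of the full model
with a Levenberg–Marquardt iteration and analytic Jacobian, run in
transformed coordinates: scaled logits for $f, d, d^*, v$ and
$T_{2fb}/500$, and $\log S_0$.  The published box constraints
($0<f<1$, $0<d<1$, $0<d^*<1$ mm$^2$ s$^{-1}$, $0<T_{2fb}<500$ ms, $0<v<1$)
therefore hold *by construction*, with no projection artifacts at the
bounds.  Five starts (the ROI-mean initializer plus four copies jittered by
25% in transformed space) guard against the pseudo-diffusion local minima
documented throughout the perfusion-MRI literature.  Estimates within
$10^{-4}$ of a bound (in logit fraction) are flagged at-bound and counted,
not censored.  Only cost-decreasing steps are accepted, so the reported
residual never exceeds the initializer's.

`nls_fit_volume()` optionally pre-smooths each volume with an isotropic
spatial Gaussian (SD in voxels; 1.0 reproduces the source-smoothing variant
of the original analysis) before fitting.

## Bayesian shrinkage prior

`bsp_fit_roi()` treats each ROI voxel's transformed parameters
$\theta_i = (\mathrm{logit}\,f, \log d, \log d^*, \log r_{2fb},
\mathrm{logit}\,v)$ as draws from a shared multivariate Gaussian
$N(\mu, \Sigma)$ and samples the joint posterior by
Metropolis-within-Gibbs:

* per-voxel componentwise Gaussian random-walk updates of $\theta_i$,
  vectorized across the ROI, against the amplitude- and noise-marginalized
  likelihood
  $\log p(S_i\mid\theta_i) = -\tfrac{N}{2}\log\big(S^TS - (S^Tg)^2/(g^Tg)\big)$
  where $g$ is the unit-amplitude model signal;
* a conjugate draw $\mu \mid \theta, \Sigma \sim N(\bar\theta, \Sigma/M)$
  (flat hyperprior);
* a conjugate draw
  $\Sigma \mid \theta, \mu \sim \mathrm{InvWishart}\big(M,\ \textstyle\sum_i
  (\theta_i-\mu)(\theta_i-\mu)^T\big)$ (Jeffreys-type hyperprior).  ROIs
  need $M \ge 7$ voxels for this conditional to be proper in 5 dimensions.

The closed-form likelihood deserves a note: integrating the Gaussian
likelihood over $S_0$ (flat) and the noise SD with the usual Jeffreys prior
gives exponent $-(N-1)/2$ and an extra $(g^Tg)^{-1/2}$ factor.  The
$-N/2$ closed form corresponds to the scale prior
$p(\sigma)\propto\sigma^{-2}$ and a flat amplitude prior in $g$-normalized
units.  The package implements the closed form exactly as published; the
test suite verifies it against a two-dimensional quadrature oracle with
precisely those priors (agreement to $10^{-2}$ in log-likelihood
differences, dominated by quadrature error).

**Sampler engineering.**  Proposal scales are per-voxel and per-parameter,
adapted every 50 iterations toward 30% acceptance during burn-in only and
frozen afterwards, preserving detailed balance.  Two departures from the
obvious defaults proved necessary and are deliberate:

1. *Likelihood tempering during early burn-in.*  Chains start at the
   voxelwise least-squares estimates, and at clinical SNR roughly a tenth
   of voxels start in deep degenerate modes (e.g. $f \to 1$ with a tiny
   $T_{2fb}$ mimicking the entire decay) that a random walk cannot leave.
   The likelihood weight is ramped $\beta: 0 \to 1$ quadratically over the
   first quarter of burn-in with $(\mu, \Sigma)$ frozen at their
   initialization moments (with a down-weighted likelihood the
   hyperparameter posterior is barely anchored and the ROI distribution
   would diffuse).  After the ramp, $\beta = 1$ exactly.
2. *Burn-in length.*  The default is `n_burn = 4000`, `n_keep = 3000`:
   with shorter burn-in the step adaptation freezes before the posterior
   reaches its equilibrium sharpness and post-burn-in acceptance decays to
   ~0.1; 4000 iterations hold it near 0.28 on the SNR-20 phantom battery.

Point estimates are the posterior median (equal in natural and transformed
units, both monotone maps) with mean and SD also reported.  Convergence is
monitored by split-$\hat R$ on the $\mu$ components; values above 1.1
trigger a warning, not an error.  RNG discipline: proposal noise is drawn
vectorized in voxel storage order, so results are bit-reproducible for a
fixed seed and mask, but permuting voxel order permutes the random stream —
exchange-invariance holds in distribution, not bit-exactly.

## Model-driven registration

Contrast varies strongly across a diffusion-relaxation series, so
registering every volume to one target fails for heavily attenuated
volumes.  `mdr_run()` instead alternates, three times by default:

1. linearized voxelwise fit of the current registered series;
2. synthesis of a noise-free model target for every protocol entry
   (uniformly for all volumes, including $b=0$);
3. pairwise FFD registration of each volume to its own target, with
   control-point spacing following the published multiresolution schedule
   (10, 5, 2.5 voxels across the three iterations).

Displacement fields are *composed* across iterations and the original
volumes are warped exactly once per iteration by the composed field, so
interpolation blur does not accumulate.  The internal registration backend
is a cubic tensor-product B-spline free-form deformation optimized by
backtracking gradient descent on the sum of squared differences plus a
bending-energy penalty on the control lattice; only cost-decreasing steps
are taken, so similarity never worsens.  SSD is an appropriate metric here
*because* moving and target share the model's intensity scale — that is the
core rationale of model-driven registration; local normalized correlation
was considered and rejected as redundant for matched-scale pairs.  Warping
uses trilinear interpolation (a deliberate simplification of the cubic
resampling used by optimized C++ FFD implementations: cubic prefiltering in
pure R would dominate runtime; the identity, round-trip and translation
contracts all hold at the stated tolerances on smooth images).  Any backend
honouring `(moving, target, config, spacing) -> list(field, warped)` can be
plugged in; a failing backend degrades to the identity field with a
warning.

Registration quality is tracked by the normalized RMS error between data
and fit; the normalizer is the mask-mean signal (the published work does
not define one; a range normalizer is available).

## Synthetic phantoms: the stated world

`make_phantom()` draws smooth random parameter fields (Gaussian-smoothed
white noise, smoothness 3 voxels by default) inside an ellipsoidal mask on
a $32\times32\times16$ grid at 2.5 mm isotropic spacing — a typical
in-plane placental DW-MRI resolution.  Default ranges are the cohort ROI
mean ± SD of the unregistered-data estimates, clipped to the fit bounds:
$f$ 0.225 (0.21), $d$ 0.0015 (0.0003), $d^*$ 0.0385 (0.018), $T_{2fb}$
181.1 (25.7) ms, $v$ 0.306 (0.051); $S_0 \in [90, 110]$ arbitrary units.
Noise is Gaussian by default — consistent with the marginalized-Gaussian
likelihood — with SD = (mask-mean $S_0$)/SNR and default SNR 20; Rician
noise is available for realism experiments, in which case simulator and
likelihood deliberately diverge (background magnitudes are then Rayleigh,
which the tests verify distributionally).

`simulate_motion()` draws per-volume smooth B-spline displacement fields
(control spacing 8 voxels, optional AR(1) temporal correlation for
breathing-like drift, default off) and rescales each axis so the
mask-average $|u|$ equals the published per-axis deformations 2.11, 2.54,
1.56 mm *exactly*.  Motion is applied to noiseless volumes before noise
injection: scanner noise arises after motion, so it must not be warped.

The motion-correction experiment in the acceptance battery uses a
$24\times24\times12$ phantom (scaled down from $32^3$ for desk runtime) at
SNR 50 on $S_0$.  The SNR choice is deliberate: after relaxation and
diffusion decay the shortest-TE volume then carries per-volume SNR ≈ 18
and the most attenuated ≈ 3 — the clinical range — whereas at the phantom
default SNR 20 every volume sits below SNR 7 and voxelwise estimator noise,
which registration cannot remove, dominates the motion signal being
measured.  Both arms of the comparison (motion-corrupted fit and post-MDR
fit) use identical 1.0-voxel source smoothing, mirroring the published
least-squares pipeline.

**What a green phantom test does not establish.**  The phantom has smooth
fields in an ellipsoid, no cotyledon structure, no through-slice
anisotropy, no fetal (rigid-organ) motion, no signal drift, and its motion
is drawn from the same B-spline family the registration optimizes over.
Green tests establish internal correctness and the direction of the
published effects, not clinical performance.

## Evaluation conventions

Relative error is $(p_{est} - p_{true})/p_{true}$ voxelwise, summarized as
the mask-mean absolute value; zero-truth voxels are excluded and counted.
ROI summaries use type-7 (linear-interpolation) percentiles — the published
work does not state a convention, so it is fixed and documented here.
Gestational age is encoded as decimal weeks (weeks + days/7).  Trend
analysis is ordinary least squares with Pearson correlation and a
two-sided t-test at $\alpha = 0.05$; constant responses are flagged
degenerate rather than producing NaN.

Conversion of $T_{2fb}$ to fetal oxygen saturation requires a calibration
$1/T_2 = A + K(1 - \mathrm{FO}_2)^2$ that the source work does not supply;
`fo2_from_t2fb()` therefore *requires* explicit constants, and
`fo2_calibration_default()` provides a clearly-labelled synthetic curve
($A = 0.004$, $K = 0.035$ ms$^{-1}$) for pipeline plumbing, not for
physiological inference.

## Numerical and degenerate-input choices

* Levenberg–Marquardt stops on relative SSE decrease $<10^{-14}$, damping
  growth beyond $10^{12}$, or 300 iterations; ties between starts resolve
  to the lowest SSE.
* A constant signal (no decay) is fitted without error and flagged via the
  at-bound counters; non-finite signals are flagged and skipped.
* The covariance Gibbs draw adds a $10^{-8}$ ridge when the scale matrix is
  numerically singular (all voxels identical) and flags it.
* NIfTI-1 I/O is implemented in-package (no NIfTI R package is available in
  the supported environment): float32 output, sform affine preserved,
  uint8/int16/int32/float32/float64 with scl slope/intercept honoured on
  input.

## Known limitations

* Pure-R registration is minutes-per-series at $32^3$; the published
  C++ FFD numerics are not reproduced, only the backend contract.
* The hierarchical prior is exchangeable across ROI voxels; no spatial
  smoothness prior, and no population-level pooling across subjects.
* $T_2^*$ effects, maternal-blood saturation gradients, and slice-to-volume
  motion are out of scope.
* The clinical cohort's correlation values cannot be reproduced without the
  cohort; the gestational-age machinery is validated on synthetic trends.
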