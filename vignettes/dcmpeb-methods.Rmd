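---
title: "Tracking fluctuating effective connectivity with hierarchical DCM for cross-spectral EEG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking fluctuating effective connectivity with hierarchical DCM for cross-spectral EEG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Resting-state EEG connectivity is not static: the directed (effective)
coupling between cortical sources drifts over seconds to minutes. This
package implements a three-level Bayesian hierarchy for characterizing those
fluctuations from windowed recordings:

1. **Window level.** A 1-min recording is cut into consecutive 1-s windows.
   Each window's multichannel data are summarized by complex cross-spectral
   density (CSD) matrices over 1–45 Hz, and a biophysical network model is
   inverted per window by variational Laplace, yielding a Gaussian posterior
   over that window's parameters — most importantly the log-gains of the
   extrinsic (between-source) connections.
2. **Within-subject level.** The window-wise log-gain trajectories are
   modelled by a Bayesian linear model over temporal basis functions — a
   constant, three orthonormal DCT components (orders 2–4) and a
   mono-exponential decay $e^{-n/16}$ — estimated by parametric empirical
   Bayes (PEB). Bayesian model reduction (BMR) scores all $2^4 = 16$
   combinations of the optional regressors; evidence is pooled over subjects
   by fixed-effects summation.
3. **Between-subject level.** The subjects' second-level posteriors enter a
   third, constant-only PEB ("group PEB"), greedy BMR pruning removes
   second-level parameters that do not pay their complexity cost, the
   surviving model set (an exhaustive sweep over the 8 least decisive
   parameters, 256 models) is Bayesian-model-averaged, and group-level
   trajectories with 90% credible bands are predicted as $X\hat\beta$.

The substantive question the hierarchy answers is a dissociation: which
components of the connectivity trajectories are *subject-specific* (they win
the within-subject model comparison but have zero group mean) and which are
*conserved over subjects* (e.g. a negative decay coefficient on forward
connections, i.e. a monotonically increasing coupling trajectory).

# The generative model

## Neural mass network

Each source contains three populations — spiny stellate cells, pyramidal
cells and inhibitory interneurons — with second-order synaptic dynamics per
channel: $\ddot v = H\kappa u - 2\kappa\dot v - \kappa^2 v$. Forward
extrinsic connections target the stellate population, backward connections
target the pyramidal and inhibitory populations, and lateral connections
target all three, following the standard cortical-hierarchy convention. The
firing-rate sigmoid is linearized at the operating point with a constant
slope, so the whole network is a linear state-space system whose Jacobian
depends on the parameters.

We use eight states per source (voltage/current pairs for the stellate,
pyramidal-excitatory, pyramidal-inhibitory and inhibitory channels). The
conventional layout carries a ninth state for the pyramidal output
$v_{pyr} = v_{pyr,e} - v_{pyr,i}$; because that state is an exact linear
combination of two others it contributes a structural zero eigenvalue, which
would defeat a strict stability check. Substituting it out leaves the
dynamics unchanged and makes "all eigenvalue real parts < 0" a meaningful
guard, enforced at every forward evaluation.

Constants (`erpConstants()`): $H_e = 4$ mV, $H_i = 32$ mV,
$\kappa_e = 1/8\,\mathrm{ms}^{-1}$, $\kappa_i = 1/16\,\mathrm{ms}^{-1}$,
intrinsic gains $(1, 4/5, 1/4, 1/4)\times 128$, extrinsic baseline gain 32
(scaled by $e^{g}$ with log-gain $g$, so connections are strictly
excitatory), intrinsic/extrinsic conduction delays 2/16 ms folded into the
Jacobian by a first-order Taylor correction (this keeps the resolvent small;
state augmentation would multiply the dimension by the delay horizon). The
sigmoid slope is 0.15: the slope is the one constant the convention does not
fix, and 0.15 places both built-in networks (default mode and saliency
presets) in a clearly stable regime — the prior-mean Jacobians have spectral
abscissa around $-10\,s^{-1}$, and all of 200 prior draws with log-gain sd
up to 0.5 remain stable. The innovations input amplitude (`uamp = 300`)
sets the units of the neuronal spectrum so that, at prior-mean
log-amplitudes, the neuronal component dominates the observation-noise
component by about an order of magnitude; it is a units convention, absorbed
by the spectral amplitude parameters.

## Spectral observation model

Innovations drive the stellate populations with spectra
$G_u(f) = e^{a_0}(1 + e^{a_1}/f)$ per source (white plus 1/f); channel noise
is $G_n(f) = (e^{b_0} + e^{b_1}/f)\,I$. With transfer function $T(f)$ from
innovations to pyramidal depolarization and a modes-by-sources gain matrix
$L$ (a stand-in for the lead field; head modelling is out of scope), the
predicted sensor CSD is

$$S_y(f) = L\,T(f)\,G_u(f)\,T(f)^{H}\,L^{T} + G_n(f),$$

which is Hermitian positive semidefinite by construction. $T(f)$ is computed
through one eigendecomposition of the delay-corrected Jacobian and reused
across frequencies; if the eigenbasis is near-defective (which happens for
exactly decoupled identical sources) the code falls back to direct
per-frequency resolvents.

## Priors

Window-level priors are zero-mean Gaussians: variance $1/16$ on every
extrinsic log-gain (so the baseline coupling is unscaled at the prior mean)
and $1/128$ on the spectral and noise log-amplitudes. The tighter amplitude
prior is deliberate and conventional: amplitude parameters trade off against
coupling gains in the spectral prediction, and constraining them is what
keeps the gains identifiable from 1-s windows.

# Data features

Observed features are per-window CSD matrices. For real recordings the path
is: EDF file → average-referenced channels × samples → projection onto the
leading spatial principal components of the whole-recording covariance
(default 8 modes, one shared projection so all windows live in one feature
space) → consecutive non-overlapping windows → multivariate autoregressive
(MAR, order 8) spectral estimation per window. CSD matrices are stacked into
real feature vectors (real diagonal, real and imaginary upper triangle, per
frequency); the stacking is bijective with Hermitian matrices.

The explained-variance diagnostic is
$100\,(1 - SS_{res}/SS_{tot})$ over the stacked real and imaginary parts.

# Inference

## Variational Laplace

The engine maximizes the Laplace free energy
$F = \text{accuracy} - \text{complexity}$ for $y = f(\theta) + e$,
$e \sim N(0, e^{-\lambda} I)$, by Gauss–Newton ascent with
Levenberg–Marquardt damping. A proposed step is evaluated
*self-consistently* (Jacobian recomputed at the candidate) and accepted only
if it does not decrease $F$ (up to a $10^{-8}$ relative slack for
floating-point ties); rejections restore the previous state and increase
damping. The noise log-precision $\lambda$ has a Gaussian hyperprior
$N(0, 1/16)$ and is updated by an inner Newton loop; data features are
scaled by the expected noise level (or a tenth of their RMS when unknown) so
this hyperprior is centred on the data scale. Convergence is declared after
four consecutive accepted steps with $|\Delta F| < 0.01$, with a cap of 64
iterations. Jacobians of the spectral forward map use central finite
differences with step $10^{-4}$ (the map is smooth and nearly quadratic in
the log-parameters at this scale). For linear-Gaussian problems one
undamped step lands exactly on the conjugate posterior and $F$ equals the
exact log evidence — the unit tests pin both to closed forms.

Unstable parameter proposals (any Jacobian eigenvalue with non-negative real
part) are treated as rejected steps; an instability at the prior mean is an
error.

## PEB, BMR and the model space

The second level is $\theta = (X \otimes I_B)\beta + \varepsilon$ with
random-effects precision $Q_0 + e^{-\gamma} Q_1$, a single log-precision
$\gamma$ per model: $Q_0 = 10^{-4} I$ is a floor, and $Q_1 = 16\,pC^{-1}$,
so at $\gamma = 0$ the random-effects covariance defaults to $pC/16$ — the
conventional between-unit default, placing the default random-effects sd
(about 0.06 on log-gains) at the scale where window-to-window and
between-subject effects actually live. For fixed $\gamma$, replacing each window's prior by the
empirical prior via the Gaussian BMR identity makes the conditional
posterior over $\beta$ available in closed form, so the scheme optimizes a
one-dimensional profile free energy over $\gamma$ (grid plus golden-section
refinement, range $[-16, 8]$) and applies a Laplace correction with the
numerical curvature. Two choices here are deliberately different from a
literal reading of their printed forms, both documented because the printed
forms are typographically ambiguous:

* the $\beta$ prior is $N(0,\, I_P \otimes pC)$ — one first-level prior
  width per regressor. Scaling this by $1/\lVert X\rVert_F^2$ (an
  alternative reading) makes the group-level prior precision grow linearly
  with the number of subjects, exactly cancelling the growth of the data
  precision, so group-level confidence could never increase with sample
  size; that reading is rejected on consistency grounds.
* the $\gamma$ hyperprior is $N(0, 4)$ rather than a sharper $N(0, 1/16)$.
  The hyperprior must cover the log-precisions of the random-effects scales
  the model is meant to estimate: window-to-window noise of a few
  hundredths (about $-0.5$ log units from the $pC/16$ default) up to
  between-subject dispersions of a few tenths (about $+2.3$ to $+3$ log
  units). A variance of $1/16$ makes the prior gradient $16|\gamma|$
  dominate the evidence gradient (roughly units × dimension / 2) whenever
  either is small, pinning the random-effects variance at its default
  regardless of the data; $N(0,4)$ spans the required ±3 log units. The
  window-level noise hyperprior keeps its conventional $1/16$ (features are
  scale-normalized so it is centred).

Reduced second-level models switch off regressor blocks by shrinking their
prior variance to $10^{-8}$; BMR yields each reduction's evidence and
posterior analytically, and replacing the prior by itself returns exactly
zero. Evidence is pooled over subjects by summation (fixed effects) and
mapped to model probabilities by softmax, exactly as in the second-level
model comparison it implements; no random-effects model selection is
offered.

## Greedy search and BMA

On the group PEB, single-parameter prunings are scored by BMR; the parameter
whose removal most improves (or least degrades, while still $\geq 0$) the
evidence is pruned, ties going to the lowest index (deterministic and
seed-free), until no single pruning helps. The final sweep enumerates all
on/off combinations of the `finalSweepSize` parameters with the smallest
absolute evidence contribution (default 8, hence 256 models), averages the
posterior over that set weighted by softmax evidence (between-model spread
included in the averaged covariance), and reports per-parameter retention
probabilities $Pp$. Parameters off in every averaged model have mean exactly
zero. Trajectory bands use $\pm 1.645$ posterior sd of $x_n^T\beta$.

A one-member "group" is a degenerate case worth knowing about: with a
proper prior and an estimated between-subject variance, the group mean of a
single subject is necessarily shrunk toward zero (the pattern, not the
amplitude, is preserved). This is inherent to empirical Bayes, not a defect.

# The synthetic-data generator

`groundTruth()`/`simulateGroup()` emulate the study conditions at the CSD
feature level: per-window extrinsic log-gains follow
$X\beta^{(s)}$ plus window noise (sd 0.05), where each subject's
coefficients are the group coefficients plus zero-mean deviations — DCT
dispersion 0.2, decay conserved over subjects by default (dispersion 0),
group decay coefficient $-0.4$ on forward connections and 0 elsewhere.
Defaults: 60 windows, 1–45 Hz grid, 160 Hz nominal sampling. Observation
noise is added to the stacked features at a tenth of their RMS — an
optimistic but defensible stand-in for MAR estimation error from 160-sample
windows. Unstable window draws are rejected and redrawn (at most 100
times). Subject $s$ uses seed $\text{master} + 10^4 s$; everything is
bit-reproducible from the master seed.

What the generator does **not** emulate: raw time series (generation is at
the feature level, so MAR estimation error enters only as the Gaussian
observation-noise stand-in), volume-conduction structure (the gain matrix
is random with unit-norm columns), artefacts, line noise, non-stationarity
within windows, or model mismatch (the data come from the same ERP model
that is fitted). Passing recovery tests therefore demonstrates the
*inferential machinery* — identifiability, calibration, and the
within-/between-subject dissociation — not robustness to the many ways real
EEG violates the model.

# Validation scale

The recovery suites run a deliberately scaled-down version of the full
study: a 2-source chain (one forward, one backward connection), 20 windows,
10 subjects, a 2–44 Hz grid in 2 Hz steps, 4 observation modes (channels
exceeding sources, as in real recordings) and 20 seeds per suite; window
inversions use independent fits (one refinement iteration). Three suites
probe calibration and power: a constant-only truth (the null model should
win or tie within 3 log units — the conventional "very strong evidence"
threshold), an injected $-0.5$ decay on the forward connection (a
decay-containing model should win by more than 3 log units, with group decay
$Pp > .95$ and a negative averaged coefficient), and subject-specific DCT
effects with zero group mean (DCT-containing models should win
within-subject while no group DCT coefficient reaches $Pp > .95$ —
the dissociation). At this scale a single subject-level inversion takes
well under 0.1 s, one full pipeline run about 13 s.

# Known limitations

* The window-level posterior information on coupling gains saturates with
  frequency resolution; what limits it is the partial collinearity between
  gains and spectral amplitudes, which the tighter amplitude priors
  mitigate but do not remove.
* The decay regressor is strongly collinear with the constant for short
  window counts (at 20 windows it spans only $1 \to 0.30$), which inflates
  the decay coefficient's posterior variance; at 60 windows the basis is
  much better conditioned.
* $\Sigma_i$ (feature noise) is a single isotropic estimated precision, a
  simplification of multi-component spectral noise models.
* Fixed-effects pooling assumes every subject expresses the same
  second-level model; outlier subjects can dominate the summed evidence.
* The first-level free energies entering `pebFit`'s hierarchical criterion
  are Laplace approximations of a nonlinear model; monotonicity of the
  outer loop is enforced by acceptance, not guaranteed by theory.
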