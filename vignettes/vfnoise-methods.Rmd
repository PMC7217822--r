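---
title: "Denoising visual fields and weighting progression analyses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising visual fields and weighting progression analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Standard automated perimetry measures retinal light sensitivity at 52
locations of the Humphrey 24-2 pattern (54 minus the two blind-spot
points). Each exam yields total-deviation (TD) values in dB relative to
the age-corrected norm; their mean, the mTD, is the whole-field damage
summary on which glaucoma progression is usually judged by ordinary
least-squares regression against time ("mTD trend analysis"), and
pointwise linear regression (PLR) plays the same role per location.
Perimetric measurements fluctuate substantially between visits even when
the conventional reliability indices (fixation losses, false positives,
false negatives) are good, and this noise is the dominant obstacle to
detecting progression early and to predicting future fields.

`vfnoise` implements a noise-reduction strategy built on a variational
autoencoder (VAE): the VAE is trained to reconstruct TD fields, and an
exam whose reconstruction disagrees with its measurement is treated as
noisy. The absolute difference between an exam's mTD and the mTD of its
reconstruction (mTD~VAE~) is used as an inverse weight in the trend
regression, and the per-point analogue weights pointwise regressions
inside a binomial whole-field test. The package also contains the full
evaluation framework for such methods (test-retest analysis, consistency
proportions, prediction errors, Kaplan-Meier time to detection) and a
synthetic longitudinal cohort generator, so the entire pipeline runs and
is testable without clinical data.

# The VAE

The encoder maps the 52 TD values (affinely scaled from [-38, 5] dB to
[0, 1]) through rectified-linear hidden layers of 38 and 26 units to the
mean and log-variance of an 8-dimensional diagonal Gaussian latent; the
decoder mirrors this (8 - 26 - 38 - 52) with a logistic output layer, so
reconstructions always lie inside the scaled range. Training maximises
the usual evidence lower bound: a reconstruction term plus the closed-form
Kullback-Leibler divergence of the latent posterior from the standard
normal prior, with one reparameterised latent sample per field per step,
optimised by Adam on minibatches. All randomness (initialisation,
shuffling, latent sampling) derives from one seed, so training runs are
bit-reproducible. At inference the decoder is applied to the posterior
mean, making reconstructions - and hence all downstream weights -
deterministic.

Design choices that the problem left open:

* **Reconstruction likelihood.** The default is binary cross-entropy
  between the scaled input and the logistic output. The natural
  alternative, a Gaussian likelihood (exposed as
  `recon_loss = "gaussian"` with scale `recon_sigma`), has a vanishing
  gradient where the logistic output saturates; in practice that
  under-reconstructs deep defects (fields near the -38 dB floor come
  back several dB too shallow), which is fatal here because deep defects
  are exactly where measurement artifacts are largest. Cross-entropy
  keeps useful gradients at both ends of the dynamic range and, viewed
  as a heteroscedastic likelihood, is tightest near the ends - matching
  the fact that the 0 dB "healthy" anchor and the measurement floor are
  the best-pinned parts of a field.
* **Scaling bounds.** Fixed constants (-38, 5) dB rather than data-driven
  extremes, so scaling does not depend on the dataset; out-of-range
  inputs are clipped with a warning.
* **Posterior mean at inference.** Decoding a latent sample is supported
  (`sample_latent = TRUE`) but not the default: regression weights must
  be reproducible.
* **kl_weight.** Default 1 (the plain variational objective). It is
  exposed because small latent spaces on low-dimensional tabular data can
  posterior-collapse under aggressive KL pressure.
* **Architecture.** Hidden sizes (38, 26) and an 8-dimensional latent by
  default, configurable via `hidden_dims`/`latent_dim`.

The gradients of the loss are hand-written reverse mode (there is no
neural-network training backend among the package's dependencies, and the
network is small enough that BLAS matrix products train it in seconds);
they are verified against central finite differences in the test suite.

# The weighting scheme

For a series of exams with mTD values $m_i$ at times $t_i$ and
reconstructions with means $\hat m_i$, the weighted trend analysis
minimises $\sum_i w_i (m_i - a - b t_i)^2$ with

$$ w_i = \frac{1}{\max(\varepsilon,\ |m_i - \hat m_i|)} , $$

i.e. exams whose reconstruction disagrees with their measurement are
downweighted. The pointwise variant applies the same reciprocal rule per
location, $w_{ij} = 1/\max(\varepsilon, |TD_{ij} - \widehat{TD}_{ij}|)$,
in the per-point regressions of the binomial PLR.

The floor $\varepsilon$ (default 0.5 dB) serves two purposes. It keeps
weights finite when a reconstruction is exact, and - more importantly -
it caps the dynamic range of the weights. The reconstruction error is an
*estimate* of the measurement error; with a very small floor (say
0.01 dB) two exams can receive weights differing by a factor of 100 on
estimation noise alone, and the fitted line then effectively
interpolates one or two exams. With the 0.5 dB floor, weight ratios stay
in the single digits: clean exams share the capped weight and clearly
artifact-laden exams (reconstruction differences of 1-3 dB) are
downweighted several-fold, which is the intended behaviour.

The significance rule for the weighted or unweighted mTD trend is the
conventional one: negative slope with two-sided $p < 0.05$
(configurable).

# Binomial PLR

Under the null hypothesis that no location deteriorates, the one-sided
deterioration p-values of the 52 pointwise regressions are uniform, so
the number below a cutoff $c$ is Binomial(52, $c$). For each cutoff in
(0.025, 0.05, 0.075, 0.1) the exact upper-tail probability
$P(X \ge k)$ of the observed count $k$ (strict inequality $p_j < c$) is
computed; the representative statistic is the **median of the four**
tail probabilities, defined as the mean of the two middle order
statistics, and the series is called significantly progressing when this
median is below 0.025. One-sided p-values are the default because the
binomial argument requires uniformity under the null and the clinical
hypothesis is deterioration; a two-sided option exists. A regression
with zero residual variance is handled by the t-statistic limit (p of
0.5, 0 or 1 for zero, negative or positive slope).

# The synthetic cohort generator

The generator's defaults are the study conditions under which everything
in the package is exercised. Per eye:

* a mixture of four spatial **defect archetypes** (superior/inferior
  arcuate, nasal step, diffuse) is drawn from independent gamma weights;
* the mixture map is turned into an elevation landscape and the baseline
  field is produced by a **"water-rise"** construction: a damage level L
  rises over the landscape until the (clamped) field mean equals the
  eye's target baseline mTD, drawn from Normal(-6.9, 6.3) dB. Positive
  targets rise "upwards" into sparse supernormal islands capped at
  +5 dB. Deep focal cores, growing extent with growing severity, and
  uninvolved points at exactly 0 dB are all features of real
  glaucomatous fields - and the 0 dB anchor is what makes exam-level
  noise correctable at all (below);
* the eye's mTD slope is drawn from Normal(-0.26, 0.46) dB/year and
  distributed across points, preferentially to already-damaged
  locations, under a capacity constraint guaranteeing that no point
  leaves [-38, 5] dB during follow-up. Per-point trajectories are
  therefore exactly linear and the noise-free mTD slope equals the drawn
  slope (except in eyes already at the floor, where the remaining
  capacity is used). Without the capacity constraint, clamping silently
  attenuates the realised slopes by ~20%;
* ten exams are placed at 0.6-year intervals jittered by +/-20%
  (about 5.4 years of follow-up).

The **noise model** has four channels:

1. damage-dependent Gaussian noise,
   $\mathrm{sd}(td) = \min(6, 1 + 0.15\,\max(0, -td))$ dB - test-retest
   variability grows with defect depth;
2. a per-exam lognormal **session factor** (SD of the log: 0.6)
   multiplying the Gaussian SDs, normalised so E[factor^2] = 1 - exams
   differ in quality, but marginal SDs are unchanged;
3. a **homogeneous shift** of the whole exam, Gaussian with SD 0.5 dB -
   the classical "homogeneous component of long-term fluctuation";
4. **gross response errors**: with per-exam probability
   0.05 x factor^2 per point (tripled at points with absolute loss,
   where every staircase presentation is a guess), the measured value is
   replaced by an extreme - near-normal values (Uniform(0, 4) dB) at
   damaged points (false-positive responses) and floor values
   (Uniform(-38, -25) dB) at healthier points (false-negative
   responses).

Channel 4 deserves explanation, because it is what gives the weighting
scheme something to detect. A reconstruction trained by mean-squared (or
cross-entropy) input reconstruction passes through the *mean* of any
perturbation that overlaps the tangent space of its learned manifold:
if the generative model had a free overall-level direction, an
exam-level shift would simply be tracked by the latent code and
$m_i - \hat m_i$ would carry no information about noise (we verified
this analytically and empirically during design). Spatially *incoherent,
signed* outliers - isolated near-normal points inside a deep defect,
isolated floor values in a healthy area - are off-manifold: the
reconstruction removes them, their signed sum moves $m_i - \hat m_i$,
and the weight correctly flags the exam. This is also the clinically
documented artifact structure of unreliable perimetry ("trigger-happy"
false positives at non-seeing locations, lapses at seeing ones). The
session factor ties artifact load to exam quality, so downweighting
flagged exams removes genuinely noisier visits.

Reliability indices are drawn from truncated normals with means/SDs
typical of reliable clinical series (FL 4.9 +/- 6.4%, FP 3.7 +/- 5.4%,
FN 2.9 +/- 4.5%) and are intentionally *uninformative* about the actual
artifact load - mirroring the observation that reconstruction error is
not explained by the standard indices.

All stages draw from named substreams derived from one seed
(structure, times, noise, reliability, mixture, training, retest), so
changing the noise model regenerates the same true fields, and identical
(seed, config) give byte-identical CSV output.

What the generator does **not** emulate: SITA staircase internals and
their asymmetric error distributions, learning and fatigue trends across
visits, cataract-driven diffuse loss dynamics, spatial correlation of
the Gaussian noise between neighbouring points, and floor effects of
pattern deviation. Consequences for interpretation: passing tests show
the pipeline behaves as designed when artifacts are incoherent,
signed and session-linked; they do not certify performance on real
perimetry, where the artifact structure is richer.

# Evaluation framework

The full-series (10-exam) significance call is the surrogate truth.
For each truncation length k = 3..9:

* **PBP** (surrogate true-positive rate) = significant on the truncated
  series among eyes significant on the full series;
* **PBNP** (surrogate true-negative rate) = non-significant on the
  truncated series among eyes non-significant on the full series;
* **PIP** (surrogate false-positive rate) = non-significant on the full
  series among eyes significant on the *truncated* series.

The denominators are reported with every proportion and 0/0 is returned
as missing. These denominators (full-series conditioned for PBP/PBNP,
truncated-significant conditioned for PIP) are chosen so that PBP/PBNP
track sensitivity/specificity surrogates while PIP can be small even
when PBNP is large; they are not forced to satisfy PIP = 1 - PBNP.

Prediction error is the mean over eyes of the squared difference between
the extrapolated and the observed 10th-exam mTD. Method comparisons
across the seven truncation lengths use the exact paired Wilcoxon
signed-rank test (zero differences dropped; missing pairs dropped; exact
by enumeration for tied samples up to n = 16, since the standard
implementation has no exact path under ties; p = 1 when no nonzero
difference remains).

Time to detection is the first truncation length (3..10) at which a
method calls progression, censored at 10; the timescale is exam count by
default (calendar years optional) because detection can only occur at
exams. Kaplan-Meier estimation and the logrank test come from the
`survival` package, with a degenerate-case guard (zero hypergeometric
variance returns chi-square 0, p 1).

# Numerical choices

* TD values are clamped to [-38, 5] dB everywhere; the generator's
  water-rise and slope-allocation root-findings use `uniroot` at 1e-10
  and 1e-12 tolerance.
* Weighted regression uses the closed-form normal equations with the
  classical t-test on n - 2 degrees of freedom; zero-residual designs
  take the t-statistic limit. Degenerate designs (all time points equal,
  or positive weight at fewer than two distinct times) are errors.
* Binomial tails use `pbinom` (exact summation), never a normal
  approximation - 52 trials is cheap.
* Baseline targets that remain unreachable after clamping (|mTD| beyond
  the dynamic range of the landscape, e.g. supernormal draws above
  +5 dB) fall back to the extreme attainable field with a warning.
* Left-eye fields are mirrored to right-eye orientation at ingest by
  within-row order reversal; the convention is a package choice, flagged
  here because acquisition software conventions differ.

# Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the Monte-Carlo error of each
check is comfortably below the effect it measures: VAE training cohorts
of 2 000 fields (200 eyes x 10 exams, 200 epochs), evaluation cohorts of
500 eyes, 104 test-retest pairs, 2 000 eyes for null-calibration and
generator-fidelity checks, and 100 held-out eyes for denoising error.

# Known limitations

* The mTD-level weight is informative only insofar as measurement
  artifacts are off-manifold (spatially incoherent or saturation-pinned);
  a purely homogeneous exam-level shift is indistinguishable from a
  severity change and passes through any input-reconstruction model.
  On series whose noise is dominated by such shifts the weighted and
  unweighted analyses coincide in expectation.
* At long series (8-9 exams) ordinary least squares is already nearly
  efficient and the measured advantage of weighting is within
  Monte-Carlo noise of zero at 500 eyes.
* The test-retest association between reconstruction error and retest
  change is moderate (R around 0.2-0.3 at the default conditions) and a
  104-pair sample detects it with limited power; some random cohorts
  yield p slightly above 0.05.
* The VAE is intentionally small and CPU-bound; it is a tabular-data
  model, not an image model, and no transfer from real perimetric data
  is attempted.
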