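# vfnoise

Measurement noise is the main obstacle to judging glaucomatous visual-field
(VF) progression: Humphrey 24-2 total-deviation (TD) values fluctuate
between visits even when the instrument's reliability indices are good, so
the ordinary least-squares trend of the mean total deviation (mTD) and
pointwise linear regression (PLR) both need long series before progression
becomes statistically visible.

`vfnoise` implements a denoising strategy for this problem and everything
needed to evaluate it:

* a **variational autoencoder** (VAE) for 52-point TD fields
  (52 → 38 → 26 → 8-dimensional Gaussian latent, mirrored decoder with a
  logistic output), trained by Adam with hand-written reverse-mode
  gradients — reconstructions are deterministic (posterior mean) and
  bit-reproducible under a seed;
* **inverse-reconstruction-error weighting**: exams are weighted by
  `w_i = 1 / max(eps, |mTD_i − mTD_VAE,i|)` in a weighted least-squares mTD
  trend, and per point by `1 / max(eps, |TD_ij − TD_VAE,ij|)` inside the
  **binomial PLR** whole-field test (counts of one-sided pointwise
  p-values under cutoffs 0.025/0.05/0.075/0.1, exact binomial tails,
  median-of-four rule, significance at 0.025);
* an **evaluation framework**: test-retest analysis, PBP/PBNP/PIP
  consistency proportions between truncated and full series, mean squared
  prediction errors of the 10th exam, exact paired Wilcoxon comparisons,
  and Kaplan-Meier time-to-detection with the logrank test;
* a **synthetic cohort generator** producing longitudinal glaucomatous
  series with archetype-structured defects (water-rise construction:
  defect depth and extent grow together, healthy points anchored at 0 dB),
  linear per-eye progression (baseline mTD −6.9 ± 6.3 dB, slopes
  −0.26 ± 0.46 dB/year, ten exams over ≈ 5.4 years), and a four-channel
  noise model (damage-dependent Gaussian noise, per-session quality
  factor, homogeneous long-term fluctuation, and signed gross response
  errors at single points).

The methods vignette (`vignettes/vfnoise-methods.Rmd`) documents the models,
parameter meanings and defaults, and the reasoning behind every open design
choice.

## Worked example

```r
library(vfnoise)

# a measured 200-eye cohort plus its noise-free truth
gen    <- generate_cohort(cohort_config(n_eyes = 200, seed = 11))
params <- vae_train(gen$measured, vae_config(seed = 1))   # ~25 s on one core

eye   <- gen$measured[["eye0014"]]
recon <- vae_reconstruct(eye, params)
round(vae_weights(eye, recon, weight_scheme("vae_mtd")), 2)
#>  [1] 1.35 2.00 0.32 1.38 1.10 0.43 2.00 0.35 2.00 0.79

mtd_trend(eye, weight_scheme("unweighted"))
#> <trend_fit> slope -0.492 dB/y (SE 0.259, p 0.09451), n = 10
mtd_trend(eye, weight_scheme("vae_mtd"), recon)
#> <trend_fit> slope -0.487 dB/y (SE 0.178, p 0.02583), n = 10
```

This eye truly progresses at −0.42 dB/year. Exams 3, 6 and 8 are noisy
sessions; their reconstructions disagree with the measurements, so they
receive small weights. The unweighted trend misses the progression at the
0.05 level (p = 0.095) while the weighted trend detects it (p = 0.026)
with the same point estimate and a smaller standard error.

The two in-study experiments run end to end from one config:

```r
rt <- run_test_retest(experiment_config(seed = 1))
c(R = rt$correlation, p = rt$p)
#>           R           p
#> 0.258797474 0.007985505

te <- run_trend_experiment(experiment_config(cohort = cohort_config(n_eyes = 500), seed = 1))
rbind(unweighted = te$errors$mtd, weighted = te$errors$mtd_vae)
#>                   3        4        5        6        7        8        9
#> unweighted 119.4339 36.36644 17.26005 10.94041 7.225523 5.735903 4.667300
#> weighted    91.7345 30.13300 14.30126  9.20160 6.359346 5.172344 4.554799
```

The first says the reconstruction error of a single exam predicts which way
the retest will move (positive slope, p < 0.01 over 104 pairs). The second
is the headline comparison: the weighted trend predicts the 10th exam's mTD
with a smaller mean squared error than the unweighted trend at every series
length from 3 to 9 exams (dB², 500 eyes).

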