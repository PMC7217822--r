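# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# small measured cohort + truth, reused by several files
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- suppressWarnings(
      generate_cohort(cohort_config(n_eyes = 30, seed = 101)))
  .fixtures$cohort
}

# a VAE trained on 2000 synthetic fields at package defaults
fixture_vae <- function() {
  if (is.null(.fixtures$vae)) {
    gen <- suppressWarnings(
      generate_cohort(cohort_config(n_eyes = 200, seed = 301)))
    .fixtures$vae <- vae_train(gen$measured, vae_config(seed = 401))
  }
  .fixtures$vae
}

# held-out cohort for denoising checks
fixture_heldout <- function() {
  if (is.null(.fixtures$heldout))
    .fixtures$heldout <- suppressWarnings(
      generate_cohort(cohort_config(n_eyes = 100, seed = 501)))
  .fixtures$heldout
}

# full trend experiment at the evaluation scale, reused by acceptance tests
fixture_trend_experiment <- function() {
  if (is.null(.fixtures$trend))
    .fixtures$trend <- suppressWarnings(run_trend_experiment(
      experiment_config(cohort = cohort_config(n_eyes = 500), seed = 1)))
  .fixtures$trend
}

# tiny untrained parameter sets for numeric checks
tiny_vae_config <- function(...) {
  vae_config(hidden_dims = c(8, 5), latent_dim = 3, epochs = 5,
             batch_size = 16, seed = 7, ...)
}

# brute-force weighted normal equations: solve X' W X b = X' W y
oracle_wls <- function(t, y, w) {
  X <- cbind(1, t)
  b <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
  c(intercept = b[1], slope = b[2])
}

random_series <- function(n = 10, seed = 1) {
  set.seed(seed)
  t <- cumsum(runif(n, 0.4, 0.8))
  td <- matrix(pmax(pmin(rnorm(n * 52, -5, 4), 5), -38), n)
  vf_series("e1", t, td)
}
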