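# End-to-end experiments on synthetic cohorts: the test-retest analysis and
# the trend/prediction/consistency/survival analysis. The VAE is always
# trained on a cohort generated from a substream disjoint from the
# evaluation cohort, mirroring the separation of training and testing data.

#' Configuration of an end-to-end experiment
#'
#' @param cohort A [cohort_config()] for the evaluation cohort (its seed is
#'   overridden by `seed`).
#' @param n_train_eyes Eyes in the independent VAE training cohort; with
#'   the default 10 exams each this gives `10 * n_train_eyes` training
#'   fields.
#' @param n_pairs Test-retest pairs for the test-retest experiment.
#' @param retest_baseline_mean,retest_baseline_sd Baseline mTD demography of
#'   the test-retest cohort, dB (defaults -9.8 and 7.4: test-retest studies
#'   recruit established glaucoma patients, who are more damaged on average
#'   than a longitudinal trend cohort).
#' @param noise A [noise_model()].
#' @param vae A [vae_config()] (its seed is overridden by `seed`).
#' @param scheme_mtd Weighting scheme for the weighted mTD trend analysis,
#'   default `"vae_mtd"`.
#' @param scheme_plr Weighting scheme for the weighted binomial PLR,
#'   default `"vae_pointwise"`.
#' @param truncations Truncated series lengths to evaluate, default 3:9.
#' @param sig_p Two-sided significance level of the mTD trend slope.
#' @param seed Master seed; all stages derive their substreams from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(n_eyes = 500),
                              n_train_eyes = 200, n_pairs = 104,
                              retest_baseline_mean = -9.8,
                              retest_baseline_sd = 7.4,
                              noise = noise_model(), vae = vae_config(),
                              scheme_mtd = weight_scheme("vae_mtd"),
                              scheme_plr = weight_scheme("vae_pointwise"),
                              truncations = 3:9, sig_p = 0.05, seed = 1) {
  if (any(truncations < 2) || any(truncations >= cohort$n_exams))
    stop("truncations must lie in 2 .. n_exams - 1")
  structure(list(cohort = cohort, n_train_eyes = as.integer(n_train_eyes),
                 n_pairs = as.integer(n_pairs),
                 retest_baseline_mean = retest_baseline_mean,
                 retest_baseline_sd = retest_baseline_sd,
                 noise = noise, vae = vae,
                 scheme_mtd = scheme_mtd, scheme_plr = scheme_plr,
                 truncations = as.integer(truncations), sig_p = sig_p,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# train the VAE on an independent synthetic cohort
.train_experiment_vae <- function(config, verbose = FALSE) {
  train_seed <- .substream_seed(config$seed, "training")
  train_cfg <- config$cohort
  train_cfg$n_eyes <- config$n_train_eyes
  train_cfg$seed <- train_seed
  train <- generate_cohort(train_cfg, config$noise)
  vae_cfg <- config$vae
  vae_cfg$seed <- train_seed
  list(params = vae_train(train$measured, vae_cfg, verbose = verbose),
       n_fields = sum(vapply(train$measured, length, integer(1))))
}

#' Test-retest experiment
#'
#' Trains the VAE on an independent synthetic cohort, generates test-retest
#' pairs, reconstructs the first ("test") exam of each pair and regresses
#' the retest-test mTD difference on the reconstruction-test mTD
#' difference. A positive significant slope means the reconstruction error
#' predicts which way the retest will move, i.e. it behaves as an estimate
#' of the measurement error of the exam.
#'
#' @param config An [experiment_config()].
#' @param verbose Print training progress.
#' @return A list with `n_pairs`, `correlation` (Pearson R, `NA` when
#'   degenerate), `slope`, `p`, the per-eye difference vectors, and the
#'   resolved `config`.
#' @export
run_test_retest <- function(config = experiment_config(), verbose = FALSE) {
  tr <- .train_experiment_vae(config, verbose)
  eval_cfg <- config$cohort
  eval_cfg$seed <- config$seed
  eval_cfg$baseline_mtd_mean <- config$retest_baseline_mean
  eval_cfg$baseline_mtd_sd <- config$retest_baseline_sd
  pairs <- generate_test_retest(eval_cfg, config$noise,
                                n_pairs = config$n_pairs)
  mtd_test <- vapply(pairs$test, compute_mtd, numeric(1))
  mtd_retest <- vapply(pairs$retest, compute_mtd, numeric(1))
  mtd_rec <- mtd_vae(pairs$test, tr$params)
  d_vae <- mtd_rec - mtd_test
  d_retest <- mtd_retest - mtd_test
  if (stats::sd(d_vae) < 1e-12 || stats::sd(d_retest) < 1e-12) {
    return(list(n_pairs = config$n_pairs, correlation = NA_real_,
                slope = NA_real_, p = NA_real_, d_vae = d_vae,
                d_retest = d_retest, n_train_fields = tr$n_fields,
                config = config))
  }
  fit <- ols_fit(d_vae, d_retest)
  list(n_pairs = config$n_pairs,
       correlation = stats::cor(d_vae, d_retest),
       slope = fit$slope, p = fit$slope_p,
       d_vae = d_vae, d_retest = d_retest,
       n_train_fields = tr$n_fields, config = config)
}

#' Trend-analysis experiment
#'
#' The full pipeline on one synthetic cohort: train the VAE on an
#' independent cohort, generate an evaluation cohort of full-length series,
#' reconstruct every exam, and run four progression methods - unweighted
#' and VAE-weighted mTD trend analysis, unweighted and VAE-weighted
#' binomial PLR - on the full series and on every truncation. The report
#' collects consistency proportions, mean squared final-exam prediction
#' errors, paired Wilcoxon comparisons of the weighted against the
#' unweighted variants, and Kaplan-Meier time-to-detection with logrank
#' tests.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return A list with elements `calls` (per method: full-series call and
#'   truncation call matrix), `consistency` (per method), `errors` (per
#'   mTD method), `wilcoxon` (named comparison p-values), `survival`
#'   (records, KM tables and logrank results), `true_slopes`, and the
#'   resolved `config`.
#' @export
run_trend_experiment <- function(config = experiment_config(),
                                 verbose = FALSE) {
  tr <- .train_experiment_vae(config, verbose)
  params <- tr$params
  if (verbose) message("VAE trained on ", tr$n_fields, " fields")

  eval_cfg <- config$cohort
  eval_cfg$seed <- config$seed
  gen <- generate_cohort(eval_cfg, config$noise)
  cohort <- gen$measured
  n_eyes <- length(cohort)
  ks <- config$truncations
  full_k <- eval_cfg$n_exams
  methods <- c("mtd", "mtd_vae", "plr", "plr_vae")

  calls_full <- matrix(NA, n_eyes, 4, dimnames = list(NULL, methods))
  calls_tr <- lapply(stats::setNames(methods, methods), function(m)
    matrix(NA, n_eyes, length(ks), dimnames = list(NULL, ks)))
  pred <- list(mtd = matrix(NA_real_, n_eyes, length(ks),
                            dimnames = list(NULL, ks)))
  pred$mtd_vae <- pred$mtd
  mtd10 <- numeric(n_eyes)
  unweighted <- weight_scheme("unweighted")

  for (i in seq_len(n_eyes)) {
    s <- cohort[[i]]
    recon <- vae_reconstruct(s, params)
    t10 <- s$t[full_k]
    mtd10[i] <- compute_mtd(vf_exam(s, full_k))
    segs <- c(ks, full_k)
    for (k in segs) {
      sk <- vf_truncate(s, k)
      rk <- vf_truncate(recon, k)
      c_mtd <- mtd_trend(sk, unweighted, sig_p = config$sig_p)$significant
      c_mtdv <- mtd_trend(sk, config$scheme_mtd, rk,
                          sig_p = config$sig_p)$significant
      c_plr <- binomial_plr_series(sk, unweighted)$significant
      c_plrv <- binomial_plr_series(sk, config$scheme_plr, rk)$significant
      if (k == full_k) {
        calls_full[i, ] <- c(c_mtd, c_mtdv, c_plr, c_plrv)
      } else {
        kc <- as.character(k)
        calls_tr$mtd[i, kc] <- c_mtd
        calls_tr$mtd_vae[i, kc] <- c_mtdv
        calls_tr$plr[i, kc] <- c_plr
        calls_tr$plr_vae[i, kc] <- c_plrv
        pred$mtd[i, kc] <- predict_future_mtd(s, k, t10, unweighted)
        pred$mtd_vae[i, kc] <- predict_future_mtd(s, k, t10,
                                                  config$scheme_mtd, recon)
      }
    }
    if (verbose && i %% 100 == 0) message("processed ", i, " eyes")
  }

  cons <- lapply(stats::setNames(methods, methods), function(m)
    consistency(calls_full[, m], calls_tr[[m]]))
  errors <- list(mtd = prediction_errors(pred$mtd, mtd10),
                 mtd_vae = prediction_errors(pred$mtd_vae, mtd10))
  wilcoxon <- list(
    mtd_pbp = paired_wilcoxon(cons$mtd_vae$pbp, cons$mtd$pbp)$p,
    mtd_pbnp = paired_wilcoxon(cons$mtd_vae$pbnp, cons$mtd$pbnp)$p,
    mtd_pip = paired_wilcoxon(cons$mtd_vae$pip, cons$mtd$pip)$p,
    mtd_errors = paired_wilcoxon(errors$mtd_vae, errors$mtd)$p,
    plr_pbp = paired_wilcoxon(cons$plr_vae$pbp, cons$plr$pbp)$p,
    plr_pbnp = paired_wilcoxon(cons$plr_vae$pbnp, cons$plr$pbnp)$p,
    plr_pip = paired_wilcoxon(cons$plr_vae$pip, cons$plr$pip)$p
  )
  lengths_all <- c(ks, full_k)
  surv_records <- lapply(stats::setNames(methods, methods), function(m)
    detection_survival(cbind(calls_tr[[m]], calls_full[, m]),
                       lengths = lengths_all))
  survival <- list(
    records = surv_records,
    km = lapply(surv_records, kaplan_meier),
    logrank_plr = logrank_test(surv_records$plr, surv_records$plr_vae),
    logrank_mtd = logrank_test(surv_records$mtd, surv_records$mtd_vae)
  )
  list(calls = list(full = calls_full, truncated = calls_tr),
       consistency = cons, errors = errors, predictions = pred,
       observed_mtd10 = mtd10, wilcoxon = wilcoxon, survival = survival,
       true_slopes = gen$slopes, n_train_fields = tr$n_fields,
       config = config)
}
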