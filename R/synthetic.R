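# Synthetic longitudinal glaucoma cohorts.
#
# The generator emulates the statistical structure of multi-centre Humphrey
# 24-2 series in treated open-angle glaucoma: spatially structured defects
# (arcuate bundles, nasal step, diffuse loss), linear per-eye progression
# with eye-specific rates, and measurement noise whose standard deviation
# grows with the depth of damage at a point. All randomness is driven by a
# single integer seed split into named substreams so that, e.g., changing
# the noise model leaves the underlying true fields untouched.

# Fixed offsets per named substream; combined with the user seed modulo the
# 32-bit integer range.
.substream_seed <- function(seed, stage) {
  offs <- c(structure = 101L, times = 211L, noise = 307L,
            reliability = 401L, mixture = 503L, training = 601L,
            retest = 701L)
  if (!stage %in% names(offs)) stop("unknown substream: ", stage)
  as.integer((as.double(seed) * 7919 + offs[[stage]]) %% 2147483647)
}

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the demographic structure of a typical longitudinal
#' glaucoma trend-analysis dataset: ten exams per eye at roughly 0.6-year
#' intervals (about 5.4 years of follow-up), baseline mTD of -6.9 +/- 6.3 dB
#' across eyes, and mTD progression rates of -0.26 +/- 0.46 dB/year.
#'
#' @param n_eyes Number of eyes.
#' @param n_exams Exams per eye (>= 2), default 10.
#' @param interval_years Mean inter-exam interval in years, default 0.6.
#'   Actual intervals are jittered uniformly by +/-20% to avoid exactly
#'   collinear designs.
#' @param baseline_mtd_mean,baseline_mtd_sd Mean and SD of the true baseline
#'   mTD across eyes, dB.
#' @param slope_mean,slope_sd Mean and SD of the true per-eye mTD progression
#'   rate, dB/year.
#' @param seed Integer seed; identical (seed, config) gives an identical
#'   cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_eyes = 100, n_exams = 10, interval_years = 0.6,
                          baseline_mtd_mean = -6.9, baseline_mtd_sd = 6.3,
                          slope_mean = -0.26, slope_sd = 0.46, seed = 1) {
  if (n_exams < 2) stop("`n_exams` must be at least 2")
  if (baseline_mtd_sd < 0 || slope_sd < 0) stop("SDs must be nonnegative")
  if (interval_years <= 0) stop("`interval_years` must be positive")
  structure(list(n_eyes = as.integer(n_eyes), n_exams = as.integer(n_exams),
                 interval_years = interval_years,
                 baseline_mtd_mean = baseline_mtd_mean,
                 baseline_mtd_sd = baseline_mtd_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sensitivity-dependent measurement-noise model
#'
#' Test-retest variability of perimetric thresholds grows with the depth of
#' damage. The per-point noise SD is
#' `min(sd_cap, sd_floor + sd_slope * max(0, -td_true))` dB: `sd_floor` at
#' healthy points, rising linearly with damage depth up to `sd_cap`. The
#' defaults (1.0, 0.15, 6.0) give whole-field test-retest mTD SDs of roughly
#' 1-2 dB in damaged eyes.
#'
#' Two further features of real perimetric noise are modelled on top of the
#' damage dependence:
#' \itemize{
#'   \item exams differ in overall quality (long-term fluctuation:
#'     attention, fatigue, lens position), modelled by a per-exam lognormal
#'     multiplier of the Gaussian noise SD with `E[factor^2] = 1`, so the
#'     marginal per-point SD over many exams is unchanged; `session_sd` is
#'     the SD of the log multiplier (0 disables it);
#'   \item isolated gross response errors: perimetric staircases end at an
#'     extreme when the patient responds without seeing (a false-positive
#'     response at a damaged point, yielding a near-normal value) or fails
#'     to respond while seeing (a false-negative response at a healthy
#'     point, yielding a floor value). Each point of each exam suffers such
#'     an error with a per-exam probability `lapse_rate * factor^2` (bad
#'     sessions lapse more; marginally the rate is `lapse_rate`): damaged
#'     points (true TD below -5 dB) are replaced by a draw from
#'     Uniform(0, 4) dB, healthier points by a draw from
#'     Uniform(-38, -25) dB. At points with absolute loss (true TD at or
#'     below -30 dB) every presentation is a guess, so the gross-error
#'     probability there is tripled. These spatially incoherent, signed
#'     outliers are the artifact a reconstruction model can actually
#'     remove.
#' }
#' The gross-error channel is not part of [noise_sd()], which describes the
#' Gaussian channels only.
#'
#' @param sd_floor Gaussian noise SD at an undamaged point, dB.
#' @param sd_slope Additional Gaussian SD per dB of true damage.
#' @param sd_cap Upper bound on the Gaussian SD, dB.
#' @param session_sd SD of the log of the per-exam noise multiplier,
#'   default 0.6.
#' @param lapse_rate Marginal per-point probability of a gross response
#'   error, default 0.05.
#' @param global_sd SD of the homogeneous per-exam shift, default 0.5 dB.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_floor = 1.0, sd_slope = 0.15, sd_cap = 6.0,
                        session_sd = 0.6, lapse_rate = 0.05,
                        global_sd = 0.5) {
  if (sd_floor < 0 || sd_slope < 0 || sd_cap < sd_floor || session_sd < 0)
    stop("need sd_floor >= 0, sd_slope >= 0, sd_cap >= sd_floor, session_sd >= 0")
  if (lapse_rate < 0 || lapse_rate >= 1 || global_sd < 0)
    stop("need 0 <= lapse_rate < 1 and global_sd >= 0")
  structure(list(sd_floor = sd_floor, sd_slope = sd_slope, sd_cap = sd_cap,
                 session_sd = session_sd, lapse_rate = lapse_rate,
                 global_sd = global_sd),
            class = "noise_model")
}

#' Per-point Gaussian noise SD under a noise model
#'
#' The marginal SD of the Gaussian noise channels (before clamping to the
#' dynamic range): the damage-dependent component
#' `min(sd_cap, sd_floor + sd_slope * max(0, -td_true))` combined with the
#' homogeneous per-exam shift, i.e. `sqrt(gauss_sd^2 + global_sd^2)`. The
#' session multiplier has unit mean square and does not change the marginal
#' SD. The gross-error channel is separate (see [noise_model()]).
#'
#' @param td_true True TD values (vector or matrix), dB.
#' @param model A [noise_model()].
#' @return Marginal Gaussian noise SDs with the shape of `td_true`;
#'   nonnegative and non-decreasing in damage depth.
#' @export
noise_sd <- function(td_true, model = noise_model()) {
  g <- pmin(model$sd_cap, model$sd_floor + model$sd_slope * pmax(0, -td_true))
  out <- sqrt(g^2 + model$global_sd^2)
  if (is.matrix(td_true)) dim(out) <- dim(td_true)
  out
}

#' Glaucomatous defect archetypes
#'
#' Spatial loading maps describing where on the 24-2 grid a defect removes
#' sensitivity. Each map is a nonnegative 52-vector summing to one, aligned
#' with [vf_grid24()]. Four archetypes are shipped: superior and inferior
#' arcuate bundles (loadings concentrated along the 15-degree arc in the
#' respective hemifield), a nasal step (loadings on the nasal points,
#' densest toward the periphery) and diffuse loss (uniform). Each map gets
#' a small uniform floor so that every point can absorb some deficit.
#'
#' @return A 52 x 4 matrix with columns `superior_arcuate`,
#'   `inferior_arcuate`, `nasal_step`, `diffuse`.
#' @export
defect_archetypes <- function() {
  g <- vf_grid24()
  r <- sqrt(g$x^2 + g$y^2)
  sup <- exp(-(r - 15)^2 / 60) * (g$y > 0)
  inf <- exp(-(r - 15)^2 / 60) * (g$y < 0)
  nas <- (g$x >= 9) * exp(-abs(g$y) / 12)
  dif <- rep(1, nrow(g))
  m <- cbind(superior_arcuate = sup, inferior_arcuate = inf,
             nasal_step = nas, diffuse = dif)
  m <- sweep(m, 2, colSums(m), "/")
  0.96 * m + 0.04 / N_POINTS
}

# Baseline field from an archetype mixture map, "water-rise" construction:
# the map is turned into an elevation landscape (most-loaded point lowest)
# and a damage level L rises over it, so that defects deepen AND enlarge
# together as severity grows - the coupling between defect depth and extent
# seen in real glaucomatous fields - while uninvolved points stay at 0 dB.
# L is chosen so the clamped field hits the target mTD; the covered depth
# mean(pmin(38, pmax(0, L - elev))) is continuous and non-decreasing in L,
# so a root always exists for reachable targets.
ELEV_SCALE <- 90

.baseline_from_target <- function(target_mtd, map) {
  elev <- ELEV_SCALE * (1 - map / max(map))
  depth_cap <- if (target_mtd < 0) -TD_MIN else TD_MAX
  sgn <- if (target_mtd < 0) -1 else 1
  f <- function(L) mean(pmin(depth_cap, pmax(0, L - elev))) - abs(target_mtd)
  hi <- ELEV_SCALE + depth_cap
  if (f(hi) < 0) {
    warning("baseline mTD target ", signif(target_mtd, 3),
            " unreachable after clamping; using extreme attainable field")
    return(rep(sgn * depth_cap, N_POINTS))
  }
  L <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  sgn * pmin(depth_cap, pmax(0, L - elev))
}

# Distribute the eye's mTD slope across points, preferentially to damaged
# locations, under the constraint that no point leaves the dynamic range
# during the follow-up (so trajectories stay exactly linear and the mTD
# slope of the noise-free series equals the drawn slope). Per point the
# allocation is sign(s) * min(capacity_j, lambda * q_j), with lambda solved
# so the allocations sum to 52 * s; when total capacity is insufficient the
# full capacity is used (best effort).
.allocate_slope <- function(base, s, t_end) {
  if (s == 0 || t_end <= 0) return(rep(0, N_POINTS))
  room <- if (s < 0) base - TD_MIN else TD_MAX - base
  cap <- pmax(room - 0.25, 0) / t_end
  q <- (1 + pmax(0, -base)) * (cap > 0)
  need <- N_POINTS * abs(s)
  if (sum(cap) <= need) return(sign(s) * cap)
  f <- function(lambda) sum(pmin(cap, lambda * q)) - need
  lambda <- stats::uniroot(f, c(0, need / max(q[q > 0]) + 1e3),
                           tol = 1e-12, extendInt = "upX")$root
  sign(s) * pmin(cap, lambda * q)
}

#' Generate a noise-free synthetic cohort
#'
#' For each eye: a defect-archetype mixture is drawn (gamma weights,
#' normalised) and turned into an elevation landscape; the baseline field
#' is produced by raising a damage level over that landscape until the true
#' baseline mTD equals a draw from
#' `Normal(baseline_mtd_mean, baseline_mtd_sd)` (within the [-38, 5] dB
#' dynamic range). Defect depth and spatial extent therefore grow together,
#' as in real glaucomatous fields, and uninvolved points sit at 0 dB. The
#' eye's mTD slope is drawn from `Normal(slope_mean, slope_sd)` and
#' distributed across points preferentially to already-damaged locations,
#' under a capacity constraint that keeps every trajectory inside the
#' dynamic range for the whole follow-up: per-point trajectories are
#' exactly linear and the noise-free mTD slope equals the drawn slope
#' (except in eyes so close to the floor that the full capacity is used).
#' Exam times start at 0 with jittered intervals.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (a [vf_cohort()] of noise-free series with
#'   zero reliability indices) and `slopes` (the drawn per-eye mTD slopes,
#'   dB/year).
#' @export
generate_true_cohort <- function(config) {
  arch <- defect_archetypes()
  set.seed(.substream_seed(config$seed, "mixture"))
  mix <- matrix(stats::rgamma(config$n_eyes * ncol(arch),
                              shape = rep(c(2, 2, 1.2, 1), each = config$n_eyes)),
                nrow = config$n_eyes)
  mix <- mix / rowSums(mix)

  set.seed(.substream_seed(config$seed, "structure"))
  m0 <- stats::rnorm(config$n_eyes, config$baseline_mtd_mean,
                     config$baseline_mtd_sd)
  sl <- stats::rnorm(config$n_eyes, config$slope_mean, config$slope_sd)

  set.seed(.substream_seed(config$seed, "times"))
  jit <- matrix(stats::runif(config$n_eyes * (config$n_exams - 1), 0.8, 1.2),
                nrow = config$n_eyes)

  series <- vector("list", config$n_eyes)
  for (i in seq_len(config$n_eyes)) {
    map <- as.numeric(arch %*% mix[i, ])
    base <- .baseline_from_target(m0[i], map)
    t <- c(0, cumsum(config$interval_years * jit[i, ]))
    pt_slope <- .allocate_slope(base, sl[i], t[length(t)])
    td <- pmin(TD_MAX, pmax(TD_MIN, outer(t, pt_slope) +
                              rep(base, each = length(t))))
    series[[i]] <- vf_series(sprintf("eye%04d", i), t, td)
  }
  list(cohort = vf_cohort(series), slopes = sl)
}

#' Add measurement noise and reliability indices to a cohort
#'
#' Independent noise is added to every point of every exam: Gaussian with
#' the damage-dependent SD scaled by the exam's session factor, plus the
#' homogeneous per-exam shift; gross response errors then overwrite lapse
#' points with extreme values (see [noise_model()]). Measured TDs are
#' clamped to the [-38, 5] dB dynamic range. Reliability
#' indices are drawn from normal
#' distributions truncated to [0, 100] with means/SDs typical of reliable
#' clinical series (FL 4.9 +/- 6.4%, FP 3.7 +/- 5.4%, FN 2.9 +/- 4.5%).
#'
#' @param cohort A noise-free [vf_cohort()].
#' @param model A [noise_model()].
#' @param seed Integer seed (use the cohort config's seed to tie streams
#'   together; a distinct substream is used internally).
#' @return A [vf_cohort()] of measured series.
#' @export
add_measurement_noise <- function(cohort, model = noise_model(), seed = 1) {
  set.seed(.substream_seed(seed, "noise"))
  noisy <- lapply(cohort, function(s) {
    n <- nrow(s$td)
    # per-exam quality factor, E[f^2] = 1 so marginal SDs are unchanged
    f <- exp(model$session_sd * stats::rnorm(n) - model$session_sd^2)
    g <- matrix(pmin(model$sd_cap,
                     model$sd_floor + model$sd_slope * pmax(0, -s$td)), n)
    shift <- stats::rnorm(n, 0, model$global_sd)
    td <- s$td + stats::rnorm(length(s$td)) * (g * f) + shift
    # gross response errors: staircase terminates at the opposite extreme;
    # at absolute scotomas every response is a guess, so errors concentrate
    rate <- matrix(pmin(0.4, model$lapse_rate * f^2), n, N_POINTS) *
      (1 + 2 * (s$td <= -30))
    lapse <- matrix(stats::runif(length(s$td)) < pmin(rate, 0.5), n)
    if (any(lapse)) {
      damaged <- s$td < -5
      k_fp <- sum(lapse & damaged)
      k_fn <- sum(lapse & !damaged)
      td[lapse & damaged] <- stats::runif(k_fp, 0, 4)
      td[lapse & !damaged] <- stats::runif(k_fn, -38, -25)
    }
    s$td <- matrix(pmin(TD_MAX, pmax(TD_MIN, td)), nrow = n)
    s
  })
  set.seed(.substream_seed(seed, "reliability"))
  noisy <- lapply(noisy, function(s) {
    n <- length(s$t)
    s$fl <- .rtruncnorm(n, 4.9, 6.4)
    s$fp <- .rtruncnorm(n, 3.7, 5.4)
    s$fn <- .rtruncnorm(n, 2.9, 4.5)
    s
  })
  vf_cohort(noisy)
}

# normal truncated to [0, 100] by redraw
.rtruncnorm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (iter in 1:100) {
    bad <- x < 0 | x > 100
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x[x < 0] <- 0
  x[x > 100] <- 100
  x
}

#' Generate a measured cohort together with its noise-free truth
#'
#' Convenience wrapper: [generate_true_cohort()] followed by
#' [add_measurement_noise()] using the config's seed.
#'
#' @param config A [cohort_config()].
#' @param model A [noise_model()].
#' @return A list with `measured`, `truth` (both [vf_cohort()]) and
#'   `slopes` (true per-eye mTD slopes).
#' @export
generate_cohort <- function(config, model = noise_model()) {
  truth <- generate_true_cohort(config)
  measured <- add_measurement_noise(truth$cohort, model, config$seed)
  list(measured = measured, truth = truth$cohort, slopes = truth$slopes)
}

#' Generate test-retest pairs
#'
#' Draws `n_pairs` eyes from the configured baseline distribution (no
#' progression: the two exams share one true field) and produces two
#' independent noisy measurements of each, a stated `retest_gap_years`
#' apart (default 0.1, i.e. within about a month).
#'
#' @param config A [cohort_config()] (only the baseline parameters and seed
#'   are used).
#' @param model A [noise_model()].
#' @param n_pairs Number of eyes, default 104.
#' @param retest_gap_years Nominal gap between test and retest, years.
#' @return A list with `test` and `retest` (each a [vf_cohort()] of
#'   single-exam series, aligned by position) and `truth` (a 52-column
#'   matrix of the shared true fields).
#' @export
generate_test_retest <- function(config, model = noise_model(),
                                 n_pairs = 104, retest_gap_years = 0.1) {
  cfg <- cohort_config(n_eyes = n_pairs, n_exams = 2,
                       interval_years = retest_gap_years,
                       baseline_mtd_mean = config$baseline_mtd_mean,
                       baseline_mtd_sd = config$baseline_mtd_sd,
                       slope_mean = 0, slope_sd = 0,
                       seed = .substream_seed(config$seed, "retest"))
  out <- generate_cohort(cfg, model)
  test <- lapply(out$measured, function(s) {
    vf_series(s$eye_id, 0, s$td[1, , drop = FALSE], s$fl[1], s$fp[1], s$fn[1])
  })
  retest <- lapply(out$measured, function(s) {
    vf_series(s$eye_id, 0, s$td[2, , drop = FALSE], s$fl[2], s$fp[2], s$fn[2])
  })
  truth <- do.call(rbind, lapply(out$truth, function(s) s$td[1, ]))
  list(test = vf_cohort(test), retest = vf_cohort(retest), truth = truth)
}
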