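# Evaluation framework: consistency proportions between truncated and
# full-series progression calls, prediction errors, paired Wilcoxon
# comparisons, and Kaplan-Meier time-to-detection with the logrank test.

#' Consistency of truncated-series calls against the full series
#'
#' The significance call on the complete series is treated as the surrogate
#' truth. For every truncation length this computes, across eyes:
#' \describe{
#'   \item{pbp}{proportion of both progressing (surrogate true-positive
#'     rate): eyes significant on the truncated series among eyes
#'     significant on the full series;}
#'   \item{pbnp}{proportion of both not progressing (surrogate true-negative
#'     rate): eyes non-significant on the truncated series among eyes
#'     non-significant on the full series;}
#'   \item{pip}{proportion of inconsistent progression (surrogate
#'     false-positive rate): eyes non-significant on the full series among
#'     eyes significant on the truncated series.}
#' }
#' Undefined proportions (0/0) are reported as `NA`; numerators and
#' denominators accompany every proportion.
#'
#' @param full Logical vector: the full-series call per eye.
#' @param truncated Logical matrix, eyes x truncation lengths (column names
#'   are kept; typically `"3"` .. `"9"`).
#' @return A data frame with one row per truncation length.
#' @export
consistency <- function(full, truncated) {
  if (!is.matrix(truncated)) truncated <- cbind(truncated)
  if (length(full) == 0) stop("no eyes to evaluate")
  if (nrow(truncated) != length(full))
    stop("`truncated` must have one row per eye")
  res <- lapply(seq_len(ncol(truncated)), function(k) {
    tr <- truncated[, k]
    data.frame(
      truncation = colnames(truncated)[k] %||% as.character(k),
      pbp_num = sum(full & tr), pbp_den = sum(full),
      pbnp_num = sum(!full & !tr), pbnp_den = sum(!full),
      pip_num = sum(tr & !full), pip_den = sum(tr)
    )
  })
  out <- do.call(rbind, res)
  out$pbp <- ifelse(out$pbp_den > 0, out$pbp_num / out$pbp_den, NA_real_)
  out$pbnp <- ifelse(out$pbnp_den > 0, out$pbnp_num / out$pbnp_den, NA_real_)
  out$pip <- ifelse(out$pip_den > 0, out$pip_num / out$pip_den, NA_real_)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean squared prediction error per truncation length
#'
#' @param predicted Numeric matrix, eyes x truncation lengths, of predicted
#'   final-exam mTDs (dB).
#' @param observed Numeric vector of observed final-exam mTDs, one per eye.
#' @return Named numeric vector of mean squared errors (dB^2), one per
#'   column of `predicted`.
#' @export
prediction_errors <- function(predicted, observed) {
  if (!is.matrix(predicted)) predicted <- cbind(predicted)
  if (nrow(predicted) != length(observed))
    stop("`predicted` must have one row per eye")
  colMeans((predicted - observed)^2)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences `a - b`. Pairs with
#' a missing value (e.g. an undefined consistency proportion) and zero
#' differences are dropped (the standard convention); if no nonzero
#' difference remains the test is degenerate and p = 1 is returned. The
#' exact null distribution is used whenever there are no ties among the
#' absolute differences (and for tied samples up to n = 16, by direct
#' enumeration of sign assignments over midranks); otherwise the normal
#' approximation with continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A list with `statistic` (V), `p` and `n` (non-zero pairs).
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0) return(list(statistic = NA_real_, p = 1, n = 0L))
  n <- length(d)
  ties <- any(duplicated(abs(d)))
  if (ties && n <= 16) {
    # exact two-sided p by enumerating all 2^n sign assignments (midranks);
    # wilcox.test has no exact path in the presence of ties
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    v_all <- as.matrix(expand.grid(rep(list(c(0, 1)), n))) %*% r
    p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
    return(list(statistic = v_obs, p = p, n = n))
  }
  exact <- !ties && n <= 50
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n)
}

#' Time to first detection of progression
#'
#' Given per-eye significance calls over growing series lengths, records
#' for each eye the first length at which the method calls progression
#' (event) or the maximum length if it never does (censored). A
#' non-monotone call pattern (significant, then not) still detects at the
#' first significant length.
#'
#' @param calls Logical matrix, eyes x series lengths; column names give
#'   the lengths (default `lengths`).
#' @param lengths Series lengths corresponding to the columns, default
#'   `3:10`.
#' @param t_years Optional numeric matrix (same shape) of calendar times;
#'   when supplied, `time` is reported in years at the detecting exam.
#' @return A data frame with `eye` (row index), `time` and `event`
#'   (1 = detected, 0 = censored at the last length).
#' @export
detection_survival <- function(calls, lengths = 3:10, t_years = NULL) {
  if (!is.matrix(calls)) calls <- rbind(calls)
  if (ncol(calls) != length(lengths))
    stop("`lengths` must have one entry per column of `calls`")
  first <- apply(calls, 1, function(z) {
    i <- which(z)[1]
    if (is.na(i)) NA_integer_ else i
  })
  event <- as.integer(!is.na(first))
  idx <- ifelse(is.na(first), length(lengths), first)
  time <- lengths[idx]
  if (!is.null(t_years))
    time <- t_years[cbind(seq_len(nrow(calls)), idx)]
  data.frame(eye = seq_len(nrow(calls)), time = time, event = event)
}

#' Kaplan-Meier estimate of the not-yet-detected fraction
#'
#' Product-limit estimator over the detection records. Without censoring
#' the estimate equals the empirical survivor function.
#'
#' @param records Data frame with `time` and `event` columns (see
#'   [detection_survival()]).
#' @return A data frame with `time`, `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(records) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Logrank test between two sets of detection records
#'
#' Standard logrank test (hypergeometric variance, 1 degree of freedom)
#' comparing the time-to-detection distributions of two methods.
#'
#' @param records_a,records_b Data frames with `time` and `event` columns.
#' @return A list with `chisq`, `df` and `p`.
#' @export
logrank_test <- function(records_a, records_b) {
  df <- rbind(data.frame(time = records_a$time, event = records_a$event,
                         group = "a"),
              data.frame(time = records_b$time, event = records_b$event,
                         group = "b"))
  # degenerate case (e.g. every eye detected at the same exam in both
  # groups): the hypergeometric variance is zero and there is no evidence
  # of a difference
  v <- 0
  for (tt in unique(df$time[df$event == 1])) {
    at <- df$time >= tt
    n <- sum(at); n1 <- sum(at & df$group == "a")
    d <- sum(df$time == tt & df$event == 1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v < .Machine$double.eps)
    return(list(chisq = 0, df = 1L, p = 1))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chisq = sd_$chisq, df = 1L,
       p = stats::pchisq(sd_$chisq, 1, lower.tail = FALSE))
}
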