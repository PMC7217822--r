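# Core data model: single exams, longitudinal series, cohorts, reliability
# filtering, 30-2 reduction and CSV persistence.

N_POINTS <- 52L
TD_MIN <- -38
TD_MAX <- 5

#' A single visual-field exam
#'
#' Bundles the 52 total-deviation (TD) values of one Humphrey 24-2 exam with
#' its time stamp and reliability indices. TD values are in dB relative to
#' the age-corrected normal, in the printout order of [vf_grid24()].
#'
#' @param td Numeric vector of 52 finite TD values (dB).
#' @param t Time since the eye's baseline exam, in years (>= 0).
#' @param fl,fp,fn Fixation-loss, false-positive and false-negative rates
#'   of the exam, in percent (0..100).
#' @return An object of class `visual_field`.
#' @examples
#' f <- visual_field(rep(-5, 52), t = 0)
#' compute_mtd(f)
#' @export
visual_field <- function(td, t = 0, fl = 0, fp = 0, fn = 0) {
  td <- as.numeric(td)
  if (length(td) != N_POINTS || !all(is.finite(td)))
    stop("`td` must contain exactly 52 finite values")
  if (!is.finite(t) || t < 0) stop("`t` must be a nonnegative time in years")
  for (r in list(fl, fp, fn))
    if (!is.finite(r) || r < 0 || r > 100)
      stop("reliability indices must be percentages in [0, 100]")
  structure(list(td = td, t = as.numeric(t), fl = as.numeric(fl),
                 fp = as.numeric(fp), fn = as.numeric(fn)),
            class = "visual_field")
}

#' A longitudinal series of visual fields from one eye
#'
#' Stores the exams of one eye in a column-aligned form: an n x 52 matrix of
#' TD values plus parallel vectors of times and reliability indices. Exams
#' are sorted by time; times must be strictly increasing after sorting.
#'
#' @param eye_id Identifier for the eye (coerced to character).
#' @param t Numeric vector of exam times in years since baseline.
#' @param td Numeric matrix with one row per exam and 52 columns, or a list
#'   of [visual_field()] objects (in which case `t`, `fl`, `fp`, `fn` are
#'   taken from them).
#' @param fl,fp,fn Reliability percentages, recycled to the number of exams.
#' @return An object of class `vf_series` with elements `eye_id`, `t`,
#'   `td`, `fl`, `fp`, `fn`.
#' @export
vf_series <- function(eye_id, t = NULL, td = NULL, fl = 0, fp = 0, fn = 0) {
  if (is.list(td) && !is.matrix(td)) {
    fields <- td
    stopifnot(all(vapply(fields, inherits, logical(1), "visual_field")))
    t <- vapply(fields, `[[`, numeric(1), "t")
    fl <- vapply(fields, `[[`, numeric(1), "fl")
    fp <- vapply(fields, `[[`, numeric(1), "fp")
    fn <- vapply(fields, `[[`, numeric(1), "fn")
    td <- do.call(rbind, lapply(fields, `[[`, "td"))
  }
  td <- matrix(as.numeric(td), ncol = N_POINTS)
  n <- nrow(td)
  if (n < 1L) stop("a series needs at least one exam")
  if (length(t) != n) stop("`t` must have one entry per exam")
  if (!all(is.finite(td))) stop("TD values must all be finite")
  o <- order(t)
  t <- t[o]
  if (any(diff(t) <= 0))
    stop("exam times must be strictly increasing for eye ", eye_id)
  structure(list(eye_id = as.character(eye_id), t = t,
                 td = td[o, , drop = FALSE],
                 fl = rep_len(as.numeric(fl), n)[o],
                 fp = rep_len(as.numeric(fp), n)[o],
                 fn = rep_len(as.numeric(fn), n)[o]),
            class = "vf_series")
}

#' @export
length.vf_series <- function(x) nrow(x$td)

#' Extract one exam of a series as a `visual_field`
#'
#' @param series A [vf_series()].
#' @param i Exam index.
#' @return A [visual_field()].
#' @export
vf_exam <- function(series, i) {
  visual_field(series$td[i, ], t = series$t[i], fl = series$fl[i],
               fp = series$fp[i], fn = series$fn[i])
}

#' Truncate a series to its first k exams
#'
#' @param series A [vf_series()].
#' @param k Number of leading exams to keep (1 <= k <= length).
#' @return A [vf_series()] of length `k`.
#' @export
vf_truncate <- function(series, k) {
  if (k < 1L || k > length(series)) stop("`k` out of range")
  idx <- seq_len(k)
  vf_series(series$eye_id, series$t[idx], series$td[idx, , drop = FALSE],
            series$fl[idx], series$fp[idx], series$fn[idx])
}

#' A cohort of visual-field series
#'
#' @param series List of [vf_series()] objects with distinct eye ids.
#' @return An object of class `vf_cohort` (a named list of series).
#' @export
vf_cohort <- function(series) {
  stopifnot(all(vapply(series, inherits, logical(1), "vf_series")))
  ids <- vapply(series, `[[`, character(1), "eye_id")
  if (anyDuplicated(ids)) stop("duplicate eye ids in cohort")
  names(series) <- ids
  structure(series, class = "vf_cohort")
}

#' Mean total deviation (mTD)
#'
#' The arithmetic mean of the 52 total-deviation values of an exam, the
#' close analogue of the instrument's Mean Deviation index. For a series
#' (or an exam-by-point matrix) the mTD of every exam is returned.
#'
#' @param x A [visual_field()], a [vf_series()], a numeric vector of 52
#'   values, or a numeric matrix with 52 columns.
#' @return A single mTD in dB, or one per exam for series/matrix input.
#' @examples
#' compute_mtd(visual_field(rep(-5, 52)))  # -5
#' @export
compute_mtd <- function(x) {
  if (inherits(x, "visual_field")) x <- x$td
  if (inherits(x, "vf_series")) x <- x$td
  if (is.matrix(x)) {
    if (ncol(x) != N_POINTS) stop("matrix must have 52 columns")
    if (!all(is.finite(x))) stop("TD values must all be finite")
    return(rowMeans(x))
  }
  if (length(x) != N_POINTS) stop("`x` must have exactly 52 values")
  if (!all(is.finite(x))) stop("TD values must all be finite")
  mean(x)
}

#' Reliability criteria for exam inclusion
#'
#' Exams are retained when every index is strictly below its threshold
#' ("less than 33%" is the conventional rule for all three indices).
#'
#' @param max_fl,max_fp,max_fn Upper thresholds in percent, each in (0, 100].
#' @return An object of class `reliability_criteria`.
#' @export
reliability_criteria <- function(max_fl = 33, max_fp = 33, max_fn = 33) {
  for (v in c(max_fl, max_fp, max_fn))
    if (!is.finite(v) || v <= 0 || v > 100)
      stop("thresholds must lie in (0, 100]")
  structure(list(max_fl = max_fl, max_fp = max_fp, max_fn = max_fn),
            class = "reliability_criteria")
}

#' Filter a series to its reliable exams
#'
#' Keeps exams with fixation losses, false positives and false negatives
#' each strictly below the criteria thresholds; order is preserved. The
#' result may have zero exams.
#'
#' @param series A [vf_series()].
#' @param criteria A [reliability_criteria()].
#' @return A `vf_series` containing only the retained exams (the class is
#'   kept even when empty).
#' @export
filter_reliable <- function(series, criteria = reliability_criteria()) {
  stopifnot(inherits(series, "vf_series"))
  keep <- series$fl < criteria$max_fl & series$fp < criteria$max_fp &
    series$fn < criteria$max_fn
  out <- series
  out$t <- series$t[keep]
  out$td <- series$td[keep, , drop = FALSE]
  out$fl <- series$fl[keep]
  out$fp <- series$fp[keep]
  out$fn <- series$fn[keep]
  out
}

#' Reduce a 30-2 total-deviation field to the 24-2 points
#'
#' Keeps only the 52 test points of the 30-2 pattern that overlap the 24-2
#' pattern, returned in 24-2 printout order. The input is the 74-value TD
#' vector of a 30-2 exam (76 locations minus the two blind-spot points), in
#' 30-2 printout order.
#'
#' @param td30 Numeric vector of 74 TD values.
#' @return Numeric vector of 52 TD values in [vf_grid24()] order.
#' @export
reduce_30_2 <- function(td30) {
  if (length(td30) != 74L)
    stop("a 30-2 total-deviation field has 74 values, got ", length(td30))
  as.numeric(td30)[vf_overlap_30_to_24()]
}

#' Read a cohort from CSV
#'
#' The expected columns are `eye_id`, `t_years`, `td_01` .. `td_52`, `fl`,
#' `fp`, `fn` (header required, '.' decimal separator). Rows may appear in
#' any order; each eye's exams are sorted by `t_years`.
#'
#' @param path Path to the CSV file.
#' @return A [vf_cohort()].
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  td_cols <- sprintf("td_%02d", 1:52)
  need <- c("eye_id", "t_years", td_cols, "fl", "fp", "fn")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  num_cols <- setdiff(need, "eye_id")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column ", cl, " at data row ", bad[1])
      df[[cl]] <- conv
    }
  }
  key <- paste(df$eye_id, df$t_years)
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1]
    stop("duplicate (eye_id, t_years) at data row ", row)
  }
  series <- lapply(split(df, df$eye_id), function(d) {
    vf_series(d$eye_id[1], d$t_years,
              as.matrix(d[, td_cols]), d$fl, d$fp, d$fn)
  })
  vf_cohort(unname(series))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]; the write/read round trip reproduces all
#' numeric values to within 1e-9.
#'
#' @param cohort A [vf_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "vf_cohort"))
  rows <- lapply(cohort, function(s) {
    td <- as.data.frame(s$td)
    names(td) <- sprintf("td_%02d", 1:52)
    cbind(data.frame(eye_id = s$eye_id, t_years = s$t), td,
          data.frame(fl = s$fl, fp = s$fp, fn = s$fn))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.vf_series <- function(x, ...) {
  cat(sprintf("<vf_series> eye %s: %d exam(s) over %.2f years, mTD %s dB\n",
              x$eye_id, length(x), diff(range(x$t)),
              paste(sprintf("%.1f", compute_mtd(x)), collapse = ", ")))
  invisible(x)
}

#' @export
print.vf_cohort <- function(x, ...) {
  n_ex <- sum(vapply(x, length, integer(1)))
  cat(sprintf("<vf_cohort> %d eye(s), %d exam(s)\n", length(x), n_ex))
  invisible(x)
}
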