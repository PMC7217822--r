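test_that("the 24-2 and 30-2 grids have the standard layout", {
  g24 <- vf_grid24()
  g30 <- vf_grid30()
  expect_equal(nrow(g24), 52)
  expect_equal(nrow(g30), 74)
  # no blind-spot points, unique locations
  expect_false(any(g24$x == 15 & abs(g24$y) == 3))
  expect_false(any(g30$x == 15 & abs(g30$y) == 3))
  expect_false(anyDuplicated(paste(g24$x, g24$y)) > 0)
  # printout order: rows superior to inferior, x ascending within row
  expect_true(all(diff(g24$y) <= 0 | diff(g24$x) > 0))
  # every 24-2 point is a 30-2 point, at matching coordinates
  ov <- vf_overlap_30_to_24()
  expect_equal(g30$x[ov], g24$x)
  expect_equal(g30$y[ov], g24$y)
})

test_that("mirroring a left-eye field is an involution that flips x", {
  td <- rnorm(52)
  m <- mirror_eye(td)
  expect_equal(mirror_eye(m), td)
  g <- vf_grid24()
  # the value moved to (x, y) came from (-x, y) on the mirrored chart
  for (i in c(1, 10, 30, 52)) {
    j <- which(g$x == -g$x[i] & g$y == g$y[i])
    if (length(j) == 1) expect_equal(m[i], td[j])
  }
})

test_that("compute_mtd is the mean and is linear and permutation-invariant", {
  expect_equal(compute_mtd(visual_field(rep(-5, 52))), -5)
  expect_equal(compute_mtd(c(rep(0, 26), rep(-10, 26))), -5)
  set.seed(3)
  td <- rnorm(52, -8, 6)
  # independent summation loop
  acc <- 0
  for (v in td) acc <- acc + v
  expect_equal(compute_mtd(td), acc / 52)
  expect_equal(compute_mtd(td[sample(52)]), compute_mtd(td))
  a <- 2.5; b <- -1
  expect_equal(compute_mtd(a * td + b), a * compute_mtd(td) + b)
  expect_error(compute_mtd(c(td[-1], NA)), "finite")
  # matrix input gives one mTD per exam
  m <- rbind(td, 2 * td)
  expect_equal(compute_mtd(m), c(compute_mtd(td), 2 * compute_mtd(td)),
               ignore_attr = TRUE)
})

test_that("reliability filtering is strict, order-preserving and idempotent", {
  s <- vf_series("e", t = 0:9,
                 td = matrix(-1, 10, 52),
                 fl = c(33, 0, 60, 10, 32.9, 0, 0, 40, 5, 33.01),
                 fp = 0, fn = 0)
  f <- filter_reliable(s)
  # fl == 33 exactly is excluded ("less than 33%")
  expect_equal(f$t, c(1, 3, 4, 5, 6, 8))
  expect_equal(length(filter_reliable(f)), length(f))
  expect_identical(filter_reliable(f)$td, f$td)
  # brute-force count over random draws
  set.seed(11)
  fl <- runif(10, 0, 60)
  s2 <- vf_series("e2", 0:9, matrix(0, 10, 52), fl = fl)
  expect_equal(length(filter_reliable(s2)), sum(fl < 33))
  # zero-index exam retained
  s3 <- vf_series("e3", 0, matrix(0, 1, 52), fl = 0, fp = 0, fn = 0)
  expect_equal(length(filter_reliable(s3)), 1)
})

test_that("30-2 reduction selects exactly the 24-2 locations", {
  expect_equal(reduce_30_2(rep(-3, 74)), rep(-3, 52))
  expect_error(reduce_30_2(rep(0, 68)), "74")
  g30 <- vf_grid30()
  # marker at a 30-2-only location is absent from the output
  only30 <- which(abs(g30$y) == 27)[1]
  td30 <- rep(0, 74)
  td30[only30] <- 99
  expect_false(99 %in% reduce_30_2(td30))
  # independent mask via coordinate lookup
  set.seed(5)
  td30 <- rnorm(74)
  g24 <- vf_grid24()
  expected <- vapply(seq_len(52), function(i)
    td30[which(g30$x == g24$x[i] & g30$y == g24$y[i])], numeric(1))
  expect_equal(reduce_30_2(td30), expected)
  # embedding a 24-2 field and reducing recovers it
  td24 <- rnorm(52)
  td30b <- rep(-99, 74)
  td30b[vf_overlap_30_to_24()] <- td24
  expect_equal(reduce_30_2(td30b), td24)
})

test_that("cohort CSV round trip is lossless and robust to row order", {
  co <- fixture_cohort()$measured[1:3]
  co <- vf_cohort(co)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(names(back), names(co))
  for (id in names(co)) {
    expect_equal(back[[id]]$td, co[[id]]$td, tolerance = 1e-9)
    expect_equal(back[[id]]$t, co[[id]]$t, tolerance = 1e-9)
    expect_equal(back[[id]]$fl, co[[id]]$fl, tolerance = 1e-9)
  }
  # shuffle rows on disk: series come back sorted by time
  df <- utils::read.csv(path)
  set.seed(2)
  utils::write.csv(df[sample(nrow(df)), ], path, row.names = FALSE)
  back2 <- read_cohort_csv(path)
  expect_equal(back2[[names(co)[1]]]$td, co[[names(co)[1]]]$td,
               tolerance = 1e-9)

  # malformed inputs name the problem
  df51 <- df[, -which(names(df) == "td_52")]
  utils::write.csv(df51, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "td_52")
  df_dup <- rbind(df, df[1, ])
  utils::write.csv(df_dup, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "duplicate")
  df_bad <- df
  df_bad$fl[3] <- "oops"
  utils::write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "non-numeric")
})

test_that("series constructor validates and sorts", {
  expect_error(vf_series("e", c(0, 0), matrix(0, 2, 52)), "increasing")
  s <- vf_series("e", c(2, 0, 1), matrix(rep(c(3, 1, 2), 52), 3), fl = c(30, 10, 20))
  expect_equal(s$t, c(0, 1, 2))
  expect_equal(s$td[, 1], c(1, 2, 3))
  expect_equal(s$fl, c(10, 20, 30))
  expect_error(visual_field(rep(0, 51)), "52")
  expect_error(visual_field(rep(0, 52), t = -1), "nonnegative")
  expect_equal(length(vf_truncate(s, 2)), 2)
  expect_error(vf_truncate(s, 4), "range")
})
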