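test_that("dichotomization thresholds and bin rules are respected", {
  # everything slower than 1 mm/s is non-movement
  v <- make_speed(rep(0.5, 50))
  b <- dichotomize(v, c(0, 10))
  expect_equal(b$n_bins, 10L)
  expect_false(any(b$moving))
  # the threshold itself counts as movement; one sample suffices
  vv <- rep(0.2, 50); vv[13] <- 1.0
  b <- dichotomize(make_speed(vv), c(0, 10))
  expect_identical(which(b$moving), 3L)
  expect_error(dichotomize(v, c(0, 10), threshold = 0), "threshold")
})

test_that("dichotomization matches a per-bin max oracle", {
  set.seed(31)
  v <- make_speed(runif(600, 0, 2), valid = runif(600) > 0.1)
  b <- dichotomize(v, c(0, 120))
  prev <- FALSE
  for (k in 1:120) {
    in_bin <- v$t >= (k - 1) & v$t < k & v$valid
    want <- if (any(in_bin)) max(v$v[in_bin]) >= 1.0 else prev
    expect_identical(b$moving[k], want)
    prev <- want
  }
})

test_that("bins without valid samples inherit the previous state", {
  vv <- c(rep(3, 5), rep(3, 5), rep(0, 5))
  val <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5))
  b <- dichotomize(make_speed(vv, valid = val), c(0, 3))
  expect_identical(b$moving, c(TRUE, TRUE, FALSE))
  # a first bin with no valid sample defaults to non-movement
  b <- dichotomize(make_speed(rep(3, 10), valid = rep(FALSE, 10)), c(0, 2))
  expect_identical(b$moving, c(FALSE, FALSE))
})

test_that("sleep scoring implements the >= 6 s quiescence criterion", {
  mkbins <- function(moving) structure(
    list(bin_start_s = seq_along(moving) - 1, moving = moving,
         n_bins = length(moving)), class = "bin_record")
  b <- mkbins(c(TRUE, rep(FALSE, 6), TRUE, TRUE))
  sc <- score_sleep(b)
  expect_equal(nrow(sc$sleep), 1L)
  expect_equal(sc$sleep$duration_s, 6)
  # 5-bin quiescence stays wake
  sc <- score_sleep(mkbins(c(TRUE, rep(FALSE, 5), TRUE)))
  expect_equal(nrow(sc$sleep), 0L)
  expect_equal(sum(sc$wake$duration_s), 7)
  # a qualifying run truncated by the record end still counts
  sc <- score_sleep(mkbins(c(TRUE, rep(FALSE, 7))))
  expect_equal(sc$sleep$duration_s, 7)
  expect_error(score_sleep(mkbins(logical(0))), "empty")
})

test_that("sleep scoring agrees with run-length enumeration exhaustively", {
  # all binary records of length 10
  for (code in 0:(2^10 - 1)) {
    moving <- as.logical(bitwAnd(bitwShiftR(code, 0:9), 1L))
    bins <- structure(list(bin_start_s = 0:9, moving = moving,
                           n_bins = 10L), class = "bin_record")
    sc <- score_sleep(bins)
    expect_identical(bouts_to_bins(sc, 0, 10), sleep_oracle(moving))
    # tiling: sleep + wake durations cover the record exactly
    expect_equal(sum(sc$sleep$duration_s) + sum(sc$wake$duration_s), 10)
  }
})

test_that("raising the sleep criterion never increases the sleep ratio", {
  set.seed(32)
  for (rep in 1:20) {
    moving <- runif(200) < 0.3
    bins <- structure(list(bin_start_s = 0:199, moving = moving,
                           n_bins = 200L), class = "bin_record")
    ratios <- vapply(c(3, 6, 9, 12), function(m)
      sum(score_sleep(bins, min_sleep_s = m)$sleep$duration_s) / 200,
      numeric(1))
    expect_true(all(diff(ratios) <= 0))
  }
})

test_that("re-scoring the implied binary record is idempotent", {
  set.seed(33)
  moving <- runif(500) < 0.4
  bins <- structure(list(bin_start_s = 0:499, moving = moving,
                         n_bins = 500L), class = "bin_record")
  sc1 <- score_sleep(bins)
  # implied record: asleep bins non-moving, everything else moving
  implied <- structure(list(bin_start_s = 0:499,
                            moving = !bouts_to_bins(sc1, 0, 500),
                            n_bins = 500L), class = "bin_record")
  sc2 <- score_sleep(implied)
  expect_equal(sc1$sleep, sc2$sleep)
})

test_that("the onset-offset sensitivity mode shifts sleep by 6 s", {
  moving <- c(TRUE, rep(FALSE, 10), TRUE)
  bins <- structure(list(bin_start_s = 0:11, moving = moving,
                         n_bins = 12L), class = "bin_record")
  sc <- score_sleep(bins, onset_offset = 6L)
  expect_equal(sc$sleep$start_s, 7)
  expect_equal(sc$sleep$duration_s, 4)
})

test_that("sleep endpoints follow their definitions", {
  # asleep the whole 10-h night
  bins <- structure(list(bin_start_s = 0:35999, moving = rep(FALSE, 36000),
                         n_bins = 36000L), class = "bin_record")
  m <- sleep_metrics(score_sleep(bins), c(0, 36000))
  expect_equal(m$sleep_ratio, 1.0)
  expect_equal(m$sleep_latency_s, 0)
  expect_equal(m$fragmentation_per_h, 0.1)   # one onset over 10 h
  expect_true(is.na(m$wake_bout_duration_s))

  # alternating 18 s sleep / 12 s wake
  moving <- rep(c(rep(FALSE, 18), rep(TRUE, 12)), 1200)
  bins <- structure(list(bin_start_s = seq_along(moving) - 1,
                         moving = moving, n_bins = length(moving)),
                    class = "bin_record")
  m <- sleep_metrics(score_sleep(bins), c(0, 36000))
  expect_equal(m$sleep_ratio, 0.6)
  expect_equal(m$fragmentation_per_h, 120)   # onsets only, not 240
  expect_equal(m$sleep_bout_duration_s, 18)
  expect_equal(m$wake_bout_duration_s, 12)
  expect_equal(m$sleep_latency_s, 0)
})

test_that("sleep_assay runs end to end on a synthetic night", {
  set.seed(34)
  g <- synth_group(dropout_prob = 0)
  tr <- simulate_larva(g, night_only_schedule(3600),
                       list(well_radius_mm = 8), "s1", "control")
  m <- sleep_assay(tr, night_only_schedule(3600))
  expect_s3_class(m, "sleep_metrics")
  expect_gte(m$sleep_ratio, 0)
  expect_lte(m$sleep_ratio, 1)
  expect_gte(m$sleep_bout_duration_s, 6)
  expect_error(sleep_assay(tr, on_only_schedule(600)), "night")
})
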