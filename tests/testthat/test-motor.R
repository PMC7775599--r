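test_that("hysteresis segmentation follows the 2/1 mm/s state machine", {
  v <- make_speed(c(0, 0, 3, 3, 3, 0, 0))
  b <- segment_movement_bouts(v, c(0, 1.4))
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_s, 0.6)

  # never exceeds the 2 mm/s initiation threshold: no bout
  v <- make_speed(c(0, 1.5, 1.5, 0))
  expect_equal(nrow(segment_movement_bouts(v, c(0, 0.8))), 0L)

  # intermediate speeds hold the moving state (hysteresis)
  v <- make_speed(c(3, 1.5, 1.5, 3, 0.5))
  b <- segment_movement_bouts(v, c(0, 1.0))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start_s, b$end_s), c(0, 0.8))

  # boundary samples keep state: initiation strict >2, cessation strict <1
  v <- make_speed(c(0, 2.0, 2.0, 0))
  expect_equal(nrow(segment_movement_bouts(v, c(0, 0.8))), 0L)
  v <- make_speed(c(3, 1.0, 1.0, 0.5))
  b <- segment_movement_bouts(v, c(0, 0.8))
  expect_equal(b$end_s, 0.6)

  # a bout open at the window end is closed at the window end
  v <- make_speed(c(0, 3, 3))
  b <- segment_movement_bouts(v, c(0, 0.6))
  expect_equal(c(b$start_s, b$end_s), c(0.2, 0.6))

  expect_error(segment_movement_bouts(v, c(0, 0.6), high = 1, low = 1),
               "exceed")
})

test_that("long untracked runs terminate a bout at the last valid sample", {
  # 6 invalid samples = 1.2 s > 1 s: bout ends at last valid sample (t=0.4)
  v <- make_speed(c(0, 3, 3, rep(3, 6), 3, 3, 0),
                  valid = c(TRUE, TRUE, TRUE, rep(FALSE, 6), TRUE, TRUE,
                            TRUE))
  b <- segment_movement_bouts(v, c(0, 2.4))
  expect_equal(nrow(b), 2L)                 # second bout after the gap
  expect_equal(b$end_s[1], 0.4)
  # 5 invalid samples = 1.0 s (not > 1 s): the state is held through
  v <- make_speed(c(0, 3, 3, rep(3, 5), 3, 3, 0),
                  valid = c(TRUE, TRUE, TRUE, rep(FALSE, 5), TRUE, TRUE,
                            TRUE))
  b <- segment_movement_bouts(v, c(0, 2.2))
  expect_equal(nrow(b), 1L)
  expect_equal(b$end_s, 2.0)
})

test_that("segmentation agrees with the brute-force oracle on random series", {
  set.seed(21)
  for (rep in 1:300) {
    n <- sample(5:40, 1)
    v <- make_speed(sample(c(0, 0.5, 1, 1.5, 2, 3), n, replace = TRUE),
                    valid = runif(n) > 0.25)
    w <- c(0, n * 0.2)
    got <- segment_movement_bouts(v, w)
    want <- bout_oracle(v, w)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
  }
})

test_that("raising the initiation threshold never increases bout count", {
  set.seed(22)
  for (rep in 1:40) {
    v <- make_speed(runif(60, 0, 5))
    w <- c(0, 12)
    n1 <- nrow(segment_movement_bouts(v, w, high = 2))
    n2 <- nrow(segment_movement_bouts(v, w, high = 3))
    expect_lte(n2, n1)
  }
})

test_that("phase metrics are consistent arithmetic over the bout list", {
  # 10 bouts of 2 s (10 samples at 3 mm/s) separated by rest
  pat <- rep(c(rep(3, 10), rep(0, 10)), 10)
  v <- make_speed(pat)
  tr <- make_speed_traj(pat)
  w <- c(0, length(pat) * 0.2)
  m <- phase_metrics(tr, w)
  expect_equal(m$frequency, 10L)
  expect_equal(m$cumulative_time_s, 20)
  expect_equal(m$bout_duration_s, 2.0)
  # cumulative movement time can never exceed the phase duration
  expect_lte(m$cumulative_time_s, w[2] - w[1])
  # no movement at all: frequency 0, undefined bout duration
  still <- make_speed_traj(rep(0.3, 100))
  m0 <- phase_metrics(still, c(0, 20))
  expect_equal(m0$frequency, 0L)
  expect_equal(m0$cumulative_time_s, 0)
  expect_true(is.na(m0$bout_duration_s))
})

test_that("measured bout frequency matches the generative Poisson rate", {
  sch <- on_only_schedule(1800)
  g <- synth_group(bout_rate_on = 0.5, bout_duration_mean_s = 2,
                   dropout_prob = 0)
  set.seed(23)
  freq <- vapply(1:200, function(i) {
    tr <- simulate_larva(g, sch, list(well_radius_mm = 8), "p", "g")
    phase_metrics(tr, c(0, 1800))$frequency
  }, numeric(1))
  lambda <- 0.5 / 60 * 1800               # expected bouts per phase
  # mean within 3 SE of the Poisson mean (small merging bias tolerated)
  expect_lt(abs(mean(freq) - lambda), 3 * sd(freq) / sqrt(200) + 0.4)
})

test_that("motor_metrics averages the five lights-on phases", {
  sch <- default_schedule(gap_s = 0, night_s = 600, phase_s = 60)
  # piecewise speed: k bouts (5 samples at 3 mm/s) in the k-th ON phase
  n <- (10 * 60 + 600) * 5
  vprof <- numeric(n - 1)
  on_rows <- which(sch$role == "photomotor" & sch$light == "on")
  for (k in seq_along(on_rows)) {
    i0 <- sch$start_s[on_rows[k]] * 5
    for (b in seq_len(k))
      vprof[i0 + (b - 1) * 10 + seq_len(5)] <- 3
  }
  tr <- make_speed_traj(vprof)
  m <- motor_metrics(tr, sch)
  expect_equal(m$mean_frequency, mean(1:5))
  expect_equal(m$mean_cumulative_time_s, mean((1:5) * 1.0))
  # distances per phase scale with bout count; mean equals their average
  expect_equal(m$mean_distance_mm, mean((1:5) * 5 * 3 * 0.2),
               tolerance = 1e-12)
  expect_error(motor_metrics(tr, sch[sch$light == "off" |
                                       sch$role != "photomotor", ]),
               "0 lights-on")
})

test_that("identical phases give a mean equal to any single phase", {
  pat <- rep(c(rep(3, 10), rep(0, 20)), 10)  # one 60-s phase pattern
  vprof <- rep(c(pat, rep(0, 300)), 5)       # ON phase + OFF phase, 5 times
  sch <- phase_schedule(seq(0, by = 60, length.out = 10),
                        seq(60, by = 60, length.out = 10),
                        rep(c("on", "off"), 5), rep("photomotor", 10))
  tr <- make_speed_traj(vprof)
  m <- motor_metrics(tr, sch)
  p1 <- phase_metrics(tr, c(0, 60))
  expect_equal(m$mean_frequency, p1$frequency)
  expect_equal(m$mean_cumulative_time_s, p1$cumulative_time_s)
  expect_equal(m$mean_bout_duration_s, p1$bout_duration_s)
})
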