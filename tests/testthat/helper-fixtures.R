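# fixture builders and independent oracles used across the suite

make_speed <- function(v, valid = rep(TRUE, length(v)), dt = 0.2, t0 = 0) {
  structure(list(t = t0 + (seq_along(v) - 1) * dt, v = as.numeric(v),
                 valid = valid, dt = dt), class = "speed_series")
}

make_traj <- function(x, y, tracked = rep(TRUE, length(x)), dt = 0.2,
                      well_radius = 8, id = "f1", group = "control",
                      t0 = 0) {
  larva_trajectory(id, t0 + (seq_along(x) - 1) * dt, x, y, tracked,
                   well_radius = well_radius, group = group)
}

# x zig-zags between +/-3 mm so any per-sample speed profile is realized
# exactly (every displacement is v*dt along the x axis)
make_speed_traj <- function(v_per_sample, dt = 0.2, well_radius = 8, ...) {
  n <- length(v_per_sample) + 1L
  x <- numeric(n); dir <- 1
  for (i in 2:n) {
    stp <- v_per_sample[i - 1L] * dt
    if (abs(x[i - 1L] + dir * stp) > 3) dir <- -dir
    x[i] <- x[i - 1L] + dir * stp
  }
  make_traj(x, numeric(n), dt = dt, well_radius = well_radius, ...)
}

# literal per-sample simulation of the bout-segmentation state machine
bout_oracle <- function(v, window, high = 2, low = 1, max_gap_s = 1) {
  idx <- which(v$t >= window[1] & v$t < window[2])
  tt <- v$t[idx]; vv <- v$v[idx]; val <- v$valid[idx]; dt <- v$dt
  n <- length(tt)
  state <- 0; cur <- NA; bs <- be <- numeric(0)
  i <- 1
  while (i <= n) {
    if (!val[i]) {
      len <- 0
      while (i + len <= n && !val[i + len]) len <- len + 1
      if (len * dt > max_gap_s && state == 1) {
        j <- i - 1                      # last valid sample before the run
        end_t <- if (j > cur) tt[j] else tt[cur] + dt
        bs <- c(bs, tt[cur]); be <- c(be, end_t)
        state <- 0
      }
      i <- i + len
    } else {
      if (state == 0 && vv[i] > high) { state <- 1; cur <- i }
      else if (state == 1 && vv[i] < low) {
        bs <- c(bs, tt[cur]); be <- c(be, tt[i]); state <- 0
      }
      i <- i + 1
    }
  }
  if (state == 1) {
    bs <- c(bs, tt[cur]); be <- c(be, min(window[2], tt[n] + dt))
  }
  data.frame(start_s = bs, end_s = be)
}

# run-length enumeration oracle for sleep scoring: per-bin asleep states
sleep_oracle <- function(moving, min_sleep = 6) {
  n <- length(moving); asleep <- logical(n)
  i <- 1
  while (i <= n) {
    if (!moving[i]) {
      j <- i
      while (j < n && !moving[j + 1]) j <- j + 1
      if (j - i + 1 >= min_sleep) asleep[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  asleep
}

# convert score_sleep bout lists back to per-bin asleep states
bouts_to_bins <- function(bouts, t0, n_bins) {
  asleep <- logical(n_bins)
  for (k in seq_len(nrow(bouts$sleep))) {
    i0 <- round(bouts$sleep$start_s[k] - t0) + 1L
    asleep[i0:(i0 + bouts$sleep$duration_s[k] - 1L)] <- TRUE
  }
  asleep
}

night_only_schedule <- function(night_s) {
  phase_schedule(0, night_s, "off", "night")
}

on_only_schedule <- function(phase_s, n = 1L) {
  phase_schedule((seq_len(n) - 1) * phase_s, seq_len(n) * phase_s,
                 rep("on", n), rep("photomotor", n))
}
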