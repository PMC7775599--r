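#' Segment movement bouts with a two-threshold hysteresis rule
#'
#' A two-state machine runs over the valid speed samples of the window:
#' starting from NOT_MOVING, movement initiates at the first sample whose
#' speed strictly exceeds `high` (2 mm/s); from MOVING, movement ceases at
#' the first sample whose speed drops strictly below `low` (1 mm/s) -- that
#' sample is not part of the bout. Samples with `low <= v <= high` keep the
#' current state (hysteresis). A bout still open at the window end is closed
#' at the window end. Untracked samples hold the state, but a run of
#' untracked samples longer than `max_gap_s` terminates an open bout at its
#' last valid sample and resets the state (avoids phantom long bouts under
#' tracking dropout).
#'
#' @param v a [speed] series.
#' @param window half-open analysis window `c(start_s, end_s)`.
#' @param high initiation threshold, mm/s (strict `>`).
#' @param low cessation threshold, mm/s (strict `<`).
#' @param max_gap_s longest untracked run (seconds) an open bout survives.
#' @return data.frame of class `movement_bouts` with columns
#'   `start_s, end_s, duration_s, distance_mm`; zero rows if no bout.
#' @export
segment_movement_bouts <- function(v, window, high = 2.0, low = 1.0,
                                   max_gap_s = 1.0) {
  if (high <= low)
    stop("initiation threshold (", high,
         ") must exceed cessation threshold (", low, ")", call. = FALSE)
  check_window(window, v$t)
  idx <- window_idx(v$t, window)
  if (!length(idx)) return(new_movement_bouts(numeric(0), numeric(0),
                                              numeric(0)))
  tt <- v$t[idx]; vv <- v$v[idx]; val <- v$valid[idx]; dt <- v$dt
  n <- length(tt)

  ev <- integer(n)                      # +1 enter, -1 exit, -2 long gap
  ev[val & vv > high] <- 1L
  ev[val & vv < low] <- -1L
  gap <- rle(!val)
  if (any(gap$values & gap$lengths * dt > max_gap_s)) {
    ends <- cumsum(gap$lengths)
    starts <- ends - gap$lengths + 1L
    long <- which(gap$values & gap$lengths * dt > max_gap_s)
    ev[starts[long]] <- -2L
  }
  last_valid <- cummax(seq_len(n) * val)
  step <- ifelse(val, vv, 0) * dt
  cdist <- cumsum(step)

  epos <- which(ev != 0L)
  nb <- 0L
  bs <- be <- dist <- numeric(length(epos) %/% 2L + 1L)
  state <- 0L; cur <- NA_integer_
  close_bout <- function(end_t, i_excl) {
    nb <<- nb + 1L
    bs[nb] <<- tt[cur]; be[nb] <<- end_t
    dist[nb] <<- cdist[max(i_excl - 1L, cur)] - cdist[cur] + step[cur]
  }
  for (i in epos) {
    e <- ev[i]
    if (state == 0L) {
      if (e == 1L) { state <- 1L; cur <- i }
    } else if (e == -1L) {
      close_bout(tt[i], i); state <- 0L
    } else if (e == -2L) {               # long untracked run while moving
      j <- last_valid[i]                 # >= cur since the bout is open
      end_t <- if (j > cur) tt[j] else tt[cur] + dt
      close_bout(end_t, max(j, cur + 1L)); state <- 0L
    }
  }
  if (state == 1L)
    close_bout(min(window[2], tt[n] + dt), n + 1L)
  length(bs) <- length(be) <- length(dist) <- nb
  new_movement_bouts(bs, be, dist)
}

new_movement_bouts <- function(start_s, end_s, distance_mm) {
  structure(list(start_s = start_s, end_s = end_s,
                 duration_s = end_s - start_s, distance_mm = distance_mm),
            row.names = .set_row_names(length(start_s)),
            class = c("movement_bouts", "data.frame"))
}

#' Photomotor endpoints of one 30-min phase
#'
#' @param traj a [larva_trajectory].
#' @param window the phase window `c(start_s, end_s)`.
#' @param v optional precomputed [speed] series.
#' @param high,low hysteresis thresholds, mm/s.
#' @return list: `distance_mm` (path distance over the phase), `frequency`
#'   (number of movement bouts), `cumulative_time_s` (summed bout
#'   durations), `bout_duration_s` (cumulative time / frequency; `NA` for a
#'   phase with no bout).
#' @export
phase_metrics <- function(traj, window, v = NULL, high = 2.0, low = 1.0) {
  if (is.null(v)) v <- speed(traj)
  bouts <- segment_movement_bouts(v, window, high = high, low = low)
  freq <- nrow(bouts)
  cum <- sum(bouts$duration_s)
  list(distance_mm = path_distance(traj, window, v = v),
       frequency = freq,
       cumulative_time_s = cum,
       bout_duration_s = if (freq == 0L) NA_real_ else cum / freq)
}

#' Per-larva photomotor endpoints over the five lights-on phases
#'
#' Each endpoint is the unweighted mean over the five lights-on photomotor
#' phases; phases with no bout contribute nothing to the bout-duration mean.
#' Mean speeds are additionally reported for lights-on and lights-off
#' phases (over all valid samples).
#'
#' @param traj a [larva_trajectory].
#' @param schedule a [phase_schedule]; must contain `required_phases`
#'   lights-on photomotor phases.
#' @param v optional precomputed [speed] series.
#' @param high,low hysteresis thresholds, mm/s.
#' @param required_phases number of lights-on phases the design requires
#'   (study design: 5).
#' @return list of class `motor_metrics`: `mean_distance_mm`,
#'   `mean_frequency`, `mean_cumulative_time_s`, `mean_bout_duration_s`,
#'   `mean_speed_on_mms`, `mean_speed_off_mms`.
#' @export
motor_metrics <- function(traj, schedule, v = NULL, high = 2.0, low = 1.0,
                          required_phases = 5L) {
  on <- schedule[schedule$role == "photomotor" & schedule$light == "on", ]
  if (nrow(on) < required_phases)
    stop("schedule holds ", nrow(on), " lights-on photomotor phase(s); ",
         required_phases, " required", call. = FALSE)
  off <- schedule[schedule$role == "photomotor" & schedule$light == "off", ]
  if (is.null(v)) v <- speed(traj)
  per <- lapply(seq_len(nrow(on)), function(i)
    phase_metrics(traj, c(on$start_s[i], on$end_s[i]), v = v,
                  high = high, low = low))
  grab <- function(f) vapply(per, `[[`, numeric(1), f)
  bd <- grab("bout_duration_s")
  spd_on <- vapply(seq_len(nrow(on)), function(i)
    mean_speed(traj, c(on$start_s[i], on$end_s[i]), v = v), numeric(1))
  spd_off <- if (nrow(off)) vapply(seq_len(nrow(off)), function(i)
    mean_speed(traj, c(off$start_s[i], off$end_s[i]), v = v), numeric(1))
    else NA_real_
  out <- list(mean_distance_mm = mean(grab("distance_mm")),
              mean_frequency = mean(grab("frequency")),
              mean_cumulative_time_s = mean(grab("cumulative_time_s")),
              mean_bout_duration_s = if (all(is.na(bd))) NA_real_
                                     else mean(bd, na.rm = TRUE),
              mean_speed_on_mms = mean(spd_on, na.rm = TRUE),
              mean_speed_off_mms = mean(spd_off, na.rm = TRUE))
  class(out) <- "motor_metrics"
  out
}

#' @export
print.motor_metrics <- function(x, ...) {
  cat("Photomotor endpoints (mean over lights-on phases)\n")
  cat(sprintf("  distance:        %8.1f mm\n", x$mean_distance_mm))
  cat(sprintf("  frequency:       %8.1f bouts/phase\n", x$mean_frequency))
  cat(sprintf("  cumulative time: %8.1f s\n", x$mean_cumulative_time_s))
  cat(sprintf("  bout duration:   %8.2f s\n", x$mean_bout_duration_s))
  cat(sprintf("  speed on/off:    %8.3f / %.3f mm/s\n",
              x$mean_speed_on_mms, x$mean_speed_off_mms))
  invisible(x)
}
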