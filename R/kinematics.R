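#' Per-sample speed of a trajectory
#'
#' Speed is the sampled displacement rate,
#' `v[i] = sqrt((x[i]-x[i-1])^2 + (y[i]-y[i-1])^2) / dt`. A speed sample is
#' valid only when both endpoints of the displacement were tracked; the first
#' sample is invalid by construction. Positions are differenced as recorded
#' (no smoothing); an optional centered moving average of window 3 can be
#' applied to the positions first for sensitivity analysis.
#'
#' @param traj a [larva_trajectory].
#' @param smooth if `TRUE`, apply a centered moving average of window 3 to
#'   x and y before differencing (default off).
#' @return object of class `speed_series`: list with `t` (s), `v` (mm/s) and
#'   `valid` (logical), all of the trajectory's length.
#' @export
speed <- function(traj, smooth = FALSE) {
  n <- length(traj$t)
  if (n < 2L) stop("trajectory of length < 2 has no speed", call. = FALSE)
  dt <- traj$t[2] - traj$t[1]
  x <- traj$x; y <- traj$y
  if (smooth) {
    ma3 <- function(z) {
      s <- z
      s[2:(n - 1)] <- (z[1:(n - 2)] + z[2:(n - 1)] + z[3:n]) / 3
      s
    }
    x <- ma3(x); y <- ma3(y)
  }
  v <- c(NA_real_, sqrt(diff(x)^2 + diff(y)^2) / dt)
  valid <- c(FALSE, traj$tracked[-1] & traj$tracked[-n])
  v[!valid] <- NA_real_
  structure(list(t = traj$t, v = v, valid = valid, dt = dt),
            class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf("<speed_series: %d samples, dt = %g s, %.1f%% valid, mean %.3g mm/s>\n",
              length(x$t), x$dt, 100 * mean(x$valid),
              mean(x$v[x$valid])))
  invisible(x)
}

#' Path distance swum within a window
#'
#' Sum of valid inter-sample displacements whose later endpoint lies in the
#' half-open window; steps bridging an untracked sample contribute 0, so the
#' distance is a lower bound under tracking dropout.
#'
#' @param traj a [larva_trajectory].
#' @param window `c(start_s, end_s)`; default the whole recording.
#' @param v optionally a precomputed [speed] series (avoids recomputation).
#' @return distance in mm.
#' @export
path_distance <- function(traj, window = NULL, v = NULL) {
  if (is.null(v)) v <- speed(traj)
  idx <- if (is.null(window)) seq_along(v$t) else {
    check_window(window, v$t)
    window_idx(v$t, window)
  }
  ok <- idx[v$valid[idx]]
  if (!length(ok)) return(0)
  sum(v$v[ok]) * v$dt
}

#' Mean speed within a window
#'
#' Arithmetic mean of the per-sample speed over valid samples in the
#' half-open window; `NA` if the window holds no valid speed sample.
#'
#' @inheritParams path_distance
#' @return mm/s, or `NA_real_` if undefined.
#' @export
mean_speed <- function(traj, window = NULL, v = NULL) {
  if (is.null(v)) v <- speed(traj)
  idx <- if (is.null(window)) seq_along(v$t) else {
    check_window(window, v$t)
    window_idx(v$t, window)
  }
  ok <- idx[v$valid[idx]]
  if (!length(ok)) return(NA_real_)
  mean(v$v[ok])
}
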