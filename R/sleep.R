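#' Dichotomize night behavior into 1-s movement bins
#'
#' The night is cut into contiguous half-open 1-s bins `[k, k+1)`. A bin is
#' scored as movement when any valid speed sample in it reaches the movement
#' threshold (`v >= threshold`; the threshold itself counts as movement since
#' only behavior *slower* than it is non-movement). A bin containing no
#' valid sample inherits the previous bin's state (the first bin defaults to
#' non-movement); tracking dropout therefore never fragments quiescence.
#'
#' @param v a [speed] series.
#' @param window the night window `c(start_s, end_s)`.
#' @param threshold movement threshold, mm/s (default 1.0).
#' @return object of class `bin_record`: list with `bin_start_s` (absolute
#'   start time of each bin), `moving` (logical) and `n_bins`.
#' @export
dichotomize <- function(v, window, threshold = 1.0) {
  if (threshold <= 0) stop("movement threshold must be > 0", call. = FALSE)
  check_window(window, v$t)
  n_bins <- floor(window[2] - window[1])
  if (n_bins < 1L) stop("window shorter than one 1-s bin", call. = FALSE)
  idx <- window_idx(v$t, c(window[1], window[1] + n_bins))
  bin <- floor(v$t[idx] - window[1]) + 1L         # 1-based bin id
  val <- v$valid[idx]
  mv <- val & v$v[idx] >= threshold
  has_valid <- tabulate(bin[val], nbins = n_bins) > 0L
  moving_raw <- tabulate(bin[mv], nbins = n_bins) > 0L
  src <- cummax(ifelse(has_valid, seq_len(n_bins), 0L))
  moving <- ifelse(src == 0L, FALSE, moving_raw[pmax(src, 1L)])
  structure(list(bin_start_s = window[1] + seq_len(n_bins) - 1,
                 moving = moving, n_bins = n_bins),
            class = "bin_record")
}

#' @export
print.bin_record <- function(x, ...) {
  cat(sprintf("<bin_record: %d 1-s bins from t = %g s, %.1f%% moving>\n",
              x$n_bins, x$bin_start_s[1], 100 * mean(x$moving)))
  invisible(x)
}

#' Score sleep and wake bouts from a dichotomized record
#'
#' A maximal run of `min_sleep_s` (default 6) or more consecutive
#' non-movement bins is a sleep bout spanning the entire run; everything
#' else (movement bins and shorter quiescence runs) merges into wake bouts.
#' The two bout lists tile the record exactly. The alternative reading of
#' the criterion -- the first seconds of every qualifying quiescence run
#' scored awake, sleep only from the following second -- is available for
#' sensitivity analysis via `onset_offset` (e.g. 6: sleep starts at the
#' seventh quiescent second).
#'
#' @param bins a [dichotomize] record.
#' @param min_sleep_s minimum quiescence run length counted as sleep, s.
#' @param onset_offset leading seconds of each qualifying quiescence run to
#'   score as wake (default 0: the whole run is sleep).
#' @return list with `sleep` and `wake`, each a data.frame
#'   `start_s, duration_s`, jointly tiling the record.
#' @export
score_sleep <- function(bins, min_sleep_s = 6L, onset_offset = 0L) {
  if (min_sleep_s < 1L) stop("min_sleep_s must be >= 1", call. = FALSE)
  if (is.null(bins$moving) || bins$n_bins < 1L)
    stop("empty bin record", call. = FALSE)
  r <- rle(bins$moving)
  len <- r$lengths
  ends <- cumsum(len); starts <- ends - len + 1L
  asleep <- logical(bins$n_bins)
  for (k in which(!r$values & len >= pmax(min_sleep_s, onset_offset + 1L))) {
    asleep[(starts[k] + onset_offset):ends[k]] <- TRUE
  }
  s <- rle(asleep)
  sl <- cumsum(s$lengths); ss <- sl - s$lengths + 1L
  t0 <- bins$bin_start_s[1]
  mk <- function(sel) data.frame(start_s = t0 + ss[sel] - 1,
                                 duration_s = as.numeric(s$lengths[sel]))
  list(sleep = mk(s$values), wake = mk(!s$values))
}

#' Per-larva sleep endpoints for one night
#'
#' Fragmentation counts sleep-bout onsets per hour of night (one-direction
#' transition count); the sleep ratio is the fraction of the night scored
#' asleep; latency is the time from lights-off to the first sleep-bout
#' onset (`NA` if the larva never sleeps); bout durations are arithmetic
#' means of the respective lists (`NA` when a list is empty); night speed is
#' the mean speed over all valid night samples.
#'
#' @param bouts a [score_sleep] result.
#' @param window the night window `c(start_s, end_s)`.
#' @param v optional [speed] series for `night_speed_mms` (`NA` if absent).
#' @return list of class `sleep_metrics`: `fragmentation_per_h`,
#'   `sleep_ratio`, `sleep_latency_s`, `night_speed_mms`,
#'   `wake_bout_duration_s`, `sleep_bout_duration_s`, `n_sleep_bouts`,
#'   `n_wake_bouts`.
#' @export
sleep_metrics <- function(bouts, window, v = NULL) {
  night_s <- window[2] - window[1]
  ns <- nrow(bouts$sleep)
  out <- list(
    fragmentation_per_h = ns / (night_s / 3600),
    sleep_ratio = sum(bouts$sleep$duration_s) / night_s,
    sleep_latency_s = if (ns) bouts$sleep$start_s[1] - window[1] else NA_real_,
    night_speed_mms = if (is.null(v)) NA_real_ else {
      idx <- window_idx(v$t, window)
      ok <- idx[v$valid[idx]]
      if (length(ok)) mean(v$v[ok]) else NA_real_
    },
    wake_bout_duration_s = if (nrow(bouts$wake))
      mean(bouts$wake$duration_s) else NA_real_,
    sleep_bout_duration_s = if (ns) mean(bouts$sleep$duration_s) else NA_real_,
    n_sleep_bouts = ns, n_wake_bouts = nrow(bouts$wake))
  class(out) <- "sleep_metrics"
  out
}

#' Full sleep assay for one larva
#'
#' Convenience wrapper: selects the night window from the schedule,
#' dichotomizes, scores sleep and computes the endpoints.
#'
#' @param traj a [larva_trajectory].
#' @param schedule a [phase_schedule] containing a night interval.
#' @param threshold movement threshold, mm/s.
#' @param min_sleep_s,onset_offset see [score_sleep].
#' @param v optional precomputed [speed] series.
#' @return a [sleep_metrics] object.
#' @export
sleep_assay <- function(traj, schedule, threshold = 1.0, min_sleep_s = 6L,
                        onset_offset = 0L, v = NULL) {
  night <- schedule[schedule$role == "night", ]
  if (nrow(night) != 1L)
    stop("schedule lacks a night window", call. = FALSE)
  w <- c(night$start_s, night$end_s)
  if (is.null(v)) v <- speed(traj)
  bins <- dichotomize(v, w, threshold = threshold)
  bouts <- score_sleep(bins, min_sleep_s = min_sleep_s,
                       onset_offset = onset_offset)
  sleep_metrics(bouts, w, v = v)
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat("Sleep endpoints (one night)\n")
  cat(sprintf("  fragmentation: %7.1f sleep-bout onsets/h\n",
              x$fragmentation_per_h))
  cat(sprintf("  sleep ratio:   %7.3f\n", x$sleep_ratio))
  cat(sprintf("  latency:       %7.1f s\n", x$sleep_latency_s))
  cat(sprintf("  night speed:   %7.3f mm/s\n", x$night_speed_mms))
  cat(sprintf("  wake bout:     %7.2f s   sleep bout: %7.2f s\n",
              x$wake_bout_duration_s, x$sleep_bout_duration_s))
  invisible(x)
}
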