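#' Construct a single-larva trajectory
#'
#' A trajectory is one larva's timestamped 2D path in well-centered
#' coordinates (origin at the well center, mm), sampled uniformly at 5 Hz,
#' together with a per-sample tracking mask. Samples where the tracker lost
#' the larva are retained with `tracked = FALSE`; they are never interpolated
#' at I/O time -- downstream modules decide how to treat them.
#'
#' @param subject_id character scalar identifying the larva.
#' @param t numeric vector of seconds since recording start; must be strictly
#'   increasing with constant step (default 0.2 s, tolerance 1e-9).
#' @param x,y numeric positions in mm, well-centered.
#' @param tracked logical vector; `FALSE` where the tracker lost the larva.
#' @param well_radius well radius in mm. Tracked samples must satisfy
#'   `sqrt(x^2 + y^2) <= well_radius + 0.5` (0.5 mm tracking tolerance).
#' @param group group label string (e.g. `"control"`, `"MPP+"`).
#' @return an object of class `larva_trajectory`.
#' @export
larva_trajectory <- function(subject_id, t, x, y, tracked = NULL,
                             well_radius, group = NA_character_) {
  n <- length(t)
  if (n < 2L) stop("trajectory needs at least 2 samples", call. = FALSE)
  if (is.null(tracked)) tracked <- rep(TRUE, n)
  tracked <- as.logical(tracked)
  stopifnot(length(x) == n, length(y) == n, length(tracked) == n)
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  bad <- which(abs(dt - dt[1]) > 1e-9)
  if (length(bad))
    stop(sprintf(
      "non-uniform sampling for subject '%s': step of %.6g s (expected %.6g s) at t = %s",
      subject_id, dt[bad[1]], dt[1],
      paste(signif(t[bad[1] + 1L], 10), collapse = ", ")), call. = FALSE)
  r <- sqrt(x^2 + y^2)
  out <- which(tracked & r > well_radius + 0.5)
  if (length(out))
    stop(sprintf(
      "subject '%s': %d tracked sample(s) outside the well (first at t = %g s, r = %.3f mm > %.3f mm)",
      subject_id, length(out), t[out[1]], r[out[1]], well_radius + 0.5),
      call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), group = group,
         t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         tracked = tracked, well_radius = well_radius),
    class = "larva_trajectory")
}

#' @export
print.larva_trajectory <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1] + (x$t[2] - x$t[1])
  cat(sprintf(
    "<larva_trajectory '%s'%s: %d samples @ %.1f Hz, %.0f s, tracked %.1f%%, well radius %g mm>\n",
    x$subject_id,
    if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    length(x$t), 1 / (x$t[2] - x$t[1]), dur,
    100 * mean(x$tracked), x$well_radius))
  invisible(x)
}

#' Tracked fraction of a trajectory within a window
#' @param traj a `larva_trajectory`.
#' @param window `c(start_s, end_s)` half-open; default the whole recording.
#' @return fraction in \[0, 1\].
#' @export
tracked_fraction <- function(traj, window = NULL) {
  idx <- if (is.null(window)) seq_along(traj$t) else {
    check_window(window, traj$t)
    window_idx(traj$t, window)
  }
  mean(traj$tracked[idx])
}

#' Read a tracking export table
#'
#' Reads a comma-delimited tracker export (header row, one row per
#' (subject, timestamp); columns `subject_id,time_s,x_mm,y_mm,tracked` with
#' tracked coded 0/1) into a list of [larva_trajectory] objects. Constant-rate
#' sampling is enforced per subject; untracked samples are retained with
#' `tracked = FALSE`.
#'
#' @param path path to the CSV file.
#' @param geometry list with at least `well_radius_mm` (see
#'   [read_plate_config]).
#' @param groups optional data.frame `subject_id, group` (or named character
#'   vector) assigning each subject to a design cell; an unknown subject in
#'   the file is an error when supplied.
#' @return named list of `larva_trajectory`, in order of first appearance.
#' @export
read_tracking_table <- function(path, geometry, groups = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty tracking table: ", path, call. = FALSE)
  need <- c("subject_id", "time_s", "x_mm", "y_mm", "tracked")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("tracking table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups$group), groups$subject_id)
  ids <- unique(tab$subject_id)
  if (!is.null(groups)) {
    unknown <- setdiff(ids, names(groups))
    if (length(unknown))
      stop("subject(s) absent from group metadata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- lapply(ids, function(id) {
    d <- tab[tab$subject_id == id, , drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    larva_trajectory(id, d$time_s, d$x_mm, d$y_mm, d$tracked != 0,
                     well_radius = geometry$well_radius_mm,
                     group = if (is.null(groups)) NA_character_ else
                       unname(groups[id]))
  })
  names(out) <- ids
  out
}

#' Write trajectories as a tracking export table
#'
#' Inverse of [read_tracking_table]; positions are written with 17
#' significant digits so that a write/read round trip reproduces them
#' bit-exactly.
#'
#' @param trajs list of `larva_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(trajs, path) {
  rows <- lapply(trajs, function(tr)
    data.frame(subject_id = tr$subject_id,
               time_s = sprintf("%.17g", tr$t),
               x_mm = sprintf("%.17g", tr$x),
               y_mm = sprintf("%.17g", tr$y),
               tracked = as.integer(tr$tracked)))
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the tracked-fraction exclusion filter
#'
#' A larva is excluded when the fraction of untracked samples within the
#' analyzed window exceeds `max_missing_fraction` (default 0.10, i.e. a larva
#' tracked < 90% of the window is dropped).
#'
#' @param trajs list of `larva_trajectory`.
#' @param window analyzed window `c(start_s, end_s)`; default the whole
#'   recording of each larva.
#' @param max_missing_fraction maximum tolerated untracked fraction.
#' @return list with `kept` (list of trajectories) and `excluded`
#'   (data.frame `subject_id, missing_fraction`).
#' @export
apply_exclusion_filter <- function(trajs, window = NULL,
                                   max_missing_fraction = 0.10) {
  stopifnot(length(trajs) > 0L)
  miss <- vapply(trajs, function(tr) 1 - tracked_fraction(tr, window),
                 numeric(1))
  drop <- miss > max_missing_fraction
  list(kept = trajs[!drop],
       excluded = data.frame(
         subject_id = vapply(trajs[drop], `[[`, character(1), "subject_id"),
         missing_fraction = unname(miss[drop]),
         row.names = NULL))
}

#' Construct a light-phase schedule
#'
#' An ordered set of non-overlapping half-open intervals `[start_s, end_s)`,
#' each with a light state (`on`/`off`) and a role (`photomotor`, `night`,
#' `acclimation`). The night window must be a single contiguous lights-off
#' interval.
#'
#' @param start_s,end_s numeric vectors of interval bounds (seconds).
#' @param light character vector, `"on"` or `"off"`.
#' @param role character vector, `"photomotor"`, `"night"` or
#'   `"acclimation"`.
#' @return data.frame of class `phase_schedule`.
#' @export
phase_schedule <- function(start_s, end_s, light, role) {
  sch <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                    light = as.character(light), role = as.character(role),
                    stringsAsFactors = FALSE)
  stopifnot(all(sch$light %in% c("on", "off")),
            all(sch$role %in% c("photomotor", "night", "acclimation")),
            all(sch$end_s > sch$start_s))
  sch <- sch[order(sch$start_s), , drop = FALSE]
  if (nrow(sch) > 1L && any(sch$start_s[-1] < sch$end_s[-nrow(sch)] - 1e-9))
    stop("schedule intervals overlap", call. = FALSE)
  night <- sch[sch$role == "night", , drop = FALSE]
  if (nrow(night) > 1L)
    stop("the night window must be a single contiguous interval", call. = FALSE)
  if (nrow(night) == 1L && night$light != "off")
    stop("the night window must be lights-off", call. = FALSE)
  rownames(sch) <- NULL
  class(sch) <- c("phase_schedule", "data.frame")
  sch
}

#' Default recording schedule of the photomotor + sleep study design
#'
#' Time zero is the start of the afternoon photomotor assay (1:00 pm).
#' The photomotor block alternates `n_on` dark and `n_on` light phases of
#' `phase_s` seconds (dark first, since larvae acclimate under light); the
#' night window (lights-off, 10:00 pm to 8:00 am in the study design, i.e.
#' 10 h) follows after an `gap_s` lights-on acclimation gap.
#'
#' @param n_on number of lights-on photomotor phases (study design: 5).
#' @param phase_s photomotor phase length in seconds (study design: 1800).
#' @param night_s night duration in seconds (study design: 36000 = 10 h).
#' @param gap_s lights-on gap between photomotor block and night (study
#'   design: 14400 = 4 h, 6 pm to 10 pm); 0 gives a compact schedule that is
#'   cheaper to simulate.
#' @return a [phase_schedule].
#' @export
default_schedule <- function(n_on = 5, phase_s = 1800, night_s = 36000,
                             gap_s = 14400) {
  k <- 2L * n_on
  starts <- (seq_len(k) - 1L) * phase_s
  light <- rep(c("off", "on"), n_on)
  pm_end <- k * phase_s
  st <- c(starts, if (gap_s > 0) pm_end, pm_end + gap_s)
  en <- c(starts + phase_s, if (gap_s > 0) pm_end + gap_s,
          pm_end + gap_s + night_s)
  li <- c(light, if (gap_s > 0) "on", "off")
  ro <- c(rep("photomotor", k), if (gap_s > 0) "acclimation", "night")
  phase_schedule(st, en, li, ro)
}

#' Slice a trajectory by schedule role and light state
#'
#' Returns the trajectory restricted to each matching schedule interval, in
#' schedule order. Boundaries are half-open: a sample at exactly `end_s`
#' belongs to the following phase. A role/light combination absent from the
#' schedule yields an empty list (not an error).
#'
#' @param traj a `larva_trajectory`.
#' @param schedule a [phase_schedule].
#' @param role phase role to select.
#' @param light optional light state to select (`"on"`/`"off"`).
#' @return list of `larva_trajectory` segments (original timestamps kept).
#' @export
slice_by_phase <- function(traj, schedule, role, light = NULL) {
  sel <- schedule$role == role
  if (!is.null(light)) sel <- sel & schedule$light == light
  rows <- which(sel)
  out <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    w <- c(schedule$start_s[rows[j]], schedule$end_s[rows[j]])
    idx <- window_idx(traj$t, w)
    if (length(idx) < 2L)
      stop(sprintf("phase [%g, %g) covers fewer than 2 samples of subject '%s'",
                   w[1], w[2], traj$subject_id), call. = FALSE)
    seg <- traj
    seg$t <- traj$t[idx]; seg$x <- traj$x[idx]; seg$y <- traj$y[idx]
    seg$tracked <- traj$tracked[idx]
    out[[j]] <- seg
  }
  out
}

#' Read a plate/assay configuration
#'
#' A single YAML (or JSON) config carrying the arena geometry, the phase
#' schedule, analysis thresholds and the subject-to-group map. Any field may
#' be omitted; defaults are the study-design values.
#'
#' @param path YAML/JSON file path.
#' @return list with elements `geometry` (`well_radius_mm`,
#'   `outer_zone_width_mm`), `schedule` ([phase_schedule]), `thresholds`
#'   (`bout_start_mms`, `bout_stop_mms`, `movement_mms`, `min_sleep_s`,
#'   `max_missing_fraction`) and `groups` (data.frame or NULL).
#' @export
read_plate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  normalize_plate_config(cfg)
}

normalize_plate_config <- function(cfg) {
  geometry <- list(
    well_radius_mm = cfg$geometry$well_radius_mm %||% 8.0,
    outer_zone_width_mm = cfg$geometry$outer_zone_width_mm %||% 3.0)
  schedule <- if (!is.null(cfg$schedule)) {
    ph <- cfg$schedule
    phase_schedule(vapply(ph, `[[`, numeric(1), "start_s"),
                   vapply(ph, `[[`, numeric(1), "end_s"),
                   vapply(ph, `[[`, character(1), "light"),
                   vapply(ph, `[[`, character(1), "role"))
  } else default_schedule()
  thr <- list(
    bout_start_mms = cfg$thresholds$bout_start_mms %||% 2.0,
    bout_stop_mms = cfg$thresholds$bout_stop_mms %||% 1.0,
    movement_mms = cfg$thresholds$movement_mms %||% 1.0,
    min_sleep_s = cfg$thresholds$min_sleep_s %||% 6L,
    max_missing_fraction = cfg$thresholds$max_missing_fraction %||% 0.10)
  groups <- if (!is.null(cfg$groups))
    data.frame(subject_id = names(cfg$groups),
               group = unlist(cfg$groups, use.names = FALSE),
               stringsAsFactors = FALSE)
  list(geometry = geometry, schedule = schedule, thresholds = thr,
       groups = groups)
}

#' Write a plate/assay configuration
#' @param config a list as returned by [read_plate_config].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_plate_config <- function(config, path) {
  sch <- config$schedule
  out <- list(
    geometry = config$geometry,
    schedule = lapply(seq_len(nrow(sch)), function(i)
      list(start_s = sch$start_s[i], end_s = sch$end_s[i],
           light = sch$light[i], role = sch$role[i])),
    thresholds = config$thresholds)
  if (!is.null(config$groups))
    out$groups <- as.list(setNames(config$groups$group,
                                   config$groups$subject_id))
  yaml::write_yaml(out, path)
  invisible(path)
}
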