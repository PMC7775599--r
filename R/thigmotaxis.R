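#' Zone of a point within a circular well
#'
#' The outer zone is the annulus extending `zone_width` mm (default 3) from
#' the well edge toward the center; the boundary is inclusive on the outer
#' side, i.e. a point at exactly `well_radius - zone_width` is outer.
#'
#' @param x,y point coordinates in mm, well-centered (vectorized).
#' @param well_radius well radius, mm.
#' @param zone_width outer-zone width, mm; must be `< well_radius`.
#' @param tol tracking tolerance beyond the wall before a point is treated
#'   as a tracking artifact (hard error), mm.
#' @return character vector, `"outer"` or `"inner"`.
#' @export
zone_of <- function(x, y, well_radius, zone_width = 3.0, tol = 0.5) {
  if (zone_width >= well_radius)
    stop("zone_width must be smaller than well_radius", call. = FALSE)
  r <- sqrt(x^2 + y^2)
  if (any(r > well_radius + tol))
    stop(sprintf("point at r = %.3f mm lies beyond the well (radius %g mm + %g tolerance): tracking artifact",
                 max(r), well_radius, tol), call. = FALSE)
  ifelse(r >= well_radius - zone_width, "outer", "inner")
}

thigmo_one_window <- function(traj, window, v, zone_width) {
  idx <- window_idx(v$t, window)
  ok <- idx[v$valid[idx]]
  # a step is assigned to the zone of its starting sample
  start_outer <- sqrt(traj$x[ok - 1L]^2 + traj$y[ok - 1L]^2) >=
    traj$well_radius - zone_width
  step <- v$v[ok] * v$dt
  tr <- idx[traj$tracked[idx]]
  list(outer = sum(step[start_outer]), total = sum(step),
       r_sum = sum(sqrt(traj$x[tr]^2 + traj$y[tr]^2)), r_n = length(tr))
}

#' Thigmotaxis endpoints over the lights-on photomotor phases
#'
#' Wall preference is scored as the fraction of the swum distance performed
#' in the outer annulus during the lights-on phases. Each valid displacement
#' step is assigned to the zone of its starting sample. By default the
#' fraction is computed per phase and averaged across phases (mirroring the
#' photomotor endpoints); `pooled = TRUE` instead divides pooled outer
#' distance by pooled total distance. The mean radial distance from the well
#' center is computed over all tracked lights-on samples.
#'
#' @param traj a [larva_trajectory].
#' @param schedule a [phase_schedule] with lights-on photomotor phases.
#' @param zone_width outer-zone width, mm (default 3).
#' @param pooled pool distance across phases instead of averaging per-phase
#'   fractions.
#' @param v optional precomputed [speed] series.
#' @return list of class `thigmo_metrics`: `outer_fraction` (`NA` when the
#'   larva swam nothing), `mean_center_distance_mm`, `total_distance_mm`.
#' @export
thigmo_metrics <- function(traj, schedule, zone_width = 3.0, pooled = FALSE,
                           v = NULL) {
  on <- schedule[schedule$role == "photomotor" & schedule$light == "on", ]
  if (nrow(on) == 0L)
    stop("schedule has no lights-on photomotor phase", call. = FALSE)
  if (is.null(v)) v <- speed(traj)
  # validate positions once (tracked samples only)
  tr <- which(traj$tracked)
  invisible(zone_of(traj$x[tr], traj$y[tr], traj$well_radius, zone_width))
  per <- lapply(seq_len(nrow(on)), function(i)
    thigmo_one_window(traj, c(on$start_s[i], on$end_s[i]), v, zone_width))
  outer <- vapply(per, `[[`, numeric(1), "outer")
  total <- vapply(per, `[[`, numeric(1), "total")
  frac <- if (pooled) {
    if (sum(total) > 0) sum(outer) / sum(total) else NA_real_
  } else {
    f <- ifelse(total > 0, outer / total, NA_real_)
    if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
  }
  r_n <- sum(vapply(per, `[[`, numeric(1), "r_n"))
  out <- list(
    outer_fraction = frac,
    mean_center_distance_mm = if (r_n > 0)
      sum(vapply(per, `[[`, numeric(1), "r_sum")) / r_n else NA_real_,
    total_distance_mm = sum(total))
  class(out) <- "thigmo_metrics"
  out
}

#' @export
print.thigmo_metrics <- function(x, ...) {
  cat("Thigmotaxis endpoints (lights-on phases)\n")
  cat(sprintf("  outer-zone fraction of distance: %.3f\n", x$outer_fraction))
  cat(sprintf("  mean distance from center:       %.2f mm\n",
              x$mean_center_distance_mm))
  cat(sprintf("  total distance:                  %.1f mm\n",
              x$total_distance_mm))
  invisible(x)
}
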