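MOTOR_ENDPOINTS <- c("mean_distance_mm", "mean_frequency",
                     "mean_cumulative_time_s", "mean_bout_duration_s",
                     "mean_speed_on_mms", "mean_speed_off_mms")
SLEEP_ENDPOINTS <- c("fragmentation_per_h", "sleep_ratio", "sleep_latency_s",
                     "night_speed_mms", "wake_bout_duration_s",
                     "sleep_bout_duration_s")
THIGMO_ENDPOINTS <- c("outer_fraction", "mean_center_distance_mm")

#' Per-larva endpoint tables for a cohort
#'
#' Computes the requested assays for every trajectory (speed series computed
#' once per larva) and returns one data.frame per assay with one row per
#' larva.
#'
#' @param trajs named list of [larva_trajectory].
#' @param schedule a [phase_schedule].
#' @param geometry list with `well_radius_mm`, `outer_zone_width_mm`.
#' @param thresholds list as in [read_plate_config] (`bout_start_mms`,
#'   `bout_stop_mms`, `movement_mms`, `min_sleep_s`).
#' @param assays character subset of `c("motor", "sleep", "thigmo")`.
#' @param required_phases lights-on phase count the motor assay requires.
#' @return named list of data.frames (`motor`, `sleep`, `thigmo`), each with
#'   `subject_id`, `group` and the assay's endpoint columns.
#' @export
cohort_endpoints <- function(trajs, schedule, geometry, thresholds,
                             assays = c("motor", "sleep", "thigmo"),
                             required_phases = 5L) {
  thr <- thresholds
  out <- lapply(setNames(nm = assays), function(a) vector("list", length(trajs)))
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    v <- speed(tr)
    base <- data.frame(subject_id = tr$subject_id, group = tr$group,
                       stringsAsFactors = FALSE)
    if ("motor" %in% assays) {
      m <- motor_metrics(tr, schedule, v = v, high = thr$bout_start_mms,
                         low = thr$bout_stop_mms,
                         required_phases = required_phases)
      out$motor[[k]] <- cbind(base, as.data.frame(unclass(m)))
    }
    if ("sleep" %in% assays) {
      s <- sleep_assay(tr, schedule, threshold = thr$movement_mms,
                       min_sleep_s = thr$min_sleep_s, v = v)
      out$sleep[[k]] <- cbind(base,
                              as.data.frame(unclass(s)[SLEEP_ENDPOINTS]))
    }
    if ("thigmo" %in% assays) {
      tg <- thigmo_metrics(tr, schedule,
                           zone_width = geometry$outer_zone_width_mm, v = v)
      out$thigmo[[k]] <- cbind(base, as.data.frame(unclass(tg)))
    }
  }
  lapply(out, function(rows) do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

endpoint_columns <- function(assay) {
  switch(assay, motor = MOTOR_ENDPOINTS, sleep = SLEEP_ENDPOINTS,
         thigmo = THIGMO_ENDPOINTS)
}

run_group_stats <- function(metrics, groups_meta, alpha = 0.05) {
  results <- list()
  for (assay in names(metrics)) {
    tab <- metrics[[assay]]
    if (is.null(tab)) next
    for (ep in intersect(endpoint_columns(assay), names(tab))) {
      vals <- tab[[ep]]
      glab <- tab$group
      k <- length(unique(glab))
      res <- tryCatch({
        if (k == 2L) {
          compare_two_groups(split(vals, glab), alpha, endpoint = ep)
        } else if (k == 3L) {
          compare_three_groups(split(vals, glab), alpha, endpoint = ep)
        } else if (k == 4L) {
          mi <- match(tab$subject_id, groups_meta$subject_id)
          compare_factorial(vals, groups_meta$toxin[mi],
                            groups_meta$treatment[mi], alpha, endpoint = ep)
        } else stop("unsupported design with ", k, " groups")
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("comparison skipped for endpoint '", ep, "': ",
                conditionMessage(res), call. = FALSE)
      } else results[[paste(assay, ep, sep = ".")]] <- res
    }
  }
  results
}

stats_table <- function(results) {
  do.call(rbind, c(lapply(results, function(r)
    data.frame(endpoint = r$endpoint, design = r$design,
               test = r$test_name, statistic = r$statistic,
               p_value = r$p_value,
               branch = if (is.na(r$normal_branch)) NA_character_
                        else if (r$normal_branch) "parametric"
                        else "nonparametric",
               stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
}

posthoc_table <- function(results) {
  rows <- lapply(results, function(r) {
    if (is.null(r$posthoc)) return(NULL)
    cbind(data.frame(endpoint = r$endpoint, stringsAsFactors = FALSE),
          r$posthoc)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  nm <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) { d[setdiff(nm, names(d))] <- NA; d[nm] })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

plot_endpoint <- function(vals, glab, main) {
  sp <- split(vals, glab)
  mu <- vapply(sp, function(v) mean(v, na.rm = TRUE), numeric(1))
  sem <- vapply(sp, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  }, numeric(1))
  ylim <- range(0, vals, mu + sem, na.rm = TRUE)
  bp <- graphics::barplot(mu, ylim = ylim * 1.05, main = main, las = 2,
                          cex.names = 0.7, col = "grey85")
  graphics::arrows(bp, mu - sem, bp, mu + sem, angle = 90, code = 3,
                   length = 0.04)
  for (i in seq_along(sp)) {
    v <- sp[[i]]
    graphics::points(jitter(rep(bp[i], length(v)), amount = 0.12), v,
                     pch = 16, cex = 0.4, col = "#00000055")
  }
}

write_summary_plots <- function(metrics, path) {
  grDevices::pdf(path, width = 9, height = 6)
  on.exit(grDevices::dev.off())
  for (assay in names(metrics)) {
    tab <- metrics[[assay]]
    if (is.null(tab)) next
    eps <- intersect(endpoint_columns(assay), names(tab))
    graphics::par(mfrow = c(2, 3), mar = c(6, 4, 2, 1))
    for (ep in eps) plot_endpoint(tab[[ep]], tab$group, ep)
  }
  invisible(path)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full phenotyping pipeline
#'
#' Orchestrates one end-to-end run: simulate a synthetic cohort (or load a
#' tracking export), apply the tracked-fraction exclusion filter, score the
#' requested assays per larva, run the group statistics, and write all stage
#' outputs (per-assay metrics CSVs, stats and post hoc CSVs, a JSON run
#' manifest, diagnostic summary plots) to `out_dir`. Rerunning with the
#' same config and seed reproduces the CSV outputs byte-identically (the
#' manifest differs only in its timestamp).
#'
#' @param config a list, or path to a YAML file, with elements:
#'   `simulate` (list: `seed`, `n_per_group`, `presets` character vector) or
#'   `input` (list: `tracks` CSV path, `config` plate-YAML path); optional
#'   `geometry`, `schedule`, `thresholds` as in [read_plate_config];
#'   optional `assays` (default all three); optional `alpha` (default 0.05).
#' @param out_dir output directory, created if needed.
#' @param plots write `summary_plots.pdf` (default TRUE).
#' @return invisibly, a list with `manifest`, `metrics` (list of
#'   data.frames), `stats` (list of `comparison_result`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, plots = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  plate <- normalize_plate_config(cfg)
  assays <- cfg$assays %||% c("motor", "sleep", "thigmo")
  alpha <- cfg$alpha %||% 0.05
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "load"
  res <- tryCatch({
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      sc <- synth_config(seed = sim$seed %||% 1L,
                         n_per_group = sim$n_per_group %||% 32L,
                         groups = unlist(sim$presets) %||% c("control", "mpp"),
                         geometry = plate$geometry, schedule = plate$schedule)
      co <- simulate_cohort(sc)
      list(trajs = co$trajectories, groups = co$groups,
           inputs = list(simulated = TRUE, seed = sc$seed,
                         n_per_group = sc$n_per_group,
                         presets = names(sc$groups)))
    } else if (!is.null(cfg$input)) {
      pl <- read_plate_config(cfg$input$config)
      plate$geometry <- pl$geometry; plate$schedule <- pl$schedule
      if (!is.null(pl$groups)) plate$groups <- pl$groups
      trajs <- read_tracking_table(cfg$input$tracks, plate$geometry,
                                   groups = plate$groups)
      gm <- plate$groups
      if (!is.null(gm) && !("toxin" %in% names(gm))) {
        gm$toxin <- ifelse(grepl("mpp", gm$group), "MPP+", "control")
        gm$treatment <- ifelse(grepl("gdnf", gm$group), "GDNF",
                               ifelse(grepl("pba", gm$group), "PBA", "none"))
      }
      list(trajs = trajs, groups = gm,
           inputs = list(simulated = FALSE, tracks = cfg$input$tracks,
                         config = cfg$input$config))
    } else stop("config must provide either 'simulate' or 'input'")
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))

  night <- plate$schedule[plate$schedule$role == "night", ]
  if ("sleep" %in% assays && nrow(night) == 0L)
    stop("pipeline stage 'validate' failed: schedule lacks role 'night' ",
         "required by the sleep assay", call. = FALSE)
  on_phases <- sum(plate$schedule$role == "photomotor" &
                     plate$schedule$light == "on")
  if (any(c("motor", "thigmo") %in% assays) && on_phases == 0L)
    stop("pipeline stage 'validate' failed: schedule lacks lights-on ",
         "photomotor phases", call. = FALSE)

  stage <- "exclusion"
  filt <- apply_exclusion_filter(
    res$trajs, max_missing_fraction = plate$thresholds$max_missing_fraction)

  stage <- "assays"
  metrics <- tryCatch(
    cohort_endpoints(filt$kept, plate$schedule, plate$geometry,
                     plate$thresholds, assays = assays,
                     required_phases = min(5L, on_phases)),
    error = function(e)
      stop("pipeline stage 'assays' failed: ", conditionMessage(e),
           call. = FALSE))

  stage <- "stats"
  results <- run_group_stats(metrics, res$groups, alpha = alpha)

  stage <- "write"
  for (assay in names(metrics))
    if (!is.null(metrics[[assay]]))
      write.csv(metrics[[assay]],
                file.path(out_dir, paste0(assay, "_metrics.csv")),
                row.names = FALSE)
  if (length(results)) {
    write.csv(stats_table(results), file.path(out_dir, "stats.csv"),
              row.names = FALSE)
    ph <- posthoc_table(results)
    if (!is.null(ph))
      write.csv(ph, file.path(out_dir, "posthoc.csv"), row.names = FALSE)
  }
  write.csv(filt$excluded, file.path(out_dir, "excluded.csv"),
            row.names = FALSE)
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = res$inputs$seed %||% NA,
    inputs = res$inputs,
    counts = list(n_input = length(res$trajs), n_kept = length(filt$kept),
                  n_excluded = nrow(filt$excluded)),
    n_comparisons = length(results),
    package_version = as.character(packageVersion("larvaphenome")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (plots) write_summary_plots(metrics, file.path(out_dir,
                                                    "summary_plots.pdf"))
  invisible(list(manifest = manifest, metrics = metrics, stats = results,
                 excluded = filt$excluded, out_dir = out_dir))
}
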