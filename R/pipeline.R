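# End-to-end pipeline: read detections -> track -> calibrate -> filter ->
# split U-turns -> directions -> metrics + visiting map -> statistics.
# Every run writes a manifest (seed, params, input hashes, stage counts)
# sufficient to reproduce it.

#' Run the full tracking and analysis pipeline
#'
#' Executes the stages in order and writes all artifacts into `out_dir`:
#' trajectory samples and metrics CSVs, the removed-trajectory report, the
#' visiting map (CSV/PGM/PNG), error cues, the straightness beta-mixture
#' report and, when the metadata supports them (at least two colonies and
#' dates), the mixed-model analyses. Any stage failure aborts with the
#' stage name and cause.
#'
#' @param detections path to a detection CSV ([read_detections()] dialect).
#' @param config path to a JSON config file, or a [trail_config()].
#' @param out_dir output directory (created if needed).
#' @param view numeric length-2 view bounds in px.
#' @param p a [track_params()].
#' @param seed integer seed for the statistical stages.
#' @param k_max largest mixture size tried by BIC selection.
#' @return invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(detections, config, out_dir, view,
                         p = track_params(), seed = 1, k_max = 6) {
  cfg <- if (inherits(config, "trail_config")) config else load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  fs <- stage("read", read_detections(detections, view, cfg$fps))
  note("read: %d detections", nrow(fs$detections))

  trajs <- stage("track", build_trajectories(fs, p))
  note("track: %d trajectories after pruning", length(trajs))

  cues <- stage("cues", extract_cues(fs, trajs, cfg, p))
  write.csv(cues, file.path(out_dir, "cues.csv"), row.names = FALSE)
  note("cues: %d (%s)", nrow(cues),
       paste(names(table(cues$cue_type)), table(cues$cue_type),
             sep = "=", collapse = ", "))

  trajs <- stage("calibrate", calibrate_trajectories(trajs, cfg))
  flt <- stage("filter", filter_edge_starts(trajs, cfg))
  write.csv(flt$report, file.path(out_dir, "removed.csv"), row.names = FALSE)
  note("filter: kept %d complete crossings, removed %d",
       length(flt$kept), length(flt$removed))

  parts <- stage("uturns", split_uturns_all(flt$kept, cfg))
  note("uturns: %d analysis trajectories after splitting", length(parts))
  parts <- stage("direction", assign_directions(parts, cfg))

  if (!length(parts)) stop("pipeline stage 'metrics' failed: no trajectories survive filtering")
  vm <- stage("visiting_map", visiting_map(parts, cfg, mode = "trajectories"))
  export_heatmap(vm, file.path(out_dir, "visiting_map"))
  vm_entries <- stage("visiting_map",
                      visiting_map(parts, cfg, mode = "entries"))
  export_heatmap(vm_entries, file.path(out_dir, "visiting_map_entries"))

  records <- stage("metrics", summarize_trajectories(parts, cfg, vm))
  write_trajectories(parts, records, file.path(out_dir, "trajectories"))
  note("metrics: %d records", nrow(records))

  stats_out <- list()
  if (nrow(records) >= 30) {
    sel <- stage("mixture", select_k_bic(
      records$ST, K_max = min(k_max, floor(nrow(records) / 10)),
      seed = seed))
    grp <- classify_groups(sel$fits[[sel$K_best]])
    stats_out$mixture <- list(K_best = sel$K_best, BIC = sel$BIC,
                              groups = grp$summary)
    note("mixture: BIC selects K = %d", sel$K_best)
  } else {
    note("mixture: skipped (need >= 30 trajectories, have %d)", nrow(records))
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  manifest <- list(
    package_version = as.character(packageVersion("trailtrack")),
    seed = seed,
    input = unname(tools::md5sum(detections)),
    config = unclass(cfg), track_params = unclass(p),
    counts = list(detections = nrow(fs$detections),
                  trajectories = length(trajs),
                  kept = length(flt$kept), removed = length(flt$removed),
                  analysis_parts = length(parts),
                  metric_records = nrow(records)),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(frame_set = fs, trajectories = parts, records = records,
                 visiting_map = vm, cues = cues, stats = stats_out,
                 manifest = manifest))
}
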