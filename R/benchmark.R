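#' Benchmark the two counting methods on simulated data
#'
#' End-to-end comparison: generate a labelled dataset, run both the naive
#' counter ([count_yolo_only()]) and the parity counter ([count_parity()]),
#' match each against ground truth and tabulate accuracy, precision, recall
#' and F1 per method. Candidate units for true negatives are the
#' threshold-separated episodes of the generated tracks, shared by both
#' methods.
#'
#' @param cfg A [sim_config()], or `NULL` for the defaults.
#' @param gap_threshold_frames Episode gap threshold for the parity counter
#'   (default: one second at the configured fps).
#' @param tolerance_frames Event-matching tolerance ([match_events()]).
#' @return A tibble (see [metric_table()]) with rows `yolo_only` and
#'   `parity`, metrics in percent; the dataset and counts are attached as
#'   attributes `dataset` and `counts`.
#' @examples
#' \donttest{
#' run_benchmark(sim_config(n_tracks = 50, seed = 7))
#' }
#' @export
run_benchmark <- function(cfg = NULL, gap_threshold_frames = NULL,
                          tolerance_frames = 240) {
  if (is.null(cfg)) cfg <- sim_config()
  if (is.null(gap_threshold_frames)) gap_threshold_frames <- cfg$vf$fps
  ds <- generate_dataset(cfg)
  units <- track_episodes(ds$tracks, cfg$vf, gap_threshold_frames)
  pred_yolo <- count_yolo_only(ds$tracks, cfg$vf)
  pred_parity <- count_parity(ds$tracks, cfg$vf, gap_threshold_frames)
  counts <- list(
    yolo_only = match_events(pred_yolo, ds$truth, tolerance_frames,
                             units = units, lineage = ds$lineage),
    parity = match_events(pred_parity, ds$truth, tolerance_frames,
                          units = units, lineage = ds$lineage)
  )
  tab <- metric_table(counts)
  attr(tab, "dataset") <- ds
  attr(tab, "counts") <- counts
  tab
}

# ---------------------------------------------------------------------------
# Command-line entry points. The installed `nestcount` script (in exec/)
# dispatches to these; they are ordinary functions so they are testable
# without a shell. Each writes a JSON manifest next to its outputs with the
# configuration, seed, paths, package version and timestamp.

.write_manifest <- function(dir, command, cfg_path, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    config = if (is.null(cfg_path)) NA else normalizePath(cfg_path),
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    tool = "nestcount",
    version = as.character(utils::packageVersion("nestcount")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Simulate a dataset to disk
#'
#' Writes a MOT-challenge tracks CSV, a truth-events CSV, a track-lineage
#' CSV and a run manifest into `out_dir`.
#'
#' @param cfg_path Optional YAML/JSON config (see [load_config()]); its
#'   `simulate:` section overrides [sim_config()] arguments.
#' @param out_dir Output directory, created if missing.
#' @param seed Overrides the config seed when non-`NULL`.
#' @return Invisibly, the list of written paths.
#' @export
cmd_simulate <- function(cfg_path = NULL, out_dir = ".", seed = NULL) {
  cfg <- load_config(cfg_path)
  sim_args <- cfg$sim
  sim_args$vf <- cfg$vf
  if (!is.null(seed)) sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  ds <- generate_dataset(scfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    tracks = file.path(out_dir, "tracks.csv"),
    truth = file.path(out_dir, "truth_events.csv"),
    lineage = file.path(out_dir, "lineage.csv")
  )
  write_tracks(ds$tracks, paths$tracks)
  write_events(ds$truth, paths$truth)
  readr::write_csv(ds$lineage, paths$lineage, progress = FALSE)
  message("simulate: ", length(unique(ds$tracks$track_id)), " tracks, ",
          nrow(ds$tracks), " detections, ", nrow(ds$truth), " truth events")
  .write_manifest(out_dir, "simulate", cfg_path, scfg$seed,
                  inputs = list(), outputs = paths)
  invisible(paths)
}

#' Count nest events from a tracks file
#'
#' Reads a MOT CSV, applies the chosen counting method and writes the
#' predicted events CSV plus a manifest.
#'
#' @param tracks_path MOT-challenge CSV of tracked detections.
#' @param out_path Output events CSV path.
#' @param method `"parity"` or `"yolo-only"` (overrides the config).
#' @inheritParams cmd_simulate
#' @return Invisibly, `out_path`.
#' @export
cmd_count <- function(tracks_path, cfg_path = NULL, method = NULL,
                      out_path = "events.csv") {
  cfg <- load_config(cfg_path)
  if (!is.null(method)) {
    if (!method %in% c("parity", "yolo-only")) {
      stop("unknown method: ", method, call. = FALSE)
    }
    cfg$method <- method
  }
  det <- read_tracks(tracks_path, cfg$vf)
  crossings <- detect_crossings(det, cfg$vf)
  events <- if (cfg$method == "parity") {
    eps <- track_episodes(det, cfg$vf, cfg$gap_threshold_frames)
    message("count: ", nrow(eps), " episodes from ", nrow(crossings),
            " crossings")
    classify_episode(eps)
  } else {
    count_yolo_only(det, cfg$vf)
  }
  message("count [", cfg$method, "]: ",
          length(unique(det$track_id)), " tracks, ",
          nrow(crossings), " crossings, ", nrow(events), " events")
  write_events(events, out_path)
  .write_manifest(dirname(out_path), "count", cfg_path, NA,
                  inputs = list(tracks = tracks_path),
                  outputs = list(events = out_path))
  invisible(out_path)
}

#' Evaluate predicted events against truth
#'
#' Reads predicted and truth event CSVs (and optionally the tracks file, to
#' form true-negative candidate units), writes a metrics CSV and prints a
#' table with the four metrics in percent.
#'
#' @param pred_path,truth_path Event CSVs ([write_events()] layout).
#' @param tracks_path Optional MOT CSV for TN units; without it TN = 0.
#' @param lineage_path Optional lineage CSV from [cmd_simulate()].
#' @param out_path Output metrics CSV.
#' @inheritParams cmd_simulate
#' @return Invisibly, the metrics tibble.
#' @export
cmd_evaluate <- function(pred_path, truth_path, tracks_path = NULL,
                         lineage_path = NULL, cfg_path = NULL,
                         out_path = "metrics.csv") {
  cfg <- load_config(cfg_path)
  pred <- read_events(pred_path)
  truth <- read_events(truth_path)
  units <- NULL
  if (!is.null(tracks_path)) {
    det <- read_tracks(tracks_path, cfg$vf)
    units <- track_episodes(det, cfg$vf, cfg$gap_threshold_frames)
  }
  lineage <- if (!is.null(lineage_path)) {
    readr::read_csv(lineage_path, col_types = "ii", progress = FALSE)
  }
  cc <- match_events(pred, truth, tolerance_frames = cfg$gap_threshold_frames,
                     units = units, lineage = lineage)
  tab <- metric_table(list(prediction = cc))
  readr::write_csv(tab, out_path, progress = FALSE)
  print(format_metric_table(tab))
  .write_manifest(dirname(out_path), "evaluate", cfg_path, NA,
                  inputs = list(predicted = pred_path, truth = truth_path),
                  outputs = list(metrics = out_path))
  invisible(tab)
}

#' Run the full two-method benchmark to disk
#'
#' Simulate, count with both methods, evaluate both, and write one metrics
#' table (percentages, one row per method) plus all intermediate files and a
#' manifest.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the metrics tibble.
#' @export
cmd_benchmark <- function(cfg_path = NULL, out_dir = ".", seed = NULL) {
  cfg <- load_config(cfg_path)
  sim_args <- cfg$sim
  sim_args$vf <- cfg$vf
  if (!is.null(seed)) sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run_benchmark(scfg, gap_threshold_frames = cfg$gap_threshold_frames)
  ds <- attr(tab, "dataset")
  write_tracks(ds$tracks, file.path(out_dir, "tracks.csv"))
  write_events(ds$truth, file.path(out_dir, "truth_events.csv"))
  out_tab <- tibble::as_tibble(tab)
  readr::write_csv(out_tab, file.path(out_dir, "metrics.csv"),
                   progress = FALSE)
  print(format_metric_table(out_tab))
  .write_manifest(out_dir, "benchmark", cfg_path, scfg$seed,
                  inputs = list(),
                  outputs = list(metrics = file.path(out_dir, "metrics.csv")))
  invisible(tab)
}

#' Format a metric table for display
#'
#' Percentages to one decimal place, one row per method.
#'
#' @param tab A tibble from [metric_table()] (percent scale).
#' @return A data frame of formatted strings.
#' @export
format_metric_table <- function(tab) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
  data.frame(
    method = tab$method,
    `accuracy (%)` = fmt(tab$accuracy),
    `precision (%)` = fmt(tab$precision),
    `recall (%)` = fmt(tab$recall),
    `F1 (%)` = fmt(tab$f1),
    check.names = FALSE
  )
}
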