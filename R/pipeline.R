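#' Full pipeline configuration
#'
#' Bundles the parameters of every analysis stage plus the RNG seed. The
#' object serializes losslessly to JSON (canonical) or YAML (if the yaml
#' package is installed) for CLI runs and provenance manifests.
#'
#' @param preprocess a [preprocess_params()].
#' @param cluster a [cluster_params()].
#' @param trimer a [trimer_params()].
#' @param tracking a [track_filter_params()].
#' @param rng_seed integer seed used for all seeded steps.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_params(),
                            cluster = cluster_params(),
                            trimer = trimer_params(),
                            tracking = track_filter_params(),
                            rng_seed = 1L) {
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(cluster, "cluster_params"),
            inherits(trimer, "trimer_params"),
            inherits(tracking, "track_filter_params"))
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(list(preprocess = preprocess, cluster = cluster, trimer = trimer,
                 tracking = tracking, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path output path; `.json` (canonical) or `.yaml`/`.yml`.
#' @return `path` / the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(config, function(p) if (is.list(p)) unclass(p) else p)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_mfx("the 'yaml' package is required for YAML configs")
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  plain <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_mfx("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  zw <- plain$preprocess$z_window
  if (!identical(zw, "auto")) zw <- as.numeric(zw)
  pipeline_config(
    preprocess = do.call(preprocess_params,
                         modifyList(plain$preprocess, list(z_window = zw))),
    cluster = do.call(cluster_params, plain$cluster),
    trimer = do.call(trimer_params, plain$trimer),
    tracking = do.call(track_filter_params, plain$tracking),
    rng_seed = plain$rng_seed)
}

#' Structural analysis pipeline
#'
#' z correction, trace filtering, two-step DBSCAN + GMM position fitting,
#' trimer identification, interblade distances — the full fixed-cell
#' branch, with a merged filter/cluster log.
#'
#' @param table raw localization table (uncorrected z) — or a table with
#'   attribute `z_corrected` already set, in which case the correction is
#'   skipped.
#' @param config a [pipeline_config()].
#' @return list: `positions`, `trimers`, `distances`, `summary`, `log`.
#' @export
analyze_structure <- function(table, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!isTRUE(attr(table, "z_corrected")))
    table <- correct_z(table, config$preprocess$z_correction)
  filt <- filter_traces(table, config$preprocess)
  labelled <- cluster_localizations(filt$table, config$cluster)
  pos <- fit_positions(labelled, config$cluster)
  tri <- identify_trimers(pos$positions, config$trimer)
  dist <- interblade_distances(tri$trimers, seed = config$rng_seed)
  list(positions = pos$positions, trimers = tri$trimers,
       distances = dist$distances, summary = dist$summary,
       log = list(filter = filt$log, positions = pos$log,
                  rejections = tri$rejections))
}

#' Tracking analysis pipeline
#'
#' z correction, gap-truncated trajectory building, per-trajectory and
#' ensemble weighted MSD fits over the microscopic and macroscopic lag
#' windows.
#'
#' @inheritParams analyze_structure
#' @return list: `trajectories`, `per_track` (d_micro/d_macro table),
#'   `ensemble` (curve + fits), `summary`, `log`.
#' @export
analyze_tracks <- function(table, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!isTRUE(attr(table, "z_corrected")))
    table <- correct_z(table, config$preprocess$z_correction)
  built <- build_trajectories(table, config$tracking)
  if (!length(built$trajectories))
    return(list(trajectories = list(), per_track = fit_trajectories(list()),
                ensemble = NULL,
                summary = list(n_trajectories = 0L), log = built$log))
  per_track <- fit_trajectories(built$trajectories, config$tracking)
  ens <- ensemble_msd(built$trajectories, config$tracking)
  list(trajectories = built$trajectories, per_track = per_track,
       ensemble = ens,
       summary = list(n_trajectories = length(built$trajectories),
                      median_d_micro = median(per_track$d_micro, na.rm = TRUE),
                      median_d_macro = median(per_track$d_macro, na.rm = TRUE),
                      ensemble_d_micro = ens$fit_micro$d,
                      ensemble_d_macro = ens$fit_macro$d),
       log = built$log)
}
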