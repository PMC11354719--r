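#' Write a raw stream to a plain-text container
#'
#' Single-column text format with a commented header carrying the metadata
#' needed to reinterpret the samples: sampling rate, nominal baseline,
#' ISO-8601 start timestamp and the sample count (which guards against
#' truncated files on read).
#'
#' @param stream A [raw_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  header <- c(
    sprintf("# sampling_rate: %.10g", stream$sampling_rate),
    if (!is.null(stream$baseline_v0)) {
      sprintf("# baseline_v0: %.10g", stream$baseline_v0)
    },
    sprintf("# start_time: %s",
            format(stream$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    sprintf("# n_samples: %d", length(stream$samples))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.17g", stream$samples), con)
  invisible(path)
}

#' Read a raw stream from its text container
#'
#' Parses the header written by [write_stream()]. A missing sampling rate
#' falls back to the instrument default of 30517 Hz with a warning; a
#' sample count that does not match the header's `n_samples` raises an
#' error rather than silently returning a partial stream.
#'
#' @param path File path.
#' @return A [raw_stream()].
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  fs <- get_field("sampling_rate")
  if (is.null(fs)) {
    warning("header lacks sampling_rate; assuming the 30517 Hz default")
    fs <- 30517
  } else {
    fs <- as.numeric(fs)
  }
  v0 <- get_field("baseline_v0")
  start <- get_field("start_time")
  samples <- as.numeric(lines[!is_header])
  if (anyNA(samples)) stop("malformed sample values in ", path)
  n_declared <- get_field("n_samples")
  if (!is.null(n_declared) && length(samples) != as.integer(n_declared)) {
    stop(sprintf("truncated stream file: %d samples found, %s declared",
                 length(samples), n_declared))
  }
  raw_stream(samples, sampling_rate = fs,
             start_time = if (!is.null(start)) {
               as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
             } else as.POSIXct("2022-01-01", tz = "UTC"),
             baseline_v0 = if (!is.null(v0)) as.numeric(v0) else NULL)
}

#' Read trap collection records
#'
#' CSV with columns `trap_id`, `collection_date` (ISO), `count`, and
#' optionally `days_since_previous`.
#'
#' @param path CSV file path.
#' @return Data frame of trap records.
#' @export
read_trap_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trap_id", "collection_date", "count")
  if (!all(need %in% names(rec))) {
    stop("trap CSV needs columns: ", paste(need, collapse = ", "))
  }
  rec$collection_date <- as.Date(rec$collection_date)
  rec
}

#' Pipeline configuration
#'
#' Validated bundle of everything one end-to-end run needs. Gate bounds and
#' physical quantities are checked at construction time, so a malformed
#' configuration fails before any signal processing starts.
#'
#' @param detection A [detection_config()] or a list of its arguments.
#' @param geometry A [beam_geometry()] or a list of its arguments.
#' @param gates List of [cluster_gate()]s or of argument lists.
#' @param density_resolution Native density bin width in seconds.
#' @param seed Integer seed controlling all randomness of the run.
#' @param scenario Optional [stream_scenario()] (or argument list) to
#'   simulate the input; alternatively set `stream_path`.
#' @param stream_path Optional path of a stored stream to analyse.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            geometry = beam_geometry(),
                            gates = default_mosquito_gates(),
                            density_resolution = 60,
                            seed = 1L,
                            scenario = NULL,
                            stream_path = NULL) {
  if (is.list(detection) && !inherits(detection, "detection_config")) {
    detection <- do.call(detection_config, detection)
  }
  if (is.list(geometry) && !inherits(geometry, "beam_geometry")) {
    geometry <- do.call(beam_geometry, geometry)
  }
  gates <- lapply(gates, function(g) {
    if (inherits(g, "cluster_gate")) g else do.call(cluster_gate, g)
  })
  stopifnot_scalar(density_resolution, "density_resolution", positive = TRUE)
  if (!is.null(scenario) && !inherits(scenario, "stream_scenario")) {
    scenario <- do.call(stream_scenario, scenario)
  }
  if (is.null(scenario) && is.null(stream_path)) {
    stop("provide either a simulation scenario or a stream path")
  }
  structure(
    list(detection = detection, geometry = geometry, gates = gates,
         density_resolution = density_resolution, seed = as.integer(seed),
         scenario = scenario, stream_path = stream_path),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML document may contain `detection`, `geometry`, `gates` (a list
#' of mappings), `density_resolution`, `seed` and either `scenario` or
#' `stream_path`, all mapping onto the [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a stream, detects and labels transit events, flags
#' rain-invalid intervals, extracts per-event features, assigns clusters,
#' and computes all-insect and per-cluster aerial density series. The run
#' is deterministic given the configuration (including its seed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the event, feature and
#'   density tables are written there as CSV.
#' @return List with `stream`, `ledger` (simulated runs only), `events`,
#'   `features` (with a `cluster` column), `validity`, `density` (named
#'   list of `density_series`: `all_insects` plus one per gate), and `log`
#'   (per-stage counts; see Details).
#' @details The run log reports `n_detected`, `n_insect`, `n_non_insect`,
#'   `invalid_s` and the package version; by construction
#'   `n_insect + n_non_insect = n_detected`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config")
  }
  if (!is.null(config$scenario)) {
    scenario <- config$scenario
    scenario$seed <- config$seed
    sim <- simulate_stream(scenario)
    stream <- sim$stream
    ledger <- sim$ledger
  } else {
    stream <- read_stream(config$stream_path)
    ledger <- NULL
  }
  cfg <- config$detection
  events <- detect_events(stream, cfg)
  events <- label_events(stream, events, cfg)
  t_end <- length(stream$samples) / stream$sampling_rate
  validity <- flag_invalid_intervals(stream, cfg,
                                     resolution = config$density_resolution)
  features <- extract_features(stream, events, cfg, config$geometry)
  if (nrow(features)) {
    features$cluster <- assign_cluster(features, config$gates)
  } else {
    features$cluster <- character()
  }
  vmask <- validity$valid
  density <- list(
    all_insects = aerial_density(features, 0, t_end,
                                 config$density_resolution,
                                 probe_volume(config$geometry), vmask)
  )
  for (g in config$gates) {
    density[[g$name]] <- aerial_density(
      features[features$cluster == g$name, , drop = FALSE], 0, t_end,
      config$density_resolution, probe_volume(config$geometry), vmask)
  }
  log <- list(
    n_detected = nrow(events),
    n_insect = sum(events$label == "insect"),
    n_non_insect = sum(events$label == "non_insect"),
    n_features = nrow(features),
    cluster_counts = if (nrow(features)) table(features$cluster) else table(character()),
    invalid_s = sum(!validity$valid) * config$density_resolution,
    version = as.character(utils::packageVersion("entosense"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(density$all_insects),
                     file.path(out_dir, "density.csv"), row.names = FALSE)
  }
  list(stream = stream, ledger = ledger, events = events,
       features = features, validity = validity, density = density,
       log = log)
}
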