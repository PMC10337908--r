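#' Read and write current traces as CSV
#'
#' Traces are exchanged as two-column CSV with the mandatory header
#' `time_s,current_nA`. Reading validates the header and that time is
#' strictly increasing; the round trip is lossless at 15 significant
#' digits.
#'
#' @param path File path.
#' @return `read_trace` returns a [current_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  if (!identical(names(df)[1:2], c("time_s", "current_nA"))) {
    stop("malformed trace header: expected 'time_s,current_nA', got '",
         paste(names(df), collapse = ","), "'")
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("trace time column is not strictly increasing")
  }
  current_trace(df$time_s, df$current_nA)
}

#' @rdname read_trace
#' @param trace A [current_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  df <- data.frame(time_s = trace$time_s, current_nA = trace$current_na)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read and write image stacks as 16-bit TIFF
#'
#' Stacks are numeric arrays with dimensions (y, x, z); a matrix is treated
#' as a single slice. Intensities are stored as 16-bit samples: values are
#' clamped to `[0, max_value]` and scaled on write, and returned on the
#' original scale on read. Integer-valued stacks round-trip exactly.
#'
#' @param path File path.
#' @param max_value Full-scale intensity mapped to 65535.
#' @return `read_stack` returns a numeric (y, x, z) array.
#' @export
read_stack <- function(path, max_value = 65535) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr * (max_value / 65535)
}

#' @rdname read_stack
#' @param stack Numeric matrix or (y, x, z) array, values in
#'   `[0, max_value]`.
#' @export
write_stack <- function(stack, path, max_value = 65535) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  scaled <- pmin(pmax(stack / max_value, 0), 1)
  pages <- lapply(seq_len(dim(stack)[3]), function(i) scaled[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read and write gonad layout tables
#'
#' CSV with columns `nucleus_id`, `animal_id`, `position` and any of the
#' status columns `collapsed`, `him8_foci`, `coloc_fraction` (plus optional
#' `zone`, `stage`).
#'
#' @param path File path.
#' @param gonad_length Axis length attached to the returned layout.
#' @return `read_layout` returns a `gonad_layout` data frame.
#' @export
read_layout <- function(path, gonad_length = NULL) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("nucleus_id", "animal_id", "position")
  if (!all(need %in% names(df))) {
    stop("layout file must contain columns: ", paste(need, collapse = ", "))
  }
  if (is.null(gonad_length)) gonad_length <- max(df$position)
  attr(df, "gonad_length") <- gonad_length
  class(df) <- c("gonad_layout", class(df))
  df
}

#' @rdname read_layout
#' @param layout A `gonad_layout` data frame.
#' @export
write_layout <- function(layout, path) {
  data.table::fwrite(as.data.frame(layout), path)
  invisible(path)
}

resolve_path <- function(path, dir) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(dir, path)
}

#' Run a configured multi-stage pipeline
#'
#' Executes the stages of a run configuration in order, writing every stage
#' output plus a JSON provenance record (`provenance.json`: effective
#' config, seed, package and R versions, timestamp). Any invocation is a
#' pure function of (config, seed): identical inputs give identical stage
#' outputs.
#'
#' Supported stages and their parameters:
#' \describe{
#'   \item{`simulate_nps`}{`n`, `mean_diameter_um`, `sd_diameter_um`,
#'     `softness`, `noise_sd_na`, plus any [simulate_nps_trace()] argument;
#'     writes `trace` (CSV) and `truth` (CSV).}
#'   \item{`analyze_nps`}{`trace` (CSV in), optional analysis `params`;
#'     writes `events` (CSV) and `summary` (JSON).}
#'   \item{`zones`}{`layout` (CSV in), `predicate`, `n_zones`,
#'     `gonad_length`; writes `summary` (CSV).}
#'   \item{`stats`}{`input` (CSV in, columns group/value), `test` one of
#'     `welch-anova`, `games-howell`, or a [standard_tests()] name; writes
#'     `result` (JSON).}
#' }
#'
#' @param config List, or path to a YAML file with the same structure:
#'   `seed`, optional `geometry` overrides, and `stages` (a named list;
#'   each element is a list of stage parameters keyed by stage type via its
#'   `stage` field).
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, a list of per-stage results; side effect: files under
#'   `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$stages)) stop("config must define 'stages'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- if (is.null(config$geometry)) {
    default_geometry()
  } else {
    do.call(channel_geometry, config$geometry)
  }

  results <- list()
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    stage <- st$stage
    if (is.null(stage)) stop("stage ", si, " lacks a 'stage' field")
    results[[si]] <- switch(stage,
      simulate_nps = {
        pop <- nucleus_population(
          n = st$n %||% 60,
          mean_diameter_um = st$mean_diameter_um %||% 3.41,
          sd_diameter_um = st$sd_diameter_um %||% 0.3,
          softness = st$softness %||% 0,
          seed = seed + si)
        sim_args <- st[setdiff(names(st), c("stage", "n", "mean_diameter_um",
                                            "sd_diameter_um", "softness",
                                            "trace", "truth"))]
        sim <- do.call(simulate_nps_trace,
                       c(list(geometry = geometry, particles = pop,
                              seed = seed + si), sim_args))
        write_trace(sim$trace, resolve_path(st$trace %||% "trace.csv", output_dir))
        data.table::fwrite(sim$truth,
                           resolve_path(st$truth %||% "truth.csv", output_dir))
        list(stage = stage, n = nrow(sim$truth))
      },
      analyze_nps = {
        tr <- read_trace(resolve_path(st$trace %||% "trace.csv", output_dir))
        meas <- analyze_run(tr, geometry, config = st$params %||% list())
        data.table::fwrite(as.data.frame(meas),
                           resolve_path(st$events %||% "events.csv", output_dir))
        jsonlite::write_json(attr(meas, "summary"),
                             resolve_path(st$summary %||% "summary.json",
                                          output_dir),
                             auto_unbox = TRUE, digits = NA)
        list(stage = stage, summary = attr(meas, "summary"))
      },
      zones = {
        lay <- read_layout(resolve_path(st$layout, output_dir),
                           gonad_length = st$gonad_length)
        zs <- zone_fractions(lay, st$predicate %||% "collapsed",
                             n_zones = st$n_zones %||% 6,
                             gonad_length = st$gonad_length)
        data.table::fwrite(as.data.frame(zs),
                           resolve_path(st$summary %||% "zone_summary.csv",
                                        output_dir))
        list(stage = stage, summary = zs)
      },
      stats = {
        df <- data.table::fread(resolve_path(st$input, output_dir),
                                data.table = FALSE)
        test <- st$test %||% "welch-anova"
        res <- switch(test,
          "welch-anova" = unclass(welch_anova(df)),
          "games-howell" = games_howell(df),
          standard_tests(test, df)["p_value"])
        jsonlite::write_json(res,
                             resolve_path(st$result %||% "stats.json",
                                          output_dir),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        list(stage = stage, result = res)
      },
      stop("unknown stage: ", stage)
    )
  }

  prov <- list(seed = seed, config = config,
               package_version = as.character(packageVersion("nucmech")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
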