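# JSON configuration loading and result serialization.

.sim_config_keys <- c(
  "N0", "K", "m", "m_size", "generations", "seed",
  "p", "s", "h", "flood_height_noise",
  "n", "c", "overlap", "adult_survival", "adult_mortality",
  "regime", "life_history"
)

.build_sim_config <- function(x) {
  unknown <- setdiff(names(x), .sim_config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown field in simulation config: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  reg_in <- if (!is.null(x$regime)) x$regime else x
  lh_in <- if (!is.null(x$life_history)) x$life_history else x
  grab <- function(lst, key, default) {
    if (is.null(lst[[key]])) default else lst[[key]]
  }
  regime <- environment_regime(
    p = grab(reg_in, "p", 0.05),
    s = grab(reg_in, "s", 1),
    h = grab(reg_in, "h", 0.4),
    flood_height_noise = grab(reg_in, "flood_height_noise", 0)
  )
  lh <- life_history(
    n = grab(lh_in, "n", 1L),
    c = grab(lh_in, "c", 5),
    overlap = grab(lh_in, "overlap", FALSE),
    adult_survival = grab(lh_in, "adult_survival", 0),
    adult_mortality = grab(lh_in, "adult_mortality", FALSE)
  )
  sim_config(
    N0 = grab(x, "N0", 5000L),
    K = grab(x, "K", 5000L),
    m = grab(x, "m", 0.001),
    m_size = grab(x, "m_size", 0.05),
    generations = grab(x, "generations", 2000L),
    seed = grab(x, "seed", 1L),
    regime = regime, life_history = lh
  )
}

#' Load a configuration from a JSON file
#'
#' Dispatches on the keys present: a file with `target` becomes a
#' [climate_change_spec()]; one with any of `p_values`, `s_values`,
#' `n_values`, `replicates` becomes a [sweep_grid()] (its `base_config`
#' sub-object, if any, is parsed as a simulation config); anything else
#' becomes a [sim_config()]. Omitted fields take the baseline defaults
#' (`N0 = K = 5000`, `m = 0.001`, `m_size = 0.05`, `h = 0.4`, `c = 5`,
#' `generations = 2000`). Unknown keys and out-of-range values raise an
#' error naming the offending field.
#'
#' @param path Path to a JSON file.
#' @return A `sim_config`, `sweep_grid`, or `climate_change_spec`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(x$target)) {
    known <- c("target", "delta", "change_generation", "followup_generations")
    unknown <- setdiff(names(x), known)
    if (length(unknown)) {
      stop(sprintf("unknown field in climate-change spec: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    args <- x[intersect(known, names(x))]
    return(do.call(climate_change_spec, args))
  }
  grid_keys <- c("p_values", "s_values", "n_values", "replicates")
  if (any(grid_keys %in% names(x))) {
    known <- c(grid_keys, "base_config")
    unknown <- setdiff(names(x), known)
    if (length(unknown)) {
      stop(sprintf("unknown field in sweep grid: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    base <- if (is.null(x$base_config)) sim_config() else
      .build_sim_config(x$base_config)
    args <- x[intersect(grid_keys, names(x))]
    args$base_config <- base
    return(do.call(sweep_grid, args))
  }
  .build_sim_config(x)
}

#' Serialize a configuration object to a JSON file
#'
#' Writes [sim_config()], [sweep_grid()], or [climate_change_spec()] objects
#' in the same layout that [load_config()] reads, so configurations
#' round-trip losslessly.
#'
#' @param config The configuration object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- if (inherits(config, "sim_config")) {
    list(N0 = config$N0, K = config$K, m = config$m, m_size = config$m_size,
         generations = config$generations, seed = config$seed,
         regime = unclass(config$regime),
         life_history = unclass(config$life_history))
  } else if (inherits(config, "sweep_grid")) {
    list(p_values = config$p_values, s_values = config$s_values,
         n_values = config$n_values, replicates = config$replicates,
         base_config = list(
           N0 = config$base_config$N0, K = config$base_config$K,
           m = config$base_config$m, m_size = config$base_config$m_size,
           generations = config$base_config$generations,
           seed = config$base_config$seed,
           regime = unclass(config$base_config$regime),
           life_history = unclass(config$base_config$life_history)))
  } else if (inherits(config, "climate_change_spec")) {
    unclass(config)
  } else {
    stop("unsupported configuration object", call. = FALSE)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.result_tables <- function(result) {
  if (inherits(result, "replicate_result")) {
    list(trajectories = result$trajectory, replicates = NULL, summary = NULL,
         seeds = result$seed)
  } else if (inherits(result, "sweep_result") ||
             inherits(result, "climate_result")) {
    list(trajectories = NULL, replicates = result$replicates,
         summary = result$summary, seeds = unique(result$replicates$seed))
  } else {
    stop("unsupported result object", call. = FALSE)
  }
}

#' Write result tables and a run manifest
#'
#' Writes deterministic, full-precision CSV tables (per-cell `summary.csv`,
#' per-replicate `replicates.csv`, and/or per-generation `trajectories.csv`,
#' depending on the result type) plus a JSON `manifest.json` recording the
#' seeds, package version, timestamp, and output paths. Re-running with the
#' same inputs reproduces the CSVs byte for byte (the manifest timestamp is
#' the only non-deterministic output).
#'
#' @param result A `replicate_result`, `sweep_result`, or `climate_result`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  tabs <- .result_tables(result)
  files <- character(0)
  for (name in c("summary", "replicates", "trajectories")) {
    if (!is.null(tabs[[name]])) {
      f <- file.path(out_dir, paste0(name, ".csv"))
      readr::write_csv(tabs[[name]], f)
      files <- c(files, f)
    }
  }
  manifest <- list(
    package = "floodhedge",
    version = as.character(utils::packageVersion("floodhedge")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    result_class = class(result)[1],
    seeds = tabs$seeds,
    files = basename(files)
  )
  if (!is.null(result$config)) {
    manifest$config <- jsonlite::fromJSON(jsonlite::toJSON(
      list(N0 = result$config$N0, K = result$config$K, m = result$config$m,
           m_size = result$config$m_size,
           generations = result$config$generations,
           seed = result$config$seed,
           regime = unclass(result$config$regime),
           life_history = unclass(result$config$life_history)),
      auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
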