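#' Load and validate a run configuration
#'
#' Reads a YAML run configuration and validates every block against its
#' module's constraints before any computation runs; validation errors
#' name the offending key and the violated bound. Omitted blocks fall
#' back to package defaults (the final coupling preset, the shipped
#' intervention library, a 20-patient fixed-baseline cohort, the default
#' sensitivity grid, seed 1 — a missing seed is injected and reported
#' with a message).
#'
#' @param path Path to a YAML configuration file; see
#'   `system.file("params", "default-config.yaml", package = "abqsp")`
#'   for the shipped template.
#' @return A list of class `run_config` with elements `coupling`,
#'   `interventions`, `cohort`, `trial`, `sensitivity_grid`, `out_dir`,
#'   `seed`, `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  bad <- function(key, msg) stop("config key `", key, "`: ", msg, call. = FALSE)

  cp <- raw$coupling
  coupling <- if (is.null(cp)) coupling_presets("final") else {
    for (nm in c("delta", "alpha", "alpha_star", "beta")) {
      v <- cp[[nm]]
      if (!is.null(v) && (!is.numeric(v) || v < 0))
        bad(paste0("coupling.", nm), "must be a non-negative number")
    }
    do.call(coupling_params, cp)
  }

  ints <- intervention_library()
  if (!is.null(raw$interventions)) {
    ints <- lapply(raw$interventions, function(iv) {
      for (nm in c("reduction_x", "reduction_y")) {
        v <- iv[[nm]]
        if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
          bad(paste0("interventions.*.", nm), "must lie in [0, 1]")
      }
      intervention(iv$name, iv$reduction_x, iv$reduction_y,
                   iv$dose_label %||% "")
    })
  }

  ch <- .fix_yaml_bool_keys(raw$cohort)
  cohort <- if (is.null(ch)) cohort_spec(20) else {
    n <- ch$n %||% 20
    if (!is.numeric(n) || n < 1) bad("cohort.n", "must be >= 1")
    gf <- ch$genotype_freq %||% c(0.25, 0.5, 0.25)
    if (abs(sum(gf) - 1) > 1e-9)
      bad("cohort.genotype_freq", "must sum to 1")
    nz <- ch$noise_sd %||% 0
    if (nz < 0) bad("cohort.noise_sd", "must be >= 0")
    bl <- .fix_yaml_bool_keys(ch$baseline)
    baseline <- if (is.null(bl)) fixed_baseline(8, 8)
    else if (identical(bl$kind, "uniform-region"))
      uniform_region_baseline(region_partition(bl$cutoff %||% 3),
                              bl$region %||% "neg")
    else {
      if (is.null(bl$x) || is.null(bl$y) ||
          any(c(bl$x, bl$y) < 0) || any(c(bl$x, bl$y) > 16))
        bad("cohort.baseline.x/y", "must lie in [0, 16]")
      fixed_baseline(bl$x, bl$y)
    }
    cohort_spec(n, baseline, gf, nz)
  }

  seed <- raw$seed
  if (is.null(seed)) {
    seed <- 1L
    message("config omits `seed`; using deterministic default seed 1")
  }
  if (!is.numeric(seed) || seed != round(seed)) bad("seed", "must be an integer")

  wk <- raw$trial$eval_weeks %||% c(0, 12, 26, 52, 78)
  if (any(wk < 0) || any(wk > 78)) bad("trial.eval_weeks", "must lie in [0, 78]")

  grid <- raw$sensitivity_grid %||% default_sensitivity_grid()
  grid <- lapply(grid, as.numeric)

  structure(list(
    coupling = coupling, interventions = ints, cohort = cohort,
    trial = trial_spec(arms = c(list(placebo = NULL), ints), cohort = cohort,
                       eval_weeks = as.numeric(wk), coupling = coupling,
                       seed = as.integer(seed)),
    sensitivity_grid = grid,
    out_dir = raw$out_dir %||% "abqsp-output",
    seed = as.integer(seed),
    log_level = raw$log_level %||% "info"
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 parses bare `n`/`y` keys as booleans; map them back so cohort
# size and load coordinates can be written unquoted
.fix_yaml_bool_keys <- function(x) {
  if (is.null(x)) return(x)
  nm <- names(x)
  nm[nm == "FALSE"] <- "n"
  nm[nm == "TRUE"] <- "y"
  names(x) <- nm
  x
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: seed %d, out_dir '%s', %d interventions\n",
              x$seed, x$out_dir, length(x$interventions)))
  print(x$coupling)
  invisible(x)
}

#' Write result tables and a run manifest
#'
#' Writes each element of `results` (data.frames) as a comma-separated
#' table with a `#`-prefixed header line naming the table, plus a
#' `manifest.csv` recording file names, row counts, the seed and the
#' package version. Re-running with the same inputs produces
#' byte-identical tables (the manifest timestamp is excluded from the
#' data files).
#'
#' @param results Named list of data.frames.
#' @param directory Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the manifest data.frame.
#' @export
write_outputs <- function(results, directory, seed = NA_integer_) {
  stopifnot(is.list(results))
  if (length(results) && (is.null(names(results)) || any(!nzchar(names(results)))))
    stop("`results` must be a named list of data.frames", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create ", directory, call. = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) stop("result `", nm, "` is not a data.frame", call. = FALSE)
    f <- file.path(directory, paste0(nm, ".csv"))
    con <- file(f, "w")
    writeLines(sprintf("# abqsp table '%s'; ADAS-Cog in points (0-70), loads in model units (0-16), weeks from trial start", nm), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    files <- c(files, f)
  }
  manifest <- data.frame(
    file = c(basename(files)),
    rows = vapply(results, nrow, integer(1)),
    seed = seed,
    package_version = as.character(utils::packageVersion("abqsp")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
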