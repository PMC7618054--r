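#' Run a reproducible analysis stage from a configuration
#'
#' Orchestrates the package's analyses behind a single entry point with a
#' validated configuration, deterministic seeding, structured logging and a
#' run manifest.  Modes:
#' \describe{
#'   \item{simulate}{integrate the model to steady state; writes the
#'     steady-state table and a tidy trajectory CSV.}
#'   \item{sweep}{dose-response sweep over `k_ap`; writes the curve CSV and
#'     its Hill-fit JSON.}
#'   \item{morris}{full Morris screen; writes long results CSV and the wide
#'     normalised-mu* heatmap CSV.}
#'   \item{synthstudy}{synthetic cytometry study; writes the well-summary
#'     CSV and its Hill-fit JSON.}
#'   \item{fit}{Hill fit of an existing curve CSV; writes the fit JSON.}
#' }
#'
#' The configuration is a YAML/JSON file (or an equivalent named list) with
#' fields `mode`, `out_dir`, `seed`, and per-mode blocks: `parameters`
#' (path to a parameter file, optional), `kap_grid` (`points`, `lo`, `hi`),
#' `design` (`p`, `R`, `r`), `space` (`span`), `study` (`fixture`,
#' `replicates`, `noise_cv`), `curve` (path, for `fit`).  Identical
#' configuration plus seed yields identical artifacts.
#'
#' @param config path to a YAML/JSON configuration, or a named list.
#' @param seed optional override of the configured seed.
#' @param out_dir optional override of the configured output directory.
#' @param quiet suppress progress messages.
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("missing config file: ", config)
    .read_flat_map(config)
  } else if (is.list(config)) config
  else stop("config must be a file path or a named list")

  cfg <- .validate_run_config(cfg, seed, out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  set.seed(cfg$seed)
  params <- if (!is.null(cfg$parameters)) {
    if (!file.exists(cfg$parameters))
      stop("missing parameter file: ", cfg$parameters)
    read_tcs_parameters(cfg$parameters)
  } else tcs_parameters()

  artifacts <- character(0)
  log <- list()

  if (cfg$mode == "simulate") {
    say("mode=simulate: integrating to steady state")
    ss <- simulate_to_steady_state(params)
    f1 <- file.path(cfg$out_dir, "steady_state.csv")
    utils::write.csv(data.frame(species = names(ss$state),
                                value = as.numeric(ss$state)),
                     f1, row.names = FALSE)
    traj <- simulate_trajectory(params, times = seq(0, ss$time, length.out = 200))
    f2 <- file.path(cfg$out_dir, "trajectory.csv")
    utils::write.csv(traj, f2, row.names = FALSE)
    artifacts <- c(f1, f2)
    log$converged <- ss$converged
  } else if (cfg$mode == "sweep") {
    grid <- do.call(default_kap_grid, cfg$kap_grid)
    say("mode=sweep: %d-point dose-response sweep", length(grid))
    curve <- sweep_dose_response(params, grid)
    f1 <- file.path(cfg$out_dir, "dose_response.csv")
    write_dose_response_csv(curve, f1)
    fit <- fit_hill(curve)
    f2 <- file.path(cfg$out_dir, "hill_fit.json")
    write_hill_fit_json(fit, f2)
    artifacts <- c(f1, f2)
    log$fit_converged <- fit$converged
  } else if (cfg$mode == "morris") {
    design <- do.call(morris_design,
                      c(cfg$design, list(seed = cfg$seed)))
    space <- default_parameter_space(params,
                                     span = cfg$space$span %||% 1)
    grid <- do.call(default_kap_grid, cfg$kap_grid)
    say("mode=morris: R=%d candidates, r=%d selected, %d-point grid",
        design$R, design$r, length(grid))
    res <- morris_screen(params, space, design, grid)
    f1 <- file.path(cfg$out_dir, "morris_results.csv")
    f2 <- file.path(cfg$out_dir, "morris_heatmap.csv")
    write_morris_csv(res, f1, f2)
    artifacts <- c(f1, f2)
    log$failed_fits <- res$n_failed
  } else if (cfg$mode == "synthstudy") {
    fixture <- hill_fixture(cfg$study$fixture %||% "asah0")
    say("mode=synthstudy: fixture '%s'", fixture$name)
    study <- generate_study(fixture,
                            replicates = cfg$study$replicates %||% 3L,
                            noise_cv = cfg$study$noise_cv %||% 0.05,
                            seed = cfg$seed)
    f1 <- file.path(cfg$out_dir, "wells.csv")
    write_wells_csv(study, f1)
    fit <- fit_study(study)
    f2 <- file.path(cfg$out_dir, "hill_fit.json")
    write_hill_fit_json(fit, f2)
    artifacts <- c(f1, f2)
    log$fit_converged <- fit$converged
  } else if (cfg$mode == "fit") {
    if (is.null(cfg$curve)) stop("config field 'curve' is required for mode=fit")
    if (!file.exists(cfg$curve)) stop("missing curve file: ", cfg$curve)
    curve <- read_dose_response_csv(cfg$curve)
    fit <- fit_hill(curve)
    f1 <- file.path(cfg$out_dir, "hill_fit.json")
    write_hill_fit_json(fit, f1)
    artifacts <- f1
    log$fit_converged <- fit$converged
  }

  manifest <- list(
    mode = cfg$mode,
    seed = cfg$seed,
    config_hash = .config_hash(cfg),
    artifacts = basename(artifacts),
    artifact_md5 = as.vector(tools::md5sum(artifacts)),
    log = log,
    package_version = as.character(utils::packageVersion("atosensor")),
    r_version = as.character(getRversion()),
    wall_time_utc = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %d artifact(s) to %s", length(artifacts), cfg$out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_modes <- c("simulate", "sweep", "morris", "synthstudy", "fit")

# Schema validation happens before any simulation so bad configs fail fast.
.validate_run_config <- function(cfg, seed = NULL, out_dir = NULL) {
  if (is.null(cfg$mode)) stop("config field 'mode' is required")
  if (!cfg$mode %in% .run_modes)
    stop("config field 'mode' must be one of: ",
         paste(.run_modes, collapse = ", "))
  cfg$seed <- as.integer(seed %||% cfg$seed %||% 1L)
  if (is.na(cfg$seed)) stop("config field 'seed' must be an integer")
  cfg$out_dir <- out_dir %||% cfg$out_dir %||% stop(
    "config field 'out_dir' is required")
  cfg$kap_grid <- cfg$kap_grid %||% list()
  # 'points' rather than 'n': a bare n is a YAML 1.1 boolean
  bad <- setdiff(names(cfg$kap_grid), c("points", "lo", "hi"))
  if (length(bad)) stop("unknown kap_grid field(s): ",
                        paste(bad, collapse = ", "))
  names(cfg$kap_grid)[names(cfg$kap_grid) == "points"] <- "n"
  if (cfg$mode == "morris") {
    cfg$design <- cfg$design %||% list()
    bad <- setdiff(names(cfg$design), c("p", "R", "r"))
    if (length(bad)) stop("unknown design field(s): ",
                          paste(bad, collapse = ", "))
    d <- c(list(p = 4, R = 1000, r = 50), cfg$design)
    if (!is.null(cfg$design$r) && !is.null(cfg$design$R) &&
        cfg$design$r > cfg$design$R)
      stop("design field 'r' must be <= 'R'")
    cfg$space <- cfg$space %||% list()
  }
  if (cfg$mode == "synthstudy") {
    cfg$study <- cfg$study %||% list()
    bad <- setdiff(names(cfg$study), c("fixture", "replicates", "noise_cv"))
    if (length(bad)) stop("unknown study field(s): ",
                          paste(bad, collapse = ", "))
  }
  cfg
}

# Deterministic hash of the effective analytical configuration (the output
# location and wall metadata are not part of the analysis' identity).
.config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
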