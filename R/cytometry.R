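#' Generate one synthetic flow-cytometry event sample
#'
#' Per-cell GFP fluorescence is drawn log-normally — the standard model for
#' single-cell fluorescence, with strictly positive support.  The log-median
#' equals `log(median_au)` and the dispersion is set so the coefficient of
#' variation equals `cv` (`sdlog = sqrt(log(1 + cv^2))`).  `cv = 0` is the
#' degenerate noise-free limit (every event exactly `median_au`).
#'
#' @param median_au true median fluorescence, arbitrary units (> 0).
#' @param cv coefficient of variation of the event distribution
#'   (`0 <= cv < 2`).
#' @param n_events events to record per sample (10,000 by default, the
#'   conventional per-well event count).
#' @param seed optional RNG seed for reproducibility.
#' @param well_id,inducer_conc,replicate sample annotations.
#' @return list of class `event_sample` with fields `values`, `well_id`,
#'   `inducer_conc`, `replicate`.
#' @export
generate_events <- function(median_au, cv = 0.4, n_events = 10000L,
                            seed = NULL, well_id = "well",
                            inducer_conc = NA_real_, replicate = 1L) {
  if (!is.finite(median_au) || median_au <= 0)
    stop("median_au must be a positive finite number")
  if (cv < 0 || cv >= 2) stop("cv must satisfy 0 <= cv < 2")
  if (n_events < 1) stop("n_events must be >= 1")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(seed)
  }
  values <- if (cv == 0) rep(median_au, n_events)
  else stats::rlnorm(n_events, meanlog = log(median_au),
                     sdlog = sqrt(log(1 + cv^2)))
  structure(list(values = values, well_id = well_id,
                 inducer_conc = inducer_conc,
                 replicate = as.integer(replicate)),
            class = "event_sample")
}

#' Synthetic rainbow calibration bead reference
#'
#' Bead peaks with known molecules-of-equivalent-fluorophore (MEF) values
#' spanning the instrument range, observed in arbitrary units through a
#' power-law instrument response `au = (mef / gain)^(1 / slope)` with
#' optional multiplicative log-normal peak noise.  Peak MEF values follow
#' the familiar 8-peak rainbow-particle ladder.
#'
#' @param gain instrument gain (MEF per a.u. when `slope = 1`).
#' @param slope true log-log slope of the instrument response.
#' @param noise_cv multiplicative noise on the observed peak a.u. (0 = exact).
#' @param seed optional RNG seed.
#' @return list of class `bead_reference` with increasing `peak_au`,
#'   `peak_mef`.
#' @export
synthetic_bead_reference <- function(gain = 2, slope = 1, noise_cv = 0,
                                     seed = NULL) {
  peak_mef <- c(792, 2079, 6588, 16471, 47497, 137049, 271647, 709431)
  peak_au <- (peak_mef / gain)^(1 / slope)
  if (noise_cv > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      })
      set.seed(seed)
    }
    peak_au <- peak_au * stats::rlnorm(length(peak_au), 0,
                                       sqrt(log(1 + noise_cv^2)))
    peak_au <- sort(peak_au)
  }
  bead_reference(peak_au, peak_mef)
}

#' @rdname synthetic_bead_reference
#' @param peak_au,peak_mef matched strictly increasing positive vectors
#'   (>= 4 peaks).
#' @export
bead_reference <- function(peak_au, peak_mef) {
  if (length(peak_au) != length(peak_mef) || length(peak_au) < 4L)
    stop("at least 4 matched bead peaks are required")
  if (any(peak_au <= 0) || any(peak_mef <= 0) ||
      is.unsorted(peak_au, strictly = TRUE) ||
      is.unsorted(peak_mef, strictly = TRUE))
    stop("bead peaks must be positive and strictly increasing")
  structure(list(peak_au = as.numeric(peak_au),
                 peak_mef = as.numeric(peak_mef)),
            class = "bead_reference")
}

#' Fit the MEF calibration from bead peaks
#'
#' Ordinary least squares of `log10(peak_mef)` on `log10(peak_au)` — the
#' standard conversion of instrument arbitrary units to absolute MEF units.
#'
#' @param beads a [bead_reference()].
#' @return list of class `mef_calibration` with `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_calibration <- function(beads) {
  stopifnot(inherits(beads, "bead_reference"))
  fit <- stats::lm(log10(beads$peak_mef) ~ log10(beads$peak_au))
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) stop("calibration slope must be positive")
  y <- log10(beads$peak_mef)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2),
            class = "mef_calibration")
}

#' The identity a.u.-to-MEF calibration
#'
#' @return an `mef_calibration` with slope 1, intercept 0.
#' @export
identity_calibration <- function() {
  structure(list(slope = 1, intercept = 0, r_squared = 1),
            class = "mef_calibration")
}

#' Convert arbitrary units to MEF through a calibration
#'
#' `mef = 10^(intercept + slope * log10(au))`; strictly monotone, so it
#' commutes with the median.
#'
#' @param cal an `mef_calibration`.
#' @param au positive fluorescence values in arbitrary units.
#' @return MEF values.
#' @export
au_to_mef <- function(cal, au) {
  stopifnot(inherits(cal, "mef_calibration"))
  10^(cal$intercept + cal$slope * log10(au))
}

#' Summarise one well: median fluorescence in a.u. and MEF
#'
#' @param events an [generate_events()] sample.
#' @param cal an `mef_calibration` (positive slope).
#' @return one-row data.frame of class `well_summary`: `well_id`,
#'   `inducer_conc`, `replicate`, `n_events`, `median_au`, `median_mef`.
#' @export
summarize_well <- function(events, cal = identity_calibration()) {
  stopifnot(inherits(events, "event_sample"), inherits(cal, "mef_calibration"))
  if (cal$slope <= 0) stop("calibration slope must be positive")
  med <- stats::median(events$values)
  out <- data.frame(
    well_id = events$well_id,
    inducer_conc = events$inducer_conc,
    replicate = events$replicate,
    n_events = length(events$values),
    median_au = med,
    median_mef = au_to_mef(cal, med),
    stringsAsFactors = FALSE
  )
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Hill-parameter fixtures for synthetic dose-response studies
#'
#' Named ground-truth transfer functions used by the recovery experiments.
#' The half-maximal doses (in uM acetoacetate) and, for `asah0`, the fold
#' change, are pinned to reported characterisations of the corresponding
#' biosensor strains; the absolute fluorescence levels and Hill coefficients
#' are this package's stand-ins (the qualitative fmin/fmax ordering between
#' constructs is preserved: the genome-expressed high-copy sensor has the
#' lowest basal level and largest amplitude; the plasmid-expressed variants
#' sit higher in fmin and lower in fmax, with the low-copy variant below the
#' high-copy one).
#'
#' \describe{
#'   \item{asah0}{K = 344 uM, fold change 115 (dynamic range 114):
#'     fmin = 100, fmax = 11500, n = 1.5.}
#'   \item{asah2j06}{K = 31.7 uM: fmin = 500, fmax = 8000, n = 1.5.}
#'   \item{asal2j06}{K = 40.1 uM: fmin = 250, fmax = 4000, n = 1.5.}
#' }
#'
#' @param name one of `"asah0"`, `"asah2j06"`, `"asal2j06"`.
#' @return list of class `hill_fixture` with `fmin`, `fmax`, `K`, `n`,
#'   `dynamic_range`, `fold_change`.
#' @export
hill_fixture <- function(name = c("asah0", "asah2j06", "asal2j06")) {
  name <- match.arg(name)
  f <- switch(name,
    asah0    = list(fmin = 100, fmax = 11500, K = 344,  n = 1.5),
    asah2j06 = list(fmin = 500, fmax = 8000,  K = 31.7, n = 1.5),
    asal2j06 = list(fmin = 250, fmax = 4000,  K = 40.1, n = 1.5)
  )
  f$dynamic_range <- (f$fmax - f$fmin) / f$fmin
  f$fold_change <- f$fmax / f$fmin
  f$name <- name
  class(f) <- "hill_fixture"
  f
}

#' Default acetoacetate concentration grid for synthetic studies (uM)
#'
#' Thirteen concentrations from 0 to 20 mM — the top of the induction range —
#' down through the sub-K1/2 regime.
#'
#' @return numeric vector of concentrations in uM.
#' @export
default_conc_grid <- function() {
  c(0, 5, 10, 25, 50, 100, 250, 500, 1000, 2500, 5000, 10000, 20000)
}

#' Generate a full synthetic dose-response study
#'
#' Emulates the study design of a plate-based biosensor characterisation:
#' for every (concentration, replicate) pair the true well median is the
#' fixture's Hill response times a multiplicative log-normal replicate factor
#' with coefficient of variation `noise_cv`; 10,000 log-normal events with
#' event-level CV `event_cv` are recorded around it, summarised by their
#' median, and calibrated to MEF.  With `noise_cv = 0` the study is the
#' idealised noise-free assay (the replicate factor is 1 and `event_cv` is
#' forced to 0, so well medians equal the Hill response exactly).
#'
#' The whole study is reproducible from `seed`.
#'
#' @param fixture a [hill_fixture()] (or any list with `fmin`, `fmax`, `K`,
#'   `n` satisfying `fmax >= fmin >= 0`, `K > 0`, `n > 0`).
#' @param conc_grid inducer concentrations, uM (non-empty, >= 0).
#' @param replicates biological replicates per concentration (>= 3, the
#'   study convention).
#' @param noise_cv CV of the replicate-to-replicate factor.
#' @param event_cv CV of the single-cell event distribution.
#' @param n_events events per well.
#' @param calibration an `mef_calibration` used for the MEF conversion (the
#'   true wells are defined in MEF units and observed in a.u. through its
#'   inverse).
#' @param seed RNG seed.
#' @param keep_events if `TRUE`, raw event samples are returned alongside
#'   the summaries.
#' @return list of class `synthetic_study`: `wells` (data.frame of one
#'   [summarize_well()] row per well), `events` (list of `event_sample`s or
#'   `NULL`), `calibration`, `fixture`, `seed`.
#' @examples
#' study <- generate_study(hill_fixture("asah0"), seed = 1)
#' fit_hill(data.frame(dose = study$wells$inducer_conc,
#'                     response = study$wells$median_mef))
#' @export
generate_study <- function(fixture, conc_grid = default_conc_grid(),
                           replicates = 3L, noise_cv = 0.05,
                           event_cv = 0.4, n_events = 10000L,
                           calibration = identity_calibration(),
                           seed = 1L, keep_events = FALSE) {
  if (is.null(fixture$fmin) || is.null(fixture$fmax) ||
      is.null(fixture$K) || is.null(fixture$n))
    stop("fixture must provide fmin, fmax, K, n")
  if (fixture$fmax < fixture$fmin || fixture$fmin < 0 ||
      fixture$K <= 0 || fixture$n <= 0)
    stop("fixture violates Hill invariants (fmax >= fmin >= 0, K > 0, n > 0)")
  if (!length(conc_grid)) stop("conc_grid must be non-empty")
  if (any(conc_grid < 0)) stop("concentrations must be >= 0")
  if (replicates < 3L) stop("at least 3 biological replicates are required")
  if (noise_cv == 0) event_cv <- 0

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  sdlog_rep <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  rows <- vector("list", length(conc_grid) * replicates)
  events <- if (keep_events) vector("list", length(rows)) else NULL
  idx <- 0L
  for (ci in seq_along(conc_grid)) {
    conc <- conc_grid[ci]
    true_mef <- hill_eval(conc, fixture$fmin, fixture$fmax, fixture$K,
                          fixture$n)
    for (rep_i in seq_len(replicates)) {
      idx <- idx + 1L
      well_mef <- if (sdlog_rep > 0)
        true_mef * stats::rlnorm(1L, 0, sdlog_rep) else true_mef
      # wells are observed in a.u.; invert the calibration map
      well_au <- 10^((log10(well_mef) - calibration$intercept) /
                       calibration$slope)
      ev <- generate_events(well_au, cv = event_cv, n_events = n_events,
                            well_id = sprintf("c%02d_r%d", ci, rep_i),
                            inducer_conc = conc, replicate = rep_i)
      rows[[idx]] <- summarize_well(ev, calibration)
      if (keep_events) events[[idx]] <- ev
    }
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  structure(list(wells = wells, events = events, calibration = calibration,
                 fixture = fixture, seed = seed),
            class = "synthetic_study")
}

#' Fit the Hill transfer function to a synthetic study's well medians
#'
#' Convenience wrapper: fits [fit_hill()] to (inducer concentration,
#' median MEF) over all wells.
#'
#' @param study a [generate_study()] result.
#' @param ... passed to [fit_hill()].
#' @return a `hill_fit`.
#' @export
fit_study <- function(study, ...) {
  stopifnot(inherits(study, "synthetic_study"))
  fit_hill(data.frame(dose = study$wells$inducer_conc,
                      response = study$wells$median_mef), ...)
}

#' Write well summaries or raw events as tidy CSV
#'
#' @param study a `synthetic_study`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wells_csv <- function(study, path) {
  utils::write.csv(study$wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wells_csv
#' @export
write_events_csv <- function(study, path) {
  if (is.null(study$events))
    stop("study was generated with keep_events = FALSE")
  long <- do.call(rbind, lapply(study$events, function(ev)
    data.frame(well_id = ev$well_id, inducer_conc = ev$inducer_conc,
               replicate = ev$replicate, value = ev$values)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
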