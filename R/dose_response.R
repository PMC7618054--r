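#' Hill transfer function with basal expression
#'
#' `response = fmin + (fmax - fmin) * dose^n / (K^n + dose^n)`.
#' At `dose = 0` the response is `fmin`; at `dose = K` it is halfway between
#' `fmin` and `fmax`; as `dose -> Inf` it approaches `fmax`.  Monotone
#' nondecreasing in dose whenever `fmax >= fmin`.
#'
#' @param dose non-negative dose (vectorised).
#' @param fmin basal response.
#' @param fmax saturating response.
#' @param K half-maximal dose (> 0); the sensor's K1/2.
#' @param n Hill coefficient (> 0).
#' @return numeric vector of responses.
#' @export
hill_eval <- function(dose, fmin, fmax, K, n) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (K <= 0) stop("K must be > 0")
  if (n <= 0) stop("n must be > 0")
  # dose^n / (K^n + dose^n) computed on the ratio scale for overflow safety
  r <- (dose / K)^n
  fmin + (fmax - fmin) * r / (1 + r)
}

#' Default grid of HK autophosphorylation rates for dose-response sweeps
#'
#' Zero dose plus `n - 1` log-spaced points spanning `lo` to `hi`
#' (four decades by default, bracketing the default model's half-maximal
#' `k_ap`).
#'
#' @param n total number of grid points (including the zero dose).
#' @param lo,hi limits of the log-spaced part.
#' @return strictly increasing numeric vector of length `n` starting at 0.
#' @export
default_kap_grid <- function(n = 13, lo = 1e-4, hi = 1) {
  stopifnot(n >= 5, lo > 0, hi > lo)
  c(0, 10^seq(log10(lo), log10(hi), length.out = n - 1L))
}

#' A steady-state dose-response curve
#'
#' Container pairing a strictly increasing dose grid with matched steady-state
#' responses (and optional replicate dispersions).  At least 5 points are
#' required — the minimum to fit the 4-parameter Hill function.
#'
#' @param dose strictly increasing, non-negative doses.
#' @param response matched finite, non-negative responses.
#' @param replicate_sd optional matched response dispersions.
#' @return data.frame of class `dose_response_curve`.
#' @export
dose_response_curve <- function(dose, response, replicate_sd = NULL) {
  if (length(dose) != length(response))
    stop("dose and response must have equal length")
  if (length(dose) < 5L)
    stop("at least 5 dose points are required to fit 4 Hill parameters")
  if (any(dose < 0) || is.unsorted(dose, strictly = TRUE))
    stop("dose must be strictly increasing and >= 0")
  if (any(!is.finite(response)) || any(response < 0))
    stop("responses must be finite and >= 0")
  out <- data.frame(dose = as.numeric(dose), response = as.numeric(response))
  if (!is.null(replicate_sd)) {
    if (length(replicate_sd) != length(dose))
      stop("replicate_sd must match dose length")
    out$replicate_sd <- as.numeric(replicate_sd)
  }
  class(out) <- c("dose_response_curve", "data.frame")
  out
}

#' Sweep the acetoacetate proxy and read the steady-state GFP response
#'
#' One steady-state solve per `k_ap` value; the response is the mature-GFP
#' concentration `Gm`.  Every point must converge.
#'
#' @param params a [tcs_parameters()] object (its own `k_ap` is overridden
#'   point by point).
#' @param kap_grid strictly increasing, non-negative `k_ap` values
#'   (length >= 5); see [default_kap_grid()].
#' @param rel_tol,t_max,use_compiled passed to [simulate_to_steady_state()].
#' @return a [dose_response_curve()] with `dose = kap_grid`.
#' @examples
#' curve <- sweep_dose_response(tcs_parameters(), default_kap_grid(9))
#' plot(curve)
#' @export
sweep_dose_response <- function(params, kap_grid = default_kap_grid(),
                                rel_tol = 1e-6, t_max = 1e6,
                                use_compiled = TRUE) {
  validate_tcs_parameters(params)
  if (length(kap_grid) < 5L)
    stop("kap_grid must have at least 5 points")
  if (any(kap_grid < 0) || is.unsorted(kap_grid, strictly = TRUE))
    stop("kap_grid must be strictly increasing and >= 0")
  response <- vapply(kap_grid, function(kap) {
    p <- params
    p["k_ap"] <- kap
    ss <- simulate_to_steady_state(p, rel_tol = rel_tol, t_max = t_max,
                                   use_compiled = use_compiled)
    if (!ss$converged)
      stop(sprintf("steady state not reached for k_ap = %g (t_max = %g)",
                   kap, t_max))
    ss$state[["Gm"]]
  }, numeric(1))
  dose_response_curve(kap_grid, response)
}

#' @export
plot.dose_response_curve <- function(x, ...) {
  graphics::plot(x$dose, x$response, log = "y",
                 xlab = "dose", ylab = "response", pch = 16, ...)
  graphics::lines(x$dose, x$response, lty = 2)
  invisible(x)
}

#' Fit the Hill transfer function to a dose-response curve
#'
#' Weighted nonlinear least squares of the four-parameter Hill function via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]), with multi-start
#' initialisation over Hill coefficients \{0.5, 1, 2, 4\}: `fmin` starts at
#' the minimum response, `fmax` at the maximum, `K` at the dose whose response
#' is closest to the midpoint.  The best converged start (lowest residual sum
#' of squares) is kept.  Parameters are bounded below by 0 and the Hill
#' coefficient above by 10.  If `replicate_sd` is present (and positive),
#' inverse-variance weights are used.
#'
#' @param curve a [dose_response_curve()], or any data.frame with columns
#'   `dose` and `response` (repeated doses allowed, e.g. replicate wells).
#' @param n_fixed if given, the Hill coefficient is clamped to this value and
#'   not estimated.
#' @return object of class `hill_fit`: the fitted `fmin`, `fmax`, `K`, `n`,
#'   their asymptotic standard errors `se_fmin` ... `se_n`, the derived
#'   `dynamic_range = (fmax - fmin)/fmin` and `fold_change = fmax/fmin`
#'   (so `fold_change - dynamic_range = 1` identically), `converged`, and
#'   `sse`.  If no start converges, `converged = FALSE` and the estimates are
#'   `NA`.
#' @examples
#' d <- default_kap_grid(13)
#' y <- hill_eval(d, 100, 11500, 0.005, 1.5)
#' fit_hill(dose_response_curve(d, y))
#' @export
fit_hill <- function(curve, n_fixed = NULL) {
  if (!is.data.frame(curve) ||
      !all(c("dose", "response") %in% names(curve)))
    stop("curve must be a data.frame with columns 'dose' and 'response'")
  dat <- data.frame(dose = as.numeric(curve$dose),
                    response = as.numeric(curve$response))
  if (any(dat$dose < 0) || any(!is.finite(dat$response)))
    stop("doses must be >= 0 and responses finite")
  if (nrow(dat) < 5L)
    stop("at least 5 points are required")

  w <- rep(1, nrow(dat))
  if (!is.null(curve$replicate_sd) && all(curve$replicate_sd > 0))
    w <- 1 / curve$replicate_sd^2

  fmin0 <- max(min(dat$response), .Machine$double.eps)
  # a strictly positive starting amplitude keeps the K and n directions
  # informative even for flat (insensitive) curves
  fmax0 <- max(max(dat$response), fmin0 * 1.05, .Machine$double.eps)
  mid <- (fmin0 + fmax0) / 2
  K0 <- dat$dose[which.min(abs(dat$response - mid))]
  if (K0 <= 0) K0 <- max(min(dat$dose[dat$dose > 0]), .Machine$double.eps)

  fit_n <- is.null(n_fixed)
  starts <- if (fit_n) c(0.5, 1, 2, 4) else as.numeric(n_fixed)
  sw <- sqrt(w)
  resid_fun <- function(par) {
    n_cur <- if (fit_n) par[4L] else as.numeric(n_fixed)
    sw * (dat$response - hill_eval(dat$dose, par[1L], par[2L],
                                   max(par[3L], 1e-300), n_cur))
  }
  # K is unidentifiable far beyond the sampled dose range; capping it well
  # outside that range terminates the K/fmax ridge without touching any
  # fit whose half-maximal dose the data can actually locate
  K_cap <- 1e3 * max(dat$dose)
  lower <- c(0, 0, 1e-12, 1e-3)[seq_len(3L + fit_n)]
  upper <- c(Inf, Inf, K_cap, 10)[seq_len(3L + fit_n)]

  best <- NULL
  for (n0 in starts) {
    par0 <- c(fmin0, fmax0, K0, if (fit_n) n0)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(par0, lower, upper, resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, maxfev = 5000))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    sse <- fit$deviance
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }

  if (is.null(best)) {
    return(structure(
      list(fmin = NA_real_, fmax = NA_real_, K = NA_real_, n = NA_real_,
           se_fmin = NA_real_, se_fmax = NA_real_, se_K = NA_real_,
           se_n = NA_real_, dynamic_range = NA_real_, fold_change = NA_real_,
           converged = FALSE, sse = NA_real_,
           diagnostics = "no start converged"),
      class = "hill_fit"))
  }

  cf <- best$fit$par
  # asymptotic standard errors from the local curvature at the optimum;
  # NA where the information matrix is singular (e.g. flat curves)
  se <- tryCatch({
    dof <- max(nrow(dat) - length(cf), 1L)
    covm <- best$sse / dof * solve(best$fit$hessian)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(cf)))
  fmin <- cf[1L]; fmax <- cf[2L]; K <- cf[3L]
  n <- if (fit_n) cf[4L] else as.numeric(n_fixed)
  names(se) <- c("fmin", "fmax", "K", if (fit_n) "n")

  structure(
    list(fmin = fmin, fmax = fmax, K = K, n = n,
         se_fmin = unname(se["fmin"]), se_fmax = unname(se["fmax"]),
         se_K = unname(se["K"]),
         se_n = if (fit_n) unname(se["n"]) else 0,
         dynamic_range = (fmax - fmin) / fmin,
         fold_change = fmax / fmin,
         converged = TRUE, sse = best$sse, diagnostics = NULL),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: NOT converged (", x$diagnostics, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Hill transfer-function fit\n")
  est <- c(fmin = x$fmin, fmax = x$fmax, K = x$K, n = x$n)
  se <- c(x$se_fmin, x$se_fmax, x$se_K, x$se_n)
  for (i in seq_along(est))
    cat(sprintf("  %-5s %12.4g  (se %.4g)\n", names(est)[i], est[i], se[i]))
  cat(sprintf("  dynamic range %.4g, fold change %.4g\n",
              x$dynamic_range, x$fold_change))
  invisible(x)
}

#' Read/write dose-response curves as tidy CSV, Hill fits as JSON
#'
#' Curve CSV columns: `dose`, `response`\[, `replicate_sd`\].  Fit JSON
#' carries every `hill_fit` field.
#'
#' @param curve a [dose_response_curve()]; `fit` a `hill_fit`.
#' @param fit a `hill_fit` object.
#' @param path file path.
#' @return the read object, or `path` invisibly for writers.
#' @export
write_dose_response_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  d <- utils::read.csv(path)
  dose_response_curve(d$dose, d$response, d$replicate_sd)
}

#' @rdname write_dose_response_csv
#' @export
write_hill_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hill_fit"))
  jsonlite::write_json(unclass(fit)[!vapply(unclass(fit), is.null, TRUE)],
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
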