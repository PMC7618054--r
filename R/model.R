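# Hand-coded mass-action derivative, kept in exact correspondence with
# build_reaction_network() (tests assert equality with the stoichiometry-
# weighted flux sum) and with the compiled routine in src/tcs_deriv.c.
.tcs_deriv_r <- function(y, p) {
  v_ap  <- p[[1L]]  * y[[1L]]              # k_ap  * S
  v_ad  <- p[[2L]]  * y[[2L]]              # k_ad  * Sp
  v_b1  <- p[[3L]]  * y[[2L]] * y[[3L]]    # k_b1  * Sp * C
  v_d1  <- p[[4L]]  * y[[5L]]              # k_d1  * SpC
  v_pt  <- p[[5L]]  * y[[5L]]              # k_pt  * SpC
  v_b2  <- p[[6L]]  * y[[1L]] * y[[4L]]    # k_b2  * S * Cp
  v_d2  <- p[[7L]]  * y[[6L]]              # k_d2  * SCp
  v_ph  <- p[[8L]]  * y[[6L]]              # k_ph  * SCp
  v_b3  <- p[[9L]]  * y[[1L]] * y[[3L]]    # k_b3  * S * C
  v_d3  <- p[[10L]] * y[[7L]]              # k_d3  * SC
  v_bnd <- p[[11L]] * y[[4L]] * y[[8L]]    # k_bnd * Cp * P
  v_unb <- p[[12L]] * y[[9L]]              # k_unbnd * PCp
  v_lg  <- p[[13L]] * y[[8L]]              # k_lgexp * P
  v_pm  <- p[[14L]] * y[[9L]]              # k_pmgexp * PCp
  v_trl <- p[[15L]] * y[[10L]]             # k_trl * M
  v_mat <- p[[16L]] * y[[11L]]             # k_mat * Gi
  v_dm  <- p[[17L]] * y[[10L]]             # d_m * M
  v_dgi <- p[[18L]] * y[[11L]]             # d_g * Gi
  v_dgm <- p[[18L]] * y[[12L]]             # d_g * Gm
  c(
    S   = -v_ap + v_ad + v_pt - v_b2 + v_d2 + v_ph - v_b3 + v_d3,
    Sp  =  v_ap - v_ad - v_b1 + v_d1,
    C   = -v_b1 + v_d1 + v_ph - v_b3 + v_d3,
    Cp  =  v_pt - v_b2 + v_d2 - v_bnd + v_unb,
    SpC =  v_b1 - v_d1 - v_pt,
    SCp =  v_b2 - v_d2 - v_ph,
    SC  =  v_b3 - v_d3,
    P   = -v_bnd + v_unb,
    PCp =  v_bnd - v_unb,
    M   =  v_lg + v_pm - v_dm,
    Gi  =  v_trl - v_mat - v_dgi,
    Gm  =  v_mat - v_dgm
  )
}

#' Time derivatives of the twelve AtoSC species
#'
#' Pure function returning the rate of change of every species under mass
#' action; identical to the stoichiometry-weighted sum of the
#' [build_reaction_network()] rate laws.  The HK, RR and promoter conservation
#' sums have derivative exactly zero by construction.
#'
#' @param state a [tcs_state()] (or named numeric vector over the 12 species).
#' @param params a [tcs_parameters()] object.
#' @return named numeric vector of derivatives, one per species.
#' @export
tcs_derivatives <- function(state, params) {
  validate_tcs_parameters(params)
  y <- as.numeric(state[.tcs_species])
  if (anyNA(y)) stop("state must contain all 12 species")
  d <- .tcs_deriv_r(y, as.numeric(params))
  names(d) <- .tcs_species
  d
}

.deriv_fun_r <- function(t, y, p) list(.tcs_deriv_r(y, p))

# One lsoda hop between two time points; errors carry the last valid state.
# A maxsteps exhaustion (istate -1) is resumed from the point reached, so
# very stiff corners get as many steps as they need; hard failures error.
.integrate_segment <- function(y, t0, t1, p, use_compiled, rtol, atol) {
  t_now <- t0
  for (attempt in 1:20) {
    out <- suppressWarnings(if (use_compiled) {
      deSolve::lsoda(y, c(t_now, t1), func = "tcs_derivs", parms = p,
                     dllname = "atosensor", initfunc = "tcs_initmod",
                     rtol = rtol, atol = atol, maxsteps = 100000L)
    } else {
      deSolve::lsoda(y, c(t_now, t1), func = .deriv_fun_r, parms = p,
                     rtol = rtol, atol = atol, maxsteps = 100000L)
    })
    istate <- attr(out, "istate")[1L]
    t_reached <- out[nrow(out), 1L]
    y <- out[nrow(out), 1L + seq_along(.tcs_species)]
    names(y) <- .tcs_species
    if (!is.na(istate) && istate >= 0L && t_reached >= t1) return(y)
    progressed <- !is.na(istate) && istate == -1L && t_reached > t_now
    if (!progressed) {
      cond <- structure(
        class = c("atosensor_integration_error", "error", "condition"),
        list(message = sprintf(
               "ODE integration failed (istate = %d) at t = %g",
               istate, t_reached),
             call = sys.call(-1L),
             last_state = y, last_time = t_reached)
      )
      stop(cond)
    }
    t_now <- t_reached
  }
  cond <- structure(
    class = c("atosensor_integration_error", "error", "condition"),
    list(message = sprintf(
           "ODE integration stalled near t = %g after repeated step-limit hits",
           t_now),
         call = sys.call(-1L), last_state = y, last_time = t_now)
  )
  stop(cond)
}

# Per-species total turnover (sum of absolute one-way fluxes): the natural
# scale against which a steady-state residual is judged small.
.tcs_flux_scale <- function(y, p) {
  v_ap  <- p[[1L]]  * y[[1L]];  v_ad  <- p[[2L]]  * y[[2L]]
  v_b1  <- p[[3L]]  * y[[2L]] * y[[3L]]; v_d1 <- p[[4L]] * y[[5L]]
  v_pt  <- p[[5L]]  * y[[5L]]
  v_b2  <- p[[6L]]  * y[[1L]] * y[[4L]]; v_d2 <- p[[7L]] * y[[6L]]
  v_ph  <- p[[8L]]  * y[[6L]]
  v_b3  <- p[[9L]]  * y[[1L]] * y[[3L]]; v_d3 <- p[[10L]] * y[[7L]]
  v_bnd <- p[[11L]] * y[[4L]] * y[[8L]]; v_unb <- p[[12L]] * y[[9L]]
  v_lg  <- p[[13L]] * y[[8L]];  v_pm  <- p[[14L]] * y[[9L]]
  v_trl <- p[[15L]] * y[[10L]]; v_mat <- p[[16L]] * y[[11L]]
  v_dm  <- p[[17L]] * y[[10L]]
  v_dgi <- p[[18L]] * y[[11L]]; v_dgm <- p[[18L]] * y[[12L]]
  c(v_ap + v_ad + v_pt + v_b2 + v_d2 + v_ph + v_b3 + v_d3,
    v_ap + v_ad + v_b1 + v_d1,
    v_b1 + v_d1 + v_ph + v_b3 + v_d3,
    v_pt + v_b2 + v_d2 + v_bnd + v_unb,
    v_b1 + v_d1 + v_pt,
    v_b2 + v_d2 + v_ph,
    v_b3 + v_d3,
    v_bnd + v_unb,
    v_bnd + v_unb,
    v_lg + v_pm + v_dm,
    v_trl + v_mat + v_dgi,
    v_mat + v_dgm)
}

# Refinement of the algebraic steady state.  The ODE right-hand side has
# rank 9 (three conserved moieties), so the rows for S, C and P are replaced
# by the conservation residuals.  The square system is solved by
# Levenberg-Marquardt in log-concentration coordinates (species at
# equilibrium can span ten-plus decades; the log transform fixes the column
# conditioning), with rows scaled by each species' total turnover so none is
# neglected in the least-squares merit.  Accepted only if every residual is
# small against its natural scale.  Returns the refined state or NULL.
.newton_polish <- function(y, p) {
  res_fun <- function(y) {
    f <- .tcs_deriv_r(y, p)
    f[1L] <- y[1L] + y[2L] + y[5L] + y[6L] + y[7L] - p[19L]          # HK
    f[3L] <- y[3L] + y[4L] + y[5L] + y[6L] + y[7L] + y[9L] - p[20L]  # RR
    f[8L] <- y[8L] + y[9L] - p[21L]                                  # promoter
    f
  }
  s0 <- .tcs_flux_scale(y, p)
  s0[c(1L, 3L, 8L)] <- p[19:21]
  s0 <- pmax(s0, 1e-12)
  z0 <- log(pmax(y, 1e-30))
  sol <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(z0, lower = rep(log(1e-30), 12L),
                         upper = rep(log(1e9), 12L),
                         fn = function(z) res_fun(exp(z)) / s0,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, maxfev = 20000,
                           ftol = 1e-15, ptol = 1e-15))),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  y_new <- exp(sol$par)
  y_new[y_new < 1e-25] <- 0   # species pinned at the log floor are zero
  f <- res_fun(y_new)
  scale <- .tcs_flux_scale(y_new, p)
  scale[c(1L, 3L, 8L)] <- p[19:21]
  if (any(abs(f) > pmax(1e-9 * scale, 1e-14))) return(NULL)
  y_new
}

#' Integrate the AtoSC model to steady state
#'
#' Runs the stiff solver ([deSolve::lsoda()]) over geometrically growing
#' horizons until the relative change of every species across a probe window
#' covering the final 10% of elapsed time falls below `rel_tol`, or `t_max` is
#' reached.  After each unconverged probe the algebraic steady state is also
#' attempted directly by damped Newton iteration on the right-hand side (with
#' the three conservation constraints built in); a Newton solution is accepted
#' only if a short re-integration from it stays within `rel_tol`, which makes
#' slowly relaxing parameter corners cheap without weakening the convergence
#' criterion.  A compiled derivative is used by default; `use_compiled =
#' FALSE` selects the pure-R reference derivative (identical results, slower).
#'
#' @param params a [tcs_parameters()] object.
#' @param init initial [tcs_state()]; defaults to [tcs_initial_state()].
#'   Must satisfy the conservation totals of `params`.
#' @param rel_tol convergence threshold on the per-species relative change
#'   over the probe window.
#' @param t_max bail-out horizon (model time units); if reached without
#'   convergence the result is flagged `converged = FALSE`.
#' @param use_compiled logical; use the compiled derivative.
#' @return list of class `tcs_steady_state` with elements `state` (a
#'   [tcs_state()]), `converged`, `time` (elapsed model time), and
#'   `max_rel_change` at the last probe.
#' @examples
#' ss <- simulate_to_steady_state(tcs_parameters(k_ap = 0.05))
#' ss$state["Gm"]
#' @export
simulate_to_steady_state <- function(params, init = tcs_initial_state(params),
                                     rel_tol = 1e-6, t_max = 1e6,
                                     use_compiled = TRUE) {
  validate_tcs_parameters(params)
  p <- as.numeric(params)
  y <- as.numeric(init[.tcs_species])
  if (anyNA(y) || any(y < 0))
    stop("init must contain all 12 species, all >= 0")
  .check_conservation(y, p, where = "init")

  rtol <- 1e-8
  atol <- 1e-10
  t_now <- 0
  horizon <- 50
  converged <- FALSE
  max_rel <- Inf

  repeat {
    horizon <- min(horizon, t_max)
    t_probe <- 0.9 * horizon
    if (t_probe > t_now) {
      y <- .integrate_segment(y, t_now, t_probe, p, use_compiled, rtol, atol)
      t_now <- t_probe
    }
    y_probe <- y
    y <- .integrate_segment(y, t_now, horizon, p, use_compiled, rtol, atol)
    t_now <- horizon
    # denominator floored at 100x the solver's absolute tolerance: species
    # indistinguishable from zero are not held to a relative criterion
    max_rel <- max(abs(y - y_probe) / pmax(abs(y), 100 * atol))
    if (max_rel < rel_tol) {
      converged <- TRUE
      break
    }
    # try to jump to the algebraic steady state, then verify by integration
    y_newton <- .newton_polish(y, p)
    if (!is.null(y_newton)) {
      window <- 0.1 * max(t_now, 100)
      y_check <- .integrate_segment(y_newton, 0, window, p, use_compiled,
                                    rtol, atol)
      max_rel <- max(abs(y_check - y_newton) / pmax(abs(y_check), 100 * atol))
      if (max_rel < rel_tol) {
        y <- y_check
        converged <- TRUE
        break
      }
    }
    if (horizon >= t_max) break
    horizon <- horizon * 2
  }

  # Clamp solver-level negative round-off; anything beyond tolerance is a bug.
  if (any(y < -1e-9))
    stop("integrator returned negative concentrations beyond tolerance: ",
         paste(.tcs_species[y < -1e-9], collapse = ", "))
  y[y < 0] <- 0
  .check_conservation(y, p, where = "steady state")

  state <- y
  names(state) <- .tcs_species
  class(state) <- "tcs_state"
  structure(list(state = state, converged = converged, time = t_now,
                 max_rel_change = max_rel),
            class = "tcs_steady_state")
}

# HK / RR / promoter moiety conservation, relative to the configured totals.
.conservation_sums <- function(y) {
  c(hk = y[[1L]] + y[[2L]] + y[[5L]] + y[[6L]] + y[[7L]],
    rr = y[[3L]] + y[[4L]] + y[[5L]] + y[[6L]] + y[[7L]] + y[[9L]],
    promoter = y[[8L]] + y[[9L]])
}

.check_conservation <- function(y, p, where, tol = 1e-6) {
  tot <- c(hk = p[[19L]], rr = p[[20L]], promoter = p[[21L]])
  rel <- abs(.conservation_sums(y) - tot) / tot
  if (any(rel > tol))
    stop(sprintf(
      "conservation violated at %s: %s (max relative deviation %.3g)",
      where, paste(names(rel)[rel > tol], collapse = ", "), max(rel)))
  invisible(rel)
}

#' @export
print.tcs_steady_state <- function(x, ...) {
  cat(sprintf("AtoSC steady state (%s, t = %g):\n",
              if (x$converged) "converged" else "NOT converged", x$time))
  print(unclass(x$state), ...)
  invisible(x)
}

#' Simulate a time course of the AtoSC model
#'
#' @param params a [tcs_parameters()] object.
#' @param times increasing vector of output times (must start at 0).
#' @param init initial [tcs_state()].
#' @param use_compiled logical; use the compiled derivative.
#' @return tidy data.frame with columns `time`, `species`, `value`.
#' @export
simulate_trajectory <- function(params, times,
                                init = tcs_initial_state(params),
                                use_compiled = TRUE) {
  validate_tcs_parameters(params)
  if (length(times) < 2L || times[1L] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and start at 0")
  p <- as.numeric(params)
  y <- as.numeric(init[.tcs_species])
  out <- if (use_compiled) {
    deSolve::lsoda(y, times, func = "tcs_derivs", parms = p,
                   dllname = "atosensor", initfunc = "tcs_initmod",
                   rtol = 1e-10, atol = 1e-12)
  } else {
    deSolve::lsoda(y, times, func = .deriv_fun_r, parms = p,
                   rtol = 1e-10, atol = 1e-12)
  }
  mat <- out[, 1L + seq_along(.tcs_species), drop = FALSE]
  data.frame(
    time = rep(out[, 1L], times = length(.tcs_species)),
    species = rep(.tcs_species, each = nrow(out)),
    value = as.vector(mat)
  )
}
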