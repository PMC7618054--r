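#' Parameter space for sensitivity screening
#'
#' Defines per-parameter bounds and sampling scales.  Sampling is uniform on
#' the stated scale: `"linear"` maps unit coordinate `x` to
#' `lower + x * (upper - lower)`; `"log10"` maps it to
#' `10^(log10(lower) + x * (log10(upper) - log10(lower)))`.
#'
#' @param names ordered parameter identifiers.
#' @param lower,upper per-parameter bounds (`lower < upper`; log10 scale
#'   requires `lower > 0`).
#' @param scale per-parameter `"linear"` or `"log10"` (recycled if length 1).
#' @return list of class `parameter_space`.
#' @export
parameter_space <- function(names, lower, upper, scale = "log10") {
  k <- length(names)
  if (anyDuplicated(names)) stop("parameter names must be unique")
  if (length(lower) != k || length(upper) != k)
    stop("lower and upper must match names in length")
  if (length(scale) == 1L) scale <- rep(scale, k)
  if (length(scale) != k) stop("scale must be length 1 or match names")
  if (!all(scale %in% c("linear", "log10")))
    stop("scale entries must be 'linear' or 'log10'")
  if (any(lower >= upper)) stop("lower < upper must hold elementwise")
  if (any(scale == "log10" & lower <= 0))
    stop("log10 scale requires lower > 0")
  structure(list(names = as.character(names), lower = as.numeric(lower),
                 upper = as.numeric(upper), scale = scale),
            class = "parameter_space")
}

# Fig-2C-style short names <-> internal parameter names for the 16 screened
# TCS quantities (k_ap is the swept dose proxy, not a screened parameter;
# reporter constants are deliberately outside the space).
.morris_name_map <- c(
  C = "C_tot", k_ad = "k_ad", k_b1 = "k_b1", k_b2 = "k_b2", k_b3 = "k_b3",
  k_bnd = "k_bnd", k_d1 = "k_d1", k_d2 = "k_d2", k_d3 = "k_d3",
  k_lgexp = "k_lgexp", k_ph = "k_ph", k_pmgexp = "k_pmgexp", k_pt = "k_pt",
  k_unbnd = "k_unbnd", pato = "P_tot", S = "S_tot"
)

#' Default screening space: the 16 TCS parameters, two decades each
#'
#' Each of the 16 two-component-system parameters (rate constants plus the
#' `S`, `C` and `pato` totals; the swept `k_ap` and the reporter cascade are
#' excluded) spans one decade either side of its nominal value in `params`,
#' sampled uniformly in log10.  These bounds are the package's stand-in
#' operating ranges, overridable per parameter.
#'
#' @param params nominal [tcs_parameters()].
#' @param span half-width of each range in decades.
#' @return a [parameter_space()] whose names are the conventional short names
#'   (`S`, `C`, `pato`, `k_ad`, ...).
#' @export
default_parameter_space <- function(params = tcs_parameters(), span = 1) {
  validate_tcs_parameters(params)
  nominal <- as.numeric(params)[match(.morris_name_map, .tcs_param_names)]
  parameter_space(names(.morris_name_map),
                  lower = nominal / 10^span,
                  upper = nominal * 10^span,
                  scale = "log10")
}

#' Morris elementary-effects design
#'
#' @param p number of grid levels (even, >= 4); the step in unit-hypercube
#'   coordinates is fixed at `delta = p / (2 * (p - 1))`.
#' @param R number of candidate trajectories to generate.
#' @param r number of optimal trajectories to keep (`r <= R`).
#' @param seed RNG seed for trajectory generation.
#' @return list of class `morris_design`.
#' @export
morris_design <- function(p = 4, R = 1000, r = 50, seed = 1) {
  if (p < 4 || p %% 2 != 0) stop("p must be even and >= 4")
  if (r > R) stop("r must be <= R")
  delta <- p / (2 * (p - 1))
  stopifnot(delta > 0, delta < 1)
  structure(list(p = as.integer(p), delta = delta, R = as.integer(R),
                 r = as.integer(r), seed = as.integer(seed)),
            class = "morris_design")
}

#' Generate candidate Morris trajectories in the unit hypercube
#'
#' Each trajectory has `k + 1` points; consecutive points differ in exactly
#' one coordinate by `+delta` or `-delta`, each coordinate is perturbed
#' exactly once (in random order), and all points lie on the `p`-level grid
#' in `[0, 1]^k`.  Starting levels are drawn uniformly from the grid levels
#' compatible with the drawn step direction.  Fully reproducible from
#' `design$seed`.
#'
#' @param space a [parameter_space()].
#' @param design a [morris_design()].
#' @return list of `design$R` matrices, each `(k + 1) x k` with parameter
#'   names as columns.
#' @export
generate_candidate_trajectories <- function(space, design) {
  stopifnot(inherits(space, "parameter_space"),
            inherits(design, "morris_design"))
  k <- length(space$names)
  p <- design$p
  delta <- design$delta
  levels <- (seq_len(p) - 1L) / (p - 1L)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(design$seed)

  lapply(seq_len(design$R), function(i) {
    dir <- sample(c(-1, 1), k, replace = TRUE)
    start <- vapply(dir, function(d) {
      ok <- levels[levels + d * delta >= -1e-12 & levels + d * delta <= 1 + 1e-12]
      ok[sample.int(length(ok), 1L)]
    }, numeric(1))
    order_perm <- sample.int(k)
    pts <- matrix(0, nrow = k + 1L, ncol = k,
                  dimnames = list(NULL, space$names))
    pts[1L, ] <- start
    x <- start
    for (step in seq_len(k)) {
      j <- order_perm[step]
      x[j] <- x[j] + dir[j] * delta
      pts[step + 1L, ] <- x
    }
    pts[pts < 0] <- 0
    pts[pts > 1] <- 1
    pts
  })
}

# Campolongo trajectory distance: sum of Euclidean distances between all
# point pairs of the two trajectories.
.trajectory_distance_matrix <- function(trajs) {
  n <- length(trajs)
  flat <- lapply(trajs, function(m) m)
  sq <- lapply(flat, function(m) rowSums(m^2))
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    Ma <- flat[[a]]
    for (b in (a + 1L):n) {
      Mb <- flat[[b]]
      cross <- outer(sq[[a]], sq[[b]], "+") - 2 * tcrossprod(Ma, Mb)
      cross[cross < 0] <- 0
      D[a, b] <- D[b, a] <- sum(sqrt(cross))
    }
  }
  D
}

# Campolongo spread of a subset: sqrt of the sum of squared pairwise
# trajectory distances.
.campolongo_spread <- function(D2, idx) {
  sub <- D2[idx, idx, drop = FALSE]
  sqrt(sum(sub[upper.tri(sub)]))
}

#' Select the maximally spread subset of Morris trajectories
#'
#' Maximises the Campolongo criterion — the root of the summed squared
#' pairwise trajectory distances, where the distance between two trajectories
#' is the sum of Euclidean distances between all their point pairs.  Search
#' is a deterministic greedy build (best pair, then best single extension)
#' followed by single-swap hill climbing until no swap improves the spread;
#' ties break toward the lowest candidate index.
#'
#' @param candidates list of trajectory matrices
#'   (from [generate_candidate_trajectories()]).
#' @param r number of trajectories to select.
#' @return list of `r` selected trajectories, with an attribute
#'   `selected_index` giving their positions among the candidates (ascending).
#' @export
select_optimal_trajectories <- function(candidates, r) {
  n <- length(candidates)
  if (r > n) stop("r must be <= the number of candidate trajectories")
  if (r == n) {
    attr(candidates, "selected_index") <- seq_len(n)
    return(candidates)
  }
  if (r < 2L) stop("r must be >= 2")
  D <- .trajectory_distance_matrix(candidates)
  D2 <- D^2

  # greedy: best pair, then extensions maximising the added squared distance
  best_pair <- which(D2 == max(D2), arr.ind = TRUE)[1L, ]
  sel <- sort(as.integer(best_pair))
  while (length(sel) < r) {
    rest <- setdiff(seq_len(n), sel)
    gain <- colSums(D2[sel, rest, drop = FALSE])
    sel <- sort(c(sel, rest[which.max(gain)]))
  }

  # single-swap hill climbing on the exact criterion
  repeat {
    improved <- FALSE
    current <- .campolongo_spread(D2, sel)
    for (s in sel) {
      for (u in setdiff(seq_len(n), sel)) {
        cand <- sort(c(setdiff(sel, s), u))
        val <- .campolongo_spread(D2, cand)
        if (val > current + 1e-12) {
          sel <- cand
          current <- val
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }

  out <- candidates[sel]
  attr(out, "selected_index") <- sel
  out
}

#' Map unit-hypercube points to model parameter values
#'
#' @param points matrix of points in `[0, 1]^k` (columns = space names), or a
#'   single point as a vector.
#' @param space a [parameter_space()].
#' @return matrix of parameter values on the natural scale.
#' @export
scale_points <- function(points, space) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  k <- length(space$names)
  if (ncol(points) != k) stop("points must have one column per parameter")
  if (any(points < -1e-12) || any(points > 1 + 1e-12))
    stop("points must lie in the unit hypercube")
  out <- points
  for (j in seq_len(k)) {
    if (space$scale[j] == "log10") {
      lo <- log10(space$lower[j]); hi <- log10(space$upper[j])
      out[, j] <- 10^(lo + points[, j] * (hi - lo))
    } else {
      out[, j] <- space$lower[j] + points[, j] * (space$upper[j] - space$lower[j])
    }
  }
  colnames(out) <- space$names
  out
}

.morris_outputs <- c("fmin", "fmax", "K", "n", "fold_change")

#' Map sample points to Hill response features of the model
#'
#' Each unit-hypercube point is scaled through `space` into a full parameter
#' set (parameters outside the space come from `base_params`; the short names
#' `S`, `C`, `pato` address the conserved totals), the model is swept over
#' `kap_grid` to steady state, and the Hill fit of the resulting curve yields
#' the features `fmin`, `fmax`, `K`, `n`, `fold_change`.  Failed fits
#' propagate as `NA` rows; if more than `max_failure_rate` of the points
#' fail, the run aborts with a diagnostic count.
#'
#' @param points matrix of points in the unit hypercube (rows = points).
#' @param space a [parameter_space()].
#' @param base_params baseline [tcs_parameters()].
#' @param kap_grid dose grid for [sweep_dose_response()].
#' @param max_failure_rate abort threshold on the fraction of failed fits.
#' @param rel_tol,t_max passed to the steady-state solver.
#' @return matrix `nrow(points) x 5` of features (NA where the fit failed),
#'   with attribute `n_failed`.
#' @export
evaluate_feature_map <- function(points, space, base_params = tcs_parameters(),
                                 kap_grid = default_kap_grid(9),
                                 max_failure_rate = 0.1,
                                 rel_tol = 1e-6, t_max = 1e6) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  vals <- scale_points(points, space)
  internal <- ifelse(space$names %in% names(.morris_name_map),
                     .morris_name_map[space$names], space$names)
  unknown <- setdiff(internal, .tcs_param_names)
  if (length(unknown))
    stop("space names not in the model: ", paste(unknown, collapse = ", "))

  feats <- matrix(NA_real_, nrow = nrow(points), ncol = 5L,
                  dimnames = list(NULL, .morris_outputs))
  n_failed <- 0L
  for (i in seq_len(nrow(points))) {
    p <- base_params
    p[internal] <- vals[i, ]
    f <- tryCatch({
      curve <- sweep_dose_response(p, kap_grid, rel_tol = rel_tol,
                                   t_max = t_max)
      fit <- fit_hill(curve)
      if (!fit$converged) NULL
      else c(fit$fmin, fit$fmax, fit$K, fit$n, fit$fold_change)
    }, error = function(e) NULL)
    if (is.null(f)) {
      n_failed <- n_failed + 1L
    } else {
      # individually non-finite features (e.g. fold change when the fitted
      # basal level is 0) propagate as missing, not as Inf
      f[!is.finite(f)] <- NA_real_
      feats[i, ] <- f
    }
  }
  if (n_failed > max_failure_rate * nrow(points))
    stop(sprintf(
      "feature map aborted: %d of %d points failed to fit (> %.0f%%)",
      n_failed, nrow(points), 100 * max_failure_rate))
  attr(feats, "n_failed") <- n_failed
  feats
}

#' Elementary effects from evaluated trajectories
#'
#' For the trajectory step that perturbs coordinate `i` from `x` to
#' `x +/- delta`, the elementary effect on each output is
#' `(y_after - y_before) / (+/- delta)`.  A missing feature at either
#' endpoint makes that effect missing (never zero).
#'
#' @param trajectories list of trajectory point matrices.
#' @param features list of matched feature matrices
#'   (`(k + 1) x n_outputs`, from [evaluate_feature_map()] per trajectory).
#' @return 3-d array `[trajectory, parameter, output]` of signed effects.
#' @export
elementary_effects <- function(trajectories, features) {
  if (length(trajectories) != length(features))
    stop("one feature matrix per trajectory is required")
  k <- ncol(trajectories[[1L]])
  pnames <- colnames(trajectories[[1L]])
  onames <- colnames(features[[1L]])
  ee <- array(NA_real_,
              dim = c(length(trajectories), k, length(onames)),
              dimnames = list(NULL, pnames, onames))
  for (tr in seq_along(trajectories)) {
    pts <- trajectories[[tr]]
    ft <- features[[tr]]
    if (nrow(ft) != nrow(pts))
      stop("features must be evaluated at every trajectory point")
    for (step in seq_len(nrow(pts) - 1L)) {
      d <- pts[step + 1L, ] - pts[step, ]
      j <- which(abs(d) > 1e-12)
      if (length(j) != 1L)
        stop("consecutive trajectory points must differ in exactly one coordinate")
      ee[tr, j, ] <- (ft[step + 1L, ] - ft[step, ]) / d[j]
    }
  }
  ee
}

#' Aggregate elementary effects into Morris sensitivity measures
#'
#' Per (parameter, output) cell: `mu` is the mean signed effect, `mu_star`
#' the mean absolute effect, `sigma` the standard deviation (denominator
#' `r - 1`); missing effects are excluded with their counts reported.
#' `mu_star_normalised` divides each output column by its maximum `mu_star`,
#' the heatmap convention for comparing parameters within one response
#' feature.
#'
#' @param ee elementary-effects array from [elementary_effects()].
#' @return list of class `morris_result` with long-format `table`
#'   (parameter, output, mu, mu_star, sigma, mu_star_normalised, n_effects)
#'   and wide matrices `mu`, `mu_star`, `sigma`, `mu_star_normalised`
#'   (rows parameters, columns outputs).
#' @export
aggregate_and_normalise <- function(ee) {
  stopifnot(length(dim(ee)) == 3L)
  pnames <- dimnames(ee)[[2L]]
  onames <- dimnames(ee)[[3L]]
  counts <- apply(ee, c(2L, 3L), function(x) sum(!is.na(x)))
  if (any(counts < 2L)) {
    bad <- which(counts < 2L, arr.ind = TRUE)
    stop("fewer than 2 non-missing elementary effects for: ",
         paste(sprintf("(%s, %s)", pnames[bad[, 1L]], onames[bad[, 2L]]),
               collapse = ", "))
  }
  mu <- apply(ee, c(2L, 3L), mean, na.rm = TRUE)
  mu_star <- apply(ee, c(2L, 3L), function(x) mean(abs(x), na.rm = TRUE))
  sigma <- apply(ee, c(2L, 3L), stats::sd, na.rm = TRUE)
  col_max <- apply(mu_star, 2L, max)
  if (any(col_max <= 0))
    col_max[col_max <= 0] <- 1  # all-zero column: leave zeros as zeros
  mu_star_norm <- sweep(mu_star, 2L, col_max, "/")

  table <- data.frame(
    parameter = rep(pnames, times = length(onames)),
    output = rep(onames, each = length(pnames)),
    mu = as.vector(mu),
    mu_star = as.vector(mu_star),
    sigma = as.vector(sigma),
    mu_star_normalised = as.vector(mu_star_norm),
    n_effects = as.vector(counts),
    stringsAsFactors = FALSE
  )
  structure(list(table = table, mu = mu, mu_star = mu_star, sigma = sigma,
                 mu_star_normalised = mu_star_norm),
            class = "morris_result")
}

#' @export
print.morris_result <- function(x, ...) {
  cat("Morris elementary-effects screen:",
      nrow(x$mu_star), "parameters x", ncol(x$mu_star), "outputs\n")
  cat("normalised mu* (columns scaled to max 1):\n")
  print(round(x$mu_star_normalised, 3))
  invisible(x)
}

#' Rank parameters by influence per output feature
#'
#' Descending `mu_star` within each output, after removing excluded
#' parameters (conventionally the reporter-cascade constants, so rankings
#' reflect the two-component system itself).  Ties break by `sigma`
#' descending, then name.
#'
#' @param result a [aggregate_and_normalise()] result.
#' @param exclude parameter names to drop before ranking.
#' @return data.frame with columns `output`, `rank`, `parameter`, `mu_star`,
#'   `sigma`.
#' @export
rank_parameters <- function(result, exclude = character()) {
  stopifnot(inherits(result, "morris_result"))
  pnames <- rownames(result$mu_star)
  unknown <- setdiff(exclude, pnames)
  if (length(unknown))
    stop("exclude contains unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  keep <- setdiff(pnames, exclude)
  if (!length(keep)) stop("no parameters left after exclusion")
  do.call(rbind, lapply(colnames(result$mu_star), function(out) {
    ms <- result$mu_star[keep, out]
    sg <- result$sigma[keep, out]
    ord <- order(-ms, -sg, keep)
    data.frame(output = out, rank = seq_along(keep),
               parameter = keep[ord], mu_star = unname(ms[ord]),
               sigma = unname(sg[ord]), stringsAsFactors = FALSE)
  }))
}

#' Run the full Morris screen of the AtoSC model
#'
#' Generates `design$R` candidate trajectories, keeps the `design$r` with
#' maximal Campolongo spread, evaluates the Hill response features of the
#' model at every trajectory point, and aggregates elementary effects into
#' `mu`, `mu_star`, `sigma` and the per-output normalised `mu_star` heatmap.
#'
#' @param base_params baseline [tcs_parameters()].
#' @param space a [parameter_space()]; defaults to the 16 TCS parameters over
#'   two decades each.
#' @param design a [morris_design()].
#' @param kap_grid dose grid for the per-point sweeps.
#' @param ... passed to [evaluate_feature_map()].
#' @return a `morris_result` with extra elements `design`, `space`,
#'   `n_failed`, and `trajectories`.
#' @export
morris_screen <- function(base_params = tcs_parameters(),
                          space = default_parameter_space(base_params),
                          design = morris_design(),
                          kap_grid = default_kap_grid(9), ...) {
  cand <- generate_candidate_trajectories(space, design)
  sel <- select_optimal_trajectories(cand, design$r)
  # the failure budget applies to the run as a whole, not per trajectory
  feats <- lapply(sel, function(pts)
    evaluate_feature_map(pts, space, base_params, kap_grid,
                         max_failure_rate = 1, ...))
  n_failed <- sum(vapply(feats, function(f) attr(f, "n_failed"), integer(1)))
  n_points <- sum(vapply(feats, nrow, integer(1)))
  if (n_failed > 0.1 * n_points)
    stop(sprintf(
      "Morris screen aborted: %d of %d points failed to fit (> 10%%)",
      n_failed, n_points))
  ee <- elementary_effects(sel, feats)
  res <- aggregate_and_normalise(ee)
  res$design <- design
  res$space <- space
  res$n_failed <- n_failed
  res$trajectories <- sel
  res
}

#' Write Morris results as tidy and wide CSV
#'
#' `path_long` receives the long table (parameter, output, mu, mu_star,
#' sigma, mu_star_normalised); `path_wide`, if given, receives the
#' normalised-mu* heatmap matrix (rows parameters, columns outputs).
#'
#' @param result a `morris_result`.
#' @param path_long,path_wide output CSV paths.
#' @return `path_long`, invisibly.
#' @export
write_morris_csv <- function(result, path_long, path_wide = NULL) {
  stopifnot(inherits(result, "morris_result"))
  utils::write.csv(result$table, path_long, row.names = FALSE)
  if (!is.null(path_wide)) {
    wide <- data.frame(parameter = rownames(result$mu_star_normalised),
                       result$mu_star_normalised, check.names = FALSE)
    utils::write.csv(wide, path_wide, row.names = FALSE)
  }
  invisible(path_long)
}
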