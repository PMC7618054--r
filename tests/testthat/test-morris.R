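space2 <- parameter_space(c("a", "b"), c(0.1, 0.1), c(10, 10))
space3 <- parameter_space(c("a", "b", "c"), rep(0.1, 3), rep(10, 3))

test_that("candidate trajectories have the one-step-per-coordinate structure", {
  design <- morris_design(p = 4, R = 50, r = 10, seed = 5)
  trajs <- generate_candidate_trajectories(space2, design)
  expect_length(trajs, 50)
  for (tr in trajs) {
    expect_identical(dim(tr), c(3L, 2L))
    expect_true(all(tr >= 0 & tr <= 1))
    moved <- integer(0)
    for (s in 1:2) {
      d <- tr[s + 1, ] - tr[s, ]
      j <- which(d != 0)
      expect_length(j, 1L)
      expect_equal(unname(abs(d[j])), 2 / 3, tolerance = 1e-12)
      moved <- c(moved, j)
    }
    expect_setequal(moved, 1:2)   # every coordinate moved exactly once
  }
})

test_that("trajectory generation is deterministic and leaves the caller's RNG alone", {
  design <- morris_design(p = 4, R = 20, r = 5, seed = 9)
  set.seed(1234)
  a <- generate_candidate_trajectories(space3, design)
  x1 <- stats::runif(1)
  set.seed(1234)
  b <- generate_candidate_trajectories(space3, design)
  x2 <- stats::runif(1)
  expect_identical(a, b)
  expect_identical(x1, x2)
})

test_that("the first perturbed coordinate is uniform over parameters", {
  design <- morris_design(p = 4, R = 1000, r = 50, seed = 7)
  trajs <- generate_candidate_trajectories(space3, design)
  first <- vapply(trajs, function(tr) which(tr[2, ] != tr[1, ]), integer(1))
  freq <- tabulate(first, 3) / 1000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("unit points map through linear and log10 scales correctly", {
  sp <- parameter_space(c("lin", "log"), c(0, 1e-3), c(10, 1e1),
                        scale = c("linear", "log10"))
  m <- scale_points(rbind(c(0.5, 0.5), c(0, 0), c(1, 1)), sp)
  expect_equal(m[, "lin"], c(5, 0, 10))
  expect_equal(m[, "log"], c(1e-1, 1e-3, 1e1), tolerance = 1e-12)
  expect_error(parameter_space("x", 0, 1, scale = "log10"), "lower > 0")
  expect_error(parameter_space("x", 2, 1), "lower < upper")
})

test_that("selecting all candidates is the identity; r > R is rejected", {
  design <- morris_design(p = 4, R = 6, r = 3, seed = 2)
  trajs <- generate_candidate_trajectories(space2, design)
  all_sel <- select_optimal_trajectories(trajs, 6)
  expect_identical(all_sel[seq_along(trajs)], trajs)
  expect_error(select_optimal_trajectories(trajs, 7), "<=")
})

test_that("greedy-plus-swap selection matches exhaustive enumeration on small instances", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    r <- sample(2:3, 1)
    trajs <- lapply(seq_len(n), function(i)
      matrix(stats::runif(12), nrow = 4, ncol = 3,
             dimnames = list(NULL, c("a", "b", "c"))))
    sel <- select_optimal_trajectories(trajs, r)
    got <- sort(attr(sel, "selected_index"))
    want <- oracle_best_subset(trajs, r)
    expect_equal(oracle_spread(trajs, got), want$spread, tolerance = 1e-10)
    expect_identical(got, sort(want$index))
  }
})

test_that("candidate sets containing duplicates are still solved optimally", {
  set.seed(32)
  base <- lapply(1:4, function(i)
    matrix(stats::runif(6), nrow = 3, ncol = 2,
           dimnames = list(NULL, c("a", "b"))))
  cands <- c(base, base[1])   # candidate 5 duplicates candidate 1
  sel <- select_optimal_trajectories(cands, 3)
  idx <- sort(attr(sel, "selected_index"))
  want <- oracle_best_subset(cands, 3)
  expect_equal(oracle_spread(cands, idx), want$spread, tolerance = 1e-10)
})

test_that("elementary effects recover a linear model exactly and flag interactions", {
  design <- morris_design(p = 4, R = 12, r = 12, seed = 3)
  trajs <- generate_candidate_trajectories(space3, design)
  a <- c(2, -0.5, 7)
  feats <- lapply(trajs, function(tr)
    matrix(tr %*% a, ncol = 1, dimnames = list(NULL, "y")))
  ee <- elementary_effects(trajs, feats)
  res <- aggregate_and_normalise(ee)
  expect_equal(unname(res$mu[, "y"]), a, tolerance = 1e-12)
  expect_equal(unname(res$mu_star[, "y"]), abs(a), tolerance = 1e-12)
  expect_equal(unname(res$sigma[, "y"]), c(0, 0, 0), tolerance = 1e-10)

  # constant output: every elementary effect is zero
  feats0 <- lapply(trajs, function(tr)
    matrix(5, nrow = nrow(tr), ncol = 1, dimnames = list(NULL, "y")))
  res0 <- aggregate_and_normalise(elementary_effects(trajs, feats0))
  expect_true(all(res0$mu_star == 0))

  # multiplicative interaction: dispersion must appear on both factors
  feats_x <- lapply(trajs, function(tr)
    matrix(tr[, 1] * tr[, 2], ncol = 1, dimnames = list(NULL, "y")))
  res_x <- aggregate_and_normalise(elementary_effects(trajs, feats_x))
  expect_gt(res_x$sigma["a", "y"], 0)
  expect_gt(res_x$sigma["b", "y"], 0)
})

test_that("aggregation arithmetic, missing handling and normalisation follow their definitions", {
  ee <- array(NA_real_, dim = c(2, 2, 1),
              dimnames = list(NULL, c("a", "b"), "y"))
  ee[, "a", "y"] <- c(1, -1)
  ee[, "b", "y"] <- c(0.5, 0.5)
  res <- aggregate_and_normalise(ee)
  expect_equal(res$mu["a", "y"], 0)
  expect_equal(res$mu_star["a", "y"], 1)
  expect_equal(res$sigma["a", "y"], sqrt(2))
  expect_equal(res$mu_star_normalised["a", "y"], 1)   # dominant parameter
  expect_equal(res$mu_star_normalised["b", "y"], 0.5)

  ee[2, "b", "y"] <- NA
  expect_error(aggregate_and_normalise(ee), "fewer than 2")
})

test_that("mu_star dominates |mu| and normalised columns attain 1 on random effects", {
  set.seed(33)
  ee <- array(stats::rnorm(5 * 4 * 3), dim = c(5, 4, 3),
              dimnames = list(NULL, letters[1:4], c("y1", "y2", "y3")))
  res <- aggregate_and_normalise(ee)
  expect_true(all(res$mu_star >= abs(res$mu) - 1e-12))
  expect_true(all(res$mu_star_normalised >= 0 &
                    res$mu_star_normalised <= 1 + 1e-12))
  expect_equal(unname(apply(res$mu_star_normalised, 2, max)), rep(1, 3))
})

test_that("the from-scratch pipeline agrees with an independent Morris tabulation", {
  design <- morris_design(p = 4, R = 40, r = 8, seed = 17)
  trajs <- generate_candidate_trajectories(space3, design)
  sel <- select_optimal_trajectories(trajs, design$r)
  # nonlinear response with interactions, evaluated outside the package
  f <- function(x) 3 * x[, 1]^2 + 2 * x[, 1] * x[, 3] - x[, 2]
  feats <- lapply(sel, function(tr)
    matrix(f(tr), ncol = 1, dimnames = list(NULL, "y")))
  res <- aggregate_and_normalise(elementary_effects(sel, feats))
  ora <- oracle_morris_stats(sel, feats)
  for (i in seq_len(nrow(ora))) {
    pn <- ora$parameter[i]
    expect_equal(res$mu[pn, "y"], ora$mu[i], tolerance = 1e-10)
    expect_equal(res$mu_star[pn, "y"], ora$mu_star[i], tolerance = 1e-10)
    expect_equal(res$sigma[pn, "y"], ora$sigma[i], tolerance = 1e-10)
  }
})

test_that("rankings respect exclusions and the sigma-then-name tie-break", {
  ee <- array(NA_real_, dim = c(3, 3, 1),
              dimnames = list(NULL, c("a", "b", "z"), "y"))
  ee[, "a", ] <- c(2, 2, 2)
  ee[, "b", ] <- c(1, 2, 3)     # same mu* = 2, higher sigma than a
  ee[, "z", ] <- c(0.1, 0.1, 0.1)
  res <- aggregate_and_normalise(ee)
  rk <- rank_parameters(res)
  expect_identical(rk$parameter[1:2], c("b", "a"))   # sigma breaks the tie

  rk2 <- rank_parameters(res, exclude = c("a", "b"))
  expect_identical(rk2$parameter, "z")
  expect_error(rank_parameters(res, exclude = "nope"), "unknown")
})

test_that("the feature map is pure and respects the log-scale midpoint", {
  sp <- parameter_space(c("S", "C"), c(0.1, 0.2), c(10, 20))
  pt <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  f <- evaluate_feature_map(pt, sp, tcs_parameters(),
                            kap_grid = default_kap_grid(5, 1e-3, 1))
  expect_equal(f[1, ], f[2, ])
  expect_equal(unname(scale_points(c(0.5, 0.5), sp)[1, ]), c(1, 2),
               tolerance = 1e-12)
})

test_that("equal leaky and induced transcription flattens the response", {
  p <- tcs_parameters(k_pmgexp = 0.01)   # equal to k_lgexp
  curve <- sweep_dose_response(p, default_kap_grid(7, 1e-3, 1))
  fit <- fit_hill(curve)
  expect_true(fit$converged)
  expect_equal(fit$fold_change, 1, tolerance = 0.01)
})
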