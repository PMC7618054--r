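test_that("parameter and state constructors validate their invariants", {
  expect_error(tcs_parameters(k_b1 = -1), "negative parameter.*k_b1")
  expect_error(tcs_parameters(S_tot = 0), "strictly positive.*S_tot")
  expect_error(tcs_parameters(nonsense = 1), "unknown parameter")
  expect_error(tcs_state(Sp = -0.1), ">= 0")
  p <- tcs_parameters(k_ap = 0.5)
  expect_s3_class(p, "tcs_parameters")
  expect_identical(p[["k_ap"]], 0.5)
})

test_that("the reaction network has one mass-action rate law per process and conserves moieties", {
  net <- build_reaction_network(tcs_parameters())
  # 15 processes of which four reversible bindings contribute a reverse law
  expect_identical(ncol(net$stoichiometry), 19L)
  expect_identical(nrow(net$stoichiometry), 12L)
  hk <- c("S", "Sp", "SpC", "SCp", "SC")
  rr <- c("C", "Cp", "SpC", "SCp", "SC", "PCp")
  prom <- c("P", "PCp")
  expect_true(all(colSums(net$stoichiometry[hk, ]) == 0))
  expect_true(all(colSums(net$stoichiometry[rr, ]) == 0))
  expect_true(all(colSums(net$stoichiometry[prom, ]) == 0))
})

test_that("rate laws vanish with their rate constant and sum as mass action dictates", {
  p0 <- tcs_parameters(k_b1 = 0)
  net0 <- build_reaction_network(p0)
  st <- tcs_state(S = 0.2, Sp = 0.3, C = 0.4, P = 0.1)
  expect_identical(net0$rates(st)[["bind_SpC"]], 0)

  # all rate constants 1, state (S = 2, C = 3): consumption of S must be
  # k_ap*2 + k_b3*2*3 = 8, via the independent flux-summation oracle
  ones <- stats::setNames(as.list(rep(1, 14)),
                          c("k_ap", "k_ad", "k_b1", "k_d1", "k_pt", "k_b2",
                            "k_d2", "k_ph", "k_b3", "k_d3", "k_bnd",
                            "k_unbnd", "k_lgexp", "k_pmgexp"))
  p1 <- do.call(tcs_parameters, c(ones, list(S_tot = 2, C_tot = 3)))
  st1 <- tcs_state(S = 2, C = 3)
  net1 <- build_reaction_network(p1)
  expect_equal(oracle_consumption_flux(net1, st1, "S"), 8)
})

test_that("derivatives equal the stoichiometry-weighted flux sum for random states", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_tcs_parameters()
    y <- tcs_state()
    y[seq_along(y)] <- stats::runif(12, 0, 2)
    class(y) <- "tcs_state"
    net <- build_reaction_network(p)
    expect_equal(unname(tcs_derivatives(y, p)),
                 unname(as.numeric(net$stoichiometry %*% net$rates(y))),
                 tolerance = 1e-12)
  }
})

test_that("derivatives respect trivial limits and the conservation identity", {
  p <- tcs_parameters()
  expect_true(all(tcs_derivatives(tcs_state(), p) == 0))

  p_ap <- tcs_parameters(k_ad = 0, k_b1 = 0, k_d1 = 0, k_pt = 0, k_b2 = 0,
                         k_d2 = 0, k_ph = 0, k_b3 = 0, k_d3 = 0, k_bnd = 0,
                         k_unbnd = 0, k_lgexp = 0, k_pmgexp = 0, k_trl = 0,
                         k_mat = 0, d_m = 0, d_g = 0, k_ap = 1)
  d <- tcs_derivatives(tcs_state(S = 1), p_ap)
  expect_equal(unname(d[c("S", "Sp")]), c(-1, 1))
  expect_true(all(d[setdiff(names(d), c("S", "Sp"))] == 0))

  set.seed(12)
  for (i in 1:20) {
    p <- random_tcs_parameters()
    y <- tcs_state()
    y[seq_along(y)] <- stats::runif(12, 0, 2)
    class(y) <- "tcs_state"
    d <- tcs_derivatives(y, p)
    expect_equal(sum(d[c("S", "Sp", "SpC", "SCp", "SC")]), 0,
                 tolerance = 1e-12)
    expect_equal(sum(d[c("C", "Cp", "SpC", "SCp", "SC", "PCp")]), 0,
                 tolerance = 1e-12)
    expect_equal(sum(d[c("P", "PCp")]), 0, tolerance = 1e-12)
  }
})

test_that("compiled and pure-R derivative paths give the same trajectories", {
  p <- tcs_parameters(k_ap = 0.05)
  times <- seq(0, 100, length.out = 11)
  a <- simulate_trajectory(p, times, use_compiled = TRUE)
  b <- simulate_trajectory(p, times, use_compiled = FALSE)
  expect_equal(a$value, b$value, tolerance = 1e-7)
})

test_that("steady state honours trivial source/sink limits", {
  # no autophosphorylation, no leak: nothing downstream is ever made
  ss <- simulate_to_steady_state(tcs_parameters(k_ap = 0, k_lgexp = 0))
  expect_true(ss$converged)
  expect_equal(unname(ss$state[c("M", "Gi", "Gm")]), c(0, 0, 0))

  # irreversible autophosphorylation only: all HK ends up phosphorylated
  p <- tcs_parameters(k_ap = 1, k_ad = 0, k_b1 = 0, k_b2 = 0, k_b3 = 0)
  ss2 <- simulate_to_steady_state(p)
  expect_true(ss2$converged)
  expect_equal(ss2$state[["Sp"]], p[["S_tot"]], tolerance = 1e-6)
  expect_equal(ss2$state[["S"]], 0, tolerance = 1e-9)
})

test_that("isolated promoter binding matches the closed-form occupancy hyperbola", {
  # only reaction Cp + P <-> PCp active; a large phospho-RR pool keeps free
  # Cp effectively fixed, so occupancy = c / (c + Kd)
  c0 <- 10
  p <- tcs_parameters(k_ap = 0, k_ad = 0, k_b1 = 0, k_d1 = 0, k_pt = 0,
                      k_b2 = 0, k_d2 = 0, k_ph = 0, k_b3 = 0, k_d3 = 0,
                      k_bnd = 2, k_unbnd = 6, C_tot = c0, P_tot = 1e-4)
  init <- tcs_state(S = p[["S_tot"]], Cp = c0, P = p[["P_tot"]])
  ss <- simulate_to_steady_state(p, init = init)
  expect_true(ss$converged)
  kd <- 6 / 2
  expect_equal(ss$state[["PCp"]] / p[["P_tot"]], c0 / (c0 + kd),
               tolerance = 1e-4)
})

test_that("steady states are idempotent under re-integration", {
  set.seed(13)
  for (i in 1:5) {
    p <- random_tcs_parameters()
    ss <- simulate_to_steady_state(p)
    if (!ss$converged) next
    ss2 <- simulate_to_steady_state(p, init = ss$state)
    expect_true(ss2$converged)
    rel <- abs(ss2$state - ss$state) / pmax(abs(ss$state), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("initial conditions violating conservation are rejected", {
  p <- tcs_parameters()
  bad <- tcs_state(S = 5, C = p[["C_tot"]], P = p[["P_tot"]])
  expect_error(simulate_to_steady_state(p, init = bad), "conservation")
})

test_that("parameter files round-trip through YAML and JSON with field-style keys", {
  p <- tcs_parameters(k_ap = 0.123, C_tot = 7)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_tcs_parameters(p, path)
    q <- read_tcs_parameters(path)
    expect_equal(as.numeric(q), as.numeric(p), tolerance = 1e-12)
  }
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(k_ap = 1, bogus = 2), path)
  expect_error(read_tcs_parameters(path), "bogus")
})
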