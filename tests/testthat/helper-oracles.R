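# Independent oracles used by the tests.  These deliberately share no code
# with the package internals they check.

# Total consumption flux of one species: sum over reactions of
# (amount consumed) * (rate law), read straight off the network object.
oracle_consumption_flux <- function(net, state, species) {
  rates <- net$rates(state)
  stoich <- net$stoichiometry[species, ]
  sum(pmax(-stoich, 0) * rates)
}

# Naive elementary-effect recomputation: walks each trajectory step by step,
# locates the perturbed coordinate by direct comparison, and tabulates the
# finite differences into per-parameter/output statistics with plain
# data-frame arithmetic.
oracle_morris_stats <- function(trajectories, features) {
  rows <- list()
  for (t_i in seq_along(trajectories)) {
    pts <- trajectories[[t_i]]
    ft <- features[[t_i]]
    for (s in seq_len(nrow(pts) - 1L)) {
      moved <- which(pts[s + 1L, ] != pts[s, ])
      step <- pts[s + 1L, moved] - pts[s, moved]
      for (o in colnames(ft)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = colnames(pts)[moved], output = o,
          ee = (ft[s + 1L, o] - ft[s, o]) / step)
      }
    }
  }
  d <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(d, list(d$parameter, d$output)),
    function(g) data.frame(
      parameter = g$parameter[1L], output = g$output[1L],
      mu = mean(g$ee), mu_star = mean(abs(g$ee)), sigma = stats::sd(g$ee))))
  rownames(out) <- NULL
  out
}

# Exhaustive Campolongo subset search, with its own distance code: the
# spread of a subset is sqrt(sum of squared pairwise trajectory distances),
# a trajectory distance being the sum of Euclidean distances over all point
# pairs.  Returns the lexicographically first maximiser.
oracle_best_subset <- function(trajectories, r) {
  n <- length(trajectories)
  tdist <- function(a, b) {
    s <- 0
    for (i in seq_len(nrow(a)))
      for (j in seq_len(nrow(b)))
        s <- s + sqrt(sum((a[i, ] - b[j, ])^2))
    s
  }
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1L))
    for (b in (a + 1L):n)
      D[a, b] <- D[b, a] <- tdist(trajectories[[a]], trajectories[[b]])
  combos <- utils::combn(n, r)
  spreads <- apply(combos, 2L, function(idx) {
    sub <- D[idx, idx]
    sqrt(sum(sub[upper.tri(sub)]^2))
  })
  list(index = combos[, which.max(spreads)], spread = max(spreads))
}

# Independent spread evaluation for a given subset.
oracle_spread <- function(trajectories, idx) {
  tdist <- function(a, b) {
    s <- 0
    for (i in seq_len(nrow(a)))
      for (j in seq_len(nrow(b)))
        s <- s + sqrt(sum((a[i, ] - b[j, ])^2))
    s
  }
  s2 <- 0
  for (a in seq_along(idx))
    for (b in seq_along(idx))
      if (a < b) s2 <- s2 + tdist(trajectories[[idx[a]]],
                                  trajectories[[idx[b]]])^2
  sqrt(s2)
}

# Random parameter draw within the default two-decade screening bounds
# (log-uniform), with an optional random k_ap.
random_tcs_parameters <- function(include_kap = TRUE) {
  space <- default_parameter_space()
  u <- matrix(stats::runif(length(space$names)), nrow = 1L)
  vals <- scale_points(u, space)
  args <- as.list(as.numeric(vals))
  names(args) <- unname(
    c(C = "C_tot", k_ad = "k_ad", k_b1 = "k_b1", k_b2 = "k_b2",
      k_b3 = "k_b3", k_bnd = "k_bnd", k_d1 = "k_d1", k_d2 = "k_d2",
      k_d3 = "k_d3", k_lgexp = "k_lgexp", k_ph = "k_ph",
      k_pmgexp = "k_pmgexp", k_pt = "k_pt", k_unbnd = "k_unbnd",
      pato = "P_tot", S = "S_tot")[space$names])
  if (include_kap) args$k_ap <- 10^stats::runif(1L, -4, 0)
  do.call(tcs_parameters, args)
}
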