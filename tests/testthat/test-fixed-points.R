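test_that("the Schlogl steady-state cubic reproduces the bulk fixed points", {
  sr <- schlogl_reservoir()
  roots <- schlogl_reservoir_fixed_points(sr["x"], sr["z"],
                                          k1 = 5.25e4, k1r = 2.85e3,
                                          k2 = 9.15e-2, k2r = 7.15e-3)
  expect_length(roots, 3)
  expect_equal(signif(roots, 3), schlogl_printed_roots)
  # k2r z = 0 with fast drain: single root at the origin
  lim <- schlogl_reservoir_fixed_points(1e-4, 0, 1, 1, 1e3, 0)
  expect_length(lim, 0)   # y = 0 root excluded (strictly positive)
})

test_that("the homotopy solver agrees with the cubic companion matrix", {
  sr <- schlogl_reservoir()
  # degenerate 1-variable system: the reservoir cubic itself
  E <- matrix(c(3L, 2L, 1L, 0L), ncol = 1)
  cc <- c(-2.85e3, 5.25e4 * unname(sr["x"]), -9.15e-2,
          7.15e-3 * unname(sr["z"]))
  sys <- make_polysys(list(E), list(cc), species = "Y", C_eps = 0.01)
  roots <- solve_all_fixed_points(sys)
  re <- sort(Re(roots[abs(Im(roots)) < 1e-8, 1]))
  expect_equal(signif(re, 3), schlogl_printed_roots)
})

test_that("the Wilhelm reduction and homotopy solver give the printed pairs", {
  x <- unname(wilhelm_reservoir()["x"])
  fp <- wilhelm_reservoir_fixed_points(x, k1 = 5.86e2, k2 = 9.26e2,
                                       k3 = 5.75e2, k4 = 9.98e-2)
  expect_equal(nrow(fp), 3)
  expect_equal(signif(fp$y, 3), wilhelm_printed$y)
  expect_equal(signif(fp$z, 3), wilhelm_printed$z)
  # degenerate discriminant: only the origin survives
  lone <- wilhelm_reservoir_fixed_points(x, 1e-3, 1, 1e6, 10)
  expect_equal(nrow(lone), 1)

  # 2-variable reservoir system solved by homotopy continuation
  k1 <- 5.86e2; k2 <- 9.26e2; k3 <- 5.75e2; k4 <- 9.98e-2
  Ey <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L, 1L, 0L), ncol = 2, byrow = TRUE)
  cy <- c(2 * k1 * x, -k2, -k3, -k4)
  Ez <- matrix(c(2L, 0L, 0L, 1L), ncol = 2, byrow = TRUE)
  cz <- c(k2, -k1 * x)
  sys <- make_polysys(list(Ey, Ez), list(cy, cz), species = c("y", "z"),
                      C_eps = 0.01)
  roots <- solve_all_fixed_points(sys)
  real <- roots[apply(abs(Im(roots)) < 1e-8, 1, all), , drop = FALSE]
  got <- Re(real)[order(Re(real[, 1])), , drop = FALSE]
  expect_equal(nrow(got), 3)
  expect_equal(signif(got[, 1], 3), wilhelm_printed$y)
  expect_equal(signif(got[, 2], 3), wilhelm_printed$z)
})

test_that("quasi-stability labels the bulk regimes as the saddle structure", {
  sr <- schlogl_reservoir()
  E <- matrix(c(3L, 2L, 1L, 0L), ncol = 1)
  cc <- c(-2.85e3, 5.25e4 * unname(sr["x"]), -9.15e-2,
          7.15e-3 * unname(sr["z"]))
  sys <- make_polysys(list(E), list(cc), species = "Y", C_eps = 1)
  labels <- vapply(schlogl_printed_roots, function(y)
    quasi_stability(sys, y, dilution = FALSE)$label, character(1))
  expect_equal(labels, c("stable", "unstable", "stable"))

  x <- unname(wilhelm_reservoir()["x"])
  k1 <- 5.86e2; k2 <- 9.26e2; k3 <- 5.75e2; k4 <- 9.98e-2
  Ey <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L, 1L, 0L), ncol = 2, byrow = TRUE)
  cy <- c(2 * k1 * x, -k2, -k3, -k4)
  Ez <- matrix(c(2L, 0L, 0L, 1L), ncol = 2, byrow = TRUE)
  cz <- c(k2, -k1 * x)
  wsys <- make_polysys(list(Ey, Ez), list(cy, cz), species = c("y", "z"),
                       C_eps = 1)
  saddle <- quasi_stability(wsys, c(1.20e-4, 1.94e-5), dilution = FALSE)
  expect_equal(saddle$label, "unstable")
  # pure decay is stable everywhere
  dsys <- make_polysys(list(matrix(1L, 1, 1)), list(-2), species = "A")
  expect_equal(quasi_stability(dsys, 0.5, dilution = FALSE)$label, "stable")
})

test_that("a linear one-species system has exactly its closed-form root", {
  none <- reaction_network(list(), species = "A")
  reactor <- vesicle_reactor(none, vesicle_environment(0.2, c(A = 0.03)),
                             membrane_spec(c(A = 1)), B_T = 1e4)
  sys <- steady_state_system(reactor, surface_from_diameter(400))
  fp <- fixed_points(reactor, surface_from_diameter(400))
  expect_equal(nrow(fp), 1)
  expect_equal(fp$A, 0.03, tolerance = 1e-10)
  expect_lt(max(poly_relative_residual_pub(sys, fp$A)), 1e-10)
})

test_that("validity filters drop complex, crowded and oversized roots", {
  reactor <- schlogl_test_reactor()
  sys <- steady_state_system(reactor, surface_from_diameter(400))
  Ce <- reactor$C_eps
  roots <- rbind(
    c(1e-4 + 2e-3i, 1e-4 - 1e-3i, 1e-4 + 0i),          # complex pair member
    c(Ce + 0i, Ce + 0i, Ce + 0i),                       # sum over C_eps
    c(-1e-3 + 0i, 1e-4 + 0i, 1e-4 + 0i))                # negative
  colnames(roots) <- sys$species
  fp <- filter_valid(roots, sys, res_tol = Inf)
  expect_equal(nrow(fp), 0)
  # oversized: tune concentrations so the volume exceeds the GUV cap
  s_huge <- rep((Ce - reactor$B_T / (10 * omega_from_diameter(2000))) / 3, 3)
  big <- matrix(complex(real = s_huge), 1, dimnames = list(NULL, sys$species))
  expect_equal(nrow(filter_valid(big, sys, res_tol = Inf)), 0)
})

test_that("homotopy roots equal the dense multistart Newton root set", {
  n_sys <- 15
  ok <- 0
  for (seed in seq_len(n_sys)) {
    set.seed(seed + 7000)
    net <- random_network(seed, n_species = 2,
                          n_reactions = sample(1:2, 1))
    reactor <- random_reactor(net, seed + 500)
    sys <- steady_state_system(reactor, surface_from_diameter(400))
    hom <- fixed_points(reactor, surface_from_diameter(400))
    ora <- newton_multistart(sys, n_starts = 300, seed = seed)
    # compare valid root sets (non-negative, below C_eps, inside cap)
    keep <- apply(ora, 1, function(s)
      all(s >= -1e-12) && sum(s) < reactor$C_eps &&
        reactor$B_T / (reactor$C_eps - sum(s)) < omega_from_diameter(2000))
    ora <- ora[keep, , drop = FALSE]
    expect_equal(nrow(hom), nrow(ora))
    if (nrow(hom) && nrow(hom) == nrow(ora)) {
      # order rows by total concentration: distinct steady states differ
      # in their totals, while single coordinates can tie to ~1e-12
      ora <- ora[order(rowSums(ora)), , drop = FALSE]
      hm <- as.matrix(hom[, net$species])
      hm <- hm[order(rowSums(hm)), , drop = FALSE]
      expect_equal(unname(hm), unname(ora), tolerance = 1e-6)
    }
    ok <- ok + 1
  }
  expect_equal(ok, n_sys)
})

test_that("every reported fixed point satisfies the steady-state system", {
  for (seed in 1:10) {
    set.seed(seed + 8000)
    net <- random_network(seed, n_species = sample(2:3, 1))
    reactor <- random_reactor(net, seed + 900)
    sys <- steady_state_system(reactor, surface_from_diameter(400))
    fp <- fixed_points(reactor, surface_from_diameter(400))
    if (!nrow(fp)) next
    for (k in seq_len(nrow(fp)))
      expect_lt(max(poly_relative_residual_pub(
        sys, as.numeric(fp[k, sys$species]))), 1e-10)
  }
})

test_that("impermeable inert species are rejected as underdetermined", {
  none <- reaction_network(list(), species = "A")
  reactor <- vesicle_reactor(none, vesicle_environment(0.2, c(A = 0.01)),
                             membrane_spec(c(A = 0)), B_T = 100)
  expect_error(steady_state_system(reactor, 1e-12), "underdetermined")
})
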