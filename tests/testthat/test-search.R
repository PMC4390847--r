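test_that("wide-area sampling respects its ranges and seed", {
  net <- schlogl_network()
  preset <- census_preset("schlogl_cs1")
  sets <- sample_wide(net, preset$ranges, 40, seed = 5)
  for (r in sets) {
    expect_true(all(r$Dx >= 1 / 5 & r$Dx <= 50))
    expect_true(r$s_eps[["Y"]] >= 0 && r$s_eps[["Y"]] <= 0.002)
    expect_equal(r$s_eps[["X"]], unname(schlogl_reservoir()["x"]))
    expect_equal(r$s_eps[["Z"]], unname(schlogl_reservoir()["z"]))
    expect_true(r$b_eps >= 0.002 * 0.6 && r$b_eps <= 0.002 * 1.4)
    expect_true(r$B_T >= 2 && r$B_T <= 2000)
    # rates pinned to the bulk regime
    expect_equal(r$network$reactions[[1]]$k, 5.25e4)
  }
  again <- sample_wide(net, preset$ranges, 40, seed = 5)
  expect_equal(sets[[17]]$Dx, again[[17]]$Dx)
  expect_equal(sets[[17]]$B_T, again[[17]]$B_T)
})

test_that("degenerate ranges produce the single determined set", {
  net <- parse_network("X -> Y (k=1)")
  ranges <- sampling_ranges(Dx_range = c(2, 2), s_eps_range = c(0.01, 0.01),
                            b_eps_range = c(0.1, 0.1),
                            B_T_range = c(500, 500), sample_rates = FALSE)
  s <- sample_wide(net, ranges, 1, seed = 3)[[1]]
  expect_equal(unname(s$Dx), c(2, 2))
  expect_equal(unname(s$s_eps), c(0.01, 0.01))
  expect_equal(s$B_T, 500)
})

test_that("hot-spot sampling perturbs within the stated fraction", {
  basis <- random_reactor(random_network(1), 10)
  hs <- sample_hotspot(basis, 30, fraction = 0.2, seed = 4)
  for (r in hs) {
    expect_true(all(r$Dx / basis$Dx >= 0.8 & r$Dx / basis$Dx <= 1.2))
    expect_true(r$B_T / basis$B_T >= 0.8 && r$B_T / basis$B_T <= 1.2)
  }
  frozen <- sample_hotspot(basis, 5, fraction = 0, seed = 4)
  for (r in frozen) {
    expect_equal(r$Dx, basis$Dx)
    expect_equal(r$B_T, basis$B_T)
    expect_equal(r$s_eps, basis$s_eps)
  }
  again <- sample_hotspot(basis, 30, fraction = 0.2, seed = 4)
  expect_equal(hs[[12]]$Dx, again[[12]]$Dx)
})

test_that("a reaction-free template censuses to one fixed point everywhere", {
  net <- reaction_network(list(), species = "A")
  ranges <- sampling_ranges(s_eps_range = c(0.001, 0.05))
  sets <- sample_wide(net, ranges, 25, seed = 9)
  cz <- census(sets)
  expect_equal(cz$n_failed, 0)
  expect_equal(cz$table$fraction[cz$table$count == 1], 1)
})

test_that("the morphology transformation is exact under re-solving", {
  reactor <- schlogl_test_reactor()
  S0 <- surface_from_diameter(400)
  fp0 <- fixed_points(reactor, S0)
  expect_gte(nrow(fp0), 1)
  a <- 2.5; b <- 3; cc <- 0.8
  tr <- transform_curve(reactor, a = a, b = b, c = cc)
  expect_equal(tr$morphology_map(fp0$Omega, fp0$S_mu0)$Omega,
               fp0$Omega * b * cc)
  # re-solve at the mapped surface: concentrations invariant, volume x bc
  fp1 <- fixed_points(tr$reactor, S0 * b / a,
                      Omega_max = omega_from_diameter(2000) * b * cc)
  expect_equal(nrow(fp1), nrow(fp0))
  for (spn in reactor$network$species)
    expect_equal(fp1[[spn]], fp0[[spn]], tolerance = 1e-8)
  expect_equal(fp1$Omega, fp0$Omega * b * cc, tolerance = 1e-8)
  # identity transform is the identity
  id <- transform_curve(reactor, 1, 1, 1)
  expect_equal(id$reactor$B_T, reactor$B_T)
  expect_equal(id$reactor$D, reactor$D)
})

test_that("concentration rescaling moves fixed points without moving morphology", {
  reactor <- schlogl_test_reactor()
  S0 <- surface_from_diameter(400)
  fp0 <- fixed_points(reactor, S0)
  sys0 <- steady_state_system(reactor, S0)
  n <- 100
  scaled <- rescale_concentrations(reactor, n)
  expect_equal(scaled$C_eps, reactor$C_eps / n)
  fp1 <- fixed_points(scaled, S0)
  sys1 <- steady_state_system(scaled, S0)
  expect_equal(nrow(fp1), nrow(fp0))
  for (spn in reactor$network$species)
    expect_equal(fp1[[spn]], fp0[[spn]] / n, tolerance = 1e-8)
  expect_equal(fp1$Omega, fp0$Omega, tolerance = 1e-8)
  # the time scale is untouched: Jacobian spectra agree
  for (k in seq_len(nrow(fp0))) {
    ev0 <- quasi_stability(sys0, as.numeric(fp0[k, sys0$species]))$eigenvalues
    ev1 <- quasi_stability(sys1, as.numeric(fp1[k, sys1$species]))$eigenvalues
    expect_equal(sort(Re(ev0)), sort(Re(ev1)), tolerance = 1e-6)
  }
  # identity rescale
  same <- rescale_concentrations(reactor, 1)
  expect_equal(same$s_eps, reactor$s_eps)
  expect_equal(same$network$reactions[[1]]$k, 5.25e4)
})

test_that("rescaling absorbs factors by reaction order", {
  net <- parse_network("X -> Y (k=2); X + Y -> Z (k=3); X + 2Y <-> 3Z (k=4, kr=5)")
  reactor <- vesicle_reactor(
    net, vesicle_environment(0.2, setNames(rep(0.01, 3), net$species)),
    membrane_spec(setNames(rep(1, 3), net$species)), B_T = 1000)
  sc <- rescale_concentrations(reactor, 10)
  ks <- vapply(sc$network$reactions, `[[`, numeric(1), "k")
  expect_equal(ks, c(2, 3 * 10, 4 * 100))
  expect_equal(sc$network$reactions[[3]]$kr, 5 * 100)  # trimolecular reverse
  expect_equal(sc$B_T, 100)
})

test_that("a single unimolecular reaction never passes the bistability search", {
  lone <- parse_network("X -> Y (k=1)")
  res <- find_bistable_regimes(lone, budget = 150, seed = 2)
  expect_length(res$candidates, 0)
  expect_true(res$diagnostics$phase1_hits == 0)
})
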