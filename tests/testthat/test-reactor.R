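test_that("osmotic volume follows the isotonic condition exactly", {
  expect_equal(volume_from_concentrations(63064, 0.2), 315320)
  expect_error(volume_from_concentrations(100, 0.2, c(A = 0.15, B = 0.05)),
               "osmotic blow-up")
  Om <- volume_from_concentrations(100, 0.2, c(A = 0.1))
  expect_equal(Om, 1000)
  # implied internal buffer closes the isotonic identity
  expect_equal(100 / Om + 0.1, 0.2, tolerance = 1e-15)
})

test_that("surface area is exact sphere geometry", {
  d <- 4e-6                               # dm, a 400-nm-diameter sphere
  Om <- osmocell_constants$N_A * pi * d^3 / 6
  expect_equal(surface_from_volume(Om), pi * d^2, tolerance = 1e-12)
  # volume x8 => surface x4
  expect_equal(surface_from_volume(8 * Om) / surface_from_volume(Om), 4,
               tolerance = 1e-12)
  # composition with reduced_surface is identically spherical
  for (Om in 10^seq(2, 12, by = 2))
    expect_equal(reduced_surface(Om, surface_from_volume(Om)), 1,
                 tolerance = 1e-12)
})

test_that("reduced surface is linear in area and labels regions", {
  Om <- 1e7
  S <- surface_from_volume(Om)
  expect_equal(reduced_surface(Om, 2 * S), 2, tolerance = 1e-12)
  expect_equal(morphology_region(0.85), "burst")
  expect_equal(morphology_region(0.95), "tense")
  expect_equal(morphology_region(1), "spherical")
  expect_equal(morphology_region(1.5), "deflated")
})

test_that("sphere-diameter conversions invert each other", {
  for (d in c(50, 400, 2000)) {
    expect_equal(diameter_from_omega(omega_from_diameter(d)), d,
                 tolerance = 1e-12)
    expect_equal(diameter_from_surface(surface_from_diameter(d)), d,
                 tolerance = 1e-12)
  }
  mp <- morphology_point(omega_from_diameter(400), surface_from_diameter(400))
  expect_equal(mp$Phi, 1, tolerance = 1e-12)
  expect_equal(mp$d_Omega_nm, 400, tolerance = 1e-10)
})

test_that("diffusion constants scale from the ribose reference", {
  mem <- membrane_spec(numeric(0))
  expect_equal(diffusion_constant(1, mem), 2.65e8 / 4e-8)
  expect_equal(diffusion_constant(0, mem), 0)
  expect_equal(diffusion_constant(50, mem), 50 * diffusion_constant(1, mem))
})

test_that("CSTR derivatives balance feed against washout", {
  net <- parse_network("X -> Y (k=1)")
  cs <- cstr_spec(c(X = 1, Y = 0), theta = 1)
  # steady state of dx = -x + (1-x), dy = x - y
  r <- rhs_cstr(net, cs, c(X = 0.5, Y = 0.5))
  expect_equal(unname(r), c(0, 0), tolerance = 1e-12)
  # equilibrium with the feed when nothing reacts
  none <- reaction_network(list(), species = c("X", "Y"))
  r0 <- rhs_cstr(none, cs, c(X = 1, Y = 0))
  expect_equal(unname(r0), c(0, 0))
  # infinite residence time leaves pure mass action
  slow <- cstr_spec(c(X = 1, Y = 0), theta = 1e12)
  s <- c(X = 0.3, Y = 0.1)
  expect_equal(rhs_cstr(net, slow, s), mak_rates(net, s), tolerance = 1e-10)
})

test_that("reservoir conditions pin species and keep intermediates", {
  net <- schlogl_network()
  sr <- schlogl_reservoir()
  pinned <- c(X = unname(sr["x"]), Z = unname(sr["z"]))
  r <- rhs_reservoir(net, pinned, c(Y = 1e-3))
  expect_equal(unname(r[c("X", "Z")]), c(0, 0))
  expect_true(abs(r[["Y"]]) > 0)
  expect_error(rhs_reservoir(net, pinned, c(Y = 1, X = 1)), "disjoint")
  none <- reaction_network(list(), species = "A")
  expect_equal(unname(rhs_reservoir(none, numeric(0), c(A = 1))), 0)
})

test_that("high-buffer vesicle reduces exactly to the CSTR under Eq-6 mapping", {
  net <- random_network(4)
  sp <- net$species
  s_eps <- setNames(runif(3, 0, 0.05), sp)
  D_mult <- 3.7
  reactor <- vesicle_reactor(net, vesicle_environment(0.2, s_eps),
                             membrane_spec(setNames(rep(D_mult, 3), sp)),
                             B_T = 63064)
  Om0 <- reactor$B_T / reactor$b_eps
  S0 <- surface_from_volume(Om0)
  D <- diffusion_constant(D_mult, reactor$membrane)
  theta <- residence_time_equivalent(reactor, S0, D)
  expect_equal(theta, reactor$B_T / (S0 * D * reactor$b_eps))
  cs <- cstr_spec(s_eps, theta)
  for (seed in 1:5) {
    set.seed(seed)
    s <- setNames(runif(3, 0, 0.05), sp)
    expect_equal(rhs_vesicle_highbuffer(reactor, Om0, S0, s),
                 rhs_cstr(net, cs, s), tolerance = 1e-12)
  }
  # doubling the buffer halves the residence time
  r2 <- reactor
  r2$b_eps <- 2 * reactor$b_eps
  expect_equal(residence_time_equivalent(r2, S0, D), theta / 2)
})

test_that("high-buffer vesicle is at rest at the external concentrations", {
  none <- reaction_network(list(), species = c("A", "B"))
  reactor <- vesicle_reactor(none,
                             vesicle_environment(0.2, c(A = 0.01, B = 0.02)),
                             membrane_spec(c(A = 1, B = 5)), B_T = 1000)
  r <- rhs_vesicle_highbuffer(reactor, 5000, 1e-12, c(A = 0.01, B = 0.02))
  expect_equal(unname(r), c(0, 0))
})

test_that("full model derivative vanishes for an inert equilibrated solute", {
  none <- reaction_network(list(), species = "A")
  reactor <- vesicle_reactor(none, vesicle_environment(0.15, c(A = 0.03)),
                             membrane_spec(c(A = 2)), B_T = 5e4)
  r <- rhs_vesicle_full(reactor, c(A = 0.03), diagnostics = TRUE)
  expect_equal(unname(r["A"]), 0, tolerance = 1e-15)
  expect_equal(attr(r, "dilution")[["A"]], 0, tolerance = 1e-15)
})

test_that("full model matches the molecule-number formulation pointwise", {
  for (seed in 1:8) {
    net <- random_network(seed, n_species = 3)
    reactor <- random_reactor(net, seed + 100)
    set.seed(seed)
    s <- setNames(runif(3, 0, reactor$C_eps / 6), net$species)
    Om <- volume_from_concentrations(reactor$B_T, reactor$C_eps, s)
    n <- s * Om
    dn <- number_space_rhs(reactor, n)
    # chain rule: ds/dt = dn/dt / Omega - s * (dOmega/dt) / Omega,
    # dOmega/dt = sum(dn)/C_eps
    ds_from_n <- dn / Om - s * sum(dn) / (reactor$C_eps * Om)
    expect_equal(unname(rhs_vesicle_full(reactor, s)[net$species]),
                 unname(ds_from_n[net$species]), tolerance = 1e-10)
  }
})

test_that("dilution term vanishes at fixed-surface fixed points", {
  # at a root of the fixed-surface system every g_i is zero, so the
  # dilution term -(s_i/C_eps) sum(g) evaluated with that surface is zero
  reactor <- schlogl_test_reactor()
  S0 <- surface_from_diameter(400)
  sys <- steady_state_system(reactor, S0)
  fp <- fixed_points(reactor, S0)
  expect_gte(nrow(fp), 1)
  s <- as.numeric(fp[1, reactor$network$species])
  g <- poly_eval(sys, s)
  dil <- -(s / reactor$C_eps) * sum(g)
  expect_lt(max(abs(dil)), 1e-16)
  expect_lt(max(abs(g)), 1e-12)
})
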