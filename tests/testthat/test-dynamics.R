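test_that("a permeable inert solute relaxes monotonically to its exterior", {
  none <- reaction_network(list(), species = "A")
  reactor <- vesicle_reactor(none, vesicle_environment(0.15, c(A = 0.05)),
                             membrane_spec(c(A = 0.5)), B_T = 63064)
  traj <- integrate_reactor(reactor, c(A = 0.005), c(0, 2000), n_out = 200)
  a <- traj$conc[, "A"]
  expect_true(all(diff(a) > -1e-12))
  expect_equal(unname(tail(a, 1)), 0.05, tolerance = 1e-6)
  st <- detect_steady_state(traj, window = 200, tol = 1e-6)
  expect_true(st$converged)
  expect_equal(unname(st$state[["A"]]), 0.05, tolerance = 1e-6)
})

test_that("trajectories respect the isotonic identity at every sample", {
  net <- random_network(2, n_species = 3)
  reactor <- random_reactor(net, 5)
  s0 <- reactor$s_eps * 0.5
  traj <- integrate_reactor(reactor, s0, c(0, 10), n_out = 100)
  ident <- reactor$B_T / traj$Omega + rowSums(traj$conc)
  expect_equal(ident, rep(reactor$C_eps, length(ident)), tolerance = 1e-8)
  # also in number space
  traj_n <- integrate_reactor(reactor, s0, c(0, 10), n_out = 100,
                              space = "number")
  ident_n <- reactor$B_T / traj_n$Omega + rowSums(traj_n$conc)
  expect_equal(ident_n, rep(reactor$C_eps, length(ident_n)),
               tolerance = 1e-8)
})

test_that("concentration-space and number-space integration agree", {
  for (seed in c(3, 8)) {
    set.seed(seed + 9000)
    net <- random_network(seed, n_species = sample(2:3, 1))
    reactor <- random_reactor(net, seed + 40)
    s0 <- reactor$s_eps * 0.25 + 1e-4
    t_end <- 20
    tc <- integrate_reactor(reactor, s0, c(0, t_end), n_out = 50,
                            space = "concentration")
    tn <- integrate_reactor(reactor, s0, c(0, t_end), n_out = 50,
                            space = "number")
    expect_equal(tc$conc[nrow(tc$conc), ], tn$conc[nrow(tn$conc), ],
                 tolerance = 1e-6)
    expect_equal(tail(tc$Omega, 1), tail(tn$Omega, 1), tolerance = 1e-6)
  }
})

test_that("injections add molecules at exactly the stated rate", {
  none <- reaction_network(list(), species = c("A", "B"))
  reactor <- vesicle_reactor(none, vesicle_environment(0.2, c(A = 0.01, B = 0.01)),
                             membrane_spec(c(A = 0, B = 0)), B_T = 1000)
  n <- c(A = 500, B = 200)
  inj <- injection_event("A", rate = 750, start = 1, duration = 2)
  base <- number_space_rhs(reactor, n)
  during <- number_space_rhs(reactor, n, list(inj), time = 1.5)
  after <- number_space_rhs(reactor, n, list(inj), time = 3.5)
  expect_equal(during[["A"]] - base[["A"]], 750)
  expect_equal(during[["B"]], base[["B"]])
  expect_equal(after, base)
})

test_that("an empty injection list integrates identically to none", {
  net <- parse_network("X -> Y (k=0.5)")
  reactor <- vesicle_reactor(net, vesicle_environment(0.2, c(X = 0.05, Y = 0.01)),
                             membrane_spec(c(X = 2, Y = 0.5)), B_T = 2e4)
  s0 <- c(X = 0.02, Y = 0.005)
  t1 <- integrate_reactor(reactor, s0, c(0, 5), injections = list(),
                          n_out = 60)
  t2 <- integrate_reactor(reactor, s0, c(0, 5), n_out = 60)
  expect_equal(t1$conc, t2$conc, tolerance = 1e-10)
})

test_that("an injection grows the vesicle and the event log is kept", {
  none <- reaction_network(list(), species = "A")
  reactor <- vesicle_reactor(none, vesicle_environment(0.2, c(A = 0.01)),
                             membrane_spec(c(A = 0)), B_T = 1e4)
  inj <- injection_event("A", rate = 1e4, start = 2, duration = 3)
  traj <- integrate_reactor(reactor, c(A = 0.005), c(0, 10),
                            injections = list(inj), n_out = 120)
  # impermeable species, so exactly rate x duration molecules are added
  n_added <- unname(tail(traj$n[, "A"], 1) - traj$n[1, "A"])
  expect_equal(n_added, 1e4 * 3, tolerance = 1e-6)
  expect_gt(tail(traj$Omega, 1), traj$Omega[1])
  expect_length(traj$events, 1)
})

test_that("a truncated relaxation is not reported as converged", {
  none <- reaction_network(list(), species = "A")
  reactor <- vesicle_reactor(none, vesicle_environment(0.15, c(A = 0.05)),
                             membrane_spec(c(A = 0.5)), B_T = 63064)
  traj <- integrate_reactor(reactor, c(A = 0.005), c(0, 0.5), n_out = 50)
  st <- detect_steady_state(traj, window = 0.2, tol = 1e-6)
  expect_false(st$converged)
  expect_error(detect_steady_state(traj, window = 10), "shorter")
})

test_that("integration refuses osmotically impossible initial states", {
  none <- reaction_network(list(), species = "A")
  reactor <- vesicle_reactor(none, vesicle_environment(0.1, c(A = 0.01)),
                             membrane_spec(c(A = 1)), B_T = 100)
  expect_error(integrate_reactor(reactor, c(A = 0.2), c(0, 1)),
               "osmotic blow-up")
})
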