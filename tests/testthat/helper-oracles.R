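# Independent oracles and fixture builders used across the suite.

# Brute-force mass-action rates: assembles the full stoichiometric matrix
# and flux vector independently of mak_rates' incremental accumulation.
oracle_mak <- function(network, s) {
  sp <- network$species
  nu <- matrix(0, length(sp), length(network$reactions),
               dimnames = list(sp, NULL))
  flux <- numeric(length(network$reactions))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (nm in names(r$reactants)) nu[nm, j] <- nu[nm, j] - r$reactants[[nm]]
    for (nm in names(r$products))  nu[nm, j] <- nu[nm, j] + r$products[[nm]]
    fwd <- r$k
    for (nm in names(r$reactants)) fwd <- fwd * s[[nm]]^r$reactants[[nm]]
    rev <- 0
    if (r$kr > 0) {
      rev <- r$kr
      for (nm in names(r$products)) rev <- rev * s[[nm]]^r$products[[nm]]
    }
    flux[j] <- fwd - rev
  }
  drop(nu %*% flux)
}

# Dense multi-start damped Newton on a steady-state polynomial system:
# real starts across (0, C_eps)^n (log-uniform and uniform mixed), damped
# steps, dedup of converged roots. Independent of the homotopy path.
newton_multistart <- function(sys, n_starts = 1000, seed = 1) {
  set.seed(seed)
  n <- length(sys$species)
  Ce <- sys$C_eps
  roots <- matrix(numeric(0), 0, n)
  for (k in seq_len(n_starts)) {
    s <- if (k %% 2 == 0) runif(n, 0, Ce) else Ce * 10^runif(n, -6, 0)
    ok <- FALSE
    for (it in 1:80) {
      f <- poly_eval(sys, s)
      J <- poly_jacobian(sys, s)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      f0 <- sum(f^2)
      repeat {
        s_new <- s + lam * step
        f1 <- sum(poly_eval(sys, s_new)^2)
        if (f1 <= f0 || lam < 1e-6) break
        lam <- lam / 2
      }
      moved <- max(abs(s_new - s))
      s <- s_new
      if (max(abs(s)) > 1e3 * Ce) break
      if (moved < 1e-13 * (1 + max(abs(s)))) { ok <- TRUE; break }
    }
    if (!ok) next
    if (max(poly_relative_residual_pub(sys, s)) > 1e-9) next
    dup <- FALSE
    if (nrow(roots)) {
      for (i in seq_len(nrow(roots)))
        if (max(abs(roots[i, ] - s)) < 1e-7 * (1 + max(abs(s)))) {
          dup <- TRUE
          break
        }
    }
    if (!dup) roots <- rbind(roots, s)
  }
  colnames(roots) <- sys$species
  roots
}

# the package's relative residual, re-exposed for the oracle
poly_relative_residual_pub <- function(sys, s)
  getFromNamespace("poly_relative_residual", "osmocell")(sys, s)

# random small mass-action networks over up to 3 species
random_network <- function(seed, n_species = 3, n_reactions = 2) {
  set.seed(seed)
  sp <- LETTERS[seq_len(n_species)]
  rxns <- lapply(seq_len(n_reactions), function(i) {
    repeat {
      nr <- sample(1:2, 1)
      np <- sample(1:2, 1)
      re <- table(sample(sp, nr, replace = TRUE))
      pr <- table(sample(sp, np, replace = TRUE))
      if (!identical(re, pr)) break
    }
    reaction(setNames(as.integer(re), names(re)),
             setNames(as.integer(pr), names(pr)),
             k = runif(1, 0.1, 5),
             kr = if (runif(1) < 0.5) runif(1, 0.01, 0.5) else NULL)
  })
  reaction_network(rxns, species = sp)
}

# random vesicle reactor around a template network
random_reactor <- function(network, seed, b_eps = NULL) {
  set.seed(seed)
  sp <- network$species
  if (is.null(b_eps)) b_eps <- runif(1, 0.05, 0.3)
  vesicle_reactor(
    network,
    vesicle_environment(b_eps, setNames(runif(length(sp), 0, 0.1), sp)),
    membrane_spec(setNames(runif(length(sp), 0.2, 50), sp)),
    B_T = runif(1, 100, 1e5))
}

# hand-constructed polynomial systems (reservoir limits), using the
# package's monomial representation
make_polysys <- function(Elist, clist, species, C_eps = 1, B_T = 1,
                         S_mu0 = 1) {
  structure(list(eqs = Map(function(E, c) list(E = E, c = c), Elist, clist),
                 species = species, K = rep(0, length(species)),
                 C_eps = C_eps, B_T = B_T, S_mu0 = S_mu0,
                 degrees = vapply(Elist, function(E)
                   as.integer(max(1, max(rowSums(E)))), integer(1))),
            class = "osmo_polysys")
}

schlogl_printed_roots <- c(5.03e-5, 4.01e-3, 7.86e-3)
wilhelm_printed <- data.frame(y = c(0, 1.20e-4, 1.07e-3),
                              z = c(0, 1.94e-5, 1.55e-3))

# a small vesicle embedding of the Schlogl bulk regime used in several tests
schlogl_test_reactor <- function() {
  sr <- schlogl_reservoir()
  vesicle_reactor(
    schlogl_network(),
    vesicle_environment(0.002, c(X = unname(sr["x"]), Y = 5e-4,
                                 Z = unname(sr["z"]))),
    membrane_spec(c(X = 1, Y = 1, Z = 1)), B_T = 1000)
}
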