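# Polynomial form of the fixed-surface steady-state equations.
#
# With the surface pinned at S_mu0 and the dilution term dropped (volume is
# stationary at steady state), each species' derivative is a multivariate
# polynomial in the concentrations:
#   r_i(s) + K_i (C_eps - sum_j s_j) (s_eps_i - s_i),  K_i = S_mu0 D_i / B_T
# Equations are stored as sparse monomial lists (exponent matrix + coeffs).

#' Fixed-surface steady-state polynomial system
#'
#' Builds, for a vesicle reactor with an imposed constant surface area, the
#' square polynomial system whose roots are its steady states. The total
#' degree of each equation is the larger of the species' maximal reaction
#' order and 2 (the diffusion-osmosis part is quadratic).
#'
#' @param reactor an `"osmo_reactor"`.
#' @param S_mu0 imposed surface area (dm^2, > 0).
#' @return An object of class `"osmo_polysys"`: equations (`eqs`, each a
#'   list with exponent matrix `E` and coefficients `c`), `species`, the
#'   diffusion constants `K`, per-equation total `degrees`, and the reactor
#'   parameters needed downstream.
#' @export
steady_state_system <- function(reactor, S_mu0) {
  stopifnot(inherits(reactor, "osmo_reactor"), S_mu0 > 0)
  sp <- reactor$network$species
  n <- length(sp)
  K <- S_mu0 * reactor$D / reactor$B_T
  eqs <- vector("list", n)
  for (i in seq_len(n)) {
    mono <- monomials_for_species(reactor, sp, i, K[i])
    if (nrow(mono$E) == 0L)
      stop("species ", sp[i], " is impermeable and chemically inert: its ",
           "steady state is underdetermined; fold it into the trapped ",
           "buffer count B_T instead")
    eqs[[i]] <- mono
  }
  structure(list(eqs = eqs, species = sp, K = K,
                 C_eps = reactor$C_eps, B_T = reactor$B_T, S_mu0 = S_mu0,
                 degrees = vapply(eqs, function(e)
                   as.integer(max(1, max(rowSums(e$E)))), integer(1))),
            class = "osmo_polysys")
}

# monomial list for one species' equation; collapses duplicates, drops zeros
monomials_for_species <- function(reactor, sp, i, Ki) {
  n <- length(sp)
  E <- matrix(0L, 0L, n)
  cf <- numeric(0)
  add <- function(expo, coef) {
    if (coef == 0) return()
    E <<- rbind(E, expo)
    cf <<- c(cf, coef)
  }
  expo_of <- function(st) {
    e <- integer(n)
    e[match(names(st), sp)] <- as.integer(st)
    e
  }
  # mass-action part
  for (rxn in reactor$network$reactions) {
    net <- (if (sp[i] %in% names(rxn$products)) rxn$products[[sp[i]]] else 0L) -
      (if (sp[i] %in% names(rxn$reactants)) rxn$reactants[[sp[i]]] else 0L)
    if (net == 0L) next
    add(expo_of(rxn$reactants), net * rxn$k)
    if (rxn$kr > 0) add(expo_of(rxn$products), -net * rxn$kr)
  }
  # diffusion-osmosis part: Ki (C_eps - sum_j s_j)(s_eps_i - s_i)
  if (Ki > 0) {
    Ce <- reactor$C_eps
    se <- reactor$s_eps[i]
    add(integer(n), Ki * Ce * se)                         # constant
    ei <- integer(n); ei[i] <- 1L
    add(ei, -Ki * Ce)                                     # -Ce s_i
    for (j in seq_len(n)) {
      ej <- integer(n); ej[j] <- 1L
      if (se != 0) add(ej, -Ki * se)                      # -se_i s_j
      eij <- ej; eij[i] <- eij[i] + 1L
      add(eij, Ki)                                        # + s_i s_j
    }
  }
  # collapse duplicate monomials
  if (nrow(E) > 1L) {
    key <- apply(E, 1L, paste, collapse = ",")
    agg <- rowsum(cf, key)
    first <- !duplicated(key)
    E <- E[first, , drop = FALSE]
    cf <- agg[match(key[first], rownames(agg)), 1L]
  }
  keep <- cf != 0
  list(E = E[keep, , drop = FALSE], c = cf[keep])
}

#' Evaluate a polynomial steady-state system
#'
#' @param sys an `"osmo_polysys"`.
#' @param s named (or species-ordered) numeric vector of concentrations.
#' @return Numeric vector of equation values (the fixed-surface
#'   concentration derivatives).
#' @export
poly_eval <- function(sys, s) {
  s <- align_state(sys, s)
  vapply(sys$eqs, function(e)
    sum(e$c * apply(t(s^t(e$E)), 1L, prod)), numeric(1))
}

#' Jacobian of a polynomial steady-state system
#'
#' @param sys an `"osmo_polysys"`.
#' @param s concentration vector.
#' @return The n x n Jacobian matrix evaluated at `s`.
#' @export
poly_jacobian <- function(sys, s) {
  s <- align_state(sys, s)
  n <- length(sys$species)
  J <- matrix(0, n, n, dimnames = list(sys$species, sys$species))
  for (i in seq_len(n)) {
    e <- sys$eqs[[i]]
    for (j in seq_len(n)) {
      ej <- e$E[, j]
      rows <- which(ej > 0L)
      if (!length(rows)) next
      val <- 0
      for (k in rows) {
        expo <- e$E[k, ]
        expo[j] <- expo[j] - 1L
        val <- val + e$c[k] * ej[k] * prod(s^expo)
      }
      J[i, j] <- val
    }
  }
  J
}

align_state <- function(sys, s) {
  if (!is.null(names(s))) {
    s <- s[sys$species]
    if (anyNA(s)) stop("state is missing species")
  }
  stopifnot(length(s) == length(sys$species))
  as.numeric(s)
}

# relative residual: |eq_i| / sum of |term| magnitudes
poly_relative_residual <- function(sys, s) {
  s <- align_state(sys, s)
  vapply(seq_along(sys$eqs), function(i) {
    e <- sys$eqs[[i]]
    terms <- e$c * apply(t(s^t(e$E)), 1L, prod)
    denom <- sum(abs(terms))
    if (denom < 1e-300) 0 else abs(sum(terms)) / denom
  }, numeric(1))
}

# substitute s = scale * u (per-variable scale vector): returns rescaled system
scale_polysys <- function(sys, scale) {
  stopifnot(length(scale) %in% c(1L, length(sys$species)), all(scale > 0))
  scale <- rep_len(scale, length(sys$species))
  out <- sys
  out$eqs <- lapply(sys$eqs, function(e) {
    fac <- apply(t(scale^t(e$E)), 1L, prod)
    cc <- e$c * fac
    m <- max(abs(cc))
    list(E = e$E, c = if (m > 0) cc / m else cc)
  })
  out$scale <- scale
  out
}
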