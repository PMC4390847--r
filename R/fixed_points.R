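# All-roots solving of the fixed-surface steady-state system, validity
# filtering, and quasi-stability classification.

# deterministic sequence of homotopy gamma angles; retried in order if any
# path fails to track
.gamma_angles <- c(0.82571, 2.11329, 4.00411, 5.55013)

#' Solve all isolated roots of a fixed-surface steady-state system
#'
#' Total-degree polynomial homotopy continuation: every combination of
#' roots of unity of the decoupled start system is path-tracked into the
#' target system with an adaptive predictor-corrector, and end points are
#' Newton-polished. Variables are internally rescaled by `C_eps` so the
#' tracked roots are O(1). Paths diverging to infinity account for the
#' deficit between the Bezout count and the number of finite roots.
#'
#' @param sys an `"osmo_polysys"` from [steady_state_system()].
#' @return Complex matrix (roots x species) of distinct finite roots, with
#'   attributes `path_failures` (paths that could not be tracked under any
#'   retry gamma) and `n_paths` (Bezout count).
#' @export
solve_all_fixed_points <- function(sys) {
  stopifnot(inherits(sys, "osmo_polysys"))
  n <- length(sys$species)
  scl <- rep(sys$C_eps, n)
  ssys <- scale_polysys(sys, scl)
  Elist <- lapply(ssys$eqs, `[[`, "E")
  clist <- lapply(ssys$eqs, `[[`, "c")
  roots <- NULL
  failures <- Inf
  for (ang in .gamma_angles) {
    res <- hc_track(Elist, clist, cos(ang), sin(ang))
    ok <- res$status == 0L
    got <- res$roots[ok, , drop = FALSE]
    roots <- if (is.null(roots)) got else rbind(roots, got)
    failures <- min(failures, sum(res$status == 2L))
    if (sum(res$status == 2L) == 0L) break
  }
  roots <- dedupe_roots(roots)
  # back to concentration scale
  roots <- sweep(roots, 2L, scl, `*`)
  colnames(roots) <- sys$species
  attr(roots, "path_failures") <- as.integer(failures)
  attr(roots, "n_paths") <- prod(sys$degrees)
  roots
}

dedupe_roots <- function(z, tol = 1e-8) {
  if (is.null(z) || nrow(z) == 0L)
    return(matrix(complex(0), 0L, if (is.null(z)) 0L else ncol(z)))
  keep <- rep(TRUE, nrow(z))
  for (i in seq_len(nrow(z))) {
    if (!keep[i]) next
    if (i < nrow(z)) {
      for (j in (i + 1L):nrow(z)) {
        if (!keep[j]) next
        d <- max(Mod(z[i, ] - z[j, ]))
        if (d < tol * (1 + max(Mod(z[i, ])))) keep[j] <- FALSE
      }
    }
  }
  z[keep, , drop = FALSE]
}

#' Filter steady-state roots down to physically valid fixed points
#'
#' Keeps roots that are real (imaginary parts below tolerance), have
#' non-negative concentrations, lead to a positive vesicle volume
#' (`sum(s) < C_eps`), and whose volume stays below a size cap (default:
#' the volume of a 2000-nm-diameter sphere, the upper end of the GUV
#' range).
#'
#' @param roots complex root matrix from [solve_all_fixed_points()].
#' @param sys the `"osmo_polysys"` the roots solve.
#' @param Omega_max volume validity cap (scaled volume).
#' @param real_tol per-coordinate imaginary-part tolerance, relative to
#'   `1 + |Re|`.
#' @param neg_tol tolerated negative-concentration undershoot (absolute, M).
#' @param res_tol maximum relative residual of the steady-state equations;
#'   near-roots of higher multiplicity on the singular `sum(s) = C_eps`
#'   manifold polish poorly and are rejected here (they have no finite
#'   volume in any case).
#' @return An `"osmo_fixedpoints"` data.frame: one row per valid fixed
#'   point (sorted by Omega), species concentration columns, `Omega`,
#'   `S_mu0`, `Phi`, and the relative residual of the steady-state system.
#' @export
filter_valid <- function(roots, sys,
                         Omega_max = omega_from_diameter(2000),
                         real_tol = 1e-8, neg_tol = 1e-14,
                         res_tol = 1e-10) {
  stopifnot(inherits(sys, "osmo_polysys"))
  sp <- sys$species
  out <- list()
  if (!is.null(roots) && nrow(roots) > 0L) {
    for (i in seq_len(nrow(roots))) {
      z <- roots[i, ]
      if (any(abs(Im(z)) > real_tol * (1 + abs(Re(z))))) next
      s <- Re(z)
      if (any(s < -neg_tol)) next
      s <- pmax(s, 0)
      tot <- sum(s)
      if (tot >= sys$C_eps) next
      Omega <- sys$B_T / (sys$C_eps - tot)
      if (Omega >= Omega_max) next
      out[[length(out) + 1L]] <- c(s, Omega = Omega)
    }
  }
  if (!length(out)) {
    df <- as.data.frame(matrix(numeric(0), 0L, length(sp) + 4L))
    names(df) <- c(sp, "Omega", "S_mu0", "Phi", "residual")
  } else {
    m <- do.call(rbind, out)
    df <- as.data.frame(m)
    names(df) <- c(sp, "Omega")
    df$S_mu0 <- sys$S_mu0
    df$Phi <- reduced_surface(df$Omega, sys$S_mu0)
    df$residual <- vapply(seq_len(nrow(df)), function(k)
      max(poly_relative_residual(sys, as.numeric(df[k, sp]))), numeric(1))
    df <- df[df$residual < res_tol, , drop = FALSE]
    df <- df[order(df$Omega), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("osmo_fixedpoints", "data.frame")
  attr(df, "species") <- sp
  df
}

#' Quasi-stability of a fixed-surface fixed point
#'
#' Eigenvalues of the Jacobian of the fixed-surface vesicle dynamics at a
#' fixed point: stable if every real part is below `-tol`, unstable if any
#' exceeds `+tol`, else marginal, with `tol` a small fraction of the
#' spectral radius. "Quasi" because surface variability is still excluded.
#'
#' With `dilution = TRUE` (the default) the Jacobian accounts for the
#' dilution term of the variable-volume dynamics, which at a fixed point
#' reduces exactly to the rank-one projection
#' `(I - s %*% t(1) / C_eps) %*% J`. This matters: large-volume steady
#' states sit close to the osmotic singular manifold `sum(s) = C_eps`
#' (their internal buffer concentration tends to zero), where the
#' unprojected Jacobian carries a large spurious positive eigenvalue along
#' the osmotic mode that the physical volume relaxation cancels. Without
#' the projection every such state — including genuinely attracting
#' large-vesicle states — would be labelled unstable. `dilution = FALSE`
#' gives the unprojected classification.
#'
#' @param sys an `"osmo_polysys"`.
#' @param s concentration vector of the fixed point.
#' @param tol_factor stability tolerance as a fraction of the spectral
#'   radius.
#' @param dilution include the dilution-term projection (default `TRUE`).
#' @return A list with `label` (`"stable"`, `"unstable"` or `"marginal"`)
#'   and `eigenvalues`.
#' @export
quasi_stability <- function(sys, s, tol_factor = 1e-9, dilution = TRUE) {
  s <- align_state(sys, s)
  J <- poly_jacobian(sys, s)
  if (dilution)
    J <- (diag(length(s)) - outer(s, rep(1, length(s))) / sys$C_eps) %*% J
  ev <- eigen(J, only.values = TRUE)$values
  tol <- tol_factor * max(Mod(ev), 1e-300)
  label <- if (all(Re(ev) < -tol)) "stable"
  else if (any(Re(ev) > tol)) "unstable"
  else "marginal"
  list(label = label, eigenvalues = ev)
}

#' Valid, classified fixed points of a vesicle reactor at fixed surface
#'
#' Convenience pipeline: build the steady-state polynomial system, solve
#' all roots by homotopy continuation, apply the validity filters, and
#' classify quasi-stability.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param S_mu0 imposed surface area (dm^2).
#' @param Omega_max validity volume cap (see [filter_valid()]).
#' @return An `"osmo_fixedpoints"` data.frame with an added `stability`
#'   column and attribute `path_failures`.
#' @export
fixed_points <- function(reactor, S_mu0,
                         Omega_max = omega_from_diameter(2000)) {
  sys <- steady_state_system(reactor, S_mu0)
  roots <- solve_all_fixed_points(sys)
  fp <- filter_valid(roots, sys, Omega_max = Omega_max)
  fp$stability <- if (nrow(fp)) vapply(seq_len(nrow(fp)), function(k)
    quasi_stability(sys, as.numeric(fp[k, sys$species]))$label,
    character(1)) else character(0)
  attr(fp, "path_failures") <- attr(roots, "path_failures")
  fp
}

# ---- closed-form reference solutions for the two bulk bistable models -------

#' Reservoir fixed points of the Schlogl model
#'
#' The Schlogl scheme `X + 2Y <-> 3Y`, `Y <-> Z` with reservoir species X
#' and Z pinned is one-dimensional; its steady states are the real positive
#' roots of the cubic `-k1r y^3 + k1 x y^2 - k2 y + k2r z = 0`, obtained
#' here from the companion matrix of the cubic (independently of the
#' homotopy code path).
#'
#' Note on the reverse trimolecular constant: with the bulk bistable regime
#' used throughout this package, only `k1r = 2.85e3` is consistent (via
#' Vieta's relations) with the known fixed points; it is the default in
#' [schlogl_network()] but remains an ordinary parameter.
#'
#' @param x,z pinned reservoir concentrations (M).
#' @param k1,k1r,k2,k2r rate constants.
#' @return Sorted numeric vector of up to 3 real positive roots.
#' @export
schlogl_reservoir_fixed_points <- function(x, z, k1, k1r, k2, k2r) {
  stopifnot(x > 0, z >= 0, k1 > 0, k1r > 0, k2 > 0, k2r >= 0)
  r <- polyroot(c(k2r * z, -k2, k1 * x, -k1r))
  re <- Re(r)[abs(Im(r)) < 1e-9 * (1 + abs(Re(r)))]
  sort(re[re > 0])
}

#' Reservoir fixed points of the Wilhelm model
#'
#' The four-reaction Wilhelm scheme with X pinned reduces at steady state
#' to `z = k2 y^2 / (k1 x)` and the quadratic
#' `(k3 k2 / (k1 x)) y^2 - k2 y + k4 = 0`, alongside the trivial state
#' (0, 0).
#'
#' @param x pinned reservoir concentration (M).
#' @param k1,k2,k3,k4 rate constants.
#' @return A data.frame with columns `y` and `z`, one row per fixed point
#'   (the origin first, then by increasing y). A negative discriminant
#'   leaves only the origin.
#' @export
wilhelm_reservoir_fixed_points <- function(x, k1, k2, k3, k4) {
  stopifnot(x > 0, k1 > 0, k2 > 0, k3 > 0, k4 > 0)
  A <- k3 * k2 / (k1 * x)
  disc <- k2^2 - 4 * A * k4
  y <- numeric(0)
  if (disc >= 0)
    y <- sort((k2 + c(-1, 1) * sqrt(disc)) / (2 * A))
  y <- y[y > 0]
  data.frame(y = c(0, y), z = c(0, k2 * y^2 / (k1 * x)))
}
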