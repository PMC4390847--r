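# Bifurcation curves through vesicle morphology space: sweep the imposed
# surface area, link fixed points into branches, and locate crossings of the
# spherical (Phi = 1) line, which are the steady states of the full
# variable-volume model.

#' Default surface-area sweep grid
#'
#' Log-spaced surface areas spanning equivalent-sphere diameters from the
#' SUV to the GUV range.
#'
#' @param d_min_nm,d_max_nm diameter range (nm).
#' @param n number of grid values.
#' @return Numeric vector of surface areas (dm^2), increasing.
#' @export
surface_grid <- function(d_min_nm = 50, d_max_nm = 2000, n = 200) {
  surface_from_diameter(exp(seq(log(d_min_nm), log(d_max_nm),
                                length.out = n)))
}

#' Sweep surface area and assemble the bifurcation curve
#'
#' For every surface value the fixed-surface steady-state system is solved
#' (all roots, homotopy continuation), filtered and classified; fixed
#' points at adjacent grid values are then linked into branches by
#' nearest-neighbour matching in `(log10 Omega, s / C_eps)` space under a
#' distance cap.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param S_grid increasing vector of surface areas (dm^2); default
#'   [surface_grid()].
#' @param Omega_max validity cap passed to [filter_valid()].
#' @param match_cap maximum linking distance per grid step.
#' @return An `"osmo_bifurcation"`: data.frame `points` (one row per fixed
#'   point with `S_mu0`, species concentrations, `Omega`, `Phi`,
#'   `stability`, `branch`), the grid, and the reactor.
#' @export
sweep_surface <- function(reactor, S_grid = surface_grid(),
                          Omega_max = omega_from_diameter(2000),
                          match_cap = 0.2) {
  stopifnot(all(diff(S_grid) > 0))
  sp <- reactor$network$species
  pts <- list()
  open <- list()   # open branches: list(id, coord)
  next_id <- 1L
  warned <- FALSE
  for (S in S_grid) {
    fp <- fixed_points(reactor, S, Omega_max = Omega_max)
    m <- nrow(fp)
    coords <- if (m) cbind(log10(fp$Omega),
                           as.matrix(fp[, sp, drop = FALSE]) / reactor$C_eps)
    else matrix(0, 0L, length(sp) + 1L)
    assigned <- integer(m)
    if (length(open) && m) {
      prev <- do.call(rbind, lapply(open, `[[`, "coord"))
      D <- as.matrix(stats::dist(rbind(prev, coords)))
      D <- D[seq_along(open), length(open) + seq_len(m), drop = FALSE]
      # greedy nearest-neighbour matching under the cap
      repeat {
        if (!length(D) || all(!is.finite(D)) || min(D) > match_cap) break
        ij <- arrayInd(which.min(D), dim(D))
        assigned[ij[2L]] <- open[[ij[1L]]]$id
        if (sum(D[ij[1L], ] <= match_cap) > 1L && !warned) {
          # more than one candidate within the cap: grid may be too coarse
          if (sum(sort(D[ij[1L], ])[2] <= match_cap, na.rm = TRUE)) {
            warning("branch matching ambiguity: multiple fixed points ",
                    "within the matching cap; consider a finer surface grid")
            warned <- TRUE
          }
        }
        D[ij[1L], ] <- Inf
        D[, ij[2L]] <- Inf
      }
    }
    newopen <- list()
    for (k in seq_len(m)) {
      if (assigned[k] == 0L) {
        assigned[k] <- next_id
        next_id <- next_id + 1L
      }
      newopen[[length(newopen) + 1L]] <- list(id = assigned[k],
                                              coord = coords[k, ])
    }
    open <- newopen
    if (m) {
      fp$branch <- assigned
      pts[[length(pts) + 1L]] <- as.data.frame(fp)
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else {
    df <- data.frame(matrix(numeric(0), 0L, length(sp) + 6L))
    names(df) <- c(sp, "Omega", "S_mu0", "Phi", "residual", "stability",
                   "branch")
    df
  }
  rownames(points) <- NULL
  structure(list(points = points, S_grid = S_grid, reactor = reactor,
                 Omega_max = Omega_max),
            class = "osmo_bifurcation")
}

#' @export
print.osmo_bifurcation <- function(x, ...) {
  cat("<osmo_bifurcation> ", length(x$S_grid), " surface values, ",
      nrow(x$points), " fixed points in ",
      length(unique(x$points$branch)), " branch(es)\n", sep = "")
  invisible(x)
}

#' Spherical (Phi = 1) crossings of a bifurcation curve
#'
#' Along each branch, sign changes of `S_mu0 - sphere_surface(Omega*)`
#' bracket surfaces at which the fixed point is exactly spherical — a
#' steady state of the full variable-volume model. Each bracket is refined
#' by bisection on the imposed surface, re-solving the steady-state system
#' locally, until `|Phi - 1| < tol`.
#'
#' @param curve an `"osmo_bifurcation"`.
#' @param tol refinement tolerance on `|Phi - 1|`.
#' @param max_iter bisection iteration cap.
#' @return Data.frame with one row per crossing: species concentrations,
#'   `Omega`, `S_mu`, `Phi`, `stability`, `branch`, sorted by `Omega`.
#'   Branches that touch the line at a grid edge are reported via the
#'   `"unresolved"` attribute.
#' @export
spherical_crossings <- function(curve, tol = 1e-6, max_iter = 80) {
  stopifnot(inherits(curve, "osmo_bifurcation"))
  reactor <- curve$reactor
  sp <- reactor$network$species
  pts <- curve$points
  out <- list()
  unresolved <- 0L
  for (b in unique(pts$branch)) {
    br <- pts[pts$branch == b, , drop = FALSE]
    br <- br[order(br$S_mu0), , drop = FALSE]
    f <- br$S_mu0 - surface_from_volume(br$Omega)
    # f and Phi - 1 share sign: Phi = S_mu0 / sphere_surface(Omega)
    if (nrow(br) < 2L) next
    sgn <- sign(f)
    for (k in seq_len(nrow(br) - 1L)) {
      if (sgn[k] == 0) { unresolved <- unresolved + 1L; next }
      if (sgn[k] * sgn[k + 1L] < 0) {
        cr <- refine_crossing(reactor, br[k, ], br[k + 1L, ], sp,
                              curve$Omega_max, tol, max_iter)
        if (!is.null(cr)) {
          cr$branch <- b
          out[[length(out) + 1L]] <- cr
        } else unresolved <- unresolved + 1L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    df <- data.frame(matrix(numeric(0), 0L, length(sp) + 5L))
    names(df) <- c(sp, "Omega", "S_mu", "Phi", "stability", "branch")
    df
  }
  if (nrow(res)) {
    res <- res[order(res$Omega), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "unresolved") <- unresolved
  res
}

# bisection on S_mu0 between two branch points straddling Phi = 1
refine_crossing <- function(reactor, p_lo, p_hi, sp, Omega_max, tol,
                            max_iter) {
  S_lo <- p_lo$S_mu0; S_hi <- p_hi$S_mu0
  ref_lo <- c(log10(p_lo$Omega), as.numeric(p_lo[sp]) / reactor$C_eps)
  ref_hi <- c(log10(p_hi$Omega), as.numeric(p_hi[sp]) / reactor$C_eps)
  f_lo <- p_lo$S_mu0 - surface_from_volume(p_lo$Omega)
  best <- NULL
  for (it in seq_len(max_iter)) {
    S_mid <- sqrt(S_lo * S_hi)
    fp <- fixed_points(reactor, S_mid, Omega_max = Omega_max)
    if (!nrow(fp)) return(best_or_null(best, tol))
    ref <- (ref_lo + ref_hi) / 2
    coords <- cbind(log10(fp$Omega),
                    as.matrix(fp[, sp, drop = FALSE]) / reactor$C_eps)
    d <- sqrt(rowSums(sweep(coords, 2L, ref, `-`)^2))
    k <- which.min(d)
    pt <- fp[k, , drop = FALSE]
    f_mid <- S_mid - surface_from_volume(pt$Omega)
    phi <- reduced_surface(pt$Omega, S_mid)
    best <- data.frame(pt[, sp, drop = FALSE], Omega = pt$Omega,
                       S_mu = S_mid, Phi = phi, stability = pt$stability)
    if (abs(phi - 1) < tol) return(best)
    if (sign(f_mid) == sign(f_lo)) {
      S_lo <- S_mid; ref_lo <- coords[k, ]; f_lo <- f_mid
    } else {
      S_hi <- S_mid; ref_hi <- coords[k, ]
    }
  }
  best_or_null(best, tol)
}

best_or_null <- function(best, tol) {
  if (!is.null(best) && abs(best$Phi - 1) < sqrt(tol)) best else NULL
}

#' Confirm the stability of a spherical steady state by integration
#'
#' Perturbs a spherical crossing along the osmotic mode — all molecule
#' numbers scaled by `1 +/- pert`, the volume following the isotonic
#' condition — integrates the full variable-volume model from both sides,
#' and checks the trajectory returns to the crossing volume. This probes
#' true full-model stability, for which the fixed-surface eigenvalues are
#' only a predictor.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param crossing one row of a [spherical_crossings()] result.
#' @param pert relative molecule-number perturbation.
#' @param t_max integration horizon (s).
#' @param d_tol relative tolerance on the terminal equivalent diameter.
#' @return `TRUE` if both perturbed trajectories return to the crossing.
#' @export
confirm_crossing_stability <- function(reactor, crossing, pert = 0.03,
                                       t_max = 2e5, d_tol = 0.01) {
  sp <- reactor$network$species
  sstar <- as.numeric(crossing[1, sp])
  names(sstar) <- sp
  d_star <- diameter_from_omega(crossing$Omega[1])
  for (f in c(1 - pert, 1 + pert)) {
    n0 <- sstar * crossing$Omega[1] * f
    Om0 <- (reactor$B_T + sum(n0)) / reactor$C_eps
    s0 <- n0 / Om0
    traj <- integrate_reactor(reactor, s0, c(0, t_max), n_out = 60)
    d_end <- tail(traj$diameter_nm, 1L)
    if (abs(d_end - d_star) > d_tol * d_star) return(FALSE)
  }
  TRUE
}

#' Classify the stability pattern of spherical steady states
#'
#' @param crossings output of [spherical_crossings()].
#' @return `"bistable"` if exactly three crossings ordered
#'   stable/unstable/stable by increasing volume, `"monostable"` for a
#'   single stable crossing, `"none"` for no crossing, otherwise
#'   `"other"`.
#' @export
classify_bistability <- function(crossings) {
  n <- nrow(crossings)
  if (n == 0L) return("none")
  st <- crossings$stability[order(crossings$Omega)]
  if (n == 3L && identical(st, c("stable", "unstable", "stable")))
    return("bistable")
  if (n == 1L && st == "stable") return("monostable")
  "other"
}
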