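# Monte-Carlo exploration of the vesicle reactor parameter space: wide-area
# and hot-spot sampling, fixed-point censuses, the morphology-space curve
# transformation, concentration rescaling, and the two-phase search for
# emergent bistability.

# evaluate expr under a given RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Uniform sampling ranges for reactor parameters
#'
#' Defaults are the wide-area ranges: forward rate constants in
#' `(0, 10)` (any order), reverse rates in `(0, k/10)`, permeability
#' multipliers in `(1/5, 50)`, external solute concentrations in
#' `(0, 0.2)` M, external buffer `0.2 M +/- 40%%`, trapped buffer count
#' `63064 +/- 40%%`. Pinned external concentrations are copied verbatim
#' into every draw and excluded from sampling; `sample_rates = FALSE`
#' pins the template network's rate constants.
#'
#' @param k_max upper bound for forward rate constants.
#' @param kr_frac reverse rates drawn in `(0, kr_frac * k)`.
#' @param Dx_range permeability multiplier range.
#' @param s_eps_range external solute concentration range (M).
#' @param b_eps_range external buffer concentration range (M).
#' @param B_T_range trapped buffer count range.
#' @param pinned_s_eps named numeric vector of pinned external
#'   concentrations (reservoir species).
#' @param sample_rates sample rate constants (`TRUE`) or keep the
#'   template's (`FALSE`).
#' @return An object of class `"osmo_ranges"`.
#' @export
sampling_ranges <- function(k_max = 10, kr_frac = 0.1,
                            Dx_range = c(1 / 5, 50),
                            s_eps_range = c(0, 0.2),
                            b_eps_range = 0.2 * c(0.6, 1.4),
                            B_T_range = 63064 * c(0.6, 1.4),
                            pinned_s_eps = numeric(0),
                            sample_rates = TRUE) {
  stopifnot(k_max > 0, kr_frac >= 0, all(Dx_range > 0), all(B_T_range > 0))
  structure(list(k_max = k_max, kr_frac = kr_frac, Dx_range = Dx_range,
                 s_eps_range = s_eps_range, b_eps_range = b_eps_range,
                 B_T_range = B_T_range, pinned_s_eps = pinned_s_eps,
                 sample_rates = sample_rates),
            class = "osmo_ranges")
}

#' Named sampling presets for the encapsulated Schlogl / Wilhelm censuses
#'
#' Ranges for sampling the fixed-surface vesicle embeddings of the bulk
#' bistable regimes: permeability multipliers in `(1/5, 50)`, intermediate
#' external concentrations in `(0, 0.002)` M, external buffer
#' `0.002 M +/- 40%%`, trapped buffer in `(2, 2000)`, reservoir species'
#' external concentrations pinned to the bulk regime (`x`, `z` for
#' Schlogl; `x` for Wilhelm, with the waste `W` sampled as an ordinary
#' diffusing species), and rate constants pinned to the bulk regimes.
#'
#' @param name `"schlogl_cs1"` or `"wilhelm_cs1"`.
#' @return A list with elements `network` (the template) and `ranges`.
#' @export
census_preset <- function(name = c("schlogl_cs1", "wilhelm_cs1")) {
  name <- match.arg(name)
  base <- function(pinned) sampling_ranges(
    Dx_range = c(1 / 5, 50), s_eps_range = c(0, 0.002),
    b_eps_range = 0.002 * c(0.6, 1.4), B_T_range = c(2, 2000),
    pinned_s_eps = pinned, sample_rates = FALSE)
  switch(name,
         schlogl_cs1 = list(
           network = schlogl_network(),
           ranges = base(c(X = unname(schlogl_reservoir()["x"]),
                           Z = unname(schlogl_reservoir()["z"])))),
         wilhelm_cs1 = list(
           network = wilhelm_network(),
           ranges = base(c(X = unname(wilhelm_reservoir()["x"])))))
}

# one uniform draw of reactor parameters for a template network
draw_reactor <- function(network, ranges) {
  sp <- network$species
  Dx <- setNames(runif(length(sp), ranges$Dx_range[1], ranges$Dx_range[2]),
                 sp)
  s_eps <- setNames(runif(length(sp), ranges$s_eps_range[1],
                          ranges$s_eps_range[2]), sp)
  pin <- ranges$pinned_s_eps
  s_eps[names(pin)] <- pin
  b_eps <- runif(1, ranges$b_eps_range[1], ranges$b_eps_range[2])
  B_T <- runif(1, ranges$B_T_range[1], ranges$B_T_range[2])
  net <- network
  if (ranges$sample_rates) {
    net$reactions <- lapply(network$reactions, function(r) {
      r$k <- runif(1, 0, ranges$k_max)
      while (r$k == 0) r$k <- runif(1, 0, ranges$k_max)
      if (r$kr > 0) r$kr <- runif(1, 0, ranges$kr_frac * r$k)
      r
    })
  }
  vesicle_reactor(net, vesicle_environment(b_eps, s_eps),
                  membrane_spec(Dx), B_T)
}

#' Wide-area Monte-Carlo sampling of reactor parameter sets
#'
#' @param network template `"osmo_network"` (its reversibility structure
#'   is kept; rate constants are resampled unless pinned by the ranges).
#' @param ranges an `"osmo_ranges"`.
#' @param n number of independent draws.
#' @param seed RNG seed (draws are reproducible given the seed).
#' @return List of `n` `"osmo_reactor"` objects.
#' @export
sample_wide <- function(network, ranges, n, seed = 1L) {
  stopifnot(inherits(ranges, "osmo_ranges"), n > 0)
  with_seed(seed, replicate(n, draw_reactor(network, ranges),
                            simplify = FALSE))
}

#' Hot-spot sampling around a basis parameter set
#'
#' Every free parameter of the basis reactor (rate constants, permeability
#' multipliers, unpinned external concentrations, external buffer, trapped
#' buffer count) is independently perturbed uniformly within
#' `+/- fraction` of its basis value.
#'
#' @param basis an `"osmo_reactor"`.
#' @param n number of perturbed sets.
#' @param fraction half-width of the relative perturbation (default 0.2).
#' @param seed RNG seed.
#' @param pinned_s_eps names of external concentrations to keep fixed.
#' @param perturb_rates also perturb rate constants (default `TRUE`).
#' @return List of `n` `"osmo_reactor"` objects.
#' @export
sample_hotspot <- function(basis, n, fraction = 0.2, seed = 1L,
                           pinned_s_eps = character(0),
                           perturb_rates = TRUE) {
  stopifnot(inherits(basis, "osmo_reactor"), fraction >= 0)
  jig <- function(v) v * runif(length(v), 1 - fraction, 1 + fraction)
  with_seed(seed, replicate(n, {
    net <- basis$network
    if (perturb_rates)
      net$reactions <- lapply(net$reactions, function(r) {
        r$k <- jig(r$k)
        if (r$kr > 0) r$kr <- jig(r$kr)
        r
      })
    s_eps <- basis$s_eps
    free <- setdiff(names(s_eps), pinned_s_eps)
    s_eps[free] <- jig(s_eps[free])
    vesicle_reactor(net, vesicle_environment(jig(basis$b_eps), s_eps),
                    membrane_spec(jig(basis$Dx),
                                  basis$membrane$D_ribose,
                                  basis$membrane$lambda),
                    jig(basis$B_T))
  }, simplify = FALSE))
}

#' Fixed-point census of sampled parameter sets
#'
#' Counts, for every sampled reactor, the valid fixed points of its
#' fixed-surface steady-state system, and aggregates the distribution of
#' counts. Sets on which path tracking failed are excluded from the
#' denominator and reported separately.
#'
#' @param reactors list of `"osmo_reactor"` objects.
#' @param S_mu0 imposed surface area (dm^2); default that of a
#'   400-nm-diameter sphere.
#' @param Omega_max validity cap (see [filter_valid()]).
#' @return An `"osmo_census"`: list with `counts` (per-set fixed point
#'   count, `NA` for solver failures), `table` (data.frame of count,
#'   n_sets, fraction over non-failed sets), `n`, `n_failed`.
#' @export
census <- function(reactors, S_mu0 = surface_from_diameter(400),
                   Omega_max = omega_from_diameter(2000)) {
  counts <- vapply(reactors, function(r) {
    fp <- tryCatch(fixed_points(r, S_mu0, Omega_max = Omega_max),
                   error = function(e) NULL)
    if (is.null(fp) ||
        (!is.null(attr(fp, "path_failures")) &&
         attr(fp, "path_failures") > 0L)) return(NA_integer_)
    nrow(fp)
  }, integer(1))
  ok <- !is.na(counts)
  lev <- 0:max(3L, counts[ok], 0L)
  tab <- data.frame(count = lev,
                    n_sets = vapply(lev, function(k) sum(counts[ok] == k),
                                    integer(1)))
  tab$fraction <- if (sum(ok)) tab$n_sets / sum(ok) else rep(NA_real_,
                                                             nrow(tab))
  structure(list(counts = counts, table = tab, n = length(reactors),
                 n_failed = sum(!ok), S_mu0 = S_mu0),
            class = "osmo_census")
}

#' @export
print.osmo_census <- function(x, ...) {
  cat("<osmo_census> ", x$n, " parameter sets (", x$n_failed,
      " solver failures)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Transform a reactor so its bifurcation curve moves in morphology space
#'
#' Scaling the diffusion constants by `a*c` and the trapped buffer count
#' by `b*c` leaves every `K_i = S_mu D_i / B_T` invariant when the surface
#' is rescaled by `b/a` and the volume by `b*c`; fixed-point
#' concentrations are unchanged while every morphology point maps as
#' `{Omega, S_mu} -> {Omega * b * c, S_mu * b / a}`.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param a,b,c positive scaling factors.
#' @return List with the transformed `reactor` and `morphology_map`, a
#'   function mapping `(Omega, S_mu)` of the original curve to their
#'   transformed positions.
#' @export
transform_curve <- function(reactor, a = 1, b = 1, c = 1) {
  stopifnot(a > 0, b > 0, c > 0)
  new <- reactor
  new$Dx <- reactor$Dx * a * c
  new$D <- reactor$D * a * c
  new$membrane <- membrane_spec(new$Dx, reactor$membrane$D_ribose,
                                reactor$membrane$lambda)
  new$B_T <- reactor$B_T * b * c
  list(reactor = new,
       morphology_map = function(Omega, S_mu)
         list(Omega = Omega * b * c, S_mu = S_mu * b / a))
}

#' Rescale a reactor to a different concentration range
#'
#' Divides all external concentrations and the trapped buffer count by
#' `n_factor` and absorbs the factor into the rate constants (first-order
#' unchanged, second-order multiplied by `n_factor`, third-order by
#' `n_factor^2`, reverse rates analogously by their own order). Fixed
#' points keep the same `{Omega, S_mu}` morphology and the same time
#' scale, with concentrations divided by `n_factor`.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param n_factor positive scale factor (e.g. 100 to go from molar to
#'   hundredth-molar regimes).
#' @return The rescaled `"osmo_reactor"`.
#' @export
rescale_concentrations <- function(reactor, n_factor) {
  stopifnot(n_factor > 0)
  net <- reactor$network
  net$reactions <- lapply(net$reactions, function(r) {
    r$k <- r$k * n_factor^(sum(r$reactants) - 1L)
    if (r$kr > 0) r$kr <- r$kr * n_factor^(sum(r$products) - 1L)
    r
  })
  vesicle_reactor(net,
                  vesicle_environment(reactor$b_eps / n_factor,
                                      reactor$s_eps / n_factor),
                  membrane_spec(reactor$Dx, reactor$membrane$D_ribose,
                                reactor$membrane$lambda),
                  reactor$B_T / n_factor)
}

#' Two-phase search for emergent bistability in the vesicle reactor
#'
#' Phase 1 samples `budget` wide-area parameter sets at a fixed imposed
#' surface and keeps those whose steady-state system has exactly three
#' valid fixed points (quasi-stable / unstable / quasi-stable by volume);
#' hot-spot sampling around the first hits amplifies the candidate pool.
#' Phase 2 computes each candidate's bifurcation curve once and steers it
#' with the exact morphology-space transformation over a log grid of
#' `(a, c)` scalings (the `b` factor is redundant given `a` and `c`) until
#' the curve crosses the spherical `Phi = 1` line three times in
#' stable/unstable/stable order inside the unilamellar size window; each
#' steering hit is then verified by re-solving the transformed reactor's
#' sweep and its spherical crossings.
#'
#' @param network template `"osmo_network"`.
#' @param ranges an `"osmo_ranges"` (wide-area defaults).
#' @param budget number of Phase-1 wide-area draws.
#' @param seed RNG seed controlling the whole pipeline.
#' @param S_mu0 Phase-1 surface area (default 400-nm-diameter sphere).
#' @param hotspot_n hot-spot draws per Phase-1 hit.
#' @param max_candidates stop after this many verified bistable regimes.
#' @param d_window unilamellar diameter window (nm) the three crossings
#'   must fall into.
#' @param sweep_n surface-grid resolution for the verification sweep.
#' @return An `"osmo_search"`: list with `candidates` (each a list with
#'   the transformed `reactor`, the Phase-1 `basis` reactor, the scaling
#'   `abc`, the verified `crossings` and `classification`) and
#'   `diagnostics` (draws tested, Phase-1 hits, steering attempts).
#' @export
find_bistable_regimes <- function(network, ranges = sampling_ranges(),
                                  budget = 2000, seed = 1L,
                                  S_mu0 = surface_from_diameter(400),
                                  hotspot_n = 200, max_candidates = 1L,
                                  d_window = c(50, 2000), sweep_n = 120) {
  diag <- list(budget = budget, phase1_hits = 0L, hotspot_hits = 0L,
               steering_attempts = 0L, verified = 0L)
  sets <- sample_wide(network, ranges, budget, seed = seed)
  hits <- list()
  for (r in sets) {
    fp <- tryCatch(fixed_points(r, S_mu0), error = function(e) NULL)
    if (!is.null(fp) && nrow(fp) == 3L)
      hits[[length(hits) + 1L]] <- r
  }
  diag$phase1_hits <- length(hits)
  candidates <- list()
  steer_pool <- function(pool) {
    for (basis in pool) {
      if (length(candidates) >= max_candidates) break
      res <- steer_to_viability(basis, d_window = d_window,
                                sweep_n = sweep_n)
      diag$steering_attempts <<- diag$steering_attempts + res$attempts
      if (!is.null(res$candidate)) {
        candidates[[length(candidates) + 1L]] <<- c(res$candidate,
                                                    list(basis = basis))
        diag$verified <<- diag$verified + 1L
      }
    }
  }
  steer_pool(hits)
  # hot-spot amplification around wide-area hits, only if steering the
  # wide hits themselves did not yield enough verified regimes
  if (length(candidates) < max_candidates && length(hits)) {
    for (j in seq_len(min(3L, length(hits)))) {
      if (length(candidates) >= max_candidates) break
      hs <- sample_hotspot(hits[[j]], hotspot_n, fraction = 0.2,
                           seed = seed + j,
                           pinned_s_eps = names(ranges$pinned_s_eps),
                           perturb_rates = ranges$sample_rates)
      amp <- list()
      for (r in hs) {
        fp <- tryCatch(fixed_points(r, S_mu0), error = function(e) NULL)
        if (!is.null(fp) && nrow(fp) == 3L) amp[[length(amp) + 1L]] <- r
      }
      diag$hotspot_hits <- diag$hotspot_hits + length(amp)
      steer_pool(amp)
    }
  }
  structure(list(candidates = candidates, diagnostics = diag,
                 seed = seed), class = "osmo_search")
}

#' @export
print.osmo_search <- function(x, ...) {
  cat("<osmo_search> ", length(x$candidates), " verified bistable ",
      "regime(s); diagnostics:\n", sep = "")
  str(x$diagnostics)
  invisible(x)
}

# Phase 2: steer a basis reactor's bifurcation curve into the viability
# window using the exact (a, c) transformation, then verify by re-solving.
#
# In log-log morphology space (equivalent-sphere diameters) the transform
# is a free translation of the curve: d_Omega scales by c^(1/3), d_S by
# a^(-1/2). The crossing pattern with the spherical line d_S = d_Omega
# therefore depends only on the diagonal offset
#   Delta = (1/2) log10 a + (1/3) log10 c
# (crossings occur where log10 d_S - log10 d_Omega = Delta on the original
# curve), while the remaining degree of freedom slides the crossings along
# the line. Delta is scanned finely for a stable/unstable/stable pattern
# and the crossings are then centred in the viability window.
steer_to_viability <- function(basis, d_window, sweep_n,
                               n_delta = 2000L, max_verify = 20L) {
  # volume cap far beyond the viability window: the transformation will
  # rescale branch volumes into it, so the basis curve must not be
  # truncated at the GUV cap (singular-plane artifacts live many orders of
  # magnitude higher still)
  cap <- omega_from_diameter(1e5)
  curve <- sweep_surface(basis, surface_grid(10, 20000, 140),
                         Omega_max = cap)
  pts <- curve$points
  attempts <- 0L
  if (!nrow(pts)) return(list(candidate = NULL, attempts = attempts))
  u <- log10(diameter_from_omega(pts$Omega))
  v <- log10(diameter_from_surface(pts$S_mu0))
  rng <- range(v - u)
  deltas <- seq(rng[1], rng[2], length.out = n_delta)
  scored <- list()
  for (Delta in deltas) {
    cr <- diagonal_crossings(pts, u, v, Delta)
    if (is.null(cr)) next
    if (!identical(cr$stability, c("stable", "unstable", "stable"))) next
    if (!all(cr$interior)) next   # fold-edge crossings rarely survive
    sep <- min(diff(cr$u))
    scored[[length(scored) + 1L]] <- list(Delta = Delta, u = cr$u,
                                          sep = sep)
  }
  if (!length(scored)) return(list(candidate = NULL, attempts = attempts))
  # only crossing triples whose log-size span fits inside the viability
  # window can be centred into it; among those prefer well-separated ones
  span_max <- diff(log10(d_window)) * 0.95
  spans <- vapply(scored, function(s) diff(range(s$u)), numeric(1))
  scored <- scored[spans <= span_max]
  if (!length(scored)) return(list(candidate = NULL, attempts = attempts))
  ord <- order(-vapply(scored, `[[`, numeric(1), "sep"))
  target_mid <- mean(log10(d_window))
  for (k in head(ord, max_verify)) {
    attempts <- attempts + 1L
    Delta <- scored[[k]]$Delta
    lc <- 3 * (target_mid - mean(scored[[k]]$u))
    la <- 2 * (Delta - lc / 3)
    d_tr <- 10^(scored[[k]]$u + lc / 3)
    if (any(d_tr < d_window[1]) || any(d_tr > d_window[2])) next
    a <- 10^la; cc <- 10^lc
    tr <- transform_curve(basis, a = a, b = 1, c = cc)
    ver <- tryCatch({
      vcurve <- sweep_surface(tr$reactor,
                              surface_grid(min(d_tr) * 0.4,
                                           max(d_tr) * 2.5, sweep_n),
                              Omega_max = cap)
      vcross <- spherical_crossings(vcurve)
      # only crossings inside the viability region count:
      # spherical states outside the unilamellar size window are not
      # viable vesicles and do not enter the classification
      inwin <- diameter_from_omega(vcross$Omega) >= d_window[1] &
        diameter_from_omega(vcross$Omega) <= d_window[2]
      vcross <- vcross[inwin, , drop = FALSE]
      list(crossings = vcross,
           classification = classify_bistability(vcross))
    }, error = function(e) NULL)
    if (!is.null(ver) && identical(ver$classification, "bistable"))
      return(list(candidate = list(reactor = tr$reactor,
                                   abc = c(a = a, b = 1, c = cc),
                                   crossings = ver$crossings,
                                   classification = ver$classification),
                  attempts = attempts))
  }
  list(candidate = NULL, attempts = attempts)
}

# crossings of the shifted diagonal v - u = Delta with the solved curve;
# returns data.frame (u at crossing, stability) ordered by u, or NULL
# unless there are exactly 3 unambiguous crossings
diagonal_crossings <- function(pts, u, v, Delta, edge_margin = 1L) {
  g <- v - u - Delta
  out_u <- numeric(0)
  out_st <- character(0)
  out_int <- logical(0)
  for (b in unique(pts$branch)) {
    idx <- which(pts$branch == b)
    idx <- idx[order(pts$S_mu0[idx])]
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      i1 <- idx[k]; i2 <- idx[k + 1L]
      if (g[i1] == 0 || g[i1] * g[i2] < 0) {
        w <- if (g[i1] == g[i2]) 0.5 else g[i1] / (g[i1] - g[i2])
        out_u <- c(out_u, (1 - w) * u[i1] + w * u[i2])
        out_st <- c(out_st,
                    if (identical(pts$stability[i1], pts$stability[i2]))
                      pts$stability[i1] else "marginal")
        out_int <- c(out_int, k > edge_margin &&
                       k < length(idx) - edge_margin)
      }
    }
  }
  if (length(out_u) != 3L) return(NULL)
  ord <- order(out_u)
  data.frame(u = out_u[ord], stability = out_st[ord],
             interior = out_int[ord])
}
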