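#' External environment of a vesicle reactor
#'
#' Holds the external buffer concentration `b_eps` and the per-species
#' external concentrations `s_eps`. The total external concentration
#' `C_eps = b_eps + sum(s_eps)` is derived and stored.
#'
#' @param b_eps external buffer concentration (M, >= 0).
#' @param s_eps named numeric vector of external solute concentrations (M);
#'   species absent from it default to 0 when the reactor is assembled.
#' @return An object of class `"osmo_environment"`.
#' @export
vesicle_environment <- function(b_eps, s_eps = numeric(0)) {
  stopifnot(is.numeric(b_eps), length(b_eps) == 1L, b_eps >= 0)
  if (length(s_eps)) {
    stopifnot(is.numeric(s_eps), !is.null(names(s_eps)), all(s_eps >= 0))
  }
  structure(list(b_eps = as.numeric(b_eps),
                 s_eps = s_eps,
                 C_eps = as.numeric(b_eps + sum(s_eps))),
            class = "osmo_environment")
}

#' Membrane permeability specification
#'
#' Per-species permeabilities are expressed as dimensionless multipliers
#' `Dx` of the reference permeability of ribose through an oleic acid
#' bilayer. A multiplier of 0 marks an impermeable species.
#'
#' @param Dx named numeric vector of permeability multipliers (>= 0).
#' @param D_ribose reference permeability (dm^2 s^-1 mol^-1).
#' @param lambda bilayer thickness (dm).
#' @return An object of class `"osmo_membrane"`.
#' @export
membrane_spec <- function(Dx, D_ribose = osmocell_constants$D_ribose,
                          lambda = osmocell_constants$lambda) {
  if (length(Dx)) stopifnot(is.numeric(Dx), !is.null(names(Dx)), all(Dx >= 0))
  stopifnot(D_ribose > 0, lambda > 0)
  structure(list(Dx = Dx, D_ribose = as.numeric(D_ribose),
                 lambda = as.numeric(lambda)),
            class = "osmo_membrane")
}

#' Species diffusion constant from its permeability multiplier
#'
#' `D_i = Dx_i * D_ribose / lambda`; the units follow the package's
#' dm-based convention so that `S_mu * D_i / Omega` has units of s^-1.
#'
#' @param Dx dimensionless multiplier (>= 0, 0 = impermeable).
#' @param membrane an `"osmo_membrane"` supplying `D_ribose` and `lambda`.
#' @return Numeric diffusion constant(s).
#' @export
diffusion_constant <- function(Dx, membrane = membrane_spec(numeric(0))) {
  stopifnot(all(Dx >= 0))
  Dx * membrane$D_ribose / membrane$lambda
}

#' Assemble a vesicle reactor
#'
#' Couples a reaction network to a membrane and environment, with `B_T`
#' impermeable non-reacting buffer molecules trapped inside. Species missing
#' from `s_eps`/`Dx` default to external concentration 0 / multiplier 0.
#'
#' @param network an `"osmo_network"`.
#' @param environment an `"osmo_environment"`.
#' @param membrane an `"osmo_membrane"`.
#' @param B_T trapped buffer molecule count (> 0, dimensionless).
#' @return An object of class `"osmo_reactor"`. Fields `s_eps` and `Dx` are
#'   aligned to the network species order; `D` holds the absolute diffusion
#'   constants.
#' @export
vesicle_reactor <- function(network, environment, membrane, B_T) {
  stopifnot(inherits(network, "osmo_network"),
            inherits(environment, "osmo_environment"),
            inherits(membrane, "osmo_membrane"))
  stopifnot(is.numeric(B_T), length(B_T) == 1L, B_T > 0)
  sp <- network$species
  s_eps <- setNames(numeric(length(sp)), sp)
  s_eps[names(environment$s_eps)[names(environment$s_eps) %in% sp]] <-
    environment$s_eps[names(environment$s_eps) %in% sp]
  extra <- setdiff(names(environment$s_eps), sp)
  if (length(extra))
    stop("external concentrations for unknown species: ",
         paste(extra, collapse = ", "))
  Dx <- setNames(numeric(length(sp)), sp)
  known <- intersect(names(membrane$Dx), sp)
  Dx[known] <- membrane$Dx[known]
  extraD <- setdiff(names(membrane$Dx), sp)
  if (length(extraD))
    stop("permeability multipliers for unknown species: ",
         paste(extraD, collapse = ", "))
  C_eps <- environment$b_eps + sum(s_eps)
  structure(list(network = network,
                 b_eps = environment$b_eps,
                 s_eps = s_eps,
                 C_eps = C_eps,
                 Dx = Dx,
                 D = diffusion_constant(Dx, membrane),
                 membrane = membrane,
                 B_T = as.numeric(B_T)),
            class = "osmo_reactor")
}

#' @export
print.osmo_reactor <- function(x, ...) {
  cat("<osmo_reactor> B_T =", format(x$B_T), " b_eps =", format(x$b_eps),
      "M  C_eps =", format(x$C_eps), "M\n")
  print(x$network)
  df <- data.frame(species = x$network$species, s_eps = x$s_eps, Dx = x$Dx)
  print(df, row.names = FALSE)
  invisible(x)
}

#' CSTR specification
#'
#' @param s_feed named numeric vector of feed concentrations (M).
#' @param theta mean residence time (s, > 0); equivalently the reactor
#'   volume divided by the feed flow rate.
#' @return An object of class `"osmo_cstr"`.
#' @export
cstr_spec <- function(s_feed, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  if (length(s_feed)) stopifnot(!is.null(names(s_feed)), all(s_feed >= 0))
  structure(list(s_feed = s_feed, theta = as.numeric(theta)),
            class = "osmo_cstr")
}

# ---- osmotic / geometric constraint functions --------------------------------

#' Vesicle volume from internal concentrations (isotonic condition)
#'
#' Under instantaneous osmotic water flow the scaled volume is
#' `Omega = B_T / (C_eps - sum(s))`; the implied internal buffer
#' concentration `b = B_T / Omega` then satisfies `b + sum(s) = C_eps`
#' identically.
#'
#' @param B_T trapped buffer count.
#' @param C_eps total external concentration (M).
#' @param s named numeric vector of internal concentrations (M); may be
#'   empty.
#' @return Scaled volume Omega (dimensionless, = N_A x liter volume).
#' @export
volume_from_concentrations <- function(B_T, C_eps, s = numeric(0)) {
  tot <- sum(s)
  if (tot >= C_eps)
    stop("osmotic blow-up: total internal solute concentration (", tot,
         ") >= total external concentration (", C_eps, ")")
  B_T / (C_eps - tot)
}

#' Sphere surface area for a scaled volume
#'
#' Exact sphere geometry: the surface (dm^2) wrapping liter volume
#' `Omega / N_A` (taken as dm^3) as a sphere, `S = (36 pi V^2)^(1/3)`.
#' The model's always-spherical membrane kinetics slave the surface to the
#' volume through this map.
#'
#' @param Omega scaled volume (> 0).
#' @return Surface area in dm^2.
#' @export
surface_from_volume <- function(Omega) {
  stopifnot(all(Omega > 0))
  (36 * pi * (Omega / osmocell_constants$N_A)^2)^(1 / 3)
}

#' Reduced surface
#'
#' `Phi = S_mu / (36 pi (Omega/N_A)^2)^(1/3)`: the ratio of the membrane
#' surface to the sphere surface for the same volume. `Phi = 1` is a
#' spherical vesicle, `Phi < 1` osmotic tension (bursting near
#' `Phi ~ 0.9`), `Phi > 1` a deflated vesicle with surplus surface.
#'
#' @param Omega scaled volume (> 0).
#' @param S_mu surface area (dm^2, > 0).
#' @return Dimensionless Phi.
#' @export
reduced_surface <- function(Omega, S_mu) {
  stopifnot(all(Omega > 0), all(S_mu > 0))
  S_mu / surface_from_volume(Omega)
}

#' Morphology region label for a reduced surface value
#'
#' @param phi reduced surface.
#' @param phi_burst burst threshold (default 0.9).
#' @return `"burst"` (phi < phi_burst), `"tense"` (phi_burst <= phi < 1),
#'   `"spherical"` (phi == 1 within 1e-9), or `"deflated"`.
#' @export
morphology_region <- function(phi, phi_burst = osmocell_constants$phi_burst) {
  out <- character(length(phi))
  out[phi < phi_burst] <- "burst"
  out[phi >= phi_burst & phi < 1 - 1e-9] <- "tense"
  out[abs(phi - 1) <= 1e-9] <- "spherical"
  out[phi > 1 + 1e-9] <- "deflated"
  out
}

# sphere geometry helpers: diameters in nm <-> Omega / S_mu in package units
# (1 nm = 1e-8 dm)

#' Convert between equivalent-sphere diameters and morphology coordinates
#'
#' Morphology-space axes express a vesicle volume Omega (or surface S_mu) as
#' the nm diameter of the sphere having that volume (or surface).
#'
#' @param d_nm sphere diameter in nm.
#' @param Omega scaled volume.
#' @param S_mu surface area (dm^2).
#' @return The requested quantity.
#' @name sphere-geometry
NULL

#' @rdname sphere-geometry
#' @export
omega_from_diameter <- function(d_nm) {
  d <- d_nm * 1e-8                      # dm
  osmocell_constants$N_A * pi * d^3 / 6
}

#' @rdname sphere-geometry
#' @export
diameter_from_omega <- function(Omega) {
  V <- Omega / osmocell_constants$N_A
  (6 * V / pi)^(1 / 3) / 1e-8
}

#' @rdname sphere-geometry
#' @export
surface_from_diameter <- function(d_nm) {
  pi * (d_nm * 1e-8)^2
}

#' @rdname sphere-geometry
#' @export
diameter_from_surface <- function(S_mu) {
  sqrt(S_mu / pi) / 1e-8
}

#' A point in vesicle morphology space
#'
#' @param Omega scaled volume (> 0).
#' @param S_mu surface area (dm^2, > 0).
#' @return A one-row data.frame with columns `Omega`, `S_mu`, `Phi`,
#'   `d_Omega_nm`, `d_S_nm` (the equivalent-sphere diameters of volume and
#'   surface, matching the morphology-space axis convention).
#' @export
morphology_point <- function(Omega, S_mu) {
  data.frame(Omega = Omega, S_mu = S_mu,
             Phi = reduced_surface(Omega, S_mu),
             d_Omega_nm = diameter_from_omega(Omega),
             d_S_nm = diameter_from_surface(S_mu))
}

# ---- reactor right-hand sides ------------------------------------------------

#' CSTR concentration derivatives
#'
#' `ds_i/dt = r_i(s) + (1/theta) (s_feed_i - s_i)`.
#'
#' @param network an `"osmo_network"`.
#' @param cstr an `"osmo_cstr"`; feed species absent from it default to 0.
#' @param s named concentration vector (M).
#' @return Named derivative vector (M/s).
#' @export
rhs_cstr <- function(network, cstr, s) {
  stopifnot(inherits(cstr, "osmo_cstr"))
  sp <- network$species
  sf <- setNames(numeric(length(sp)), sp)
  known <- intersect(names(cstr$s_feed), sp)
  sf[known] <- cstr$s_feed[known]
  mak_rates(network, s) + (sf - s[sp]) / cstr$theta
}

#' Reservoir-condition concentration derivatives
#'
#' Pinned (reservoir) species are held at their given concentrations with
#' zero derivative; intermediate species follow pure mass-action kinetics.
#'
#' @param network an `"osmo_network"`.
#' @param pinned named numeric vector of reservoir species concentrations.
#' @param s named concentrations of the intermediate species.
#' @return Named derivative vector over all species (pinned entries 0).
#' @export
rhs_reservoir <- function(network, pinned, s) {
  if (length(intersect(names(pinned), names(s))))
    stop("pinned species must be disjoint from intermediates")
  full <- c(s, pinned)[network$species]
  r <- mak_rates(network, full)
  r[names(pinned)] <- 0
  r
}

#' High-buffer vesicle concentration derivatives
#'
#' The limit of a large external buffer: volume is pinned at `Omega0` and
#' the surface at `S_mu0`, giving
#' `ds_i/dt = r_i(s) + (S_mu0 D_i / Omega0) (s_eps_i - s_i)`.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param Omega0 constant scaled volume (> 0).
#' @param S_mu0 constant surface area (dm^2, > 0).
#' @param s named concentration vector.
#' @return Named derivative vector (M/s).
#' @export
rhs_vesicle_highbuffer <- function(reactor, Omega0, S_mu0, s) {
  stopifnot(Omega0 > 0, S_mu0 > 0)
  sp <- reactor$network$species
  s <- s[sp]
  mak_rates(reactor$network, s) +
    (S_mu0 / Omega0) * reactor$D * (reactor$s_eps - s)
}

#' Full variable-volume vesicle concentration derivatives
#'
#' The surface is slaved to the osmotically determined volume, and a
#' dilution term accounts for the changing solvent volume. With
#' `g_i = r_i(s) + S_mu D_i / B_T (C_eps - sum(s)) (s_eps_i - s_i)` the
#' derivative is `ds_i/dt = g_i - (s_i / C_eps) sum_j g_j`; the subtracted
#' term is exactly the dilution term `-(s_i/Omega) dOmega/dt` after the
#' isotonic volume relation is substituted.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param s named concentration vector with `sum(s) < C_eps`.
#' @param diagnostics if `TRUE`, attach `Omega`, `S_mu`, `Phi` and the
#'   per-species dilution term as attributes.
#' @return Named derivative vector (M/s).
#' @export
rhs_vesicle_full <- function(reactor, s, diagnostics = FALSE) {
  sp <- reactor$network$species
  s <- s[sp]
  Omega <- volume_from_concentrations(reactor$B_T, reactor$C_eps, s)
  S_mu <- surface_from_volume(Omega)
  g <- mak_rates(reactor$network, s) +
    (S_mu / reactor$B_T) * reactor$D * (reactor$C_eps - sum(s)) *
      (reactor$s_eps - s)
  dil <- -(s / reactor$C_eps) * sum(g)
  ds <- g + dil
  if (diagnostics) {
    attr(ds, "Omega") <- Omega
    attr(ds, "S_mu") <- S_mu
    attr(ds, "Phi") <- 1
    attr(ds, "dilution") <- dil
  }
  ds
}

#' CSTR-equivalent mean residence time of a high-buffer vesicle
#'
#' When every species shares one diffusion constant `D` and external
#' concentrations play the role of feed concentrations, the high-buffer
#' vesicle reduces exactly to a CSTR with
#' `theta = B_T / (S_mu0 * D * b_eps)`.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param S_mu0 constant surface area (dm^2).
#' @param D shared diffusion constant.
#' @return Residence time theta (s).
#' @export
residence_time_equivalent <- function(reactor, S_mu0, D) {
  stopifnot(S_mu0 > 0, D > 0, reactor$b_eps > 0)
  reactor$B_T / (S_mu0 * D * reactor$b_eps)
}
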