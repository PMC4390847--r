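# Time integration of the variable-volume vesicle reactor, including the
# simulated-syringe injection protocol, and the molecule-number formulation
# that serves as an independent dual of the concentration ODEs.

#' A syringe injection event
#'
#' Molecules of one species are released into the vesicle water pool at a
#' constant rate over a time window.
#'
#' @param species species name.
#' @param rate injection rate (molecules per second, >= 0).
#' @param start start time (s).
#' @param duration window length (s, > 0).
#' @return An object of class `"osmo_injection"`.
#' @export
injection_event <- function(species, rate, start, duration) {
  stopifnot(is.character(species), length(species) == 1L,
            rate >= 0, duration > 0, start >= 0)
  structure(list(species = species, rate = as.numeric(rate),
                 start = as.numeric(start), duration = as.numeric(duration)),
            class = "osmo_injection")
}

#' Molecule-number derivatives of the vesicle reactor
#'
#' Mass balance in molecule-number space:
#' `dn_i/dt = Omega r_i(s) + S_mu D_i (s_eps_i - s_i) [+ injection rate]`,
#' with the volume recovered exactly from the isotonic condition as
#' `Omega = (B_T + sum(n)) / C_eps` and `s = n / Omega`. No dilution term
#' is needed in this formulation, which makes it an independent check on
#' the concentration-space derivatives.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param n named molecule-number vector (>= 0).
#' @param injections list of [injection_event()]s.
#' @param time current time (s), used to gate injections.
#' @return Named vector of number derivatives (molecules/s).
#' @export
number_space_rhs <- function(reactor, n, injections = list(), time = 0) {
  sp <- reactor$network$species
  n <- n[sp]
  Omega <- (reactor$B_T + sum(n)) / reactor$C_eps
  s <- n / Omega
  S_mu <- surface_from_volume(Omega)
  dn <- Omega * mak_rates(reactor$network, s) +
    S_mu * reactor$D * (reactor$s_eps - s)
  for (inj in injections) {
    if (time >= inj$start && time < inj$start + inj$duration)
      dn[inj$species] <- dn[inj$species] + inj$rate
  }
  dn
}

#' Integrate the full variable-volume vesicle reactor
#'
#' Stiff adaptive integration (lsoda) of the full model. Without
#' injections the concentration ODEs (with dilution term) are integrated
#' directly; with injections the system is integrated in molecule-number
#' space — where an injection is an exact `+rate` on one number
#' derivative — and converted back to concentrations, so no time-dependent
#' dilution correction is ever needed. Integration is segmented at
#' injection window boundaries.
#'
#' @param reactor an `"osmo_reactor"`.
#' @param s0 named initial concentrations (M) with `sum(s0) < C_eps`.
#' @param t_span numeric length-2, start and end time (s).
#' @param injections list of [injection_event()]s.
#' @param rtol,atol relative / absolute integration tolerances.
#' @param n_out number of output samples.
#' @param space `"auto"` (number space iff injections present),
#'   `"concentration"` or `"number"`.
#' @return An `"osmo_trajectory"`: list with `time`, concentration matrix
#'   `conc`, molecule-number matrix `n`, `Omega`, `S_mu`, `diameter_nm`,
#'   and the injection `events`.
#' @export
integrate_reactor <- function(reactor, s0, t_span, injections = list(),
                              rtol = 1e-8, atol = 1e-12, n_out = 400,
                              space = c("auto", "concentration", "number")) {
  space <- match.arg(space)
  sp <- reactor$network$species
  s0 <- s0[sp]
  if (anyNA(s0)) stop("initial state missing species")
  if (sum(s0) >= reactor$C_eps)
    stop("osmotic blow-up in initial state: sum(s0) >= C_eps")
  if (inherits(injections, "osmo_injection")) injections <- list(injections)
  use_numbers <- switch(space,
                        auto = length(injections) > 0L,
                        concentration = FALSE,
                        number = TRUE)
  if (space == "concentration" && length(injections))
    stop("injections require number-space integration")
  t0 <- t_span[1]; t1 <- t_span[2]
  stopifnot(t1 > t0)
  bounds <- sort(unique(c(t0, t1, unlist(lapply(injections, function(e)
    c(e$start, e$start + e$duration))))))
  bounds <- bounds[bounds >= t0 & bounds <= t1]
  times <- sort(unique(c(seq(t0, t1, length.out = n_out), bounds)))

  if (use_numbers) {
    Omega0 <- volume_from_concentrations(reactor$B_T, reactor$C_eps, s0)
    y0 <- s0 * Omega0
    deriv <- function(t, y, parms) {
      y <- pmax(y, 0)
      names(y) <- sp
      list(as.numeric(number_space_rhs(reactor, y, injections, t)))
    }
  } else {
    y0 <- s0
    deriv <- function(t, y, parms) {
      names(y) <- sp
      tot <- sum(pmax(y, 0))
      if (tot >= reactor$C_eps)
        stop("osmotic blow-up during integration: sum(s) >= C_eps")
      list(as.numeric(rhs_vesicle_full(reactor, pmax(y, 0))))
    }
  }
  # segment at injection boundaries so lsoda never steps across a
  # discontinuous rate
  segs <- if (length(bounds) > 2L) bounds else c(t0, t1)
  out <- NULL
  ycur <- y0
  for (k in seq_len(length(segs) - 1L)) {
    tt <- times[times >= segs[k] & times <= segs[k + 1L]]
    tt <- sort(unique(c(segs[k], tt, segs[k + 1L])))
    seg <- deSolve::lsoda(y = ycur, times = tt, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    ycur <- as.numeric(seg[nrow(seg), -1L])
    out <- if (is.null(out)) seg else rbind(out, seg[-1L, , drop = FALSE])
  }
  yy <- out[, -1L, drop = FALSE]
  if (min(yy) < -1000 * atol)
    stop("negative state beyond tolerance during integration: ", min(yy))
  yy <- pmax(yy, 0)
  tgrid <- out[, 1L]
  if (use_numbers) {
    nmat <- yy
    Omega <- (reactor$B_T + rowSums(nmat)) / reactor$C_eps
    conc <- nmat / Omega
  } else {
    conc <- yy
    Omega <- reactor$B_T / (reactor$C_eps - rowSums(conc))
    nmat <- conc * Omega
  }
  colnames(conc) <- colnames(nmat) <- sp
  S_mu <- surface_from_volume(Omega)
  structure(list(time = tgrid, conc = conc, n = nmat, Omega = Omega,
                 S_mu = S_mu, diameter_nm = diameter_from_omega(Omega),
                 events = injections, reactor = reactor),
            class = "osmo_trajectory")
}

#' @export
print.osmo_trajectory <- function(x, ...) {
  cat("<osmo_trajectory> ", length(x$time), " samples over [",
      format(min(x$time)), ", ", format(max(x$time)), "] s; species: ",
      paste(colnames(x$conc), collapse = ", "), "\n", sep = "")
  cat("  final diameter ", format(tail(x$diameter_nm, 1L)), " nm\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.osmo_trajectory <- function(x, ...) {
  df <- data.frame(time = x$time)
  for (sp in colnames(x$conc)) df[[paste0("s_", sp)]] <- x$conc[, sp]
  for (sp in colnames(x$n)) df[[paste0("n_", sp)]] <- x$n[, sp]
  df$Omega <- x$Omega
  df$S_mu <- x$S_mu
  df$Phi <- 1
  df$diameter_nm <- x$diameter_nm
  df
}

#' Detect convergence of a trajectory to steady state
#'
#' Converged when the maximum relative concentration change over the
#' trailing `window` seconds of the trajectory is below `tol`.
#'
#' @param trajectory an `"osmo_trajectory"`.
#' @param window trailing window length (s); must be shorter than the
#'   trajectory.
#' @param tol relative-change tolerance.
#' @return A list with `converged` (logical) and `state` (the terminal
#'   concentrations).
#' @export
detect_steady_state <- function(trajectory, window, tol = 1e-6) {
  tt <- trajectory$time
  if (window >= diff(range(tt)))
    stop("window must be shorter than the trajectory")
  idx <- tt >= (max(tt) - window)
  seg <- trajectory$conc[idx, , drop = FALSE]
  fin <- seg[nrow(seg), ]
  scale <- pmax(abs(fin), 1e-12)
  rel <- max(abs(sweep(seg, 2L, fin, `-`)) / rep(scale, each = nrow(seg)))
  list(converged = rel < tol, state = fin)
}
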