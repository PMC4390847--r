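# Osmotic coupling response curves: how the steady-state particle number of
# one chemically-independent reaction set responds to the extra buffer
# contributed by another set sharing the vesicle, and the cyclic-condition
# crossings that are the joint system's fixed points.

#' Steady-state particle-number response of a reaction set to extra buffer
#'
#' For a single chemically-independent sub-network at a fixed imposed
#' surface, sweeps the number `B_extra` of additional effectively-inert
#' buffer molecules (supplied by the other reaction set) and returns the
#' total molecule number `B_own = Omega* sum(s*)` the sub-network itself
#' holds at steady state. The steady state is solved numerically from the
#' sub-network's fixed-surface system with trapped buffer `B_T + B_extra`.
#'
#' @param reactor an `"osmo_reactor"` containing only the sub-network's
#'   species (the full external environment is retained through `C_eps`).
#' @param S_mu0 imposed surface area (dm^2).
#' @param B_extra_grid numeric vector of extra buffer counts (>= 0).
#' @param Omega_max validity cap for the steady states.
#' @return Data.frame with columns `B_extra`, `B_own`, `Omega`, `branch_n`
#'   (number of valid steady states found; rows are repeated per steady
#'   state when several coexist). Grid values with no valid steady state
#'   are recorded with `NA` in `B_own`.
#' @export
coupling_response_curve <- function(reactor, S_mu0, B_extra_grid,
                                    Omega_max = omega_from_diameter(5000)) {
  stopifnot(all(B_extra_grid >= 0))
  sp <- reactor$network$species
  rows <- list()
  for (B2 in B_extra_grid) {
    r2 <- reactor
    r2$B_T <- reactor$B_T + B2
    fp <- fixed_points(r2, S_mu0, Omega_max = Omega_max)
    if (!nrow(fp)) {
      rows[[length(rows) + 1L]] <- data.frame(B_extra = B2, B_own = NA_real_,
                                              Omega = NA_real_, branch_n = 0L)
    } else {
      for (k in seq_len(nrow(fp))) {
        s <- as.numeric(fp[k, sp])
        rows[[length(rows) + 1L]] <- data.frame(
          B_extra = B2, B_own = fp$Omega[k] * sum(s),
          Omega = fp$Omega[k], branch_n = nrow(fp))
      }
    }
  }
  do.call(rbind, rows)
}

#' Cyclic-condition crossings of two coupling response curves
#'
#' The joint two-reaction-set system is at steady state when
#' `B1 = f_R1(B2)` and `B2 = f_R2(B1)` hold simultaneously. Crossings are
#' located by segment-pair intersection of the two sampled curves, each
#' treated as a polyline in the `(B1, B2)` plane.
#'
#' @param curve1 response curve of set 1: `B_own = f_R1(B_extra)`, plotted
#'   as `(B1 = B_own, B2 = B_extra)`.
#' @param curve2 response curve of set 2: `(B1 = B_extra, B2 = B_own)`.
#' @return Data.frame with columns `B1`, `B2`, one row per intersection.
#' @export
cyclic_condition_crossings <- function(curve1, curve2) {
  c1 <- curve1[!is.na(curve1$B_own), , drop = FALSE]
  c2 <- curve2[!is.na(curve2$B_own), , drop = FALSE]
  p1 <- cbind(c1$B_own, c1$B_extra)   # (B1, B2)
  p2 <- cbind(c2$B_extra, c2$B_own)   # (B1, B2)
  out <- list()
  if (nrow(p1) >= 2L && nrow(p2) >= 2L) {
    for (i in seq_len(nrow(p1) - 1L)) {
      for (j in seq_len(nrow(p2) - 1L)) {
        hit <- segment_intersection(p1[i, ], p1[i + 1L, ],
                                    p2[j, ], p2[j + 1L, ])
        if (!is.null(hit))
          out[[length(out) + 1L]] <- data.frame(B1 = hit[1], B2 = hit[2])
      }
    }
  }
  if (!length(out)) return(data.frame(B1 = numeric(0), B2 = numeric(0)))
  res <- do.call(rbind, out)
  # merge near-duplicate intersections from adjacent segment pairs
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i < nrow(res))
      for (j in (i + 1L):nrow(res)) {
        if (keep[j] &&
            max(abs(res[i, ] - res[j, ])) <
              1e-6 * (1 + max(abs(res[i, ])))) keep[j] <- FALSE
      }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# intersection point of segments a1-a2 and b1-b2, or NULL
segment_intersection <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1
  d2 <- b2 - b1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-300) return(NULL)
  t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
  u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
  eps <- 1e-12
  if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) return(NULL)
  a1 + t * d1
}
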