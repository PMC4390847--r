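# Built-in reaction schemes: the two bulk-bistable reference models and the
# simple sequences / unimolecular pairs studied for emergent bistability.

#' Schlogl reaction network
#'
#' `X + 2Y <-> 3Y; Y <-> Z` — the simplest mass-action scheme that is
#' bistable under reservoir conditions. Defaults are the bulk bistable
#' regime used throughout the package (concentrations molar). The reverse
#' trimolecular constant defaults to `2.85e3` M^-2 s^-1, the value
#' consistent with the regime's known fixed points (see
#' [schlogl_reservoir_fixed_points()]).
#'
#' @param k1,k1r,k2,k2r rate constants.
#' @return An `"osmo_network"` over species X, Y, Z.
#' @export
schlogl_network <- function(k1 = 5.25e4, k1r = 2.85e3,
                            k2 = 9.15e-2, k2r = 7.15e-3) {
  reaction_network(list(
    reaction(c(X = 1, Y = 2), c(Y = 3), k = k1, kr = k1r),
    reaction(c(Y = 1), c(Z = 1), k = k2, kr = k2r)
  ), species = c("X", "Y", "Z"))
}

#' Bulk reservoir regime of the Schlogl model
#'
#' The pinned reservoir concentrations of the bistable bulk regime.
#' @return Named vector `c(x = 6.47e-4, z = 6.32e-4)` (M).
#' @export
schlogl_reservoir <- function() c(x = 6.47e-4, z = 6.32e-4)

#' Wilhelm reaction network
#'
#' Four irreversible reactions `X + Z -> 2Y; 2Y -> Y + Z; Y + Z -> Z + W;
#' Y -> W`, the smallest bistable scheme built from at most bimolecular
#' irreversible steps. Defaults are the bulk bistable regime.
#'
#' @param k1,k2,k3,k4 rate constants.
#' @return An `"osmo_network"` over species X, Y, Z, W.
#' @export
wilhelm_network <- function(k1 = 5.86e2, k2 = 9.26e2,
                            k3 = 5.75e2, k4 = 9.98e-2) {
  reaction_network(list(
    reaction(c(X = 1, Z = 1), c(Y = 2), k = k1),
    reaction(c(Y = 2), c(Y = 1, Z = 1), k = k2),
    reaction(c(Y = 1, Z = 1), c(Z = 1, W = 1), k = k3),
    reaction(c(Y = 1), c(W = 1), k = k4)
  ), species = c("X", "Y", "Z", "W"))
}

#' Bulk reservoir regime of the Wilhelm model
#' @return Named vector `c(x = 1.17e-3)` (M); W is treated as free waste.
#' @export
wilhelm_reservoir <- function() c(x = 1.17e-3)

#' Two-step reaction sequences showing emergent vesicle bistability
#'
#' The irreversible sequences `2X -> Z; Z -> 2Y` (`seq_2X_Z_2Y`) and
#' `X -> 2Z; 2Z -> Y` (`seq_X_2Z_Y`), and the chemically-independent
#' unimolecular pair `X -> Y; P -> Q` (`pair_unimolecular`) plus the
#' `X -> 2Y; 2P -> Q` variant (`pair_mixed`). None of these is bistable in
#' reservoir or CSTR conditions; inside the variable-volume vesicle they
#' can be.
#'
#' @param k1,k2,c1 rate constants.
#' @return An `"osmo_network"`.
#' @name emergent-schemes
NULL

#' @rdname emergent-schemes
#' @export
seq_2X_Z_2Y <- function(k1 = 1, k2 = 1) {
  reaction_network(list(
    reaction(c(X = 2), c(Z = 1), k = k1),
    reaction(c(Z = 1), c(Y = 2), k = k2)
  ), species = c("X", "Z", "Y"))
}

#' @rdname emergent-schemes
#' @export
seq_X_2Z_Y <- function(k1 = 1, k2 = 1) {
  reaction_network(list(
    reaction(c(X = 1), c(Z = 2), k = k1),
    reaction(c(Z = 2), c(Y = 1), k = k2)
  ), species = c("X", "Z", "Y"))
}

#' @rdname emergent-schemes
#' @export
pair_unimolecular <- function(k1 = 1, c1 = 1) {
  reaction_network(list(
    reaction(c(X = 1), c(Y = 1), k = k1),
    reaction(c(P = 1), c(Q = 1), k = c1)
  ), species = c("X", "Y", "P", "Q"))
}

#' @rdname emergent-schemes
#' @export
pair_mixed <- function(k1 = 1, c1 = 1) {
  reaction_network(list(
    reaction(c(X = 1), c(Y = 2), k = k1),
    reaction(c(P = 2), c(Q = 1), k = c1)
  ), species = c("X", "Y", "P", "Q"))
}
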