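#' Create an elementary mass-action reaction
#'
#' A reaction is described by integer reactant and product stoichiometries,
#' a forward rate constant and an optional reverse rate constant. Only
#' elementary steps up to trimolecular (total molecularity 3) on either side
#' are accepted.
#'
#' @param reactants named integer vector of reactant stoichiometric counts
#'   (species name -> positive integer), or an empty vector.
#' @param products named integer vector of product stoichiometric counts.
#' @param k forward rate constant (> 0), units M^(1-order) s^-1.
#' @param kr reverse rate constant (>= 0); `NULL` or 0 means irreversible.
#' @return An object of class `"osmo_reaction"`.
#' @examples
#' reaction(c(X = 1, Y = 2), c(Y = 3), k = 5.25e4, kr = 2.85e3)
#' @export
reaction <- function(reactants, products, k, kr = NULL) {
  reactants <- validate_stoich(reactants, "reactants")
  products  <- validate_stoich(products, "products")
  if (sum(reactants) > 3L)
    stop("total reactant molecularity ", sum(reactants),
         " exceeds 3 (at most trimolecular steps)")
  if (sum(products) > 3L)
    stop("total product molecularity ", sum(products), " exceeds 3")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("forward rate constant k must be a single positive number")
  if (is.null(kr)) kr <- 0
  if (!is.numeric(kr) || length(kr) != 1L || !is.finite(kr) || kr < 0)
    stop("reverse rate constant kr must be a single non-negative number")
  structure(list(reactants = reactants, products = products,
                 k = as.numeric(k), kr = as.numeric(kr)),
            class = "osmo_reaction")
}

validate_stoich <- function(x, what) {
  if (length(x) == 0L) return(setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named vector")
  if (anyDuplicated(names(x)))
    stop("duplicate species in ", what)
  xi <- as.integer(x)
  if (any(is.na(xi)) || any(xi != x) || any(xi <= 0L))
    stop(what, " stoichiometric counts must be positive integers")
  setNames(xi, names(x))
}

#' Total reactant molecularity (order) of a reaction
#' @param rxn an `"osmo_reaction"`.
#' @param reverse if `TRUE`, return the product-side (reverse) order.
#' @return Integer order.
#' @export
reaction_order <- function(rxn, reverse = FALSE) {
  if (reverse) sum(rxn$products) else sum(rxn$reactants)
}

#' Assemble a reaction network
#'
#' @param species character vector of unique species names; every species
#'   appearing in a reaction must be listed. If `NULL`, the species list is
#'   inferred from the reactions in order of first appearance.
#' @param reactions list of [reaction()] objects.
#' @return An object of class `"osmo_network"` with fields `species` and
#'   `reactions`.
#' @export
reaction_network <- function(reactions, species = NULL) {
  if (inherits(reactions, "osmo_reaction")) reactions <- list(reactions)
  stopifnot(is.list(reactions))
  for (r in reactions)
    if (!inherits(r, "osmo_reaction")) stop("reactions must be osmo_reaction objects")
  used <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  if (is.null(species)) species <- used
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species names must be unique")
  missing <- setdiff(used, species)
  if (length(missing))
    stop("species used in reactions but not declared: ",
         paste(missing, collapse = ", "))
  structure(list(species = species, reactions = reactions),
            class = "osmo_network")
}

#' @export
print.osmo_network <- function(x, ...) {
  cat("<osmo_network> ", length(x$species), " species {",
      paste(x$species, collapse = ", "), "}, ",
      length(x$reactions), " reaction(s)\n", sep = "")
  for (r in x$reactions) cat("  ", format_reaction(r), "\n", sep = "")
  invisible(x)
}

format_side <- function(st) {
  if (length(st) == 0L) return("0")
  paste(ifelse(st == 1L, names(st), paste0(st, names(st))), collapse = " + ")
}

format_reaction <- function(r, digits = 6L) {
  arrow <- if (r$kr > 0) "<->" else "->"
  fmt <- paste0("%.", digits, "g")
  rate <- if (r$kr > 0)
    sprintf(paste0("(k=", fmt, ", kr=", fmt, ")"), r$k, r$kr)
  else sprintf(paste0("(k=", fmt, ")"), r$k)
  paste(format_side(r$reactants), arrow, format_side(r$products), rate)
}

#' Parse a reaction network from its compact text form
#'
#' The schema is a semicolon- or newline-separated list of reactions written
#' as `"X + 2Y <-> 3Y (k=5.25e4, kr=2.85e3)"`. `->` denotes an irreversible
#' step, `<->` a reversible one (which requires `kr`). Stoichiometric
#' coefficients are integer prefixes; species names start with a letter.
#'
#' @param text the network description.
#' @param species optional explicit species ordering (see
#'   [reaction_network()]).
#' @return An `"osmo_network"`.
#' @examples
#' parse_network("X + 2Y <-> 3Y (k=5.25e4, kr=2.85e3); Y <-> Z (k=9.15e-2, kr=7.15e-3)")
#' @export
parse_network <- function(text, species = NULL) {
  stopifnot(is.character(text))
  parts <- unlist(strsplit(paste(text, collapse = "\n"), "[;\n]"))
  parts <- trimws(parts)
  parts <- parts[nzchar(parts) & !grepl("^#", parts)]
  if (!length(parts)) stop("no reactions found in network text")
  reaction_network(lapply(parts, parse_reaction_string), species = species)
}

parse_reaction_string <- function(txt) {
  m <- regmatches(txt, regexec(
    "^\\s*(.*?)\\s*(<->|->)\\s*(.*?)\\s*\\(\\s*k\\s*=\\s*([^,\\)]+)\\s*(?:,\\s*kr\\s*=\\s*([^\\)]+))?\\)\\s*$",
    txt, perl = TRUE))[[1]]
  if (length(m) == 0L)
    stop("cannot parse reaction: ", sQuote(txt))
  lhs <- parse_side(m[2], txt)
  arrow <- m[3]
  rhs <- parse_side(m[4], txt)
  k <- as.numeric(m[5])
  kr <- if (nzchar(m[6])) as.numeric(m[6]) else NULL
  if (is.na(k)) stop("bad rate constant in ", sQuote(txt))
  if (identical(arrow, "<->") && is.null(kr))
    stop("reversible reaction missing kr: ", sQuote(txt))
  if (identical(arrow, "->") && !is.null(kr))
    stop("irreversible reaction must not carry kr: ", sQuote(txt))
  reaction(lhs, rhs, k = k, kr = kr)
}

parse_side <- function(side, ctx) {
  side <- trimws(side)
  if (side %in% c("", "0")) return(setNames(integer(0), character(0)))
  terms <- trimws(unlist(strsplit(side, "\\+")))
  st <- integer(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_]*)$", tm))[[1]]
    if (length(m) == 0L) stop("cannot parse species term ", sQuote(tm),
                              " in ", sQuote(ctx))
    coef <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    sp <- m[3]
    st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0L) + coef
  }
  st
}

#' Write a network back to its compact text form
#' @param network an `"osmo_network"`.
#' @param digits significant digits for the rate constants.
#' @return A single string; [parse_network()] of it round-trips the network.
#' @export
deparse_network <- function(network, digits = 15L) {
  stopifnot(inherits(network, "osmo_network"))
  paste(vapply(network$reactions, format_reaction, character(1),
               digits = digits),
        collapse = "; ")
}

#' Net mass-action production rates
#'
#' Evaluates, for every species, the sum over reactions of the net
#' stoichiometric change times the mass-action flux
#' `k * prod(reactant concentrations) - kr * prod(product concentrations)`.
#'
#' @param network an `"osmo_network"`.
#' @param s named numeric vector of concentrations (M); must cover every
#'   network species.
#' @return Named numeric vector of net rates (M/s), in species order.
#' @export
mak_rates <- function(network, s) {
  stopifnot(inherits(network, "osmo_network"))
  s <- s[network$species]
  if (anyNA(s)) stop("concentration map is missing species: ",
                     paste(network$species[is.na(s)], collapse = ", "))
  r <- setNames(numeric(length(network$species)), network$species)
  for (rxn in network$reactions) {
    flux <- rxn$k * prod(s[names(rxn$reactants)]^rxn$reactants)
    if (rxn$kr > 0)
      flux <- flux - rxn$kr * prod(s[names(rxn$products)]^rxn$products)
    for (sp in names(rxn$reactants)) r[sp] <- r[sp] - rxn$reactants[[sp]] * flux
    for (sp in names(rxn$products))  r[sp] <- r[sp] + rxn$products[[sp]] * flux
  }
  r
}

#' Net molecule change per reaction
#'
#' Total product molecularity minus total reactant molecularity for each
#' reaction; a network whose reactions all return 0 conserves molecule
#' number (one consumed molecule per produced one), so any volume change it
#' drives must come from differing membrane permeabilities alone.
#'
#' @param network an `"osmo_network"`.
#' @return Integer vector, one entry per reaction.
#' @export
net_stoichiometry_change <- function(network) {
  stopifnot(inherits(network, "osmo_network"))
  vapply(network$reactions,
         function(r) sum(r$products) - sum(r$reactants), integer(1))
}
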