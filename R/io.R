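# Configuration files, result serialization, and packaged fixture
# generation. Configs are YAML (JSON-compatible); tabular results go to
# CSV, summaries to JSON.

#' Load a vesicle reactor run configuration
#'
#' The config schema (YAML, JSON-compatible):
#' \preformatted{
#' reactions: "X + 2Y <-> 3Y (k=5.25e4, kr=2.85e3); Y <-> Z (k=9.15e-2, kr=7.15e-3)"
#' species: [X, Y, Z]        # optional explicit ordering
#' reactor:
#'   B_T: 63064              # required
#'   b_eps: 0.2              # required (M)
#'   s_eps: {X: 6.47e-4}     # per-species external concentrations (M)
#'   Dx: {X: 1.0, Y: 1.0}    # permeability multipliers
#'   D_ribose: 2.65e8        # optional override
#'   lambda: 4.0e-8          # optional override
#' task: steady              # optional: simulate|steady|sweep|census|...
#' options: {...}            # optional task options
#' seed: 1                   # optional
#' }
#'
#' @param path file path.
#' @return A list with `reactor` (an `"osmo_reactor"`), `task`, `options`
#'   and `seed` (defaulted to `"steady"`, empty list, 1).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("reactions", "reactor"))
    if (is.null(cfg[[field]]))
      stop("config field missing: ", sQuote(field))
  rc <- cfg$reactor
  for (field in c("B_T", "b_eps"))
    if (is.null(rc[[field]]))
      stop("config field missing: ", sQuote(paste0("reactor.", field)))
  sp_decl <- if (!is.null(cfg$species)) unlist(cfg$species)
  network <- if (!nzchar(trimws(paste(cfg$reactions, collapse = "")))) {
    # reaction-free reactor: inert diffusing species only
    reaction_network(list(), species = sp_decl)
  } else parse_network(cfg$reactions, species = sp_decl)
  s_eps <- unlist(rc$s_eps %||% list())
  Dx <- unlist(rc$Dx %||% list())
  env <- vesicle_environment(rc$b_eps,
                             if (length(s_eps)) s_eps else numeric(0))
  mem <- membrane_spec(if (length(Dx)) Dx else numeric(0),
                       D_ribose = rc$D_ribose %||%
                         osmocell_constants$D_ribose,
                       lambda = rc$lambda %||% osmocell_constants$lambda)
  list(reactor = vesicle_reactor(network, env, mem, rc$B_T),
       task = cfg$task %||% "steady",
       options = cfg$options %||% list(),
       seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reactor back to a configuration file
#'
#' @param reactor an `"osmo_reactor"`.
#' @param path output path; the written file round-trips through
#'   [load_config()].
#' @param task,options,seed optional run fields to embed.
#' @return `path`, invisibly.
#' @export
write_config <- function(reactor, path, task = NULL, options = NULL,
                         seed = NULL) {
  stopifnot(inherits(reactor, "osmo_reactor"))
  cfg <- list(
    reactions = deparse_network(reactor$network),
    species = reactor$network$species,
    reactor = list(B_T = reactor$B_T, b_eps = reactor$b_eps,
                   s_eps = as.list(reactor$s_eps),
                   Dx = as.list(reactor$Dx),
                   D_ribose = reactor$membrane$D_ribose,
                   lambda = reactor$membrane$lambda))
  if (!is.null(task)) cfg$task <- task
  if (!is.null(options)) cfg$options <- options
  if (!is.null(seed)) cfg$seed <- seed
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write a result object to disk
#'
#' Tabular objects (fixed points, bifurcation points, trajectories,
#' coupling curves, any data.frame) are written as CSV; censuses and
#' search results as JSON summaries.
#'
#' @param result the object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  if (inherits(result, "osmo_trajectory")) {
    write.csv(as.data.frame(result), path, row.names = FALSE)
  } else if (inherits(result, "osmo_bifurcation")) {
    write.csv(result$points, path, row.names = FALSE)
  } else if (inherits(result, "osmo_census")) {
    jsonlite::write_json(list(n = result$n, n_failed = result$n_failed,
                              S_mu0 = result$S_mu0, table = result$table),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(result, "osmo_search")) {
    summ <- list(diagnostics = result$diagnostics, seed = result$seed,
                 candidates = lapply(result$candidates, function(cand)
                   list(abc = as.list(cand$abc),
                        classification = cand$classification,
                        crossings = cand$crossings)))
    jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA)
  } else if (is.data.frame(result)) {
    write.csv(result, path, row.names = FALSE)
  } else if (is.list(result)) {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA)
  } else stop("do not know how to serialize a ", class(result)[1])
  invisible(path)
}

#' Generate the packaged example configurations
#'
#' Writes, into `dir`: the Schlogl and Wilhelm bulk regimes embedded in
#' the vesicle reactor (reservoir species' external concentrations pinned
#' to the bulk values), a reaction-free reactor, and — when
#' `include_search = TRUE` — a bistable two-unimolecular-reaction
#' parameter set discovered by a seeded [find_bistable_regimes()] run.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the search-derived fixture; the packaged
#'   `pair_unimolecular_bistable.yaml` was produced with `seed = 101` and
#'   `budget = 4000`.
#' @param include_search run the (slower) bistability search fixture.
#' @return Character vector of written file paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 101L, include_search = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  sr <- schlogl_reservoir()
  schlogl <- vesicle_reactor(
    schlogl_network(),
    vesicle_environment(0.002, c(X = unname(sr["x"]), Y = 0.0005,
                                 Z = unname(sr["z"]))),
    membrane_spec(c(X = 1, Y = 1, Z = 1)), B_T = 1000)
  paths <- c(paths, write_config(schlogl, file.path(dir, "schlogl_vesicle.yaml"),
                                 task = "steady"))
  wr <- wilhelm_reservoir()
  wilhelm <- vesicle_reactor(
    wilhelm_network(),
    vesicle_environment(0.002, c(X = unname(wr["x"]), Y = 0.0005,
                                 Z = 0.0005, W = 0.0002)),
    membrane_spec(c(X = 1, Y = 1, Z = 1, W = 1)), B_T = 1000)
  paths <- c(paths, write_config(wilhelm, file.path(dir, "wilhelm_vesicle.yaml"),
                                 task = "steady"))
  inert <- vesicle_reactor(
    reaction_network(list(), species = "A"),
    vesicle_environment(0.15, c(A = 0.05)),
    membrane_spec(c(A = 1)), B_T = 63064)
  paths <- c(paths, write_config(inert, file.path(dir, "reaction_free.yaml"),
                                 task = "sweep"))
  if (include_search) {
    found <- find_bistable_regimes(pair_unimolecular(), budget = 4000,
                                   seed = seed)
    if (length(found$candidates))
      paths <- c(paths, write_config(
        found$candidates[[1]]$reactor,
        file.path(dir, "pair_unimolecular_bistable.yaml"),
        task = "sweep", seed = seed))
  }
  invisible(paths)
}
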