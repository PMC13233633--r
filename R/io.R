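#' Serialize a network to JSON
#'
#' Weights are stored row-major with thresholds and construction metadata,
#' so a network round-trips bit-identically.
#'
#' @param net an `isn`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNetworkJSON <- function(net, path) {
  net <- asNetwork(net)
  p <- net$pair
  obj <- list(
    n_pairs = net$n_pairs,
    unit_order = "interleaved (e1, i1, e2, i2, ...)",
    weights_row_major = as.vector(t(net$weights)),
    thresholds = as.vector(net$thresholds),
    pair = list(w_ee = p$w_ee, w_ie = p$w_ie, w_ei = p$w_ei, w_ii = p$w_ii,
                theta_e = p$theta_e, theta_i = p$theta_i, tau = p$tau),
    meta = net$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path file written by [writeNetworkJSON()].
#' @return An `isn`.
#' @export
readNetworkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- obj$pair
  pair <- ispParams(pp$w_ee, pp$w_ie, pp$w_ei, pp$w_ii,
                    pp$theta_e, pp$theta_i, pp$tau)
  n <- 2L * obj$n_pairs
  W <- matrix(obj$weights_row_major, n, n, byrow = TRUE)
  meta <- obj$meta
  if (is.null(meta)) meta <- list()
  newISN(W, obj$thresholds, pair, meta)
}

#' Write a trajectory as CSV
#'
#' Columns `time_s` then one column per unit (`e1`, `i1`, ...).
#'
#' @param traj an `isn_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  stopifnot(inherits(traj, "isn_trajectory"))
  df <- data.frame(time_s = traj$times, traj$rates, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a sweep result
#'
#' Writes the per-cell table as CSV and the (`f_sd`, `tolerance`) summary
#' as JSON next to it.
#'
#' @param sw a `sweep_result` from [stimulusSweep()].
#' @param csv_path cell table destination; the JSON summary replaces the
#'   extension with `.json`.
#' @return `csv_path`, invisibly.
#' @export
writeSweepResult <- function(sw, csv_path) {
  stopifnot(inherits(sw, "sweep_result"))
  write.csv(sw$cells, csv_path, row.names = FALSE)
  json_path <- sub("\\.[^.]*$", ".json", csv_path)
  jsonlite::write_json(list(f_sd = sw$f_sd, tolerance = sw$tolerance),
                       json_path, auto_unbox = TRUE, digits = I(17))
  invisible(csv_path)
}

# igraph view of a transition graph or state machine
asIgraph <- function(x) {
  if (inherits(x, "transition_graph")) {
    n <- length(x$targets)
    sigs <- vapply(x$catalogue$states[seq_len(n)], function(s)
      paste(s$signature, collapse = ""), character(1))
    edges <- cbind(seq_len(n), x$targets)
    edges <- edges[!is.na(edges[, 2]), , drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    g <- igraph::set_vertex_attr(g, "signature", value = sigs[seq_len(igraph::vcount(g))])
    return(g)
  }
  if (inherits(x, "state_machine")) {
    n <- nrow(x$delta)
    el <- list()
    for (q in seq_len(n)) for (s in 1:2) {
      if (!is.na(x$delta[q, s])) el[[length(el) + 1L]] <- c(q, x$delta[q, s], s)
    }
    el <- do.call(rbind, el)
    g <- igraph::graph_from_edgelist(el[, 1:2, drop = FALSE], directed = TRUE)
    g <- igraph::set_edge_attr(g, "cue", value = c("L", "R")[el[, 3]])
    if (!is.null(x$labels))
      g <- igraph::set_vertex_attr(g, "label", value = x$labels[seq_len(igraph::vcount(g))])
    return(g)
  }
  stop("cannot convert object of class ", class(x)[1], " to a graph")
}

#' Export a transition graph or machine
#'
#' @param x a `transition_graph` or `state_machine`.
#' @param path destination file.
#' @param format `"dot"`, `"graphml"` or `"csv"` (edge list).
#' @return `path`, invisibly.
#' @export
writeGraph <- function(x, path, format = c("dot", "graphml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (inherits(x, "transition_graph")) {
      df <- data.frame(from = seq_along(x$targets), to = x$targets)
    } else {
      df <- data.frame(from = rep(seq_len(nrow(x$delta)), 2),
                       cue = rep(c("L", "R"), each = nrow(x$delta)),
                       to = as.vector(x$delta))
    }
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  igraph::write_graph(asIgraph(x), path, format = format)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) configuration,
#' applies documented defaults, and normalizes units: any key ending in
#' `_ms` is converted to seconds under the same name without the suffix.
#'
#' @param path configuration file.
#' @return A named list with defaults applied (class `run_config`).
#' @export
loadRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- normalizeConfig(raw)
  defaults <- list(pairs = 1L, seed = 1L, dt = 1e-5, dt_settle = 1e-4,
                   settle_time = 12, tau = 0.010)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

normalizeConfig <- function(x) {
  out <- list()
  for (k in names(x)) {
    v <- x[[k]]
    if (is.list(v) && !is.null(names(v))) v <- normalizeConfig(v)
    if (grepl("_ms$", k) && is.numeric(v)) {
      out[[sub("_ms$", "", k)]] <- v / 1000
    } else out[[k]] <- v
  }
  out
}

#' Export an attractor catalogue
#'
#' @param cat an `attractor_catalogue`.
#' @param path JSON destination.
#' @return `path`, invisibly.
#' @export
writeCatalogueJSON <- function(cat, path) {
  stopifnot(inherits(cat, "attractor_catalogue"))
  states <- lapply(cat$states, function(s)
    list(id = s$id, signature = s$signature, rates = as.vector(s$rates),
         settled_by = s$settled_by, multiplicity = s$multiplicity))
  jsonlite::write_json(list(method = cat$method, n_pairs = cat$n_pairs,
                            n_states = cat$n_states, states = states),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
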