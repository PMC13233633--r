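#' Apply a stimulus from an attractor state and resettle
#'
#' Simulates the pulse from the given rates, then relaxes the network and
#' matches the settled state against the catalogue; a genuinely new settled
#' state is appended.
#'
#' @param net an `isn`.
#' @param rates starting rates (an attractor state's rate vector).
#' @param amplitude,duration rectangular pulse parameters.
#' @param catalogue an `attractor_catalogue` (exhaustive style, with
#'   per-state multiplicity 1).
#' @param weights optional per-unit stimulus weight vector (cue identity).
#' @param dt_stimulus,dt_settle integration steps, seconds.
#' @param settle_time equilibration time, seconds.
#' @param tol state-matching tolerance, Hz.
#' @return List with `target` (state id or `NA` on non-convergence) and the
#'   possibly extended `catalogue`.
#' @export
applyAndSettle <- function(net, rates, amplitude, duration, catalogue,
                           weights = NULL, dt_stimulus = 2e-5,
                           dt_settle = 1e-4, settle_time = 12, tol = 0.5) {
  net <- asNetwork(net)
  pulse <- simulateISN(net, rates, stimulusSpec(amplitude, duration,
                                                weights = weights),
                       t_end = duration, dt = dt_stimulus,
                       sample_every = 1e6L)
  res <- settleNetwork(net, pulse$final, settle_time = settle_time,
                       dt = dt_settle, tol = tol)
  if (!res$converged) return(list(target = NA_integer_, catalogue = catalogue))
  id <- matchState(catalogue$states, res$signature, res$rates, tol)
  if (is.na(id)) {
    id <- length(catalogue$states) + 1L
    catalogue$states[[id]] <- list(id = id, rates = res$rates,
                                   signature = res$signature,
                                   settled_by = res$settled_by,
                                   multiplicity = 1)
    catalogue$n_states <- catalogue$n_states + 1
  }
  list(target = id, catalogue = catalogue)
}

#' Single-stimulus transition graph over a catalogue
#'
#' For one (amplitude, duration) stimulus applied uniformly to all units,
#' computes the functional map from every attractor state to its
#' post-stimulus attractor state.
#'
#' @inheritParams applyAndSettle
#' @param ... passed to [applyAndSettle()].
#' @return An object of class `transition_graph`: `targets` (integer vector
#'   indexed by state id, `NA` marks a non-converged edge), the extended
#'   `catalogue`, and the stimulus parameters.
#' @export
transitionGraph <- function(net, catalogue, amplitude, duration, ...) {
  net <- asNetwork(net)
  targets <- integer(0)
  i <- 1L
  while (i <= length(catalogue$states)) {
    st <- catalogue$states[[i]]
    ans <- applyAndSettle(net, st$rates, amplitude, duration, catalogue, ...)
    catalogue <- ans$catalogue
    targets[i] <- ans$target
    i <- i + 1L
  }
  structure(list(targets = targets, catalogue = catalogue,
                 amplitude = amplitude, duration = duration),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("Transition graph: %d states, stimulus (I_app = %g, dur = %g s)\n",
              length(x$targets), x$amplitude, x$duration))
  cat(sprintf("  longest itinerant path L = %d\n", longestItinerantPath(x)))
  invisible(x)
}

# walk a functional map from one start node; count transitions taken,
# not counting a terminal self-loop, but counting an edge that closes onto
# a previously visited different state
walkLength <- function(targets, start) {
  visited <- logical(length(targets))
  cur <- start
  len <- 0L
  repeat {
    visited[cur] <- TRUE
    nxt <- targets[cur]
    if (is.na(nxt)) return(len)           # non-converged edge terminates walk
    if (nxt == cur) return(len)           # terminal self-loop not counted
    len <- len + 1L
    if (visited[nxt]) return(len)         # closing edge counted
    cur <- nxt
  }
}

#' Longest itinerant path of a transition graph
#'
#' The maximum, over start states, of the number of transitions taken when
#' the single-stimulus map is iterated until a state repeats.
#'
#' @param g a `transition_graph` (or bare integer target vector).
#' @return Non-negative integer L.
#' @export
longestItinerantPath <- function(g) {
  targets <- if (inherits(g, "transition_graph")) g$targets else g
  if (length(targets) == 0) return(0L)
  max(vapply(seq_along(targets), function(s) walkLength(targets, s),
             integer(1)))
}

#' Itinerancy over a stimulus grid
#'
#' Builds the transition graph and records the longest itinerant path L for
#' every cell of an (amplitude, duration) grid.
#'
#' @param net an `isn`.
#' @param catalogue base `attractor_catalogue` of the unstimulated network.
#' @param amp_grid,dur_grid positive stimulus grids.
#' @param ... passed to [transitionGraph()].
#' @return Data frame with columns `amplitude`, `duration`, `L`,
#'   `n_states` (catalogue size after any stimulus-discovered states) and
#'   `n_components` (weakly connected components of the graph).
#' @export
itinerancySweep <- function(net, catalogue, amp_grid, dur_grid, ...) {
  stopifnot(all(amp_grid > 0), all(dur_grid > 0))
  cells <- expand.grid(amplitude = amp_grid, duration = dur_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$L <- NA_integer_
  cells$n_states <- NA_integer_
  cells$n_components <- NA_integer_
  for (j in seq_len(nrow(cells))) {
    g <- transitionGraph(net, catalogue, cells$amplitude[j],
                         cells$duration[j], ...)
    cells$L[j] <- longestItinerantPath(g)
    cells$n_states[j] <- length(g$targets)
    cells$n_components[j] <- graphComponents(g)
  }
  cells
}

# number of weakly connected components of the functional graph
graphComponents <- function(g) {
  targets <- g$targets
  n <- length(targets)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (s in seq_len(n)) {
    t <- targets[s]
    if (!is.na(t)) {
      rs <- find(s); rt <- find(t)
      if (rs != rt) parent[rs] <- rt
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# --- homogeneous fast path -------------------------------------------------

#' Class-level transition map of a homogeneous network
#'
#' In a homogeneous network under a uniform stimulus, all UP pairs respond
#' identically and all DOWN pairs respond identically, so the transition
#' from any state with k UP pairs is determined by k alone: the originally
#' UP group and the originally DOWN group each end UP or DOWN as a block.
#'
#' @param net a homogeneous `isn`.
#' @param amplitude,duration uniform pulse parameters.
#' @param stable_k integer vector of stable UP-counts (from the
#'   symmetry-reduced [enumerateAttractors()]).
#' @param rep_states optional list of precomputed representative attractor
#'   rate vectors, named by k (see [homogeneousRepStates()]); computed on
#'   the fly when missing.
#' @param dt_stimulus,dt_settle integration steps, seconds.
#' @param settle_time equilibration time, seconds.
#' @param tol state-matching tolerance, Hz.
#' @return Data frame with one row per k: `k`, `up_stays` (originally UP
#'   pairs end UP), `down_rises` (originally DOWN pairs end UP), and
#'   `converged`.
#' @export
homogeneousTransitionMap <- function(net, amplitude, duration, stable_k,
                                     rep_states = NULL,
                                     dt_stimulus = 2e-5, dt_settle = 1e-4,
                                     settle_time = 12, tol = 0.5) {
  net <- asNetwork(net)
  stopifnot(isHomogeneous(net))
  N <- net$n_pairs
  if (is.null(rep_states))
    rep_states <- homogeneousRepStates(net, stable_k,
                                       settle_time = settle_time,
                                       dt = dt_settle, tol = tol)
  out <- data.frame(k = stable_k, up_stays = NA, down_rises = NA,
                    converged = NA)
  for (j in seq_along(stable_k)) {
    k <- stable_k[j]
    r0 <- rep_states[[as.character(k)]]
    if (is.null(r0)) next
    pulse <- simulateISN(net, r0, stimulusSpec(amplitude, duration),
                         t_end = duration, dt = dt_stimulus,
                         sample_every = 1e6L)
    res <- settleNetwork(net, pulse$final, settle_time = settle_time,
                         dt = dt_settle, tol = tol)
    out$converged[j] <- res$converged
    if (!res$converged) next
    sig <- res$signature
    up_grp <- seq_len(k)
    dn_grp <- setdiff(seq_len(N), up_grp)
    up_final <- if (k > 0) unique(sig[up_grp]) else integer(0)
    dn_final <- if (length(dn_grp)) unique(sig[dn_grp]) else integer(0)
    if (length(up_final) > 1 || length(dn_final) > 1) {
      out$converged[j] <- FALSE   # symmetry numerically broken; treat as bad
      next
    }
    out$up_stays[j] <- if (k > 0) up_final == 1L else NA
    out$down_rises[j] <- if (length(dn_grp)) dn_final == 1L else NA
  }
  out
}

#' Longest itinerant path of a homogeneous network from its class map
#'
#' Walks the full 2^N functional graph symbolically: from a generic subset S
#' of k UP pairs the only reachable states are S, its complement, all-UP and
#' all-DOWN, so the walk is tracked over those four labels.
#'
#' @param map output of [homogeneousTransitionMap()].
#' @param n_pairs N.
#' @return Non-negative integer L (maximum over all start states).
#' @export
homogeneousLongestPath <- function(map, n_pairs) {
  N <- n_pairs
  lookup <- function(k) {
    row <- map[map$k == k, , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$converged) || !row$converged) return(NULL)
    row
  }
  # node labels: "S" (the start subset, size k0), "C" (complement),
  # "F" (all-UP), "E" (all-DOWN)
  nodeSize <- function(lab, k0) switch(lab, S = k0, C = N - k0, F = N, E = 0L)
  canon <- function(lab, k0) {
    sz <- nodeSize(lab, k0)
    if (sz == N) "F" else if (sz == 0L) "E" else lab
  }
  step <- function(lab, k0) {
    row <- lookup(nodeSize(lab, k0))
    if (is.null(row)) return(NA_character_)
    u <- row$up_stays; d <- row$down_rises
    sz <- nodeSize(lab, k0)
    up_part <- if (sz > 0 && isTRUE(u)) lab else NULL
    dn_part_rises <- sz < N && isTRUE(d)
    # resulting set: (kept originally-UP block) union (risen originally-DOWN block)
    if (!is.null(up_part) && dn_part_rises) return("F")
    if (!is.null(up_part)) return(canon(lab, k0))
    if (dn_part_rises) {
      comp <- switch(lab, S = "C", C = "S", F = "E", E = "F")
      return(canon(comp, k0))
    }
    "E"
  }
  best <- 0L
  for (k0 in map$k) {
    row <- lookup(k0)
    if (is.null(row)) next
    start <- canon("S", k0)
    visited <- character(0)
    cur <- start; len <- 0L
    repeat {
      visited <- c(visited, cur)
      nxt <- step(cur, k0)
      if (is.na(nxt)) break
      if (nxt == cur) break
      len <- len + 1L
      if (nxt %in% visited) break
      cur <- nxt
    }
    best <- max(best, len)
  }
  best
}

#' Homogeneous itinerancy sweep
#'
#' [itinerancySweep()] specialised to homogeneous networks with uniform
#' stimuli, using the O(N) class-level transition map per grid cell instead
#' of the O(2^N) state-by-state graph.
#'
#' @param net a homogeneous `isn`.
#' @param stable_k stable UP-counts from symmetry-reduced enumeration.
#' @param amp_grid,dur_grid stimulus grids.
#' @param ... passed to [homogeneousTransitionMap()].
#' @return Data frame with `amplitude`, `duration`, `L`.
#' @export
homogeneousItinerancySweep <- function(net, stable_k, amp_grid, dur_grid,
                                       ...) {
  cells <- expand.grid(amplitude = amp_grid, duration = dur_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$L <- NA_integer_
  reps <- homogeneousRepStates(net, stable_k)
  for (j in seq_len(nrow(cells))) {
    m <- homogeneousTransitionMap(net, cells$amplitude[j], cells$duration[j],
                                  stable_k, rep_states = reps, ...)
    cells$L[j] <- homogeneousLongestPath(m, net$n_pairs)
  }
  cells
}

#' Representative attractor states of a homogeneous network
#'
#' Settles, once per stable UP-count k, the symmetric attractor with the
#' first k pairs UP.
#'
#' @param net a homogeneous `isn`.
#' @param stable_k stable UP-counts.
#' @param ... passed to [settleNetwork()].
#' @return Named list (by k) of settled rate vectors; k values whose
#'   representative fails to settle at that count are dropped.
#' @export
homogeneousRepStates <- function(net, stable_k, ...) {
  net <- asNetwork(net)
  N <- net$n_pairs
  up <- upFixedPoint(net$pair)$location
  reps <- list()
  for (k in stable_k) {
    r <- numeric(2L * N)
    if (k > 0) {
      r[2L * seq_len(k) - 1L] <- up[1]
      r[2L * seq_len(k)] <- up[2]
      st <- settleNetwork(net, r, ...)
      if (!st$converged || sum(st$signature) != k) next
      r <- st$rates
    }
    reps[[as.character(k)]] <- r
  }
  reps
}
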