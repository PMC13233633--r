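#' Deterministic finite-state machine over a two-cue alphabet
#'
#' A machine is a transition table over states 1..n and the alphabet
#' `c("L", "R")`, with a fixed initial state. Output labels (the per-state
#' decision) are usually assigned afterwards by [machineReliability()],
#' which finds the optimal labeling.
#'
#' @param delta integer n x 2 matrix; `delta[q, s]` is the successor of
#'   state `q` on symbol `s` (columns L, R). `NA` marks a non-converged
#'   edge, making the machine partial.
#' @param q0 initial state (default 1).
#' @param labels optional per-state outputs in `c("L", "R", "none")`.
#' @param states optional list of per-state payloads (e.g. attractor
#'   states).
#' @return An object of class `state_machine`.
#' @export
stateMachine <- function(delta, q0 = 1L, labels = NULL, states = NULL) {
  delta <- as.matrix(delta)
  stopifnot(ncol(delta) == 2, q0 >= 1, q0 <= nrow(delta))
  colnames(delta) <- c("L", "R")
  ok <- delta[!is.na(delta)]
  stopifnot(all(ok >= 1), all(ok <= nrow(delta)))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(delta),
                                  all(labels %in% c("L", "R", "none")))
  structure(list(delta = delta, q0 = as.integer(q0), labels = labels,
                 states = states, partial = anyNA(delta)),
            class = "state_machine")
}

#' @export
print.state_machine <- function(x, ...) {
  cat(sprintf("Finite-state machine: %d states, initial state %d%s\n",
              nrow(x$delta), x$q0, if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Extract the finite-state machine a network implements
#'
#' Breadth-first traversal from the quiescent (all-DOWN) state: for each
#' reachable attractor state and each cue, the transition is discovered by
#' simulating the pulse and the post-stimulus equilibration, with each
#' (state, cue) edge simulated once and cached. Traversal stops when no new
#' states are found.
#'
#' @param net an `isn`.
#' @param cue_l,cue_r [makeCueVector()] objects (or bare weight vectors)
#'   for the left and right cue.
#' @param amplitude,duration shared pulse parameters of both cues.
#' @param ... passed to [applyAndSettle()] (integration steps, settle time).
#' @return A `state_machine` whose `states` are the reachable attractor
#'   states (state 1 = quiescent). The machine is flagged `partial` if any
#'   edge failed to converge.
#' @export
extractFSM <- function(net, cue_l, cue_r, amplitude, duration, ...) {
  net <- asNetwork(net)
  n <- 2L * net$n_pairs
  wl <- if (inherits(cue_l, "cue_vector")) cue_l$weights else cue_l
  wr <- if (inherits(cue_r, "cue_vector")) cue_r$weights else cue_r
  stopifnot(length(wl) == n, length(wr) == n)
  q0rates <- exactFixedPoint(net, integer(0))
  if (is.null(q0rates))
    stop("quiescent state is not stable for this network")
  catalogue <- newCatalogue(list(list(id = 1L, rates = q0rates,
                                      signature = rep(0L, net$n_pairs),
                                      settled_by = "proximity",
                                      multiplicity = 1)),
                            "fsm", net$n_pairs)
  # edge oracle: simulating one (state, cue) pulse; extends the catalogue
  edge_fun <- function(q, s) {
    w <- if (s == 1L) wl else wr
    ans <- applyAndSettle(net, catalogue$states[[q]]$rates, amplitude,
                          duration, catalogue, weights = w, ...)
    catalogue <<- ans$catalogue
    ans$target
  }
  delta <- bfsMachine(edge_fun, n_known = function() length(catalogue$states))
  stateMachine(delta, q0 = 1L, states = catalogue$states)
}

# breadth-first discovery of a transition table over a growing state set:
# edge_fun(q, s) returns the successor id of state q on symbol s (possibly
# a new id, possibly NA for a dead edge); n_known() reports how many states
# exist so far. Each edge is evaluated exactly once.
bfsMachine <- function(edge_fun, n_known) {
  delta <- matrix(NA_integer_, max(1L, n_known()), 2)
  frontier <- 1L
  explored <- logical(nrow(delta))
  while (length(frontier)) {
    q <- frontier[1]; frontier <- frontier[-1]
    if (explored[q]) next
    explored[q] <- TRUE
    for (s in 1:2) {
      target <- edge_fun(q, s)
      n_states <- n_known()
      if (n_states > nrow(delta)) {
        delta <- rbind(delta, matrix(NA_integer_, n_states - nrow(delta), 2))
        explored <- c(explored, logical(n_states - length(explored)))
      }
      delta[q, s] <- target
      if (!is.na(target) && !explored[target])
        frontier <- c(frontier, target)
    }
  }
  delta
}

#' Trace cue sequences through a machine
#'
#' @param m a `state_machine`.
#' @param sequences integer matrix, one row per sequence, entries 1 (L) or
#'   2 (R); defaults to all 64 six-cue sequences.
#' @return Integer vector of final states (`NA` where a partial machine
#'   loses the trace).
#' @export
traceSequences <- function(m, sequences = cueSequences()$cues) {
  stopifnot(inherits(m, "state_machine"))
  apply(sequences, 1L, function(seq) {
    q <- m$q0
    for (s in seq) {
      q <- m$delta[q, s]
      if (is.na(q)) return(NA_integer_)
    }
    q
  })
}

#' Best reliability over all machines of a given size
#'
#' Exhaustively enumerates every deterministic two-symbol machine with
#' `n_states` states (initial state 1; relabeling makes this exhaustive up
#' to isomorphism) and scores each on the six-cue task with the optimal
#' output labeling. Feasible up to `n_states = 4` (4^8 = 65536 machines).
#'
#' @param n_states number of states (1..4).
#' @return List with `best` (maximum reliability) and `delta` of one
#'   machine attaining it.
#' @export
searchMachines <- function(n_states) {
  stopifnot(n_states >= 1, n_states <= 4)
  n <- as.integer(n_states)
  n_slots <- 2L * n
  M <- n^n_slots
  # machine j (0-based) has transition table digits of j base n
  codes <- 0:(M - 1)
  delta_all <- matrix(0L, M, n_slots)   # column (q-1)*2 + s
  tmp <- codes
  for (slot in seq_len(n_slots)) {
    delta_all[, slot] <- (tmp %% n) + 1L
    tmp <- tmp %/% n
  }
  sq <- cueSequences()
  cues <- sq$cues
  finals <- matrix(0L, M, nrow(cues))
  for (j in seq_len(nrow(cues))) {
    state <- rep(1L, M)
    for (t in 1:6) {
      slot <- (state - 1L) * 2L + cues[j, t]
      state <- delta_all[cbind(seq_len(M), slot)]
    }
    finals[, j] <- state
  }
  lcol <- which(sq$majority == "L"); rcol <- which(sq$majority == "R")
  score <- numeric(M)
  for (i in seq_len(n)) {
    cl <- rowSums(finals[, lcol, drop = FALSE] == i)
    cr <- rowSums(finals[, rcol, drop = FALSE] == i)
    score <- score + pmax(cl, cr)
  }
  rel <- score / (length(lcol) + length(rcol))
  bestj <- which.max(rel)
  list(best = max(rel),
       delta = matrix(delta_all[bestj, ], n, 2, byrow = TRUE))
}

#' Reference machines for the six-cue task
#'
#' Hand-built machines used as task baselines: a single-state machine (no
#' discrimination), a machine deciding by one fixed cue position, and a
#' signed-difference counter that solves the task perfectly.
#'
#' @param which `"one_state"`, `"last_cue"`, `"first_cue"` or `"counter"`.
#' @return A `state_machine`.
#' @export
referenceMachine <- function(which = c("one_state", "last_cue", "first_cue",
                                       "counter")) {
  which <- match.arg(which)
  switch(which,
    one_state = stateMachine(matrix(1L, 1, 2)),
    # states: 1 = last cue L (also start), 2 = last cue R
    last_cue = stateMachine(rbind(c(1L, 2L), c(1L, 2L))),
    # states: 1 start, 2 first cue was L, 3 first cue was R (absorbing)
    first_cue = stateMachine(rbind(c(2L, 3L), c(2L, 2L), c(3L, 3L))),
    counter = counterMachine())
}

# counter over #L - #R in [-6, 6]: 13 states, start at difference 0
counterMachine <- function() {
  diffs <- -6:6
  idx <- function(d) match(max(-6, min(6, d)), diffs)
  delta <- t(vapply(diffs, function(d) c(idx(d + 1), idx(d - 1)),
                    integer(2)))
  stateMachine(delta, q0 = idx(0))
}
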