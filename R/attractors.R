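#' Exact fixed point for a given set of active units
#'
#' On the interior of a clamping region the dynamics are linear, so the
#' fixed point with a prescribed active set solves
#' `(I - W_AA) r_A = -theta_A` with inactive units at zero. The candidate is
#' valid only if all active rates are positive and every inactive unit's net
#' input is at or below its threshold (its clamped derivative at zero is
#' non-positive).
#'
#' @param net an `isn`.
#' @param active logical or integer index of active (non-zero) units.
#' @return Rate vector of the verified fixed point, or `NULL` if the
#'   candidate is invalid.
#' @export
exactFixedPoint <- function(net, active) {
  net <- asNetwork(net)
  n <- 2L * net$n_pairs
  act <- logical(n); act[active] <- TRUE
  r <- numeric(n)
  if (any(act)) {
    A <- which(act)
    M <- diag(length(A)) - net$weights[A, A, drop = FALSE]
    rA <- tryCatch(solve(M, -net$thresholds[A]), error = function(e) NULL)
    if (is.null(rA) || any(!is.finite(rA)) || any(rA <= 0)) return(NULL)
    r[A] <- rA
  }
  inact <- which(!act)
  if (length(inact)) {
    input <- as.vector(net$weights[inact, , drop = FALSE] %*% r)
    if (any(input - net$thresholds[inact] > 1e-9)) return(NULL)
  }
  names(r) <- unitNames(net$n_pairs)
  r
}

#' UP/DOWN signature of a rate vector
#'
#' @param rates length-2N rate vector.
#' @param n_pairs number of pairs.
#' @param up_threshold a pair counts as UP when its excitatory rate exceeds
#'   this (Hz, default 0.5).
#' @return Integer vector of length N with entries 0 (DOWN) or 1 (UP).
#' @export
signatureOf <- function(rates, n_pairs, up_threshold = 0.5) {
  as.integer(rates[eIndices(n_pairs)] > up_threshold)
}

#' Relax the network to an attractor
#'
#' Integrates the autonomous dynamics for up to `settle_time` seconds and
#' decides convergence by either of two criteria: (1) proximity - every unit
#' stays within `tol` Hz of the final state for the last `window` seconds;
#' (2) decay envelope - over the final `envelope_window` seconds the
#' oscillation amplitude around the candidate fixed point (the exact linear
#' fixed point of the current active set), measured as the maximum distance
#' per quarter-window, shrinks strictly from quarter to quarter, in which
#' case the trajectory is extrapolated to that point. Settled rates
#' are refined to the exact linear fixed point of the active set whenever
#' that candidate is valid and within `tol` of the endpoint.
#'
#' @param net an `isn` or [ispParams()].
#' @param r0 initial rates.
#' @param settle_time maximum equilibration time, seconds (default 12).
#' @param dt integration step for settling, seconds (default 1e-4; see
#'   [verifyAttractor()] for the fine-step verification pass).
#' @param tol convergence tolerance, Hz (default 0.5).
#' @param window proximity window, seconds (default 0.5).
#' @param envelope_window decay-envelope window, seconds (default 2).
#' @param sample_dt sampling interval for the convergence checks, seconds.
#' @return List with `converged`, `rates`, `signature`, `settled_by`
#'   (`"proximity"`, `"decay-envelope"` or `NA`), and `t_elapsed`.
#' @export
settleNetwork <- function(net, r0, settle_time = 12, dt = 1e-4, tol = 0.5,
                          window = 0.5, envelope_window = 2,
                          sample_dt = 2e-3) {
  net <- asNetwork(net)
  n <- 2L * net$n_pairs
  stopifnot(length(r0) == n, all(r0 >= 0))
  out <- cpp_settle(net$weights, net$thresholds, as.numeric(r0),
                    net$pair$tau, dt, settle_time, sample_dt, window, tol,
                    TRUE)
  refine <- function(rates) {
    ex <- exactFixedPoint(net, rates > 1e-3)
    if (!is.null(ex) && max(abs(ex - rates)) < tol) ex else rates
  }
  if (out$proximity) {
    rates <- refine(out$final)
    return(list(converged = TRUE, rates = rates,
                signature = signatureOf(rates, net$n_pairs),
                settled_by = "proximity", t_elapsed = out$t_elapsed))
  }
  # decay-envelope: oscillations around the candidate must consistently shrink
  samp <- out$rates
  times <- out$times
  keep <- times >= max(times) - envelope_window
  tail_r <- samp[keep, , drop = FALSE]
  cand <- exactFixedPoint(net, colMeans(tail_r) > 1e-3)
  if (!is.null(cand)) {
    d <- apply(tail_r, 1L, function(r) max(abs(r - cand)))
    # block envelope: the oscillation amplitude, measured as the maximum
    # distance to the candidate in each quarter of the window, must shrink
    # strictly from quarter to quarter
    qrt <- cut(seq_along(d), 4, labels = FALSE)
    env <- tapply(d, qrt, max)
    if (all(diff(env) < 0)) {
      return(list(converged = TRUE, rates = cand,
                  signature = signatureOf(cand, net$n_pairs),
                  settled_by = "decay-envelope", t_elapsed = out$t_elapsed))
    }
  }
  list(converged = FALSE, rates = out$final,
       signature = signatureOf(out$final, net$n_pairs),
       settled_by = NA_character_, t_elapsed = out$t_elapsed)
}

#' Verify that a candidate state is stationary
#'
#' Recomputes the clamped rate derivative at the candidate point.
#'
#' @param net an `isn`.
#' @param rates candidate rate vector.
#' @return Max absolute clamped derivative (Hz/s).
#' @export
verifyAttractor <- function(net, rates) max(abs(rateDerivative(rates, net)))

newCatalogue <- function(states, method, n_pairs, non_converged = 0L) {
  n_states <- if (length(states)) sum(vapply(states, function(s)
    s$multiplicity, numeric(1))) else 0
  structure(list(states = states, n_states = n_states, method = method,
                 n_pairs = n_pairs, non_converged = non_converged),
            class = "attractor_catalogue")
}

#' @export
print.attractor_catalogue <- function(x, ...) {
  cat(sprintf("Attractor catalogue (%s): %d state(s) over %d pairs\n",
              x$method, x$n_states, x$n_pairs))
  if (x$non_converged > 0)
    cat(sprintf("  %d initialization(s) did not converge\n", x$non_converged))
  invisible(x)
}

# match settled rates against catalogued states: signature first, then rates
matchState <- function(states, signature, rates, tol = 0.5) {
  for (s in states) {
    if (identical(s$signature, signature) &&
        max(abs(s$rates - rates)) < tol) return(s$id)
  }
  NA_integer_
}

#' Enumerate the attractor states of a network
#'
#' Exhaustive method: for every one of the 2^N UP/DOWN patterns and each of
#' three initial-rate guesses for the UP pairs (the isolated-pair UP rates
#' scaled by `guesses`), relax the network and collect the distinct settled
#' states (3 * 2^N initializations). Symmetry-reduced method (homogeneous
#' cross-connectivity only): relax one representative pattern per count k of
#' UP pairs (3 * (N+1) initializations) and add `choose(N, k)` states for
#' every k found stable.
#'
#' @param net an `isn`.
#' @param method `"exhaustive"` or `"symmetry"`.
#' @param guesses scale factors for the three UP-rate initial guesses.
#' @param max_pairs_exhaustive cost guard for the exhaustive method.
#' @param ... further arguments to [settleNetwork()].
#' @return An `attractor_catalogue`: states carry exact `rates`,
#'   `signature`, `settled_by`, `multiplicity` and `id`; `n_states` counts
#'   permutation multiplicity for the symmetry-reduced method.
#' @export
enumerateAttractors <- function(net, method = c("exhaustive", "symmetry"),
                                guesses = c(0.5, 1, 2),
                                max_pairs_exhaustive = 12L, ...) {
  net <- asNetwork(net)
  method <- match.arg(method)
  N <- net$n_pairs
  up <- upFixedPoint(net$pair)$location
  initFor <- function(up_pairs, scale) {
    r0 <- numeric(2L * N)
    r0[2L * up_pairs - 1L] <- scale * up[1]
    r0[2L * up_pairs] <- scale * up[2]
    r0
  }
  if (method == "exhaustive") {
    if (N > max_pairs_exhaustive)
      stop("exhaustive enumeration limited to ", max_pairs_exhaustive,
           " pairs (3*2^N initializations)")
    states <- list(); bad <- 0L
    for (code in 0:(2^N - 1)) {
      pat <- which(bitwAnd(code, bitwShiftL(1L, 0:(N - 1L))) > 0)
      for (g in guesses) {
        res <- settleNetwork(net, initFor(pat, g), ...)
        if (!res$converged) { bad <- bad + 1L; next }
        if (is.na(matchState(states, res$signature, res$rates))) {
          states[[length(states) + 1L]] <-
            list(id = length(states) + 1L, rates = res$rates,
                 signature = res$signature, settled_by = res$settled_by,
                 multiplicity = 1)
        }
      }
    }
    return(newCatalogue(states, "exhaustive", N, bad))
  }
  if (!isHomogeneous(net))
    stop("symmetry-reduced enumeration requires homogeneous cross-connectivity")
  states <- list(); bad <- 0L; seen_k <- integer(0)
  for (k in 0:N) {
    for (g in guesses) {
      res <- settleNetwork(net, initFor(seq_len(k), g), ...)
      if (!res$converged) { bad <- bad + 1L; next }
      k_final <- sum(res$signature)
      if (k_final %in% seen_k) next
      # require the symmetric pattern: the settled state groups into
      # identical UP pairs and identical DOWN pairs
      if (!symmetricState(res$rates, N)) next
      seen_k <- c(seen_k, k_final)
      states[[length(states) + 1L]] <-
        list(id = length(states) + 1L, rates = res$rates,
             signature = res$signature, settled_by = res$settled_by,
             multiplicity = choose(N, k_final), k = k_final)
    }
  }
  newCatalogue(states, "symmetry", N, bad)
}

#' Is the cross-connectivity homogeneous?
#'
#' @param net an `isn`.
#' @param tol equality tolerance on the cross entries within each class.
#' @return `TRUE` when, within each connection class, all between-pair
#'   weights are identical.
#' @export
isHomogeneous <- function(net, tol = 1e-12) {
  net <- asNetwork(net)
  N <- net$n_pairs
  if (N == 1) return(TRUE)
  eIdx <- eIndices(N); iIdx <- iIndices(N)
  for (post_set in list(eIdx, iIdx)) {
    for (pre_set in list(eIdx, iIdx)) {
      vals <- c()
      for (post in post_set) {
        pair <- (post + 1L) %/% 2L
        pre <- setdiff(pre_set, pre_set[pair])
        vals <- c(vals, net$weights[post, pre])
      }
      if (length(vals) && diff(range(vals)) > tol) return(FALSE)
    }
  }
  TRUE
}

# UP pairs all share one rate pattern, DOWN pairs another
symmetricState <- function(rates, n_pairs, tol = 1e-6) {
  sig <- signatureOf(rates, n_pairs)
  for (v in c(0L, 1L)) {
    pairs <- which(sig == v)
    if (length(pairs) > 1) {
      re <- rates[2L * pairs - 1L]; ri <- rates[2L * pairs]
      if (diff(range(re)) > tol || diff(range(ri)) > tol) return(FALSE)
    }
  }
  TRUE
}
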