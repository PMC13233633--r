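#' Rectangular current pulse
#'
#' A stimulus is a rectangular pulse of current of amplitude `amplitude`
#' applied from `onset` for `duration` seconds (onset-inclusive,
#' offset-exclusive: the pulse is on for t in \[onset, onset + duration)).
#' A per-unit weight vector distinguishes cue identities; the default of
#' all ones drives every unit identically.
#'
#' @param amplitude pulse amplitude, rate units.
#' @param duration pulse duration, seconds (> 0).
#' @param onset pulse onset, seconds.
#' @param weights optional non-negative per-unit weight vector (length 2N);
#'   `NULL` means uniform.
#' @return An object of class `stimulus_spec`.
#' @export
stimulusSpec <- function(amplitude, duration, onset = 0, weights = NULL) {
  stopifnot(is.finite(amplitude), duration > 0, onset >= 0)
  if (!is.null(weights)) stopifnot(all(weights >= 0))
  structure(list(amplitude = amplitude, duration = duration, onset = onset,
                 weights = weights),
            class = "stimulus_spec")
}

#' Assemble a network object from its parts
#'
#' Low-level constructor; most users build networks with [assembleISN()] or
#' coerce a single pair with [asISN()]. Units are interleaved
#' (E1, I1, E2, I2, ...), so within-pair weights occupy the diagonal
#' 2x2 blocks.
#'
#' @param weights 2N x 2N signed weight matrix.
#' @param thresholds length-2N threshold vector (Hz).
#' @param pair the [ispParams()] shared by every within-pair block.
#' @param meta optional construction record (seed, distribution targets).
#' @return An object of class `isn`.
#' @export
newISN <- function(weights, thresholds, pair, meta = list()) {
  n <- nrow(weights)
  stopifnot(n %% 2 == 0, ncol(weights) == n, length(thresholds) == n,
            inherits(pair, "isp_params"))
  nm <- unitNames(n / 2)
  dimnames(weights) <- list(nm, nm)
  names(thresholds) <- nm
  structure(list(n_pairs = n / 2L, weights = weights,
                 thresholds = thresholds, pair = pair, meta = meta),
            class = "isn")
}

unitNames <- function(n_pairs)
  as.vector(rbind(paste0("e", seq_len(n_pairs)), paste0("i", seq_len(n_pairs))))

eIndices <- function(n_pairs) seq(1L, 2L * n_pairs, by = 2L)
iIndices <- function(n_pairs) seq(2L, 2L * n_pairs, by = 2L)

#' Coerce a single pair to a one-pair network
#'
#' @param p an [ispParams()] object.
#' @return An `isn` with `n_pairs = 1`.
#' @export
asISN <- function(p) {
  stopifnot(inherits(p, "isp_params"))
  newISN(ispWeightMatrix(p), c(p$theta_e, p$theta_i), p,
         meta = list(family = "single pair"))
}

#' @export
print.isn <- function(x, ...) {
  cat(sprintf("Inhibition-stabilized network: %d pair(s), %d units\n",
              x$n_pairs, 2 * x$n_pairs))
  if (!is.null(x$meta$family))
    cat(sprintf("  cross-connectivity: %s\n", x$meta$family))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %d\n", x$meta$seed))
  invisible(x)
}

asNetwork <- function(net) {
  if (inherits(net, "isp_params")) asISN(net) else {
    stopifnot(inherits(net, "isn"))
    net
  }
}

# stack a stimulus list into the argument vectors the C++ integrator takes
stimulusArrays <- function(stimuli, n_units) {
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  k <- length(stimuli)
  amp <- numeric(k); onset <- numeric(k); dur <- numeric(k)
  w <- matrix(1, n_units, max(k, 1L))
  for (j in seq_len(k)) {
    s <- stimuli[[j]]
    stopifnot(inherits(s, "stimulus_spec"))
    amp[j] <- s$amplitude; onset[j] <- s$onset; dur[j] <- s$duration
    if (!is.null(s$weights)) {
      stopifnot(length(s$weights) == n_units)
      w[, j] <- s$weights
    }
  }
  if (k == 0) w <- matrix(1, n_units, 0)
  list(amp = amp, onset = onset, dur = dur, w = w)
}

#' Clamped rate derivative
#'
#' The instantaneous rate of change of the threshold-linear system,
#' `(-r + W r - theta + drive) / tau`, with the projection that units at
#' zero rate whose raw derivative is negative do not decrease.
#'
#' @param r non-negative rate vector, length 2N.
#' @param net an `isn` (or [ispParams()]).
#' @param drive per-unit input current at the evaluation time (scalar is
#'   recycled), rate units.
#' @return Rate-change vector, Hz/s.
#' @export
rateDerivative <- function(r, net, drive = 0) {
  net <- asNetwork(net)
  n <- 2 * net$n_pairs
  if (length(drive) == 1) drive <- rep(drive, n)
  if (length(r) != n || length(drive) != n)
    stop(sprintf("dimension mismatch: network has %d units, got length(r) = %d, length(drive) = %d",
                 n, length(r), length(drive)))
  stopifnot(all(r >= 0))
  dr <- as.vector(-r + net$weights %*% r - net$thresholds + drive) / net$pair$tau
  dr[r <= 0 & dr < 0] <- 0
  dr
}

#' Integrate the network under a stimulus protocol
#'
#' Fourth-order Runge-Kutta integration of the clamped threshold-linear
#' dynamics. Rates are clamped non-negative after every full step; by
#' default the intermediate stage states are clamped too.
#'
#' @param net an `isn` or [ispParams()].
#' @param r0 initial rate vector (length 2N, non-negative).
#' @param stimuli a [stimulusSpec()] or list of them (may be empty).
#' @param t_end end time, seconds.
#' @param dt integration step, seconds (default 1e-5).
#' @param sample_every record every this-many steps (default 100).
#' @param clamp_stages clamp intermediate Runge-Kutta stages (default TRUE).
#' @return An object of class `isn_trajectory`: list with `times`, a
#'   samples-by-units `rates` matrix (columns e1, i1, ...), `final` rates
#'   and the integration `config`.
#' @export
simulateISN <- function(net, r0, stimuli = list(), t_end, dt = 1e-5,
                        sample_every = 100L, clamp_stages = TRUE) {
  net <- asNetwork(net)
  n <- 2 * net$n_pairs
  stopifnot(t_end > 0, dt > 0, length(r0) == n, all(r0 >= 0))
  sa <- stimulusArrays(stimuli, n)
  out <- cpp_simulate(net$weights, net$thresholds, as.numeric(r0),
                      net$pair$tau, dt, t_end, sa$amp, sa$onset, sa$dur, sa$w,
                      as.integer(sample_every), clamp_stages)
  colnames(out$rates) <- unitNames(net$n_pairs)
  structure(list(times = out$times, rates = out$rates, final = out$final,
                 config = list(dt = dt, clamp_stages = clamp_stages,
                               sample_every = sample_every)),
            class = "isn_trajectory")
}

#' @export
print.isn_trajectory <- function(x, ...) {
  cat(sprintf("Rate trajectory: %d samples, %d units, t in [0, %g] s\n",
              length(x$times), ncol(x$rates), max(x$times)))
  invisible(x)
}
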