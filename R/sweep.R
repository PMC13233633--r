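#' State-dependence of one stimulus on a bistable pair
#'
#' Applies the same rectangular pulse once from the DOWN state (the origin)
#' and once from the UP state, relaxes each trajectory, and reports whether
#' both a DOWN-to-UP and an UP-to-DOWN transition occurred. The DOWN state
#' is identified by all rates below `tol` after settling; the UP state by
#' proximity to the closed-form UP fixed point.
#'
#' @param p an [ispParams()] that passes [bistabilityCheck()].
#' @param amplitude,duration stimulus amplitude (rate units) and duration
#'   (seconds).
#' @param settle_time post-stimulus equilibration, seconds (default 12).
#' @param dt_stimulus integration step during the pulse, seconds.
#' @param dt_settle integration step for the equilibration, seconds.
#' @param tol state-identity tolerance, Hz (default 0.5).
#' @return List with logicals `down_to_up`, `up_to_down`, `state_dependent`
#'   and `indeterminate` (`TRUE` when either run failed to converge; the
#'   transition flags are then `NA`).
#' @export
stateDependenceTest <- function(p, amplitude, duration, settle_time = 12,
                                dt_stimulus = 1e-5, dt_settle = 1e-4,
                                tol = 0.5) {
  stopifnot(inherits(p, "isp_params"))
  up <- upFixedPoint(p)$location
  net <- asISN(p)
  finalState <- function(r0) {
    pulse <- simulateISN(net, r0, stimulusSpec(amplitude, duration),
                         t_end = duration, dt = dt_stimulus,
                         sample_every = 1e6L)
    res <- settleNetwork(net, pulse$final, settle_time = settle_time,
                         dt = dt_settle, tol = tol)
    if (!res$converged) return(NA_character_)
    if (all(res$rates < tol)) "down"
    else if (max(abs(res$rates - up)) < tol) "up"
    else NA_character_
  }
  from_down <- finalState(c(0, 0))
  from_up <- finalState(up)
  if (is.na(from_down) || is.na(from_up)) {
    return(list(down_to_up = NA, up_to_down = NA, state_dependent = NA,
                indeterminate = TRUE))
  }
  d2u <- from_down == "up"
  u2d <- from_up == "down"
  list(down_to_up = d2u, up_to_down = u2d,
       state_dependent = d2u && u2d, indeterminate = FALSE)
}

#' Sweep a stimulus grid for state-dependent responses
#'
#' Runs [stateDependenceTest()] on every (amplitude, duration) cell of a
#' grid and summarizes the fraction of state-dependent cells and the
#' resulting [toleranceScore()].
#'
#' @param p an [ispParams()].
#' @param amp_grid,dur_grid positive, sorted stimulus amplitude and duration
#'   grids (linear or log spacing both work; the tolerance uses only the
#'   extremes of the state-dependent set).
#' @param ... passed to [stateDependenceTest()].
#' @return An object of class `sweep_result`: data frame `cells` (amplitude,
#'   duration, down_to_up, up_to_down, state_dependent), plus `f_sd` and
#'   `tolerance`. Indeterminate cells are recorded and excluded from `f_sd`.
#' @export
stimulusSweep <- function(p, amp_grid, dur_grid, ...) {
  stopifnot(all(amp_grid > 0), all(dur_grid > 0),
            !is.unsorted(amp_grid), !is.unsorted(dur_grid))
  cells <- expand.grid(amplitude = amp_grid, duration = dur_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(j)
    stateDependenceTest(p, cells$amplitude[j], cells$duration[j], ...))
  cells$down_to_up <- vapply(res, `[[`, logical(1), "down_to_up")
  cells$up_to_down <- vapply(res, `[[`, logical(1), "up_to_down")
  cells$state_dependent <- vapply(res, `[[`, logical(1), "state_dependent")
  determinate <- !is.na(cells$state_dependent)
  f_sd <- if (any(determinate)) mean(cells$state_dependent[determinate]) else 0
  sd_cells <- cells[determinate & cells$state_dependent, , drop = FALSE]
  tolv <- if (nrow(sd_cells) == 0) 0 else
    toleranceScore(f_sd, sd_cells$amplitude, sd_cells$duration)
  structure(list(cells = cells, f_sd = f_sd, tolerance = tolv,
                 n_indeterminate = sum(!determinate)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Stimulus sweep: %d cells, f_sd = %.3f, tolerance = %.3f\n",
              nrow(x$cells), x$f_sd, x$tolerance))
  if (x$n_indeterminate > 0)
    cat(sprintf("  %d indeterminate cell(s)\n", x$n_indeterminate))
  invisible(x)
}

#' Default log-spaced stimulus grids
#'
#' A 100-fold amplitude range and a 1000-fold duration range, log-spaced.
#'
#' @param n_amp,n_dur grid sizes (default 40 each).
#' @param amp_range,dur_range ranges (rate units; seconds).
#' @return List with `amplitude` and `duration` grids.
#' @export
defaultStimulusGrids <- function(n_amp = 40, n_dur = 40,
                                 amp_range = c(5, 500),
                                 dur_range = c(1e-3, 1)) {
  list(amplitude = 10^seq(log10(amp_range[1]), log10(amp_range[2]),
                          length.out = n_amp),
       duration = 10^seq(log10(dur_range[1]), log10(dur_range[2]),
                         length.out = n_dur))
}
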