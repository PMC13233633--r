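#' Parameters of a single inhibition-stabilized pair
#'
#' An ISP is one excitatory and one inhibitory threshold-linear rate unit
#' with four within-pair weights and two activation thresholds. Weights are
#' signed: connections from the inhibitory unit (`w_ie`, `w_ii`) are stored
#' as non-positive numbers (Dale's law).
#'
#' @param w_ee E-to-E weight, dimensionless, >= 0.
#' @param w_ie I-to-E weight, <= 0.
#' @param w_ei E-to-I weight, >= 0.
#' @param w_ii I-to-I weight, <= 0.
#' @param theta_e,theta_i activation thresholds, rate units (Hz).
#' @param tau rate time constant in seconds (default 0.010 s).
#' @return An object of class `isp_params`.
#' @export
ispParams <- function(w_ee, w_ie, w_ei, w_ii, theta_e, theta_i, tau = 0.010) {
  stopifnot(tau > 0, is.finite(c(w_ee, w_ie, w_ei, w_ii, theta_e, theta_i)))
  if (w_ee < 0 || w_ei < 0)
    stop("excitatory-source weights w_ee, w_ei must be >= 0 (Dale's law)")
  if (w_ie > 0 || w_ii > 0)
    stop("inhibitory-source weights w_ie, w_ii must be <= 0 (Dale's law)")
  structure(list(w_ee = w_ee, w_ie = w_ie, w_ei = w_ei, w_ii = w_ii,
                 theta_e = theta_e, theta_i = theta_i, tau = tau),
            class = "isp_params")
}

#' @export
print.isp_params <- function(x, ...) {
  cat("Inhibition-stabilized pair\n")
  cat(sprintf("  W_EE = %.6g  W_IE = %.6g\n  W_EI = %.6g  W_II = %.6g\n",
              x$w_ee, x$w_ie, x$w_ei, x$w_ii))
  cat(sprintf("  theta_E = %.6g Hz  theta_I = %.6g Hz  tau = %g s\n",
              x$theta_e, x$theta_i, x$tau))
  invisible(x)
}

# 2x2 weight matrix / threshold vector of a bare pair (unit order E, I)
ispWeightMatrix <- function(p) {
  matrix(c(p$w_ee, p$w_ei, p$w_ie, p$w_ii), 2, 2,
         dimnames = list(c("e", "i"), c("e", "i")))
}

#' Non-zero (UP) fixed point of an ISP with constant input
#'
#' Evaluates the closed-form UP fixed point of the two-unit threshold-linear
#' system under a constant input `I` applied to both units, together with the
#' trace and determinant of the Jacobian at that point and its linear
#' stability classification.
#'
#' @param p an [ispParams()] object.
#' @param I constant input current (rate units), default 0.
#' @return An object of class `fp_report`: list with `location` (named
#'   rates `r_e`, `r_i`), `trace` (1/s), `determinant` (1/s^2) and `kind`
#'   (one of `"stable node"`, `"stable spiral"`, `"unstable"`, `"saddle"`,
#'   `"invalid"` when either rate is negative).
#' @export
upFixedPoint <- function(p, I = 0) {
  stopifnot(inherits(p, "isp_params"))
  denom <- (p$w_ii - 1) * (p$w_ee - 1) - p$w_ei * p$w_ie
  if (abs(denom) < 1e-12)
    stop("degenerate system: (W_II-1)(W_EE-1) - W_EI*W_IE is zero")
  r_e <- -(p$w_ie * (p$theta_i - I) + (1 - p$w_ii) * (p$theta_e - I)) / denom
  r_i <- -(p$w_ei * (p$theta_e - I) + (1 - p$w_ee) * (p$theta_i - I)) / denom
  tr <- (p$w_ee + p$w_ii - 2) / p$tau
  det <- denom / p$tau^2
  kind <- classifyJacobian(tr, det)
  if (r_e < 0 || r_i < 0) kind <- "invalid"
  structure(list(location = c(r_e = r_e, r_i = r_i),
                 trace = tr, determinant = det, kind = kind),
            class = "fp_report")
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("Fixed point (r_E*, r_I*) = (%.4f, %.4f) Hz : %s\n",
              x$location[1], x$location[2], x$kind))
  cat(sprintf("  Tr = %.4g /s   Det = %.4g /s^2\n", x$trace, x$determinant))
  invisible(x)
}

# standard planar linear classification from trace and determinant
classifyJacobian <- function(tr, det) {
  if (det < 0) return("saddle")
  if (tr >= 0) return("unstable")
  if (tr^2 > 4 * det) "stable node" else "stable spiral"
}

#' Stability class of the UP fixed point
#'
#' @inheritParams upFixedPoint
#' @return A string: the `kind` field of [upFixedPoint()].
#' @export
classifyUp <- function(p) upFixedPoint(p)$kind

#' Bistability check for a single pair
#'
#' A pair is bistable (coexisting quiescent DOWN state and non-zero UP state)
#' when the inhibitory threshold exceeds the excitatory threshold and both
#' are positive, the inhibitory nullcline has higher gain than the excitatory
#' nullcline, and the UP fixed point is stable with both rates positive.
#'
#' @inheritParams upFixedPoint
#' @return Logical scalar with attributes `reason` (first failed condition,
#'   `"ok"` when bistable) and `report` (the [upFixedPoint()] report, when
#'   computable).
#' @export
bistabilityCheck <- function(p) {
  stopifnot(inherits(p, "isp_params"))
  fail <- function(reason, report = NULL)
    structure(FALSE, reason = reason, report = report)
  if (!(p$theta_i > p$theta_e && p$theta_e > 0))
    return(fail("threshold ordering violated: need theta_I > theta_E > 0"))
  if (p$w_ie == 0)
    return(fail("no feedback inhibition onto E (W_IE = 0)"))
  gain_i <- p$w_ei / (1 - p$w_ii)
  gain_e <- (p$w_ee - 1) / (-p$w_ie)
  if (!(gain_i > gain_e))
    return(fail("inhibitory nullcline gain does not exceed excitatory gain"))
  rep <- tryCatch(upFixedPoint(p), error = function(e) NULL)
  if (is.null(rep)) return(fail("degenerate UP fixed point"))
  if (rep$kind == "invalid")
    return(fail("UP fixed point has a negative rate", rep))
  if (!(rep$kind %in% c("stable node", "stable spiral")))
    return(fail(paste("UP unstable:", rep$kind), rep))
  if (any(rep$location <= 0))
    return(fail("UP fixed point rate not strictly positive", rep))
  structure(TRUE, reason = "ok", report = rep)
}

#' Solve ISP weights from a target Jacobian and UP rates
#'
#' Inverse design of a pair: given the desired trace and determinant of the
#' Jacobian at the UP state, the two firing thresholds and the target UP
#' rates, find the four within-pair weights. Fixing the UP-rate constraints
#' reduces the system to a single linear equation in `W_EE`, so the solution
#' is exact (the round-trip residual is checked against 1e-9).
#'
#' @param trace target Jacobian trace; 1/s unless `dimensionless = TRUE`.
#' @param determinant target Jacobian determinant; 1/s^2 unless
#'   `dimensionless = TRUE`.
#' @param theta_e,theta_i firing thresholds (Hz); require
#'   `theta_i > theta_e > 0`.
#' @param r_e_up,r_i_up target UP rates (Hz), both positive.
#' @param tau time constant, seconds.
#' @param dimensionless if `TRUE`, `trace` and `determinant` are interpreted
#'   as `tau * Tr` and `tau^2 * Det`.
#' @return An [ispParams()] object whose [upFixedPoint()] reproduces the
#'   requested rates, trace and determinant.
#' @export
solveISPFromSpec <- function(trace, determinant, theta_e, theta_i,
                             r_e_up, r_i_up, tau = 0.010,
                             dimensionless = FALSE) {
  stopifnot(r_e_up > 0, r_i_up > 0, tau > 0)
  if (!(theta_i > theta_e && theta_e > 0))
    stop("require theta_i > theta_e > 0 for the bistable regime")
  Tn <- if (dimensionless) trace else tau * trace
  Dn <- if (dimensionless) determinant else tau^2 * determinant
  if (!(Tn < 0 && Dn > 0))
    stop("target UP state must be stable: trace < 0 and determinant > 0")
  # With a = W_EE - 1, d = W_II - 1 and the two fixed-point constraints
  # substituted, the determinant equation is linear in a:
  #   a * (theta_i/r_i - theta_e/r_e) = D + theta_e*theta_i/(r_e*r_i) - theta_e*T/r_e
  slope <- theta_i / r_i_up - theta_e / r_e_up
  if (abs(slope) < 1e-12)
    stop("no solution: theta_i/r_i equals theta_e/r_e (degenerate constraints)")
  a <- (Dn + theta_e * theta_i / (r_e_up * r_i_up) - theta_e * Tn / r_e_up) / slope
  d <- Tn - a
  w_ee <- 1 + a
  w_ii <- 1 + d
  w_ie <- (theta_e - a * r_e_up) / r_i_up
  w_ei <- (theta_i - d * r_i_up) / r_e_up
  if (w_ee < 0 || w_ei < 0 || w_ie > 0 || w_ii > 0)
    stop(sprintf(paste0("solution violates Dale sign convention ",
                        "(W_EE=%.4g, W_IE=%.4g, W_EI=%.4g, W_II=%.4g)"),
                 w_ee, w_ie, w_ei, w_ii))
  p <- ispParams(w_ee, w_ie, w_ei, w_ii, theta_e, theta_i, tau)
  rep <- upFixedPoint(p)
  resid <- max(abs(rep$location - c(r_e_up, r_i_up)),
               abs(p$tau * rep$trace - Tn),
               abs(p$tau^2 * rep$determinant - Dn))
  if (resid > 1e-9)
    stop(sprintf("solver round-trip residual %.3g exceeds 1e-9", resid))
  attr(p, "target") <- list(trace = Tn / tau, determinant = Dn / tau^2,
                            r_e_up = r_e_up, r_i_up = r_i_up)
  p
}

#' Tolerance: log-scale effective diameter of the state-dependent region
#'
#' Converts the fraction of sampled stimuli with state-dependent responses
#' into a scale- and sampling-invariant robustness score: the fold-range
#' (minus one) of an equivalent circle, on log10 axes, with the same area as
#' the state-dependent region.
#'
#' @param f_sd fraction of sampled (amplitude, duration) stimuli with a
#'   state-dependent response, in \[0, 1\].
#' @param amp_set,dur_set positive stimulus amplitudes / durations spanning
#'   the region in which any state-dependent response was seen.
#' @return Non-negative scalar; 0 when `f_sd` is 0.
#' @export
toleranceScore <- function(f_sd, amp_set, dur_set) {
  stopifnot(f_sd >= 0, f_sd <= 1, length(amp_set) >= 1, length(dur_set) >= 1,
            all(amp_set > 0), all(dur_set > 0))
  if (f_sd == 0) return(0)
  area <- (4 * f_sd / pi) *
    log10(max(amp_set) / min(amp_set)) *
    log10(max(dur_set) / min(dur_set))
  10^sqrt(area) - 1
}
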