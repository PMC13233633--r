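#' All six-cue sequences and their majority partition
#'
#' The evidence-accumulation task presents six cues, each left (L) or right
#' (R). The 64 sequences partition into 22 left-majority (>= 4 L), 22
#' right-majority (>= 4 R) and 20 ties (3-3); ties carry no correct answer
#' and are excluded from reliability.
#'
#' @return List with `cues` (64 x 6 integer matrix, 1 = L, 2 = R),
#'   `n_left` (left-cue count per sequence) and `majority`
#'   (`"L"`, `"R"` or `"tie"`).
#' @export
cueSequences <- function() {
  cues <- as.matrix(expand.grid(rep(list(1:2), 6), KEEP.OUT.ATTRS = FALSE))
  dimnames(cues) <- NULL
  n_left <- rowSums(cues == 1L)
  majority <- ifelse(n_left >= 4, "L", ifelse(n_left <= 2, "R", "tie"))
  list(cues = cues, n_left = n_left, majority = majority)
}

#' Task reliability of a machine with the optimal output labeling
#'
#' Traces all 64 six-cue sequences to their final states, groups the
#' non-tie sequences by final state and scores
#' `sum_i max(|S_i n L|, |S_i n R|) / (|L| + |R|)`: the fraction of
#' majority-labeled sequences classified correctly under the per-state
#' majority labeling, which is the globally optimal output function.
#'
#' @param m a total `state_machine`.
#' @return List with `reliability` (in \[0.5, 1\]), `labels` (optimal
#'   per-state output, `"none"` on exact ties or unreached states) and
#'   `final_states` (per-sequence).
#' @export
machineReliability <- function(m) {
  stopifnot(inherits(m, "state_machine"))
  if (m$partial) stop("machine is partial (non-converged edges); refusing to score")
  sq <- cueSequences()
  finals <- traceSequences(m, sq$cues)
  n <- nrow(m$delta)
  labels <- rep("none", n)
  correct <- 0L
  for (i in seq_len(n)) {
    cl <- sum(finals == i & sq$majority == "L")
    cr <- sum(finals == i & sq$majority == "R")
    correct <- correct + max(cl, cr)
    if (cl > cr) labels[i] <- "L" else if (cr > cl) labels[i] <- "R"
  }
  denom <- sum(sq$majority != "tie")
  list(reliability = correct / denom, labels = labels,
       final_states = finals)
}

#' Primacy and recency scores of a machine
#'
#' Over the non-tie sequences whose final-state label is L or R, the
#' fraction whose decision matches the first cue (primacy) and the last cue
#' (recency).
#'
#' @param m a total `state_machine`.
#' @param labels optional per-state labels; defaults to the optimal labeling
#'   from [machineReliability()].
#' @return Named numeric vector `c(primacy = , recency = )` (`NaN` when no
#'   sequence receives a decision).
#' @export
primacyRecency <- function(m, labels = NULL) {
  rel <- machineReliability(m)
  if (is.null(labels)) labels <- rel$labels
  sq <- cueSequences()
  decision <- labels[rel$final_states]
  keep <- sq$majority != "tie" & decision != "none"
  first <- c("L", "R")[sq$cues[, 1]]
  last <- c("L", "R")[sq$cues[, 6]]
  c(primacy = mean(decision[keep] == first[keep]),
    recency = mean(decision[keep] == last[keep]))
}

#' Psychometric curve and logistic-vs-linear fit comparison
#'
#' Computes P(left decision | k left cues), k = 0..6, aggregated over one or
#' more machines. Sequences whose final state is labeled `"none"` contribute
#' half a left decision (and are also tallied separately). Binary decisions
#' (excluding `"none"`) are fit with a logistic regression and a linear
#' probability model and the log-likelihoods compared.
#'
#' @param machines a `state_machine` or list of them (all total).
#' @return List with `curve` (data frame: `n_left`, `p_left`,
#'   `p_none`, `n`), `loglik_logistic`, `loglik_linear` and
#'   `delta_loglik` (logistic minus linear; positive favors the logistic).
#' @export
psychometricCurve <- function(machines) {
  if (inherits(machines, "state_machine")) machines <- list(machines)
  sq <- cueSequences()
  rows <- list()
  for (m in machines) {
    rel <- machineReliability(m)
    decision <- rel$labels[rel$final_states]
    rows[[length(rows) + 1L]] <-
      data.frame(n_left = sq$n_left, decision = decision)
  }
  df <- do.call(rbind, rows)
  df$p <- ifelse(df$decision == "L", 1, ifelse(df$decision == "R", 0, 0.5))
  curve <- do.call(rbind, lapply(0:6, function(k) {
    sub <- df[df$n_left == k, ]
    data.frame(n_left = k, p_left = mean(sub$p),
               p_none = mean(sub$decision == "none"), n = nrow(sub))
  }))
  bin <- df[df$decision != "none", ]
  bin$y <- as.integer(bin$decision == "L")
  fit_log <- suppressWarnings(glm(y ~ n_left, family = binomial(), data = bin))
  fit_lin <- lm(y ~ n_left, data = bin)
  # both models scored by the binomial log-likelihood of the binary
  # decisions at their fitted probabilities (clipped into (0, 1))
  binll <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(bin$y * log(p) + (1 - bin$y) * log(1 - p))
  }
  ll_log <- binll(fitted(fit_log))
  ll_lin <- binll(fitted(fit_lin))
  list(curve = curve, loglik_logistic = ll_log, loglik_linear = ll_lin,
       delta_loglik = ll_log - ll_lin, fit_logistic = fit_log,
       fit_linear = fit_lin)
}

#' Reliability, primacy and recency over a stimulus grid
#'
#' Extracts the machine implemented by the network at every (amplitude,
#' duration) cell for a fixed cue pair and scores it on the task.
#'
#' @param net an `isn`.
#' @param cue_l,cue_r cue weight vectors.
#' @param amp_grid,dur_grid positive stimulus grids.
#' @param ... passed to [extractFSM()].
#' @return Data frame with `amplitude`, `duration`, `reliability`,
#'   `primacy`, `recency`, `n_states`, `partial`. Partial machines get `NA`
#'   scores.
#' @export
reliabilityStimulusSweep <- function(net, cue_l, cue_r, amp_grid, dur_grid,
                                     ...) {
  cells <- expand.grid(amplitude = amp_grid, duration = dur_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$reliability <- NA_real_
  cells$primacy <- NA_real_
  cells$recency <- NA_real_
  cells$n_states <- NA_integer_
  cells$partial <- FALSE
  for (j in seq_len(nrow(cells))) {
    m <- extractFSM(net, cue_l, cue_r, cells$amplitude[j],
                    cells$duration[j], ...)
    cells$n_states[j] <- nrow(m$delta)
    cells$partial[j] <- m$partial
    if (m$partial) next
    rel <- machineReliability(m)
    pr <- primacyRecency(m, rel$labels)
    cells$reliability[j] <- rel$reliability
    cells$primacy[j] <- pr["primacy"]
    cells$recency[j] <- pr["recency"]
  }
  cells
}

#' Heterogeneity experiment: itinerancy and performance vs cross-connection CV
#'
#' For each coefficient of variation, builds `n_matrices` gamma-family
#' networks at fixed class means, enumerates their attractors, sweeps a
#' stimulus grid for itinerancy, and (optionally) scores task reliability
#' for a fixed cue pair over the same grid.
#'
#' @param p within-pair [ispParams()].
#' @param cv_levels non-negative CVs to test (0 is the homogeneous limit).
#' @param n_matrices networks per level (default 10).
#' @param n_pairs network size (default 5).
#' @param amp_grid,dur_grid stimulus grids for the itinerancy sweep.
#' @param beta cross-connection mean multiplier (see [defaultCrossSpec()]).
#' @param cue_seeds optional length-2 integer vector; when given, task
#'   reliability is scored with this cue pair at every grid cell.
#' @param seed base seed; matrix b at level j uses seed
#'   `seed + 1000*j + b`.
#' @param baseline reliability baseline for `frac_above` (default 8/11).
#' @param ... passed to the settling routines.
#' @return Data frame, one row per (cv, matrix): `cv`, `matrix`,
#'   `n_states`, `mean_L`, `max_L`, and when cues are given `max_rel`,
#'   `mean_rel`, `frac_above`.
#' @export
heterogeneityExperiment <- function(p, cv_levels, n_matrices = 10L,
                                    n_pairs = 5L, amp_grid, dur_grid,
                                    beta = 1, cue_seeds = NULL, seed = 1L,
                                    baseline = 8 / 11, ...) {
  out <- list()
  for (j in seq_along(cv_levels)) {
    cv <- cv_levels[j]
    for (b in seq_len(n_matrices)) {
      spec <- defaultCrossSpec(p, beta = beta, family = "gamma", cv = cv)
      net <- assembleISN(p, n_pairs, spec, seed = seed + 1000L * j + b)
      cat_ex <- enumerateAttractors(net, "exhaustive", ...)
      itin <- itinerancySweep(net, cat_ex, amp_grid, dur_grid, ...)
      row <- data.frame(cv = cv, matrix = b, n_states = cat_ex$n_states,
                        mean_L = mean(itin$L, na.rm = TRUE),
                        max_L = max(itin$L, na.rm = TRUE))
      if (!is.null(cue_seeds)) {
        cl <- makeCueVector(n_pairs, cue_seeds[1], "L")
        cr <- makeCueVector(n_pairs, cue_seeds[2], "R")
        rel <- reliabilityStimulusSweep(net, cl, cr, amp_grid, dur_grid, ...)
        row$max_rel <- suppressWarnings(max(rel$reliability, na.rm = TRUE))
        row$mean_rel <- mean(rel$reliability, na.rm = TRUE)
        row$frac_above <- mean(rel$reliability > baseline, na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Fit exponential growth of state counts with network size
#'
#' Least-squares fit of `y = a * b^x + c` to (size, count) data.
#'
#' @param sizes network sizes x (>= 4 points).
#' @param counts observed state counts y.
#' @return List with `a`, `b`, `c`, `fitted`, `degenerate` (`TRUE` when the
#'   data are constant and the family collapses) and the `nls` fit object
#'   (`NULL` when degenerate).
#' @export
fitExponentialGrowth <- function(sizes, counts) {
  stopifnot(length(sizes) == length(counts), length(sizes) >= 4)
  if (diff(range(counts)) == 0) {
    return(list(a = 0, b = 1, c = counts[1], fitted = counts,
                degenerate = TRUE, fit = NULL))
  }
  # log-difference heuristic for starting values
  o <- order(sizes)
  xs <- sizes[o]; ys <- counts[o]
  dy <- diff(ys)
  b0 <- if (all(dy > 0)) exp(mean(diff(log(dy)) / diff(xs[-1]))) else 1.5
  if (!is.finite(b0) || b0 <= 1) b0 <- 1.5
  a0 <- max((ys[length(ys)] - ys[1]) / (b0^xs[length(xs)] - b0^xs[1]), 1e-6)
  c0 <- ys[1] - a0 * b0^xs[1]
  fit <- minpack.lm::nlsLM(y ~ a * b^x + c,
                           data = data.frame(x = sizes, y = counts),
                           start = list(a = a0, b = b0, c = c0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       fitted = as.numeric(fitted(fit)), degenerate = FALSE, fit = fit)
}
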