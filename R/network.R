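#' Cross-connectivity specification
#'
#' Target statistics for the weak random connections between pairs, one
#' (mean, sd) pair per connection class: `ee` (E to E), `ei` (E to I),
#' `ie` (I to E), `ii` (I to I). Targets are magnitudes before Dale signs
#' and before the 1/N scaling applied at assembly; each accepted row must
#' match its target mean to within `mean_tol` (relative) and its target sd
#' to within `sd_tol`.
#'
#' @param family `"lognormal"`, `"gamma"` or `"homogeneous"` (all entries
#'   exactly at the class mean).
#' @param mean named numeric vector of positive class means
#'   (`ee`, `ei`, `ie`, `ii`).
#' @param cv coefficient of variation shared by all classes (sd = cv * mean);
#'   0 collapses to the homogeneous limit.
#' @param mean_tol,sd_tol relative acceptance tolerances for the row
#'   resampling (defaults 5% and 10%).
#' @return An object of class `cross_spec`.
#' @export
crossSpec <- function(family = c("lognormal", "gamma", "homogeneous"),
                      mean, cv = 0.5, mean_tol = 0.05, sd_tol = 0.10) {
  family <- match.arg(family)
  stopifnot(length(mean) == 4, all(mean >= 0), cv >= 0,
            mean_tol > 0, sd_tol > 0)
  if (is.null(names(mean))) names(mean) <- c("ee", "ei", "ie", "ii")
  stopifnot(setequal(names(mean), c("ee", "ei", "ie", "ii")))
  if (cv == 0) family <- "homogeneous"
  structure(list(family = family, mean = mean[c("ee", "ei", "ie", "ii")],
                 cv = cv, mean_tol = mean_tol, sd_tol = sd_tol),
            class = "cross_spec")
}

#' Default cross-connectivity targets for a given pair
#'
#' Sets each class mean to `beta/10` times the magnitude of the matching
#' within-pair weight, so the summed cross input of each class is roughly a
#' tenth of the within-pair input at `beta = 1` (the within-pair-dominated
#' regime that produces inhibitory stabilization).
#'
#' @param p an [ispParams()].
#' @param beta multiplier on the cross-connection class means.
#' @inheritParams crossSpec
#' @return A [crossSpec()].
#' @export
defaultCrossSpec <- function(p, beta = 1, family = "lognormal", cv = 0.5) {
  stopifnot(inherits(p, "isp_params"), beta >= 0)
  m <- beta / 10 * abs(c(ee = p$w_ee, ei = p$w_ei, ie = p$w_ie, ii = p$w_ii))
  crossSpec(family, m, cv)
}

# draw n magnitudes from the chosen family with arithmetic mean m, sd s
drawMagnitudes <- function(n, m, s, family) {
  switch(family,
    homogeneous = rep(m, n),
    lognormal = {
      sigma2 <- log(1 + (s / m)^2)
      rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    gamma = {
      shape <- (m / s)^2
      rgamma(n, shape = shape, rate = shape / m)
    })
}

#' Sample one row of cross-connection magnitudes
#'
#' Draws `n_targets` magnitudes from the requested family and resamples the
#' whole row until its sample mean is within `mean_tol` of the target and
#' (for rows of two or more entries with a non-zero sd target) its sample sd
#' within `sd_tol`, so every unit receives near-identical summed input from
#' each connection class. Signs are applied by the caller according to the
#' presynaptic class.
#'
#' @param n_targets number of connections in the row (>= 1).
#' @param m,s target arithmetic mean and sd of the magnitudes.
#' @param family distribution family (see [crossSpec()]).
#' @param mean_tol,sd_tol relative acceptance tolerances.
#' @param max_tries resampling cap (default 10000).
#' @return Numeric vector of `n_targets` positive magnitudes.
#' @export
sampleCrossRow <- function(n_targets, m, s, family = "lognormal",
                           mean_tol = 0.05, sd_tol = 0.10,
                           max_tries = 10000L) {
  stopifnot(n_targets >= 1, m >= 0, s >= 0)
  if (m == 0) return(rep(0, n_targets))
  if (s == 0 || family == "homogeneous") return(rep(m, n_targets))
  check_sd <- n_targets >= 2
  for (try in seq_len(max_tries)) {
    x <- drawMagnitudes(n_targets, m, s, family)
    ok <- abs(mean(x) - m) / m <= mean_tol &&
      (!check_sd || abs(sd(x) - s) / s <= sd_tol)
    if (ok) return(x)
  }
  stop(sprintf(paste0("infeasible row statistics: no draw of %d values matched ",
                      "mean %.4g (5%%) / sd %.4g (10%%) in %d attempts ",
                      "(last draw: mean %.4g, sd %.4g)"),
               n_targets, m, s, max_tries, mean(x),
               if (check_sd) sd(x) else NA))
}

#' Assemble an inhibition-stabilized network
#'
#' Builds a 2N-unit network: every within-pair 2x2 block is set exactly to
#' `p`, and the between-pair connections are sampled row by row and class by
#' class from `spec`, with class means and sds scaled by 1/N so the total
#' cross input per unit stays constant as the network grows. Dale's law is
#' enforced by the presynaptic class sign.
#'
#' @param p the within-pair [ispParams()]; must pass [bistabilityCheck()].
#' @param n_pairs number of pairs N (>= 1).
#' @param spec a [crossSpec()]; `NULL` (the default) uses
#'   [defaultCrossSpec()].
#' @param seed optional integer seed recorded in the metadata; when given,
#'   identical calls are bit-identical.
#' @return An `isn` object.
#' @export
assembleISN <- function(p, n_pairs, spec = NULL, seed = NULL) {
  stopifnot(inherits(p, "isp_params"), n_pairs >= 1)
  bi <- bistabilityCheck(p)
  if (!bi) stop("pair is not bistable: ", attr(bi, "reason"))
  if (is.null(spec)) spec <- defaultCrossSpec(p)
  stopifnot(inherits(spec, "cross_spec"))
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_pairs)
  n <- 2L * N
  W <- matrix(0, n, n)
  eIdx <- eIndices(N); iIdx <- iIndices(N)
  for (k in seq_len(N)) {
    b <- 2L * (k - 1L)
    W[b + 1L, b + 1L] <- p$w_ee; W[b + 1L, b + 2L] <- p$w_ie
    W[b + 2L, b + 1L] <- p$w_ei; W[b + 2L, b + 2L] <- p$w_ii
  }
  if (N > 1) {
    classes <- list(
      ee = list(post = eIdx, pre = eIdx, sign = +1),
      ie = list(post = eIdx, pre = iIdx, sign = -1),
      ei = list(post = iIdx, pre = eIdx, sign = +1),
      ii = list(post = iIdx, pre = iIdx, sign = -1))
    for (cls in names(classes)) {
      cl <- classes[[cls]]
      m <- spec$mean[[cls]] / N
      s <- spec$cv * m
      for (post in cl$post) {
        own_pair <- (post + 1L) %/% 2L
        pre <- setdiff(cl$pre, cl$pre[own_pair])
        W[post, pre] <- cl$sign *
          sampleCrossRow(length(pre), m, s, spec$family,
                         spec$mean_tol, spec$sd_tol)
      }
    }
  }
  theta <- rep(c(p$theta_e, p$theta_i), N)
  newISN(W, theta, p,
         meta = list(family = spec$family, cv = spec$cv,
                     base_mean = spec$mean, seed = seed))
}

#' Cue weight vector
#'
#' Per-unit input weights identifying one cue: entries drawn from a standard
#' log-normal distribution and rescaled to unit mean.
#'
#' @param n_pairs number of pairs N.
#' @param seed optional integer seed for reproducibility.
#' @param label cue identity label (e.g. `"L"` or `"R"`).
#' @return An object of class `cue_vector`: list with `weights` (length 2N,
#'   positive, mean exactly 1), `label` and `seed`.
#' @export
makeCueVector <- function(n_pairs, seed = NULL, label = "cue") {
  stopifnot(n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- rlnorm(2L * n_pairs, 0, 1)
  w <- w / mean(w)
  structure(list(weights = w, label = label, seed = seed),
            class = "cue_vector")
}

#' Dale's-law column-sign check
#'
#' @param net an `isn`.
#' @return `TRUE` if every column of the weight matrix has the sign of its
#'   presynaptic unit type (E columns >= 0, I columns <= 0).
#' @export
daleCheck <- function(net) {
  net <- asNetwork(net)
  eIdx <- eIndices(net$n_pairs); iIdx <- iIndices(net$n_pairs)
  all(net$weights[, eIdx] >= 0) && all(net$weights[, iIdx] <= 0)
}

#' Within-pair vs cross-pair input dominance
#'
#' Ratio of summed within-pair incoming weight magnitude to summed
#' cross-pair incoming weight magnitude, per unit. Values above 1 indicate
#' the within-pair-dominated regime.
#'
#' @param net an `isn`.
#' @return Numeric vector, one ratio per unit (Inf for an isolated pair).
#' @export
couplingDominance <- function(net) {
  net <- asNetwork(net)
  n <- 2L * net$n_pairs
  ratio <- numeric(n)
  for (u in seq_len(n)) {
    pair <- (u + 1L) %/% 2L
    own <- c(2L * pair - 1L, 2L * pair)
    within <- sum(abs(net$weights[u, own]))
    cross <- sum(abs(net$weights[u, -own]))
    ratio[u] <- if (cross == 0) Inf else within / cross
  }
  names(ratio) <- unitNames(net$n_pairs)
  ratio
}
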