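# independent oracle: steady state of the linear (unclamped) 2x2 system
linearSteadyState <- function(p, I = 0) {
  W <- rbind(c(p$w_ee, p$w_ie), c(p$w_ei, p$w_ii))
  solve(diag(2) - W, c(I - p$theta_e, I - p$theta_i))
}

test_that("UP fixed point matches an independent 2x2 linear solve", {
  p <- ispParams(2, -1, 3, -0.5, 1, 3)
  fp <- upFixedPoint(p)
  expect_equal(unname(fp$location), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(fp$location), linearSteadyState(p), tolerance = 1e-12)
  # and under non-zero constant input
  p2 <- fiducialISP()
  expect_equal(unname(upFixedPoint(p2, I = 3)$location),
               linearSteadyState(p2, I = 3), tolerance = 1e-10)
})

test_that("zero-weight zero-threshold pair has its fixed point at the origin", {
  p <- ispParams(0, 0, 0, 0, 0, 1e-12)
  expect_equal(unname(upFixedPoint(p)$location), c(0, 0), tolerance = 1e-9)
})

test_that("degenerate denominator raises an explicit error", {
  # (W_II - 1)(W_EE - 1) = W_EI * W_IE with w_ee=2, w_ii=-1: -2 = w_ei*w_ie
  p <- ispParams(2, -1, 2, -1, 1, 3)
  expect_error(upFixedPoint(p), "degenerate")
})

test_that("trace/determinant classification matches the worked spiral case", {
  p <- ispParams(2, -1, 3, -0.5, 1, 3, tau = 0.01)
  fp <- upFixedPoint(p)
  expect_equal(fp$trace, -50)
  expect_equal(fp$determinant, 1.5e4)
  expect_true(fp$trace^2 < 4 * fp$determinant)
  expect_identical(classifyUp(p), "stable spiral")
})

test_that("positive trace is unstable and negative determinant a saddle", {
  # w_ee + w_ii > 2 gives Tr > 0
  p_un <- ispParams(3.5, -3, 2, -0.5, 1, 3)
  expect_identical(upFixedPoint(p_un)$kind, "unstable")
  # determinant < 0 with both fixed-point rates positive
  p_sad <- ispParams(2.5, -0.3, 2, -0.2, 1, 1.2)
  fp <- upFixedPoint(p_sad)
  expect_lt(fp$determinant, 0)
  expect_true(all(fp$location > 0))
  expect_identical(fp$kind, "saddle")
})

# re-derive the kind ignoring rate validity, as the eigen oracle does
classifyJacobianForTest <- function(tr, det) {
  if (det < 0) "saddle"
  else if (tr >= 0) "unstable"
  else if (tr^2 > 4 * det) "stable node" else "stable spiral"
}

test_that("classification agrees with an eigen-decomposition of the Jacobian", {
  set.seed(42)
  for (i in 1:50) {
    p <- ispParams(runif(1, 0, 3), -runif(1, 0.05, 3), runif(1, 0.05, 3),
                   -runif(1, 0, 3), 1, 3, tau = 0.01)
    J <- rbind(c(p$w_ee - 1, p$w_ie), c(p$w_ei, p$w_ii - 1)) / p$tau
    ev <- eigen(J, only.values = TRUE)$values
    expected <- if (is.complex(ev)) {
      if (all(Re(ev) < 0)) "stable spiral" else "unstable"
    } else {
      if (all(ev < 0)) "stable node"
      else if (all(ev > 0)) "unstable" else "saddle"
    }
    fp <- upFixedPoint(p)
    kind <- classifyJacobianForTest(fp$trace, fp$determinant)
    expect_identical(kind, expected)
  }
})

test_that("bistability requires the threshold ordering and nullcline gains", {
  expect_true(bistabilityCheck(fiducialISP()))
  p_eq <- ispParams(2, -1, 3, -0.5, 3, 3)
  res <- bistabilityCheck(p_eq)
  expect_false(res)
  expect_match(attr(res, "reason"), "threshold ordering")
  # unstable UP state is rejected with a diagnostic
  p_un <- ispParams(3.5, -3, 2, -0.5, 1, 3)
  res2 <- bistabilityCheck(p_un)
  expect_false(res2)
  expect_match(attr(res2, "reason"), "UP unstable")
})

test_that("an unstable UP state lets simulation escape the fixed point", {
  p_un <- ispParams(3.5, -3, 2, -0.5, 1, 3)
  fp <- unname(upFixedPoint(p_un)$location)
  tr <- simulateISN(p_un, pmax(fp + 0.01, 0), list(), t_end = 1, dt = 1e-4)
  expect_gt(max(abs(tr$final - fp)), 1)
})

test_that("inverse solve round-trips rates, trace and determinant to 1e-9", {
  for (tr in c(-20, -50, -120)) {
    for (det in c(5e3, 1.5e4, 4e4)) {
      p <- solveISPFromSpec(tr, det, 5.34, 82.43, 5, 10)
      fp <- upFixedPoint(p)
      expect_lt(max(abs(unname(fp$location) - c(5, 10))), 1e-9)
      expect_lt(abs(fp$trace - tr), 1e-9 / p$tau)
      expect_lt(abs(fp$determinant - det), 1e-9 / p$tau^2)
      # definitional trace identity
      expect_equal((p$w_ee + p$w_ii - 2) / p$tau, tr, tolerance = 1e-12)
    }
  }
})

test_that("solved pairs at the printed thresholds are bistable spirals when requested", {
  p <- fiducialISP()
  expect_true(bistabilityCheck(p))
  expect_identical(classifyUp(p), "stable spiral")
  expect_equal(unname(upFixedPoint(p)$location), c(5, 10), tolerance = 1e-10)
})

test_that("inverse solve agrees with a brute-force grid search", {
  target_tr <- -50; target_det <- 1.5e4
  tau <- 0.01
  # oracle: scan w_ee, derive the remaining weights from the trace and
  # fixed-point constraints, pick the grid point whose determinant is closest
  w_ee_grid <- seq(1.01, 4, by = 1e-4)
  best <- Inf; best_wee <- NA
  for (w_ee in w_ee_grid) {
    w_ii <- 2 + tau * target_tr - w_ee
    a <- w_ee - 1; d <- w_ii - 1
    w_ie <- (5.34 - a * 5) / 10
    w_ei <- (82.43 - d * 10) / 5
    det <- (a * d - w_ei * w_ie) / tau^2
    if (abs(det - target_det) < best) { best <- abs(det - target_det); best_wee <- w_ee }
  }
  p <- solveISPFromSpec(target_tr, target_det, 5.34, 82.43, 5, 10)
  expect_lt(abs(p$w_ee - best_wee), 1e-4)
})

test_that("inverse solve rejects unstable targets and degenerate constraints", {
  expect_error(solveISPFromSpec(10, 1.5e4, 5.34, 82.43, 5, 10), "stable")
  expect_error(solveISPFromSpec(-50, -100, 5.34, 82.43, 5, 10), "stable")
  # theta_i / r_i == theta_e / r_e collapses the linear equation
  expect_error(solveISPFromSpec(-50, 1.5e4, 5, 10, 5, 10), "no solution")
})

test_that("dimensionless trace/determinant inputs are accepted", {
  p1 <- solveISPFromSpec(-50, 1.5e4, 5.34, 82.43, 5, 10, tau = 0.01)
  p2 <- solveISPFromSpec(-0.5, 1.5, 5.34, 82.43, 5, 10, tau = 0.01,
                         dimensionless = TRUE)
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-12)
})

test_that("tolerance reproduces the worked circular-coverage values", {
  expect_equal(toleranceScore(pi / 4, c(1, 10), c(1e-3, 1e-2)), 9,
               tolerance = 1e-12)
  expect_identical(toleranceScore(0, c(1, 10), c(1, 10)), 0)
  expect_equal(toleranceScore(1, c(1, 10), c(1, 10)),
               10^(2 / sqrt(pi)) - 1, tolerance = 1e-12)
})

test_that("tolerance is monotone non-decreasing in the state-dependent fraction", {
  f <- seq(0, 1, by = 0.05)
  v <- sapply(f, toleranceScore, amp_set = c(2, 80), dur_set = c(1e-3, 0.3))
  expect_true(all(diff(v) >= 0))
})
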