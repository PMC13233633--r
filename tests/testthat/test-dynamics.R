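test_that("origin is a fixed point when thresholds are positive", {
  p <- ispParams(2, -1, 3, -0.5, 1, 3)
  expect_equal(rateDerivative(c(0, 0), p), c(0, 0))
  tr <- simulateISN(p, c(0, 0), list(), t_end = 0.05, dt = 1e-5)
  expect_identical(tr$final, c(0, 0))
})

test_that("pure leak: uncoupled unit with zero threshold decays at rate 1/tau", {
  net <- newISN(matrix(0, 2, 2), c(0, 0), ispParams(0, 0, 0, 0, 0, 1, 0.01))
  expect_equal(rateDerivative(c(1, 0), net), c(-1 / 0.01, 0))
})

test_that("rate derivative rejects mismatched dimensions", {
  p <- fiducialISP()
  expect_error(rateDerivative(c(1, 1, 1), p), "dimension mismatch")
  expect_error(rateDerivative(c(1, 1), p, drive = c(1, 2, 3)),
               "dimension mismatch")
})

test_that("derivative vanishes at the closed-form UP point, with and without drive", {
  p <- fiducialISP()
  for (I in c(0, 2.5)) {
    fp <- upFixedPoint(p, I)
    expect_lt(max(abs(rateDerivative(unname(fp$location), p, drive = I))),
              1e-9)
  }
})

test_that("integration matches the closed-form exponential decay", {
  net <- newISN(matrix(0, 2, 2), c(0, 0), ispParams(0, 0, 0, 0, 0, 1, 0.01))
  tr <- simulateISN(net, c(1, 0), list(), t_end = 0.02, dt = 1e-5,
                    sample_every = 500)
  expect_lt(max(abs(tr$rates[, 1] - exp(-tr$times / 0.01))), 1e-8)
})

test_that("error against the linear closed form scales like dt^4", {
  net <- newISN(matrix(0, 2, 2), c(0, 0), ispParams(0, 0, 0, 0, 0, 1, 0.01))
  err <- sapply(c(1e-4, 2e-4), function(dt) {
    tr <- simulateISN(net, c(1, 0), list(), t_end = 0.01, dt = dt,
                      sample_every = 1e6)
    abs(tr$final[1] - exp(-0.01 / 0.01))
  })
  ratio <- err[2] / err[1]
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("a unit clamped at zero under net negative drive stays exactly zero", {
  # inhibitory unit drives E below threshold; E starts at 0 and must not move
  p <- ispParams(0, -2, 0, 0, 1, 0.5, 0.01)
  tr <- simulateISN(p, c(0, 3), list(), t_end = 0.05, dt = 1e-5)
  expect_true(all(tr$rates[, 1] == 0))
})

test_that("trajectories are autonomous: zero-amplitude stimuli change nothing", {
  p <- fiducialISP()
  r0 <- c(3, 4)
  a <- simulateISN(p, r0, list(), t_end = 0.1, dt = 2e-5)
  b <- simulateISN(p, r0, stimulusSpec(0, duration = 0.01, onset = 0.03),
                   t_end = 0.1, dt = 2e-5)
  expect_identical(a$rates, b$rates)
})

test_that("all sampled rates are non-negative along stimulated trajectories", {
  p <- fiducialISP()
  tr <- simulateISN(p, c(0, 0), stimulusSpec(52.15, 1e-3), t_end = 0.5,
                    dt = 1e-5, sample_every = 50)
  expect_true(all(tr$rates >= 0))
})

test_that("the reference pulse flips the fiducial pair from DOWN to UP and back", {
  # rectangular pulse I_app = 52.15 for 1 ms, uniform weights
  p <- fiducialISP()
  res <- stateDependenceTest(p, 52.15, 1e-3)
  expect_true(res$down_to_up)
  expect_true(res$up_to_down)
  expect_true(res$state_dependent)
})

test_that("halving the step leaves the settled state unchanged to 0.01 Hz", {
  p <- fiducialISP()
  finals <- lapply(c(1e-5, 5e-6), function(dt) {
    tr <- simulateISN(p, c(0, 0), stimulusSpec(52.15, 1e-3), t_end = 0.5,
                      dt = dt, sample_every = 1e6)
    tr$final
  })
  expect_lt(max(abs(finals[[1]] - finals[[2]])), 0.01)
})

test_that("stage clamping is optional but the full-step clamp always applies", {
  p <- fiducialISP()
  tr <- simulateISN(p, c(0, 0), stimulusSpec(52.15, 1e-3), t_end = 0.2,
                    dt = 1e-5, clamp_stages = FALSE)
  expect_true(all(tr$rates >= 0))
})

test_that("stimulus pulse is onset-inclusive and offset-exclusive", {
  # a unit with theta = 0 integrates the pulse; duration exactly tau_dur
  net <- newISN(matrix(0, 2, 2), c(0, 0), ispParams(0, 0, 0, 0, 0, 1, 0.01))
  dur <- 1e-3
  tr <- simulateISN(net, c(0, 0), stimulusSpec(10, dur, onset = 0),
                    t_end = dur, dt = 1e-5, sample_every = 1e6)
  # closed form for tau dr = -r + I on [0, dur); the step straddling the
  # offset discontinuity contributes an O(dt) local error
  expect_equal(tr$final[1], 10 * (1 - exp(-dur / 0.01)), tolerance = 1e-2)
})
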