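test_that("the 64 sequences partition into 22 / 22 / 20", {
  sq <- cueSequences()
  expect_identical(nrow(sq$cues), 64L)
  expect_identical(sum(sq$majority == "L"), 22L)
  expect_identical(sum(sq$majority == "R"), 22L)
  expect_identical(sum(sq$majority == "tie"), 20L)
})

test_that("reference machines score 0.50, 8/11 and 1.00", {
  expect_equal(machineReliability(referenceMachine("one_state"))$reliability,
               0.5)
  expect_equal(machineReliability(referenceMachine("last_cue"))$reliability,
               8 / 11, tolerance = 1e-12)
  expect_equal(machineReliability(referenceMachine("first_cue"))$reliability,
               8 / 11, tolerance = 1e-12)
  expect_equal(machineReliability(referenceMachine("counter"))$reliability,
               1)
})

test_that("every single-position decision rule scores exactly 8/11", {
  # independent oracle: score the partition directly, no machine involved
  sq <- cueSequences()
  for (pos in 1:6) {
    for (pol in 1:2) {
      decided_l <- sq$cues[, pos] == pol
      score <- 0
      for (side in c(TRUE, FALSE)) {
        grp <- decided_l == side
        score <- score + max(sum(grp & sq$majority == "L"),
                             sum(grp & sq$majority == "R"))
      }
      expect_equal(score / 44, 8 / 11, tolerance = 1e-12)
    }
  }
})

test_that("reliability is bounded in [0.5, 1] for arbitrary machines", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    delta <- matrix(sample(n, 2 * n, replace = TRUE), n, 2)
    rel <- machineReliability(stateMachine(delta))$reliability
    expect_gte(rel, 0.5)
    expect_lte(rel, 1)
  }
})

test_that("per-state majority labeling is optimal among all labelings", {
  sq <- cueSequences()
  set.seed(12)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    m <- stateMachine(matrix(sample(n, 2 * n, replace = TRUE), n, 2))
    rel <- machineReliability(m)
    finals <- rel$final_states
    # oracle: exhaustive search over all 3^n labelings
    labs <- c("L", "R", "none")
    grid <- expand.grid(rep(list(labs), n), stringsAsFactors = FALSE)
    best <- max(apply(grid, 1, function(lab) {
      dec <- lab[finals]
      sum(dec == sq$majority & sq$majority != "tie") / 44
    }))
    expect_equal(rel$reliability, best, tolerance = 1e-12)
  }
})

test_that("partial machines are refused", {
  m <- stateMachine(rbind(c(2L, NA), c(1L, 2L)))
  expect_true(m$partial)
  expect_error(machineReliability(m), "partial")
})

test_that("primacy and recency match enumeration for the positional deciders", {
  sq <- cueSequences()
  pr_last <- primacyRecency(referenceMachine("last_cue"))
  expect_equal(unname(pr_last["recency"]), 1)
  # oracle: over non-tie sequences, P(first cue == last cue)
  nontie <- sq$majority != "tie"
  expect_equal(unname(pr_last["primacy"]),
               mean(sq$cues[nontie, 1] == sq$cues[nontie, 6]),
               tolerance = 1e-12)
  pr_first <- primacyRecency(referenceMachine("first_cue"))
  expect_equal(unname(pr_first["primacy"]), 1)
  expect_equal(unname(pr_first["recency"]),
               mean(sq$cues[nontie, 1] == sq$cues[nontie, 6]),
               tolerance = 1e-12)
})

test_that("psychometric curves match counting arguments", {
  # perfect counter: forced step curve
  ps <- psychometricCurve(referenceMachine("counter"))
  expect_equal(ps$curve$p_left[ps$curve$n_left >= 4], rep(1, 3))
  expect_equal(ps$curve$p_left[ps$curve$n_left <= 2], rep(0, 3))
  # last-cue decider: P(left | k) = k/6 by exchangeability
  ps2 <- psychometricCurve(referenceMachine("last_cue"))
  expect_equal(ps2$curve$p_left, (0:6) / 6, tolerance = 1e-12)
  # the step curve is better described by the logistic than the line
  expect_gte(ps$delta_loglik, 0)
})

test_that("sub-threshold cue amplitudes leave the network at chance", {
  net <- fiducialNet5()
  cl <- makeCueVector(5, 101, "L")
  cr <- makeCueVector(5, 901, "R")
  sweep <- reliabilityStimulusSweep(net, cl, cr, amp_grid = c(0.2, 0.5),
                                    dur_grid = c(0.01))
  expect_true(all(sweep$reliability == 0.5))
  expect_true(all(sweep$n_states == 1))
})

test_that("exponential growth fits recover exact and noisy coefficients", {
  x <- 2:8
  y <- 0.75 * 2.02^x
  fit <- fitExponentialGrowth(x, y)
  expect_lt(abs(fit$a - 0.75), 1e-6)
  expect_lt(abs(fit$b - 2.02), 1e-6)
  expect_lt(abs(fit$c), 1e-6)
  # constant data collapse the family
  expect_true(fitExponentialGrowth(2:6, rep(4, 5))$degenerate)
  # noisy recovery: median error within 10%
  set.seed(13)
  errs <- replicate(100, {
    yn <- pmax(y + rnorm(length(y), 0, 0.05 * y), 0.1)
    f <- tryCatch(fitExponentialGrowth(x, yn), error = function(e) NULL)
    if (is.null(f)) NA else abs(f$b - 2.02) / 2.02
  })
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})
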