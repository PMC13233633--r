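test_that("zero-amplitude stimuli give the identity transition map", {
  net <- fiducialNet5()
  cat5 <- fiducialCat5()
  g <- transitionGraph(net, cat5, amplitude = 0, duration = 0.01)
  expect_identical(g$targets, seq_along(g$targets))
  expect_identical(longestItinerantPath(g), 0L)
})

test_that("longest path follows the walk-until-repeat convention", {
  # identity map
  expect_identical(longestItinerantPath(1:4), 0L)
  # chain a -> b -> c -> d -> c: from a, four transitions
  expect_identical(longestItinerantPath(c(2L, 3L, 4L, 3L)), 4L)
  # two-cycle: a -> b -> a counts both edges
  expect_identical(longestItinerantPath(c(2L, 1L)), 2L)
  # non-converged edges terminate the walk where they are hit
  expect_identical(longestItinerantPath(c(2L, NA, 1L)), 2L)
})

test_that("longest path agrees with a brute-force walk enumeration", {
  # oracle: explicitly replay every start with a visited list
  oracle <- function(targets) {
    lens <- sapply(seq_along(targets), function(s) {
      seen <- s; len <- 0
      repeat {
        nxt <- targets[tail(seen, 1)]
        if (is.na(nxt) || nxt == tail(seen, 1)) break
        len <- len + 1
        if (nxt %in% seen) break
        seen <- c(seen, nxt)
      }
      len
    })
    max(lens)
  }
  set.seed(7)
  for (i in 1:30) {
    n <- sample(2:12, 1)
    targets <- sample(n, n, replace = TRUE)
    expect_identical(longestItinerantPath(targets), as.integer(oracle(targets)))
  }
})

test_that("the fiducial pair's printed pulse flips both states bidirectionally", {
  p <- fiducialISP()
  cat1 <- enumerateAttractors(asISN(p), "exhaustive")
  g <- transitionGraph(asISN(p), cat1, amplitude = 52.15, duration = 1e-3)
  # two states, each mapping to the other
  expect_identical(sort(g$targets), 1:2)
  expect_true(all(g$targets != seq_along(g$targets)))
})

test_that("an overwhelming stimulus erases history", {
  net <- fiducialNet5()
  cat5 <- fiducialCat5()
  g <- transitionGraph(net, cat5, amplitude = 2000, duration = 0.05)
  expect_identical(length(unique(g$targets)), 1L)
})

test_that("a heterogeneous network exceeds the homogeneous itinerancy bound", {
  net <- fiducialNet5()
  cat5 <- fiducialCat5()
  it <- itinerancySweep(net, cat5, c(1.7, 5, 10.12), c(0.01, 0.0199))
  expect_gte(max(it$L, na.rm = TRUE), 5)
})

test_that("homogeneous class-level transitions reproduce the explicit graph", {
  net <- homogeneousNet(4)
  ks <- homogeneousStableK(4)
  cat4 <- enumerateAttractors(net, "exhaustive")
  for (amp in c(7.1, 52.15)) {
    g <- transitionGraph(net, cat4, amplitude = amp, duration = 1e-3)
    m <- homogeneousTransitionMap(net, amp, 1e-3, ks)
    expect_identical(homogeneousLongestPath(m, 4),
                     as.integer(longestItinerantPath(g)))
  }
})

test_that("BFS recovers a hand-specified transition table exactly", {
  # mock dynamical system: a fixed table served by lookup
  tab <- rbind(c(2L, 3L), c(2L, 4L), c(1L, 3L), c(4L, 4L))
  known <- 1L
  edge_fun <- function(q, s) {
    t <- tab[q, s]
    known <<- max(known, t)
    t
  }
  delta <- isnet:::bfsMachine(edge_fun, function() known)
  expect_identical(unname(delta), unname(tab))
})

test_that("edge caching does not change extraction results", {
  net <- fiducialNet5()
  cl <- makeCueVector(5, 101, "L")
  cr <- makeCueVector(5, 901, "R")
  m1 <- extractFSM(net, cl, cr, amplitude = 7.1, duration = 0.008)
  m2 <- extractFSM(net, cl, cr, amplitude = 7.1, duration = 0.008)
  expect_identical(m1$delta, m2$delta)
})

test_that("graph exports round-trip through GraphML", {
  net <- fiducialNet5()
  cat5 <- fiducialCat5()
  g <- transitionGraph(net, cat5, amplitude = 5, duration = 0.0199)
  path <- tempfile(fileext = ".graphml")
  writeGraph(g, path, format = "graphml")
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(back), sum(!is.na(g$targets)))
  expect_identical(igraph::vertex_attr(back, "signature"),
                   vapply(g$catalogue$states[seq_len(igraph::vcount(back))],
                          function(s) paste(s$signature, collapse = ""),
                          character(1)))
  dot <- tempfile(fileext = ".dot")
  writeGraph(g, dot, format = "dot")
  expect_gt(file.size(dot), 0)
})
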