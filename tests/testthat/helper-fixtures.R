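# objects shared across test files, built once per run
.fx <- new.env()

# the fiducial pair: printed thresholds 5.34 / 82.43 Hz, UP rates 5 / 10 Hz,
# a stable spiral with Tr = -50 /s, Det = 1.5e4 /s^2
fiducialISP <- function() {
  if (is.null(.fx$isp))
    .fx$isp <- solveISPFromSpec(-50, 1.5e4, 5.34, 82.43, 5, 10)
  .fx$isp
}

fiducialNet5 <- function() {
  if (is.null(.fx$net5))
    .fx$net5 <- assembleISN(fiducialISP(), 5,
                            defaultCrossSpec(fiducialISP()), seed = 7)
  .fx$net5
}

fiducialCat5 <- function() {
  if (is.null(.fx$cat5))
    .fx$cat5 <- enumerateAttractors(fiducialNet5(), "exhaustive")
  .fx$cat5
}

# homogeneous network at the same pair and mean coupling
homogeneousNet <- function(n_pairs) {
  key <- paste0("hom", n_pairs)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- assembleISN(fiducialISP(), n_pairs,
                              defaultCrossSpec(fiducialISP(),
                                               family = "homogeneous",
                                               cv = 0))
  .fx[[key]]
}

homogeneousStableK <- function(n_pairs) {
  key <- paste0("homk", n_pairs)
  if (is.null(.fx[[key]])) {
    cat <- enumerateAttractors(homogeneousNet(n_pairs), "symmetry")
    .fx[[key]] <- sort(vapply(cat$states, function(s) s$k, numeric(1)))
  }
  .fx[[key]]
}
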