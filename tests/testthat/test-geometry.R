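test_that("superposition is exact for identical and rigidly moved frames", {
  sys <- makeToyComplex(15, 15, 4, seed = 3)
  sel <- bindingSiteSelection(sys, alpha_range = 1:15, beta_range = 1:15)
  ref <- referenceCoords(sys)
  expect_equal(superpose(ref, ref, sys, sel)$rmsd, 0, tolerance = 1e-10)
  moved <- rigidTransform(ref, seed = 11)
  fit <- superpose(moved, ref, sys, sel)
  expect_lt(fit$rmsd, 1e-8)
  # the whole frame is mapped back, not only the fit selection
  expect_lt(max(abs(fit$coords - ref)), 1e-8)
})

test_that("superposition needs at least three selected atoms", {
  n <- 2
  sys <- molecularSystem(rep("CA", n), 1:n, rep("GLY", n), rep("A", n),
                        rbind(c(0, 0, 0), c(3.8, 0, 0)))
  sel <- residueSelection("A", 1:n)
  expect_error(superpose(referenceCoords(sys), referenceCoords(sys), sys, sel),
               "geometry error")
})

test_that("Kabsch agrees with a rotation-grid oracle on 4-point sets", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(12, sd = 3), 4, 3)
    Q <- matrix(rnorm(12, sd = 3), 4, 3)
    ours <- pmhcdyn:::kabsch(P, Q)$rmsd
    oracle <- gridRmsdOracle(P, Q)
    expect_lt(abs(ours - oracle), 1e-3)
  }
})

test_that("superposition agrees with an established reference implementation", {
  sys <- makeToyComplex(20, 20, 5, seed = 7)
  sel <- bindingSiteSelection(sys, alpha_range = 1:20, beta_range = 1:20)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.6, seed = 5), 10)
  idx <- pmhcdyn:::selectionAtomIndices(sys, sel, atom_names = "CA")
  ref <- frames(traj)[1, , ]
  ours <- seriesValues(rmsdSeries(traj, sel))
  flat <- function(X) as.numeric(t(X))
  theirs <- vapply(1:10, function(t)
    bio3d::rmsd(flat(ref), flat(frames(traj)[t, , ]),
                a.inds = rep(3 * (idx - 1), each = 3) + rep(1:3, length(idx)),
                b.inds = rep(3 * (idx - 1), each = 3) + rep(1:3, length(idx)),
                fit = TRUE), numeric(1))
  # the reference implementation prints at 1e-3 precision
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("rmsd series: zero noise gives zeros; single frame gives length 1", {
  sys <- makeToyComplex(80, 95, 14, seed = 1)
  bs <- bindingSiteSelection(sys)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0, seed = 1), 12)
  expect_equal(seriesValues(rmsdSeries(traj, bs)), rep(0, 12), tolerance = 1e-9)
  t1 <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.1, seed = 1), 1)
  expect_length(seriesValues(rmsdSeries(t1, bs)), 1)
})

test_that("mean RMSD under isotropic noise matches a Monte-Carlo oracle", {
  sys <- makeToyComplex(80, 95, 14, seed = 1)
  bs <- bindingSiteSelection(sys)
  sigma <- 0.3
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = sigma, seed = 21), 300)
  ref <- referenceCoords(sys)
  ours <- mean(seriesValues(rmsdSeries(traj, bs, reference = ref)))
  # oracle: independent draws from the same displacement model, RMSD after
  # fit via the reference implementation
  idx <- pmhcdyn:::selectionAtomIndices(sys, bs, atom_names = "CA")
  flat <- function(X) as.numeric(t(X))
  set.seed(77)
  inds <- rep(3 * (idx - 1), each = 3) + rep(1:3, length(idx))
  mc <- replicate(300, {
    fr <- ref + matrix(rnorm(length(ref), sd = sigma), ncol = 3)
    bio3d::rmsd(flat(ref), flat(fr), a.inds = inds, b.inds = inds, fit = TRUE)
  })
  expect_lt(abs(ours - mean(mc)) / mean(mc), 0.02)
})

test_that("distributions normalize, find planted modes, and match binomial bins", {
  cst <- distributionSummary(rep(2.5, 100), bin_width = 0.1)
  expect_equal(sum(cst@probability), 1)
  expect_equal(sum(cst@probability > 0), 1)
  expect_equal(nrow(modes(cst)), 1)
  expect_equal(modes(cst)$location, 2.5, tolerance = 0.05)
  expect_equal(modes(cst)$mass, 1)

  # balanced two-state series at 10 and 13 Angstrom
  set.seed(5)
  x <- c(rnorm(300, 10, 0.1), rnorm(300, 13, 0.1))
  ds <- distributionSummary(x, bin_width = 0.25)
  expect_equal(nrow(modes(ds)), 2)
  expect_lt(abs(modes(ds)$location[1] - 10), 0.25)
  expect_lt(abs(modes(ds)$location[2] - 13), 0.25)
  expect_true(all(abs(modes(ds)$mass - 0.5) < 0.05))

  # uniform samples: every bin mass within 3 binomial sigmas of 0.1
  set.seed(6)
  u <- runif(5000)
  du <- distributionSummary(u, bin_width = 0.1)
  p <- du@probability[du@probability > 0]
  sigma3 <- 3 * sqrt(0.1 * 0.9 / 5000)
  expect_true(all(abs(p - 0.1) < sigma3 + 1e-9))
})

test_that("compartment distances reproduce hand-computed centre-of-mass values", {
  # 3-4-5 triangle: single heavy atoms at (0,0,0) and (3,4,0)
  sys <- molecularSystem(c("CA", "CA"), c(1, 1), c("GLY", "GLY"), c("A", "B"),
                        rbind(c(0, 0, 0), c(3, 4, 0)))
  cmap <- compartmentSelections(sys, list(T1 = list(alpha = 1, beta = 1)))
  traj <- trajectorySeries(sys, array(referenceCoords(sys), c(1, 2, 3)))
  d <- compartmentDistanceSeries(traj, cmap)
  expect_equal(seriesValues(d$T1), 5.0, tolerance = 1e-9)

  # equal-mass two-atom side vs single atom: COM (1,0,0) vs (5,0,0)
  sys2 <- molecularSystem(c("CA", "CA", "CA"), c(1, 1, 1),
                         rep("GLY", 3), c("A", "A", "B"),
                         rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0)))
  cmap2 <- compartmentSelections(sys2, list(T1 = list(alpha = 1, beta = 1)))
  traj2 <- trajectorySeries(sys2, array(referenceCoords(sys2), c(1, 3, 3)))
  expect_equal(seriesValues(compartmentDistanceSeries(traj2, cmap2)$T1), 4.0,
               tolerance = 1e-9)
})

test_that("RMSD and groove widths are invariant under whole-frame rigid motion", {
  sys <- makeToyComplex(80, 95, 14, seed = 1)
  bs <- bindingSiteSelection(sys)
  cmap <- compartmentSelections(sys)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.2, seed = 9), 6)
  moved <- frames(traj)
  for (t in 1:6) moved[t, , ] <- rigidTransform(moved[t, , ], seed = 100 + t)
  tmoved <- trajectorySeries(sys, moved, frameInterval(traj))
  r0 <- seriesValues(rmsdSeries(traj, bs, reference = referenceCoords(sys)))
  r1 <- seriesValues(rmsdSeries(tmoved, bs, reference = referenceCoords(sys)))
  expect_equal(r0, r1, tolerance = 1e-6)
  w0 <- compartmentDistanceSeries(traj, cmap)
  w1 <- compartmentDistanceSeries(tmoved, cmap)
  for (nm in names(w0))
    expect_equal(seriesValues(w0[[nm]]), seriesValues(w1[[nm]]),
                 tolerance = 1e-6)
})

test_that("empty heavy-atom compartment sides raise a named geometry error", {
  # a side consisting of hydrogens only cannot define a centre of mass
  sys <- molecularSystem(c("CA", "H1"), c(1, 1), c("GLY", "HOH"), c("A", "B"),
                        rbind(c(0, 0, 0), c(3, 0, 0)))
  cmap <- compartmentSelections(sys, list(D9 = list(alpha = 1, beta = 1)))
  traj <- trajectorySeries(sys, array(referenceCoords(sys), c(1, 2, 3)))
  expect_error(compartmentDistanceSeries(traj, cmap), "D9")
})
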