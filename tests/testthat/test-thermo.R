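test_that("per-mode oscillator entropy matches the two-term closed form", {
  expect_equal(qhModeEntropy(1), 1 / (exp(1) - 1) - log(1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(qhModeEntropy(1), 1.0407, tolerance = 1e-4)
  # classical limit grows, stiff limit vanishes
  expect_gt(qhModeEntropy(0.01), qhModeEntropy(1))
  expect_lt(qhModeEntropy(50), 1e-10)
})

test_that("a frozen trajectory has zero configurational entropy", {
  sys <- makeToyComplex(20, 20, 5, seed = 1)
  sel <- bindingSiteSelection(sys, alpha_range = 1:20, beta_range = 1:20)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0, seed = 1), 10)
  e <- suppressWarnings(quasiharmonicEntropy(traj, sel))
  expect_equal(e@TS, 0)
  expect_length(e@eigenvalues, 0)
})

test_that("entropy matches the closed form on a known Gaussian ensemble", {
  sys <- caChain(30)
  Sig <- rigidFreeCovariance(referenceCoords(sys))
  TS_true <- entropyClosedForm(Sig, atoms(sys)$mass)
  traj <- sampleTrajectory(sys, fluctuationSpec("full_covariance",
                                                covariance = Sig, seed = 600),
                           600)
  est <- suppressWarnings(
    quasiharmonicEntropy(traj, residueSelection("A", 1:30)))
  expect_lt(abs(est@TS - TS_true) / TS_true, 0.05)
  expect_equal(est@nFramesUsed, 600L)
})

test_that("entropy is rigid-motion invariant and grows with amplitude", {
  sys <- makeToyComplex(15, 15, 4, seed = 2)
  sel <- bindingSiteSelection(sys, alpha_range = 1:15, beta_range = 1:15)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.3, seed = 3), 80)
  moved <- frames(traj)
  for (t in seq_len(nFrames(traj)))
    moved[t, , ] <- rigidTransform(moved[t, , ], seed = 300 + t)
  tmoved <- trajectorySeries(sys, moved, frameInterval(traj))
  e0 <- suppressWarnings(quasiharmonicEntropy(traj, sel))
  e1 <- suppressWarnings(quasiharmonicEntropy(tmoved, sel))
  expect_equal(e0@TS, e1@TS, tolerance = 1e-6)

  amp <- c(0.1, 0.2, 0.4)
  ts <- vapply(amp, function(a) suppressWarnings(
    quasiharmonicEntropy(sampleTrajectory(
      sys, fluctuationSpec(amplitude = a, seed = 4), 80), sel))@TS, numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("SIE components obey the closed forms and the scaling invariant", {
  p <- loadParamTable()
  cb <- p[p$residue == "ALA" & p$atom == "CB", ]
  rmin <- 2 * cb$rmin_half
  mk <- function(d) molecularSystem(c("CB", "CB"), c(1, 1), c("ALA", "ALA"),
                                   c("A", "P"), rbind(c(0, 0, 0), c(d, 0, 0)))
  rec <- residueSelection("A", 1); lig <- residueSelection("P", 1)
  pars <- sieParams(gamma = 0)
  # two neutral LJ atoms at the combined rmin: well depth exactly
  b <- sieComponents(referenceCoords(mk(rmin)), mk(rmin), rec, lig, pars)
  expect_equal(b@eVdw, -cb$epsilon, tolerance = 1e-12)
  expect_equal(b@eCoulomb, 0)
  expect_equal(b@dgReactionField, 0)
  # invariant: total = alpha * sum + constant
  expect_equal(b@total,
               pars$alpha * (b@eCoulomb + b@dgReactionField + b@eVdw +
                             b@surfaceTerm) + pars$constant)
  # zero charge, gamma 0, beyond the LJ cutoff: total equals the constant
  far <- sieComponents(referenceCoords(mk(12)), mk(12), rec, lig, pars)
  expect_equal(far@total, pars$constant)
  # doubling alpha doubles (total - constant)
  pars2 <- sieParams(alpha = 2 * pars$alpha, gamma = 0)
  b2 <- sieComponents(referenceCoords(mk(rmin)), mk(rmin), rec, lig, pars2)
  expect_equal(b2@total - pars2$constant, 2 * (b@total - pars$constant),
               tolerance = 1e-12)
})

test_that("SIE is symmetric under swapping receptor and ligand labels", {
  sys <- makeToyComplex(12, 12, 4, seed = 6)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.1, seed = 2), 1,
                           frame_interval = 20)
  rec <- residueSelection("B", 1:12); lig <- residueSelection("P", 1:4)
  b1 <- sieComponents(frames(traj)[1, , ], sys, rec, lig)
  b2 <- sieComponents(frames(traj)[1, , ], sys, lig, rec)
  expect_equal(b1@total, b2@total, tolerance = 1e-9)
  expect_equal(b1@surfaceTerm, b2@surfaceTerm, tolerance = 1e-9)
})

test_that("overlapping atoms trigger a clash warning", {
  sys <- molecularSystem(c("CB", "CB"), c(1, 1), c("ALA", "ALA"), c("A", "P"),
                        rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_warning(
    sieComponents(referenceCoords(sys), sys, residueSelection("A", 1),
                  residueSelection("P", 1), sieParams(gamma = 0),
                  frame_label = 7),
    "clash.*7")
})

test_that("trajectory SIE respects the stride and summarizes frames", {
  sys <- makeToyComplex(12, 12, 4, seed = 6)
  rec <- residueSelection("B", 1:12); lig <- residueSelection("P", 1:4)
  pars <- sieParams(gamma = 0)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.1, seed = 2), 10,
                           frame_interval = 10)
  br <- sieTrajectory(traj, rec, lig, pars, stride_ps = 20)
  expect_equal(nrow(br@perFrame), 5)
  expect_equal(br@perFrame$frame, c(1, 3, 5, 7, 9))
  expect_equal(br@dgMean, mean(br@perFrame$total))
  expect_error(sieTrajectory(traj, rec, lig, pars, stride_ps = 5),
               "configuration error")

  frozen <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0, seed = 1), 4,
                             frame_interval = 20)
  bf <- sieTrajectory(frozen, rec, lig, pars, stride_ps = 20)
  expect_equal(bf@dgSd, 0)

  two <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.2, seed = 3), 2,
                          frame_interval = 20)
  bt <- sieTrajectory(two, rec, lig, pars, stride_ps = 20)
  hand <- vapply(1:2, function(t)
    sieComponents(frames(two)[t, , ], sys, rec, lig, pars)@total, numeric(1))
  expect_equal(bt@dgMean, mean(hand))
})

test_that("alanine scanning is local, exact for alanine, and fails for glycine", {
  # ligand residue 2 (leucine) is planted against the receptor wall; residue
  # 4 (leucine) stays across the groove, far from every receptor atom
  sys <- makeToyComplex(12, 12, 4, seed = 6,
                        pep_seq = c("SER", "LEU", "ALA", "LEU"),
                        beta_seq = rep("VAL", 12))
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.05, seed = 2), 4,
                           frame_interval = 20)
  traj <- plantInteraction(traj, plantedInteraction(
    "hydrophobic", a = c("B", 6), b = c("P", 2), target_fraction = 1, seed = 1))
  rec <- residueSelection("B", 1:12); lig <- residueSelection("P", 1:4)
  pars <- sieParams(gamma = 0)
  sc <- alanineScan(traj, list(c("P", 2), c("P", 4)), rec, lig, pars,
                    stride_ps = 20)
  # removing the planted contact loses favorable dispersion: ddG > 0
  expect_gt(sc$ddg[sc$resno == 2], 0.05)
  # the non-contacting residue contributes nothing
  expect_lt(abs(sc$ddg[sc$resno == 4]), 0.01)
  expect_warning(
    sc_ala <- alanineScan(traj, list(c("P", 3)), rec, lig, pars, 20),
    "already alanine")
  expect_equal(sc_ala$ddg, 0)
  sysG <- makeToyComplex(12, 12, 4, seed = 6, pep_seq = c("SER", "GLY"))
  trajG <- sampleTrajectory(sysG, fluctuationSpec(amplitude = 0, seed = 1), 2,
                            frame_interval = 20)
  expect_error(alanineScan(trajG, list(c("P", 2)), rec, lig, pars, 20),
               "glycine")
})

test_that("free-energy/IC50 conversion reproduces the published arithmetic", {
  # protective-allele rows: -12.2 -> 2.5 nM and -17.5 -> 4.6e-4 nM at 310 K
  expect_equal(signif(ic50FromDg(-12.2, 310), 2), 2.5)
  expect_equal(signif(ic50FromDg(-17.5, 310), 2), 4.6e-4)
  expect_equal(ic50FromDg(0, 310), 1e9)
  # round trip is the identity
  for (dg in c(-20, -12.2, -1, 0, 3))
    expect_equal(dgFromIc50(ic50FromDg(dg, 310), 310), dg, tolerance = 1e-12)
  # ratios are invariant to the concentration unit
  v_nM <- c(a = 2.5, b = 4.6e-4)
  expect_equal(ic50Ratio(v_nM, "b"), ic50Ratio(v_nM * 1e-9, "b"))
})

test_that("IC50 ratios and binder classification follow the conventions", {
  ic <- ic50FromDg(c(MBP = -17.5, EBNA1 = -12.2), 310)
  r <- ic50Ratio(ic, "MBP")
  expect_equal(unname(r["MBP"]), 1)
  expect_equal(unname(r["EBNA1"]), 5434, tolerance = 0.005)
  # predisposing-allele ratio rounds to the printed integer
  r15 <- ic50Ratio(ic50FromDg(c(MBP = -16.7, EBNA1 = -16.0), 310), "MBP")
  expect_equal(round(unname(r15["EBNA1"])), 3)
  expect_equal(ic50Ratio(c(x = 2, y = 1), "y"), c(x = 2, y = 1))
  expect_error(ic50Ratio(c(x = 1), "z"), "reference")
  expect_error(ic50Ratio(c(x = -1, z = 2), "z"), "positive")

  expect_equal(classifyBinder(2.5), "binder")
  expect_equal(classifyBinder(1000), "binder")
  expect_equal(classifyBinder(1e6), "non-binder")
})
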