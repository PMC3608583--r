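# direct geometric cases use hand-placed residues on tiny custom systems

# one glycine donor residue (N-H) on chain A and one glycine acceptor
# (backbone O) on chain B, with the N-H axis pointing at the acceptor
hbondToy <- function(d_NO, angle_deg = 180, T_ = 5) {
  # donor N at origin, H along +x; acceptor O placed so the N-H...O angle
  # at H equals angle_deg and d(N, O) = d_NO
  H <- c(1.0, 0, 0)
  th <- (180 - angle_deg) * pi / 180
  # O lies at distance r from H under the given interior angle
  # solve |N O| = d via law of cosines on triangle N-H-O
  NH <- 1.0
  r <- -NH * cos(th) + sqrt(d_NO^2 - (NH * sin(th))^2)
  O <- H + r * c(cos(th), sin(th), 0)
  sys <- molecularSystem(c("N", "H", "CA", "C", "O", "CA"),
                        c(1, 1, 1, 2, 2, 2),
                        rep("GLY", 6), c("A", "A", "A", "B", "B", "B"),
                        rbind(c(0, 0, 0), H, c(-1, 1, 0),
                              O + c(1.2, 0.5, 0), O, O + c(2.2, 1.2, 0)))
  trajectorySeries(sys, array(rep(referenceCoords(sys), each = T_),
                              c(T_, 6, 3)))
}

test_that("hydrogen-bond criteria gate on distance and angle", {
  sA <- residueSelection("A", 1)
  sB <- residueSelection("B", 2)
  good <- hbondToy(2.8, 180)
  rec <- records(detectHbonds(good, sB, sA))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$persistence, 1.0)
  # distance fails
  expect_equal(nrow(records(detectHbonds(hbondToy(3.5, 180), sB, sA))), 0)
  # angle fails (bent below the cutoff)
  expect_equal(nrow(records(detectHbonds(hbondToy(2.8, 100), sB, sA))), 0)
  # boundary angle passes
  expect_equal(records(detectHbonds(hbondToy(2.9, 135), sB, sA))$persistence, 1)
})

ringCoords <- function(center, normal, radius = 1.39) {
  normal <- normal / sqrt(sum(normal^2))
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  t(vapply(th, function(x) center + radius * (cos(x) * e1 + sin(x) * e2),
           numeric(3)))
}

stackToy <- function(sep, normal_b = c(0, 0, 1), T_ = 4) {
  ringA <- ringCoords(c(0, 0, 0), c(0, 0, 1))
  ringB <- ringCoords(c(0, 0, sep), normal_b)
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  sys <- molecularSystem(c(nm, nm), rep(1, 12), rep("PHE", 12),
                        rep(c("A", "B"), each = 6), rbind(ringA, ringB))
  trajectorySeries(sys, array(rep(referenceCoords(sys), each = T_),
                              c(T_, 12, 3)))
}

test_that("stacking criteria gate on plane angle and centroid distance", {
  sA <- residueSelection("A", 1); sB <- residueSelection("B", 1)
  expect_equal(records(detectStacking(stackToy(4.0), sA, sB))$persistence, 1)
  # perpendicular rings at the same distance fail the dihedral cutoff
  expect_equal(nrow(records(detectStacking(stackToy(4.0, c(1, 0, 0)), sA, sB))),
               0)
  # centroid distance beyond 5.0 fails
  expect_equal(nrow(records(detectStacking(stackToy(5.5), sA, sB))), 0)
})

hydrophobicToy <- function(d_CB, water_at = NULL, T_ = 4) {
  nmV <- c("CB", "CG1", "CG2")
  xyzA <- rbind(c(0, 0, 0), c(-0.7, -1, 0.4), c(0.7, -1, 0.4))
  xyzB <- rbind(c(0, d_CB, 0), c(-0.7, d_CB + 1, 0.4), c(0.7, d_CB + 1, 0.4))
  name <- c(nmV, nmV); resn <- rep("VAL", 6); chain <- rep(c("A", "B"), each = 3)
  resno <- rep(1, 6); xyz <- rbind(xyzA, xyzB)
  if (!is.null(water_at)) {
    name <- c(name, "O"); resn <- c(resn, "HOH"); chain <- c(chain, "W")
    resno <- c(resno, 1); xyz <- rbind(xyz, water_at)
  }
  sys <- molecularSystem(name, resno, resn, chain, xyz)
  trajectorySeries(sys, array(rep(referenceCoords(sys), each = T_),
                              c(T_, nrow(xyz), 3)))
}

test_that("hydrophobic contacts respect the cutoff and the water veto", {
  sA <- residueSelection("A", 1); sB <- residueSelection("B", 1)
  expect_equal(records(detectHydrophobic(hydrophobicToy(3.8), sA, sB))$persistence,
               1)
  expect_equal(nrow(records(detectHydrophobic(hydrophobicToy(5.5), sA, sB))), 0)
  # a water oxygen 3.0 A from a contact atom vetoes every frame
  wet <- hydrophobicToy(3.8, water_at = c(0, 0, 3))
  expect_equal(nrow(records(detectHydrophobic(wet, sA, sB))), 0)
  # a remote water does not
  far <- hydrophobicToy(3.8, water_at = c(0, 0, 20))
  expect_equal(records(detectHydrophobic(far, sA, sB))$persistence, 1)
})

test_that("loosening any cutoff never removes records nor lowers persistence", {
  sys <- cleanComplex(beta = c(`6` = "PHE", `40` = "VAL", `82` = "SER"),
                      pep = c(`3` = "PHE", `5` = "VAL"), seed = 1)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.08, seed = 2), 120)
  traj <- plantInteraction(traj, plantedInteraction(
    "hbond", a = c("B", 82), b = c("P", 7), target_fraction = 0.4, seed = 3))
  traj <- plantInteraction(traj, plantedInteraction(
    "stacking", a = c("B", 6), b = c("P", 3), target_fraction = 0.5, seed = 4))
  traj <- plantInteraction(traj, plantedInteraction(
    "hydrophobic", a = c("B", 40), b = c("P", 5), target_fraction = 0.3, seed = 5))
  key <- function(tab) paste(tab$res_a, tab$res_b)
  persOf <- function(tab) setNames(tab$persistence, key(tab))
  checkMono <- function(tight, loose) {
    expect_true(all(key(tight) %in% key(loose)))
    shared <- intersect(key(tight), key(loose))
    expect_true(all(persOf(loose)[shared] >= persOf(tight)[shared] - 1e-12))
  }
  checkMono(records(detectHbonds(traj, selBeta(), selPep(), hbondCriteria(3.1, 130, 0.1))),
            records(detectHbonds(traj, selBeta(), selPep(), hbondCriteria(3.5, 120, 0.1))))
  checkMono(records(detectStacking(traj, selBeta(), selPep(), stackCriteria(30, 5, 0.1))),
            records(detectStacking(traj, selBeta(), selPep(), stackCriteria(45, 6.5, 0.1))))
  checkMono(records(detectHydrophobic(traj, selBeta(), selPep(), hydrophobicCriteria(4, 4, 0.1))),
            records(detectHydrophobic(traj, selBeta(), selPep(), hydrophobicCriteria(5, 3, 0.1))))
})

test_that("frame decisions agree with the brute-force oracle on random frames", {
  # small mixed system, random frames with plants at assorted fractions
  sys <- makeToyComplex(8, 8, 4, with_waters = 2, seed = 3,
                        alpha_seq = c("SER", "PHE", "VAL", "ASN", "GLY",
                                      "LEU", "THR", "ILE"),
                        beta_seq = c("VAL", "TYR", "ALA", "SER", "HIS",
                                     "ASP", "PHE", "LEU"),
                        pep_seq = c("VAL", "PHE", "SER", "LEU"))
  expect_lte(nAtoms(sys), 200)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 1.2, seed = 8), 50)
  traj <- plantInteraction(traj, plantedInteraction(
    "hbond", a = c("B", 4), b = c("P", 3), target_fraction = 0.5, seed = 1))
  traj <- plantInteraction(traj, plantedInteraction(
    "stacking", a = c("B", 2), b = c("P", 2), target_fraction = 0.5, seed = 2))
  traj <- plantInteraction(traj, plantedInteraction(
    "hydrophobic", a = c("B", 1), b = c("P", 1), target_fraction = 0.5,
    geometry = list(water = list(resno = 1, fraction = 0.5)), seed = 3))
  sB <- residueSelection("B", 1:8); sP <- residueSelection("P", 1:4)
  at <- atoms(sys)
  resIdx <- function(ch, r) which(at$chain_id == ch & at$residue_index == r)

  checkKind <- function(detect, brute, criteria) {
    got <- detect(traj, sB, sP, criteria)
    gotKey <- paste(records(got)$res_a, records(got)$res_b)
    pm <- presenceMatrix(got)
    for (rb in 1:8) for (rp in 1:4) {
      ib <- resIdx("B", rb); ip <- resIdx("P", rp)
      truth <- vapply(1:50, function(t)
        brute(frames(traj)[t, , ], at, ib, ip), logical(1))
      k <- match(paste(rb, rp), gotKey)
      mine <- if (is.na(k)) rep(FALSE, 50) else pm[, k]
      expect_identical(mine, truth)
    }
  }
  checkKind(detectHbonds, bruteHbondFrame, hbondCriteria(persistence_threshold = 0))
  checkKind(detectStacking, bruteStackFrame,
            stackCriteria(persistence_threshold = 0))
  checkKind(detectHydrophobic, bruteHydrophobicFrame,
            hydrophobicCriteria(persistence_threshold = 0))
})

test_that("network summaries merge detectors and stay deterministic", {
  expect_equal(nrow(networkSummary()), 0)
  # histidine rings for the stacking plant: planar but not in the
  # hydrophobic class, so the three planted records are the whole network
  sys <- cleanComplex(beta = c(`6` = "HIS", `82` = "SER"),
                      pep = c(`3` = "HIS"), seed = 1)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.05, seed = 2), 100)
  traj <- plantInteraction(traj, plantedInteraction(
    "hbond", a = c("B", 82), b = c("P", 7), target_fraction = 0.6, seed = 3))
  traj <- plantInteraction(traj, plantedInteraction(
    "hbond", a = c("B", 30), b = c("P", 10), target_fraction = 0.4, seed = 4))
  traj <- plantInteraction(traj, plantedInteraction(
    "stacking", a = c("B", 6), b = c("P", 3), target_fraction = 0.5, seed = 5))
  tab <- networkSummary(detectHbonds(traj, selBeta(), selPep()),
                        detectStacking(traj, selBeta(), selPep()),
                        detectHydrophobic(traj, selBeta(), selPep()))
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$kind, c("hbond", "hbond", "stacking"))
  # identical planted systems give identical tables
  traj2 <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.05, seed = 2), 100)
  traj2 <- plantInteraction(traj2, plantedInteraction(
    "hbond", a = c("B", 82), b = c("P", 7), target_fraction = 0.6, seed = 3))
  traj2 <- plantInteraction(traj2, plantedInteraction(
    "hbond", a = c("B", 30), b = c("P", 10), target_fraction = 0.4, seed = 4))
  traj2 <- plantInteraction(traj2, plantedInteraction(
    "stacking", a = c("B", 6), b = c("P", 3), target_fraction = 0.5, seed = 5))
  tab2 <- networkSummary(detectHbonds(traj2, selBeta(), selPep()),
                         detectStacking(traj2, selBeta(), selPep()),
                         detectHydrophobic(traj2, selBeta(), selPep()))
  expect_identical(tab, tab2)
})

test_that("selections without donors or acceptors yield empty results", {
  # proline-only groups have no N-H donor and the detector finds nothing
  # between backbone-only glycines across a wide groove
  sys <- cleanComplex(seed = 2)
  traj <- sampleTrajectory(sys, fluctuationSpec(amplitude = 0.05, seed = 1), 10)
  out <- detectHbonds(traj, selBeta(), selPep())
  expect_s4_class(out, "InteractionSet")
  expect_equal(nrow(records(out)), 0)
})
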