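# Quasi-harmonic configurational entropy, SIE binding free energies over
# frames, virtual alanine scanning, and the free-energy <-> IC50 conversion.

#' Per-mode quantum harmonic oscillator entropy
#'
#' Entropy (in units of kB) of one harmonic mode with reduced frequency
#' `alpha = hbar * omega / (kB * T)`:
#' `S/kB = alpha/(exp(alpha) - 1) - log(1 - exp(-alpha))`.
#'
#' @param alpha reduced mode frequency (dimensionless), vectorized.
#' @return entropy per mode in units of kB.
#' @export
qhModeEntropy <- function(alpha) {
  alpha / (exp(alpha) - 1) - log1p(-exp(-alpha))
}

#' Quasi-harmonic configurational entropy of a trajectory
#'
#' Estimates configurational entropy from the eigen-spectrum of the
#' mass-weighted covariance of C-alpha Cartesian fluctuations: frames are
#' superposed on their mean structure over the selection, the 3n x 3n
#' mass-weighted covariance is diagonalized, each eigenvalue `lambda`
#' (amu Angstrom^2) defines a mode frequency `omega = sqrt(kB T / lambda)`,
#' and each mode contributes quantum harmonic oscillator entropy
#' (see [qhModeEntropy()]). Eigenvalues below `drop_tol` are treated as
#' rigid-body/rank-deficiency artifacts and dropped (six are expected from
#' superposition alone).
#'
#' @param traj a [TrajectorySeries-class] with at least 2 frames.
#' @param selection a [ResidueSelection-class]; the estimate uses its C-alpha
#'   atoms.
#' @param temperature K.
#' @param fit superpose frames on the mean structure first (default TRUE;
#'   entropy is then invariant under rigid-body motion of the frames).
#' @param drop_tol eigenvalue floor, amu Angstrom^2.
#' @return an [EntropyResult-class] with `TS` in kcal/mol.
#' @export
quasiharmonicEntropy <- function(traj, selection, temperature = 310,
                                 fit = TRUE, drop_tol = 1e-12) {
  T_ <- nFrames(traj)
  if (T_ < 2) stop("entropy estimation needs at least 2 frames")
  sys <- traj@system
  idx <- selectionAtomIndices(sys, selection, atom_names = "CA")
  if (!length(idx))
    stop("selection maps to no C-alpha atoms")
  n <- length(idx)
  X <- array(traj@frames[, idx, , drop = FALSE], dim = c(T_, n, 3))
  if (fit && n >= 3) {
    ref <- X[1, , ]
    for (iter in 1:2) {
      for (t in seq_len(T_)) {
        k <- kabsch(X[t, , ], ref)
        X[t, , ] <- sweep(t(k$R %*% t(sweep(X[t, , ], 2, k$center_mobile))),
                          2, k$center_ref, "+")
      }
      ref <- apply(X, c(2, 3), mean)
    }
  }
  if (T_ - 1 < 3 * n)
    warning(sprintf("rank warning: %d frames give covariance rank <= %d of %d modes",
                    T_, T_ - 1, 3 * n))
  flat <- matrix(X, nrow = T_)  # columns: atom-major, coord blocks x,y,z
  # reorder to (x1,y1,z1,x2,...) so mass weighting is per-atom blocks
  ord <- as.vector(t(matrix(seq_len(3 * n), nrow = n)))
  flat <- flat[, ord, drop = FALSE]
  C <- stats::cov(flat)
  w <- sqrt(rep(sys@atoms$mass[idx], each = 3))
  Cm <- C * outer(w, w)  # amu Angstrom^2
  lam <- eigen(Cm, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > drop_tol]
  if (!length(lam)) {
    return(new("EntropyResult", TS = 0, temperature = temperature,
               eigenvalues = numeric(0), nFramesUsed = as.integer(T_)))
  }
  lam_SI <- lam * .amuA2_to_SI
  alpha <- .hbar_SI / sqrt(.kB_SI * temperature * lam_SI)
  TS <- .kB_kcal * temperature * sum(qhModeEntropy(alpha))
  new("EntropyResult", TS = TS, temperature = temperature,
      eigenvalues = lam, nFramesUsed = as.integer(T_))
}

#' SIE scaling and continuum parameters
#'
#' Defaults are the published AMBER-trained SIE coefficient set:
#' global scale `alpha = 0.1048`, interior dielectric `d_in = 2.25`, surface
#' coefficient `gamma = 0.0129` kcal/(mol Angstrom^2) and additive constant
#' `-2.89` kcal/mol. The reaction-field term uses a generalized-Born
#' continuum with outer dielectric `d_out = 78.5` and the per-atom Born
#' radius seeds of the parameter table.
#'
#' @param alpha global scale (dimensionless, > 0).
#' @param d_in interior dielectric (>= 1).
#' @param gamma surface coefficient, kcal/(mol Angstrom^2).
#' @param constant additive offset, kcal/mol.
#' @param temperature K.
#' @param d_out exterior (solvent) dielectric.
#' @param lj_cutoff Lennard-Jones cutoff, Angstrom.
#' @param probe solvent probe radius for the buried-surface term, Angstrom.
#' @param sasa_points sphere points per atom in the surface estimator.
#' @return an `SIEParams` list.
#' @export
sieParams <- function(alpha = 0.1048, d_in = 2.25, gamma = 0.0129,
                      constant = -2.89, temperature = 310, d_out = 78.5,
                      lj_cutoff = 10, probe = 1.4, sasa_points = 240) {
  stopifnot(alpha > 0, d_in >= 1, temperature > 0, d_out > d_in)
  structure(list(alpha = alpha, d_in = d_in, gamma = gamma,
                 constant = constant, temperature = temperature,
                 d_out = d_out, lj_cutoff = lj_cutoff, probe = probe,
                 sasa_points = sasa_points),
            class = "SIEParams")
}

# deterministic golden-spiral unit sphere points
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Shrake-Rupley solvent-accessible surface over heavy atoms
# coords: n x 3; radii: vdW/Born seeds; returns total area in Angstrom^2
shrakeRupleySASA <- function(coords, radii, probe = 1.4, n_points = 240) {
  n <- nrow(coords)
  if (n == 0) return(0)
  R <- radii + probe
  pts <- .spherePoints(n_points)
  total <- 0
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    P <- sweep(pts * R[i], 2, coords[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(P, 2, coords[j, ])^2)
        free <- free & dj2 > R[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    total <- total + frac * 4 * pi * R[i]^2
  }
  total
}

#' SIE energy components for one frame
#'
#' Computes the intermolecular screened Coulomb energy, intermolecular
#' Lennard-Jones energy, the change in generalized-Born reaction-field
#' solvation energy upon binding (with fixed Born radii the per-molecule
#' self terms cancel, leaving the receptor-ligand cross term), and the
#' buried-molecular-surface term `gamma * dMSA` with
#' `dMSA = MSA(complex) - MSA(receptor) - MSA(ligand)` (negative upon
#' burial). The scaled total follows the [EnergyBreakdown-class] invariant.
#'
#' @param coords N x 3 frame coordinates, Angstrom.
#' @param system a [MolecularSystem-class].
#' @param receptor,ligand disjoint [ResidueSelection-class] groups.
#' @param params an [sieParams()].
#' @param frame_label frame index used in clash warnings.
#' @return an [EnergyBreakdown-class].
#' @export
sieComponents <- function(coords, system, receptor, ligand,
                          params = sieParams(), frame_label = NA) {
  ir <- selectionAtomIndices(system, receptor)
  il <- selectionAtomIndices(system, ligand)
  if (length(intersect(ir, il)))
    stop("receptor and ligand selections must be disjoint")
  if (!length(ir) || !length(il)) stop("empty receptor or ligand selection")
  a <- system@atoms
  Xr <- coords[ir, , drop = FALSE]; Xl <- coords[il, , drop = FALSE]
  D2 <- outer(rowSums(Xr^2), rowSums(Xl^2), "+") - 2 * Xr %*% t(Xl)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  if (any(D < 0.5))
    warning(sprintf("clash warning: interatomic distance < 0.5 A in frame %s",
                    frame_label))
  qq <- outer(a$charge[ir], a$charge[il])
  e_coul <- .coulombConst / params$d_in * sum(qq / pmax(D, 1e-6))
  eps <- sqrt(outer(a$epsilon[ir], a$epsilon[il]))
  rmin <- outer(a$rmin_half[ir], a$rmin_half[il], "+")
  sr6 <- (rmin / pmax(D, 1e-6))^6
  lj <- eps * (sr6^2 - 2 * sr6)
  lj[D > params$lj_cutoff] <- 0
  e_vdw <- sum(lj)
  RiRj <- outer(a$radius[ir], a$radius[il])
  fgb <- sqrt(D2 + RiRj * exp(-D2 / (4 * RiRj)))
  dg_rf <- -.coulombConst * (1 / params$d_in - 1 / params$d_out) * sum(qq / fgb)
  if (params$gamma != 0) {
    heavy_r <- ir[a$is_heavy[ir]]; heavy_l <- il[a$is_heavy[il]]
    A_r <- shrakeRupleySASA(coords[heavy_r, , drop = FALSE],
                            a$radius[heavy_r], params$probe, params$sasa_points)
    A_l <- shrakeRupleySASA(coords[heavy_l, , drop = FALSE],
                            a$radius[heavy_l], params$probe, params$sasa_points)
    hc <- c(heavy_r, heavy_l)
    A_c <- shrakeRupleySASA(coords[hc, , drop = FALSE],
                            a$radius[hc], params$probe, params$sasa_points)
    surf <- params$gamma * (A_c - A_r - A_l)
  } else surf <- 0
  total <- params$alpha * (e_coul + dg_rf + e_vdw + surf) + params$constant
  new("EnergyBreakdown", eCoulomb = e_coul, dgReactionField = dg_rf,
      eVdw = e_vdw, surfaceTerm = surf, total = total)
}

#' SIE binding free energy over a trajectory
#'
#' Evaluates [sieComponents()] on frames taken at a fixed time stride
#' (default 20 ps), and summarizes the per-frame totals.
#'
#' @param traj a [TrajectorySeries-class].
#' @param receptor,ligand disjoint [ResidueSelection-class] groups.
#' @param params an [sieParams()].
#' @param stride_ps evaluation stride, ps; must be at least the frame
#'   interval.
#' @return a [BindingResult-class].
#' @export
sieTrajectory <- function(traj, receptor, ligand, params = sieParams(),
                          stride_ps = 20) {
  if (stride_ps < traj@frameInterval)
    stop("configuration error: stride_ps (", stride_ps,
         " ps) is below the frame interval (", traj@frameInterval, " ps)")
  step <- max(1L, as.integer(round(stride_ps / traj@frameInterval)))
  at <- seq(1L, nFrames(traj), by = step)
  if (!length(at)) stop("configuration error: stride selects no frames")
  rows <- lapply(at, function(t) {
    b <- sieComponents(traj@frames[t, , ], traj@system, receptor, ligand,
                       params, frame_label = t)
    data.frame(frame = t, e_coulomb = b@eCoulomb,
               dg_reaction_field = b@dgReactionField, e_vdw = b@eVdw,
               surface_term = b@surfaceTerm, total = b@total)
  })
  pf <- do.call(rbind, rows)
  dg_mean <- mean(pf$total)
  dg_sd <- if (nrow(pf) > 1) stats::sd(pf$total) else 0
  new("BindingResult", dgMean = dg_mean, dgSd = dg_sd, perFrame = pf,
      ic50nM = ic50FromDg(dg_mean, params$temperature),
      stridePs = step * traj@frameInterval)
}

#' Virtual alanine scan (single-trajectory approximation)
#'
#' For each listed position independently, side-chain atoms beyond C-beta
#' are deleted, C-beta is reassigned alanine parameters, and the SIE
#' trajectory score is recomputed on the same frames (no re-simulation).
#' `ddG = dG_mutant - dG_wildtype`.
#'
#' @param traj a [TrajectorySeries-class].
#' @param positions list of `c(chain_id, residue_index)` pairs; positions
#'   must not be glycine (no C-beta); an alanine position yields a zero row
#'   with a warning.
#' @param receptor,ligand disjoint [ResidueSelection-class] groups.
#' @param params an [sieParams()].
#' @param stride_ps evaluation stride, ps.
#' @return data.frame with columns `chain`, `resno`, `resname`, `dg_wt`,
#'   `dg_mut`, `ddg` (kcal/mol).
#' @export
alanineScan <- function(traj, positions, receptor, ligand,
                        params = sieParams(), stride_ps = 20) {
  sys <- traj@system
  a <- sys@atoms
  wt <- sieTrajectory(traj, receptor, ligand, params, stride_ps)
  alaKeep <- c("N", "H", "CA", "C", "O", "CB")
  rows <- lapply(positions, function(pos) {
    ch <- pos[1]; rn <- as.integer(pos[2])
    idx <- residueAtomIndices(sys, ch, rn)
    if (!length(idx)) stop("position ", ch, ":", rn, " not found")
    resname <- a$residue_name[idx[1]]
    if (resname == "GLY")
      stop("cannot scan glycine at ", ch, ":", rn, " (no C-beta)")
    if (resname == "ALA") {
      warning("position ", ch, ":", rn, " is already alanine; ddG = 0")
      return(data.frame(chain = ch, resno = rn, resname = resname,
                        dg_wt = wt@dgMean, dg_mut = wt@dgMean, ddg = 0))
    }
    drop <- idx[!(a$atom_name[idx] %in% alaKeep)]
    keep <- setdiff(seq_len(nrow(a)), drop)
    rname <- a$residue_name; rname[idx] <- "ALA"
    mut_sys <- buildSystem(a$atom_name[keep], a$residue_index[keep],
                           rname[keep], a$chain_id[keep],
                           sys@referenceCoords[keep, , drop = FALSE],
                           loadParamTable())
    mut_traj <- new("TrajectorySeries", system = mut_sys,
                    frames = traj@frames[, keep, , drop = FALSE],
                    frameInterval = traj@frameInterval)
    mut <- sieTrajectory(mut_traj, receptor, ligand, params, stride_ps)
    data.frame(chain = ch, resno = rn, resname = resname,
               dg_wt = wt@dgMean, dg_mut = mut@dgMean,
               ddg = mut@dgMean - wt@dgMean)
  })
  do.call(rbind, rows)
}

#' Convert a binding free energy to IC50
#'
#' Uses the Boltzmann relation `dG = kB T ln(IC50)` with IC50 in mol/L
#' inside the logarithm; the result is returned in nM.
#'
#' @param dg binding free energy, kcal/mol (vectorized).
#' @param temperature K.
#' @return IC50 in nM.
#' @export
ic50FromDg <- function(dg, temperature = 310) {
  stopifnot(temperature > 0)
  exp(dg / (.kB_kcal * temperature)) * 1e9
}

#' Convert an IC50 back to a binding free energy
#'
#' Inverse of [ic50FromDg()].
#'
#' @param ic50_nM IC50 in nM (vectorized, > 0).
#' @param temperature K.
#' @return free energy in kcal/mol.
#' @export
dgFromIc50 <- function(ic50_nM, temperature = 310) {
  stopifnot(temperature > 0, all(ic50_nM > 0))
  .kB_kcal * temperature * log(ic50_nM * 1e-9)
}

#' IC50 ratios relative to a reference
#'
#' @param values named numeric vector of IC50s (any single concentration
#'   unit; ratios are unit-free).
#' @param reference_label name of the reference entry.
#' @return named numeric vector of `values / values[reference_label]`.
#' @export
ic50Ratio <- function(values, reference_label) {
  if (!reference_label %in% names(values))
    stop("reference label '", reference_label, "' not present")
  if (any(values <= 0)) stop("numeric error: IC50 values must be positive")
  values / values[[reference_label]]
}

#' Classify binding by the standard IC50 threshold
#'
#' Peptides with IC50 at or below 1000 nM are classified as binders.
#'
#' @param ic50_nM IC50 in nM (vectorized, > 0).
#' @param threshold_nM classification threshold, nM.
#' @return character vector, `"binder"` or `"non-binder"`.
#' @export
classifyBinder <- function(ic50_nM, threshold_nM = 1000) {
  stopifnot(all(ic50_nM > 0))
  ifelse(ic50_nM <= threshold_nM, "binder", "non-binder")
}
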