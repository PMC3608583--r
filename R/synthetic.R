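# Synthetic peptide-MHC-like systems and trajectories with planted,
# detector-aligned ground truth. Geometry is deliberately coarse: backbone
# plus the minimal side-chain atoms each analysis stage needs. The point is
# testable analysis math, not molecular realism.

# Local residue templates. Coordinates are (t1, t2, t3) offsets from CA in a
# right-handed frame: t1 = chain axis, t2 = "inward" vector pointing into
# the groove, t3 = their cross product. Bond lengths are approximate.
.hexagon <- function(center_t2, radius = 1.39) {
  ang <- (c(-90, -30, 30, 90, 150, 210)) * pi / 180
  cbind(radius * cos(ang), center_t2 + radius * sin(ang), 0)
}

.residueTemplate <- function(resname) {
  bb <- rbind(
    N = c(-1.20, 0.00, 0.90),
    H = c(-1.20, 0.98, 0.90),
    CA = c(0, 0, 0),
    C = c(1.20, 0.00, 0.90),
    O = c(1.20, 1.23, 0.90)
  )
  if (resname == "PRO") bb <- bb[rownames(bb) != "H", , drop = FALSE]
  if (resname %in% .waterResnames) {
    return(rbind(O = c(0, 0, 0), H1 = c(0.76, 0.59, 0), H2 = c(-0.76, 0.59, 0)))
  }
  CB <- c(0, 1.53, 0)
  sc <- switch(resname,
    GLY = NULL,
    ALA = rbind(CB = CB),
    VAL = rbind(CB = CB, CG1 = c(0.7, 2.6, 0.6), CG2 = c(-0.7, 2.6, 0.6)),
    LEU = rbind(CB = CB, CG = c(0, 2.9, 0.3), CD1 = c(0.8, 3.9, 0.3),
                CD2 = c(-0.8, 3.9, 0.3)),
    ILE = rbind(CB = CB, CG1 = c(0.7, 2.6, 0.4), CG2 = c(-0.7, 2.6, 0.4),
                CD1 = c(0.7, 4.0, 0.4)),
    PRO = rbind(CB = CB, CG = c(-0.8, 2.3, 0.5), CD = c(-1.6, 1.2, 0.6)),
    MET = rbind(CB = CB, CG = c(0, 2.9, 0.3), SD = c(0, 4.7, 0.3),
                CE = c(0.9, 5.9, 0.3)),
    SER = rbind(CB = CB, OG = c(0, 2.9, 0.2), HG = c(0, 3.5, 0.9)),
    THR = rbind(CB = CB, OG1 = c(0.6, 2.8, 0.2), HG1 = c(0.6, 3.4, 0.9),
                CG2 = c(-0.8, 2.5, 0.5)),
    CYS = rbind(CB = CB, SG = c(0, 3.3, 0.2), HG = c(0, 4.3, 0.9)),
    ASN = rbind(CB = CB, CG = c(0, 2.9, 0.2), OD1 = c(1.0, 3.6, 0.2),
                ND2 = c(-1.0, 3.6, 0.2), HD21 = c(-1.0, 4.6, 0.2),
                HD22 = c(-1.8, 3.1, 0.2)),
    ASP = rbind(CB = CB, CG = c(0, 2.9, 0.2), OD1 = c(1.0, 3.6, 0.2),
                OD2 = c(-1.0, 3.6, 0.2)),
    GLN = rbind(CB = CB, CG = c(0, 2.9, 0.3), CD = c(0, 4.4, 0.3),
                OE1 = c(1.0, 5.1, 0.3), NE2 = c(-1.0, 5.1, 0.3),
                HE21 = c(-1.0, 6.1, 0.3), HE22 = c(-1.8, 4.6, 0.3)),
    GLU = rbind(CB = CB, CG = c(0, 2.9, 0.3), CD = c(0, 4.4, 0.3),
                OE1 = c(1.0, 5.1, 0.3), OE2 = c(-1.0, 5.1, 0.3)),
    LYS = rbind(CB = CB, CG = c(0, 2.9, 0.3), CD = c(0, 4.4, 0.3),
                CE = c(0, 5.9, 0.3), NZ = c(0, 7.3, 0.3),
                HZ1 = c(0.8, 7.9, 0.3), HZ2 = c(-0.8, 7.9, 0.3),
                HZ3 = c(0, 7.9, 1.1)),
    ARG = rbind(CB = CB, CG = c(0, 2.9, 0.3), CD = c(0, 4.4, 0.3),
                NE = c(0, 5.8, 0.3), HE = c(0.9, 6.3, 0.3),
                CZ = c(-0.6, 6.9, 0.3), NH1 = c(0.1, 8.0, 0.3),
                NH2 = c(-1.9, 7.0, 0.3), HH11 = c(1.1, 8.0, 0.3),
                HH12 = c(-0.4, 8.9, 0.3), HH21 = c(-2.4, 7.9, 0.3),
                HH22 = c(-2.4, 6.2, 0.3)),
    PHE = {
      ring <- .hexagon(4.3)
      rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      rbind(CB = CB, ring)
    },
    TYR = {
      ring <- .hexagon(4.3)
      rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      rbind(CB = CB, ring, OH = c(0, 4.3 + 1.39 + 1.40, 0),
            HH = c(0, 4.3 + 1.39 + 2.36, 0))
    },
    HIS = {
      ang <- c(-90, -18, 54, 126, 198) * pi / 180
      ring <- cbind(1.16 * cos(ang), 4.1 + 1.16 * sin(ang), 0)
      rownames(ring) <- c("CG", "ND1", "CE1", "NE2", "CD2")
      rbind(CB = CB, ring, HD1 = c(2.1, 3.9, 0))
    },
    TRP = {
      ind <- rbind(CG = c(0.00, 0.00), CD1 = c(1.09, 0.84), NE1 = c(0.71, 2.15),
                   CE2 = c(-0.68, 2.16), CD2 = c(-1.15, 0.85),
                   CE3 = c(-2.51, 0.47), CZ3 = c(-3.49, 1.44),
                   CH2 = c(-3.12, 2.76), CZ2 = c(-1.74, 3.15))
      ring <- cbind(ind[, 1], 2.9 + ind[, 2], 0)
      rownames(ring) <- rownames(ind)
      rbind(CB = CB, ring, HE1 = c(1.41, 5.65, 0))
    },
    stop("no residue template for '", resname, "'")
  )
  rbind(bb, sc)
}

# Default sequence palette: short side chains only, so the default layout
# is free of incidental steric contacts between the walls and the peptide;
# residues with long or planar side chains are introduced explicitly via
# the *_seq arguments where a test or plant needs them.
.defaultPalette <- c("ALA", "VAL", "SER", "LEU", "THR", "ASN", "ILE", "GLY",
                     "ASP")

# lay one chain: residues spaced along x at height y0, side chains along
# `inward` (+1 or -1 in y); direction -1 runs the chain antiparallel
.layChain <- function(resnames, chain_id, y0, inward, spacing = 3.5,
                      x0 = 0, z0 = 0, direction = 1) {
  out_name <- character(0); out_res <- integer(0); out_rn <- character(0)
  coords <- NULL
  for (i in seq_along(resnames)) {
    tmpl <- .residueTemplate(resnames[i])
    # frame: e1 = chain direction, u = inward * +y, e3 = e1 x u
    u <- c(0, inward, 0)
    e1 <- c(direction, 0, 0)
    e3 <- c(0, 0, direction * inward)  # keeps frame right-handed
    ca <- c(x0 + direction * (i - 1) * spacing, y0, z0)
    xyz <- t(apply(tmpl, 1, function(t.)
      ca + t.[1] * e1 + t.[2] * u + t.[3] * e3))
    out_name <- c(out_name, rownames(tmpl))
    out_res <- c(out_res, rep(i, nrow(tmpl)))
    out_rn <- c(out_rn, rep(resnames[i], nrow(tmpl)))
    coords <- rbind(coords, xyz)
  }
  list(atom_name = out_name, residue_index = out_res, residue_name = out_rn,
       chain_id = rep(chain_id, length(out_name)), coords = coords)
}

#' Generate a toy peptide-MHC-like complex
#'
#' Builds a coarse two-chain receptor (chains `A` and `B` as roughly parallel
#' extended walls flanking a groove) with an extended peptide (chain `P`)
#' between them, plus optional explicit waters (chain `W`) parked outside the
#' groove. Every atom carries force-field parameters from the packaged table.
#' Construction is deterministic for a fixed seed (the seed drives a small
#' coordinate jitter that breaks exact symmetries).
#'
#' @param n_alpha,n_beta,n_pep residue counts for chains A, B and the peptide
#'   (use `n_alpha >= 76`, `n_beta >= 90` if the default binding-site and
#'   compartment selections will be applied downstream).
#' @param with_waters number of water residues to add.
#' @param seed integer seed.
#' @param alpha_seq,beta_seq,pep_seq optional residue-name vectors (3-letter
#'   codes), recycled to the chain length; defaults cycle a mixed palette.
#' @param spacing residue spacing along the chain axis, Angstrom.
#' @param groove_halfwidth half the wall-to-wall distance, Angstrom.
#' @param jitter amplitude of the deterministic construction jitter, Angstrom.
#' @return a [MolecularSystem-class].
#' @export
makeToyComplex <- function(n_alpha, n_beta, n_pep, with_waters = 0, seed = 1,
                           alpha_seq = NULL, beta_seq = NULL, pep_seq = NULL,
                           spacing = 3.5, groove_halfwidth = 12, jitter = 0.02) {
  stopifnot(n_alpha >= 1, n_beta >= 1, n_pep >= 0)
  seq_of <- function(s, n) {
    if (is.null(s)) s <- .defaultPalette
    rep_len(s, n)
  }
  # The beta chain runs antiparallel to the alpha chain, as in the real
  # groove, so the default compartment pairs (alpha 50-51 vs beta 85-86,
  # ...) face each other across the cleft. For paper-sized chains the
  # offset aligns the four compartments on average; smaller systems align
  # the chain centres instead.
  x0B <- if (n_alpha >= 76 && n_beta >= 90) 130 * spacing
         else ((n_alpha - 1) + (n_beta - 1)) / 2 * spacing
  parts <- list(
    .layChain(seq_of(alpha_seq, n_alpha), "A", +groove_halfwidth, -1, spacing),
    .layChain(seq_of(beta_seq, n_beta), "B", -groove_halfwidth, +1, spacing,
              x0 = x0B, direction = -1)
  )
  if (n_pep > 0) {
    xA <- c(0, (n_alpha - 1) * spacing)
    xB <- sort(c(x0B, x0B - (n_beta - 1) * spacing))
    overlap <- c(max(xA[1], xB[1]), min(xA[2], xB[2]))
    ctr <- if (overlap[1] < overlap[2]) mean(overlap) else mean(c(xA, xB))
    x0P <- ctr - (n_pep - 1) / 2 * spacing
    parts <- c(parts, list(
      .layChain(seq_of(pep_seq, n_pep), "P", 0, +1, spacing, x0 = x0P)))
  }
  if (with_waters > 0) {
    wn <- character(0); wres <- integer(0); wcoord <- NULL
    per_row <- max(1L, ceiling(sqrt(with_waters)))
    for (i in seq_len(with_waters)) {
      tmpl <- .residueTemplate("HOH")
      origin <- c(((i - 1) %% per_row) * 3.1,
                  ((i - 1) %/% per_row) * 3.1, 14)
      wcoord <- rbind(wcoord, sweep(tmpl, 2, origin, "+"))
      wn <- c(wn, rownames(tmpl)); wres <- c(wres, rep(i, nrow(tmpl)))
    }
    parts <- c(parts, list(list(
      atom_name = wn, residue_index = wres,
      residue_name = rep("HOH", length(wn)),
      chain_id = rep("W", length(wn)), coords = wcoord)))
  }
  atom_name <- unlist(lapply(parts, `[[`, "atom_name"))
  residue_index <- unlist(lapply(parts, `[[`, "residue_index"))
  residue_name <- unlist(lapply(parts, `[[`, "residue_name"))
  chain_id <- unlist(lapply(parts, `[[`, "chain_id"))
  coords <- do.call(rbind, lapply(parts, `[[`, "coords"))
  if (jitter > 0) {
    coords <- coords + withSeed(seed,
      matrix(stats::runif(length(coords), -jitter, jitter), ncol = 3))
  }
  buildSystem(atom_name, residue_index, residue_name, chain_id, coords,
              loadParamTable())
}

#' Fluctuation specification for synthetic trajectories
#'
#' @param mode one of `"isotropic_gaussian"` (iid Gaussian displacement of
#'   every coordinate), `"full_covariance"` (one multivariate Gaussian over
#'   all 3N coordinates) or `"two_state"` (rigid translation of one groove
#'   compartment's beta wall between two target widths).
#' @param amplitude isotropic standard deviation, Angstrom.
#' @param covariance 3N x 3N positive semi-definite matrix (Angstrom^2),
#'   `full_covariance` mode only.
#' @param state_means pair of target compartment widths, Angstrom
#'   (`two_state` mode).
#' @param state_occupancy fraction of frames in state 1 (`two_state` mode);
#'   realized exactly via seeded sampling without replacement.
#' @param compartment compartment name whose beta wall moves (`two_state`).
#' @param seed integer seed for the displacement draw.
#' @return a `FluctuationSpec` list.
#' @export
fluctuationSpec <- function(mode = c("isotropic_gaussian", "full_covariance",
                                     "two_state"),
                            amplitude = 0, covariance = NULL,
                            state_means = NULL, state_occupancy = 0.5,
                            compartment = "D1", seed = 1) {
  mode <- match.arg(mode)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (state_occupancy < 0 || state_occupancy > 1)
    stop("state_occupancy must lie in [0, 1]")
  if (mode == "full_covariance") {
    if (is.null(covariance)) stop("full_covariance mode requires a covariance")
    if (max(abs(covariance - t(covariance))) > 1e-8)
      stop("covariance must be symmetric")
  }
  if (mode == "two_state" && (is.null(state_means) || length(state_means) != 2))
    stop("two_state mode requires two state_means")
  structure(list(mode = mode, amplitude = amplitude, covariance = covariance,
                 state_means = state_means, state_occupancy = state_occupancy,
                 compartment = compartment, seed = seed),
            class = "FluctuationSpec")
}

#' Sample a synthetic trajectory around a system's reference coordinates
#'
#' Frame `t` is the reference plus a displacement drawn according to the
#' [fluctuationSpec()]. In `two_state` mode the beta wall of the chosen
#' compartment is rigidly translated along the cross-groove axis so the
#' compartment's heavy-atom centre-of-mass distance equals the target width
#' of the state active in that frame; state occupancy is realized exactly.
#' Deterministic for a fixed seed.
#'
#' @param system a [MolecularSystem-class].
#' @param spec a [fluctuationSpec()].
#' @param n_frames number of frames.
#' @param frame_interval ps between frames.
#' @return a [TrajectorySeries-class].
#' @export
sampleTrajectory <- function(system, spec, n_frames, frame_interval = 200) {
  stopifnot(inherits(spec, "FluctuationSpec"), n_frames >= 1)
  ref <- system@referenceCoords
  N <- nrow(ref)
  fr <- array(0, dim = c(n_frames, N, 3))
  if (spec$mode == "isotropic_gaussian") {
    noise <- withSeed(spec$seed,
      array(stats::rnorm(n_frames * N * 3, sd = spec$amplitude),
            dim = c(n_frames, N, 3)))
    for (t in seq_len(n_frames))
      fr[t, , ] <- ref + noise[t, , ]
  } else if (spec$mode == "full_covariance") {
    S <- spec$covariance
    if (nrow(S) != 3 * N)
      stop(sprintf("covariance is %d x %d but system needs %d x %d",
                   nrow(S), ncol(S), 3 * N, 3 * N))
    eg <- eigen(S, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values)))
      stop("numeric error: covariance is not positive semi-definite")
    lam <- pmax(eg$values, 0)
    L <- eg$vectors %*% diag(sqrt(lam), length(lam))
    Z <- withSeed(spec$seed,
                  matrix(stats::rnorm(n_frames * 3 * N), nrow = 3 * N))
    D <- L %*% Z  # 3N x T, coordinate order (x1,y1,z1,x2,...)
    for (t in seq_len(n_frames))
      fr[t, , ] <- ref + matrix(D[, t], ncol = 3, byrow = TRUE)
  } else {  # two_state
    cmap <- compartmentSelections(system)
    if (!spec$compartment %in% names(compartments(cmap)))
      stop("unknown compartment '", spec$compartment, "'")
    cp <- compartments(cmap)[[spec$compartment]]
    ia <- selectionAtomIndices(system, cp$alpha, heavy_only = TRUE)
    ib <- selectionAtomIndices(system, cp$beta, heavy_only = TRUE)
    m <- system@atoms$mass
    comA <- massCenter(ref[ia, , drop = FALSE], m[ia])
    comB <- massCenter(ref[ib, , drop = FALSE], m[ib])
    v <- unitVector(comB - comA)
    d0 <- vnorm(comB - comA)
    # atoms translated with the wall: every atom of the beta-wall residues
    wall <- selectionAtomIndices(system, cp$beta)
    n1 <- round(spec$state_occupancy * n_frames)
    in1 <- withSeed(spec$seed, sample(n_frames, n1))
    state <- rep(2L, n_frames); state[in1] <- 1L
    for (t in seq_len(n_frames)) {
      fr[t, , ] <- ref
      shift <- (spec$state_means[state[t]] - d0) * v
      fr[t, wall, ] <- sweep(fr[t, wall, , drop = FALSE][1, , ], 2, shift, "+")
    }
    if (spec$amplitude > 0) {
      noise <- withSeed(spec$seed + 1L,
        array(stats::rnorm(n_frames * N * 3, sd = spec$amplitude),
              dim = c(n_frames, N, 3)))
      fr <- fr + noise
    }
  }
  traj <- new("TrajectorySeries", system = system, frames = fr,
              frameInterval = frame_interval)
  attr(traj, "truth") <- list(spec = spec[c("mode", "amplitude", "state_means",
                                            "state_occupancy", "compartment",
                                            "seed")])
  traj
}

#' Planted interaction specification
#'
#' Ground truth for the interaction detectors: in exactly
#' `round(target_fraction * T)` frames (chosen by a seeded draw without
#' replacement) the planted geometry satisfies the corresponding detector's
#' default criteria with margin; in the remaining frames the partner residue
#' is displaced far outside every cutoff.
#'
#' @param kind `"hbond"`, `"stacking"` or `"hydrophobic"`.
#' @param a,b the two partners, each `c(chain_id, residue_index)`; for
#'   `hbond` the donor is `b` and the acceptor `a` by default.
#' @param target_fraction fraction of frames that must satisfy the criteria.
#' @param geometry per-kind overrides: `d_sat` (satisfying heavy-atom
#'   distance), `stack_sep` (ring centroid separation), `water` (a list
#'   `list(resno =, fraction =)` placing a water oxygen 3 Angstrom from the
#'   hydrophobic contact in that fraction of satisfying frames).
#' @param seed integer seed for the frame draw.
#' @return a `PlantedInteraction` list.
#' @export
plantedInteraction <- function(kind = c("hbond", "stacking", "hydrophobic"),
                               a, b, target_fraction,
                               geometry = list(), seed = 1) {
  kind <- match.arg(kind)
  if (target_fraction < 0 || target_fraction > 1)
    stop("target_fraction must lie in [0, 1]")
  structure(list(kind = kind, a = a, b = b,
                 target_fraction = target_fraction,
                 geometry = geometry, seed = seed),
            class = "PlantedInteraction")
}

# rotation matrix taking unit vector u onto unit vector v
.rotationBetween <- function(u, v) {
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis orthogonal to u
    ax <- if (abs(u[1]) < 0.9) unitVector(pracmaFreeCross(u, c(1, 0, 0)))
          else unitVector(pracmaFreeCross(u, c(0, 1, 0)))
    return(2 * outer(ax, ax) - diag(3))
  }
  w <- pracmaFreeCross(u, v)
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

# plain cross product (avoid extra deps)
pracmaFreeCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Plant a residue-residue interaction into a trajectory
#'
#' Overwrites the coordinates of the partner residues frame by frame so the
#' detector criteria for `plant$kind` hold exactly in the planted fraction of
#' frames (see [plantedInteraction()]). The modified trajectory carries the
#' accumulated planted truth in its `"truth"` attribute.
#'
#' @param traj a [TrajectorySeries-class].
#' @param plant a [plantedInteraction()].
#' @return the modified [TrajectorySeries-class].
#' @export
plantInteraction <- function(traj, plant) {
  stopifnot(inherits(plant, "PlantedInteraction"))
  sys <- traj@system
  T_ <- nFrames(traj)
  fr <- traj@frames
  n_sat <- round(plant$target_fraction * T_)
  sat <- sort(withSeed(plant$seed, sample(T_, n_sat)))
  idx_a <- residueAtomIndices(sys, plant$a[1], as.integer(plant$a[2]))
  idx_b <- residueAtomIndices(sys, plant$b[1], as.integer(plant$b[2]))
  if (!length(idx_a) || !length(idx_b))
    stop("configuration error: planted partner residue not found")
  aname <- sys@atoms$atom_name

  if (plant$kind == "hbond") {
    d_sat <- plant$geometry$d_sat %||% 2.8
    iN <- idx_b[aname[idx_b] == "N"]; iH <- idx_b[aname[idx_b] == "H"]
    iO <- idx_a[aname[idx_a] == "O"]
    if (!length(iN) || !length(iH) || !length(iO))
      stop("configuration error: hbond plant needs donor N-H and acceptor O")
    for (t in seq_len(T_)) {
      Np <- fr[t, iN, ]; Hp <- fr[t, iH, ]
      dir <- unitVector(Hp - Np)
      target_O <- if (t %in% sat) Np + d_sat * dir else Np + dir * 2 + c(0, 0, 15)
      delta <- target_O - fr[t, iO, ]
      fr[t, idx_a, ] <- sweep(fr[t, idx_a, , drop = FALSE][1, , ], 2, delta, "+")
    }
  } else if (plant$kind == "stacking") {
    sep <- plant$geometry$stack_sep %||% 3.6
    ring_a <- residueAtomIndices(sys, plant$a[1], as.integer(plant$a[2]),
                                 ringAtomNames(sys, plant$a))
    ring_b <- residueAtomIndices(sys, plant$b[1], as.integer(plant$b[2]),
                                 ringAtomNames(sys, plant$b))
    if (length(ring_a) < 3 || length(ring_b) < 3)
      stop("configuration error: stacking plant needs planar residues")
    for (t in seq_len(T_)) {
      A <- fr[t, ring_a, , drop = FALSE][1, , ]
      pa <- fitPlane(A)
      if (t %in% sat) {
        B <- fr[t, ring_b, , drop = FALSE][1, , ]
        pb <- fitPlane(B)
        R <- .rotationBetween(pb$normal, pa$normal)
        all_b <- fr[t, idx_b, , drop = FALSE][1, , ]
        rot <- t(R %*% t(sweep(all_b, 2, pb$centroid)))
        target_centroid <- pa$centroid + sep * pa$normal
        fr[t, idx_b, ] <- sweep(rot, 2, target_centroid, "+")
      } else {
        delta <- pa$centroid + c(0, 0, 15) -
          colMeans(fr[t, ring_b, , drop = FALSE][1, , ])
        fr[t, idx_b, ] <- sweep(fr[t, idx_b, , drop = FALSE][1, , ], 2, delta, "+")
      }
    }
  } else {  # hydrophobic
    d_sat <- plant$geometry$d_sat %||% 3.6
    iCBa <- idx_a[aname[idx_a] == "CB"]
    iCBb <- idx_b[aname[idx_b] == "CB"]
    if (!length(iCBa) || !length(iCBb))
      stop("configuration error: hydrophobic plant needs CB atoms on both partners")
    w <- plant$geometry$water
    wat_frames <- integer(0)
    if (!is.null(w)) {
      iWO <- residueAtomIndices(sys, "W", as.integer(w$resno), "O")
      iW <- residueAtomIndices(sys, "W", as.integer(w$resno))
      if (!length(iWO)) stop("configuration error: water residue not found")
      n_wet <- round((w$fraction %||% 0.5) * n_sat)
      wat_frames <- sort(withSeed(plant$seed + 7L, sample(sat, n_wet)))
    }
    # inward direction of residue a: from the chain wall towards the groove
    u_a <- switch(plant$a[1], A = c(0, -1, 0), B = c(0, 1, 0), c(0, 1, 0))
    for (t in seq_len(T_)) {
      CBa <- fr[t, iCBa, ]
      target_CB <- if (t %in% sat) CBa + d_sat * u_a else CBa + c(0, 0, 15)
      delta <- target_CB - fr[t, iCBb, ]
      fr[t, idx_b, ] <- sweep(fr[t, idx_b, , drop = FALSE][1, , ], 2, delta, "+")
      if (!is.null(w)) {
        wo_target <- if (t %in% wat_frames) CBa + c(0, 0, 3.0)
                     else sys@referenceCoords[iWO, ]
        dw <- wo_target - fr[t, iWO, ]
        fr[t, iW, ] <- sweep(fr[t, iW, , drop = FALSE][1, , ], 2, dw, "+")
      }
    }
  }
  out <- new("TrajectorySeries", system = sys, frames = fr,
             frameInterval = traj@frameInterval)
  truth <- attr(traj, "truth") %||% list()
  truth$plants <- c(truth$plants, list(list(
    kind = plant$kind, a = plant$a, b = plant$b,
    target_fraction = plant$target_fraction,
    realized_fraction = n_sat / T_, frames = sat, seed = plant$seed)))
  attr(out, "truth") <- truth
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write the planted ground truth of a synthetic trajectory to JSON
#'
#' @param traj a [TrajectorySeries-class] produced by [sampleTrajectory()]
#'   and/or [plantInteraction()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTruthFile <- function(traj, path) {
  truth <- attr(traj, "truth")
  if (is.null(truth)) stop("trajectory carries no planted truth")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
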