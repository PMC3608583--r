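# Persistence-based interaction detectors: hydrogen bonds, aromatic/planar
# stacking, and water-excluded hydrophobic contacts between two residue
# groups over a trajectory.

#' Hydrogen-bond detection criteria
#'
#' A frame counts for a residue pair if any donor/acceptor atom pair has a
#' donor-acceptor heavy-atom distance at or below `da_cutoff` and a
#' donor-hydrogen-acceptor angle at or above `angle_cutoff` (near-linear
#' bonds pass).
#'
#' @param da_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cutoff minimum donor-H-acceptor angle, degrees.
#' @param persistence_threshold minimum fraction of frames for reporting.
#' @return an `HBondCriteria` list.
#' @export
hbondCriteria <- function(da_cutoff = 3.1, angle_cutoff = 130,
                          persistence_threshold = 0.2) {
  stopifnot(da_cutoff > 0, angle_cutoff > 0,
            persistence_threshold >= 0, persistence_threshold <= 1)
  structure(list(da_cutoff = da_cutoff, angle_cutoff = angle_cutoff,
                 persistence_threshold = persistence_threshold),
            class = "HBondCriteria")
}

#' Aromatic/planar stacking detection criteria
#'
#' A frame counts if the acute angle between the least-squares planes of the
#' two planar side-chain groups is at or below `dihedral_cutoff` and the
#' ring-centroid distance at or below `centroid_cutoff`. Arginine's
#' guanidinium group counts as planar.
#'
#' @param dihedral_cutoff maximum plane-plane angle, degrees.
#' @param centroid_cutoff maximum centroid distance, Angstrom.
#' @param persistence_threshold minimum fraction of frames for reporting.
#' @param planar_residues residue names carrying a planar/ring group.
#' @return a `StackCriteria` list.
#' @export
stackCriteria <- function(dihedral_cutoff = 30, centroid_cutoff = 5.0,
                          persistence_threshold = 0.2,
                          planar_residues = c("HIS", "PHE", "TYR", "TRP", "ARG")) {
  stopifnot(dihedral_cutoff > 0, centroid_cutoff > 0,
            persistence_threshold >= 0, persistence_threshold <= 1)
  structure(list(dihedral_cutoff = dihedral_cutoff,
                 centroid_cutoff = centroid_cutoff,
                 persistence_threshold = persistence_threshold,
                 planar_residues = planar_residues),
            class = "StackCriteria")
}

#' Hydrophobic-contact detection criteria
#'
#' A frame counts if the minimum side-chain heavy-atom distance between the
#' two residues is at or below `contact_cutoff` and no water oxygen lies
#' within `water_exclusion_radius` of any contact-forming atom.
#'
#' @param contact_cutoff side-chain heavy-atom distance cutoff, Angstrom.
#' @param water_exclusion_radius water-oxygen exclusion radius, Angstrom.
#' @param persistence_threshold minimum fraction of frames for reporting.
#' @param hydrophobic_residues residue names in the hydrophobic class.
#' @return a `HydrophobicCriteria` list.
#' @export
hydrophobicCriteria <- function(contact_cutoff = 4.0,
                                water_exclusion_radius = 4.0,
                                persistence_threshold = 0.2,
                                hydrophobic_residues = c("ALA", "VAL", "LEU",
                                                         "ILE", "PRO", "PHE",
                                                         "MET", "TRP")) {
  stopifnot(contact_cutoff > 0, water_exclusion_radius > 0,
            persistence_threshold >= 0, persistence_threshold <= 1)
  structure(list(contact_cutoff = contact_cutoff,
                 water_exclusion_radius = water_exclusion_radius,
                 persistence_threshold = persistence_threshold,
                 hydrophobic_residues = hydrophobic_residues),
            class = "HydrophobicCriteria")
}

# donor (heavy, hydrogen) atom-name pairs per residue; backbone N-H is added
# for every non-proline amino acid
.sideChainDonors <- list(
  ARG = list(c("NE", "HE"), c("NH1", "HH11"), c("NH1", "HH12"),
             c("NH2", "HH21"), c("NH2", "HH22")),
  ASN = list(c("ND2", "HD21"), c("ND2", "HD22")),
  GLN = list(c("NE2", "HE21"), c("NE2", "HE22")),
  HIS = list(c("ND1", "HD1")),
  LYS = list(c("NZ", "HZ1"), c("NZ", "HZ2"), c("NZ", "HZ3")),
  SER = list(c("OG", "HG")),
  THR = list(c("OG1", "HG1")),
  TYR = list(c("OH", "HH")),
  TRP = list(c("NE1", "HE1")),
  CYS = list(c("SG", "HG")),
  HOH = list(c("O", "H1"), c("O", "H2")),
  WAT = list(c("O", "H1"), c("O", "H2")),
  TIP3 = list(c("O", "H1"), c("O", "H2"))
)

# acceptor atom names per residue; backbone O is added for amino acids
.sideChainAcceptors <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = "NE2", SER = "OG", THR = "OG1", TYR = "OH", MET = "SD",
  HOH = "O", WAT = "O", TIP3 = "O"
)

.ringAtoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  ARG = c("CZ", "NE", "NH1", "NH2")
)

# ring atom names for a (chain, resno) partner
ringAtomNames <- function(system, partner) {
  a <- system@atoms
  rn <- a$residue_name[a$chain_id == partner[1] &
                       a$residue_index == as.integer(partner[2])][1]
  if (is.na(rn) || is.null(.ringAtoms[[rn]]))
    stop("configuration error: residue ", partner[1], ":", partner[2],
         " (", rn, ") has no planar group")
  .ringAtoms[[rn]]
}

# least-squares plane through an n x 3 point set
fitPlane <- function(X) {
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

# donor triples (heavy idx, H idx) for one residue; atoms actually present
.residueDonors <- function(system, idx) {
  a <- system@atoms
  rn <- a$residue_name[idx[1]]
  pairs <- .sideChainDonors[[rn]]
  if (!rn %in% c(.waterResnames) && rn != "PRO")
    pairs <- c(list(c("N", "H")), pairs)
  out <- NULL
  for (p in pairs) {
    iD <- idx[a$atom_name[idx] == p[1]]
    iH <- idx[a$atom_name[idx] == p[2]]
    if (length(iD) && length(iH)) out <- rbind(out, c(iD, iH))
  }
  out
}

.residueAcceptors <- function(system, idx) {
  a <- system@atoms
  rn <- a$residue_name[idx[1]]
  nm <- .sideChainAcceptors[[rn]]
  if (!rn %in% .waterResnames) nm <- c("O", nm)
  idx[a$atom_name[idx] %in% nm]
}

# split a selection into its residues, returning list of atom index vectors
.selectionResidues <- function(system, selection) {
  mem <- members(selection)
  out <- list()
  for (i in seq_len(nrow(mem))) {
    idx <- residueAtomIndices(system, mem$chain[i], mem$resno[i])
    if (length(idx)) out[[length(out) + 1L]] <- idx
  }
  out
}

# per-frame distance between two atoms, vectorized over frames
.frameDist <- function(fr, i, j) {
  sqrt((fr[, i, 1] - fr[, j, 1])^2 + (fr[, i, 2] - fr[, j, 2])^2 +
       (fr[, i, 3] - fr[, j, 3])^2)
}

# assemble an InteractionSet from candidate records
.makeInteractionSet <- function(kind, system, pairs, presence, threshold) {
  a <- system@atoms
  if (length(pairs) == 0) {
    return(new("InteractionSet",
               records = data.frame(kind = character(0), chain_a = character(0),
                                    res_a = integer(0), name_a = character(0),
                                    chain_b = character(0), res_b = integer(0),
                                    name_b = character(0),
                                    persistence = numeric(0)),
               presence = matrix(FALSE, nrow = 0, ncol = 0)))
  }
  pers <- vapply(presence, mean, numeric(1))
  keep <- pers >= threshold & (pers > 0 | threshold == 0)
  rec <- do.call(rbind, lapply(which(keep), function(k) {
    ia <- pairs[[k]]$a[1]; ib <- pairs[[k]]$b[1]
    data.frame(kind = kind,
               chain_a = a$chain_id[ia], res_a = a$residue_index[ia],
               name_a = a$residue_name[ia],
               chain_b = a$chain_id[ib], res_b = a$residue_index[ib],
               name_b = a$residue_name[ib],
               persistence = pers[k], stringsAsFactors = FALSE)
  }))
  if (is.null(rec))
    rec <- data.frame(kind = character(0), chain_a = character(0),
                      res_a = integer(0), name_a = character(0),
                      chain_b = character(0), res_b = integer(0),
                      name_b = character(0), persistence = numeric(0))
  pm <- if (nrow(rec)) do.call(cbind, presence[keep]) else
    matrix(FALSE, nrow = length(presence[[1]]), ncol = 0)
  new("InteractionSet", records = rec, presence = pm)
}

# cheap residue-pair prefilter: minimum over frames of CA-CA (or first-atom)
# distance must be below reach for the pair ever to interact
.pairReachable <- function(fr, system, idx_a, idx_b, reach) {
  a <- system@atoms
  ca_a <- idx_a[a$atom_name[idx_a] %in% c("CA", "O")][1]
  ca_b <- idx_b[a$atom_name[idx_b] %in% c("CA", "O")][1]
  if (is.na(ca_a)) ca_a <- idx_a[1]
  if (is.na(ca_b)) ca_b <- idx_b[1]
  min(.frameDist(fr, ca_a, ca_b)) <= reach
}

#' Detect persistent hydrogen bonds between two residue groups
#'
#' Evaluates every residue pair across the two groups in both donor/acceptor
#' directions; multiple atom pairs within one residue pair are OR-combined
#' into a single residue-level record. Records with persistence at or above
#' the criteria threshold are returned (a threshold of 0 returns all
#' candidate pairs).
#'
#' @param traj a [TrajectorySeries-class] (explicit polar hydrogens required
#'   on donors).
#' @param group_a,group_b [ResidueSelection-class] groups (e.g. beta-chain
#'   binding-site residues vs the peptide).
#' @param criteria an [hbondCriteria()].
#' @return an [InteractionSet-class].
#' @export
detectHbonds <- function(traj, group_a, group_b, criteria = hbondCriteria()) {
  sys <- traj@system
  fr <- traj@frames
  T_ <- nFrames(traj)
  resA <- .selectionResidues(sys, group_a)
  resB <- .selectionResidues(sys, group_b)
  reach <- 18 + criteria$da_cutoff
  pairs <- list(); presence <- list()
  for (ia in resA) for (ib in resB) {
    if (!.pairReachable(fr, sys, ia, ib, reach)) next
    donA <- .residueDonors(sys, ia); accA <- .residueAcceptors(sys, ia)
    donB <- .residueDonors(sys, ib); accB <- .residueAcceptors(sys, ib)
    pres <- rep(FALSE, T_)
    hit <- function(don, acc) {
      if (is.null(don) || !length(acc)) return()
      for (r in seq_len(nrow(don))) {
        iD <- don[r, 1]; iH <- don[r, 2]
        for (iA in acc) {
          dda <- .frameDist(fr, iD, iA)
          cand <- which(dda <= criteria$da_cutoff & !pres)
          if (!length(cand)) next
          v1 <- fr[cand, iD, , drop = FALSE][, 1, ] - fr[cand, iH, , drop = FALSE][, 1, ]
          v2 <- fr[cand, iA, , drop = FALSE][, 1, ] - fr[cand, iH, , drop = FALSE][, 1, ]
          if (length(cand) == 1) { v1 <- matrix(v1, 1); v2 <- matrix(v2, 1) }
          cosang <- rowSums(v1 * v2) /
            (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          pres[cand[ang >= criteria$angle_cutoff]] <<- TRUE
        }
      }
    }
    hit(donB, accA)  # donor on b, acceptor on a
    hit(donA, accB)
    if (any(pres) || criteria$persistence_threshold == 0) {
      pairs[[length(pairs) + 1L]] <- list(a = ia, b = ib)
      presence[[length(presence) + 1L]] <- pres
    }
  }
  .makeInteractionSet("hbond", sys, pairs, presence,
                      criteria$persistence_threshold)
}

#' Detect persistent planar stacking between two residue groups
#'
#' Candidate pairs are those where both residues belong to the criteria's
#' planar class and carry their full ring/planar atom set. Planes are
#' least-squares fits; the plane-plane angle is the acute angle between
#' normals.
#'
#' @inheritParams detectHbonds
#' @param criteria a [stackCriteria()].
#' @return an [InteractionSet-class].
#' @export
detectStacking <- function(traj, group_a, group_b, criteria = stackCriteria()) {
  sys <- traj@system
  a <- sys@atoms
  fr <- traj@frames
  T_ <- nFrames(traj)
  ringIdx <- function(idx) {
    rn <- a$residue_name[idx[1]]
    if (!rn %in% criteria$planar_residues) return(NULL)
    nm <- .ringAtoms[[rn]]
    if (is.null(nm)) return(NULL)
    ri <- idx[a$atom_name[idx] %in% nm]
    if (length(ri) < length(nm))
      stop("configuration error: planar residue ", a$chain_id[idx[1]], ":",
           a$residue_index[idx[1]], " (", rn, ") is missing ring atoms")
    ri
  }
  resA <- .selectionResidues(sys, group_a)
  resB <- .selectionResidues(sys, group_b)
  pairs <- list(); presence <- list()
  for (ia in resA) {
    ra <- ringIdx(ia); if (is.null(ra)) next
    for (ib in resB) {
      rb <- ringIdx(ib); if (is.null(rb)) next
      if (!.pairReachable(fr, sys, ia, ib, 18 + criteria$centroid_cutoff)) next
      pres <- rep(FALSE, T_)
      for (t in seq_len(T_)) {
        A <- fr[t, ra, , drop = FALSE][1, , ]
        B <- fr[t, rb, , drop = FALSE][1, , ]
        cA <- colMeans(A); cB <- colMeans(B)
        if (vnorm(cA - cB) > criteria$centroid_cutoff) next
        nA <- fitPlane(A)$normal; nB <- fitPlane(B)$normal
        ang <- acos(pmin(abs(sum(nA * nB)), 1)) * 180 / pi
        pres[t] <- ang <= criteria$dihedral_cutoff
      }
      if (any(pres) || criteria$persistence_threshold == 0) {
        pairs[[length(pairs) + 1L]] <- list(a = ia, b = ib)
        presence[[length(presence) + 1L]] <- pres
      }
    }
  }
  .makeInteractionSet("stacking", sys, pairs, presence,
                      criteria$persistence_threshold)
}

#' Detect persistent water-excluded hydrophobic contacts
#'
#' Candidate pairs are those where both residues belong to the hydrophobic
#' class. A frame counts if the minimum side-chain heavy-atom distance is at
#' or below the contact cutoff and no water oxygen lies within the exclusion
#' radius of any contact-forming atom.
#'
#' @inheritParams detectHbonds
#' @param criteria a [hydrophobicCriteria()].
#' @return an [InteractionSet-class].
#' @export
detectHydrophobic <- function(traj, group_a, group_b,
                              criteria = hydrophobicCriteria()) {
  sys <- traj@system
  a <- sys@atoms
  fr <- traj@frames
  T_ <- nFrames(traj)
  bbNames <- c("N", "H", "CA", "C", "O")
  scIdx <- function(idx) {
    rn <- a$residue_name[idx[1]]
    if (!rn %in% criteria$hydrophobic_residues) return(NULL)
    si <- idx[!(a$atom_name[idx] %in% bbNames) & a$is_heavy[idx]]
    if (!length(si)) return(NULL)
    si
  }
  watO <- which(a$chain_id == "W" & a$atom_name == "O")
  resA <- .selectionResidues(sys, group_a)
  resB <- .selectionResidues(sys, group_b)
  pairs <- list(); presence <- list()
  for (ia in resA) {
    sa <- scIdx(ia); if (is.null(sa)) next
    for (ib in resB) {
      sb <- scIdx(ib); if (is.null(sb)) next
      if (!.pairReachable(fr, sys, ia, ib, 18 + criteria$contact_cutoff)) next
      pres <- rep(FALSE, T_)
      for (t in seq_len(T_)) {
        A <- matrix(fr[t, sa, ], ncol = 3)
        B <- matrix(fr[t, sb, ], ncol = 3)
        D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
        ok <- D2 <= criteria$contact_cutoff^2 + 1e-12
        if (!any(ok)) next
        if (length(watO)) {
          contact <- c(sa[unique(which(ok, arr.ind = TRUE)[, 1])],
                       sb[unique(which(ok, arr.ind = TRUE)[, 2])])
          Cc <- matrix(fr[t, contact, ], ncol = 3)
          Wc <- matrix(fr[t, watO, ], ncol = 3)
          DW2 <- outer(rowSums(Cc^2), rowSums(Wc^2), "+") - 2 * Cc %*% t(Wc)
          if (any(DW2 <= criteria$water_exclusion_radius^2 + 1e-12)) next
        }
        pres[t] <- TRUE
      }
      if (any(pres) || criteria$persistence_threshold == 0) {
        pairs[[length(pairs) + 1L]] <- list(a = ia, b = ib)
        presence[[length(presence) + 1L]] <- pres
      }
    }
  }
  .makeInteractionSet("hydrophobic", sys, pairs, presence,
                      criteria$persistence_threshold)
}

#' Merge detector outputs into one network table
#'
#' @param ... [InteractionSet-class] objects from the three detectors, run
#'   on the same trajectory.
#' @return data.frame keyed by (kind, chain_a, res_a, chain_b, res_b) with
#'   residue names and persistence, sorted for stable comparison across
#'   systems.
#' @export
networkSummary <- function(...) {
  sets <- list(...)
  tabs <- lapply(sets, function(s) records(s))
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0) {
    return(data.frame(kind = character(0), chain_a = character(0),
                      res_a = integer(0), name_a = character(0),
                      chain_b = character(0), res_b = integer(0),
                      name_b = character(0), persistence = numeric(0)))
  }
  key <- with(tab, paste(kind, chain_a, res_a, chain_b, res_b))
  if (anyDuplicated(key))
    stop("internal error: duplicate interaction keys; detectors must pre-aggregate")
  tab[order(tab$kind, tab$chain_a, tab$res_a, tab$res_b), , drop = FALSE]
}
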