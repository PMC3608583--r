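# Shared fixtures and independent oracles, built in code.

# glycine background sequence with named substitutions, e.g.
# glySeq(95, `82` = "SER")
glySeq <- function(n, ...) {
  subs <- list(...)
  s <- rep("GLY", n)
  for (pos in names(subs)) s[as.integer(pos)] <- subs[[pos]]
  s
}

# full-size toy complex on a clean glycine background with substitutions
# given as lists: beta = c(`82` = "SER"), pep = c(`5` = "VAL")
cleanComplex <- function(beta = NULL, pep = NULL, alpha = NULL,
                         with_waters = 0, seed = 1) {
  mk <- function(n, subs) {
    s <- rep("GLY", n)
    for (pos in names(subs)) s[as.integer(pos)] <- subs[[pos]]
    s
  }
  makeToyComplex(80, 95, 14, with_waters = with_waters, seed = seed,
                 alpha_seq = mk(80, alpha), beta_seq = mk(95, beta),
                 pep_seq = mk(14, pep))
}

selBeta <- function() residueSelection("B", 5:90, "beta_site")
selPep <- function() residueSelection("P", 1:14, "peptide")

# random rigid transformation of an N x 3 coordinate matrix
rigidTransform <- function(X, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  shift <- rnorm(3, sd = 20)
  sweep(X %*% t(R), 2, shift, "+")
}

# --- independent superposition oracle: coarse rotation grid + Nelder-Mead
# polish over Euler angles; never calls the package's Kabsch path -------------
gridRmsdOracle <- function(P, Q, coarse_deg = 20) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  rotFromEuler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((P0 %*% t(rotFromEuler(a)) - Q0)^2)))
  step <- coarse_deg * pi / 180
  grid <- expand.grid(a1 = seq(0, 2 * pi - step, by = step),
                      a2 = seq(0, pi, by = step),
                      a3 = seq(0, 2 * pi - step, by = step))
  vals <- apply(grid, 1, obj)
  best <- order(vals)[1:5]
  opt <- Inf
  for (b in best) {
    r <- stats::optim(as.numeric(grid[b, ]), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    opt <- min(opt, r$value)
  }
  opt
}

# --- independent brute-force interaction detectors ---------------------------
# Naive per-frame re-implementations of the three criteria, written as plain
# loops straight from their definitions.

.bfDonorPairs <- list(
  ARG = list(c("NE", "HE"), c("NH1", "HH11"), c("NH1", "HH12"),
             c("NH2", "HH21"), c("NH2", "HH22")),
  ASN = list(c("ND2", "HD21"), c("ND2", "HD22")),
  GLN = list(c("NE2", "HE21"), c("NE2", "HE22")),
  HIS = list(c("ND1", "HD1")),
  LYS = list(c("NZ", "HZ1"), c("NZ", "HZ2"), c("NZ", "HZ3")),
  SER = list(c("OG", "HG")), THR = list(c("OG1", "HG1")),
  TYR = list(c("OH", "HH")), TRP = list(c("NE1", "HE1")),
  CYS = list(c("SG", "HG")),
  HOH = list(c("O", "H1"), c("O", "H2"))
)
.bfAcceptors <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = "NE2", SER = "OG", THR = "OG1", TYR = "OH", MET = "SD", HOH = "O"
)
.bfRings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  ARG = c("CZ", "NE", "NH1", "NH2")
)

# one frame, one residue pair: does any donor/acceptor combination qualify?
bruteHbondFrame <- function(coords, at, resA, resB, da = 3.1, ang_min = 130) {
  angle <- function(p1, p2, p3) {
    v1 <- p1 - p2; v2 <- p3 - p2
    acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
  }
  oneWay <- function(don_idx, acc_idx) {
    rn <- at$residue_name[don_idx[1]]
    pairs <- .bfDonorPairs[[rn]]
    if (!rn %in% c("HOH", "WAT", "TIP3", "PRO")) pairs <- c(list(c("N", "H")), pairs)
    rn2 <- at$residue_name[acc_idx[1]]
    accn <- .bfAcceptors[[rn2]]
    if (!rn2 %in% c("HOH", "WAT", "TIP3")) accn <- c("O", accn)
    for (p in pairs) {
      iD <- don_idx[at$atom_name[don_idx] == p[1]]
      iH <- don_idx[at$atom_name[don_idx] == p[2]]
      if (!length(iD) || !length(iH)) next
      for (iA in acc_idx[at$atom_name[acc_idx] %in% accn]) {
        if (sqrt(sum((coords[iD, ] - coords[iA, ])^2)) > da) next
        if (angle(coords[iD, ], coords[iH, ], coords[iA, ]) >= ang_min)
          return(TRUE)
      }
    }
    FALSE
  }
  oneWay(resB, resA) || oneWay(resA, resB)
}

bruteStackFrame <- function(coords, at, resA, resB, dih = 30, cent = 5.0) {
  ringOf <- function(idx) {
    nm <- .bfRings[[at$residue_name[idx[1]]]]
    if (is.null(nm)) return(NULL)
    ri <- idx[at$atom_name[idx] %in% nm]
    if (length(ri) < 3) NULL else ri
  }
  ra <- ringOf(resA); rb <- ringOf(resB)
  if (is.null(ra) || is.null(rb)) return(FALSE)
  A <- coords[ra, , drop = FALSE]; B <- coords[rb, , drop = FALSE]
  cA <- colMeans(A); cB <- colMeans(B)
  if (sqrt(sum((cA - cB)^2)) > cent) return(FALSE)
  nrm <- function(X) {
    sv <- svd(sweep(X, 2, colMeans(X)))
    sv$v[, 3]
  }
  a <- acos(min(abs(sum(nrm(A) * nrm(B))), 1)) * 180 / pi
  a <= dih
}

bruteHydrophobicFrame <- function(coords, at, resA, resB, cutoff = 4.0,
                                  wexcl = 4.0,
                                  hclass = c("ALA", "VAL", "LEU", "ILE",
                                             "PRO", "PHE", "MET", "TRP")) {
  bb <- c("N", "H", "CA", "C", "O")
  scOf <- function(idx) {
    if (!at$residue_name[idx[1]] %in% hclass) return(NULL)
    si <- idx[!(at$atom_name[idx] %in% bb) & at$is_heavy[idx]]
    if (length(si)) si else NULL
  }
  sa <- scOf(resA); sb <- scOf(resB)
  if (is.null(sa) || is.null(sb)) return(FALSE)
  contact <- integer(0)
  found <- FALSE
  for (i in sa) for (j in sb) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
      found <- TRUE
      contact <- union(contact, c(i, j))
    }
  }
  if (!found) return(FALSE)
  wat <- which(at$chain_id == "W" & at$atom_name == "O")
  for (w in wat) for (i in contact)
    if (sqrt(sum((coords[w, ] - coords[i, ])^2)) <= wexcl) return(FALSE)
  TRUE
}

# --- entropy closed form on a known covariance -------------------------------
entropyClosedForm <- function(Sigma, masses_per_atom, temperature = 310,
                              drop_tol = 1e-10) {
  m <- rep(masses_per_atom, each = 3)
  lam <- eigen((sqrt(m) %o% sqrt(m)) * Sigma, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > drop_tol]
  kB <- 1.9872e-3; kBSI <- 1.380649e-23; hbar <- 1.054571817e-34
  al <- hbar / sqrt(kBSI * temperature * lam * 1.66053906660e-27 * 1e-20)
  s <- al / (exp(al) - 1) - log(1 - exp(-al))
  kB * temperature * sum(s)
}

# covariance over n atoms whose variance lies in the rigid-motion-free
# subspace at the given reference coordinates (plus a small floor there)
rigidFreeCovariance <- function(coords, n_modes = 8, sd = 0.15,
                                floor = 0.01, seed = 99) {
  n <- nrow(coords)
  X0 <- sweep(coords, 2, colMeans(coords))
  basis <- matrix(0, 3 * n, 6)
  for (d in 1:3) basis[seq(d, 3 * n, by = 3), d] <- 1
  for (i in seq_len(n)) {
    r <- X0[i, ]
    basis[(3 * i - 2):(3 * i), 4] <- c(0, -r[3], r[2])
    basis[(3 * i - 2):(3 * i), 5] <- c(r[3], 0, -r[1])
    basis[(3 * i - 2):(3 * i), 6] <- c(-r[2], r[1], 0)
  }
  Q <- qr.Q(qr(basis))
  P <- diag(3 * n) - Q %*% t(Q)
  set.seed(seed)
  A <- matrix(rnorm(3 * n * n_modes, sd = sd), 3 * n, n_modes)
  P %*% (A %*% t(A) + floor * diag(3 * n)) %*% P
}

# 30-CA chain used by the entropy oracle tests
caChain <- function(n = 30) {
  coords <- cbind(seq(0, by = 3.8, length.out = n),
                  sin(seq_len(n)), cos(seq_len(n)) * 0.5)
  molecularSystem(rep("CA", n), seq_len(n), rep("GLY", n), rep("A", n), coords)
}

# hand-rolled minimal PDB writer for hand-written fixtures
pdbLines <- function(name, resn, chain, resno, xyz) {
  vapply(seq_along(name), function(i) {
    nm <- name[i]
    nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, nmfmt, resn[i], chain[i], resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
}
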