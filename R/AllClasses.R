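#' @import methods
NULL

#' MolecularSystem: topology plus reference coordinates
#'
#' Static description of a peptide-MHC-like molecular system: one row per
#' atom (name, element, chain, residue, mass, partial charge, Lennard-Jones
#' parameters, Born radius seed) together with an N x 3 matrix of reference
#' Cartesian coordinates in Angstrom.
#'
#' Chain identifiers follow the MHC class II convention used throughout the
#' package: `A` = MHC alpha chain, `B` = MHC beta chain, `P` = bound peptide,
#' `W` = water.
#'
#' @slot atoms data.frame with columns `atom_name`, `element`,
#'   `residue_index` (1-based, per chain), `residue_name`, `chain_id`,
#'   `mass` (amu), `charge` (e), `epsilon` (kcal/mol), `rmin_half` (Angstrom),
#'   `radius` (Angstrom), `is_heavy` (logical).
#' @slot referenceCoords numeric N x 3 matrix, Angstrom.
#' @slot chainIndex named list mapping each chain id to its atom indices.
#'
#' @exportClass MolecularSystem
setClass("MolecularSystem",
  representation(
    atoms = "data.frame",
    referenceCoords = "matrix",
    chainIndex = "list"
  )
)

setValidity("MolecularSystem", function(object) {
  a <- object@atoms
  need <- c("atom_name", "element", "residue_index", "residue_name",
            "chain_id", "mass", "charge", "epsilon", "rmin_half",
            "radius", "is_heavy")
  miss <- setdiff(need, names(a))
  if (length(miss)) return(paste("atoms lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(object@referenceCoords) != nrow(a))
    return(sprintf("referenceCoords has %d rows but %d atoms",
                   nrow(object@referenceCoords), nrow(a)))
  if (ncol(object@referenceCoords) != 3) return("referenceCoords must be N x 3")
  if (any(a$mass <= 0)) return("atom masses must be positive")
  if (any(a$residue_index < 1)) return("residue_index must be strictly positive")
  if (any(a$is_heavy != (a$element != "H")))
    return("is_heavy must equal (element != 'H')")
  for (ch in unique(a$chain_id)) {
    if (is.null(object@chainIndex[[ch]]))
      return(sprintf("chain '%s' missing from chainIndex", ch))
  }
  TRUE
})

#' TrajectorySeries: ordered coordinate frames for a MolecularSystem
#'
#' @slot system the [MolecularSystem-class] the frames belong to.
#' @slot frames numeric T x N x 3 array, Angstrom.
#' @slot frameInterval time between consecutive frames, picoseconds.
#'
#' @exportClass TrajectorySeries
setClass("TrajectorySeries",
  representation(
    system = "MolecularSystem",
    frames = "array",
    frameInterval = "numeric"
  )
)

setValidity("TrajectorySeries", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3 || d[3] != 3) return("frames must be a T x N x 3 array")
  if (d[1] < 1) return("trajectory must contain at least one frame")
  if (d[2] != nrow(object@system@atoms))
    return(sprintf("frames have %d atoms but system has %d",
                   d[2], nrow(object@system@atoms)))
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    return("frameInterval must be a single positive number (ps)")
  TRUE
})

#' ResidueSelection: a named set of (chain, residue) members
#'
#' @slot label character label for provenance.
#' @slot chain character vector of chain ids, parallel to `resno`.
#' @slot resno integer vector of 1-based per-chain residue indices.
#'
#' @exportClass ResidueSelection
setClass("ResidueSelection",
  representation(label = "character", chain = "character", resno = "integer")
)

setValidity("ResidueSelection", function(object) {
  if (length(object@chain) != length(object@resno))
    return("chain and resno must have equal length")
  if (length(object@resno) == 0) return("selection must be non-empty")
  if (anyDuplicated(paste(object@chain, object@resno)))
    return("selection members must be unique")
  TRUE
})

#' CompartmentMap: paired alpha/beta groove-wall selections
#'
#' The binding groove of an MHC class II molecule is dissected into named
#' compartments (default D1-D4), each defined by a residue range on the
#' alpha-chain wall and one on the beta-chain wall. Cross-groove
#' centre-of-mass distances per compartment track local groove width.
#'
#' @slot compartments named list; each element is a list with elements
#'   `alpha` and `beta`, both [ResidueSelection-class] objects.
#'
#' @exportClass CompartmentMap
setClass("CompartmentMap", representation(compartments = "list"))

setValidity("CompartmentMap", function(object) {
  if (length(object@compartments) == 0) return("at least one compartment required")
  if (is.null(names(object@compartments)) || any(names(object@compartments) == ""))
    return("compartments must be named")
  for (nm in names(object@compartments)) {
    cp <- object@compartments[[nm]]
    if (!is(cp$alpha, "ResidueSelection") || !is(cp$beta, "ResidueSelection"))
      return(sprintf("compartment '%s' must hold alpha and beta ResidueSelections", nm))
    ka <- paste(cp$alpha@chain, cp$alpha@resno)
    kb <- paste(cp$beta@chain, cp$beta@resno)
    if (length(intersect(ka, kb)))
      return(sprintf("compartment '%s': alpha and beta selections overlap", nm))
  }
  TRUE
})

#' ScalarSeries: one scalar observable per trajectory frame
#'
#' @slot values numeric vector, one value per frame (Angstrom for RMSD and
#'   groove-width series).
#' @slot frameInterval ps between frames.
#' @slot label observable label.
#'
#' @exportClass ScalarSeries
setClass("ScalarSeries",
  representation(values = "numeric", frameInterval = "numeric", label = "character")
)

setValidity("ScalarSeries", function(object) {
  if (length(object@values) < 1) return("series must be non-empty")
  if (object@frameInterval <= 0) return("frameInterval must be positive")
  TRUE
})

#' DistributionSummary: normalized histogram plus smoothed mode list
#'
#' @slot binEdges numeric histogram bin edges (Angstrom).
#' @slot probability per-bin probability mass (sums to 1).
#' @slot modes data.frame with columns `location` (Angstrom) and `mass`
#'   (fraction of samples in the mode's kernel-density basin), sorted by
#'   location.
#' @slot bandwidth Gaussian kernel bandwidth used for mode detection.
#'
#' @exportClass DistributionSummary
setClass("DistributionSummary",
  representation(binEdges = "numeric", probability = "numeric",
                 modes = "data.frame", bandwidth = "numeric")
)

setValidity("DistributionSummary", function(object) {
  if (length(object@binEdges) != length(object@probability) + 1)
    return("binEdges must have one more element than probability")
  if (abs(sum(object@probability) - 1) > 1e-9)
    return("probability must sum to 1")
  if (nrow(object@modes) > 1 && is.unsorted(object@modes$location))
    return("modes must be sorted by location")
  TRUE
})

#' InteractionSet: residue-pair interaction records with per-frame presence
#'
#' One row per detected residue-pair interaction of a single kind (hydrogen
#' bond, aromatic stacking or water-excluded hydrophobic contact), with the
#' per-frame boolean presence retained so persistence (the mean of the
#' presence series) can always be re-derived.
#'
#' @slot records data.frame with columns `kind`, `chain_a`, `res_a`,
#'   `name_a`, `chain_b`, `res_b`, `name_b`, `persistence`.
#' @slot presence logical T x nrow(records) matrix of per-frame presence.
#'
#' @exportClass InteractionSet
setClass("InteractionSet",
  representation(records = "data.frame", presence = "matrix")
)

setValidity("InteractionSet", function(object) {
  if (nrow(object@records) != ncol(object@presence) && nrow(object@records) > 0)
    return("presence must have one column per record")
  if (nrow(object@records) > 0) {
    p <- colMeans(object@presence)
    if (any(abs(p - object@records$persistence) > 1e-12))
      return("persistence must equal mean(presence)")
  }
  TRUE
})

#' EntropyResult: quasi-harmonic configurational entropy
#'
#' @slot TS entropy contribution T*S in kcal/mol at `temperature`.
#' @slot temperature K.
#' @slot eigenvalues mass-weighted covariance eigenvalues (amu * Angstrom^2),
#'   after dropping rigid-body/rank-deficiency modes.
#' @slot nFramesUsed number of frames entering the covariance.
#'
#' @exportClass EntropyResult
setClass("EntropyResult",
  representation(TS = "numeric", temperature = "numeric",
                 eigenvalues = "numeric", nFramesUsed = "integer")
)

setValidity("EntropyResult", function(object) {
  if (object@TS < 0) return("TS must be non-negative")
  if (any(object@eigenvalues < 0)) return("eigenvalues must be non-negative")
  TRUE
})

#' EnergyBreakdown: SIE components for one frame
#'
#' Total binding free energy is the scaled sum
#' `total = alpha * (e_coulomb + dg_reaction_field + e_vdw + surface_term) + constant`.
#'
#' @slot eCoulomb screened intermolecular Coulomb energy, kcal/mol.
#' @slot dgReactionField change in continuum reaction-field solvation energy
#'   upon binding, kcal/mol.
#' @slot eVdw intermolecular Lennard-Jones energy, kcal/mol.
#' @slot surfaceTerm gamma times the buried molecular surface area, kcal/mol.
#' @slot total scaled total, kcal/mol.
#'
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
  representation(eCoulomb = "numeric", dgReactionField = "numeric",
                 eVdw = "numeric", surfaceTerm = "numeric", total = "numeric")
)

#' BindingResult: SIE free energy over a trajectory
#'
#' @slot dgMean mean SIE binding free energy over evaluated frames, kcal/mol.
#' @slot dgSd standard deviation over evaluated frames, kcal/mol.
#' @slot perFrame data.frame with one row per evaluated frame (frame index,
#'   components, total).
#' @slot ic50nM IC50 from `dgMean` via the Boltzmann relation, nmol/L.
#' @slot stridePs evaluation stride, ps.
#'
#' @exportClass BindingResult
setClass("BindingResult",
  representation(dgMean = "numeric", dgSd = "numeric", perFrame = "data.frame",
                 ic50nM = "numeric", stridePs = "numeric")
)

setValidity("BindingResult", function(object) {
  if (object@ic50nM <= 0) return("ic50nM must be positive")
  if (nrow(object@perFrame) > 0 &&
      abs(mean(object@perFrame$total) - object@dgMean) > 1e-9)
    return("dgMean must equal the mean of per-frame totals")
  TRUE
})
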