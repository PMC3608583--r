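#' Load a per-atom force-field parameter table
#'
#' Reads a tab-separated table with columns `residue`, `atom`, `element`,
#' `charge` (e), `epsilon` (kcal/mol), `rmin_half` (Angstrom), `radius`
#' (Angstrom, Born radius seed) and `mass` (amu). The package ships a
#' default table covering the twenty standard amino acids (polar hydrogens
#' explicit) and water.
#'
#' @param path path to a TSV parameter table; `NULL` for the packaged default.
#' @return data.frame keyed by (residue, atom).
#' @export
loadParamTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "forcefield_params.tsv", package = "pmhcdyn")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("residue", "atom", "element", "charge", "epsilon", "rmin_half",
            "radius", "mass")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table lacks columns: ", paste(miss, collapse = ", "))
  tab
}

# residue names interpreted as water and mapped to chain class W
.waterResnames <- c("HOH", "WAT", "TIP3")

# build a MolecularSystem from parallel atom vectors + coordinates
buildSystem <- function(atom_name, residue_index, residue_name, chain_id,
                        coords, params) {
  key <- paste(residue_name, atom_name)
  pkey <- paste(params$residue, params$atom)
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    stop(sprintf(
      "parameterization error: no parameters for atom '%s' of residue '%s' (%s:%d)",
      atom_name[bad], residue_name[bad], chain_id[bad], residue_index[bad]))
  }
  p <- params[hit, , drop = FALSE]
  atoms <- data.frame(
    atom_name = atom_name,
    element = p$element,
    residue_index = as.integer(residue_index),
    residue_name = residue_name,
    chain_id = chain_id,
    mass = p$mass,
    charge = p$charge,
    epsilon = p$epsilon,
    rmin_half = p$rmin_half,
    radius = p$radius,
    is_heavy = p$element != "H",
    stringsAsFactors = FALSE
  )
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  chainIndex <- split(seq_len(nrow(atoms)), atoms$chain_id)
  new("MolecularSystem", atoms = atoms, referenceCoords = coords,
      chainIndex = chainIndex)
}

#' Construct a MolecularSystem from atom vectors
#'
#' Low-level constructor: builds a fully parameterized system from parallel
#' per-atom vectors and a coordinate matrix, resolving each
#' (residue, atom) pair in the parameter table.
#'
#' @param atom_name,residue_index,residue_name,chain_id parallel per-atom
#'   vectors.
#' @param coords N x 3 coordinate matrix, Angstrom.
#' @param params parameter data.frame from [loadParamTable()]; `NULL` uses
#'   the packaged defaults.
#' @return a [MolecularSystem-class].
#' @export
molecularSystem <- function(atom_name, residue_index, residue_name, chain_id,
                            coords, params = NULL) {
  if (is.null(params)) params <- loadParamTable()
  buildSystem(atom_name, residue_index, residue_name, chain_id, coords, params)
}

#' Construct a TrajectorySeries from a frame array
#'
#' @param system a [MolecularSystem-class].
#' @param frames T x N x 3 coordinate array, Angstrom.
#' @param frame_interval ps between frames.
#' @return a [TrajectorySeries-class].
#' @export
trajectorySeries <- function(system, frames, frame_interval = 200) {
  new("TrajectorySeries", system = system, frames = frames,
      frameInterval = frame_interval)
}

#' Construct a ResidueSelection
#'
#' @param chain chain id vector (recycled against `resno`).
#' @param resno residue index vector.
#' @param label selection label.
#' @return a [ResidueSelection-class].
#' @export
residueSelection <- function(chain, resno, label = "selection") {
  n <- max(length(chain), length(resno))
  makeSelection(label, rep_len(chain, n), rep_len(resno, n))
}

#' Read a PDB structure and attach force-field parameters
#'
#' Parses a standard PDB file and resolves every (residue, atom) pair in the
#' supplied parameter table, producing a fully parameterized
#' [MolecularSystem-class]. Chain identifiers are remapped to the package
#' convention: water residues (HOH/WAT/TIP3) go to chain class `W`;
#' non-water chains other than `A`/`B` are treated as the bound peptide and
#' mapped to `P` (configurable via `chain_map`). Residue numbering is taken
#' verbatim from the file (1-based, per chain); insertion codes are ignored.
#'
#' @param path PDB file path.
#' @param param_table path to a parameter TSV, or a data.frame from
#'   [loadParamTable()]; `NULL` uses the packaged defaults.
#' @param chain_map optional named character vector mapping file chain ids to
#'   the convention `A`/`B`/`P` (e.g. `c(C = "P")`).
#' @return a [MolecularSystem-class].
#' @export
readStructure <- function(path, param_table = NULL, chain_map = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  params <- if (is.data.frame(param_table)) param_table else loadParamTable(param_table)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("parse error reading '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("parse error: no atoms in '", path, "'")
  chain <- as.character(at$chain)
  chain[is.na(chain) | chain == ""] <- "P"
  if (!is.null(chain_map)) {
    mapped <- chain_map[chain]
    chain[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  chain[at$resid %in% .waterResnames] <- "W"
  chain[!(chain %in% c("A", "B", "W"))] <- "P"
  buildSystem(atom_name = as.character(at$elety),
              residue_index = at$resno,
              residue_name = as.character(at$resid),
              chain_id = chain,
              coords = cbind(at$x, at$y, at$z),
              params = params)
}

#' Write a system (and optionally trajectory frames) to PDB
#'
#' Single-frame output is a plain PDB; a [TrajectorySeries-class] is written
#' as a multi-model PDB, the text trajectory format the package reads back
#' with [readTrajectory()].
#'
#' @param x a [MolecularSystem-class] or [TrajectorySeries-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  if (is(x, "TrajectorySeries")) {
    sys <- x@system
    T_ <- nFrames(x)
    # flatten frames to T x 3N in x1,y1,z1,x2,... order
    xyz <- matrix(0, nrow = T_, ncol = 3 * nAtoms(x))
    for (d in 1:3) xyz[, seq(d, ncol(xyz), by = 3)] <- x@frames[, , d]
  } else if (is(x, "MolecularSystem")) {
    sys <- x
    xyz <- matrix(t(x@referenceCoords), nrow = 1)
  } else stop("writeStructure expects a MolecularSystem or TrajectorySeries")
  a <- sys@atoms
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_index, resid = a$residue_name,
                   elety = a$atom_name, chain = a$chain_id)
  invisible(path)
}

#' Read trajectory frames for an existing system
#'
#' Reads a multi-model PDB trajectory whose per-frame atom count must match
#' the system. Coordinates are returned in Angstrom.
#'
#' @param system the [MolecularSystem-class] the frames belong to.
#' @param path multi-model PDB trajectory path.
#' @param frame_interval ps between frames (trajectory metadata; default 200,
#'   i.e. 600 frames spanning 120 ns).
#' @return a [TrajectorySeries-class].
#' @export
readTrajectory <- function(system, path, frame_interval = 200) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty trajectory file '", path, "'")
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("parse error reading '", path, "': ",
                                           conditionMessage(e)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_file <- ncol(xyz) / 3
  n_sys <- nAtoms(system)
  if (n_file != n_sys)
    stop(sprintf("shape error: trajectory frames have %d atoms but system has %d",
                 n_file, n_sys))
  T_ <- nrow(xyz)
  fr <- array(0, dim = c(T_, n_sys, 3))
  for (d in 1:3) fr[, , d] <- xyz[, seq(d, ncol(xyz), by = 3), drop = FALSE]
  new("TrajectorySeries", system = system, frames = fr,
      frameInterval = frame_interval)
}

#' Binding-site residue selection
#'
#' The peptide binding site of the MHC class II groove: alpha1-domain
#' residues 5-76 on chain A and beta1-domain residues 5-90 on chain B,
#' intersected with the residues actually present in the system.
#'
#' @param system a [MolecularSystem-class].
#' @param alpha_range,beta_range inclusive residue ranges (defaults 5:76 and
#'   5:90).
#' @return a [ResidueSelection-class].
#' @export
bindingSiteSelection <- function(system, alpha_range = 5:76, beta_range = 5:90) {
  a <- system@atoms
  for (ch in c("A", "B")) {
    if (!ch %in% a$chain_id)
      stop("configuration error: chain ", ch, " not present in system")
  }
  resA <- sort(intersect(alpha_range, unique(a$residue_index[a$chain_id == "A"])))
  resB <- sort(intersect(beta_range, unique(a$residue_index[a$chain_id == "B"])))
  if (length(resA) + length(resB) == 0)
    stop("configuration error: binding-site selection is empty")
  makeSelection("binding_site",
                c(rep("A", length(resA)), rep("B", length(resB))),
                c(resA, resB))
}

# default groove compartments: name -> alpha range, beta range
.defaultCompartmentTable <- function() {
  list(
    D1 = list(alpha = 50:51, beta = 85:86),
    D2 = list(alpha = 53:55, beta = 78:83),
    D3 = list(alpha = 60:65, beta = 65:70),
    D4 = list(alpha = 68:73, beta = 56:61)
  )
}

#' Groove compartment selections
#'
#' Dissects the binding groove into paired alpha/beta wall selections whose
#' cross-groove centre-of-mass distance measures local groove width. The
#' default four compartments cover the classical anchoring pockets:
#' D1 (alpha 50-51 / beta 85-86), D2 (alpha 53-55 / beta 78-83),
#' D3 (alpha 60-65 / beta 65-70) and D4 (alpha 68-73 / beta 56-61).
#'
#' @param system a [MolecularSystem-class].
#' @param table optional override: a named list of
#'   `list(alpha = <residue vector>, beta = <residue vector>)` entries.
#' @return a [CompartmentMap-class].
#' @export
compartmentSelections <- function(system, table = NULL) {
  if (is.null(table)) table <- .defaultCompartmentTable()
  a <- system@atoms
  presentA <- unique(a$residue_index[a$chain_id == "A"])
  presentB <- unique(a$residue_index[a$chain_id == "B"])
  comps <- list()
  for (nm in names(table)) {
    ra <- table[[nm]]$alpha
    rb <- table[[nm]]$beta
    missA <- setdiff(ra, presentA)
    missB <- setdiff(rb, presentB)
    if (length(missA))
      stop(sprintf("configuration error: compartment %s requires missing residue A:%d",
                   nm, missA[1]))
    if (length(missB))
      stop(sprintf("configuration error: compartment %s requires missing residue B:%d",
                   nm, missB[1]))
    comps[[nm]] <- list(
      alpha = makeSelection(paste0(nm, "_alpha"), rep("A", length(ra)), ra),
      beta = makeSelection(paste0(nm, "_beta"), rep("B", length(rb)), rb)
    )
  }
  new("CompartmentMap", compartments = comps)
}

#' Serialize selections to JSON for provenance
#'
#' @param x a [ResidueSelection-class] or [CompartmentMap-class].
#' @param path output path; `NULL` returns the JSON string.
#' @return JSON string (invisibly when written to file).
#' @export
selectionToJSON <- function(x, path = NULL) {
  obj <- if (is(x, "ResidueSelection")) {
    list(label = x@label, members = members(x))
  } else if (is(x, "CompartmentMap")) {
    lapply(compartments(x), function(cp)
      list(alpha = members(cp$alpha), beta = members(cp$beta)))
  } else stop("selectionToJSON expects a ResidueSelection or CompartmentMap")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
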