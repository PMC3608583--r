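#' Number of frames in a trajectory
#' @param x a [TrajectorySeries-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a [MolecularSystem-class] or [TrajectorySeries-class]
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom table accessor
#' @param x a [MolecularSystem-class] or [TrajectorySeries-class]
#' @return data.frame of per-atom topology and parameters
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Reference coordinates accessor
#' @param x a [MolecularSystem-class]
#' @return N x 3 matrix, Angstrom
#' @export
setGeneric("referenceCoords", function(x) standardGeneric("referenceCoords"))

#' Coordinate frames accessor
#' @param x a [TrajectorySeries-class]
#' @return T x N x 3 array, Angstrom
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Frame interval accessor
#' @param x a [TrajectorySeries-class] or [ScalarSeries-class]
#' @return picoseconds between frames
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Series values accessor
#' @param x a [ScalarSeries-class]
#' @return numeric per-frame values
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' Selection members accessor
#' @param x a [ResidueSelection-class]
#' @return data.frame with columns `chain` and `resno`
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Compartment list accessor
#' @param x a [CompartmentMap-class]
#' @return named list of alpha/beta selection pairs
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' Interaction records accessor
#' @param x an [InteractionSet-class]
#' @return data.frame of interaction records
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Per-frame presence matrix accessor
#' @param x an [InteractionSet-class]
#' @return logical T x n_records matrix
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' Distribution modes accessor
#' @param x a [DistributionSummary-class]
#' @return data.frame with columns `location` and `mass`
#' @export
setGeneric("modes", function(x) standardGeneric("modes"))
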