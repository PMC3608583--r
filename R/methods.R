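#' @describeIn nAtoms atom count of a system
#' @export
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))

#' @describeIn nAtoms atom count of the underlying system
#' @export
setMethod("nAtoms", "TrajectorySeries", function(x) dim(x@frames)[2])

#' @describeIn nFrames frame count
#' @export
setMethod("nFrames", "TrajectorySeries", function(x) dim(x@frames)[1])

#' @describeIn atoms atom table of a system
#' @export
setMethod("atoms", "MolecularSystem", function(x) x@atoms)

#' @describeIn atoms atom table of the trajectory's system
#' @export
setMethod("atoms", "TrajectorySeries", function(x) x@system@atoms)

#' @describeIn referenceCoords reference coordinates
#' @export
setMethod("referenceCoords", "MolecularSystem", function(x) x@referenceCoords)

#' @describeIn frames coordinate frames
#' @export
setMethod("frames", "TrajectorySeries", function(x) x@frames)

#' @describeIn frameInterval trajectory frame spacing
#' @export
setMethod("frameInterval", "TrajectorySeries", function(x) x@frameInterval)

#' @describeIn frameInterval series frame spacing
#' @export
setMethod("frameInterval", "ScalarSeries", function(x) x@frameInterval)

#' @describeIn seriesValues per-frame values
#' @export
setMethod("seriesValues", "ScalarSeries", function(x) x@values)

#' @describeIn members selection members as a data.frame
#' @export
setMethod("members", "ResidueSelection", function(x)
  data.frame(chain = x@chain, resno = x@resno, stringsAsFactors = FALSE))

#' @describeIn compartments named compartment list
#' @export
setMethod("compartments", "CompartmentMap", function(x) x@compartments)

#' @describeIn records interaction record table
#' @export
setMethod("records", "InteractionSet", function(x) x@records)

#' @describeIn presenceMatrix per-frame presence
#' @export
setMethod("presenceMatrix", "InteractionSet", function(x) x@presence)

#' @describeIn modes mode table
#' @export
setMethod("modes", "DistributionSummary", function(x) x@modes)

setMethod("show", "MolecularSystem", function(object) {
  a <- object@atoms
  ch <- table(a$chain_id)
  cat("MolecularSystem:", nrow(a), "atoms,",
      length(unique(paste(a$chain_id, a$residue_index))), "residues\n")
  cat("  chains:", paste(sprintf("%s(%d atoms)", names(ch), ch), collapse = ", "), "\n")
})

setMethod("show", "TrajectorySeries", function(object) {
  cat("TrajectorySeries:", nFrames(object), "frames x", nAtoms(object),
      "atoms, frame interval", object@frameInterval, "ps\n")
})

setMethod("show", "ResidueSelection", function(object) {
  cat("ResidueSelection '", object@label, "': ", length(object@resno),
      " residues on chain(s) ", paste(unique(object@chain), collapse = ","),
      "\n", sep = "")
})

setMethod("show", "CompartmentMap", function(object) {
  cat("CompartmentMap with", length(object@compartments), "compartments:\n")
  for (nm in names(object@compartments)) {
    cp <- object@compartments[[nm]]
    cat(sprintf("  %s: alpha %s, beta %s\n", nm,
                .rangeLabel(cp$alpha), .rangeLabel(cp$beta)))
  }
})

.rangeLabel <- function(sel) {
  sprintf("%s:%d-%d", sel@chain[1], min(sel@resno), max(sel@resno))
}

setMethod("show", "ScalarSeries", function(object) {
  cat(sprintf("ScalarSeries '%s': %d frames, mean %.3f A (sd %.3f)\n",
              object@label, length(object@values),
              mean(object@values), stats::sd(object@values)))
})

setMethod("show", "DistributionSummary", function(object) {
  cat("DistributionSummary:", length(object@probability), "bins,",
      nrow(object@modes), "mode(s)\n")
  if (nrow(object@modes))
    print(round(object@modes, 3))
})

setMethod("show", "InteractionSet", function(object) {
  cat("InteractionSet:", nrow(object@records), "record(s) over",
      nrow(object@presence), "frames\n")
  if (nrow(object@records)) print(object@records)
})

setMethod("show", "EntropyResult", function(object) {
  cat(sprintf("EntropyResult: T*S = %.2f kcal/mol at %g K (%d modes, %d frames)\n",
              object@TS, object@temperature, length(object@eigenvalues),
              object@nFramesUsed))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf(paste0("EnergyBreakdown (kcal/mol): Coul %.3f, RF %.3f, vdW %.3f, ",
                     "surface %.3f -> total %.3f\n"),
              object@eCoulomb, object@dgReactionField, object@eVdw,
              object@surfaceTerm, object@total))
})

setMethod("show", "BindingResult", function(object) {
  cat(sprintf("BindingResult: dG = %.2f +/- %.2f kcal/mol, IC50 = %.3g nM (%d frames, stride %g ps)\n",
              object@dgMean, object@dgSd, object@ic50nM,
              nrow(object@perFrame), object@stridePs))
})
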