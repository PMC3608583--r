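# internal helpers

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched. All package randomness funnels through here.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# atom indices of a ResidueSelection within a system, optionally restricted
# to given atom names and/or heavy atoms
selectionAtomIndices <- function(system, selection, atom_names = NULL,
                                 heavy_only = FALSE) {
  a <- system@atoms
  key <- paste(a$chain_id, a$residue_index)
  want <- paste(selection@chain, selection@resno)
  idx <- which(key %in% want)
  if (!is.null(atom_names)) idx <- idx[a$atom_name[idx] %in% atom_names]
  if (heavy_only) idx <- idx[a$is_heavy[idx]]
  idx
}

# atom indices of one residue
residueAtomIndices <- function(system, chain, resno, atom_names = NULL) {
  a <- system@atoms
  idx <- which(a$chain_id == chain & a$residue_index == resno)
  if (!is.null(atom_names)) idx <- idx[a$atom_name[idx] %in% atom_names]
  idx
}

# mass-weighted centre of a coordinate block (n x 3) with masses w
massCenter <- function(xyz, w) {
  colSums(xyz * w) / sum(w)
}

vnorm <- function(v) sqrt(sum(v^2))

unitVector <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# single residue selection constructor used internally
makeSelection <- function(label, chain, resno) {
  new("ResidueSelection", label = label,
      chain = as.character(chain), resno = as.integer(resno))
}

# physical constants
.kB_kcal <- 1.9872e-3          # kcal/(mol K)
.kB_SI <- 1.380649e-23         # J/K
.hbar_SI <- 1.054571817e-34    # J s
.amuA2_to_SI <- 1.66053906660e-27 * 1e-20  # amu A^2 -> kg m^2
.coulombConst <- 332.0637      # kcal/mol * A / e^2
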