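# Superposition-based RMSD statistics and the four-compartment groove-width
# dissection.

# Kabsch algorithm on two n x 3 coordinate sets (already paired rows).
# Returns rotation R, translation, and post-fit RMSD. Reflections are
# excluded by the usual determinant sign correction.
kabsch <- function(P, Q) {
  if (nrow(P) < 3) stop("geometry error: superposition needs at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pfit <- t(R %*% t(P0))
  rmsd <- sqrt(mean(rowSums((Pfit - Q0)^2)))
  list(R = R, center_mobile = cp, center_ref = cq, rmsd = rmsd)
}

#' Optimal rigid superposition of one frame onto another
#'
#' Least-squares rigid-body fit (rotation plus translation, reflections
#' excluded) of the mobile frame onto the reference over the C-alpha atoms of
#' a residue selection, with the post-fit RMSD over those atoms.
#'
#' @param mobile,reference N x 3 coordinate matrices sharing the system's
#'   atom order, Angstrom.
#' @param system the [MolecularSystem-class] both frames belong to.
#' @param selection a [ResidueSelection-class]; the fit and the RMSD use its
#'   atoms restricted to `fit_atoms`.
#' @param fit_atoms atom names used for fitting; default C-alpha only, use
#'   `c("N","CA","C","O")` for a full-backbone fit.
#' @return list with `coords` (the whole transformed mobile frame) and
#'   `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference, system, selection,
                      fit_atoms = "CA") {
  idx <- selectionAtomIndices(system, selection, atom_names = fit_atoms)
  if (length(idx) < 3)
    stop("geometry error: fewer than 3 selected atoms for superposition")
  k <- kabsch(mobile[idx, , drop = FALSE], reference[idx, , drop = FALSE])
  moved <- sweep(mobile, 2, k$center_mobile)
  moved <- t(k$R %*% t(moved))
  moved <- sweep(moved, 2, k$center_ref, "+")
  list(coords = moved, rmsd = k$rmsd)
}

#' Per-frame RMSD series after superposition
#'
#' For every frame, the C-alpha RMSD over the selection after optimal rigid
#' superposition onto a fixed reference (default: the first frame of the
#' trajectory, i.e. deviation with respect to the initial production
#' structure).
#'
#' @param traj a [TrajectorySeries-class].
#' @param selection a [ResidueSelection-class] (typically the binding site).
#' @param reference N x 3 reference coordinates; `NULL` uses the first frame.
#' @param fit_atoms see [superpose()].
#' @return a [ScalarSeries-class].
#' @export
rmsdSeries <- function(traj, selection, reference = NULL, fit_atoms = "CA") {
  if (is.null(reference)) reference <- traj@frames[1, , ]
  vals <- vapply(seq_len(nFrames(traj)), function(t)
    superpose(traj@frames[t, , ], reference, traj@system, selection,
              fit_atoms)$rmsd, numeric(1))
  new("ScalarSeries", values = vals, frameInterval = traj@frameInterval,
      label = paste0("rmsd_", selection@label))
}

#' Normalized histogram and mode list of a scalar series
#'
#' Bins the series into a normalized histogram and locates modes as local
#' maxima of a Gaussian kernel density estimate (bandwidth = 2 x bin width)
#' with a minimum prominence of `min_prominence` times the highest peak.
#' Each sample is assigned to the basin of its nearest density minimum
#' boundary, so mode masses sum to 1 across modes.
#'
#' @param series a [ScalarSeries-class] or numeric vector.
#' @param bin_width histogram bin width, Angstrom (0.1 is the package default
#'   for RMSD, 0.25 for groove widths).
#' @param min_prominence minimum peak density relative to the highest peak.
#' @return a [DistributionSummary-class].
#' @export
distributionSummary <- function(series, bin_width = 0.1,
                                min_prominence = 0.05) {
  x <- if (is(series, "ScalarSeries")) series@values else as.numeric(series)
  if (!length(x)) stop("series must be non-empty")
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < max(x)) edges <- c(edges, edges[length(edges)] + bin_width)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  prob <- h$counts / length(x)

  bw <- 2 * bin_width
  dens <- stats::density(x, bw = bw, n = 1024,
                         from = lo - 3 * bw, to = hi + 3 * bw)
  y <- dens$y; gx <- dens$x
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  peaks <- which(is_max & y >= min_prominence * max(y))
  # clamp mode locations into the data range
  locs <- pmin(pmax(gx[peaks], min(x)), max(x))
  ord <- order(locs)
  locs <- locs[ord]; peaks <- peaks[ord]
  if (length(peaks) == 0) {
    modes <- data.frame(location = numeric(0), mass = numeric(0))
  } else if (length(peaks) == 1) {
    modes <- data.frame(location = locs, mass = 1)
  } else {
    # basin boundaries: density minima between consecutive peaks
    bounds <- vapply(seq_len(length(peaks) - 1), function(i) {
      seg <- peaks[i]:peaks[i + 1]
      gx[seg[which.min(y[seg])]]
    }, numeric(1))
    bins <- findInterval(x, bounds)
    mass <- vapply(seq_along(peaks) - 1, function(b) mean(bins == b), numeric(1))
    modes <- data.frame(location = locs, mass = mass)
  }
  new("DistributionSummary", binEdges = h$breaks, probability = prob,
      modes = modes, bandwidth = bw)
}

#' Per-compartment groove-width series
#'
#' For each compartment, the per-frame Euclidean distance between the
#' mass-weighted centres of the heavy atoms of the alpha-wall and beta-wall
#' selections. An internal coordinate: invariant under rigid motion of the
#' whole frame.
#'
#' @param traj a [TrajectorySeries-class].
#' @param cmap a [CompartmentMap-class].
#' @return named list of [ScalarSeries-class], one per compartment.
#' @export
compartmentDistanceSeries <- function(traj, cmap) {
  sys <- traj@system
  m <- sys@atoms$mass
  T_ <- nFrames(traj)
  out <- list()
  for (nm in names(compartments(cmap))) {
    cp <- compartments(cmap)[[nm]]
    ia <- selectionAtomIndices(sys, cp$alpha, heavy_only = TRUE)
    ib <- selectionAtomIndices(sys, cp$beta, heavy_only = TRUE)
    if (!length(ia) || !length(ib))
      stop("geometry error: compartment ", nm, " has an empty heavy-atom side")
    wa <- m[ia] / sum(m[ia]); wb <- m[ib] / sum(m[ib])
    # centre of mass per frame via matrix products over the atom axis
    Xa <- matrix(traj@frames[, ia, 1], nrow = T_) %*% wa
    Ya <- matrix(traj@frames[, ia, 2], nrow = T_) %*% wa
    Za <- matrix(traj@frames[, ia, 3], nrow = T_) %*% wa
    Xb <- matrix(traj@frames[, ib, 1], nrow = T_) %*% wb
    Yb <- matrix(traj@frames[, ib, 2], nrow = T_) %*% wb
    Zb <- matrix(traj@frames[, ib, 3], nrow = T_) %*% wb
    d <- sqrt((Xa - Xb)^2 + (Ya - Yb)^2 + (Za - Zb)^2)[, 1]
    out[[nm]] <- new("ScalarSeries", values = d,
                     frameInterval = traj@frameInterval,
                     label = paste0("width_", nm))
  }
  out
}

#' Export a scalar series as a two-column data.frame
#'
#' @param series a [ScalarSeries-class].
#' @return data.frame with columns `time_ps` and `value`.
#' @export
seriesAsDataFrame <- function(series) {
  data.frame(time_ps = (seq_along(series@values) - 1) * series@frameInterval,
             value = series@values)
}
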