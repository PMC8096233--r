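#' Solvent-accessible surface area by Shrake-Rupley sphere sampling
#'
#' Places quasi-uniform points (a Fibonacci/golden-spiral lattice) on the
#' solvent-expanded sphere of every selected atom (radius `r_i + probe`)
#' and counts the points not buried inside any neighbouring atom's expanded
#' sphere. The accessible fraction times the expanded-sphere area gives the
#' per-atom SASA.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom); either a numeric
#'   vector of length n or a named lookup resolved from `elements`.
#' @param elements optional element symbols (used when `radii` is a named
#'   table); unknown elements without an explicit radius are an error.
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param nPoints sample points per atom (default 960).
#' @param selection atoms whose area is computed (default all); all atoms
#'   still occlude.
#' @return Numeric vector of per-atom areas (Angstrom^2) for the selection,
#'   with attribute `"total"`.
#' @export
sasa <- function(xyz, radii, elements = NULL, probe = 1.4, nPoints = 960,
                 selection = seq_len(nrow(xyz))) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  n <- nrow(xyz)
  if (!is.null(names(radii)) && !is.null(elements)) {
    miss <- setdiff(unique(elements), names(radii))
    if (length(miss))
      stop("no van der Waals radius for element(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    radii <- unname(radii[elements])
  }
  stopIfNot(length(radii) == n, "one radius per atom required")
  stopIfNot(all(radii > 0), "radii must be positive")
  # golden-spiral lattice on the unit sphere
  i <- seq_len(nPoints) - 0.5
  phi <- acos(1 - 2 * i / nPoints)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rExp <- radii + probe
  areas <- vapply(selection, function(a) {
    sp <- pts * rExp[a]
    sp <- sweep(sp, 2, xyz[a, ], "+")
    free <- rep(TRUE, nPoints)
    for (b in seq_len(n)) {
      if (b == a) next
      d2ab <- sum((xyz[a, ] - xyz[b, ])^2)
      if (d2ab >= (rExp[a] + rExp[b])^2) next  # spheres cannot intersect
      d2 <- (sp[, 1] - xyz[b, 1])^2 + (sp[, 2] - xyz[b, 2])^2 +
        (sp[, 3] - xyz[b, 3])^2
      free <- free & d2 > rExp[b]^2
      if (!any(free)) break
    }
    4 * pi * rExp[a]^2 * sum(free) / nPoints
  }, numeric(1))
  names(areas) <- selection
  attr(areas, "total") <- sum(areas)
  areas
}

#' Per-frame SASA of a trajectory selection
#'
#' Applies [sasa()] to every frame of a trajectory. Pseudo-atoms carry
#' explicit radii via `radii`.
#'
#' @param traj a [TailTrajectory-class].
#' @param radii per-atom radii for all atoms of the trajectory.
#' @param selection atoms whose summed area is reported.
#' @param probe,nPoints see [sasa()].
#' @return Numeric vector of total selection SASA per frame (Angstrom^2).
#' @export
sasaTrajectory <- function(traj, radii, selection, probe = 1.4,
                           nPoints = 240) {
  vapply(seq_len(nFrames(traj)), function(f) {
    a <- sasa(traj@coords[f, , , drop = TRUE], radii, probe = probe,
              nPoints = nPoints, selection = selection)
    attr(a, "total")
  }, numeric(1))
}
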