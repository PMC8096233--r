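#' @import methods
NULL

#' TailTrajectory: frames x atoms x 3 coordinates plus topology
#'
#' Container for a (coarse or all-atom) trajectory of a nucleosomal particle.
#' Coordinates are in Angstrom. The topology table carries, per atom: chain
#' id, residue number, residue name, atom name, a heavy-atom flag and a role
#' tag (`"tail"`, `"core"` or `"DNA"`). H3 tails are residues 1-37 of the H3
#' chains; residues 38-55 are the initial region of the core.
#'
#' @slot coords numeric array, frames x atoms x 3 (Angstrom).
#' @slot topology data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `heavy` (logical), `role` (character).
#' @slot dtPs frame spacing in picoseconds (bookkeeping only).
#' @slot trimmed fraction of frames already removed as equilibration.
#' @export
setClass("TailTrajectory",
  representation(coords = "array", topology = "data.frame",
                 dtPs = "numeric", trimmed = "numeric"),
  prototype(dtPs = 10, trimmed = 0))

setValidity("TailTrajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be a frames x atoms x 3 array")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  need <- c("chain", "resno", "resname", "atom", "heavy", "role")
  if (!all(need %in% names(object@topology)))
    msg <- c(msg, paste("topology must have columns:",
                        paste(need, collapse = ", ")))
  else if (length(d) == 3L && nrow(object@topology) != d[2])
    msg <- c(msg, "topology rows must match atom count")
  else if (!all(object@topology$role %in% c("tail", "core", "DNA")))
    msg <- c(msg, "role must be one of tail, core, DNA")
  if (length(msg)) msg else TRUE
})

#' ExposureFit: constrained weighted single-exponential proteolysis fit
#'
#' Result of fitting the mean fraction of full-length H3 remaining to
#' `A0 * exp(-k * t)` with no constant offset (the curve is constrained to
#' decay to zero) and `0 < A0 <= 1`. Under rapid conformational
#' pre-equilibrium the observed rate constant `k_obs` is proportional to the
#' site-exposure equilibrium constant of the H3 tail.
#'
#' @slot species species label of the fitted time course.
#' @slot kObs observed rate constant (1/min).
#' @slot kObsError standard error of `kObs` from the fit covariance.
#' @slot a0 fitted y-intercept (initial intact fraction), in (0, 1].
#' @slot a0Error standard error of `a0`.
#' @slot cov 2 x 2 parameter covariance matrix (A0, k).
#' @slot wrss weighted residual sum of squares at the solution.
#' @slot atBoundary TRUE when `a0` sits at the upper bound 1 or `kObs` at 0.
#' @slot nPoints number of fitted timepoints.
#' @export
setClass("ExposureFit",
  representation(species = "character", kObs = "numeric",
                 kObsError = "numeric", a0 = "numeric", a0Error = "numeric",
                 cov = "matrix", wrss = "numeric", atBoundary = "logical",
                 nPoints = "integer"))

setValidity("ExposureFit", function(object) {
  msg <- character()
  if (object@kObs < 0) msg <- c(msg, "kObs must be >= 0")
  if (object@a0 <= 0 || object@a0 > 1 + 1e-12)
    msg <- c(msg, "a0 must be in (0, 1]")
  if (object@kObsError < 0 || object@a0Error < 0)
    msg <- c(msg, "errors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: time-averaged H3 tail-DNA heavy-atom contact counts
#'
#' Rows are tail residues of one H3 copy, columns DNA base pairs; entries are
#' per-frame mean counts of heavy-atom pairs within the cutoff (default
#' 4.5 Angstrom).
#'
#' @slot counts numeric matrix, tail residue x base pair, dimnames set.
#' @slot cutoff contact cutoff in Angstrom.
#' @slot framesUsed number of trajectory frames averaged.
#' @slot chain H3 chain id the rows belong to.
#' @export
setClass("ContactMatrix",
  representation(counts = "matrix", cutoff = "numeric",
                 framesUsed = "integer", chain = "character"))

setValidity("ContactMatrix", function(object) {
  if (any(object@counts < 0)) "contact counts must be >= 0" else TRUE
})
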