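#' Select atom indices from a trajectory topology
#'
#' Convenience filter over the topology table; all supplied conditions are
#' combined with AND.
#'
#' @param traj a [TailTrajectory-class].
#' @param role,chain,atom,resno optional filters; `resno` is a vector of
#'   residue numbers.
#' @param heavyOnly keep only heavy atoms (default FALSE).
#' @return Integer atom indices.
#' @export
selectAtoms <- function(traj, role = NULL, chain = NULL, atom = NULL,
                        resno = NULL, heavyOnly = FALSE) {
  tp <- topology(traj)
  keep <- rep(TRUE, nrow(tp))
  if (!is.null(role)) keep <- keep & tp$role %in% role
  if (!is.null(chain)) keep <- keep & tp$chain %in% chain
  if (!is.null(atom)) keep <- keep & tp$atom %in% atom
  if (!is.null(resno)) keep <- keep & tp$resno %in% resno
  if (heavyOnly) keep <- keep & tp$heavy
  which(keep)
}

#' Discard the equilibration portion of a trajectory
#'
#' Removes the first `floor(fraction * nFrames)` frames. The default 0.4
#' mirrors analysing the last 150 ns of 250 ns runs after 100 ns of
#' equilibration.
#'
#' @param traj a [TailTrajectory-class].
#' @param fraction fraction of frames to drop, in [0, 1).
#' @return The trimmed [TailTrajectory-class].
#' @export
trimEquilibration <- function(traj, fraction = 0.4) {
  stopIfNot(fraction >= 0 && fraction < 1, "trim fraction must be in [0, 1)")
  if (fraction == 0) return(traj)
  nF <- nFrames(traj)
  drop <- floor(fraction * nF)
  new("TailTrajectory", coords = traj@coords[(drop + 1L):nF, , , drop = FALSE],
      topology = traj@topology, dtPs = traj@dtPs,
      trimmed = traj@trimmed + fraction)
}

#' Remove global translation and rotation by least-squares superposition
#'
#' Fits every frame onto a reference by the Kabsch algorithm over the given
#' atom selection (proper rotations only; mirror images are rejected). The
#' reference is the frame-average structure, refined once: frames are first
#' fitted to the raw average, the average is recomputed from the fitted
#' frames, and the fit is repeated.
#'
#' @param traj a [TailTrajectory-class].
#' @param selection atom indices used for the fit (e.g. the histone-core
#'   backbone); default all atoms.
#' @return List with `trajectory` (aligned [TailTrajectory-class]) and
#'   `rmsd` (per-frame RMSD over the selection after fitting).
#' @export
superposeTrajectory <- function(traj, selection = seq_len(nAtoms(traj))) {
  stopIfNot(length(selection) >= 3L, "selection needs at least 3 atoms")
  x <- traj@coords
  nF <- dim(x)[1]
  alignTo <- function(x, ref) {
    out <- x
    rmsd <- numeric(nF)
    for (f in seq_len(nF)) {
      fit <- kabsch(x[f, selection, , drop = TRUE], ref)
      out[f, , ] <- applyKabsch(x[f, , , drop = TRUE], fit)
      rmsd[f] <- fit$rmsd
    }
    list(x = out, rmsd = rmsd)
  }
  meanSel <- function(x) apply(x[, selection, , drop = FALSE], c(2, 3), mean)
  pass1 <- alignTo(x, meanSel(x))
  pass2 <- alignTo(pass1$x, meanSel(pass1$x))
  list(trajectory = new("TailTrajectory", coords = pass2$x,
                        topology = traj@topology, dtPs = traj@dtPs,
                        trimmed = traj@trimmed),
       rmsd = pass2$rmsd)
}

# per-atom RMSF of an aligned coordinate array over frames
rmsfAtoms <- function(x) {
  stopIfNot(dim(x)[1] >= 2L, "RMSF needs at least 2 frames")
  mu <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mu)^2
  sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and axes, times 3 axes
}

#' Per-residue RMSF profile with across-replicate mean and SEM
#'
#' Computes, for each replicate trajectory, the root mean square fluctuation
#' of each selected atom about its time-average position, then averages the
#' per-residue profiles across replicates and reports the standard error of
#' the mean. Trajectories must already be superposed (see
#' [superposeTrajectory()], typically on the histone-core selection).
#'
#' @param trajs list of aligned [TailTrajectory-class] replicates.
#' @param selection atom indices (per trajectory) to profile; default the
#'   tail C-alpha beads of all chains.
#' @return data.frame with `chain`, `resno`, `rmsf`, `sem`, and one
#'   `rep<i>` column per replicate.
#' @export
rmsfProfile <- function(trajs, selection = NULL) {
  if (is(trajs, "TailTrajectory")) trajs <- list(trajs)
  if (is.null(selection))
    selection <- selectAtoms(trajs[[1]], role = "tail", atom = "CA")
  tp <- topology(trajs[[1]])[selection, ]
  per <- vapply(trajs, function(tr) {
    rmsfAtoms(tr@coords[, selection, , drop = FALSE])
  }, numeric(length(selection)))
  per <- matrix(per, nrow = length(selection))
  m <- rowMeans(per)
  sem <- if (ncol(per) > 1) apply(per, 1, sd) / sqrt(ncol(per)) else
    rep(0, nrow(per))
  out <- data.frame(chain = tp$chain, resno = tp$resno, rmsf = m, sem = sem)
  colnames(per) <- paste0("rep", seq_len(ncol(per)))
  cbind(out, per)
}

#' RMS average correlation (RAC) convergence curve
#'
#' For each window length `tau`, coordinates are averaged over every
#' contiguous window of `tau` frames and the RMSD of each window average to
#' the whole-trajectory average structure is computed; RAC(tau) is the mean
#' of these RMSDs. At `tau = 1` this is the standard average RMSD over the
#' trajectory; at `tau = N` the window average equals the global average
#' and RAC is 0 by construction. A decaying RAC indicates the running
#' average is converging. The trajectory should be aligned beforehand.
#'
#' @param traj aligned [TailTrajectory-class].
#' @param tauGrid window lengths in frames (default a spread from 1 to N).
#' @param selection atom indices (default all atoms).
#' @return data.frame with `tau`, `rac`.
#' @export
racCurve <- function(traj, tauGrid = NULL, selection = seq_len(nAtoms(traj))) {
  x <- traj@coords[, selection, , drop = FALSE]
  nF <- dim(x)[1]
  if (is.null(tauGrid))
    tauGrid <- unique(round(seq(1, nF, length.out = min(20, nF))))
  stopIfNot(all(tauGrid >= 1 & tauGrid <= nF),
            "tau must lie within 1..nFrames")
  flat <- matrix(x, nrow = nF)  # frames x (atoms*3)
  cums <- rbind(0, apply(flat, 2, cumsum))
  globalAvg <- colMeans(flat)
  nSel <- length(selection)
  rac <- vapply(tauGrid, function(tau) {
    starts <- seq_len(nF - tau + 1L)
    tot <- (cums[starts + tau, , drop = FALSE] -
              cums[starts, , drop = FALSE]) / tau
    dev <- sweep(tot, 2, globalAvg)
    mean(sqrt(rowSums(dev^2) / nSel))
  }, numeric(1))
  data.frame(tau = tauGrid, rac = rac)
}

#' Per-frame radius of gyration
#'
#' Mass-uniform radius of gyration of the selected atoms:
#' `sqrt(mean |x_i - centroid|^2)` per frame.
#'
#' @param traj a [TailTrajectory-class].
#' @param selection atom indices (default all atoms).
#' @return Numeric vector, one value per frame (Angstrom).
#' @export
radiusOfGyration <- function(traj, selection = seq_len(nAtoms(traj))) {
  stopIfNot(length(selection) >= 1L, "empty selection")
  x <- traj@coords[, selection, , drop = FALSE]
  vapply(seq_len(dim(x)[1]), function(f) {
    xf <- x[f, , , drop = TRUE]
    if (is.null(dim(xf))) xf <- matrix(xf, ncol = 3)
    sqrt(mean(rowSums(sweep(xf, 2, colMeans(xf))^2)))
  }, numeric(1))
}

#' Time-averaged inter-residue distance map of a tail
#'
#' Symmetric matrix of mean pairwise C-alpha (bead) distances over frames;
#' reports tail compactness as the mean distance between residues at least
#' `longRange` apart in sequence.
#'
#' @param traj a [TailTrajectory-class].
#' @param selection atom indices of the tail C-alpha beads, in residue
#'   order.
#' @param longRange sequence separation defining long-range pairs
#'   (default 10).
#' @return Distance matrix with attribute `"compactness"`.
#' @export
interResidueDistances <- function(traj, selection, longRange = 10) {
  stopIfNot(length(selection) >= 2L, "need at least 2 residues")
  x <- traj@coords[, selection, , drop = FALSE]
  n <- length(selection)
  acc <- matrix(0, n, n)
  for (f in seq_len(dim(x)[1]))
    acc <- acc + as.matrix(stats::dist(x[f, , , drop = TRUE]))
  acc <- acc / dim(x)[1]
  resno <- topology(traj)$resno[selection]
  dimnames(acc) <- list(resno, resno)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  attr(acc, "compactness") <- mean(acc[sep >= longRange])
  acc
}
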