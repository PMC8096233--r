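#' Pseudo-dihedral angles along a bead chain
#'
#' Torsion angles over each four consecutive beads (C-alpha pseudo-
#' dihedrals), the coarse-chain analogue of backbone phi/psi, in degrees in
#' [-180, 180).
#'
#' @param traj a [TailTrajectory-class].
#' @param selection atom indices of the chain beads, in sequence order
#'   (at least 4).
#' @return Matrix frames x (n-3) of dihedral angles; column `i` spans beads
#'   `i..i+3`.
#' @export
pseudoDihedrals <- function(traj, selection) {
  stopIfNot(length(selection) >= 4L, "need at least 4 beads")
  x <- traj@coords[, selection, , drop = FALSE]
  nF <- dim(x)[1]
  nD <- length(selection) - 3L
  out <- matrix(NA_real_, nF, nD)
  for (f in seq_len(nF)) {
    p <- x[f, , , drop = TRUE]
    for (i in seq_len(nD)) {
      b1 <- p[i + 1, ] - p[i, ]
      b2 <- p[i + 2, ] - p[i + 1, ]
      b3 <- p[i + 3, ] - p[i + 2, ]
      n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
              b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
              b2[3] * b3[1] - b2[1] * b3[3],
              b2[1] * b3[2] - b2[2] * b3[1])
      m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
              n1[3] * b2[1] - n1[1] * b2[3],
              n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
      ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
      out[f, i] <- if (ang >= 180) ang - 360 else ang
    }
  }
  out
}

# Histogram KLD between two angle samples over fixed circular bins.
histKld <- function(a, b, bins = 60, pseudoCount = 0.5) {
  breaks <- seq(-180, 180, length.out = bins + 1)
  wrap <- function(x) ((x + 180) %% 360) - 180
  ca <- tabulate(findInterval(wrap(a), breaks, rightmost.closed = TRUE),
                 nbins = bins)
  cb <- tabulate(findInterval(wrap(b), breaks, rightmost.closed = TRUE),
                 nbins = bins)
  pa <- (ca + pseudoCount) / (sum(ca) + bins * pseudoCount)
  pb <- (cb + pseudoCount) / (sum(cb) + bins * pseudoCount)
  sum(pa * log(pa / pb))
}

#' Kullback-Leibler divergence between dihedral-angle ensembles
#'
#' Compares per-angle distributions of two conformational ensembles via
#' histogram KLD with pseudo-count regularisation (so empty bins never
#' produce infinities and the estimate is always >= 0). Direction is
#' KLD(A || B), i.e. system versus reference; `symmetrized = TRUE` returns
#' the Jensen-Shannon divergence instead. Significance is assessed by a
#' permutation test: replicate-run labels are shuffled between the two
#' ensembles and the KLD recomputed.
#'
#' @param ensA,ensB matrices of angle samples (degrees), samples x angles;
#'   equal numbers of columns. For permutation testing, supply lists of
#'   per-replicate matrices instead.
#' @param bins histogram bins over [-180, 180) (default 60).
#' @param pseudoCount additive regularisation per bin (default 0.5).
#' @param nPerm permutations for the p-value (default 1000; 0 disables).
#' @param symmetrized return Jensen-Shannon divergence instead of KLD.
#' @param seed seed for the permutation draw.
#' @return data.frame with `angle`, `kld` and, when permutations ran,
#'   `p.value`.
#' @export
dihedralKld <- function(ensA, ensB, bins = 60, pseudoCount = 0.5,
                        nPerm = 0, symmetrized = FALSE, seed = 1L) {
  repsA <- if (is.list(ensA) && !is.data.frame(ensA)) ensA else list(ensA)
  repsB <- if (is.list(ensB) && !is.data.frame(ensB)) ensB else list(ensB)
  A <- do.call(rbind, repsA)
  B <- do.call(rbind, repsB)
  stopIfNot(ncol(A) == ncol(B), "ensembles must share the angle set")
  stopIfNot(nrow(A) >= 100 && nrow(B) >= 100,
            "need at least 100 samples per ensemble")
  div <- function(a, b) {
    if (symmetrized) {
      # Jensen-Shannon via two KLDs against the midpoint sample mixture
      0.5 * histKld(a, c(a, b), bins, pseudoCount) +
        0.5 * histKld(b, c(a, b), bins, pseudoCount)
    } else histKld(a, b, bins, pseudoCount)
  }
  observed <- vapply(seq_len(ncol(A)), function(j) div(A[, j], B[, j]),
                     numeric(1))
  out <- data.frame(angle = seq_len(ncol(A)), kld = observed)
  if (nPerm > 0) {
    reps <- c(repsA, repsB)
    isA <- seq_along(reps) <= length(repsA)
    stopIfNot(length(reps) >= 2, "permutation test needs replicates")
    perms <- withSeed(seed, replicate(nPerm, sample(isA), simplify = FALSE))
    null <- matrix(NA_real_, nPerm, ncol(A))
    for (p in seq_len(nPerm)) {
      Ap <- do.call(rbind, reps[perms[[p]]])
      Bp <- do.call(rbind, reps[!perms[[p]]])
      null[p, ] <- vapply(seq_len(ncol(A)), function(j)
        div(Ap[, j], Bp[, j]), numeric(1))
    }
    out$p.value <- vapply(seq_len(ncol(A)), function(j)
      (1 + sum(null[, j] >= observed[j])) / (nPerm + 1), numeric(1))
  }
  out
}
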