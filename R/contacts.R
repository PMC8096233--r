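#' Time-averaged H3 tail-DNA heavy-atom contact matrix
#'
#' A contact is a (tail heavy atom, DNA heavy atom) pair within `cutoff`
#' Angstrom (inclusive). Per frame, contacts are counted for each (tail
#' residue, DNA base pair) cell and the matrix holds the per-frame mean
#' counts. DNA base pairs are identified by residue number irrespective of
#' strand. The total number of contacts of a tail is the rounded sum of
#' the matrix (see [totalContacts()]).
#'
#' @param traj a [TailTrajectory-class].
#' @param chain H3 chain id whose tail is profiled (default `"A"`).
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @param tailResidues residue numbers defining the tail (default 1:37).
#' @return A [ContactMatrix-class].
#' @export
contactMatrix <- function(traj, chain = "A", cutoff = 4.5,
                          tailResidues = 1:37) {
  tp <- topology(traj)
  tailIdx <- selectAtoms(traj, role = "tail", chain = chain,
                         resno = tailResidues, heavyOnly = TRUE)
  dnaIdx <- selectAtoms(traj, role = "DNA", heavyOnly = TRUE)
  stopIfNot(length(tailIdx) > 0, "no heavy tail atoms selected")
  stopIfNot(length(dnaIdx) > 0, "no heavy DNA atoms selected")
  tailRes <- tp$resno[tailIdx]
  dnaBp <- tp$resno[dnaIdx]
  resLevels <- sort(unique(tailRes))
  bpLevels <- sort(unique(dnaBp))
  counts <- matrix(0, length(resLevels), length(bpLevels),
                   dimnames = list(resLevels, bpLevels))
  nF <- nFrames(traj)
  cut2 <- cutoff^2
  ri <- match(tailRes, resLevels)
  bi <- match(dnaBp, bpLevels)
  for (f in seq_len(nF)) {
    xt <- matrix(traj@coords[f, tailIdx, , drop = FALSE], ncol = 3)
    xd <- matrix(traj@coords[f, dnaIdx, , drop = FALSE], ncol = 3)
    # squared distance matrix, vectorised
    d2 <- outer(rowSums(xt^2), rowSums(xd^2), "+") - 2 * tcrossprod(xt, xd)
    hit <- which(d2 <= cut2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      idx <- cbind(ri[hit[, 1]], bi[hit[, 2]])
      tab <- table(paste(idx[, 1], idx[, 2]))
      ij <- do.call(rbind, strsplit(names(tab), " "))
      counts[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <-
        counts[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] +
        as.numeric(tab)
    }
  }
  new("ContactMatrix", counts = counts / nF, cutoff = cutoff,
      framesUsed = as.integer(nF), chain = chain)
}

# Independent brute-force oracle: plain double loop over atom pairs.
# Kept deliberately naive; used in tests to validate contactMatrix().
contactMatrixBruteForce <- function(traj, chain = "A", cutoff = 4.5,
                                    tailResidues = 1:37) {
  tp <- topology(traj)
  tailIdx <- which(tp$role == "tail" & tp$chain == chain &
                     tp$resno %in% tailResidues & tp$heavy)
  dnaIdx <- which(tp$role == "DNA" & tp$heavy)
  resLevels <- sort(unique(tp$resno[tailIdx]))
  bpLevels <- sort(unique(tp$resno[dnaIdx]))
  counts <- matrix(0, length(resLevels), length(bpLevels),
                   dimnames = list(resLevels, bpLevels))
  for (f in seq_len(nFrames(traj))) {
    for (a in tailIdx) {
      for (b in dnaIdx) {
        d <- sqrt(sum((traj@coords[f, a, ] - traj@coords[f, b, ])^2))
        if (d <= cutoff) {
          i <- match(tp$resno[a], resLevels)
          j <- match(tp$resno[b], bpLevels)
          counts[i, j] <- counts[i, j] + 1
        }
      }
    }
  }
  counts / nFrames(traj)
}

#' Superhelical location of a base pair
#'
#' Maps a 1-based base-pair index to its superhelical location (SHL):
#' `(bp - dyad) / 10`, rounded to the nearest half-integer (half up) and
#' clamped to [-7, 7]. SHL 0 is the dyad.
#'
#' @param bp base-pair index (1-based), vectorised.
#' @param dyad dyad base-pair index (default 74).
#' @param nBp total base pairs (default 147); indices outside 1..nBp error.
#' @return Numeric SHL values in steps of 0.5.
#' @export
shlAssign <- function(bp, dyad = 74, nBp = 147) {
  stopIfNot(all(bp >= 1 & bp <= nBp), "bp index out of range")
  raw <- (bp - dyad) / 10
  shl <- floor(raw * 2 + 0.5) / 2  # half-up rounding to 0.5 bins
  pmin(pmax(shl, -7), 7)
}

#' Sum a contact matrix into a per-SHL profile
#'
#' Collapses the base-pair columns of a [ContactMatrix-class] by
#' superhelical location, summing the frame-averaged counts over all tail
#' residues and all base pairs in each SHL bin.
#'
#' @param cm a [ContactMatrix-class].
#' @param dyad dyad base-pair index (default 74).
#' @param nBp total base pairs (default 147).
#' @return data.frame with `shl` and `contacts` (one row per occupied
#'   half-integer SHL, zeros included across the full [-7, 7] grid).
#' @export
contactsByShl <- function(cm, dyad = 74, nBp = 147) {
  counts <- contactCounts(cm)
  bp <- as.integer(colnames(counts))
  shl <- shlAssign(bp, dyad = dyad, nBp = nBp)
  colSums_ <- colSums(counts)
  grid <- seq(-7, 7, by = 0.5)
  prof <- vapply(grid, function(s) sum(colSums_[shl == s]), numeric(1))
  data.frame(shl = grid, contacts = prof)
}
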