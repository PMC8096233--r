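#' Principal component analysis of H3 tail C-alpha coordinates
#'
#' Pools frames across species (each trajectory should already be
#' superposed on its tail atoms only), builds the 3n x 3n covariance
#' matrix of the selected tail C-alpha coordinates, and eigen-decomposes
#' it. Projections of every frame onto PC1/PC2 are returned per species.
#' Sign convention: PC1 is oriented so that the most extended pooled
#' conformation (largest tail radius of gyration) projects negative, so
#' more extended ensembles appear at more negative PC1.
#'
#' @param trajs named list of aligned [TailTrajectory-class] objects (names
#'   are species labels).
#' @param selection atom indices of the tail C-alpha beads (default: tail
#'   role, CA atoms, residues 1-37 of the first trajectory's topology).
#' @return List with `eigenvalues`, `varianceFraction`, `vectors`
#'   (3n x 3n, columns are PCs), and `projections` (data.frame: `species`,
#'   `frame`, `pc1`, `pc2`).
#' @export
pcaTails <- function(trajs, selection = NULL) {
  stopIfNot(length(trajs) >= 1, "no trajectories supplied")
  if (is.null(names(trajs)))
    names(trajs) <- paste0("system", seq_along(trajs))
  if (is.null(selection))
    selection <- selectAtoms(trajs[[1]], role = "tail", atom = "CA",
                             resno = 1:37)
  mats <- lapply(trajs, function(tr) {
    x <- tr@coords[, selection, , drop = FALSE]
    matrix(x, nrow = dim(x)[1])  # frames x 3n
  })
  pooled <- do.call(rbind, mats)
  stopIfNot(nrow(pooled) >= 2, "need at least 2 frames")
  mu <- colMeans(pooled)
  centred <- sweep(pooled, 2, mu)
  cv <- crossprod(centred) / (nrow(pooled) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # orient PC1: most extended pooled frame (max Rg of the selection)
  # projects negative
  rg <- apply(pooled, 1, function(v) {
    m <- matrix(v, ncol = 3)
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  })
  extProj <- sum(centred[which.max(rg), ] * vecs[, 1])
  if (extProj > 0) vecs[, 1] <- -vecs[, 1]
  proj <- centred %*% vecs[, 1:2, drop = FALSE]
  species <- rep(names(trajs), vapply(mats, nrow, integer(1)))
  frame <- unlist(lapply(mats, function(m) seq_len(nrow(m))))
  list(eigenvalues = vals,
       varianceFraction = vals / sum(vals),
       vectors = vecs,
       center = mu,
       projections = data.frame(species = species, frame = frame,
                                pc1 = proj[, 1], pc2 = proj[, 2]))
}
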