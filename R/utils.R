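#' @importFrom stats aov coef complete.cases median nls.control pf pt qt rnorm
#'   runif sd setNames t.test TukeyHSD var vcov
#' @importFrom utils read.delim write.table packageVersion
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage substream seed derived from a root seed, kept
# below 2^31 so it is always a valid R integer.
deriveSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Optimal rigid-body superposition of one coordinate set onto another
#'
#' Kabsch algorithm: returns the proper rotation and translation minimising
#' the RMSD between `mobile` and `target` (n x 3 matrices). Reflections are
#' rejected by flipping the sign of the smallest singular direction when the
#' rotation determinant would be negative.
#'
#' @param mobile n x 3 coordinate matrix to move.
#' @param target n x 3 coordinate matrix to fit onto.
#' @return List with `rotation` (3 x 3), `translation` (length 3) such that
#'   `sweep(mobile, 2, cm) %*% rotation + translation` superposes onto
#'   `target`, and `rmsd` after fitting.
#' @keywords internal
kabsch <- function(mobile, target) {
  stopifnot(is.matrix(mobile), is.matrix(target),
            ncol(mobile) == 3L, all(dim(mobile) == dim(target)))
  if (nrow(mobile) < 3L)
    stop("superposition needs at least 3 atoms", call. = FALSE)
  cmM <- colMeans(mobile)
  cmT <- colMeans(target)
  A <- sweep(mobile, 2, cmM)
  B <- sweep(target, 2, cmT)
  # degenerate (collinear) selections have a rank-deficient cross-covariance
  H <- crossprod(A, B)
  s <- svd(H)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300))
    stop("degenerate (collinear) atom selection for superposition",
         call. = FALSE)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)  # maps centred mobile -> centred target
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = t(R), translation = cmT, rmsd = rmsd, center = cmM)
}

applyKabsch <- function(coords, fit) {
  sweep(coords, 2, fit$center) %*% fit$rotation +
    matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

rmsdCoords <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# first-order (delta-method) error of a ratio x/y with independent errors
ratioError <- function(x, sx, y, sy) {
  r <- x / y
  abs(r) * sqrt((sx / x)^2 + (sy / y)^2)
}
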