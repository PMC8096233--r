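#' Specify a toy superhelical nucleosome-like particle
#'
#' Defines a coarse generative model of a (sub)nucleosome for exercising the
#' trajectory metrics: 147 pseudo-bp of DNA on an ideal left-handed
#' superhelix (straight tangent extensions for unwrapped base pairs), a
#' rigid jittering histone core, and two 37-bead H3 tails whose beads follow
#' independent AR(1) (discretised Ornstein-Uhlenbeck) fluctuations about
#' anchored mean positions, so RMSF and time-correlation metrics have
#' closed-form expectations.
#'
#' Species presets encode the wrapping states: the nucleosome is fully
#' wrapped; the hexasome keeps the dimer on the high-bp side and unwraps
#' 40 bp on the low-bp side, with the tail on the unwrapped side given
#' larger fluctuation amplitudes; the tetrasome unwraps both sides leaving
#' 66 bp wrapped.
#'
#' @param species preset: `"nucleosome"`, `"hexasome"` or `"tetrasome"`;
#'   individual arguments override the preset.
#' @param nBp number of pseudo base pairs (default 147).
#' @param dyadBp 1-based dyad index (default 74).
#' @param radius superhelix radius in Angstrom (default 41.9).
#' @param pitch superhelix pitch in Angstrom per turn (default 25.9).
#' @param turns total superhelical turns over `nBp` (default 1.84).
#' @param unwrapLeft,unwrapRight base pairs released to straight tangent
#'   lines at the low-bp / high-bp ends.
#' @param sigmaTailA,sigmaTailE per-bead stationary fluctuation SD
#'   (Angstrom, per axis) for the H3 tails anchored on the low-bp (chain A)
#'   and high-bp (chain E) sides; scalar or length-37 vector.
#' @param rho per-frame AR(1) temporal correlation, in [0, 1).
#' @param coreJitterSd SD of iid Gaussian jitter of core beads (Angstrom).
#' @param nFrames number of frames to generate.
#' @param dtPs frame spacing in ps (bookkeeping only).
#' @param seed integer seed.
#' @return A `toyParticleSpec` list, validated.
#' @export
toyParticleSpec <- function(species = c("nucleosome", "hexasome", "tetrasome"),
                            nBp = 147L, dyadBp = 74L, radius = 41.9,
                            pitch = 25.9, turns = 1.84,
                            unwrapLeft = NULL, unwrapRight = NULL,
                            sigmaTailA = NULL, sigmaTailE = NULL,
                            rho = 0.9, coreJitterSd = 0.1,
                            nFrames = 200L, dtPs = 10, seed = 1L) {
  species <- match.arg(species)
  nTail <- 37L
  sigmaBase <- 0.5 + 2.5 * (seq_len(nTail) - 1) / (nTail - 1)
  preset <- switch(species,
    nucleosome = list(ul = 0L, ur = 0L, sA = sigmaBase, sE = sigmaBase),
    hexasome   = list(ul = 40L, ur = 0L, sA = 1.6 * sigmaBase,
                      sE = sigmaBase),
    tetrasome  = list(ul = 40L, ur = 41L, sA = 1.6 * sigmaBase,
                      sE = 1.6 * sigmaBase))
  if (is.null(unwrapLeft)) unwrapLeft <- preset$ul
  if (is.null(unwrapRight)) unwrapRight <- preset$ur
  if (is.null(sigmaTailA)) sigmaTailA <- preset$sA
  if (is.null(sigmaTailE)) sigmaTailE <- preset$sE
  if (length(sigmaTailA) == 1L) sigmaTailA <- rep(sigmaTailA, nTail)
  if (length(sigmaTailE) == 1L) sigmaTailE <- rep(sigmaTailE, nTail)
  stopIfNot(unwrapLeft + unwrapRight < nBp,
            "unwrapped bp counts must leave at least one wrapped bp")
  stopIfNot(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  stopIfNot(all(sigmaTailA >= 0) && all(sigmaTailE >= 0),
            "tail fluctuation SDs must be >= 0")
  stopIfNot(length(sigmaTailA) == nTail && length(sigmaTailE) == nTail,
            "per-bead sigma must have length 37")
  stopIfNot(coreJitterSd >= 0, "core jitter SD must be >= 0")
  stopIfNot(dyadBp >= 1 && dyadBp <= nBp, "dyad must lie within 1..nBp")
  structure(list(species = species, nBp = as.integer(nBp),
                 dyadBp = as.integer(dyadBp), radius = radius, pitch = pitch,
                 turns = turns, unwrapLeft = as.integer(unwrapLeft),
                 unwrapRight = as.integer(unwrapRight),
                 sigmaTailA = sigmaTailA, sigmaTailE = sigmaTailE, rho = rho,
                 coreJitterSd = coreJitterSd, nFrames = as.integer(nFrames),
                 dtPs = dtPs, seed = seed),
            class = "toyParticleSpec")
}

# Mean DNA geometry: base pseudo-atom centreline positions plus the two
# strand offsets. Wrapped bp lie on the ideal left-handed superhelix;
# unwrapped bp continue along the tangent at the last wrapped bp with the
# superhelical per-bp arc length preserved.
dnaMeanGeometry <- function(spec) {
  n <- spec$nBp
  dTheta <- spec$turns * 2 * pi / (n - 1)
  cz <- -spec$pitch / (2 * pi)  # left-handed
  theta <- (seq_len(n) - spec$dyadBp) * dTheta
  centre <- cbind(spec$radius * cos(theta), spec$radius * sin(theta),
                  cz * theta)
  tangentAt <- function(th) {
    v <- c(-spec$radius * sin(th), spec$radius * cos(th), cz)
    v / sqrt(sum(v^2))
  }
  arc <- dTheta * sqrt(spec$radius^2 + cz^2)
  if (spec$unwrapLeft > 0) {
    i0 <- spec$unwrapLeft + 1L
    tv <- tangentAt(theta[i0])
    for (i in seq_len(spec$unwrapLeft))
      centre[i, ] <- centre[i0, ] - (i0 - i) * arc * tv
  }
  if (spec$unwrapRight > 0) {
    i0 <- n - spec$unwrapRight
    tv <- tangentAt(theta[i0])
    for (i in (i0 + 1L):n)
      centre[i, ] <- centre[i0, ] + (i - i0) * arc * tv
  }
  # radial unit vectors give the strand backbone offsets (9 A off-centre);
  # in the unwrapped stretches the frame at the last wrapped bp is reused so
  # base atoms stay exactly collinear
  radial <- cbind(cos(theta), sin(theta), 0)
  if (spec$unwrapLeft > 0)
    radial[seq_len(spec$unwrapLeft), ] <-
      radial[rep(spec$unwrapLeft + 1L, spec$unwrapLeft), ]
  if (spec$unwrapRight > 0)
    radial[(n - spec$unwrapRight + 1L):n, ] <-
      radial[rep(n - spec$unwrapRight, spec$unwrapRight), ]
  list(centre = centre, radial = radial, arc = arc)
}

# Mean positions of all pseudo-atoms plus the topology table.
particleMeanStructure <- function(spec) {
  g <- dnaMeanGeometry(spec)
  n <- spec$nBp
  strandOff <- 9
  dnaI <- g$centre + strandOff * g$radial
  dnaJ <- g$centre - strandOff * g$radial
  dnaB <- g$centre
  nTail <- 37L
  nCore <- 18L  # residues 38-55
  anchorBp <- function(side) {
    bp <- if (side == "A") spec$dyadBp - 25L else spec$dyadBp + 25L
    g$centre[bp, ]
  }
  tailMean <- function(side) {
    a <- anchorBp(side)
    dir <- a - c(0, 0, a[3])
    dir <- dir / sqrt(sum(dir^2))
    outer(3.8 * seq_len(nTail), dir) + rep(a, each = nTail)
  }
  coreMean <- function(side) {
    ang <- seq(0, pi, length.out = nCore) + if (side == "A") 0 else pi
    cbind(12 * cos(ang), 12 * sin(ang), if (side == "A") -4 else 4)
  }
  xyz <- rbind(dnaI, dnaJ, dnaB,
               tailMean("A"), coreMean("A"),
               tailMean("E"), coreMean("E"))
  topo <- rbind(
    data.frame(chain = "I", resno = seq_len(n), resname = "DA", atom = "P",
               heavy = TRUE, role = "DNA"),
    data.frame(chain = "J", resno = seq_len(n), resname = "DT", atom = "P",
               heavy = TRUE, role = "DNA"),
    data.frame(chain = "I", resno = seq_len(n), resname = "DA", atom = "B",
               heavy = TRUE, role = "DNA"),
    data.frame(chain = "A", resno = 1:37, resname = "GLY", atom = "CA",
               heavy = TRUE, role = "tail"),
    data.frame(chain = "A", resno = 38:55, resname = "GLY", atom = "CA",
               heavy = TRUE, role = "core"),
    data.frame(chain = "E", resno = 1:37, resname = "GLY", atom = "CA",
               heavy = TRUE, role = "tail"),
    data.frame(chain = "E", resno = 38:55, resname = "GLY", atom = "CA",
               heavy = TRUE, role = "core"))
  list(xyz = xyz, topology = topo)
}

#' Simulate a coarse trajectory of a toy (sub)nucleosomal particle
#'
#' DNA pseudo-atoms and histone-core beads stay at their mean positions
#' (core beads with iid Gaussian jitter); each tail bead evolves as an AR(1)
#' process about its anchor: `x_f = a + rho * (x_{f-1} - a) +
#' sqrt(1 - rho^2) * N(0, sigma_b)` per coordinate, started from the
#' stationary distribution, so the stationary per-axis SD is exactly
#' `sigma_b` and the per-axis autocorrelation at lag L is `rho^L`.
#'
#' @param spec a [toyParticleSpec()].
#' @return A [TailTrajectory-class] object.
#' @export
simulateParticleTrajectory <- function(spec) {
  stopifnot(inherits(spec, "toyParticleSpec"))
  ms <- particleMeanStructure(spec)
  nAtoms <- nrow(ms$xyz)
  nF <- spec$nFrames
  topo <- ms$topology
  coords <- array(rep(ms$xyz, each = nF), dim = c(nF, nAtoms, 3))
  withSeed(spec$seed, {
    tailIdx <- function(ch) which(topo$chain == ch & topo$role == "tail")
    for (side in c("A", "E")) {
      idx <- tailIdx(side)
      sig <- if (side == "A") spec$sigmaTailA else spec$sigmaTailE
      for (b in seq_along(idx)) {
        if (sig[b] == 0) next
        for (ax in 1:3) {
          innov <- rnorm(nF, 0, sig[b])
          dev <- numeric(nF)
          dev[1] <- innov[1]
          if (nF > 1) {
            w <- sqrt(1 - spec$rho^2)
            for (f in 2:nF) dev[f] <- spec$rho * dev[f - 1] + w * innov[f]
          }
          coords[, idx[b], ax] <- coords[, idx[b], ax] + dev
        }
      }
    }
    if (spec$coreJitterSd > 0) {
      coreIdx <- which(topo$role == "core")
      coords[, coreIdx, ] <- coords[, coreIdx, ] +
        rnorm(nF * length(coreIdx) * 3, 0, spec$coreJitterSd)
    }
  })
  new("TailTrajectory", coords = coords, topology = topo, dtPs = spec$dtPs,
      trimmed = 0)
}
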