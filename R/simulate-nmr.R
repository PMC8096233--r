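#' Paper-style 15N relaxation delay schedules
#'
#' Interleaved duplicate delay lists: longitudinal (T1) loop lengths
#' 10, 100, 200, 500, 1000, 2000 ms (each twice) and transverse (T2) CPMG
#' loop lengths 16.96, 50.88, 67.84, 101.76, 152.64, 203.52 ms (each twice).
#'
#' @param type `"T1"` or `"T2"`.
#' @return Numeric vector of delays in ms, duplicates included.
#' @export
relaxationDelays <- function(type = c("T1", "T2")) {
  type <- match.arg(type)
  base <- switch(type,
    T1 = c(10, 100, 200, 500, 1000, 2000),
    T2 = c(16.96, 50.88, 67.84, 101.76, 152.64, 203.52))
  rep(base, each = 2)
}

#' Simulate paired amide peak lists for nucleosome, tetrasome and hexasome
#'
#' Generates Sparky-style peak tables with planted structure: the tetrasome
#' peaks are offset from the nucleosome reference so that the combined amide
#' chemical-shift difference averages `meanCsd`; the hexasome carries two
#' peaks per residue, one overlapping the nucleosome positions (hex-N, the
#' tail adjacent to the retained H2A/H2B dimer) and one overlapping the
#' tetrasome positions (hex-T, the tail on the unwrapped side), with hex-T
#' heights a planted `foldAsymmetry` multiple of hex-N heights.
#'
#' The combined shift difference used throughout is
#' `sqrt(ddH^2 + (0.154 * ddN)^2)`.
#'
#' @param residues integer residue numbers (default 1:36, the observable H3
#'   tail amides).
#' @param foldAsymmetry planted hex-T/hex-N height ratio (default 2.4).
#' @param meanCsd target mean combined shift difference between nucleosome
#'   and tetrasome peaks, ppm (default 0.09).
#' @param hexOffsetCsd mean combined shift difference between each hexasome
#'   subset and its parent species (default 0.006: the subsets overlay
#'   their parent spectra nearly coincidently, well below the 0.03
#'   similarity threshold).
#' @param minSeparation minimum per-residue combined nucleosome-tetrasome
#'   separation enforced by resampling (default 0.02 ppm).
#' @param heightNoiseSd multiplicative height noise, fractional SD
#'   (default 0.05).
#' @param shiftNoiseH,shiftNoiseN additive position noise SD in ppm for the
#'   1H and 15N dimensions (defaults 0.002 and 0.002/0.154).
#' @param baseHeight hex-N / reference mean peak height (arbitrary units).
#' @param seed integer seed.
#' @return Named list of peak-list data.frames (`nucleosome`, `tetrasome`,
#'   `hexasome`) with columns `species`, `residue`, `dH`, `dN`, `height`,
#'   `subset` (ground-truth `"hex-N"`/`"hex-T"` for the hexasome, `NA`
#'   otherwise) and `overlap` (logical).
#' @export
simulatePeakLists <- function(residues = 1:36, foldAsymmetry = 2.4,
                              meanCsd = 0.09, hexOffsetCsd = 0.006,
                              minSeparation = 0.02, heightNoiseSd = 0.05,
                              shiftNoiseH = 0.002,
                              shiftNoiseN = 0.002 / 0.154,
                              baseHeight = 100, seed = 1L) {
  stopIfNot(length(residues) > 0, "empty residue range")
  stopIfNot(!anyDuplicated(residues), "residues must be unique")
  stopIfNot(foldAsymmetry > 0, "fold asymmetry must be > 0")
  n <- length(residues)
  withSeed(seed, {
    # reference (nucleosome) amide positions in the typical H3 tail region
    ref <- data.frame(residue = residues,
                      dH = runif(n, 7.9, 8.6),
                      dN = runif(n, 108, 127))
    # tetrasome offsets: isotropic in combined-shift units, rejection-sampled
    # to keep every residue separated by at least minSeparation
    s <- meanCsd / sqrt(pi / 2)
    drawOffsets <- function(scale) {
      dH <- rnorm(n, 0, scale)
      dN <- rnorm(n, 0, scale / 0.154)
      csd <- sqrt(dH^2 + (0.154 * dN)^2)
      list(dH = dH, dN = dN, csd = csd)
    }
    off <- drawOffsets(s)
    for (i in 1:50) {
      bad <- off$csd < minSeparation
      if (!any(bad)) break
      redraw <- drawOffsets(s)
      off$dH[bad] <- redraw$dH[bad]
      off$dN[bad] <- redraw$dN[bad]
      off$csd <- sqrt(off$dH^2 + (0.154 * off$dN)^2)
    }
    sHex <- hexOffsetCsd / sqrt(pi / 2)
    hexN <- drawOffsets(sHex)
    hexT <- drawOffsets(sHex)

    jitter <- function(k) list(h = rnorm(k, 0, shiftNoiseH),
                               n = rnorm(k, 0, shiftNoiseN))
    heights <- function(mu, k) mu * pmax(1 + rnorm(k, 0, heightNoiseSd), 0.05)

    jN <- jitter(n); jT <- jitter(n); jHN <- jitter(n); jHT <- jitter(n)
    nuc <- data.frame(species = "nucleosome", residue = residues,
                      dH = ref$dH + jN$h, dN = ref$dN + jN$n,
                      height = heights(baseHeight, n),
                      subset = NA_character_, overlap = FALSE)
    tet <- data.frame(species = "tetrasome", residue = residues,
                      dH = ref$dH + off$dH + jT$h,
                      dN = ref$dN + off$dN + jT$n,
                      height = heights(baseHeight, n),
                      subset = NA_character_, overlap = FALSE)
    hex <- rbind(
      data.frame(species = "hexasome", residue = residues,
                 dH = ref$dH + hexN$dH + jHN$h,
                 dN = ref$dN + hexN$dN + jHN$n,
                 height = heights(baseHeight, n),
                 subset = "hex-N", overlap = FALSE),
      data.frame(species = "hexasome", residue = residues,
                 dH = ref$dH + off$dH + hexT$dH + jHT$h,
                 dN = ref$dN + off$dN + hexT$dN + jHT$n,
                 height = heights(baseHeight * foldAsymmetry, n),
                 subset = "hex-T", overlap = FALSE))
    list(nucleosome = nuc, tetrasome = tet,
         hexasome = hex[order(hex$residue, hex$subset), ])
  })
}

#' Simulate single-exponential 15N relaxation decays
#'
#' Peak heights decay as `H0 * exp(-delay / T)` without offset; Gaussian
#' noise of SD `noiseSd * H0` is added per measurement.
#'
#' @param trueT named numeric vector of true relaxation times (ms), one per
#'   residue; names are residue numbers.
#' @param delays relaxation delays in ms (duplicates allowed; see
#'   [relaxationDelays()]).
#' @param h0 height at zero delay (default 100).
#' @param noiseSd fractional noise SD relative to `h0` (default 0.02).
#' @param seed integer seed.
#' @return data.frame with columns `residue`, `delay_ms`, `height`, plus
#'   attribute `h0`.
#' @export
simulateRelaxation <- function(trueT, delays, h0 = 100, noiseSd = 0.02,
                               seed = 1L) {
  stopIfNot(all(trueT > 0), "true relaxation times must be > 0")
  stopIfNot(all(delays >= 0), "delays must be non-negative")
  resnames <- names(trueT)
  if (is.null(resnames)) resnames <- as.character(seq_along(trueT))
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_along(trueT), function(i) {
      h <- h0 * exp(-delays / trueT[i]) + rnorm(length(delays), 0, noiseSd * h0)
      data.frame(residue = as.integer(resnames[i]), delay_ms = delays,
                 height = h)
    }))
    attr(out, "h0") <- h0
    out
  })
}
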