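#' Specify a synthetic proteolysis experiment
#'
#' Defines the generative truth for a trypsin time course: one or more
#' exponential decay states (rate in 1/min, initial intact fraction, weight)
#' whose weighted sum is the fraction of full-length H3 remaining. A
#' hexasome is modelled as a half/half mixture of a nucleosome-like and a
#' tetrasome-like state, matching its one nucleosomal plus one tetrasomal H3
#' tail.
#'
#' @param species species label, e.g. `"nucleosome"`.
#' @param k true observed rate constant(s), 1/min.
#' @param a0 true initial intact fraction(s), in (0, 1].
#' @param weights state weights, must sum to 1; default single state.
#' @param timepoints sampling times in minutes; non-negative, strictly
#'   increasing, first must be 0. Default is the digestion schedule
#'   0, 2, 5, 10, 15, 20, 30, 50 min.
#' @param replicates number of gel replicates (default 3).
#' @param noiseSd densitometry noise SD in fraction units (default 0.02).
#' @param seed integer seed; mandatory for reproducibility.
#' @return A `proteolysisSpec` list, validated.
#' @export
proteolysisSpec <- function(species, k, a0, weights = rep(1 / length(k), length(k)),
                            timepoints = c(0, 2, 5, 10, 15, 20, 30, 50),
                            replicates = 3L, noiseSd = 0.02, seed = 1L) {
  stopIfNot(length(k) == length(a0) && length(k) == length(weights),
            "k, a0 and weights must have equal length")
  stopIfNot(all(k >= 0), "rates must be >= 0")
  stopIfNot(all(a0 > 0 & a0 <= 1), "intercepts must be in (0, 1]")
  stopIfNot(abs(sum(weights) - 1) < 1e-9, "mixture weights must sum to 1")
  stopIfNot(all(timepoints >= 0), "timepoints must be non-negative")
  stopIfNot(all(diff(timepoints) > 0), "timepoints must be strictly increasing")
  stopIfNot(timepoints[1] == 0, "first timepoint must be 0")
  stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
  structure(list(species = species, k = k, a0 = a0, weights = weights,
                 timepoints = timepoints, replicates = as.integer(replicates),
                 noiseSd = noiseSd, seed = seed),
            class = "proteolysisSpec")
}

#' Noiseless proteolysis decay model
#'
#' Evaluates the mixture decay `sum_j w_j * A0_j * exp(-k_j * t)` of a
#' [proteolysisSpec()] at arbitrary times.
#'
#' @param spec a `proteolysisSpec`.
#' @param t times in minutes.
#' @return Fraction of full-length H3 remaining at `t`.
#' @export
proteolysisModel <- function(spec, t) {
  vapply(t, function(tt) sum(spec$weights * spec$a0 * exp(-spec$k * tt)),
         numeric(1))
}

#' Simulate a gel-densitometry table for a trypsin digestion time course
#'
#' Generates band volumes for the full-length H3 band: per replicate, a
#' pre-digestion reference lane (`reference = TRUE`, the lane taken before
#' trypsin addition that all later lanes are normalised to) with volume
#' `v0`, and one measured lane per timepoint with volume
#' `v0 * (model(t) + noise)`, clamped at zero because densitometry volumes
#' are non-negative. With `a0 < 1` the measured t = 0 lane sits below the
#' reference, emulating particles lost to rapid mixing.
#'
#' @param spec a [proteolysisSpec()].
#' @param v0 reference lane volume in arbitrary density units (default 1000).
#' @return A `GelTable` data.frame with columns `species`, `time_min`,
#'   `replicate`, `band`, `volume`, `reference`.
#' @export
simulateProteolysis <- function(spec, v0 = 1000) {
  stopifnot(inherits(spec, "proteolysisSpec"))
  withSeed(spec$seed, {
    rows <- lapply(seq_len(spec$replicates), function(r) {
      f <- proteolysisModel(spec, spec$timepoints) +
        rnorm(length(spec$timepoints), 0, spec$noiseSd)
      f <- pmax(f, 0)
      rbind(
        data.frame(species = spec$species, time_min = 0, replicate = r,
                   band = "H3", volume = v0, reference = TRUE),
        data.frame(species = spec$species, time_min = spec$timepoints,
                   replicate = r, band = "H3", volume = v0 * f,
                   reference = FALSE))
    })
    do.call(rbind, rows)
  })
}

#' Simulate endpoint digests at several trypsin concentrations
#'
#' Emulates the fixed-endpoint assay (fraction full-length H3 at t = 20 min)
#' across trypsin dilutions for several species, in triplicate. The rate at
#' each dilution scales linearly with trypsin concentration (first-order
#' dependence on enzyme under rapid pre-equilibrium).
#'
#' @param specs list of [proteolysisSpec()], one per species (their `k` is
#'   the rate at the reference trypsin concentration).
#' @param trypsinRel relative trypsin concentrations (reference = 1).
#' @param tEnd endpoint time in minutes (default 20).
#' @param seed integer seed.
#' @return data.frame with columns `species`, `trypsin`, `replicate`,
#'   `fraction`.
#' @export
simulateEndpoints <- function(specs, trypsinRel = c(5, 1, 0.2), tEnd = 20,
                              seed = 1L) {
  withSeed(seed, {
    out <- list()
    for (spec in specs) {
      for (tr in trypsinRel) {
        scaled <- spec
        scaled$k <- spec$k * tr
        f <- proteolysisModel(scaled, tEnd) +
          rnorm(spec$replicates, 0, spec$noiseSd)
        out[[length(out) + 1L]] <- data.frame(
          species = spec$species, trypsin = tr,
          replicate = seq_len(spec$replicates), fraction = pmax(f, 0))
      }
    }
    do.call(rbind, out)
  })
}
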