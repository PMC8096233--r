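#' Fraction of full-length H3 remaining over a digestion time course
#'
#' For each (species, replicate), divides the full-length H3 band volume at
#' every timepoint by the pre-digestion reference volume: the lane flagged
#' `reference = TRUE` when the table has a `reference` column, otherwise the
#' t = 0 lane (in which case the t = 0 fraction is 1 by construction).
#' Replicate fractions are then averaged per timepoint.
#'
#' @param gel a gel-densitometry data.frame with columns `species`,
#'   `time_min`, `replicate`, `band`, `volume` and optionally `reference`.
#' @return A `TimeCourse` data.frame with columns `species`, `time_min`,
#'   `mean`, `sd`, `n`; attribute `"replicates"` holds the per-replicate
#'   fractions.
#' @export
fractionFullLength <- function(gel) {
  need <- c("species", "time_min", "replicate", "band", "volume")
  stopIfNot(all(need %in% names(gel)), paste(
    "gel table must have columns:", paste(need, collapse = ", ")))
  stopIfNot(all(gel$volume >= 0), "band volumes must be >= 0")
  h3 <- gel[gel$band == "H3", ]
  hasRef <- "reference" %in% names(gel)
  reps <- list()
  for (sp in unique(h3$species)) {
    gs <- h3[h3$species == sp, ]
    for (r in unique(gs$replicate)) {
      gr <- gs[gs$replicate == r, ]
      ref <- if (hasRef) gr[gr$reference, ] else gr[gr$time_min == 0, ]
      if (nrow(ref) == 0)
        stop(sprintf("no t=0 H3 reference lane for %s replicate %s", sp, r),
             call. = FALSE)
      if (ref$volume[1] <= 0)
        stop(sprintf("zero t=0 H3 volume for %s replicate %s", sp, r),
             call. = FALSE)
      meas <- if (hasRef) gr[!gr$reference, ] else gr
      reps[[length(reps) + 1L]] <- data.frame(
        species = sp, time_min = meas$time_min, replicate = r,
        fraction = meas$volume / ref$volume[1])
    }
  }
  reps <- do.call(rbind, reps)
  agg <- do.call(rbind, lapply(split(
    reps, list(reps$species, reps$time_min), drop = TRUE), function(d)
      data.frame(species = d$species[1], time_min = d$time_min[1],
                 mean = mean(d$fraction), sd = sd(d$fraction),
                 n = nrow(d))))
  agg <- agg[order(agg$species, agg$time_min), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- reps
  class(agg) <- c("TimeCourse", "data.frame")
  agg
}

#' Relative histone band composition normalised to H3
#'
#' Reports each band's volume relative to the full-length H3 band of the
#' same lane, averaged over replicates. H2A and H2B bands are integrated
#' together (they are poorly separated on these gels). Only the
#' pre-digestion lane (reference or t = 0) of each replicate is used.
#'
#' @param gel gel table as in [fractionFullLength()], with one row per band.
#' @return data.frame with columns `species`, `band`, `mean`, `sd`, `n`.
#' @export
histoneComposition <- function(gel) {
  hasRef <- "reference" %in% names(gel)
  lane <- if (hasRef) gel[gel$reference, ] else gel[gel$time_min == 0, ]
  stopIfNot(nrow(lane) > 0, "no pre-digestion lane in gel table")
  lane$band[lane$band %in% c("H2A", "H2B")] <- "H2A+H2B"
  out <- list()
  for (sp in unique(lane$species)) {
    ls <- lane[lane$species == sp, ]
    rel <- list()
    for (r in unique(ls$replicate)) {
      lr <- ls[ls$replicate == r, ]
      h3 <- sum(lr$volume[lr$band == "H3"])
      if (h3 <= 0)
        stop(sprintf("zero H3 volume for %s replicate %s", sp, r),
             call. = FALSE)
      v <- tapply(lr$volume, lr$band, sum)
      rel[[as.character(r)]] <- v / h3
    }
    bands <- unique(unlist(lapply(rel, names)))
    for (b in bands) {
      vals <- vapply(rel, function(x) unname(x[b]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, band = b, mean = mean(vals),
        sd = if (length(vals) > 1) sd(vals) else 0, n = length(vals))
    }
  }
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' Fit site-exposure kinetics: constrained weighted single exponential
#'
#' Fits the per-timepoint mean fraction of full-length H3 to
#' `A0 * exp(-k_obs * t)` by weighted least squares with weights
#' `1 / sd^2`. The curve is constrained to decay to zero (no constant
#' offset) and the y-intercept to `0 < A0 <= 1`, allowing for a
#' subpopulation of particles lost during initial mixing. Zero or missing
#' per-timepoint SDs are floored at the median nonzero SD of the series
#' (equal weights when no nonzero SD exists), so the weighting never becomes
#' infinite and the fit is invariant to uniform rescaling of all SDs.
#' Parameter errors are square roots of the fit covariance diagonal.
#'
#' @param tc a single-species `TimeCourse` from [fractionFullLength()], or
#'   any data.frame with columns `time_min`, `mean`, `sd`.
#' @return An [ExposureFit-class] object.
#' @export
fitExposureKinetics <- function(tc) {
  stopIfNot(all(c("time_min", "mean") %in% names(tc)),
            "time course needs time_min and mean columns")
  sp <- if ("species" %in% names(tc)) as.character(tc$species[1]) else ""
  if ("species" %in% names(tc))
    stopIfNot(length(unique(tc$species)) == 1L,
              "fit one species at a time")
  t <- tc$time_min
  y <- tc$mean
  stopIfNot(length(unique(t)) >= 4L, "need at least 4 distinct timepoints")
  s <- if ("sd" %in% names(tc)) tc$sd else rep(NA_real_, length(t))
  s[!is.finite(s) | s <= 0] <- NA_real_
  floorSd <- median(s, na.rm = TRUE)
  if (!is.finite(floorSd)) s[] <- 1 else s[is.na(s)] <- floorSd
  w <- 1 / s^2

  # starting values from a log-linear regression on the positive points
  pos <- y > 1e-10
  kStart <- if (sum(pos) >= 2) {
    sl <- -coef(stats::lm(log(y[pos]) ~ t[pos]))[2]
    max(min(sl, 100), 1e-4)
  } else 0.1
  a0Start <- min(max(y[t == min(t)][1], 1e-3), 1)

  fit <- minpack.lm::nlsLM(
    y ~ a0 * exp(-k * t),
    start = list(a0 = a0Start, k = kStart),
    lower = c(a0 = 1e-6, k = 0), upper = c(a0 = 1, k = Inf),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  atBound <- cf[["a0"]] > 1 - 1e-7 || cf[["k"]] < 1e-10
  if (cf[["k"]] < 1e-10)
    warning("fitted rate at the k = 0 boundary (no measurable decay)",
            call. = FALSE)
  res <- (y - cf[["a0"]] * exp(-cf[["k"]] * t)) * sqrt(w)
  new("ExposureFit", species = sp, kObs = unname(cf[["k"]]),
      kObsError = unname(se[2]), a0 = unname(min(cf[["a0"]], 1)),
      a0Error = unname(se[1]), cov = unname(vc), wrss = sum(res^2),
      atBoundary = atBound, nPoints = length(t))
}

#' Ratio of site-exposure equilibrium constants from two kinetic fits
#'
#' Under rapid conformational pre-equilibrium and first-order dependence of
#' the observed rate on enzyme concentration, the ratio of observed rate
#' constants equals the ratio of site-exposure equilibrium constants of the
#' two species. The error is first-order propagation from the two rate
#' errors.
#'
#' @param fitNum,fitDen [ExposureFit-class] objects (numerator and
#'   denominator species).
#' @return data.frame with `numerator`, `denominator`, `ratio`, `error`.
#' @export
siteExposureRatio <- function(fitNum, fitDen) {
  stopIfNot(kObs(fitDen) > 0, "denominator rate constant is zero")
  data.frame(
    numerator = fitNum@species, denominator = fitDen@species,
    ratio = kObs(fitNum) / kObs(fitDen),
    error = ratioError(kObs(fitNum), fitNum@kObsError,
                       kObs(fitDen), fitDen@kObsError))
}

#' Predicted time course of a mixture of kinetic states
#'
#' Builds the weighted sum of exponential decays
#' `f(t) = sum_j w_j * A0_j * exp(-k_j * t)`. With the nucleosome and
#' tetrasome fits each weighted one-half this is the predicted hexasome
#' time course (one nucleosomal plus one tetrasomal H3 tail).
#'
#' @param fits list of [ExposureFit-class] objects (or lists with elements
#'   `kObs`, `a0`).
#' @param weights numeric weights summing to 1 (default equal).
#' @return A function of time `t` (minutes) returning the predicted
#'   fraction of full-length H3 remaining.
#' @export
predictMixture <- function(fits, weights = rep(1 / length(fits), length(fits))) {
  stopIfNot(length(fits) == length(weights), "one weight per component")
  stopIfNot(abs(sum(weights) - 1) < 1e-9, "mixture weights must sum to 1")
  ks <- vapply(fits, function(f)
    if (is(f, "ExposureFit")) kObs(f) else f$kObs, numeric(1))
  a0s <- vapply(fits, function(f)
    if (is(f, "ExposureFit")) intercept(f) else f$a0, numeric(1))
  function(t) vapply(t, function(tt) sum(weights * a0s * exp(-ks * tt)),
                     numeric(1))
}

#' Compare an observed time course to a predicted curve
#'
#' Welch two-sample t-test between the observed per-timepoint means and the
#' predicted values at the same timepoints. A high p-value indicates the
#' observed course is statistically indistinguishable from the prediction.
#'
#' @param tc single-species `TimeCourse`.
#' @param predicted function of time, e.g. from [predictMixture()].
#' @return data.frame with `statistic`, `df`, `p.value`.
#' @export
compareToPrediction <- function(tc, predicted) {
  stopIfNot(nrow(tc) >= 2L, "need at least 2 timepoints")
  obs <- tc$mean
  pred <- predicted(tc$time_min)
  if (isTRUE(all.equal(obs, pred, tolerance = 1e-12)))
    return(data.frame(statistic = 0, df = 2 * (length(obs) - 1),
                      p.value = 1))
  tt <- t.test(obs, pred)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p.value = tt$p.value)
}

#' Two-way ANOVA with Tukey post-hoc on digestion endpoints
#'
#' Fixed-effects two-factor ANOVA of the endpoint fraction of full-length
#' H3 on species and trypsin level (with interaction), followed by Tukey
#' HSD comparisons; the pairwise table is restricted to species contrasts
#' within the same trypsin level.
#'
#' @param endpoints data.frame with columns `species`, `trypsin`,
#'   `replicate`, `fraction`.
#' @param alpha significance cutoff (default 0.05).
#' @return List with `anova` (the ANOVA table), `tukey` (data.frame of
#'   within-trypsin species contrasts: `trypsin`, `pair`, `diff`, `p.adj`,
#'   `significant`).
#' @export
endpointAnova <- function(endpoints, alpha = 0.05) {
  need <- c("species", "trypsin", "replicate", "fraction")
  stopIfNot(all(need %in% names(endpoints)),
            paste("endpoints must have columns:", paste(need, collapse = ", ")))
  stopIfNot(length(unique(endpoints$species)) >= 2 &&
              length(unique(endpoints$trypsin)) >= 2,
            "need at least 2 levels per factor")
  cell <- table(endpoints$species, endpoints$trypsin)
  stopIfNot(all(cell >= 2), "need at least 2 replicates per cell")
  d <- data.frame(fraction = endpoints$fraction,
                  species = factor(endpoints$species),
                  trypsin = factor(endpoints$trypsin))
  fit <- aov(fraction ~ species * trypsin, data = d)
  tk <- TukeyHSD(fit, "species:trypsin")[["species:trypsin"]]
  lab <- strsplit(rownames(tk), "-")
  keep <- vapply(lab, function(p) {
    a <- strsplit(p[1], ":")[[1]]
    b <- strsplit(p[2], ":")[[1]]
    a[2] == b[2]
  }, logical(1))
  tks <- tk[keep, , drop = FALSE]
  lv <- vapply(strsplit(rownames(tks), "-"), function(p)
    strsplit(p[1], ":")[[1]][2], character(1))
  pair <- vapply(strsplit(rownames(tks), "-"), function(p)
    paste(strsplit(p[1], ":")[[1]][1], strsplit(p[2], ":")[[1]][1],
          sep = " vs "), character(1))
  list(anova = summary(fit)[[1]],
       tukey = data.frame(trypsin = lv, pair = pair,
                          diff = unname(tks[, "diff"]),
                          p.adj = unname(tks[, "p adj"]),
                          significant = unname(tks[, "p adj"]) < alpha))
}

#' Log-fraction proxy for the observed rate constant
#'
#' At a fixed digestion time `t`, `-log(fraction remaining) / t` is a rough
#' proxy for `k_obs` (exact only for a pure single exponential with
#' `A0 = 1`); used for checking the linearity of the observed rate in
#' enzyme concentration. Documented as approximate.
#'
#' @param fraction fraction of full-length H3 remaining at time `t`.
#' @param t digestion time (minutes).
#' @return Proxy rate, 1/min.
#' @export
kObsProxy <- function(fraction, t) {
  stopIfNot(all(fraction > 0), "fractions must be positive")
  stopIfNot(t > 0, "time must be positive")
  -log(fraction) / t
}
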