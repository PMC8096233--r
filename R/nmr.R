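#' Combined amide chemical-shift difference between two peak lists
#'
#' For every residue present in both lists computes
#' `dd = sqrt(ddH^2 + (0.154 * ddN)^2)` where `ddH` and `ddN` are the 1H and
#' 15N amide shift differences. The 0.154 nitrogen weight is fixed;
#' overriding it is possible but logged with a warning. Unmatched residues
#' are reported in the `"unmatched"` attribute, never silently dropped; the
#' summary mean excludes residues flagged as overlapped in either list.
#'
#' @param a,b peak-list data.frames with columns `residue`, `dH`, `dN` and
#'   optionally `subset` and `overlap`.
#' @param nWeight 15N scaling weight (default 0.154).
#' @return A `CSDProfile` data.frame with columns `residue`, `ddH`, `ddN`,
#'   `csd`, `overlap`; attributes `"unmatched"` (residues present in only
#'   one list) and `"meanCsd"` (mean over matched, non-overlapped residues).
#' @export
chemicalShiftDifference <- function(a, b, nWeight = 0.154) {
  if (!identical(nWeight, 0.154))
    warning("non-standard 15N weight ", nWeight,
            " (conventional amide weighting uses 0.154)", call. = FALSE)
  key <- function(x) {
    k <- as.character(x$residue)
    if ("subset" %in% names(x) && any(!is.na(x$subset)))
      k <- paste(k, x$subset, sep = "/")
    k
  }
  ka <- key(a); kb <- key(b)
  # subset labels only participate in matching when both lists carry them
  if (!any(grepl("/", ka)) || !any(grepl("/", kb))) {
    ka <- as.character(a$residue); kb <- as.character(b$residue)
  }
  common <- intersect(ka, kb)
  stopIfNot(length(common) > 0, "no residues matched between peak lists")
  ia <- match(common, ka); ib <- match(common, kb)
  ovl <- function(x, i) if ("overlap" %in% names(x)) x$overlap[i]
                        else rep(FALSE, length(i))
  ddH <- a$dH[ia] - b$dH[ib]
  ddN <- a$dN[ia] - b$dN[ib]
  out <- data.frame(residue = a$residue[ia], ddH = ddH, ddN = ddN,
                    csd = sqrt(ddH^2 + (nWeight * ddN)^2),
                    overlap = ovl(a, ia) | ovl(b, ib))
  out <- out[order(out$residue), ]
  rownames(out) <- NULL
  attr(out, "unmatched") <- c(setdiff(ka, kb), setdiff(kb, ka))
  attr(out, "meanCsd") <- mean(out$csd[!out$overlap])
  class(out) <- c("CSDProfile", "data.frame")
  out
}

#' Classify hexasome H3 tail peaks as nucleosome-like or tetrasome-like
#'
#' Each hexasome residue contributes up to two amide peaks. A peak is
#' labelled `hex-N` when its combined shift difference to the nucleosome
#' reference peak is smaller than to the tetrasome reference, else `hex-T`.
#' When a residue has two peaks the two possible assignments are scored by
#' total shift difference and the global minimum wins, so each label is
#' used at most once per residue. A peak whose two reference distances
#' differ by less than `ambiguityTol` is flagged ambiguous; exact ties go
#' to `hex-N`.
#'
#' @param hex hexasome peak list (up to two rows per residue).
#' @param nuc,tet single-peak-per-residue reference lists.
#' @param ambiguityTol ambiguity threshold on `|dd_N - dd_T|` in ppm
#'   (default 0.005).
#' @return The hexasome peak list with columns `subset` (assigned label),
#'   `ambiguous`, `csdN`, `csdT`; any pre-existing `subset` column is
#'   preserved as `truth`.
#' @export
classifyHexasomePeaks <- function(hex, nuc, tet, ambiguityTol = 0.005) {
  if ("subset" %in% names(hex)) {
    hex$truth <- hex$subset
    hex$subset <- NULL
  }
  csdTo <- function(peaks, ref) {
    i <- match(peaks$residue, ref$residue)
    sqrt((peaks$dH - ref$dH[i])^2 + (0.154 * (peaks$dN - ref$dN[i]))^2)
  }
  hex$csdN <- csdTo(hex, nuc)
  hex$csdT <- csdTo(hex, tet)
  hex$subset <- NA_character_
  hex$ambiguous <- FALSE
  for (res in unique(hex$residue)) {
    i <- which(hex$residue == res)
    if (length(i) > 2L)
      stop("residue ", res, " has more than two hexasome peaks",
           call. = FALSE)
    if (length(i) == 1L) {
      dN <- hex$csdN[i]; dT <- hex$csdT[i]
      hex$subset[i] <- if (dN <= dT) "hex-N" else "hex-T"
      hex$ambiguous[i] <- is.finite(dN) && is.finite(dT) &&
        abs(dN - dT) < ambiguityTol
    } else {
      # peak1 -> N, peak2 -> T versus the swap: global minimum total csd
      c1 <- hex$csdN[i[1]] + hex$csdT[i[2]]
      c2 <- hex$csdN[i[2]] + hex$csdT[i[1]]
      if (c1 <= c2) {
        hex$subset[i] <- c("hex-N", "hex-T")
      } else {
        hex$subset[i] <- c("hex-T", "hex-N")
      }
      hex$ambiguous[i] <- abs(hex$csdN[i] - hex$csdT[i]) < ambiguityTol
    }
  }
  hex
}

#' Hexasome peak intensity asymmetry (hex-T / hex-N fold ratio)
#'
#' Computes the per-residue ratio of hex-T to hex-N peak heights over a
#' residue window and summarises it as mean and SD. Residues flagged as
#' overlapped, or missing either peak, are excluded and reported.
#'
#' @param labeled classified hexasome peak list (see
#'   [classifyHexasomePeaks()] or simulator ground truth) with columns
#'   `residue`, `height`, `subset`, optionally `overlap`.
#' @param window residue numbers to include (default all).
#' @return data.frame of per-residue ratios; attributes `"mean"`, `"sd"`,
#'   `"skipped"` (residues without both peaks or excluded as overlapped).
#' @export
intensityAsymmetry <- function(labeled, window = NULL) {
  stopIfNot(all(c("residue", "height", "subset") %in% names(labeled)),
            "need residue, height and subset columns")
  if (is.null(window)) window <- sort(unique(labeled$residue))
  d <- labeled[labeled$residue %in% window, ]
  if ("overlap" %in% names(d)) {
    skippedOverlap <- unique(d$residue[d$overlap])
    d <- d[!d$residue %in% skippedOverlap, ]
  } else skippedOverlap <- integer()
  ratios <- list()
  skipped <- skippedOverlap
  for (res in sort(unique(d$residue))) {
    hT <- d$height[d$residue == res & d$subset == "hex-T"]
    hN <- d$height[d$residue == res & d$subset == "hex-N"]
    if (length(hT) == 1L && length(hN) == 1L && hN > 0) {
      ratios[[length(ratios) + 1L]] <-
        data.frame(residue = res, ratio = hT / hN)
    } else skipped <- c(skipped, res)
  }
  stopIfNot(length(ratios) > 0, "no residues with both hex-N and hex-T peaks")
  out <- do.call(rbind, ratios)
  attr(out, "mean") <- mean(out$ratio)
  attr(out, "sd") <- sd(out$ratio)
  attr(out, "skipped") <- skipped
  out
}

#' Fit single-exponential 15N relaxation decays per residue
#'
#' Fits peak heights to `H0 * exp(-delay / T)` without offset by least
#' squares; duplicate delays are independent observations. The relaxation
#' time error is taken from the fit covariance, and the rate `R = 1/T`
#' carries a first-order propagated error.
#'
#' @param series relaxation data.frame with columns `residue`, `delay_ms`,
#'   `height`.
#' @return data.frame per residue: `residue`, `T_ms`, `T_err`, `R_s`
#'   (1/s), `R_err`, `h0`, `converged`.
#' @export
fitRelaxationTime <- function(series) {
  stopIfNot(all(c("residue", "delay_ms", "height") %in% names(series)),
            "need residue, delay_ms, height columns")
  stopIfNot(all(series$delay_ms >= 0), "delays must be non-negative")
  out <- lapply(split(series, series$residue), function(d) {
    if (length(unique(d$delay_ms)) < 3L)
      stop("need at least 3 distinct delays per residue", call. = FALSE)
    h0Start <- max(d$height)
    pos <- d$height > 0
    tStart <- if (sum(pos) >= 2) {
      sl <- coef(stats::lm(log(d$height[pos]) ~ d$delay_ms[pos]))[2]
      if (is.finite(sl) && sl < 0) -1 / sl else max(d$delay_ms) / 2
    } else max(d$delay_ms) / 2
    tStart <- unname(tStart)
    fit <- tryCatch(
      minpack.lm::nlsLM(height ~ h0 * exp(-delay_ms / Tr), data = d,
                        start = list(h0 = h0Start, Tr = tStart),
                        lower = c(h0 = 0, Tr = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(residue = d$residue[1], T_ms = NA_real_,
                        T_err = NA_real_, R_s = NA_real_, R_err = NA_real_,
                        h0 = NA_real_, converged = FALSE))
    cf <- coef(fit)
    se <- sqrt(pmax(diag(vcov(fit)), 0))
    Tms <- unname(cf[["Tr"]])
    Terr <- unname(se[2])
    data.frame(residue = d$residue[1], T_ms = Tms, T_err = Terr,
               R_s = 1000 / Tms, R_err = 1000 * Terr / Tms^2,
               h0 = unname(cf[["h0"]]), converged = TRUE)
  })
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r[order(r$residue), ]
}

#' Steady-state heteronuclear NOE from saturated/reference peak heights
#'
#' `NOE = H_sat / H_ref` per residue, with the error from standard
#' propagation of the two per-spectrum noise estimates:
#' `|NOE| * sqrt((sigmaSat/H_sat)^2 + (sigmaRef/H_ref)^2)`.
#'
#' @param saturated,reference peak lists with columns `residue`, `height`.
#' @param sigmaSat,sigmaRef single per-spectrum noise estimates (same units
#'   as heights).
#' @return data.frame with `residue`, `noe`, `error`, `flagged` (TRUE when
#'   the reference height is zero and the NOE is undefined).
#' @export
hetNoe <- function(saturated, reference, sigmaSat = 0, sigmaRef = 0) {
  common <- intersect(saturated$residue, reference$residue)
  stopIfNot(length(common) > 0, "no residues matched")
  is <- match(common, saturated$residue)
  ir <- match(common, reference$residue)
  hs <- saturated$height[is]
  hr <- reference$height[ir]
  bad <- hr == 0
  noe <- ifelse(bad, NA_real_, hs / hr)
  err <- ifelse(bad, NA_real_,
                abs(noe) * sqrt((sigmaSat / hs)^2 + (sigmaRef / hr)^2))
  data.frame(residue = common, noe = noe, error = err, flagged = bad)
}

#' Per-residue T1/T2 ratio with propagated error
#'
#' Merges two relaxation fits by residue and reports the ratio of
#' relaxation times with first-order propagated error. Residues missing in
#' either fit are skipped and reported via the `"skipped"` attribute;
#' overlap flags, when present, are carried through.
#'
#' @param t1,t2 per-residue fits from [fitRelaxationTime()].
#' @return data.frame with `residue`, `ratio`, `error` (and `overlap` when
#'   supplied in either input).
#' @export
t1t2Ratio <- function(t1, t2) {
  common <- intersect(t1$residue, t2$residue)
  skipped <- c(setdiff(t1$residue, t2$residue),
               setdiff(t2$residue, t1$residue))
  stopIfNot(length(common) > 0, "no residues in common")
  i1 <- match(common, t1$residue)
  i2 <- match(common, t2$residue)
  out <- data.frame(
    residue = common,
    ratio = t1$T_ms[i1] / t2$T_ms[i2],
    error = ratioError(t1$T_ms[i1], t1$T_err[i1],
                       t2$T_ms[i2], t2$T_err[i2]))
  if ("overlap" %in% names(t1) || "overlap" %in% names(t2)) {
    o1 <- if ("overlap" %in% names(t1)) t1$overlap[i1] else FALSE
    o2 <- if ("overlap" %in% names(t2)) t2$overlap[i2] else FALSE
    out$overlap <- o1 | o2
  }
  attr(out, "skipped") <- skipped
  out
}
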