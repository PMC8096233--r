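#' @rdname TailTrajectory-class
#' @param x,object a `TailTrajectory`.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname TailTrajectory-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname TailTrajectory-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname TailTrajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname ExposureFit-class
#' @param x,object an `ExposureFit`.
#' @export
setGeneric("kObs", function(x) standardGeneric("kObs"))

#' @rdname ExposureFit-class
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname ContactMatrix-class
#' @param x,object a `ContactMatrix`.
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))

#' @rdname TailTrajectory-class
setMethod("nFrames", "TailTrajectory", function(x) dim(x@coords)[1])

#' @rdname TailTrajectory-class
setMethod("nAtoms", "TailTrajectory", function(x) dim(x@coords)[2])

#' @rdname TailTrajectory-class
setMethod("coords", "TailTrajectory", function(x) x@coords)

#' @rdname TailTrajectory-class
setMethod("topology", "TailTrajectory", function(x) x@topology)

#' @rdname TailTrajectory-class
setMethod("show", "TailTrajectory", function(object) {
  tp <- object@topology
  cat("TailTrajectory:", dim(object@coords)[1], "frames x",
      dim(object@coords)[2], "atoms\n")
  cat("  chains:", paste(unique(tp$chain), collapse = " "),
      "| tail atoms:", sum(tp$role == "tail"),
      "| DNA atoms:", sum(tp$role == "DNA"), "\n")
  cat("  frame spacing:", object@dtPs, "ps; equilibration trimmed:",
      object@trimmed, "\n")
  invisible(NULL)
})

#' @rdname ExposureFit-class
setMethod("kObs", "ExposureFit", function(x) x@kObs)

#' @rdname ExposureFit-class
setMethod("intercept", "ExposureFit", function(x) x@a0)

#' @rdname ExposureFit-class
setMethod("show", "ExposureFit", function(object) {
  cat(sprintf(
    "ExposureFit [%s]: k_obs = %.4g +/- %.2g 1/min; A0 = %.3g +/- %.2g%s\n",
    object@species, object@kObs, object@kObsError, object@a0,
    object@a0Error, if (object@atBoundary) " (at constraint boundary)" else ""))
  invisible(NULL)
})

#' @rdname ContactMatrix-class
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)

#' @rdname ContactMatrix-class
setMethod("totalContacts", "ContactMatrix",
          function(x) round(sum(x@counts)))

#' @rdname ContactMatrix-class
setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix: chain", object@chain, "|",
      nrow(object@counts), "tail residues x", ncol(object@counts),
      "bp | cutoff", object@cutoff, "A | frames", object@framesUsed, "\n")
  cat("  total contacts (frame-averaged, rounded):",
      totalContacts(object), "\n")
  invisible(NULL)
})
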