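#' Accessors for network, stack and trace objects
#'
#' @param object a \linkS4class{VascularNetwork}, \linkS4class{DepthStack} or
#'   \linkS4class{VelocityTrace}.
#' @return \code{vesselSegments}/\code{vesselJunctions}/\code{networkCrossings}
#'   return the underlying data.frames; \code{depthLabels} the slab depths
#'   (um); \code{traceSamples} the velocity samples (mm/s); \code{traceRate}
#'   the sampling rate (Hz).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vesselSegments", function(object) standardGeneric("vesselSegments"))
#' @rdname accessors
#' @export
setMethod("vesselSegments", "VascularNetwork", function(object) object@segments)

#' @rdname accessors
#' @export
setGeneric("vesselJunctions", function(object) standardGeneric("vesselJunctions"))
#' @rdname accessors
#' @export
setMethod("vesselJunctions", "VascularNetwork", function(object) object@junctions)

#' @rdname accessors
#' @export
setGeneric("networkCrossings", function(object) standardGeneric("networkCrossings"))
#' @rdname accessors
#' @export
setMethod("networkCrossings", "VascularNetwork", function(object) object@crossings)

#' @rdname accessors
#' @export
setGeneric("depthLabels", function(object) standardGeneric("depthLabels"))
#' @rdname accessors
#' @export
setMethod("depthLabels", "DepthStack", function(object) object@depthLabels)

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))
#' @rdname accessors
#' @export
setMethod("traceSamples", "VelocityTrace", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("traceRate", function(object) standardGeneric("traceRate"))
#' @rdname accessors
#' @export
setMethod("traceRate", "VelocityTrace", function(object) object@rate)

setMethod("show", "VascularNetwork", function(object) {
  cat("VascularNetwork:", nrow(object@segments), "segments,",
      nrow(object@junctions), "junctions (",
      sum(object@junctions$kind == "BIFURCATION"), "bifurcations /",
      sum(object@junctions$kind == "CONFLUENCE"), "confluences ),",
      nrow(object@crossings), "crossings\n")
  d <- object@segments$diameter_um
  if (any(!is.na(d)))
    cat("  lumen diameter:", sprintf("%.2f", mean(d, na.rm = TRUE)), "um mean,",
        sprintf("%.2f-%.2f", min(d, na.rm = TRUE), max(d, na.rm = TRUE)),
        "um range\n")
})

setMethod("show", "DepthStack", function(object) {
  d <- dim(object@slabs[[1]])
  cat("DepthStack:", length(object@slabs), "slabs of", d[1], "x", d[2],
      "px,", object@slabThickness, "um thick, depths",
      min(object@depthLabels), "-", max(object@depthLabels), "um from PR1\n")
})

setMethod("show", "VelocityTrace", function(object) {
  cat(sprintf("VelocityTrace: %d samples at %g Hz (%.2f s), %.2f-%.2f mm/s\n",
              length(object@samples), object@rate,
              length(object@samples) / object@rate,
              min(object@samples), max(object@samples)))
})

setMethod("show", "FlowSummary", function(object) {
  cat(sprintf("FlowSummary: Vave %.3f, Vmin %.3f, Vmax %.3f mm/s, pulsatility %.3f\n",
              object@vAve, object@vMin, object@vMax, object@pulsatility))
})

setMethod("show", "DiameterEstimate", function(object) {
  cat(sprintf("DiameterEstimate: %.2f um (blur sd %.2f um)", object@diameter,
              object@blurSd))
  if (!is.na(object@ciLower))
    cat(sprintf(", 95%% CI [%.2f, %.2f] um from %d bootstrap resamples",
                object@ciLower, object@ciUpper, object@nBoot))
  cat("\n")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: seed", object@seed, "-", object@nFeeders,
      "feeder(s) x", object@treeDepth, "generations; exponent",
      sprintf("%.2f +/- %.2f", object@exponentMean, object@exponentSd),
      "; capillary diameter",
      sprintf("%.2f +/- %.2f um", object@capillaryDiameter[1],
              object@capillaryDiameter[2]), "\n")
})
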