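#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Directed parafoveal vascular network
#'
#' Container for a traced microvascular network: one row per vessel segment,
#' one row per three-way junction (bifurcation or confluence), and an
#' optional table of crossings (segments that overlap in the en-face image
#' without connecting; stored but never traversed).
#'
#' The \code{segments} table requires columns \code{id}, \code{length_um} and
#' \code{diameter_um} (lumen diameter); optional columns \code{depth_um} and
#' \code{is_feeder} are carried through. The \code{junctions} table has
#' columns \code{junction_id}, \code{kind} (\code{"BIFURCATION"} or
#' \code{"CONFLUENCE"}), \code{major_id} (the single parent at a bifurcation,
#' the collector at a confluence) and \code{minor1_id}/\code{minor2_id}
#' (the two daughters, resp. the two draining vessels). Flow direction is
#' implied by the kind: a bifurcation sends blood major -> minors, a
#' confluence sends minors -> major.
#'
#' @slot segments data.frame of vessel segments.
#' @slot junctions data.frame of junctions.
#' @slot crossings data.frame with columns \code{seg_a}, \code{seg_b}.
#' @seealso [buildNetwork()], [vesselSegments()], [vesselJunctions()]
#' @export
setClass("VascularNetwork",
  representation(segments = "data.frame", junctions = "data.frame",
                 crossings = "data.frame"),
  prototype(crossings = data.frame(seg_a = character(), seg_b = character(),
                                   stringsAsFactors = FALSE)))

setValidity("VascularNetwork", function(object) {
  seg <- object@segments
  jn <- object@junctions
  msg <- character()
  need <- c("id", "length_um", "diameter_um")
  if (!all(need %in% names(seg)))
    msg <- c(msg, paste("segments table lacks column(s):",
                        paste(setdiff(need, names(seg)), collapse = ", ")))
  else {
    if (anyDuplicated(seg$id))
      msg <- c(msg, paste("duplicate segment id(s):",
                          paste(unique(seg$id[duplicated(seg$id)]), collapse = ", ")))
    if (any(!is.na(seg$length_um) & seg$length_um <= 0))
      msg <- c(msg, "segment lengths must be > 0")
    if (any(!is.na(seg$diameter_um) & seg$diameter_um <= 0))
      msg <- c(msg, "segment diameters must be > 0")
  }
  needj <- c("junction_id", "kind", "major_id", "minor1_id", "minor2_id")
  if (!all(needj %in% names(jn)))
    msg <- c(msg, paste("junctions table lacks column(s):",
                        paste(setdiff(needj, names(jn)), collapse = ", ")))
  else if (nrow(jn)) {
    if (!all(jn$kind %in% c("BIFURCATION", "CONFLUENCE")))
      msg <- c(msg, "junction kind must be BIFURCATION or CONFLUENCE")
    ref <- unique(c(jn$major_id, jn$minor1_id, jn$minor2_id))
    unknown <- setdiff(ref, seg$id)
    if (length(unknown))
      msg <- c(msg, paste("junction references unknown segment id(s):",
                          paste(unknown, collapse = ", ")))
    arity <- apply(jn[, c("major_id", "minor1_id", "minor2_id")], 1,
                   function(r) length(unique(r)))
    if (any(arity != 3))
      msg <- c(msg, paste("junction(s) without 3 distinct incident segments:",
                          paste(jn$junction_id[arity != 3], collapse = ", ")))
    if (anyDuplicated(jn$junction_id))
      msg <- c(msg, "duplicate junction id(s)")
  }
  if (length(msg)) msg else TRUE
})

#' OCTA depth-slab stack
#'
#' An ordered set of en-face OCT-angiography slab images, each labeled by its
#' axial distance (um) above the PR1 reference layer (the hyper-reflective
#' band at the photoreceptor inner/outer segment boundary). The default
#' acquisition spans 60 to 220 um in 20 um steps with 40-um-thick slabs.
#'
#' @slot slabs list of numeric matrices, all the same dimension.
#' @slot depthLabels numeric vector of slab depths (um from PR1), strictly
#'   increasing, one per slab.
#' @slot slabThickness numeric scalar, slab thickness in um.
#' @seealso [extractProfile()], [peakDepth()], [depthTable()]
#' @export
setClass("DepthStack",
  representation(slabs = "list", depthLabels = "numeric",
                 slabThickness = "numeric"),
  prototype(slabThickness = 40))

setValidity("DepthStack", function(object) {
  msg <- character()
  if (length(object@slabs) != length(object@depthLabels))
    msg <- c(msg, "number of slabs and depth labels differ")
  if (length(object@depthLabels) > 1 && any(diff(object@depthLabels) <= 0))
    msg <- c(msg, "depth labels must be strictly increasing")
  if (length(object@slabs)) {
    dims <- vapply(object@slabs, function(m) paste(dim(m), collapse = "x"),
                   character(1))
    if (length(unique(dims)) != 1)
      msg <- c(msg, "all slab images must have the same shape")
  }
  if (length(object@slabThickness) != 1 || object@slabThickness <= 0)
    msg <- c(msg, "slabThickness must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Single-vessel velocity trace
#'
#' Red-blood-cell velocity samples (mm/s) for one capillary, acquired at 200
#' or 300 Hz for at most 3.4 s.
#'
#' @slot samples numeric vector of velocities (mm/s).
#' @slot rate sampling rate in Hz (200 or 300).
#' @seealso [summarizeTrace()]
#' @export
setClass("VelocityTrace",
  representation(samples = "numeric", rate = "numeric"))

setValidity("VelocityTrace", function(object) {
  msg <- character()
  if (length(object@rate) != 1 || !object@rate %in% c(200, 300))
    msg <- c(msg, "rate must be 200 or 300 Hz")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@rate) == 1 && object@rate > 0 &&
      length(object@samples) / object@rate > 3.4 + 1e-9)
    msg <- c(msg, "trace duration exceeds 3.4 s")
  if (length(msg)) msg else TRUE
})

#' Straightened "division" vessel image
#'
#' A motion-contrast image of a single vessel after straightening: rows are
#' successive cross-sections along the vessel, columns run across it, and the
#' vessel axis lies at a (possibly fractional) column index.
#'
#' @slot image numeric matrix (rows = positions along the vessel).
#' @slot pxSize pixel size in um.
#' @slot centerlineCol column index of the vessel axis (may be half-integer).
#' @seealso [thresholdLumen()], [estimateDiameter()], [bootstrapDiameter()]
#' @export
setClass("StraightenedVessel",
  representation(image = "matrix", pxSize = "numeric",
                 centerlineCol = "numeric"))

setValidity("StraightenedVessel", function(object) {
  msg <- character()
  if (length(object@pxSize) != 1 || object@pxSize <= 0)
    msg <- c(msg, "pxSize must be a positive scalar")
  if (length(object@centerlineCol) != 1 ||
      object@centerlineCol < 1 || object@centerlineCol > ncol(object@image))
    msg <- c(msg, "centerlineCol must lie within the image width")
  if (length(msg)) msg else TRUE
})

#' Lumen diameter estimate with bootstrap confidence limits
#'
#' @slot diameter point estimate of lumen diameter (um).
#' @slot blurSd fitted Gaussian edge-blur standard deviation (um; nuisance).
#' @slot ciLower,ciUpper 95\% percentile bootstrap confidence limits (um);
#'   \code{NA} when no bootstrap was run.
#' @slot nBoot number of bootstrap resamples (0 when none).
#' @slot seed RNG seed used for the bootstrap.
#' @export
setClass("DiameterEstimate",
  representation(diameter = "numeric", blurSd = "numeric",
                 ciLower = "numeric", ciUpper = "numeric",
                 nBoot = "integer", seed = "integer"),
  prototype(ciLower = NA_real_, ciUpper = NA_real_, nBoot = 0L, seed = NA_integer_))

setValidity("DiameterEstimate", function(object) {
  msg <- character()
  if (!is.na(object@ciLower) && !is.na(object@ciUpper)) {
    if (object@ciLower > object@diameter || object@diameter > object@ciUpper)
      msg <- c(msg, "point estimate must lie within its confidence interval")
  }
  if (object@diameter <= 0) msg <- c(msg, "diameter must be > 0")
  if (length(msg)) msg else TRUE
})

#' Raw flow-parameter summary of a velocity trace
#'
#' @slot vMax,vMin,vAve extreme and mean velocities (mm/s).
#' @slot pulsatility (vMax - vMin) / (vMax + vMin), unitless.
#' @export
setClass("FlowSummary",
  representation(vMax = "numeric", vMin = "numeric", vAve = "numeric",
                 pulsatility = "numeric"))

setValidity("FlowSummary", function(object) {
  if (object@vMin > object@vAve + 1e-9 || object@vAve > object@vMax + 1e-9)
    "requires vMin <= vAve <= vMax" else TRUE
})

#' Configuration for the synthetic-data generators
#'
#' Holds every tunable of the synthetic study conditions: network topology,
#' junction-exponent distribution, capillary calibre, depth mixture,
#' velocity-waveform parameters and noise levels. Construct with
#' [syntheticConfig()], which documents the defaults.
#'
#' @slot seed integer RNG seed.
#' @slot nFeeders number of feeding arterioles (independent trees).
#' @slot treeDepth bifurcation generations per tree (>= 1).
#' @slot exponentMean,exponentSd junction-exponent distribution (truncated
#'   normal on [0.5, 6]; \code{exponentSd = 0} fixes the exponent).
#' @slot capillaryDiameter length-2 (mean, sd) of terminal capillary lumen
#'   diameter, um.
#' @slot feederDiameterMin feeding arterioles are wider than this (um).
#' @slot depthMeans,depthSds,depthWeights two-component Gaussian mixture of
#'   vessel depth (um from PR1).
#' @slot samplingRate velocity sampling rate, Hz (200 or 300).
#' @slot duration trace duration, s.
#' @slot cardiacFreq cardiac frequency, Hz.
#' @slot pulsatilityAtFeeder pulsatility at zero feeder distance (P0).
#' @slot pulsatilityDecay linear decay of pulsatility per um (or 1/tau for
#'   the exponential model).
#' @slot pulsatilityModel \code{"linear"} or \code{"exponential"}.
#' @slot vminIntercept,vminSlope diastolic velocity at the feeder (mm/s) and
#'   its rise per um of feeder distance.
#' @slot traceNoiseSd additive velocity noise, mm/s.
#' @slot stackAmplitude,stackNoiseSd peak vessel intensity and additive noise
#'   of synthetic OCTA slabs (arbitrary units).
#' @slot depthSigma axial spread (um) of a vessel's intensity across slabs.
#' @slot unorthodoxFraction fraction of terminal sibling pairs rewired into a
#'   confluence-then-bifurcation ("unorthodox") motif.
#' @export
setClass("SyntheticConfig",
  representation(seed = "integer", nFeeders = "integer", treeDepth = "integer",
                 exponentMean = "numeric", exponentSd = "numeric",
                 capillaryDiameter = "numeric", feederDiameterMin = "numeric",
                 depthMeans = "numeric", depthSds = "numeric",
                 depthWeights = "numeric",
                 samplingRate = "numeric", duration = "numeric",
                 cardiacFreq = "numeric",
                 pulsatilityAtFeeder = "numeric", pulsatilityDecay = "numeric",
                 pulsatilityModel = "character",
                 vminIntercept = "numeric", vminSlope = "numeric",
                 traceNoiseSd = "numeric",
                 stackAmplitude = "numeric", stackNoiseSd = "numeric",
                 depthSigma = "numeric",
                 unorthodoxFraction = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nFeeders < 1L) msg <- c(msg, "nFeeders must be >= 1")
  if (object@treeDepth < 1L) msg <- c(msg, "treeDepth must be >= 1")
  sds <- c(object@exponentSd, object@capillaryDiameter[2], object@depthSds,
           object@traceNoiseSd, object@stackNoiseSd)
  if (any(sds < 0)) msg <- c(msg, "standard deviations must be >= 0")
  if (abs(sum(object@depthWeights) - 1) > 1e-9)
    msg <- c(msg, "depth mixture weights must sum to 1")
  if (!object@samplingRate %in% c(200, 300))
    msg <- c(msg, "samplingRate must be 200 or 300 Hz")
  n <- object@samplingRate * object@duration
  if (abs(n - round(n)) > 1e-9)
    msg <- c(msg, "duration x samplingRate must be an integer sample count")
  if (object@unorthodoxFraction < 0 || object@unorthodoxFraction > 1)
    msg <- c(msg, "unorthodoxFraction must be in [0, 1]")
  if (!object@pulsatilityModel %in% c("linear", "exponential"))
    msg <- c(msg, "pulsatilityModel must be 'linear' or 'exponential'")
  if (length(msg)) msg else TRUE
})
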