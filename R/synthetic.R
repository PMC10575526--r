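#' Configure the synthetic study conditions
#'
#' Defaults reproduce the statistical structure the analysis assumes in real
#' parafoveal data: terminal capillary lumen diameters of 4.33 +/- 0.9 um,
#' feeding arterioles wider than 8 um, junction exponents around 2.2
#' (truncated to [0.5, 6]), a bimodal depth mixture with peaks at 150 and
#' 200 um from PR1 (weights 35/52 and 17/52), 3-second velocity traces at
#' 200 Hz with a ~1 Hz cardiac waveform, pulsatility decaying and diastolic
#' velocity rising with feeder distance.
#'
#' @param seed integer RNG seed.
#' @param nFeeders,treeDepth topology: number of feeding arterioles and
#'   bifurcation generations per tree.
#' @param exponentMean,exponentSd junction-exponent distribution; set
#'   \code{exponentSd = 0} for a fixed exponent.
#' @param capillaryDiameter (mean, sd) terminal capillary diameter, um.
#' @param feederDiameterMin minimum feeder diameter, um.
#' @param depthMeans,depthSds,depthWeights depth mixture (um from PR1).
#' @param samplingRate,duration,cardiacFreq velocity trace sampling (Hz),
#'   length (s) and cardiac frequency (Hz).
#' @param pulsatilityAtFeeder,pulsatilityDecay,pulsatilityModel pulsatility
#'   P0 at the feeder and its decay with distance (\code{"linear"}: P0 -
#'   decay * d, clamped to [0, 0.95]; \code{"exponential"}: P0 *
#'   exp(-decay * d)).
#' @param vminIntercept,vminSlope diastolic velocity at the feeder (mm/s)
#'   and rise per um.
#' @param traceNoiseSd additive velocity noise, mm/s.
#' @param stackAmplitude,stackNoiseSd,depthSigma synthetic OCTA slab model:
#'   peak ROI intensity, background noise sd, axial Gaussian spread (um,
#'   about half the 40 um slab thickness).
#' @param unorthodoxFraction fraction of terminal sibling pairs rewired into
#'   the confluence-then-bifurcation motif.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(seed = 1L, nFeeders = 1L, treeDepth = 4L,
                            exponentMean = 2.2, exponentSd = 0.8,
                            capillaryDiameter = c(4.33, 0.9),
                            feederDiameterMin = 8,
                            depthMeans = c(150, 200), depthSds = c(12, 10),
                            depthWeights = c(35, 17) / 52,
                            samplingRate = 200, duration = 3,
                            cardiacFreq = 1,
                            pulsatilityAtFeeder = 0.6,
                            pulsatilityDecay = 5e-4,
                            pulsatilityModel = "linear",
                            vminIntercept = 0.5, vminSlope = 8e-4,
                            traceNoiseSd = 0.05,
                            stackAmplitude = 1, stackNoiseSd = 0.2,
                            depthSigma = 20,
                            unorthodoxFraction = 0) {
  new("SyntheticConfig", seed = as.integer(seed),
      nFeeders = as.integer(nFeeders), treeDepth = as.integer(treeDepth),
      exponentMean = exponentMean, exponentSd = exponentSd,
      capillaryDiameter = capillaryDiameter,
      feederDiameterMin = feederDiameterMin,
      depthMeans = depthMeans, depthSds = depthSds,
      depthWeights = depthWeights,
      samplingRate = samplingRate, duration = duration,
      cardiacFreq = cardiacFreq,
      pulsatilityAtFeeder = pulsatilityAtFeeder,
      pulsatilityDecay = pulsatilityDecay,
      pulsatilityModel = pulsatilityModel,
      vminIntercept = vminIntercept, vminSlope = vminSlope,
      traceNoiseSd = traceNoiseSd,
      stackAmplitude = stackAmplitude, stackNoiseSd = stackNoiseSd,
      depthSigma = depthSigma,
      unorthodoxFraction = unorthodoxFraction)
}

## truncated-normal draw by rejection (bounds always within a few sd here)
.rtrunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] < lower | out[todo] > upper]
  }
  out
}

.drawExponent <- function(n, config)
  .rtrunc(n, config@exponentMean, config@exponentSd, 0.5, 6)

.drawDepth <- function(n, config, lower = 70, upper = 215) {
  comp <- sample.int(length(config@depthMeans), n, replace = TRUE,
                     prob = config@depthWeights)
  .rtruncVec(config@depthMeans[comp], config@depthSds[comp], lower, upper)
}

.rtruncVec <- function(mean, sd, lower, upper) {
  n <- length(mean)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean[todo], sd[todo])
    todo <- todo[out[todo] < lower | out[todo] > upper]
  }
  out
}

#' Generate a synthetic vascular network with ground truth
#'
#' Builds, per feeding arteriole, a binary bifurcation tree of
#' \code{treeDepth} generations ending in terminal capillaries, which drain
#' pairwise through confluences into a single collecting venule (the mirror
#' tree). Every junction's major-vessel radius satisfies the generalized
#' Murray relation exactly at that junction's drawn exponent, so exponent
#' fits on noiseless output recover truth. Optionally a fraction of terminal
#' sibling pairs is rewired into a confluence-then-bifurcation motif,
#' planting "unorthodox" (WC) capillaries. All radii are rescaled so the
#' mean terminal capillary diameter matches the configured calibre while the
#' feeder stays wider than \code{feederDiameterMin} (the junction relation
#' is scale invariant, so rescaling preserves it).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{network} (a \linkS4class{VascularNetwork} whose
#'   segments carry \code{depth_um} and \code{is_feeder}) and \code{truth}
#'   (list of data.frames: \code{segments} with true depth, diameter, branch
#'   order and feeder distance; \code{junctions} with the true exponent).
#' @export
generateNetwork <- function(config) {
  methods::validObject(config)
  withSeed(config@seed, .generateNetworkImpl(config))
}

.generateNetworkImpl <- function(config) {
  segs <- list()   # id -> list(radius, length, parents, order, dist, role)
  jns <- list()    # rows junction_id, kind, major, minor1, minor2, exponent
  addSeg <- function(id, radius, length, role)
    segs[[id]] <<- list(radius = radius, length = length, role = role,
                        order = NA_integer_, dist = NA_real_)
  addJn <- function(id, kind, major, minor1, minor2, x)
    jns[[length(jns) + 1L]] <<- data.frame(
      junction_id = id, kind = kind, major_id = major, minor1_id = minor1,
      minor2_id = minor2, exponent = x, stringsAsFactors = FALSE)
  segLen <- function(n = 1) stats::rlnorm(n, log(60), 0.25)

  for (f in seq_len(config@nFeeders)) {
    sid <- function(k) sprintf("F%02d_S%03d", f, k)
    jid <- function(k) sprintf("F%02d_J%03d", f, k)
    sc <- 0L; jc <- 0L
    nextSid <- function() { sc <<- sc + 1L; sid(sc) }
    nextJid <- function() { jc <<- jc + 1L; jid(jc) }

    feeder <- nextSid()
    addSeg(feeder, radius = 1, length = stats::rlnorm(1, log(90), 0.2),
           role = "feeder")
    segs[[feeder]]$order <- 1L
    segs[[feeder]]$dist <- segs[[feeder]]$length / 2

    bifurcate <- function(parent) {
      x <- .drawExponent(1, config)
      u <- stats::runif(1, 0.35, 0.65)
      rp <- segs[[parent]]$radius
      kids <- c(nextSid(), nextSid())
      r <- rp * c(u, 1 - u)^(1 / x)
      for (i in 1:2) {
        addSeg(kids[i], r[i], segLen(), "capillary")
        segs[[kids[i]]]$order <<- segs[[parent]]$order + 1L
        segs[[kids[i]]]$dist <<- segs[[parent]]$dist +
          segs[[parent]]$length / 2 + segs[[kids[i]]]$length / 2
      }
      addJn(nextJid(), "BIFURCATION", parent, kids[1], kids[2], x)
      kids
    }
    conflue <- function(p1, p2, role = "collector") {
      x <- .drawExponent(1, config)
      rc <- (segs[[p1]]$radius^x + segs[[p2]]$radius^x)^(1 / x)
      cid <- nextSid()
      addSeg(cid, rc, segLen(), role)
      up <- c(segs[[p1]]$dist + segs[[p1]]$length / 2,
              segs[[p2]]$dist + segs[[p2]]$length / 2)
      pick <- if (up[1] <= up[2]) p1 else p2
      segs[[cid]]$order <<- segs[[pick]]$order
      segs[[cid]]$dist <<- min(up) + segs[[cid]]$length / 2
      addJn(nextJid(), "CONFLUENCE", cid, p1, p2, x)
      cid
    }

    level <- feeder
    for (g in seq_len(config@treeDepth))
      level <- unlist(lapply(level, bifurcate))
    terminals <- level

    ## unorthodox rewiring: chosen sibling pairs conflue into a WC segment
    ## that bifurcates again before draining
    nPairs <- length(terminals) / 2
    nW <- round(config@unorthodoxFraction * nPairs)
    if (nW > 0) {
      chosen <- sort(sample.int(nPairs, nW))
      for (p in chosen) {
        i <- 2 * p - 1
        w <- conflue(terminals[i], terminals[i + 1], role = "unorthodox")
        terminals[c(i, i + 1)] <- bifurcate(w)
      }
    }

    drain <- terminals
    while (length(drain) > 1) {
      stopifnot(length(drain) %% 2 == 0)
      drain <- vapply(seq_len(length(drain) / 2), function(p)
        conflue(drain[2 * p - 1], drain[2 * p]), character(1))
    }
    segs[[drain]]$role <- "venule"

    ## rescale this tree's radii: terminal capillaries at the target
    ## calibre, feeder still wider than the threshold
    ids <- grep(sprintf("^F%02d_", f), names(segs), value = TRUE)
    term <- terminals
    meanTerm <- mean(vapply(term, function(i) segs[[i]]$radius, numeric(1)))
    sc1 <- (config@capillaryDiameter[1] / 2) / meanTerm
    if (sc1 * 2 * segs[[feeder]]$radius <= config@feederDiameterMin)
      sc1 <- (config@feederDiameterMin * 1.2 / 2) / segs[[feeder]]$radius
    for (i in ids) segs[[i]]$radius <- segs[[i]]$radius * sc1
  }

  ids <- names(segs)
  depth <- .drawDepth(length(ids), config)
  segdf <- data.frame(
    id = ids,
    length_um = vapply(segs, `[[`, numeric(1), "length"),
    diameter_um = 2 * vapply(segs, `[[`, numeric(1), "radius"),
    depth_um = depth,
    is_feeder = vapply(segs, function(s) s$role == "feeder", logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  jndf <- do.call(rbind, jns)
  net <- buildNetwork(segdf, jndf[, c("junction_id", "kind", "major_id",
                                      "minor1_id", "minor2_id")])
  truth <- list(
    segments = data.frame(
      id = ids, depth_um = depth, diameter_um = segdf$diameter_um,
      branch_order = vapply(segs, `[[`, integer(1), "order"),
      feeder_distance_um = vapply(segs, `[[`, numeric(1), "dist"),
      role = vapply(segs, `[[`, character(1), "role"),
      stringsAsFactors = FALSE, row.names = NULL),
    junctions = jndf[, c("junction_id", "exponent")])
  list(network = net, truth = truth)
}

#' Generate pulsatile velocity traces for a network
#'
#' Each segment receives a raised-cosine cardiac waveform
#' v(t) = Vave (1 + P cos(2 pi f t + phi)) plus Gaussian noise, where the
#' pulsatility P decays with the segment's feeder distance and the diastolic
#' velocity Vmin rises with it (Vave = Vmin / (1 - P)). Samples are clamped
#' to stay positive.
#'
#' @param net a \linkS4class{VascularNetwork} (used for segment identity).
#' @param truth ground truth from [generateNetwork()]; the feeder distance
#'   of every segment must be present.
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{traces} (named list of
#'   \linkS4class{VelocityTrace}) and \code{params} (data.frame of the true
#'   per-segment waveform parameters).
#' @export
generateVelocityTraces <- function(net, truth, config) {
  tseg <- truth$segments
  if (any(is.na(tseg$feeder_distance_um)))
    stop("missing feeder distance for segment(s): ",
         paste(tseg$id[is.na(tseg$feeder_distance_um)], collapse = ", "))
  withSeed(config@seed + 1L, {
    n <- round(config@samplingRate * config@duration)
    t <- (seq_len(n) - 1) / config@samplingRate
    d <- tseg$feeder_distance_um
    P <- switch(config@pulsatilityModel,
      linear = pmax(0, pmin(0.95, config@pulsatilityAtFeeder -
                              config@pulsatilityDecay * d)),
      exponential = pmin(0.95, config@pulsatilityAtFeeder *
                           exp(-config@pulsatilityDecay * d)))
    vmin <- config@vminIntercept + config@vminSlope * d
    vave <- vmin / (1 - P)
    phase <- stats::runif(nrow(tseg), 0, 2 * pi)
    traces <- lapply(seq_len(nrow(tseg)), function(i) {
      v <- vave[i] * (1 + P[i] * cos(2 * pi * config@cardiacFreq * t +
                                       phase[i]))
      if (config@traceNoiseSd > 0)
        v <- v + stats::rnorm(n, 0, config@traceNoiseSd)
      VelocityTrace(pmax(v, 1e-3), config@samplingRate)
    })
    names(traces) <- tseg$id
    list(traces = traces,
         params = data.frame(id = tseg$id, pulsatility = P, v_ave = vave,
                             v_min = vmin, phase = phase,
                             stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic OCTA slab stack with ROI masks
#'
#' Lays the network's vessels out on a grid of small rectangular ROIs and
#' renders one en-face image per slab depth. A vessel's ROI intensity
#' follows a Gaussian in depth centered at its true depth (axial spread
#' \code{depthSigma}, about half the 40-um slab thickness), over additive
#' background noise, reproducing the bell-shaped intensity-vs-depth curves
#' seen in real slab stacks.
#'
#' @param net a \linkS4class{VascularNetwork}.
#' @param truth ground truth from [generateNetwork()].
#' @param config a \linkS4class{SyntheticConfig}.
#' @param depthLabels slab depths to render (um from PR1).
#' @return list with \code{stack} (a \linkS4class{DepthStack}) and
#'   \code{masks} (named list of logical ROI matrices).
#' @export
generateDepthStack <- function(net, truth, config,
                               depthLabels = seq(60, 220, by = 20)) {
  tseg <- truth$segments
  bad <- tseg$depth_um < min(depthLabels) | tseg$depth_um > max(depthLabels)
  if (any(bad))
    stop("true depth outside the scanned range for segment(s): ",
         paste(tseg$id[bad], collapse = ", "))
  withSeed(config@seed + 2L, {
    nv <- nrow(tseg)
    k <- ceiling(sqrt(nv))
    cell <- 8L
    dimpx <- k * cell
    masks <- vector("list", nv)
    for (i in seq_len(nv)) {
      r0 <- ((i - 1) %/% k) * cell
      c0 <- ((i - 1) %% k) * cell
      m <- matrix(FALSE, dimpx, dimpx)
      m[r0 + 2:7, c0 + 3:6] <- TRUE
      masks[[i]] <- m
    }
    names(masks) <- tseg$id
    slabs <- lapply(depthLabels, function(lab) {
      img <- matrix(stats::rnorm(dimpx^2, 0, config@stackNoiseSd),
                    dimpx, dimpx)
      for (i in seq_len(nv)) {
        amp <- config@stackAmplitude *
          exp(-(lab - tseg$depth_um[i])^2 / (2 * config@depthSigma^2))
        img[masks[[i]]] <- img[masks[[i]]] + amp
      }
      img
    })
    list(stack = DepthStack(slabs, depthLabels), masks = masks)
  })
}

#' Generate a straightened "division" vessel image
#'
#' Rows are identical cross-sections of a bright band of width
#' \code{trueDiameter} centered between the two middle columns (the
#' centerline sits at a half-integer column, so an integer-pixel band covers
#' whole pixels). The band edge is the uniform-chord profile convolved with
#' a Gaussian blur of sd \code{blurSd}; with zero blur, partial pixel
#' coverage is rendered as proportional gray. Gaussian noise is added on
#' top.
#'
#' @param trueDiameter lumen diameter, um (> one pixel).
#' @param lengthPx number of rows (cross-sections).
#' @param pxSize pixel size, um.
#' @param blurSd Gaussian edge blur, um (0 for a sharp band).
#' @param noiseSd additive intensity noise sd.
#' @param seed integer RNG seed for the noise.
#' @return a \linkS4class{StraightenedVessel}.
#' @export
generateDivisionImage <- function(trueDiameter, lengthPx = 200, pxSize = 1,
                                  blurSd = 0, noiseSd = 0, seed = 1L) {
  if (trueDiameter <= 0 || pxSize <= 0)
    stop("trueDiameter and pxSize must be positive")
  if (trueDiameter < pxSize)
    stop("diameter smaller than one pixel cannot be rendered")
  halfw <- ceiling(trueDiameter / pxSize / 2) + 8L
  W <- 2L * halfw
  ccol <- W / 2 + 0.5
  d <- (seq_len(W) - ccol) * pxSize
  h <- trueDiameter / 2
  prof <- if (blurSd <= 0) {
    pmax(0, pmin(d + pxSize / 2, h) - pmax(d - pxSize / 2, -h)) / pxSize
  } else {
    stats::pnorm((d + h) / blurSd) - stats::pnorm((d - h) / blurSd)
  }
  img <- matrix(prof, nrow = lengthPx, ncol = W, byrow = TRUE)
  if (noiseSd > 0)
    img <- img + withSeed(as.integer(seed),
                          matrix(stats::rnorm(length(img), 0, noiseSd),
                                 nrow = lengthPx))
  StraightenedVessel(img, pxSize = pxSize, centerlineCol = ccol)
}
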