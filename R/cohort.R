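#' Generate a statistics-scale synthetic cohort
#'
#' Generates \code{n} vessels of interest with network covariates (feeder
#' distance, depth, branch order, and upstream/downstream junction-exponent
#' truth with exactly consistent junction radii) and per-vessel velocity
#' traces whose summarized flow parameters embed chosen population
#' correlations: \code{targetRJeVave} between the downstream junction
#' exponent and the average velocity, and \code{targetRDistVmin} between
#' feeder distance and the diastolic velocity. Depth and branch order are
#' drawn independently of flow (null effects). Covariates are sampled
#' independently at realistic marginals (distances ~178-900 um, depths from
#' the bimodal mixture, branch orders 1-9 with median ~6, exponents
#' truncated normal around 2.2); the geometric tree generator
#' ([generateNetwork()]) is the place where topology-linked structure lives.
#'
#' @param config a \linkS4class{SyntheticConfig} (seed, cardiac and trace
#'   settings, exponent and depth distributions are used).
#' @param n cohort size.
#' @param targetRJeVave population correlation of the downstream exponent
#'   with average velocity.
#' @param targetRDistVmin population correlation of feeder distance with
#'   minimum velocity.
#' @return list with \code{truth} (per-vessel data.frame including junction
#'   radii and true flow parameters) and \code{traces} (named list of
#'   \linkS4class{VelocityTrace}).
#' @seealso [cohortRecords()] to run the analysis pipeline on the cohort.
#' @export
generateCohort <- function(config, n = 500, targetRJeVave = -0.6,
                           targetRDistVmin = 0.45) {
  stopifnot(abs(targetRJeVave) <= 1, abs(targetRDistVmin) <= 1)
  withSeed(config@seed + 3L, {
    dist <- pmin(pmax(stats::rlnorm(n, log(430), 0.35), 150), 900)
    depth <- .drawDepth(n, config, lower = 125, upper = 220)
    border <- sample(1:9, n, replace = TRUE, prob = stats::dbinom(0:8, 8, 0.62))
    jeUp <- .drawExponent(n, config)
    jeDown <- .drawExponent(n, config)
    diam <- .rtrunc(n, config@capillaryDiameter[1], config@capillaryDiameter[2],
                    2.5, 7)
    rVoi <- diam / 2
    rSibUp <- rVoi * stats::runif(n, 0.7, 1)
    rSibDown <- rVoi * stats::runif(n, 0.7, 1)
    rParentUp <- predictParentRadius(rVoi, rSibUp, jeUp)
    rParentDown <- predictParentRadius(rVoi, rSibDown, jeDown)

    z1 <- as.numeric(scale(jeDown))
    z2 <- as.numeric(scale(dist))
    vave <- pmax(2.0 + 0.45 * (targetRJeVave * z1 +
                                 sqrt(1 - targetRJeVave^2) * stats::rnorm(n)),
                 0.6)
    vmin <- 1.0 + 0.22 * (targetRDistVmin * z2 +
                            sqrt(1 - targetRDistVmin^2) * stats::rnorm(n))
    vmin <- pmin(pmax(vmin, 0.05), 0.92 * vave)
    P <- (vave - vmin) / vave

    m <- round(config@samplingRate * config@duration)
    t <- (seq_len(m) - 1) / config@samplingRate
    phase <- stats::runif(n, 0, 2 * pi)
    ids <- sprintf("V%04d", seq_len(n))
    traces <- lapply(seq_len(n), function(i) {
      v <- vave[i] * (1 + P[i] * cos(2 * pi * config@cardiacFreq * t + phase[i]))
      if (config@traceNoiseSd > 0)
        v <- v + stats::rnorm(m, 0, config@traceNoiseSd)
      VelocityTrace(pmax(v, 1e-3), config@samplingRate)
    })
    names(traces) <- ids
    truth <- data.frame(
      vessel_id = ids, feeder_distance_um = dist, depth_um = depth,
      branch_order = border, je_upstream = jeUp, je_downstream = jeDown,
      diameter_um = diam,
      r_parent_up = rParentUp, r_sib_up = rSibUp,
      r_parent_down = rParentDown, r_sib_down = rSibDown,
      v_ave = vave, v_min = vmin, pulsatility = P,
      stringsAsFactors = FALSE)
    list(truth = truth, traces = traces)
  })
}

#' Analyze a synthetic cohort with the package pipeline
#'
#' Recomputes every analyzed quantity from the cohort's raw materials using
#' the package's own operations: junction exponents are re-fit from the
#' junction radii by the brute-force grid search, and flow parameters are
#' summarized from the velocity traces. The result feeds directly into
#' [networkFlowTable()] and [outlierRerun()].
#'
#' @param cohort output of [generateCohort()].
#' @param grid exponent search grid.
#' @return per-vessel records data.frame with columns \code{vessel_id},
#'   \code{feeder_distance_um}, \code{depth_um}, \code{branch_order},
#'   \code{je_upstream}, \code{je_downstream}, \code{v_ave}, \code{v_min},
#'   \code{v_max}, \code{pulsatility}.
#' @export
cohortRecords <- function(cohort, grid = exponentGrid()) {
  tr <- cohort$truth
  n <- nrow(tr)
  fitOne <- function(rp, r1, r2) {
    f <- fitJunctionExponent(rp, r1, r2, grid = grid)
    if (f$status == "FIT") f$exponent else NA_real_
  }
  jeUp <- vapply(seq_len(n), function(i)
    fitOne(tr$r_parent_up[i], tr$diameter_um[i] / 2, tr$r_sib_up[i]),
    numeric(1))
  jeDown <- vapply(seq_len(n), function(i)
    fitOne(tr$r_parent_down[i], tr$diameter_um[i] / 2, tr$r_sib_down[i]),
    numeric(1))
  flows <- lapply(cohort$traces, summarizeTrace)
  data.frame(
    vessel_id = tr$vessel_id,
    feeder_distance_um = tr$feeder_distance_um,
    depth_um = tr$depth_um,
    branch_order = tr$branch_order,
    je_upstream = jeUp, je_downstream = jeDown,
    v_ave = vapply(flows, function(f) f@vAve, numeric(1)),
    v_min = vapply(flows, function(f) f@vMin, numeric(1)),
    v_max = vapply(flows, function(f) f@vMax, numeric(1)),
    pulsatility = vapply(flows, function(f) f@pulsatility, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
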