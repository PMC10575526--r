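#' Construct a velocity trace
#'
#' @param samples velocity samples, mm/s.
#' @param rate sampling rate in Hz (200 or 300).
#' @return a \linkS4class{VelocityTrace}.
#' @export
VelocityTrace <- function(samples, rate = 200) {
  new("VelocityTrace", samples = as.numeric(samples), rate = as.numeric(rate))
}

#' Raw flow parameters of a velocity trace
#'
#' Computes the raw flow measures of a capillary velocity trace: the maximum
#' and minimum velocity (extrema of the trace, optionally after moving-median
#' smoothing), the average velocity (arithmetic mean of the same trace) and
#' the pulsatility (Vmax - Vmin) / (Vmax + Vmin), a unitless index of the
#' cardiac modulation of flow.
#'
#' @param trace a \linkS4class{VelocityTrace}.
#' @param smoothWindow odd window length for [stats::runmed()] smoothing of
#'   the extrema; \code{NULL} (default) uses the raw trace.
#' @return a \linkS4class{FlowSummary}.
#' @examples
#' tr <- VelocityTrace(2 * (1 + 0.25 * cos(2 * pi * seq(0, 2.995, by = 0.005))))
#' summarizeTrace(tr)  # pulsatility 0.25
#' @export
summarizeTrace <- function(trace, smoothWindow = NULL) {
  x <- trace@samples
  if (length(x) < 2) stop("need at least 2 samples to summarize a trace")
  xs <- x
  if (!is.null(smoothWindow)) {
    if (smoothWindow %% 2 != 1) stop("smoothWindow must be odd")
    xs <- stats::runmed(x, smoothWindow)
  }
  vmax <- max(xs); vmin <- min(xs)
  if (vmax + vmin == 0)
    stop("pulsatility undefined: Vmax + Vmin is zero")
  new("FlowSummary", vMax = vmax, vMin = vmin, vAve = mean(xs),
      pulsatility = (vmax - vmin) / (vmax + vmin))
}
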