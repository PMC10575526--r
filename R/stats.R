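#' Two-tailed Pearson correlation test
#'
#' Sample Pearson correlation on complete pairs, with a two-tailed p-value
#' from the t statistic r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom. Implemented from the closed form; \code{stats::cor.test} serves
#' as an independent cross-check in the test suite.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list with \code{r}, \code{p}, \code{n} and \code{strength} (see
#'   [strengthCategory()]).
#' @export
pearsonTest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs for a correlation")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector")
  xd <- x - mean(x); yd <- y - mean(y)
  r <- sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n, strength = strengthCategory(r))
}

#' Correlation strength category
#'
#' Bins the absolute correlation: [0, 0.30) negligible, [0.30, 0.50) low,
#' [0.50, 0.70) moderate, [0.70, 0.90) high, [0.90, 1] very_high. Boundaries
#' belong to the upper bin.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @return character vector of categories.
#' @export
strengthCategory <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  cut(abs(r), breaks = c(0, 0.3, 0.5, 0.7, 0.9, 1 + 1e-12),
      labels = c("negligible", "low", "moderate", "high", "very_high"),
      right = FALSE, include.lowest = TRUE) |> as.character()
}

.networkVars <- c(feeder_distance_um = "Feeding arteriole distance (um)",
                  depth_um = "Vessel depths (um)",
                  branch_order = "Branch orders (n)",
                  je_upstream = "JE_upstream",
                  je_downstream = "JE_downstream")
.flowVars <- c("v_ave", "v_min", "v_max", "pulsatility")

#' Correlations of network variables with flow parameters
#'
#' Builds the summary report relating each network variable (feeder
#' distance, depth, branch order, upstream and downstream junction exponent)
#' to each raw flow parameter (Vave, Vmin, Vmax, pulsatility): per-variable
#' sample size, average (median for branch order), observed range, and the
#' Pearson r per flow variable with significance flags at 0.05 (*) and
#' 0.01 (**). Correlations use complete-case deletion per pair; cells with
#' fewer than 3 complete pairs are \code{NA}.
#'
#' @param records data.frame of per-vessel records with (any of) columns
#'   \code{feeder_distance_um}, \code{depth_um}, \code{branch_order},
#'   \code{je_upstream}, \code{je_downstream}, \code{v_ave}, \code{v_min},
#'   \code{v_max}, \code{pulsatility}.
#' @return data.frame of class \code{"networkFlowTable"}, one row per
#'   network variable, with columns \code{variable}, \code{n},
#'   \code{average}, \code{min}, \code{max}, then \code{r_<flow>},
#'   \code{p_<flow>}, \code{sig_<flow>} per flow parameter.
#' @export
networkFlowTable <- function(records) {
  rows <- lapply(names(.networkVars), function(var) {
    out <- data.frame(variable = .networkVars[[var]], stringsAsFactors = FALSE)
    if (!var %in% names(records) || !any(!is.na(records[[var]]))) {
      out$n <- NA_integer_; out$average <- NA_real_
      out$min <- NA_real_; out$max <- NA_real_
      for (fv in .flowVars) {
        out[[paste0("r_", fv)]] <- NA_real_
        out[[paste0("p_", fv)]] <- NA_real_
        out[[paste0("sig_", fv)]] <- ""
      }
      return(out)
    }
    x <- records[[var]]
    out$n <- sum(!is.na(x))
    out$average <- if (var == "branch_order") stats::median(x, na.rm = TRUE)
                   else mean(x, na.rm = TRUE)
    out$min <- min(x, na.rm = TRUE)
    out$max <- max(x, na.rm = TRUE)
    for (fv in .flowVars) {
      y <- if (fv %in% names(records)) records[[fv]] else NA
      res <- tryCatch(pearsonTest(x, y), error = function(e) NULL)
      out[[paste0("r_", fv)]] <- if (is.null(res)) NA_real_ else res$r
      out[[paste0("p_", fv)]] <- if (is.null(res)) NA_real_ else res$p
      out[[paste0("sig_", fv)]] <-
        if (is.null(res)) "" else if (res$p < 0.01) "**"
        else if (res$p < 0.05) "*" else ""
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("networkFlowTable", "data.frame")
  out
}

#' @export
print.networkFlowTable <- function(x, ...) {
  cat("Network variables vs raw flow parameters (Pearson r; * p<0.05, ** p<0.01)\n\n")
  fmt <- function(r, s) ifelse(is.na(r), "NA", paste0(sprintf("%.2f", r), s))
  disp <- data.frame(
    variable = x$variable, n = x$n,
    average = ifelse(is.na(x$average), NA, sprintf("%.3g", x$average)),
    range = ifelse(is.na(x$min), NA,
                   sprintf("%.3g-%.3g", x$min, x$max)),
    Vave = fmt(x$r_v_ave, x$sig_v_ave),
    Vmin = fmt(x$r_v_min, x$sig_v_min),
    Vmax = fmt(x$r_v_max, x$sig_v_max),
    Pulsatility = fmt(x$r_pulsatility, x$sig_pulsatility),
    check.names = FALSE)
  print(disp, row.names = FALSE, ...)
  invisible(x)
}

#' Downstream junction-exponent outlier re-analysis
#'
#' Repeats the correlations of the downstream junction exponent with average
#' and minimum velocity after removing vessels with an exponent above the
#' threshold (default 4), reporting how many were removed. Used to check
#' that a correlation is not driven by a few high-leverage junctions.
#'
#' @param records per-vessel data.frame with \code{je_downstream},
#'   \code{v_ave}, \code{v_min}.
#' @param jeThreshold exclusion threshold on the downstream exponent.
#' @return list with \code{n_removed}, and \code{v_ave}/\code{v_min}
#'   correlation results (as from [pearsonTest()]) on the retained subset.
#' @export
outlierRerun <- function(records, jeThreshold = 4) {
  if (!"je_downstream" %in% names(records))
    stop("records lack 'je_downstream'")
  present <- !is.na(records$je_downstream)
  drop <- present & records$je_downstream > jeThreshold
  keep <- records[present & !drop, , drop = FALSE]
  if (nrow(keep) < 3) stop("fewer than 3 vessels remain below the threshold")
  list(n_removed = sum(drop),
       v_ave = pearsonTest(keep$je_downstream, keep$v_ave),
       v_min = pearsonTest(keep$je_downstream, keep$v_min))
}
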