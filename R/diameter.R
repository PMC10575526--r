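#' Construct a straightened vessel image
#'
#' @param image numeric matrix; rows are cross-sections along the vessel.
#' @param pxSize pixel size in um.
#' @param centerlineCol column index of the vessel axis; defaults to the
#'   image mid-line (half-integer for even widths).
#' @return a \linkS4class{StraightenedVessel}.
#' @export
StraightenedVessel <- function(image, pxSize = 1,
                               centerlineCol = (ncol(image) + 1) / 2) {
  new("StraightenedVessel", image = image, pxSize = pxSize,
      centerlineCol = centerlineCol)
}

#' Automatic lumen thresholding
#'
#' Otsu's histogram split applied to the straightened-vessel ROI; pixels
#' above the threshold are lumen. Use \code{polarity = "dark"} for
#' inverted-contrast images.
#'
#' @param v a \linkS4class{StraightenedVessel}.
#' @param polarity \code{"bright"} (lumen brighter than background, default)
#'   or \code{"dark"}.
#' @return logical matrix, \code{TRUE} for lumen pixels.
#' @export
thresholdLumen <- function(v, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  x <- v@image
  if (polarity == "dark") x <- -x
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  xn <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  xn > thr
}

## Signed distance (um) of each column's pixel centers from the centerline.
.colDistances <- function(v) (seq_len(ncol(v@image)) - v@centerlineCol) * v@pxSize

## Cross-section shape of a blurred lumen: uniform occupancy on [-D/2, D/2]
## convolved with a Gaussian edge blur of sd sigma, integrated over the
## pixel footprint [d - w/2, d + w/2] so that sharp bands identify D
## exactly. Uses the closed-form antiderivative of Phi.
.bandShape <- function(d, D, sigma, w) {
  h <- D / 2
  F <- function(u, hh) {
    z <- (u + hh) / sigma
    sigma * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  a <- d - w / 2; b <- d + w / 2
  ((F(b, h) - F(a, h)) - (F(b, -h) - F(a, -h))) / w
}

## Residual sum of squares of the column-mean profile y against
## bg + amp * shape(D, sigma), with (bg, amp) profiled out by linear LS.
## Gaussian-noise ML in (D, sigma) is equivalent to minimizing this RSS.
.widthRSS <- function(par, d, y, w, sigmaMin) {
  D <- exp(par[1])
  sigma <- sigmaMin + exp(par[2])
  s <- .bandShape(d, D, sigma, w)
  X <- cbind(1, s)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || stats::var(s) < 1e-12) return(sum((y - mean(y))^2))
  sum(fit$residuals^2)
}

.fitWidth <- function(d, y, w, start = NULL, sigmaMin = NULL) {
  if (is.null(sigmaMin)) sigmaMin <- 0.02 * w
  if (is.null(start)) {
    ## moment-based width guess from the above-midline mass of the profile
    y0 <- y - min(y)
    D0 <- max(sum(y0) / max(y0) * w * 0.9, w)
    start <- c(log(D0), log(0.5 * w))
  }
  fit <- stats::optim(start, .widthRSS, d = d, y = y, w = w,
                      sigmaMin = sigmaMin, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  list(D = exp(fit$par[1]), sigma = sigmaMin + exp(fit$par[2]),
       par = fit$par, rss = fit$value)
}

#' Maximum-likelihood lumen diameter from a straightened vessel image
#'
#' Fits the cross-sectional intensity profile (column means, expressed by
#' signed distance from the centerline) by maximum likelihood under a
#' generative model of the blurred lumen: uniform occupancy on
#' [-D/2, +D/2] convolved with a Gaussian edge blur (nuisance parameter),
#' plus a background offset and amplitude. Pixel footprints are integrated,
#' so a noiseless sharp band — including its partially covered edge pixels —
#' identifies D exactly and sub-pixel width differences (e.g. 6 um vs 5 um)
#' are resolved. The thresholded lumen mask localizes the vessel and
#' guards against fitting empty images.
#'
#' @param v a \linkS4class{StraightenedVessel}.
#' @param mask lumen mask from [thresholdLumen()]; computed automatically
#'   when omitted.
#' @param method \code{"ml"} (default) or \code{"halfmax"}, the
#'   full-width-at-half-maximum of the column-mean profile, provided for
#'   comparison.
#' @return a \linkS4class{DiameterEstimate} (no confidence limits; see
#'   [bootstrapDiameter()]).
#' @export
estimateDiameter <- function(v, mask = thresholdLumen(v),
                             method = c("ml", "halfmax")) {
  method <- match.arg(method)
  if (method == "halfmax") return(.halfmaxDiameter(v))
  if (sum(mask) < 10)
    stop("fewer than 10 lumen pixels; insufficient data for a width fit")
  d <- .colDistances(v)
  y <- colMeans(v@image)
  D0 <- max(sum(mask) / nrow(v@image) * v@pxSize, v@pxSize)
  fit <- .fitWidth(d, y, v@pxSize,
                   start = c(log(D0), log(0.5 * v@pxSize)))
  new("DiameterEstimate", diameter = fit$D, blurSd = fit$sigma)
}

.halfmaxDiameter <- function(v) {
  prof <- colMeans(v@image)
  prof <- prof - min(prof)
  half <- max(prof) / 2
  above <- which(prof >= half)
  if (!length(above)) stop("flat profile; cannot locate half-maximum")
  ## linear interpolation of the two half-maximum crossings
  cross <- function(i0, i1) {
    if (i0 < 1 || i0 > length(prof) || prof[i1] == prof[i0]) return(NA_real_)
    i0 + (half - prof[i0]) / (prof[i1] - prof[i0]) * (i1 - i0)
  }
  left <- cross(min(above) - 1, min(above))
  right <- cross(max(above) + 1, max(above))
  lo <- if (is.na(left)) min(above) - 0.5 else left
  hi <- if (is.na(right)) max(above) + 0.5 else right
  new("DiameterEstimate", diameter = (hi - lo) * v@pxSize, blurSd = NA_real_)
}

#' Bootstrap confidence limits for the lumen diameter
#'
#' Rows of the straightened image (different cross-sections through the
#' vessel) are drawn with replacement and the diameter re-fit on each
#' resample; the 95\% percentile interval over \code{nBoot} resamples forms
#' the confidence limits (expanded, if necessary, to contain the point
#' estimate). Deterministic for a fixed seed.
#'
#' @param v a \linkS4class{StraightenedVessel} with at least 10 rows.
#' @param nBoot number of bootstrap resamples (default 1000; below 100 a
#'   warning is issued and the computation proceeds).
#' @param seed integer RNG seed; the global RNG state is left untouched.
#' @param mask optional precomputed lumen mask.
#' @return a \linkS4class{DiameterEstimate} with confidence limits.
#' @export
bootstrapDiameter <- function(v, nBoot = 1000, seed = 1L,
                              mask = thresholdLumen(v)) {
  nr <- nrow(v@image)
  if (nr < 10) stop("need at least 10 rows to bootstrap cross-sections")
  if (nBoot < 100) warning("nBoot < 100; confidence limits will be coarse")
  point <- estimateDiameter(v, mask)
  d <- .colDistances(v)
  w <- v@pxSize
  start <- c(log(point@diameter), log(max(point@blurSd - 0.02 * w, 1e-3)))
  img <- v@image
  boots <- withSeed(as.integer(seed), {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(nr, nr, replace = TRUE)
      y <- colMeans(img[idx, , drop = FALSE])
      .fitWidth(d, y, w, start = start)$D
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  new("DiameterEstimate", diameter = point@diameter, blurSd = point@blurSd,
      ciLower = min(ci[1], point@diameter),
      ciUpper = max(ci[2], point@diameter),
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded generators never perturb global
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
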