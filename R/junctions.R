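#' Default junction-exponent search grid
#'
#' Candidate exponents 0.01, 0.02, ..., 10.00. Zero is excluded because the
#' 1/x root is undefined there; the 0.01 step makes two-decimal exponents
#' exactly representable.
#'
#' @param lower,upper,step grid bounds and spacing.
#' @return numeric vector of candidate exponents.
#' @export
exponentGrid <- function(lower = 0.01, upper = 10, step = 0.01) {
  if (lower <= 0) stop("exponent grid must be positive (1/x root undefined at 0)")
  seq(lower, upper, by = step)
}

#' Admissibility check for junction-exponent fitting
#'
#' A junction can be fit only when all three radii are available and the
#' major ("parent") vessel is strictly the widest: the generalized Murray
#' relation cannot support a major vessel narrower than (or equal, within
#' the 0.01 um measurement precision, to) its widest minor vessel.
#'
#' @param rParent,rD1,rD2 radii in um (lumen diameter / 2); \code{NA} marks a
#'   missing measurement.
#' @param precision equality tolerance of the widest-vessel check, um.
#' @return one of \code{"FIT"}, \code{"NONFIT_MISSING_RADIUS"},
#'   \code{"NONFIT_PARENT_NOT_WIDEST"}.
#' @export
checkFittable <- function(rParent, rD1, rD2, precision = 0.01) {
  r <- c(rParent, rD1, rD2)
  if (any(!is.na(r) & r <= 0)) stop("radii must be positive")
  if (any(is.na(r))) return("NONFIT_MISSING_RADIUS")
  if (rParent - max(rD1, rD2) <= precision) return("NONFIT_PARENT_NOT_WIDEST")
  "FIT"
}

#' Parent radius predicted by a junction exponent
#'
#' Evaluates (rD1^x + rD2^x)^(1/x), the parent (major-vessel) radius implied
#' by the two daughter radii under exponent x; Murray's law is the case
#' x = 3. Computed in scaled form for numerical stability at large x, where
#' the prediction approaches max(rD1, rD2).
#'
#' @param rD1,rD2 daughter radii, um (> 0).
#' @param x junction exponent (> 0); vectorized.
#' @return predicted parent radius, um.
#' @examples
#' predictParentRadius(4, 4, 3)   # 4 * 2^(1/3)
#' predictParentRadius(3, 4, 2)   # 5
#' @export
predictParentRadius <- function(rD1, rD2, x) {
  if (any(rD1 <= 0) || any(rD2 <= 0)) stop("daughter radii must be > 0")
  if (any(x <= 0)) stop("exponent must be > 0")
  m <- pmax(rD1, rD2)
  m * ((rD1 / m)^x + (rD2 / m)^x)^(1 / x)
}

#' Fit the junction exponent by brute-force grid search
#'
#' For each candidate exponent on the grid, the parent radius is predicted
#' from the daughters and the squared error against the measured parent
#' radius is computed; the exponent minimizing this error is returned (ties
#' go to the smallest exponent). Inadmissible junctions (missing radius, or
#' parent not strictly the widest) return their NONFIT status with no
#' exponent.
#'
#' @inheritParams checkFittable
#' @param grid candidate exponents, see [exponentGrid()].
#' @return list with elements \code{status}, \code{exponent}, \code{sse}
#'   (um^2), \code{r_parent}, \code{r_d1}, \code{r_d2}.
#' @examples
#' fitJunctionExponent(5, 3, 4)$exponent               # 2
#' fitJunctionExponent(predictParentRadius(3, 4, 2.5), 3, 4)$exponent  # 2.5
#' @export
fitJunctionExponent <- function(rParent, rD1, rD2, grid = exponentGrid()) {
  status <- checkFittable(rParent, rD1, rD2)
  if (status != "FIT")
    return(list(status = status, exponent = NA_real_, sse = NA_real_,
                r_parent = rParent, r_d1 = rD1, r_d2 = rD2))
  sse <- (rParent - predictParentRadius(rD1, rD2, grid))^2
  i <- which.min(sse)  # first minimum = smallest exponent on an ascending grid
  list(status = "FIT", exponent = grid[i], sse = sse[i],
       r_parent = rParent, r_d1 = rD1, r_d2 = rD2)
}

#' Fit junction exponents at both ends of each vessel of interest
#'
#' For every VOI, fits the exponent of the supplying (upstream, always a
#' bifurcation) and collecting (downstream, always a confluence) junction
#' where that junction exists in the network. Radii are taken as lumen
#' diameters / 2.
#'
#' @param net a \linkS4class{VascularNetwork} with diameters.
#' @param voiIds vessels of interest; default all segments.
#' @param grid candidate exponents.
#' @return data.frame with one row per (VOI, side): \code{voi_id},
#'   \code{junction_id}, \code{side} (\code{UPSTREAM}/\code{DOWNSTREAM}),
#'   \code{status}, \code{exponent}, \code{sse}, \code{r_parent},
#'   \code{r_d1}, \code{r_d2}. The attribute \code{"fit_counts"} tabulates
#'   statuses.
#' @export
fitJunctionExponents <- function(net, voiIds = net@segments$id,
                                 grid = exponentGrid()) {
  seg <- net@segments
  jn <- net@junctions
  radius <- function(id) {
    d <- seg$diameter_um[match(id, seg$id)]
    d / 2
  }
  rows <- list()
  for (voi in voiIds) {
    ## upstream junction: bifurcation where the VOI is a daughter
    upi <- which(jn$kind == "BIFURCATION" &
                   (jn$minor1_id == voi | jn$minor2_id == voi))
    ## downstream junction: confluence the VOI drains into
    dni <- which(jn$kind == "CONFLUENCE" &
                   (jn$minor1_id == voi | jn$minor2_id == voi))
    for (side in c("UPSTREAM", "DOWNSTREAM")) {
      i <- if (side == "UPSTREAM") upi else dni
      if (!length(i)) next
      j <- jn[i[1], ]
      fit <- fitJunctionExponent(radius(j$major_id), radius(j$minor1_id),
                                 radius(j$minor2_id), grid = grid)
      rows[[length(rows) + 1L]] <- data.frame(
        voi_id = voi, junction_id = j$junction_id, side = side,
        status = fit$status, exponent = fit$exponent, sse = fit$sse,
        r_parent = fit$r_parent, r_d1 = fit$r_d1, r_d2 = fit$r_d2,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(voi_id = character(), junction_id = character(),
               side = character(), status = character(),
               exponent = numeric(), sse = numeric(), r_parent = numeric(),
               r_d1 = numeric(), r_d2 = numeric(), stringsAsFactors = FALSE)
  attr(out, "fit_counts") <- table(out$status)
  out
}
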