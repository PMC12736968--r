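#' @include AllClasses.R
NULL

#' Quantify one scanline's artifact displacement
#'
#' Signed displacement between the reference origin g and the closest
#' defined artifact candidate position, by the piecewise rule: missing g
#' gives missing; with only the complement position defined, q = g - pBar;
#' with only the primary position defined, q = g - p; with both,
#' q = g - p when |g - p| <= |g - pBar| and q = g - pBar otherwise.
#' A result with |q| > tauMaq is suppressed.
#'
#' @param g reference origin index, or NA.
#' @param p artifact candidate position, or NA.
#' @param pBar complement candidate position, or NA.
#' @param tauMaq plausibility threshold in pixels (> 0).
#' @return list(q = value or NA, status = "valid"|"missing"|"suppressed").
#' @export
maqScanline <- function(g, p, pBar, tauMaq = 112) {
  if (tauMaq <= 0) stop("tauMaq must be > 0")
  if (is.na(g) || (is.na(p) && is.na(pBar)))
    return(list(q = NA_real_, status = "missing"))
  q <- if (is.na(p)) {
    g - pBar
  } else if (is.na(pBar)) {
    g - p
  } else if (abs(g - p) <= abs(g - pBar)) {
    g - p
  } else {
    g - pBar
  }
  if (abs(q) > tauMaq) return(list(q = NA_real_, status = "suppressed"))
  list(q = q, status = "valid")
}

#' Quantify all scanlines of one direction
#'
#' Converts each detected second-peak lag l into candidate positions via
#' the lag mapping (default "origin-centered": p = g + l, pBar = g - l, so
#' |q| equals the detected lag magnitude) and applies [maqScanline()]
#' per scanline.
#'
#' @param origins a [ReferenceOrigins-class].
#' @param peaks a [PeakLocations-class] over the same scanlines.
#' @param tauMaq plausibility threshold in pixels.
#' @param direction direction label carried into the result.
#' @param lagMapping candidate-position strategy.
#' @return a [MAQSet-class].
#' @export
maqMatrix <- function(origins, peaks, tauMaq = 112, direction = "",
                      lagMapping = "origin-centered") {
  K <- length(origins@origins)
  if (length(peaks@lags) != K)
    stop("origins and peaks must index the same scanlines")
  if (!identical(lagMapping, "origin-centered"))
    stop("unknown lagMapping: ", lagMapping)
  q <- rep(NA_real_, K)
  status <- character(K)
  for (k in seq_len(K)) {
    g <- origins@origins[k]
    l <- peaks@lags[k]
    if (is.na(l)) {
      res <- maqScanline(g, NA, NA, tauMaq)
    } else {
      res <- maqScanline(g, g + l, g - l, tauMaq)
    }
    q[k] <- res$q
    status[k] <- res$status
  }
  new("MAQSet", q = q, status = status, direction = direction, tauMaq = tauMaq)
}

#' Valid displacement values of a MAQ set
#' @param maq a [MAQSet-class].
#' @return numeric vector of the non-missing, non-suppressed q values.
#' @export
validQ <- function(maq) maq@q[maq@status == "valid"]
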