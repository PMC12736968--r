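#' @include AllClasses.R config.R
NULL

#' Rotate an image by 90 degrees
#'
#' Counterclockwise rotation of the displayed scene under the package's
#' convention (x right, y up): a feature oriented along angle a in the input
#' is oriented along a + 90 in the output.
#'
#' @param image a numeric matrix.
#' @return the rotated matrix.
#' @export
rotate90 <- function(image) {
  t(image)[ncol(image):1, , drop = FALSE]
}

#' Center the dark object and crop to a square window
#'
#' Locates the intensity-weighted centroid of the dark object (pixels darker
#' than \code{threshold}, weighted by their darkness below it), translates it
#' to the center of a square window of side \code{side}, and pads any region
#' falling outside the source frame with white.
#'
#' @param image numeric matrix in [0, 1].
#' @param side side of the square output window in pixels.
#' @param threshold intensity below which a pixel counts as object.
#' @return a side x side numeric matrix.
#' @export
cropCenter <- function(image, side = 224, threshold = 0.5) {
  w <- pmax(0, threshold - image)
  total <- sum(w)
  if (total == 0) stop("no object detected")
  ri <- sum(row(image) * w) / total
  ci <- sum(col(image) * w) / total
  c0 <- (side + 1) / 2   # geometric window center, fractional for even sides
  out <- matrix(1, side, side)
  rows <- round(ri + (seq_len(side) - c0))
  cols <- round(ci + (seq_len(side) - c0))
  rok <- which(rows >= 1 & rows <= nrow(image))
  cok <- which(cols >= 1 & cols <= ncol(image))
  out[rok, cok] <- image[rows[rok], cols[cok]]
  out
}

# collect diagonal (i+j=k) or antidiagonal (j-i+M=k) scanlines of a square
# matrix, ordered by increasing row index within each scanline
.diagonalRows <- function(image, anti = FALSE) {
  M <- nrow(image)
  ks <- if (!anti) 2:(2 * M) else 1:(2 * M - 1)
  lapply(ks, function(k) {
    i <- seq_len(M)
    j <- if (!anti) k - i else i + k - M
    ok <- j >= 1 & j <= M
    image[cbind(i[ok], j[ok])]
  })
}

# center-align variable-length scanlines to a common width, padding each
# side with the scanline's own edge value
.alignRows <- function(rows, width) {
  c0 <- floor(width / 2) + 1
  t(vapply(rows, function(v) {
    len <- length(v)
    mid <- floor(len / 2) + 1
    left <- c0 - mid
    c(rep(v[1], left), v, rep(v[len], width - left - len))
  }, numeric(width)))
}

#' Build the four directional scanline matrices
#'
#' Extracts scanlines along the four principal directions of a centered
#' square frame. Horizontal scanlines are the image rows; vertical scanlines
#' are the rows of the 90-degree-rotated image; diagonal scanline k collects
#' the pixels with i + j = k (orientation 45 degrees under the package
#' convention) and antidiagonal scanline k those with j - i + M = k
#' (orientation 135 degrees). Diagonal scanlines shorter than
#' \code{diagFraction * M} are dropped; the rest are center-aligned (middle
#' element on a common column) and padded with their own edge values to a
#' common length.
#'
#' @param image square numeric matrix (output of [cropCenter()]).
#' @param diagFraction minimum retained diagonal length as a fraction of M.
#' @return named list of four [DirectionalMatrix-class] objects
#'   (horizontal, diagonal, vertical, antidiagonal).
#' @export
buildDirectionalMatrices <- function(image, diagFraction = 0.5) {
  if (nrow(image) != ncol(image)) stop("image must be square")
  M <- nrow(image)
  minLen <- ceiling(diagFraction * M)
  mk <- function(direction, values, window) {
    new("DirectionalMatrix", direction = direction, values = values,
        cropWindow = as.integer(window))
  }
  diagonal <- .diagonalRows(image, anti = FALSE)
  anti <- .diagonalRows(image, anti = TRUE)
  dkeep <- which(lengths(diagonal) >= minLen)
  akeep <- which(lengths(anti) >= minLen)
  list(
    horizontal = mk("horizontal", image, c(1L, M)),
    diagonal = mk("diagonal", .alignRows(diagonal[dkeep], M), range(dkeep)),
    vertical = mk("vertical", rotate90(image), c(1L, M)),
    antidiagonal = mk("antidiagonal", .alignRows(anti[akeep], M), range(akeep))
  )
}

#' Collect raw (pre-crop) diagonal scanlines
#'
#' Utility exposing the unaligned per-k pixel collections, mainly for
#' verifying pixel conservation.
#'
#' @param image square numeric matrix.
#' @param anti FALSE for diagonal (i + j = k), TRUE for antidiagonal
#'   (j - i + M = k).
#' @return list of numeric vectors, one per k.
#' @export
diagonalScanlines <- function(image, anti = FALSE) {
  .diagonalRows(image, anti = anti)
}

#' Row-wise z-normalization of a scanline matrix
#'
#' Each scanline is centered by its mean and scaled by its population
#' standard deviation. Scanlines with spread below 1e-12 are emitted as
#' all zeros and flagged invalid.
#'
#' @param matrix a [DirectionalMatrix-class] or plain numeric matrix.
#' @return a [NormalizedMatrix-class].
#' @export
normalizeRows <- function(matrix) {
  m <- if (is(matrix, "DirectionalMatrix")) matrix@values else matrix
  if (!length(m)) stop("empty matrix")
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  valid <- sdv > 1e-12
  out <- (m - mu) / ifelse(valid, sdv, 1)
  out[!valid, ] <- 0
  new("NormalizedMatrix", values = out, validRowMask = valid)
}
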