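#' @include AllClasses.R
NULL

#' Read a grayscale image
#'
#' Reads a PNG or TIFF file into a numeric matrix in [0, 1]. Multi-channel
#' (RGB) inputs are converted by the channel average; an alpha channel, if
#' present, is dropped before averaging.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix in [0, 1].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 2L) img <- img[, , 1] else {
      if (nc == 4L) img <- img[, , 1:3, drop = FALSE]
      img <- apply(img, c(1, 2), mean)
    }
  }
  img
}

#' Write a grayscale frame as PNG or TIFF
#'
#' Writes the intensity matrix (8-bit PNG or 16-bit TIFF depending on
#' \code{bits}) and, for a [SyntheticFrame-class], a JSON ground-truth
#' sidecar \code{<path>.json} with the orientation, velocity and generator
#' parameters.
#'
#' @param frame a [SyntheticFrame-class] or numeric matrix in [0, 1].
#' @param path output path ending in .png, .tif or .tiff.
#' @param bits 8 or 16.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(frame, path, bits = 8) {
  img <- if (is(frame, "SyntheticFrame")) frame@intensities else frame
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path,
                           bits.per.sample = if (bits == 16) 16L else 8L),
    stop("unsupported image format: .", ext)
  )
  if (is(frame, "SyntheticFrame")) {
    p <- frame@meta$params
    sidecar <- list(
      phi_deg = frame@truthPhi, v_mps = frame@truthV,
      params = list(A = p@A, omega = p@omega, exposure = p@exposure,
                    step = p@step, pixelsPerMeter = p@pixelsPerMeter,
                    objectRadius = frame@meta$objectRadius,
                    psf = frame@meta$psf@kind, sigma = frame@meta$psf@sigma,
                    renderer = frame@meta$renderer))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write estimation results
#'
#' DirectionEstimate objects are written as JSON (stable field order,
#' floats at 6 decimals); sweep data.frames as CSV with the record columns
#' verbatim.
#'
#' @param x a [DirectionEstimate-class] or a sweep data.frame.
#' @param path output path.
#' @param format "json" or "csv".
#' @return the path, invisibly.
#' @export
writeResults <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!is(x, "DirectionEstimate")) stop("json output expects a DirectionEstimate")
    st <- x@diagnostics$stats
    out <- list(
      theta_deg = round(x@theta, 6),
      theta_complement_deg = round(x@thetaComplement, 6),
      q_px = round(x@q, 6),
      per_direction = lapply(seq_along(st@directions), function(d) list(
        direction = st@directions[d],
        mean = round(st@qbar[d], 6),
        std = round(st@sigma[d], 6),
        reliability = round(st@reliability[d], 6),
        n_valid = st@nValid[d])),
      triplet_indices = x@diagnostics$triplet@indices,
      segment_index = x@diagnostics$segmentIndex)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    if (!is.data.frame(x)) stop("csv output expects a sweep data.frame")
    utils::write.csv(format(x, digits = 15), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read estimation results back
#'
#' @param path a JSON file written by [writeResults()].
#' @return named list of the stored fields.
#' @export
readResults <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
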