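# Image and sidecar IO. Images are numeric matrices (gray) or H x W x C
# arrays in [0, 1]; PNG and TIFF are read natively, JPEG when the jpeg
# package is installed.

#' Read an image from disk
#'
#' @param path PNG, TIFF, or JPEG file.
#' @param gray Reduce multi-channel input with the luminance rule
#'   ([to_gray()]).
#' @return Numeric matrix (or array when `gray = FALSE`).
#' @export
read_image_grid <- function(path, gray = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the jpeg package")
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) {
    img <- img[, , 1:3]  # drop alpha
  }
  if (gray) to_gray(img) else img
}

#' Write an image to disk
#'
#' Values are clamped to [0, 1]. Format follows the file extension (PNG or
#' TIFF).
#'
#' @param image Numeric matrix or H x W x C array.
#' @param path Output path.
#' @export
write_image_grid <- function(image, path) {
  img <- clamp01(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported output format: ", ext)
  )
  invisible(path)
}

#' Write a directional response map stack with a JSON sidecar
#'
#' The H x W x P stack from [response_map()] is written as a multi-page TIFF
#' (one page per orientation, responses min-max normalised jointly) next to a
#' JSON sidecar recording the filter parameters, order, and border policy so
#' the maps are self-describing.
#'
#' @param stack H x W x P response array.
#' @param params The [filter_params()] used.
#' @param order Derivative order.
#' @param border Border policy string.
#' @param path Output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_response_maps <- function(stack, params, order, border, path) {
  rng <- range(stack, na.rm = TRUE)
  scaled <- (stack - rng[1L]) / max(rng[2L] - rng[1L], .Machine$double.eps)
  scaled[is.na(scaled)] <- 0
  pages <- lapply(seq_len(dim(stack)[3L]), function(p) scaled[, , p])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(sigma = params$sigma, rho = params$rho,
         support_radius = params$support_radius,
         n_orientations = params$n_orientations,
         order = order, border_policy = border,
         value_range = rng),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
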