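#' @keywords internal
"_PACKAGE"

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library internals never perturb user-level random streams.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Rotate a matrix (or H x W x C array) by 180 degrees, exactly.
rot180 <- function(x) {
  if (length(dim(x)) == 3L) {
    x[rev(seq_len(dim(x)[1L])), rev(seq_len(dim(x)[2L])), , drop = FALSE]
  } else {
    x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE]
  }
}

# Mirror columns (horizontal flip).
fliplr <- function(x) {
  if (length(dim(x)) == 3L) {
    x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
  } else {
    x[, rev(seq_len(ncol(x))), drop = FALSE]
  }
}

#' Convert an image to a single-channel gray matrix
#'
#' Multi-channel images are reduced with the Rec. 601 luminance weights
#' (0.299, 0.587, 0.114); single-channel input is returned unchanged as a
#' matrix.
#'
#' @param image A numeric matrix, or an H x W x C array with C of 1 or 3.
#' @return A numeric matrix of intensities.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) {
    return(image)
  }
  d <- dim(image)
  if (length(d) == 3L && d[3L] == 1L) {
    return(image[, , 1L])
  }
  if (length(d) == 3L && d[3L] == 3L) {
    return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
  }
  stop("expected a matrix or an H x W x {1,3} array")
}

check_image <- function(image) {
  img <- to_gray(image)
  if (!all(is.finite(img))) stop("image contains non-finite values")
  img
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
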