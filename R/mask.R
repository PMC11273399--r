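#' Convert a mask raster to a binary mask
#'
#' Any pixel whose intensity exceeds `threshold` becomes foreground. Colored
#' (multi-channel) rasters are collapsed with a per-pixel channel maximum
#' first, so any nonzero instance label counts as pig.
#'
#' @param image Numeric matrix (grayscale) or 3-d array (H x W x channels)
#'   of intensities, on any scale (0-255 files, 0-1 from [png::readPNG()]).
#' @param threshold Foreground threshold; a pixel is pig iff
#'   `intensity > threshold`. Default 0.
#' @return Logical matrix of the same height/width (`TRUE` = foreground).
#' @examples
#' binarize(matrix(c(0, 255, 0, 12), 2, 2), threshold = 0)
#' @export
binarize <- function(image, threshold = 0) {
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), max)
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix or array", call. = FALSE)
  if (length(image) == 0) stop("`image` is empty", call. = FALSE)
  image > threshold
}

# offsets of the elliptical (discrete disc) structuring element of nominal
# diameter `size`: all integer offsets within Euclidean radius size/2
disc_offsets <- function(size) {
  r <- size / 2
  m <- floor(r)
  g <- expand.grid(dr = -m:m, dc = -m:m)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Morphological opening with an elliptical structuring element
#'
#' Erosion followed by dilation with a discrete disc of nominal diameter
#' `size` (all pixel offsets within Euclidean radius `size/2`). Pixels
#' outside the frame count as background (background padding), so the
#' operation is anti-extensive and idempotent and removes any connected
#' speck that cannot contain the element. Implemented with an exact squared
#' Euclidean distance transform, which is equivalent to the sliding
#' min/max-filter definition.
#'
#' @param mask Logical matrix.
#' @param size Nominal element diameter in pixels (default 70, the noise
#'   scale of the mask-cleanup stage).
#' @return Logical matrix.
#' @export
morphological_open <- function(mask, size = 70) {
  assert_mask(mask)
  if (size < 1) stop("`size` must be >= 1", call. = FALSE)
  if (2 * floor(size / 2) + 1 > min(dim(mask)))
    stop("structuring element is larger than the image", call. = FALSE)
  r2 <- (size / 2)^2
  if (!any(mask)) return(mask)
  # crop to the foreground bounding box plus a margin that preserves border
  # semantics exactly
  m <- floor(size / 2) + 1L
  idx <- which(mask, arr.ind = TRUE)
  i0 <- max(1L, min(idx[, 1]) - m); i1 <- min(nrow(mask), max(idx[, 1]) + m)
  j0 <- max(1L, min(idx[, 2]) - m); j1 <- min(ncol(mask), max(idx[, 2]) + m)
  sub <- mask[i0:i1, j0:j1, drop = FALSE]

  # erosion: keep fg pixels whose distance to the nearest background pixel
  # (inside the frame or beyond its border) exceeds the element radius
  d2bg <- sqdist_to_true(!sub)
  # squared distance to the true frame border (outside pixels are
  # background), evaluated in full-frame coordinates of the crop rows/cols
  gi <- i0:i1
  gj <- j0:j1
  ei <- pmin(gi, nrow(mask) + 1L - gi)
  ej <- pmin(gj, ncol(mask) + 1L - gj)
  edge2 <- outer(as.numeric(ei), as.numeric(ej), pmin)^2
  eroded <- sub & (pmin(d2bg, edge2) > r2)

  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (any(eroded)) {
    dilated <- sqdist_to_true(eroded) <= r2
    out[i0:i1, j0:j1] <- dilated
  }
  out
}

#' Keep only the largest connected foreground component
#'
#' Components are 8-connected; ties in size are broken towards the component
#' whose topmost-then-leftmost pixel comes first.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return Logical matrix containing a single component.
#' @export
largest_component <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("no animal detected: mask has no foreground pixels", call. = FALSE)
  lab <- label_components_cpp(mask, 8L)
  n <- attr(lab, "n_components")
  if (n == 1L) return(mask)
  counts <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which.max(counts) # first max = earliest top-left pixel
  lab == keep
}

#' Trace the boundary contour of a mask
#'
#' Moore-neighbour tracing of the outer boundary, clockwise, starting from
#' the topmost-then-leftmost foreground pixel. The mask must contain exactly
#' one 8-connected component.
#'
#' @param mask Logical matrix.
#' @return A tibble with columns `row`, `col` (1-based pixel coordinates),
#'   consecutive points 8-adjacent, the loop closing back to the first point.
#' @export
extract_contour <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("cannot trace contour of an empty mask", call. = FALSE)
  lab <- label_components_cpp(mask, 8L)
  if (attr(lab, "n_components") > 1L)
    stop("mask has multiple components; apply largest_component() first", call. = FALSE)
  pts <- trace_contour_cpp(mask)
  tibble::tibble(row = pts[, 1], col = pts[, 2])
}

#' Clean a raw mask raster
#'
#' The standard cleanup chain: binarize, morphological opening, keep the
#' largest component.
#'
#' @inheritParams binarize
#' @param kernel_size Opening element diameter (see [morphological_open()]).
#' @return Logical matrix with a single foreground component.
#' @export
clean_mask <- function(image, threshold = 0, kernel_size = 70) {
  mask <- if (is.logical(image) && is.matrix(image)) image else binarize(image, threshold)
  opened <- morphological_open(mask, kernel_size)
  largest_component(opened)
}

#' Read and write binary mask PNGs
#'
#' Masks are stored as 8-bit grayscale PNGs with 0 = background and
#' 255 = foreground. `read_mask_png()` returns intensities on the 0-255
#' scale (multi-channel files are collapsed by channel maximum).
#'
#' @param path File path.
#' @return `read_mask_png()`: numeric matrix of 0-255 intensities.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , seq_len(min(3, dim(x)[3])), drop = FALSE],
                                      c(1, 2), max)
  round(255 * x)
}

#' @rdname read_mask_png
#' @param mask Logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
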