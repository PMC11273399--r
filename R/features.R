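#' Shape features of a cleaned binary mask
#'
#' The six per-frame image features used for weight estimation:
#' \describe{
#'   \item{area (`area_px2`)}{foreground pixel count; each pixel is one unit
#'     square.}
#'   \item{perimeter (`per_px`)}{length of the traced boundary polygon:
#'     Euclidean distance between consecutive contour points, closing the
#'     loop (axial steps count 1, diagonal steps sqrt(2)).}
#'   \item{PBL / PHW (`pbl_px`, `phw_px`)}{longer and shorter side of the
#'     minimum-area rotated bounding rectangle, the pixel proxies of body
#'     length and hip width.}
#'   \item{eccentricity (`ecc`)}{sqrt(1 - b^2/a^2) of the ellipse with the
#'     region's central second moments; 0 for a circle.}
#'   \item{deviation (`dev`)}{background fraction of the frame,
#'     `1 - area/(H*W)`; grows as the animal's image footprint shrinks, so
#'     it carries camera-distance (depth) information.}
#' }
#'
#' @param mask Logical matrix containing one cleaned foreground component.
#' @return `extract_features()`: a one-row tibble with columns `area_px2`,
#'   `per_px`, `pbl_px`, `phw_px`, `ecc`, `dev`.
#' @examples
#' sc <- render_mask(sample_biometry(1, seed = 2), seed = 2)
#' extract_features(sc$mask)
#' @export
extract_features <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("cannot extract features from an empty mask", call. = FALSE)
  contour <- extract_contour(mask)
  rect <- min_area_rect(mask)
  tibble::tibble(
    area_px2 = mask_area(mask),
    per_px = mask_perimeter(contour),
    pbl_px = rect$pbl,
    phw_px = rect$phw,
    ecc = mask_eccentricity(mask),
    dev = mask_deviation(mask)
  )
}

#' @rdname extract_features
#' @return `mask_area()`: foreground pixel count (scalar).
#' @export
mask_area <- function(mask) {
  assert_mask(mask)
  sum(mask)
}

#' @rdname extract_features
#' @param contour Contour tibble from [extract_contour()] (or an n x 2
#'   matrix of points).
#' @return `mask_perimeter()`: boundary length in pixels (scalar).
#' @export
mask_perimeter <- function(contour) {
  pts <- if (is.data.frame(contour)) cbind(contour$row, contour$col) else contour
  if (is.null(dim(pts)) || nrow(pts) < 1) stop("contour needs at least one point", call. = FALSE)
  n <- nrow(pts)
  if (n == 1) return(0)
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  close <- sqrt((pts[1, 1] - pts[n, 1])^2 + (pts[1, 2] - pts[n, 2])^2)
  sum(d) + close
}

#' @rdname extract_features
#' @return `min_area_rect()`: one-row tibble with `pbl` (longer side, px),
#'   `phw` (shorter side, px) and `angle` (degrees of the long side,
#'   in `[0, 180)`). Sides are the pixel-centre projection extents plus one
#'   pixel (exact for axis-aligned rectangles; oblique sides carry about
#'   +-1 px digitization uncertainty). The rectangle minimizes the area
#'   over the convex hull's edge directions (rotating calipers).
#' @export
min_area_rect <- function(mask) {
  assert_mask(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) stop("min-area rectangle needs at least 3 foreground pixels", call. = FALSE)
  x <- pts[, 2]; y <- pts[, 1]
  h <- grDevices::chull(x, y)
  if (length(h) < 3) stop("foreground pixels are collinear", call. = FALSE)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  ex <- hx[c(2:nh, 1)] - hx
  ey <- hy[c(2:nh, 1)] - hy
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  ex <- ex[keep] / len[keep]
  ey <- ey[keep] / len[keep]
  if (length(ex) == 0) stop("foreground pixels are collinear", call. = FALSE)
  best <- NULL
  for (k in seq_along(ex)) {
    u <- c(ex[k], ey[k])
    v <- c(-ey[k], ex[k])
    pu <- hx * u[1] + hy * u[2]
    pv <- hx * v[1] + hy * v[2]
    w <- diff(range(pu)) + 1
    g <- diff(range(pv)) + 1
    if (is.null(best) || w * g < best$area - 1e-12) {
      ang <- if (w >= g) atan2(u[2], u[1]) else atan2(v[2], v[1])
      best <- list(area = w * g, a = max(w, g), b = min(w, g),
                   angle = (ang * 180 / pi) %% 180)
    }
  }
  tibble::tibble(pbl = best$a, phw = best$b, angle = best$angle)
}

#' @rdname extract_features
#' @param min_area Minimum foreground pixel count for a stable moment
#'   ellipse (default 16).
#' @return `mask_eccentricity()`: eccentricity in `[0, 1)` (scalar).
#' @export
mask_eccentricity <- function(mask, min_area = 16) {
  assert_mask(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < min_area)
    stop(sprintf("eccentricity needs at least %d foreground pixels", min_area), call. = FALSE)
  x <- pts[, 2] - mean(pts[, 2])
  y <- pts[, 1] - mean(pts[, 1])
  mu20 <- mean(x^2)
  mu02 <- mean(y^2)
  mu11 <- mean(x * y)
  tr <- mu20 + mu02
  det <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + det) / 2
  l2 <- (tr - det) / 2
  if (l1 <= 0) stop("zero-variance region: eccentricity undefined", call. = FALSE)
  sqrt(1 - max(l2, 0) / l1)
}

#' @rdname extract_features
#' @return `mask_deviation()`: background fraction in `[0, 1]` (scalar);
#'   `dev + area/(H*W) = 1` holds exactly.
#' @export
mask_deviation <- function(mask) {
  assert_mask(mask)
  1 - sum(mask) / (nrow(mask) * ncol(mask))
}
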