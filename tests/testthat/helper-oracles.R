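# Independent oracle implementations and fixture builders. These stay
# deliberately naive (direct definitions, brute force) so they check the
# package's algorithms from a different route.

# --- fixtures ---------------------------------------------------------------

make_disc_mask <- function(radius, H = 2 * radius + 21, W = H,
                           cy = H / 2, cx = W / 2) {
  row <- matrix(seq_len(H) - 0.5, H, W)
  col <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  (row - cy)^2 + (col - cx)^2 <= radius^2
}

# filled ellipse, semi-axes (a, b) along (col, row) before rotation by theta
make_ellipse_mask <- function(a, b, theta = 0, H = 2 * ceiling(max(a, b)) + 21,
                              W = H) {
  row <- matrix(seq_len(H) - 0.5 - H / 2, H, W)
  col <- matrix(seq_len(W) - 0.5 - W / 2, H, W, byrow = TRUE)
  u <- col * cos(theta) + row * sin(theta)
  v <- -col * sin(theta) + row * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# filled rectangle of size len x wid (col x row), rotated by theta (radians)
make_rect_mask <- function(len, wid, theta = 0, H = NULL, W = NULL) {
  ext <- (len + wid) # generous
  H <- H %||% (2 * ceiling(ext / 2) + 21)
  W <- W %||% H
  row <- matrix(seq_len(H) - 0.5 - H / 2, H, W)
  col <- matrix(seq_len(W) - 0.5 - W / 2, H, W, byrow = TRUE)
  u <- col * cos(theta) + row * sin(theta)
  v <- -col * sin(theta) + row * cos(theta)
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

# random filled convex blob: rasterized convex hull of random points
make_convex_blob <- function(n_pts = 12, extent = 120, H = extent + 40,
                             W = extent + 40) {
  ang <- stats::runif(n_pts, 0, 2 * pi)
  rad <- extent / 2 * sqrt(stats::runif(n_pts, 0.2, 1))
  sx <- stats::runif(1, 0.4, 1)
  px <- W / 2 + rad * cos(ang) * sx
  py <- H / 2 + rad * sin(ang)
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h] # counterclockwise in (x, up-y)? orientation handled below
  row <- matrix(seq_len(H) - 0.5, H, W)
  col <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  inside <- matrix(TRUE, H, W)
  nh <- length(h)
  # ensure consistent orientation via signed area
  area2 <- sum(hx * hy[c(2:nh, 1)] - hx[c(2:nh, 1)] * hy)
  s <- sign(area2)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1 else i + 1
    cross <- (hx[j] - hx[i]) * (row - hy[i]) - (hy[j] - hy[i]) * (col - hx[i])
    inside <- inside & (s * cross >= 0)
  }
  inside
}

# random multi-blob mask: union of discs (may touch)
make_blob_mask <- function(n_blobs = 3, H = 80, W = 80, rmin = 3, rmax = 10) {
  m <- matrix(FALSE, H, W)
  for (i in seq_len(n_blobs)) {
    r <- stats::runif(1, rmin, rmax)
    cy <- stats::runif(1, r + 1, H - r - 1)
    cx <- stats::runif(1, r + 1, W - r - 1)
    m <- m | make_disc_mask(r, H, W, cy, cx)
  }
  m
}

# --- morphology oracle: literal sliding min/max filter ----------------------

oracle_disc_offsets <- function(size) {
  r <- size / 2
  m <- floor(r)
  offs <- expand.grid(dr = -m:m, dc = -m:m)
  offs[offs$dr^2 + offs$dc^2 <= r^2, , drop = FALSE]
}

shift_logical <- function(mask, dr, dc, pad) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(pad, H, W)
  ri <- seq_len(H) + dr
  ci <- seq_len(W) + dc
  ok_r <- ri >= 1 & ri <= H
  ok_c <- ci >= 1 & ci <= W
  out[ok_r, ok_c] <- mask[ri[ok_r], ci[ok_c]]
  out
}

oracle_erode <- function(mask, size) {
  offs <- oracle_disc_offsets(size)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs)))
    out <- out & shift_logical(mask, offs$dr[k], offs$dc[k], pad = FALSE)
  out
}

oracle_dilate <- function(mask, size) {
  offs <- oracle_disc_offsets(size)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs)))
    out <- out | shift_logical(mask, offs$dr[k], offs$dc[k], pad = FALSE)
  out
}

oracle_open <- function(mask, size) oracle_dilate(oracle_erode(mask, size), size)

# --- boundary-pixel scan oracle --------------------------------------------

oracle_boundary_set <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  nb <- shift_logical(bg, 1, 0, TRUE) | shift_logical(bg, -1, 0, TRUE) |
    shift_logical(bg, 0, 1, TRUE) | shift_logical(bg, 0, -1, TRUE)
  which(mask & nb, arr.ind = TRUE)
}

# --- flood-fill component oracle (4/8-connected BFS in plain R) -------------

oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbrs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        ii <- p[1] + nbrs[k, 1]; jj <- p[2] + nbrs[k, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# --- dense angle-sweep min-area-rectangle oracle ----------------------------

oracle_min_rect <- function(mask, step_deg = 0.25) {
  pts <- which(mask, arr.ind = TRUE)
  x <- pts[, 2]; y <- pts[, 1]
  best <- Inf; ba <- NA; bb <- NA
  for (th in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    w <- diff(range(u)) + 1; g <- diff(range(v)) + 1
    if (w * g < best) { best <- w * g; ba <- max(w, g); bb <- min(w, g) }
  }
  c(pbl = ba, phw = bb)
}

# --- metric formulas, independent transcription -----------------------------

oracle_metrics <- function(y, yhat) {
  M <- length(y)
  c(mae = sum(abs(yhat - y)) / M,
    mape = 100 / M * sum(abs(yhat - y) / y),
    rmse = sqrt(sum((yhat - y)^2) / M),
    r2 = 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2))
}

# --- exhaustive depth-1 split search ----------------------------------------

oracle_best_split <- function(X, y) {
  n <- length(y)
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  best <- list(gain = -Inf)
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    for (t in (xs[-length(xs)] + xs[-1]) / 2) {
      L <- y[X[, f] <= t]; R <- y[X[, f] > t]
      gain <- sse(y) - sse(L) - sse(R)
      if (gain > best$gain + 1e-12) best <- list(gain = gain, feature = f, threshold = t)
    }
  }
  best
}

# small straight/bent herd features used by several tests (cached per run)
tiny_herd <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      plan <- simulate_frames(10, 4, curvature_sd = 0.004, seed = 77)
      cache <<- list(plan = plan,
                     features = extract_features_plan(plan, clean = FALSE))
    }
    cache
  }
})
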