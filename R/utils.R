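# Shared internal helpers: seeding, geometry, thresholds, contours.
# Convention (whole package): images are numeric matrices on the 0..255
# intensity scale, indexed [row, col], 1-based, pixel-centered; angles are
# measured in degrees from 12 o'clock, clockwise positive.

#' Signal a classed error
#' @noRd
abort2 <- function(msg, class) {
  stop(structure(
    class = c(class, "blastograde_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into independent streams
#' (dataset, per-image, split, GA, weight init). Kept strictly below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stream integer stream identifier.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stream) {
  m <- as.double(as.integer(master) %% 1000003L)
  s <- as.double(as.integer(stream) %% 1000003L)
  as.integer((m * 40013 + s * 7919 + 104729) %% 2147483587)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

clip_intensity <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Boolean disk mask centered at (cy, cx) with radius r.
disk_mask <- function(nr, nc, cy, cx, r) {
  outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+") <= r * r
}

# Per-pixel polar coordinates about (cy, cx): distance and the clockwise
# angle from 12 o'clock in degrees, in [0, 360).
polar_grid <- function(nr, nc, cy, cx) {
  dy <- matrix(seq_len(nr) - cy, nr, nc)
  dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  list(
    rho = sqrt(dy * dy + dx * dx),
    theta = (atan2(dx, -dy) * 180 / pi) %% 360
  )
}

# Clockwise-from-up angle of points (py, px) about center (cy, cx).
point_angle <- function(py, px, cy, cx) {
  (atan2(px - cx, -(py - cy)) * 180 / pi) %% 360
}

#' Otsu threshold over an arbitrary set of intensities
#'
#' Histogram-based Otsu on the 0..255 scale for masked (non-rectangular)
#' pixel sets. Returns the bin midpoint maximizing between-class variance.
#' @noRd
masked_otsu <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) < 2L || max(v) - min(v) < 1e-12) return(if (length(v)) v[1] else 0)
  lo <- min(v); hi <- max(v)
  h <- tabulate(pmin(nbins, floor((v - lo) / (hi - lo) * nbins) + 1L), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 1e-12, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

# Sobel gradients. Returns gx (d/dcol), gy (d/drow) and magnitude.
sobel_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  # replicate-padded shifts
  up    <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- img[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  shl <- function(m) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]   # from left
  shr <- function(m) m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  gx <- (shr(up) + 2 * shr(img) + shr(down)) - (shl(up) + 2 * shl(img) + shl(down))
  gy <- (shl(down) + 2 * down + shr(down)) - (shl(up) + 2 * up + shr(up))
  list(gx = gx, gy = gy, mag = sqrt(gx * gx + gy * gy))
}

# Morphological gradient (3x3 box dilation minus erosion), grayscale,
# with replicate padding so frame borders carry no spurious gradient.
morph_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- list(c(1L, seq_len(nr - 1L)), seq_len(nr), c(seq_len(nr - 1L) + 1L, nr))
  ci <- list(c(1L, seq_len(nc - 1L)), seq_len(nc), c(seq_len(nc - 1L) + 1L, nc))
  mx <- mn <- img
  for (a in 1:3) for (b in 1:3) {
    if (a == 2L && b == 2L) next
    s <- img[ri[[a]], ci[[b]], drop = FALSE]
    mx <- pmax(mx, s); mn <- pmin(mn, s)
  }
  mx - mn
}

# Ordered outer contour of the largest object in a boolean mask,
# as an n x 2 matrix of (row, col), 1-based.
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  if (length(oc) == 0L) return(NULL)
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]]
  pts + 1  # EBImage contours are 0-based
}

# Perimeter of a boolean mask: polygon length of the circularly smoothed
# outer contour (window k); accurate to ~1% on digitized disks.
mask_perimeter <- function(mask, k = 7L) {
  pts <- mask_contour(mask)
  if (is.null(pts) || nrow(pts) < 4L) return(if (is.null(pts)) 0 else nrow(pts))
  n <- nrow(pts)
  half <- k %/% 2L
  idx <- ((seq_len(n) - 1L + rep(-half:half, each = n)) %% n) + 1L
  sm <- cbind(
    rowMeans(matrix(pts[idx, 1L], n)),
    rowMeans(matrix(pts[idx, 2L], n))
  )
  d <- sm - sm[c(2:n, 1L), , drop = FALSE]
  sum(sqrt(rowSums(d * d)))
}

# Bilinear sampling of img at (continuous) coordinates (ry, cx); points
# outside the raster return `fill`.
bilinear_sample <- function(img, ry, cx, fill) {
  nr <- nrow(img); nc <- ncol(img)
  ry <- as.numeric(ry); cx <- as.numeric(cx)
  r0 <- floor(ry); c0 <- floor(cx)
  fr <- ry - r0; fc <- cx - c0
  inside <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # edge rows/cols: clamp for exact boundary coordinates
  edge <- !inside & ry >= 1 & ry <= nr & cx >= 1 & cx <= nc
  r0i <- pmin(pmax(r0, 1L), nr - 1L); c0i <- pmin(pmax(c0, 1L), nc - 1L)
  v00 <- img[cbind(r0i, c0i)]
  v01 <- img[cbind(r0i, c0i + 1L)]
  v10 <- img[cbind(r0i + 1L, c0i)]
  v11 <- img[cbind(r0i + 1L, c0i + 1L)]
  frc <- pmin(pmax(fr + (r0 - r0i), 0), 1)
  fcc <- pmin(pmax(fc + (c0 - c0i), 0), 1)
  out <- (1 - frc) * ((1 - fcc) * v00 + fcc * v01) + frc * ((1 - fcc) * v10 + fcc * v11)
  out[!(inside | edge)] <- fill
  out
}

stopifnot_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    abort2("`image` must be a non-empty numeric matrix", "schema_error")
}
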