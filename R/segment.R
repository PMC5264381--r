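# Embryo segmentation: circular Hough detection, background stripping,
# ring/inner partition, binary gradient map and marker-controlled watershed.

#' Embryo circle
#'
#' @param cx,cy center column and row (pixels, 1-based).
#' @param r radius in pixels.
#' @param accumulator_peak normalized Hough vote strength in [0, 1].
#' @return Object of class \code{embryo_circle}.
#' @export
embryo_circle <- function(cx, cy, r, accumulator_peak = NA_real_) {
  if (r <= 0) abort2("radius must be positive", "configuration_error")
  structure(list(cx = cx, cy = cy, r = r, accumulator_peak = accumulator_peak),
            class = "embryo_circle")
}

#' @export
print.embryo_circle <- function(x, ...) {
  cat(sprintf("<embryo_circle> center (row %.1f, col %.1f), r %.1f, peak %.3f\n",
              x$cy, x$cx, x$r, x$accumulator_peak))
  invisible(x)
}

# box-pooled accumulator: sum over a (2*half+1)^2 window, edge-clipped
pool_box <- function(acc, half) {
  nr <- nrow(acc); nc <- ncol(acc)
  cs <- rbind(0, apply(acc, 2, cumsum))
  v <- cs[pmin(nr, seq_len(nr) + half) + 1L, , drop = FALSE] -
       cs[pmax(0L, seq_len(nr) - half - 1L) + 1L, , drop = FALSE]
  cs2 <- cbind(0, t(apply(v, 1, cumsum)))
  cs2[, pmin(nc, seq_len(nc) + half) + 1L, drop = FALSE] -
    cs2[, pmax(0L, seq_len(nc) - half - 1L) + 1L, drop = FALSE]
}

#' Detect the embryo by a circular Hough transform
#'
#' Two-stage Hough gradient method. Stage 1: Sobel edge pixels of the
#' lightly smoothed image (magnitude above the Otsu level) vote along their
#' full gradient line, both polarities, at all distances in the radius
#' window; all circle normals intersect at the center, so the pooled
#' accumulator maximum locates it robustly even when isolated boundary arcs
#' vote coherently elsewhere. Stage 2: the radius is the smoothed mode of
#' the center-to-edge distance histogram over radially aligned edges. The
#' reported \code{accumulator_peak} is the winning support normalized per
#' circumference: the fraction of 1-degree sectors around the center
#' containing an aligned edge within 3 px of the fitted radius, so an
#' ideal circle scores 1.
#'
#' @param image numeric matrix.
#' @param r_min,r_max radius search window in pixels; defaults to
#'   [0.2, 0.45] of the smaller image side.
#' @param min_peak reject detections whose normalized peak (angular
#'   support) falls below this.
#' @param max_edges strongest-magnitude edge budget.
#' @return An \code{\link{embryo_circle}}.
#' @export
detect_embryo_circle <- function(image,
                                 r_min = NULL, r_max = NULL,
                                 min_peak = 0.08,
                                 max_edges = 2500L) {
  stopifnot_image(image)
  nr <- nrow(image); nc <- ncol(image)
  sz <- min(nr, nc)
  if (is.null(r_min)) r_min <- round(0.20 * sz)
  if (is.null(r_max)) r_max <- round(0.45 * sz)
  if (!(r_min > 0 && r_min < r_max && r_max < sz / 2))
    abort2("need 0 < r_min < r_max < image_size/2", "configuration_error")

  g <- sobel_gradient(as.matrix(EBImage::gblur(image, sigma = 2)))
  thr <- masked_otsu(as.numeric(g$mag))
  edge <- which(g$mag > thr & g$mag > 1e-9)
  if (length(edge) < 8L) abort2("no embryo found: too few edge pixels", "no_embryo_found_error")
  edge <- edge[order(g$mag[edge], decreasing = TRUE)]
  if (length(edge) > max_edges) edge <- edge[seq_len(max_edges)]
  n_e <- length(edge)
  er <- ((edge - 1L) %% nr) + 1L
  ec <- ((edge - 1L) %/% nr) + 1L
  uy <- g$gy[edge] / g$mag[edge]
  ux <- g$gx[edge] / g$mag[edge]

  # stage 1: line voting along the gradient at every admissible distance.
  # Only the strongest edges vote for the center: the embryo's outer
  # boundary carries the largest intensity step, while weaker interior
  # edges (ICM, trophectoderm) would cast coherent off-center vote fans.
  ctr <- seq_len(min(n_e, 1200L))  # edges are already magnitude-sorted
  ery <- er[ctr]; ecx <- ec[ctr]; uyc <- uy[ctr]; uxc <- ux[ctr]
  dists <- seq(r_min, r_max)
  nd <- length(dists)
  dd <- rep(dists, each = length(ctr))
  rr <- as.integer(round(c(rep(ery, nd) - dd * rep(uyc, nd), rep(ery, nd) + dd * rep(uyc, nd))))
  cc <- as.integer(round(c(rep(ecx, nd) - dd * rep(uxc, nd), rep(ecx, nd) + dd * rep(uxc, nd))))
  # centers must leave room for the smallest circle (2 px clipping tolerance)
  ok <- rr >= r_min - 1L & rr <= nr - r_min + 2L & cc >= r_min - 1L & cc <= nc - r_min + 2L
  if (!any(ok)) abort2("no embryo found: no admissible circle center", "no_embryo_found_error")
  acc <- matrix(tabulate((cc[ok] - 1L) * nr + rr[ok], nr * nc), nr, nc)
  pooled <- pool_box(acc, 3L)

  # candidate centers: the strongest well-separated accumulator maxima
  ord <- order(pooled, decreasing = TRUE)[seq_len(min(4000L, length(pooled)))]
  cand_ctr <- matrix(0, 0, 2)
  for (i in ord) {
    pt <- c(((i - 1L) %% nr) + 1L, ((i - 1L) %/% nr) + 1L)
    if (nrow(cand_ctr) == 0 ||
        min((cand_ctr[, 1] - pt[1])^2 + (cand_ctr[, 2] - pt[2])^2) > 15^2)
      cand_ctr <- rbind(cand_ctr, pt)
    if (nrow(cand_ctr) >= 6L) break
  }
  # extra seed: centroid of the strongest edges -- for a closed boundary it
  # estimates the center without bias even when vote fans are diffuse
  cand_ctr <- rbind(cand_ctr, c(round(mean(er[ctr])), round(mean(ec[ctr]))))

  # stage 2, per candidate: radius from the distance histogram of radially
  # aligned edges, iterated with an algebraic (Kasa) circle refit; the
  # refined circle that best explains the strongest edges wins
  refine <- function(cy0, cx0) {
    r_hat <- NA_real_
    for (it in 1:4) {
      dy <- er - cy0; dx <- ec - cx0
      d_all <- sqrt(dy * dy + dx * dx)
      align <- abs(dy * uy + dx * ux) / pmax(d_all, 1e-9) > cos(20 * pi / 180)
      inw <- align & d_all >= r_min - 2 & d_all <= r_max + 2
      if (!any(inw)) return(NULL)
      bins <- as.integer(round(d_all[inw])) - (r_min - 2L) + 1L
      h <- tabulate(bins, r_max - r_min + 5L)
      hs <- as.numeric(stats::filter(h, rep(1, 5), sides = 2))
      hs[is.na(hs)] <- 0
      r0 <- (which.max(hs) - 1L) + (r_min - 2L)
      sel <- inw & abs(d_all - r0) <= 4
      if (sum(sel) < 8L) { r_hat <- r0; break }
      x <- ec[sel]; y <- er[sel]
      fit <- tryCatch(qr.solve(cbind(2 * x, 2 * y, 1), x * x + y * y),
                      error = function(e) NULL)
      if (is.null(fit)) { r_hat <- mean(d_all[sel]); break }
      cx0 <- fit[1]; cy0 <- fit[2]
      r_hat <- sqrt(max(fit[3] + fit[1]^2 + fit[2]^2, 1))
    }
    if (!is.finite(r_hat)) return(NULL)
    # support among the strongest edges (the outer embryo boundary):
    # Gaussian truncated residual loss tolerant of mild irregularity
    res <- sqrt((er[ctr] - cy0)^2 + (ec[ctr] - cx0)^2) - r_hat
    list(cy = cy0, cx = cx0, r = r_hat, support = mean(exp(-(res / 6)^2)))
  }
  fits <- Filter(Negate(is.null),
                 lapply(seq_len(nrow(cand_ctr)),
                        function(k) refine(cand_ctr[k, 1], cand_ctr[k, 2])))
  if (!length(fits))
    abort2("no embryo found: no radially aligned edge support", "no_embryo_found_error")
  best <- fits[[which.max(vapply(fits, `[[`, 0, "support"))]]
  cy0 <- best$cy; cx0 <- best$cx
  # keep the circle inside the frame (2 px clipping tolerance)
  r_hat <- min(best$r, cy0 - 1 + 2, cx0 - 1 + 2, nr - cy0 + 2, nc - cx0 + 2)

  dy <- er - cy0; dx <- ec - cx0
  d_all <- sqrt(dy * dy + dx * dx)
  align <- abs(dy * uy + dx * ux) / pmax(d_all, 1e-9) > cos(20 * pi / 180)
  ring <- align & abs(d_all - r_hat) <= 3
  sectors <- unique(floor(point_angle(er[ring], ec[ring], cy0, cx0)))
  peak <- length(sectors) / 360
  if (peak < min_peak)
    abort2("no embryo found: Hough peak below threshold", "no_embryo_found_error")
  embryo_circle(cx = cx0, cy = cy0, r = r_hat,
                accumulator_peak = min(1, peak))
}

#' Region masks of one segmented embryo
#'
#' @param embryo boolean matrix of the embryo disk.
#' @param ring,inner optional boolean matrices partitioning the embryo into
#'   the zona/trophectoderm annulus and the inner (ICM + blastocoel) disk.
#' @return Object of class \code{region_masks} with a \code{background}
#'   complement.
#' @export
region_masks <- function(embryo, ring = NULL, inner = NULL) {
  if (!is.null(ring) && !is.null(inner)) {
    if (any(ring & inner)) abort2("ring and inner masks overlap", "schema_error")
    if (!identical(ring | inner, embryo))
      abort2("ring and inner must partition the embryo mask", "schema_error")
  }
  structure(list(embryo = embryo, ring = ring, inner = inner,
                 background = !embryo), class = "region_masks")
}

#' Strip the background around the detected embryo
#'
#' @param image numeric matrix.
#' @param circle an \code{\link{embryo_circle}}.
#' @param margin extra radius fraction kept around the circle.
#' @return List: \code{masks} (a \code{\link{region_masks}} with embryo and
#'   background) and \code{masked} (a copy of the image with background set
#'   to 0).
#' @export
mask_background <- function(image, circle, margin = 0) {
  stopifnot_image(image)
  embryo <- disk_mask(nrow(image), ncol(image), circle$cy, circle$cx,
                      circle$r * (1 + margin))
  masked <- image
  masked[!embryo] <- 0
  list(masks = region_masks(embryo), masked = masked)
}

#' Split the embryo into the zona/trophectoderm ring and the inner disk
#'
#' @param image numeric matrix (used for its dimensions).
#' @param circle an \code{\link{embryo_circle}}.
#' @param ring_fraction fraction of the radius occupied by the ring
#'   (default 0.25: zona pellucida plus trophectoderm in the outer quarter).
#' @return A \code{\link{region_masks}} with embryo, ring, inner and
#'   background.
#' @export
split_ring_and_inner <- function(image, circle, ring_fraction = 0.25) {
  stopifnot_image(image)
  if (ring_fraction <= 0 || ring_fraction >= 1)
    abort2("ring_fraction must lie in (0, 1)", "configuration_error")
  nr <- nrow(image); nc <- ncol(image)
  embryo <- disk_mask(nr, nc, circle$cy, circle$cx, circle$r)
  inner <- disk_mask(nr, nc, circle$cy, circle$cx, circle$r * (1 - ring_fraction))
  region_masks(embryo, ring = embryo & !inner, inner = inner & embryo)
}

#' Binary gradient map inside a mask
#'
#' Morphological gradient (3x3 dilation minus erosion) thresholded at the
#' within-mask Otsu level.
#'
#' @param image numeric matrix.
#' @param mask boolean matrix.
#' @return Boolean matrix, a subset of \code{mask}.
#' @export
gradient_binary <- function(image, mask) {
  stopifnot_image(image)
  if (!any(mask)) abort2("mask is empty", "degenerate_input_error")
  g <- as.matrix(morph_gradient(image))
  v <- g[mask]
  if (max(v) - min(v) < 1e-12) return(mask & FALSE)
  (g > masked_otsu(v)) & mask
}

#' Watershed segmentation of the embryo interior
#'
#' Marker-controlled watershed on the morphological-gradient surface:
#' regional minima deeper than \code{h} (h-minima suppression) seed the
#' basins; the labels exactly partition the mask.
#'
#' @param image numeric matrix.
#' @param mask boolean matrix to segment.
#' @param h basin depth in intensity units below which adjacent minima are
#'   merged (default 10).
#' @return Object of class \code{watershed_labels}: integer \code{labels}
#'   matrix (0 outside the mask) and \code{n_regions}.
#' @export
watershed_regions <- function(image, mask, h = 10) {
  stopifnot_image(image)
  if (!any(mask)) abort2("mask is empty", "degenerate_input_error")
  g <- as.matrix(morph_gradient(image))
  # invert: basins of the gradient become peaks the flood fills from
  surf <- matrix(0, nrow(image), ncol(image))
  surf[mask] <- max(g[mask]) - g[mask] + 1
  lab <- EBImage::watershed(surf, tolerance = h, ext = 1)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  labs <- sort(unique(lab[lab > 0L]))
  # compact label ids
  lab[lab > 0L] <- match(lab[lab > 0L], labs)
  structure(list(labels = lab, n_regions = length(labs)),
            class = "watershed_labels")
}

#' Data-driven embryo outline mask
#'
#' Re-estimates the actual (possibly irregular) embryo outline around the
#' Hough circle: within-disk Otsu threshold, hole filling and largest
#' connected component. Used for boundary-shape features, where the ideal
#' Hough disk would hide boundary irregularity.
#'
#' @param image numeric matrix.
#' @param circle an \code{\link{embryo_circle}}.
#' @return Boolean matrix.
#' @export
estimate_embryo_mask <- function(image, circle) {
  stopifnot_image(image)
  nr <- nrow(image); nc <- ncol(image)
  roi <- disk_mask(nr, nc, circle$cy, circle$cx, circle$r * 1.25)
  thr <- masked_otsu(image[roi])
  bin <- matrix(as.integer(image > thr & roi), nr, nc)
  bin <- EBImage::closing(bin, EBImage::makeBrush(5L, "disc"))
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab < 1L) abort2("embryo outline not found", "no_embryo_found_error")
  areas <- tabulate(lab[lab > 0], nlab)
  lab == which.max(areas)
}
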