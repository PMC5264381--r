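# Brightness standardization and ICM pose normalization.
#
# Micrographs arrive with arbitrary illumination; an affine intensity remap
# brings the embryo foreground to a fixed mean/sd, and the frame is rotated
# about the embryo center so the inner cell mass sits at 12 o'clock, giving
# all downstream texture/region statistics a canonical pose.

#' Standardize image brightness by an affine intensity remap
#'
#' Computes gain and offset such that the (foreground) mean and standard
#' deviation equal the targets before clipping to [0, 255]. When a mask is
#' supplied (typically the detected embryo disk) the statistics are taken
#' over the mask only, otherwise globally.
#'
#' @param image numeric matrix on the 0..255 scale.
#' @param target_mean,target_sd target foreground mean and sd
#'   (defaults 128 and 30).
#' @param mask optional boolean matrix restricting the statistics.
#' @return An object of class \code{standardized_image}: fields
#'   \code{image} (clipped), \code{applied_gain}, \code{applied_offset},
#'   \code{rotation_deg} (0; filled by the pose stage).
#' @export
standardize_brightness <- function(image, target_mean = 128, target_sd = 30,
                                   mask = NULL) {
  stopifnot_image(image)
  v <- if (is.null(mask)) as.numeric(image) else image[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-9)
    abort2("constant image: zero intensity variance", "degenerate_input_error")
  gain <- target_sd / s
  offset <- target_mean - gain * mean(v)
  out <- clip_intensity(gain * image + offset)
  structure(list(
    image = out,
    applied_gain = gain,
    applied_offset = offset,
    rotation_deg = 0
  ), class = "standardized_image")
}

#' Locate the inner cell mass angle
#'
#' Detects the ICM as the densest compact bright region inside the embryo
#' cavity: pixels above the within-circle Otsu level -- restricted to the
#' interior disk that excludes the bright zona/trophectoderm shell, whose
#' annulus would otherwise dominate -- are eroded (to cut thin bridges),
#' labeled, and each component scored by area x mean intensity x
#' compactness; the winner's centroid gives the clock angle (degrees from
#' 12 o'clock, clockwise).
#'
#' @param image numeric matrix.
#' @param circle an \code{embryo_circle}.
#' @param min_area smallest candidate component in pixels.
#' @param inner_fraction radius fraction of the searched interior disk.
#' @return Angle in degrees, in [0, 360).
#' @export
locate_icm_angle <- function(image, circle, min_area = 25L, inner_fraction = 0.72) {
  stopifnot_image(image)
  disk <- disk_mask(nrow(image), ncol(image), circle$cy, circle$cx, circle$r)
  thr <- masked_otsu(image[disk])
  disk <- disk_mask(nrow(image), ncol(image), circle$cy, circle$cx,
                    circle$r * inner_fraction)
  bin <- (image > thr) & disk
  if (!any(bin)) abort2("no region above threshold inside circle", "icm_not_found_error")
  bin <- EBImage::erode(matrix(as.integer(bin), nrow(image)), EBImage::makeBrush(3L, "disc")) > 0
  lab <- EBImage::bwlabel(matrix(as.integer(bin), nrow(image)))
  nlab <- max(lab)
  if (nlab < 1L) abort2("no compact bright region found (ICM)", "icm_not_found_error")
  areas <- tabulate(lab[lab > 0], nlab)
  best <- -Inf; best_c <- NULL
  for (k in seq_len(nlab)) {
    if (areas[k] < min_area) next
    mk <- lab == k
    a <- areas[k]
    p <- mask_perimeter(mk)
    comp <- if (p > 0) min(1, 4 * pi * a / (p * p)) else 0
    sc <- a * mean(image[mk]) * comp
    if (sc > best) {
      best <- sc
      best_c <- c(mean(row(mk)[mk]), mean(col(mk)[mk]))
    }
  }
  if (is.null(best_c))
    abort2("no compact bright region found (ICM)", "icm_not_found_error")
  point_angle(best_c[1], best_c[2], circle$cy, circle$cx)
}

#' Rotate the image so the ICM moves to 12 o'clock
#'
#' Rotates the content by \code{-angle} (i.e. counterclockwise by the ICM's
#' clock angle) about the given center with bilinear interpolation, so a
#' structure at clock angle \code{angle} ends up at the top. Pixels mapped
#' from outside the frame are filled with the image's border median.
#'
#' @param image numeric matrix.
#' @param angle ICM clock angle in degrees, in [0, 360).
#' @param center rotation center \code{c(cy, cx)}; defaults to the frame
#'   center.
#' @return The rotated numeric matrix.
#' @export
rotate_icm_to_top <- function(image, angle, center = NULL) {
  stopifnot_image(image)
  if (angle < 0 || angle >= 360) abort2("angle must lie in [0, 360)", "configuration_error")
  if (angle == 0) return(image)
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- angle * pi / 180
  y <- matrix(seq_len(nr) - center[1], nr, nc)
  x <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  # inverse map: source point sits at clock angle (phi + angle)
  xs <- x * cos(th) - y * sin(th)
  ys <- x * sin(th) + y * cos(th)
  border <- c(image[1, ], image[nr, ], image[, 1], image[, nc])
  out <- bilinear_sample(image, ys + center[1], xs + center[2],
                         fill = stats::median(border))
  matrix(out, nr, nc)
}
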