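# The 36-variable embryo descriptor: circularity, per-region intensity,
# GLCM texture and watershed-region statistics, in a fixed registry order.

#' The fixed 36-feature registry
#'
#' Single source of truth for the descriptor's names, order and provenance
#' (which region and operator produced each value): 3 circularity features,
#' 4 intensity statistics for each of embryo/ring/inner, 2 area fractions,
#' the 5 Haralick statistics (distance-averaged) on inner and ring, 4
#' distance-2 texture features, 4 watershed statistics and the normalized
#' embryo radius.
#'
#' @return data.frame with columns \code{name}, \code{region},
#'   \code{operator}; exactly 36 rows.
#' @export
feature_registry <- function() {
  rows <- list(
    c("circ_hough_peak", "embryo", "hough"),
    c("circ_isoperimetric", "embryo", "shape"),
    c("circ_radial_sd", "embryo", "shape")
  )
  for (reg in c("embryo", "ring", "inner"))
    for (st in c("mean", "sd", "p10", "p90"))
      rows[[length(rows) + 1L]] <- c(paste(reg, st, sep = "_"), reg, "intensity")
  rows[[length(rows) + 1L]] <- c("ring_area_frac", "ring", "area")
  rows[[length(rows) + 1L]] <- c("inner_area_frac", "inner", "area")
  for (reg in c("inner", "ring"))
    for (st in c("contrast", "correlation", "energy", "homogeneity", "entropy"))
      rows[[length(rows) + 1L]] <- c(paste(reg, "glcm", st, sep = "_"), reg, "glcm")
  for (reg in c("inner", "ring"))
    for (st in c("contrast", "energy"))
      rows[[length(rows) + 1L]] <- c(paste(reg, "glcm", st, "d2", sep = "_"), reg, "glcm_d2")
  for (st in c("n_regions", "area_mean", "area_cv", "largest_frac"))
    rows[[length(rows) + 1L]] <- c(paste("ws", st, sep = "_"), "embryo", "watershed")
  rows[[length(rows) + 1L]] <- c("embryo_radius_norm", "embryo", "geometry")
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "region", "operator")
  stopifnot(nrow(out) == 36L, !anyDuplicated(out$name))
  out
}

#' Feature extraction parameters
#'
#' @param target_mean,target_sd brightness-standardization targets.
#' @param ring_fraction radius fraction of the zona/trophectoderm ring.
#' @param glcm a \code{\link{glcm_spec}} (its \code{distances} must include
#'   1 and 2 for the registry's distance-averaged and distance-2 features).
#' @param h_min watershed basin depth (intensity units).
#' @param r_window Hough radius window as fractions of the image side.
#' @param rotate normalize ICM pose before measuring (skipped, with the
#'   image left as-is, when no ICM is detectable).
#' @return Object of class \code{feature_params}.
#' @export
feature_params <- function(target_mean = 128, target_sd = 30,
                           ring_fraction = 0.25,
                           glcm = glcm_spec(),
                           h_min = 10,
                           r_window = c(0.20, 0.45),
                           rotate = TRUE) {
  structure(list(target_mean = target_mean, target_sd = target_sd,
                 ring_fraction = ring_fraction, glcm = glcm, h_min = h_min,
                 r_window = r_window, rotate = rotate),
            class = "feature_params")
}

#' Circularity features of the segmented embryo
#'
#' @param circle the detected \code{\link{embryo_circle}}.
#' @param embryo_mask boolean outline mask (data-driven, see
#'   \code{\link{estimate_embryo_mask}}).
#' @return Named list: \code{hough_peak}, \code{isoperimetric_ratio}
#'   (\eqn{4\pi A / P^2}), \code{radial_sd} (sd of boundary distance to the
#'   center, normalized by the radius).
#' @export
circularity_features <- function(circle, embryo_mask) {
  if (!any(embryo_mask)) abort2("embryo mask is empty", "degenerate_input_error")
  a <- sum(embryo_mask)
  p <- mask_perimeter(embryo_mask)
  pts <- mask_contour(embryo_mask)
  d <- sqrt((pts[, 1] - circle$cy)^2 + (pts[, 2] - circle$cx)^2)
  list(
    hough_peak = circle$accumulator_peak,
    isoperimetric_ratio = if (p > 0) 4 * pi * a / (p * p) else 0,
    radial_sd = stats::sd(d) / circle$r
  )
}

#' Per-region intensity statistics
#'
#' @param image numeric matrix.
#' @param masks a \code{\link{region_masks}} with embryo, ring and inner.
#' @return Nested list per region (embryo, ring, inner) of \code{mean},
#'   \code{sd}, \code{p10}, \code{p90}, \code{area_fraction} (relative to
#'   the embryo area).
#' @export
region_stats <- function(image, masks) {
  stopifnot_image(image)
  a_embryo <- sum(masks$embryo)
  out <- lapply(c(embryo = "embryo", ring = "ring", inner = "inner"), function(rn) {
    m <- masks[[rn]]
    if (is.null(m) || !any(m)) abort2(sprintf("region '%s' is empty", rn),
                                      "degenerate_input_error")
    v <- image[m]
    q <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
    list(mean = mean(v), sd = stats::sd(v), p10 = q[1], p90 = q[2],
         area_fraction = sum(m) / a_embryo)
  })
  out
}

#' Watershed-region summary statistics
#'
#' @param ws a \code{\link{watershed_regions}} result.
#' @return Named list: \code{n_regions}, \code{region_area_mean},
#'   \code{region_area_cv} (0 for a single region), \code{largest_fraction}.
#' @export
watershed_stats <- function(ws) {
  if (ws$n_regions < 1L) abort2("need at least one watershed region", "degenerate_input_error")
  areas <- tabulate(ws$labels[ws$labels > 0L], ws$n_regions)
  m <- mean(areas)
  list(
    n_regions = ws$n_regions,
    region_area_mean = m,
    region_area_cv = if (ws$n_regions > 1L) stats::sd(areas) / m else 0,
    largest_fraction = max(areas) / sum(areas)
  )
}

#' Assemble the full 36-variable descriptor of one micrograph
#'
#' Runs the whole measurement chain on a raw image: Hough circle detection,
#' within-circle brightness standardization, ICM pose normalization,
#' ring/inner partition, data-driven outline, GLCM texture at distances 1
#' and 2 (angle-averaged) and watershed statistics, and returns the values
#' in registry order.
#'
#' @param image numeric matrix on the 0..255 scale.
#' @param params a \code{\link{feature_params}}.
#' @return Named numeric vector of length 36 (class \code{feature_vector})
#'   with the registry as attribute \code{"provenance"}.
#' @export
assemble_vector <- function(image, params = feature_params()) {
  stopifnot_image(image)
  sz <- min(dim(image))
  circle <- detect_embryo_circle(image,
                                 r_min = round(params$r_window[1] * sz),
                                 r_max = round(params$r_window[2] * sz))
  std <- standardize_brightness(image, params$target_mean, params$target_sd,
                                mask = disk_mask(nrow(image), ncol(image),
                                                 circle$cy, circle$cx, circle$r))
  img <- std$image
  if (params$rotate) {
    ang <- tryCatch(locate_icm_angle(img, circle),
                    icm_not_found_error = function(e) NULL)
    if (!is.null(ang) && ang > 0)
      img <- rotate_icm_to_top(img, ang, center = c(circle$cy, circle$cx))
  }
  masks <- split_ring_and_inner(img, circle, params$ring_fraction)
  est_mask <- estimate_embryo_mask(img, circle)
  circ <- circularity_features(circle, est_mask)
  rs <- region_stats(img, masks)
  ws <- watershed_stats(watershed_regions(img, masks$embryo, h = params$h_min))

  hl <- list()
  for (reg in c("inner", "ring")) {
    for (d in c(1L, 2L)) {
      gm <- compute_glcm(img, masks[[reg]],
                         glcm_spec(levels = params$glcm$levels, distances = d,
                                   angles = params$glcm$angles,
                                   symmetric = params$glcm$symmetric,
                                   normalized = params$glcm$normalized))
      hl[[paste(reg, d, sep = "_")]] <- haralick_features(gm)
    }
  }
  avg <- function(reg, st) (hl[[paste(reg, 1, sep = "_")]][[st]] +
                            hl[[paste(reg, 2, sep = "_")]][[st]]) / 2

  reg_df <- feature_registry()
  vals <- c(
    circ_hough_peak = circ$hough_peak,
    circ_isoperimetric = circ$isoperimetric_ratio,
    circ_radial_sd = circ$radial_sd
  )
  for (reg in c("embryo", "ring", "inner"))
    for (st in c("mean", "sd", "p10", "p90"))
      vals[paste(reg, st, sep = "_")] <- rs[[reg]][[st]]
  vals["ring_area_frac"] <- rs$ring$area_fraction
  vals["inner_area_frac"] <- rs$inner$area_fraction
  for (reg in c("inner", "ring"))
    for (st in c("contrast", "correlation", "energy", "homogeneity", "entropy"))
      vals[paste(reg, "glcm", st, sep = "_")] <- avg(reg, st)
  for (reg in c("inner", "ring"))
    for (st in c("contrast", "energy"))
      vals[paste(reg, "glcm", st, "d2", sep = "_")] <- hl[[paste(reg, 2, sep = "_")]][[st]]
  vals["ws_n_regions"] <- ws$n_regions
  vals["ws_area_mean"] <- ws$region_area_mean
  vals["ws_area_cv"] <- ws$region_area_cv
  vals["ws_largest_frac"] <- ws$largest_fraction
  vals["embryo_radius_norm"] <- circle$r / sz

  vals <- vals[reg_df$name]
  bad <- !is.finite(vals)
  if (any(bad))
    abort2(paste("non-finite feature(s):", paste(names(vals)[bad], collapse = ", ")),
           "extraction_error")
  structure(vals, class = c("feature_vector", "numeric"), provenance = reg_df)
}

#' Extract the feature table of a whole dataset
#'
#' @param dataset list of \code{labeled_image} (see
#'   \code{\link{generate_dataset}} / \code{\link{read_dataset}}).
#' @param params a \code{\link{feature_params}}.
#' @return data.frame: \code{id}, the 36 registry features, \code{consensus}
#'   and \code{true_grade}.
#' @export
extract_features <- function(dataset, params = feature_params()) {
  reg <- feature_registry()
  mat <- t(vapply(dataset, function(li) as.numeric(assemble_vector(li$image, params)),
                  numeric(36L)))
  colnames(mat) <- reg$name
  out <- data.frame(id = seq_along(dataset), mat, check.names = FALSE)
  out$consensus <- vapply(dataset, function(li) as.integer(li$consensus), 0L)
  out$true_grade <- vapply(dataset, function(li) as.integer(li$truth$true_grade), 0L)
  out
}
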