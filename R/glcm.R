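# Gray-level co-occurrence matrices and Haralick texture statistics.

#' GLCM specification
#'
#' @param levels quantization bins (>= 2, default 32).
#' @param distances pixel offsets (default 1 and 2).
#' @param angles offset directions in degrees (default 0, 45, 90, 135).
#' @param symmetric count each pair in both orders.
#' @param normalized scale counts to sum to 1.
#' @return Object of class \code{glcm_spec}.
#' @export
glcm_spec <- function(levels = 32L, distances = c(1L, 2L),
                      angles = c(0, 45, 90, 135),
                      symmetric = TRUE, normalized = TRUE) {
  if (levels < 2L) abort2("levels must be >= 2", "configuration_error")
  if (any(distances < 1L)) abort2("distances must be >= 1", "configuration_error")
  structure(list(levels = as.integer(levels), distances = as.integer(distances),
                 angles = angles, symmetric = symmetric, normalized = normalized),
            class = "glcm_spec")
}

# (row, col) offset of one GLCM direction at distance d; angle 0 points
# along the row (horizontal pairs), 90 along the column, matching the
# usual GLCM convention.
glcm_offset <- function(angle, d) {
  switch(as.character(angle %% 180),
    "0" = c(0L, d),
    "45" = c(-d, d),
    "90" = c(-d, 0L),
    "135" = c(-d, -d),
    abort2("angle must be one of 0, 45, 90, 135", "configuration_error")
  )
}

# Quantize masked intensities to 1..levels over the mask's range; 0 outside.
quantize_levels <- function(image, mask, levels) {
  v <- image[mask]
  q <- matrix(0L, nrow(image), ncol(image))
  rng <- range(v)
  if (rng[2] - rng[1] < 1e-12) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(levels, floor((image[mask] - rng[1]) / (rng[2] - rng[1]) * levels) + 1L)
  }
  q
}

#' Compute a gray-level co-occurrence matrix inside a mask
#'
#' Counts quantized-intensity pairs at the requested distance/angle offsets,
#' restricted to pixel pairs that both lie in the mask; symmetrized and
#' normalized to sum to 1 when flagged. Offsets are aggregated by summing
#' counts before normalization.
#'
#' @param image numeric matrix.
#' @param mask boolean matrix.
#' @param spec a \code{\link{glcm_spec}}.
#' @return \code{levels x levels} numeric matrix.
#' @export
compute_glcm <- function(image, mask, spec = glcm_spec()) {
  stopifnot_image(image)
  if (sum(mask) < 2L) abort2("mask too small for GLCM", "degenerate_input_error")
  L <- spec$levels
  q <- quantize_levels(image, mask, L)
  counts <- matrix(0, L, L)
  nr <- nrow(q); nc <- ncol(q)
  for (d in spec$distances) {
    for (a in spec$angles) {
      off <- glcm_offset(a, d)
      r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
      c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
      if (!length(r1) || !length(c1)) next
      A <- q[r1, c1, drop = FALSE]
      B <- q[r1 + off[1], c1 + off[2], drop = FALSE]
      keep <- A > 0L & B > 0L
      if (!any(keep)) next
      idx <- (A[keep] - 1L) * L + B[keep]
      counts <- counts + matrix(tabulate(idx, L * L), L, L, byrow = TRUE)
    }
  }
  if (sum(counts) == 0)
    abort2("mask admits no co-occurring pixel pairs at the given offsets",
           "degenerate_input_error")
  if (spec$symmetric) counts <- counts + t(counts)
  if (spec$normalized) counts <- counts / sum(counts)
  counts
}

#' Haralick statistics of a normalized GLCM
#'
#' Contrast \eqn{\sum p(i,j)(i-j)^2}, energy \eqn{\sum p^2}, homogeneity
#' \eqn{\sum p/(1+|i-j|)}, entropy \eqn{-\sum p \log p} (natural log,
#' \eqn{0 \log 0 = 0}) and correlation from the marginal means/sds
#' (defined as 0 for a zero-variance matrix).
#'
#' @param glcm normalized co-occurrence matrix.
#' @return Named list with \code{contrast}, \code{correlation},
#'   \code{energy}, \code{homogeneity}, \code{entropy}.
#' @export
haralick_features <- function(glcm) {
  s <- sum(glcm)
  if (abs(s - 1) > 1e-6) glcm <- glcm / s
  L <- nrow(glcm)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  contrast <- sum(glcm * (i - j)^2)
  energy <- sum(glcm^2)
  homogeneity <- sum(glcm / (1 + abs(i - j)))
  p <- glcm[glcm > 0]
  entropy <- -sum(p * log(p))
  px <- rowSums(glcm); py <- colSums(glcm)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  correlation <- if (sx < 1e-12 || sy < 1e-12) 0 else
    (sum(i * j * glcm) - mux * muy) / (sx * sy)
  list(contrast = contrast, correlation = correlation, energy = energy,
       homogeneity = homogeneity, entropy = entropy)
}
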