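# Synthetic blastocyst micrograph generator with simulated examiner panels.
#
# Emulates the structures a grader sees in a 2-D bovine blastocyst
# micrograph: a bright zona pellucida shell, a trophectoderm band just
# inside it, a dark fluid-filled blastocoel, and a compact bright inner
# cell mass (ICM) at a random clock position. Image quality degrades with
# IETS grade (1 excellent/good, 2 regular, 3 poor) through intensity
# speckle, boundary irregularity, extracellular debris and ICM
# fragmentation. Three simulated examiners label each image with
# adjacent-grade confusion; the consensus is their mode.

#' Synthetic dataset configuration
#'
#' Defines the rendering geometry, grade priors, per-grade degradation and
#' the examiner error rate for the synthetic blastocyst generator. The
#' defaults are the package's reference study conditions: 256 px frames,
#' embryo radii 70--95 px, equiprobable grades and a 10\% adjacent-grade
#' examiner confusion.
#'
#' @param image_size side of the square frame in pixels.
#' @param embryo_radius_range numeric length-2, min/max embryo radius (px).
#' @param zona_thickness zona pellucida shell thickness as a fraction of the
#'   embryo radius.
#' @param grade_priors probability vector over grades 1..3; must sum to 1.
#' @param degradation data.frame with columns \code{grade}, \code{speckle_sd}
#'   (intensity units), \code{boundary_jitter} (fraction of radius),
#'   \code{debris_count} (integer), \code{icm_fragmentation} (0--1);
#'   \code{speckle_sd}, \code{boundary_jitter} and \code{debris_count} must
#'   strictly increase from grade 1 to grade 3.
#' @param examiner_confusion probability, in [0, 0.5), that a single
#'   examiner reports a grade adjacent to the true one.
#' @param seed default master seed for dataset generation.
#' @return An object of class \code{synth_config}.
#' @examples
#' cfg <- synth_config()
#' img <- render_embryo(cfg, grade = 1, seed = 7)
#' dim(img$image)
#' @export
synth_config <- function(image_size = 256L,
                         embryo_radius_range = c(70, 95),
                         zona_thickness = 0.12,
                         grade_priors = c(1, 1, 1) / 3,
                         degradation = default_degradation(),
                         examiner_confusion = 0.1,
                         seed = 42L) {
  cfg <- structure(list(
    image_size = as.integer(image_size),
    embryo_radius_range = as.numeric(embryo_radius_range),
    zona_thickness = zona_thickness,
    grade_priors = grade_priors,
    degradation = degradation,
    examiner_confusion = examiner_confusion,
    seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' Reference per-grade degradation table
#'
#' Speckle noise, boundary jitter, debris and ICM fragmentation all worsen
#' with grade, with mild overlap between adjacent grades.
#' @return data.frame with one row per grade 1..3.
#' @export
default_degradation <- function() {
  data.frame(
    grade = 1:3,
    speckle_sd = c(4, 9, 16),
    boundary_jitter = c(0.010, 0.035, 0.070),
    debris_count = c(0L, 4L, 9L),
    icm_fragmentation = c(0.05, 0.35, 0.70)
  )
}

validate_synth_config <- function(cfg) {
  if (abs(sum(cfg$grade_priors) - 1) > 1e-9 || length(cfg$grade_priors) != 3L)
    abort2("grade_priors must be 3 probabilities summing to 1", "configuration_error")
  if (cfg$examiner_confusion < 0 || cfg$examiner_confusion >= 0.5)
    abort2("examiner_confusion must lie in [0, 0.5)", "configuration_error")
  d <- cfg$degradation
  need <- c("grade", "speckle_sd", "boundary_jitter", "debris_count", "icm_fragmentation")
  if (!all(need %in% names(d)) || nrow(d) != 3L)
    abort2("degradation must have one row per grade with the standard columns", "configuration_error")
  d <- d[order(d$grade), ]
  for (col in c("speckle_sd", "boundary_jitter", "debris_count"))
    if (any(diff(d[[col]]) <= 0))
      abort2(sprintf("degradation$%s must strictly increase with grade", col), "configuration_error")
  rmax <- max(cfg$embryo_radius_range)
  if (rmax * (1 + cfg$zona_thickness) + 8 > cfg$image_size / 2)
    abort2("image_size too small to contain embryo_radius_range", "configuration_error")
  invisible(cfg)
}

# intensity palette (8-bit scale) of the rendered structures
.palette <- list(background = 40, blastocoel = 90, troph = 150, zona = 200, icm = 185)

#' Render one labeled synthetic blastocyst image
#'
#' Deterministic for fixed (config, grade, seed). The returned list carries
#' the 8-bit image, the geometric ground truth (true grade, ICM clock angle,
#' embryo circle, per-structure masks) and a simulated 3-examiner panel with
#' its mode consensus.
#'
#' @param config a \code{\link{synth_config}}.
#' @param grade true IETS grade in {1, 2, 3}.
#' @param seed integer seed for this image.
#' @return An object of class \code{labeled_image} with fields
#'   \code{image}, \code{truth}, \code{examiner_grades}, \code{consensus}.
#' @export
render_embryo <- function(config, grade, seed) {
  validate_synth_config(config)
  if (!grade %in% 1:3) abort2("grade must be 1, 2 or 3", "configuration_error")
  if (seed < 0) abort2("seed must be >= 0", "configuration_error")
  deg <- config$degradation[config$degradation$grade == grade, ]
  n <- config$image_size
  pal <- .palette

  img_and_truth <- with_seed(seed, {
    r <- runif(1, config$embryo_radius_range[1], config$embryo_radius_range[2])
    cy <- n / 2 + runif(1, -4, 4)
    cx <- n / 2 + runif(1, -4, 4)
    icm_angle <- runif(1, 0, 360)

    pg <- polar_grid(n, n, cy, cx)
    # smooth radial boundary perturbation from low-order harmonics with
    # 1/k amplitude decay (gentle ovality and bulges, not high-frequency
    # wiggle), unit-variance over angle, scaled by the grade's jitter
    # fraction
    ks <- 2:5
    amp <- rnorm(length(ks)) / ks; phs <- runif(length(ks), 0, 2 * pi)
    amp <- amp / sqrt(sum(amp^2) / 2)  # sd over theta of sum a_k cos(...) == 1
    th <- pg$theta * pi / 180
    delta <- matrix(0, n, n)
    for (j in seq_along(ks)) delta <- delta + amp[j] * cos(ks[j] * th + phs[j])
    Rb <- r * (1 + deg$boundary_jitter * delta)  # outer embryo boundary per pixel

    rho <- pg$rho
    embryo <- rho <= Rb
    zona <- embryo & rho > Rb * (1 - config$zona_thickness)
    troph <- embryo & !zona & rho > Rb * 0.75
    inner <- embryo & rho <= Rb * 0.75

    # inner cell mass: compact bright blob, fragmented at poor grades
    f <- deg$icm_fragmentation
    icm_dist <- 0.38 * r
    icm_cy <- cy - icm_dist * cos(icm_angle * pi / 180)
    icm_cx <- cx + icm_dist * sin(icm_angle * pi / 180)
    icm_r <- 0.28 * r * (1 - 0.45 * f)
    icm <- disk_mask(n, n, icm_cy, icm_cx, icm_r) & inner
    n_frag <- floor(f * 4)
    if (n_frag > 0) {
      for (k in seq_len(n_frag)) {
        a <- runif(1, 0, 2 * pi); d <- runif(1, 0.10, 0.30) * r
        fr <- runif(1, 0.07, 0.13) * r
        icm <- icm | (disk_mask(n, n, icm_cy + d * cos(a), icm_cx + d * sin(a), fr) & inner)
      }
    }
    blastocoel <- inner & !icm

    img <- matrix(pal$background, n, n)
    img[blastocoel] <- pal$blastocoel
    img[troph] <- pal$troph
    img[zona] <- pal$zona
    img[icm] <- pal$icm - 35 * f

    # debris: small off-embryo blobs
    n_debris <- deg$debris_count
    if (n_debris > 0) {
      for (k in seq_len(n_debris)) {
        dd <- runif(1, r * (1 + config$zona_thickness) + 6, n / 2 - 4)
        aa <- runif(1, 0, 2 * pi)
        dr <- runif(1, 2, 5)
        dv <- runif(1, 120, 220)
        dmask <- disk_mask(n, n, cy + dd * cos(aa), cx + dd * sin(aa), dr) & !embryo
        img[dmask] <- dv
      }
    }

    img <- EBImage::gblur(img, sigma = 1.2)
    img <- img + rnorm(n * n, 0, 1.5)                  # sensor noise
    img[embryo] <- img[embryo] + rnorm(sum(embryo), 0, deg$speckle_sd)
    img <- round(clip_intensity(img))

    list(
      image = img,
      truth = list(
        true_grade = as.integer(grade),
        icm_angle = icm_angle,
        circle = embryo_circle(cx = cx, cy = cy, r = r, accumulator_peak = 1),
        region_masks = list(zona = zona, trophectoderm = troph,
                            icm = icm, blastocoel = blastocoel)
      )
    )
  })

  ex <- simulate_examiners(grade, config$examiner_confusion, derive_seed(seed, 101L))
  structure(list(
    image = img_and_truth$image,
    truth = img_and_truth$truth,
    examiner_grades = ex,
    consensus = consensus_mode(ex)
  ), class = "labeled_image")
}

#' Simulate a three-examiner grading panel
#'
#' Each examiner independently reports the true grade with probability
#' \code{1 - confusion} and an adjacent grade otherwise; for true grade 2
#' the confusion mass splits equally between grades 1 and 3.
#'
#' @param true_grade grade in {1, 2, 3}.
#' @param confusion per-examiner adjacent-confusion probability in [0, 0.5).
#' @param seed integer seed.
#' @return Integer vector of 3 grades.
#' @export
simulate_examiners <- function(true_grade, confusion, seed) {
  if (confusion < 0 || confusion >= 0.5)
    abort2("confusion must lie in [0, 0.5)", "configuration_error")
  if (!true_grade %in% 1:3) abort2("true_grade must be 1, 2 or 3", "configuration_error")
  with_seed(seed, {
    u <- runif(3)
    side <- runif(3)
    g <- rep(as.integer(true_grade), 3)
    wrong <- u < confusion
    adj <- switch(as.character(true_grade),
      "1" = rep(2L, 3),
      "3" = rep(2L, 3),
      "2" = ifelse(side < 0.5, 1L, 3L)
    )
    g[wrong] <- adj[wrong]
    g
  })
}

#' Consensus grade of a three-examiner panel
#'
#' Returns the mode of the three grades; when all three differ the ordinal
#' median (grade 2) is returned.
#'
#' @param grades integer vector of 3 grades in {1, 2, 3}.
#' @return A single integer grade.
#' @export
consensus_mode <- function(grades) {
  if (length(grades) != 3L || !all(grades %in% 1:3))
    abort2("grades must be 3 values in {1, 2, 3}", "schema_error")
  counts <- tabulate(as.integer(grades), 3L)
  top <- which(counts == max(counts))
  if (length(top) == 1L) as.integer(top) else 2L
}

#' Draw true grades from the configured priors
#'
#' @param n number of draws.
#' @param priors probability vector over grades 1..3.
#' @param seed integer seed.
#' @return Integer vector of grades.
#' @export
draw_grades <- function(n, priors, seed) {
  if (abs(sum(priors) - 1) > 1e-9) abort2("priors must sum to 1", "configuration_error")
  with_seed(seed, sample.int(3L, n, replace = TRUE, prob = priors))
}

#' Generate a labeled synthetic dataset
#'
#' Grades are drawn from the configured priors; every image gets its own
#' seed derived deterministically from the master seed, so the full dataset
#' is byte-identical across runs.
#'
#' @param config a \code{\link{synth_config}}.
#' @param n number of images (>= 1).
#' @param seed master seed; defaults to \code{config$seed}.
#' @return List of \code{labeled_image} objects, with the grade vector in
#'   attribute \code{"grades"}.
#' @export
generate_dataset <- function(config, n, seed = config$seed) {
  validate_synth_config(config)
  if (n < 1) abort2("n must be >= 1", "configuration_error")
  grades <- draw_grades(n, config$grade_priors, derive_seed(seed, 1L))
  items <- lapply(seq_len(n), function(i)
    render_embryo(config, grades[i], derive_seed(seed, 1000L + i)))
  attr(items, "grades") <- grades
  items
}

#' Write a synthetic dataset to PNG images plus a CSV manifest
#'
#' @param dataset list of \code{labeled_image} (from
#'   \code{\link{generate_dataset}}).
#' @param dir output directory (created if needed).
#' @param write_masks also write per-structure ground-truth masks as
#'   single-channel PNGs.
#' @return Invisibly, the manifest data.frame (also written as
#'   \code{manifest.csv}).
#' @export
write_dataset <- function(dataset, dir, write_masks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    li <- dataset[[i]]
    fn <- sprintf("embryo_%04d.png", i)
    png::writePNG(li$image / 255, file.path(dir, fn))
    if (write_masks) {
      for (mn in names(li$truth$region_masks))
        png::writePNG(li$truth$region_masks[[mn]] * 1,
                      file.path(dir, sprintf("embryo_%04d_mask_%s.png", i, mn)))
    }
    data.frame(
      image_path = fn,
      true_grade = li$truth$true_grade,
      examiner1 = li$examiner_grades[1],
      examiner2 = li$examiner_grades[2],
      examiner3 = li$examiner_grades[3],
      consensus = li$consensus,
      icm_angle_deg = li$truth$icm_angle,
      cx = li$truth$circle$cx,
      cy = li$truth$circle$cy,
      r = li$truth$circle$r
    )
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param dir dataset directory containing \code{manifest.csv}.
#' @return List of \code{labeled_image} objects (without ground-truth masks).
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    arr <- png::readPNG(file.path(dir, m$image_path))
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    structure(list(
      image = round(arr * 255),
      truth = list(
        true_grade = m$true_grade,
        icm_angle = m$icm_angle_deg,
        circle = embryo_circle(cx = m$cx, cy = m$cy, r = m$r, accumulator_peak = 1),
        region_masks = NULL
      ),
      examiner_grades = c(m$examiner1, m$examiner2, m$examiner3),
      consensus = m$consensus
    ), class = "labeled_image")
  })
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf(
    "<labeled_image> %dx%d, true grade %d, examiners (%s), consensus %d\n",
    nrow(x$image), ncol(x$image), x$truth$true_grade,
    paste(x$examiner_grades, collapse = ","), x$consensus))
  invisible(x)
}
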