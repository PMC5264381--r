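test_that("GLCM matches a brute-force pair count on a small fixture", {
  img <- fix_seeded(5, matrix(sample(0:255, 36, replace = TRUE), 6, 6))
  mask <- matrix(TRUE, 6, 6); mask[1, 1] <- FALSE
  spec <- glcm_spec(levels = 4, distances = 1, angles = 0,
                    symmetric = FALSE, normalized = FALSE)
  got <- compute_glcm(img, mask, spec)

  # independent oracle: explicit double loop over horizontal pairs
  v <- img[mask]
  q <- matrix(0L, 6, 6)
  rng <- range(v)
  q[mask] <- pmin(4, floor((img[mask] - rng[1]) / (rng[2] - rng[1]) * 4) + 1)
  want <- matrix(0, 4, 4)
  for (r in 1:6) for (cc in 1:5)
    if (q[r, cc] > 0 && q[r, cc + 1] > 0)
      want[q[r, cc], q[r, cc + 1]] <- want[q[r, cc], q[r, cc + 1]] + 1
  expect_equal(got, want)
})

test_that("GLCM closed forms: constant image and checkerboard", {
  const <- matrix(100, 16, 16)
  m <- matrix(TRUE, 16, 16)
  g <- compute_glcm(const, m, glcm_spec(levels = 8, distances = 1))
  expect_equal(sum(g), 1)
  expect_equal(g[1, 1], 1)  # single co-occurring pair type on the diagonal

  hl <- haralick_features(g)
  expect_equal(hl$contrast, 0)
  expect_equal(hl$energy, 1)
  expect_equal(hl$homogeneity, 1)
  expect_equal(hl$entropy, 0)

  # 2-level checkerboard at distance 1, angle 0: all mass off-diagonal,
  # contrast (L-1)^2 with L = 2 levels
  cb <- checkerboard_image(16)
  g2 <- compute_glcm(cb, m, glcm_spec(levels = 2, distances = 1, angles = 0))
  expect_equal(sum(diag(g2)), 0)
  expect_equal(haralick_features(g2)$contrast, 1)
})

test_that("GLCM normalization and Haralick bounds hold on random fixtures", {
  for (s in 1:100) {
    img <- fix_seeded(s, matrix(runif(144, 0, 255), 12, 12))
    mask <- fix_seeded(s + 1000, matrix(runif(144) < 0.8, 12, 12))
    if (sum(mask) < 6) next
    g <- compute_glcm(img, mask, glcm_spec(levels = 8))
    expect_equal(sum(g), 1, tolerance = 1e-9)
    hl <- haralick_features(g)
    expect_true(hl$energy > 0 && hl$energy <= 1)
    expect_true(hl$homogeneity > 0 && hl$homogeneity <= 1)
    expect_gte(hl$entropy, 0)
    expect_gte(hl$contrast, 0)
    expect_true(abs(hl$correlation) <= 1 + 1e-9)
  }
})

test_that("mask too small for the offsets is a degenerate input", {
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE; m[8, 8] <- TRUE
  expect_error(compute_glcm(matrix(1:64, 8, 8), m,
                            glcm_spec(levels = 4, distances = 1)),
               class = "degenerate_input_error")
})

test_that("circularity features follow closed-form shapes", {
  # ideal disk: isoperimetric ratio ~ 1, tiny radial sd
  dsk <- fix_disk(201, 201, 101, 101, 80)
  circ <- embryo_circle(cx = 101, cy = 101, r = 80, accumulator_peak = 0.95)
  cf <- circularity_features(circ, dsk)
  expect_equal(cf$hough_peak, 0.95)
  expect_gt(cf$isoperimetric_ratio, 0.95)
  expect_lt(cf$isoperimetric_ratio, 1.05)
  expect_lt(cf$radial_sd, 0.02)

  # square of side a: 4*pi*a^2 / (4a)^2 = pi/4 (digital perimeter bias
  # allows ~10%)
  sq <- matrix(FALSE, 201, 201); sq[51:150, 51:150] <- TRUE
  cfs <- circularity_features(embryo_circle(cx = 100.5, cy = 100.5, r = 50), sq)
  expect_equal(cfs$isoperimetric_ratio, pi / 4, tolerance = 0.1)
})

test_that("boundary irregularity raises radial_sd from grade 1 to grade 3", {
  cfg <- synth_config()
  rsd <- function(g, s) {
    li <- render_embryo(cfg, g, s)
    circ <- detect_embryo_circle(li$image)
    circularity_features(circ, estimate_embryo_mask(li$image, circ))$radial_sd
  }
  r1 <- vapply(1:5, function(s) rsd(1, 300 + s), 0)
  r3 <- vapply(1:5, function(s) rsd(3, 300 + s), 0)
  expect_gt(mean(r3), mean(r1))
})

test_that("region statistics summarize intensity and area correctly", {
  img <- ideal_disk_image(128, r = 40, lo = 30, hi = 90)
  circ <- embryo_circle(cx = 64.5, cy = 64.5, r = 40)
  masks <- split_ring_and_inner(img, circ)
  rs <- region_stats(img, masks)
  # constant regions: sd 0, p10 == p90 == mean
  expect_equal(rs$inner$sd, 0)
  expect_equal(rs$inner$p10, rs$inner$mean)
  expect_equal(rs$inner$p90, rs$inner$mean)
  # partition of area fractions
  expect_equal(rs$ring$area_fraction + rs$inner$area_fraction, 1, tolerance = 1e-6)

  # bright ring / dark inner ordering on a synthetic render
  li <- render_embryo(synth_config(), grade = 1, seed = 3)
  circ2 <- li$truth$circle
  rs2 <- region_stats(li$image, split_ring_and_inner(li$image, circ2))
  expect_gt(rs2$ring$mean, rs2$inner$mean)
})

test_that("watershed statistics cover the degenerate and two-basin cases", {
  one <- structure(list(labels = matrix(c(0L, 1L, 1L, 1L), 2, 2), n_regions = 1L),
                   class = "watershed_labels")
  ws1 <- watershed_stats(one)
  expect_equal(ws1$region_area_cv, 0)
  expect_equal(ws1$largest_fraction, 1)

  fx <- two_blob_fixture()
  ws <- watershed_stats(watershed_regions(fx$image, fx$mask, h = 5))
  expect_equal(ws$n_regions, 2L)
  expect_lt(ws$region_area_cv, 0.05)
  expect_equal(ws$largest_fraction, 0.5, tolerance = 0.05)
  expect_equal(ws$region_area_mean * ws$n_regions, sum(fx$mask))
})

test_that("assemble_vector returns 36 registry-ordered finite features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 36L)
  li <- ref_dataset()[[1]]
  fv <- assemble_vector(li$image)
  expect_length(fv, 36L)
  expect_identical(names(fv), reg$name)
  expect_true(all(is.finite(fv)))
  # determinism
  expect_identical(as.numeric(fv), as.numeric(assemble_vector(li$image)))
})

test_that("the isoperimetric shape feature is rotation invariant", {
  li <- render_embryo(synth_config(), grade = 1, seed = 12)
  fv <- assemble_vector(li$image)
  rot90 <- t(li$image)[, nrow(li$image):1]  # 90-degree rotation
  fv90 <- assemble_vector(rot90)
  expect_equal(fv90[["circ_isoperimetric"]], fv[["circ_isoperimetric"]],
               tolerance = 0.02)
})

test_that("inner-region GLCM contrast increases across grade cohorts", {
  cfg <- synth_config()
  contrast_of <- function(g, s) {
    li <- render_embryo(cfg, g, 5000 + s)
    tr <- li$truth$circle
    inner <- fix_disk(256, 256, tr$cy, tr$cx, tr$r * 0.75)
    haralick_features(compute_glcm(li$image, inner, glcm_spec(distances = 1)))$contrast
  }
  m <- vapply(1:3, function(g) mean(vapply(1:30, function(s) contrast_of(g, s), 0)), 0)
  expect_true(all(diff(m) > 0))
})
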