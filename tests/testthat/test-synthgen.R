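test_that("rendering is deterministic and grade-structured", {
  cfg <- synth_config()
  a <- render_embryo(cfg, grade = 1, seed = 7)
  b <- render_embryo(cfg, grade = 1, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$examiner_grades, b$examiner_grades)
  expect_equal(a$truth$true_grade, 1L)

  # grade-3 degradation raises within-embryo intensity variance
  g3 <- render_embryo(cfg, grade = 3, seed = 7)
  emb <- function(li) with(li$truth$region_masks, zona | trophectoderm | icm | blastocoel)
  expect_gt(var(g3$image[emb(g3)]), var(a$image[emb(a)]))

  # image dimensions and 8-bit range
  expect_equal(dim(a$image), c(256L, 256L))
  expect_true(all(a$image >= 0 & a$image <= 255))
})

test_that("ground-truth region masks are disjoint and lie within the embryo", {
  li <- render_embryo(synth_config(), grade = 2, seed = 11)
  m <- li$truth$region_masks
  overlap <- m$zona + m$trophectoderm + m$icm + m$blastocoel
  expect_true(all(overlap <= 1L))
  cir <- li$truth$circle
  allowed <- fix_disk(nrow(li$image), ncol(li$image), cir$cy, cir$cx,
                      cir$r * (1 + 0.12) * 1.35)  # jitter + zona headroom
  expect_true(all(!(overlap > 0 & !allowed)))
  expect_true(li$truth$icm_angle >= 0 && li$truth$icm_angle < 360)
})

test_that("a zero debris count leaves nothing bright outside the embryo", {
  # grade 1 carries no debris under the reference degradation table
  li <- render_embryo(synth_config(), grade = 1, seed = 1)
  outside <- !fix_disk(256, 256, li$truth$circle$cy, li$truth$circle$cx,
                       li$truth$circle$r * 1.2)
  expect_equal(sum(li$image > 100 & outside), 0L)
  # grade 3 does scatter debris there
  li3 <- render_embryo(synth_config(), grade = 3, seed = 1)
  outside3 <- !fix_disk(256, 256, li3$truth$circle$cy, li3$truth$circle$cx,
                        li3$truth$circle$r * 1.2)
  expect_gt(sum(li3$image > 100 & outside3), 0L)
})

test_that("examiner panels follow the adjacent-confusion model", {
  # no confusion: unanimous truth
  expect_identical(simulate_examiners(2, 0, seed = 5), rep(2L, 3))
  # adjacent-only: grade 3 never reported as 1
  for (s in 1:50) expect_false(1L %in% simulate_examiners(3, 0.2, seed = s))
  # Monte-Carlo rate: labels equal truth with probability 1 - confusion
  labs <- unlist(lapply(1:4000, function(s) simulate_examiners(1, 0.2, seed = s)))
  expect_equal(mean(labs == 1L), 0.8, tolerance = 0.025)
  # grade 2 confusion splits between 1 and 3 roughly equally
  labs2 <- unlist(lapply(1:4000, function(s) simulate_examiners(2, 0.3, seed = s)))
  wrong <- labs2[labs2 != 2L]
  expect_equal(mean(wrong == 1L), 0.5, tolerance = 0.05)
})

test_that("consensus mode matches the exhaustive counting oracle", {
  expect_equal(consensus_mode(c(1, 1, 3)), 1L)
  expect_equal(consensus_mode(c(1, 2, 3)), 2L)
  triples <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  for (i in seq_len(nrow(triples))) {
    g <- as.integer(unlist(triples[i, ]))
    counts <- c(sum(g == 1), sum(g == 2), sum(g == 3))
    oracle <- if (max(counts) >= 2) which.max(counts) else sort(g)[2]
    expect_equal(consensus_mode(g), as.integer(oracle))
  }
})

test_that("dataset generation is deterministic and respects priors", {
  cfg <- synth_config()
  d1 <- generate_dataset(cfg, 1, seed = 0)
  d2 <- generate_dataset(cfg, 1, seed = 0)
  expect_identical(d1[[1]]$image, d2[[1]]$image)
  expect_identical(d1[[1]]$examiner_grades, d2[[1]]$examiner_grades)

  # degenerate prior: every grade 1
  cfg1 <- synth_config(grade_priors = c(1, 0, 0))
  g <- draw_grades(50, cfg1$grade_priors, seed = 3)
  expect_true(all(g == 1L))

  # empirical frequencies converge to the priors (3 multinomial sd at 1e4)
  pr <- c(0.5, 0.3, 0.2)
  g <- draw_grades(10000, pr, seed = 21)
  freq <- tabulate(g, 3) / 10000
  expect_true(all(abs(freq - pr) <= 3 * sqrt(pr * (1 - pr) / 10000)))
})

test_that("the reference dataset has experiment size and valid consensus labels", {
  ds <- ref_dataset()
  expect_length(ds, 126L)
  for (li in ds[c(1, 50, 126)])
    expect_equal(li$consensus, consensus_mode(li$examiner_grades))
})

test_that("maximal degradation contrast is separable by embryo variance alone", {
  cfg <- synth_config(examiner_confusion = 0)
  v <- function(g, s) {
    li <- render_embryo(cfg, g, s)
    m <- with(li$truth$region_masks, zona | trophectoderm | icm | blastocoel)
    var(li$image[m])
  }
  v1 <- vapply(1:12, function(s) v(1, 9000 + s), 0)
  v3 <- vapply(1:12, function(s) v(3, 9000 + s), 0)
  # a single threshold separates the cohorts perfectly
  expect_lt(max(v1), min(v3))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(grade_priors = c(0.5, 0.5, 0.5)), class = "configuration_error")
  expect_error(synth_config(examiner_confusion = 0.6), class = "configuration_error")
  bad <- default_degradation(); bad$speckle_sd <- c(5, 5, 5)
  expect_error(synth_config(degradation = bad), class = "configuration_error")
  expect_error(synth_config(image_size = 64L), class = "configuration_error")
  expect_error(simulate_examiners(2, 0.7, 1), class = "configuration_error")
})

test_that("datasets round-trip through PNG + manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synth_config(), 3, seed = 5)
  man <- write_dataset(ds, dir)
  expect_equal(nrow(man), 3L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  expect_identical(back[[2]]$image, ds[[2]]$image)
  expect_equal(back[[2]]$consensus, ds[[2]]$consensus)
  expect_equal(back[[2]]$truth$circle$r, ds[[2]]$truth$circle$r, tolerance = 1e-6)
})
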