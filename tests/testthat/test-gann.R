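test_that("split sizes follow largest-remainder rounding", {
  # n = 126 at 0.70/0.15/0.15 -> 88/19/19
  y <- rep(1:3, each = 42)
  sp <- split_dataset(126, split_spec(seed = 1), labels = y)
  expect_equal(vapply(sp, length, 0L), c(train = 88L, valid = 19L, test = 19L))

  # exact fractions at n = 100
  sp100 <- split_dataset(100, split_spec(seed = 1, stratified = FALSE))
  expect_equal(vapply(sp100, length, 0L), c(train = 70L, valid = 15L, test = 15L))

  # partition contract
  expect_setequal(unlist(sp), 1:126)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$train, sp$valid), 0L)
  expect_length(intersect(sp$valid, sp$test), 0L)
})

test_that("stratified splits balance classes and are deterministic", {
  y <- c(rep(1L, 60), rep(2L, 40), rep(3L, 26))
  sp <- split_dataset(126, split_spec(seed = 9), labels = y)
  for (part in sp) {
    tab <- tabulate(y[part], 3)
    expect_true(all(tab >= 1L))
  }
  # class proportions in train close to the population's
  expect_equal(tabulate(y[sp$train], 3) / 88, c(60, 40, 26) / 126, tolerance = 0.03)

  sp2 <- split_dataset(126, split_spec(seed = 9), labels = y)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(126, split_spec(seed = 10), labels = y)
  expect_false(identical(sp, sp3))

  # a class too rare to appear in all splits is an error
  y_bad <- c(rep(1L, 124), 2L, 3L)
  expect_error(split_dataset(126, split_spec(seed = 1), labels = y_bad),
               class = "stratification_error")
  expect_error(split_dataset(5, split_spec()), class = "configuration_error")
  expect_error(split_spec(0.7, 0.2, 0.2), class = "configuration_error")
})

test_that("training solves linearly separable data and is seed-deterministic", {
  d <- separable_blobs()
  g <- ann_genome(n_hidden_layers = 1, hidden_sizes = c(8, 8),
                  activation = "tanh", learning_rate = 0.05, momentum = 0.8,
                  epochs = 80, weight_seed = 5)
  m <- train_ann(g, d$X, d$y)
  acc <- mean(predict_grade(m, d$X)$grades == d$y)
  expect_gte(acc, 0.95)
  expect_length(m$train_loss_curve, 80L)
  expect_lt(tail(m$train_loss_curve, 1), m$train_loss_curve[1])

  m2 <- train_ann(g, d$X, d$y)
  expect_identical(m$weights, m2$weights)

  # independent learner cross-check: nnet reaches the same regime
  skip_if_not_installed("nnet")
  nn <- nnet::nnet(d$X, nnet::class.ind(d$y), size = 8, softmax = TRUE,
                   maxit = 200, trace = FALSE)
  expect_gte(mean(max.col(predict(nn, d$X)) == d$y), 0.95)
})

test_that("zero epochs returns the untouched initialization", {
  d <- separable_blobs(n_per_class = 10)
  g <- ann_genome(epochs = 0, weight_seed = 3)
  m <- train_ann(g, d$X, d$y)
  expect_length(m$train_loss_curve, 0L)
  m2 <- train_ann(g, d$X, d$y)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$biases, m2$biases)
})

test_that("divergent learning rates raise a divergence error naming the rate", {
  d <- separable_blobs(n_per_class = 30, p = 4)
  g <- ann_genome(hidden_sizes = c(64, 64), n_hidden_layers = 2,
                  activation = "relu", learning_rate = 0.3, momentum = 0.95,
                  epochs = 200, weight_seed = 1)
  err <- tryCatch(train_ann(g, d$X * 1e6, d$y), condition = function(e) e)
  expect_s3_class(err, "divergence_error")
  expect_match(conditionMessage(err), "0.3")
})

test_that("prediction returns calibrated softmax output with a low-grade tie rule", {
  d <- separable_blobs(n_per_class = 20)
  m <- train_ann(ann_genome(epochs = 30, weight_seed = 2), d$X, d$y)
  pr <- predict_grade(m, d$X)
  expect_true(all(abs(rowSums(pr$probabilities) - 1) < 1e-9))
  expect_true(all(pr$grades %in% 1:3))

  # exact tie (all-zero weights): every class equal, lower grade wins
  stub <- linear_stub_model(matrix(0, 4, 3))
  expect_equal(predict_grade(stub, rep(1, 4))$grade, 1L)

  expect_error(predict_grade(m, rep(0, 5)), class = "schema_error")
})

test_that("blind evaluation matches a hand-counted confusion matrix", {
  # identity stub: score_k = x_k, so the argmax is the one-hot class
  stub <- linear_stub_model(diag(3))
  X <- rbind(
    c(9, 0, 0), c(0, 9, 0), c(0, 0, 9),  # predicted 1, 2, 3
    c(9, 0, 0), c(0, 0, 9), c(0, 0, 9)   # predicted 1, 3, 3
  )
  y <- c(1, 2, 3, 2, 1, 2)
  ev <- evaluate_blind(stub, X, y)
  # hand count: correct on rows 1-3; row 4 consensus 2 pred 1; row 5
  # consensus 1 pred 3 (critical); row 6 consensus 2 pred 3
  expect_equal(ev$exact_accuracy, 3 / 6)
  expect_equal(ev$n_test, 6L)
  expect_equal(ev$critical_errors, 1L)
  want <- matrix(0L, 3, 3, dimnames = list(consensus = 1:3, predicted = 1:3))
  want[1, 1] <- 1L; want[2, 2] <- 1L; want[3, 3] <- 1L
  want[2, 1] <- 1L; want[1, 3] <- 1L; want[2, 3] <- 1L
  expect_equal(ev$confusion, want)
  expect_equal(ev$critical_errors, ev$confusion[1, 3] + ev$confusion[3, 1])

  # a constant grade-2 predictor can never commit a critical error
  const2 <- linear_stub_model(matrix(0, 3, 3), b = c(0, 9, 0))
  ev2 <- evaluate_blind(const2, X, y)
  expect_equal(ev2$critical_errors, 0L)
})

test_that("a perfect predictor scores 1.0 with zero critical errors", {
  stub <- linear_stub_model(diag(3))
  X <- diag(3) * 9
  ev <- evaluate_blind(stub, X, 1:3)
  expect_equal(ev$exact_accuracy, 1)
  expect_equal(ev$critical_errors, 0L)
})

test_that("the GA is elitist, deterministic and never ends below the baseline", {
  d <- noisy_blobs()
  sp <- split_dataset(nrow(d$X), split_spec(seed = 2), labels = d$y)
  Xtr <- d$X[sp$train, ]; ytr <- d$y[sp$train]
  Xva <- d$X[sp$valid, ]; yva <- d$y[sp$valid]

  # small deterministic run
  cfg <- ga_config(n_islands = 1, island_size = 4, generations = 2, seed = 5)
  r1 <- ga_evolve(Xtr, ytr, Xva, yva, cfg)
  r2 <- ga_evolve(Xtr, ytr, Xva, yva, cfg)
  expect_identical(r1$best_genome, r2$best_genome)
  expect_identical(r1$history, r2$history)

  # elitism: best fitness is non-decreasing in every run
  expect_true(all(diff(r1$history$best_fitness) >= 0))

  # 20-generation reference-shaped run beats (or ties) the seeded baseline
  cfg20 <- ga_config(n_islands = 2, island_size = 6, generations = 20,
                     migration_interval = 5, seed = 11)
  r20 <- ga_evolve(Xtr, ytr, Xva, yva, cfg20)
  expect_true(all(diff(r20$history$best_fitness) >= 0))
  base <- train_ann(default_genome(), Xtr, ytr)
  base_acc <- mean(predict_grade(base, Xva)$grades == yva)
  expect_gte(r20$best_fitness, base_acc)

  expect_error(ga_evolve(Xtr, ytr, Xtr[0, , drop = FALSE], integer(0), cfg),
               class = "configuration_error")
})

test_that("genome validation rejects out-of-range hyperparameters", {
  expect_error(ann_genome(n_hidden_layers = 3), class = "configuration_error")
  expect_error(ann_genome(hidden_sizes = c(1, 8)), class = "configuration_error")
  expect_error(ann_genome(activation = "softplus"), class = "configuration_error")
  expect_error(ann_genome(momentum = 1), class = "configuration_error")
  sp <- genome_space()
  g <- fix_seeded(1, random_genome(sp))
  expect_s3_class(g, "ann_genome")
})
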