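# Feed-forward softmax classifier trained by seeded mini-batch gradient
# descent with momentum; the genome describes everything the island GA is
# allowed to evolve (topology + training hyperparameters).

#' Network genome
#'
#' The evolvable description of one classifier: topology (1 or 2 hidden
#' layers of 2--64 units), activation, and the backprop hyperparameters.
#'
#' @param n_hidden_layers 1 or 2.
#' @param hidden_sizes integer vector of layer widths (length 2; only the
#'   first \code{n_hidden_layers} are used).
#' @param activation one of \code{"logistic"}, \code{"tanh"}, \code{"relu"}.
#' @param learning_rate positive step size.
#' @param momentum in [0, 1).
#' @param epochs training epochs (>= 0).
#' @param weight_seed seed for weight initialization and batch shuffling.
#' @return Object of class \code{ann_genome}.
#' @export
ann_genome <- function(n_hidden_layers = 1L, hidden_sizes = c(16L, 8L),
                       activation = "logistic", learning_rate = 0.05,
                       momentum = 0.9, epochs = 150L, weight_seed = 1L) {
  g <- structure(list(
    n_hidden_layers = as.integer(n_hidden_layers),
    hidden_sizes = as.integer(rep_len(hidden_sizes, 2L)),
    activation = activation,
    learning_rate = learning_rate,
    momentum = momentum,
    epochs = as.integer(epochs),
    weight_seed = as.integer(weight_seed)
  ), class = "ann_genome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  sp <- genome_space()
  if (!g$n_hidden_layers %in% sp$n_hidden_layers)
    abort2("n_hidden_layers must be 1 or 2", "configuration_error")
  if (any(g$hidden_sizes < sp$hidden_range[1]) || any(g$hidden_sizes > sp$hidden_range[2]))
    abort2("hidden_sizes out of range", "configuration_error")
  if (!g$activation %in% sp$activations)
    abort2("unknown activation", "configuration_error")
  if (g$learning_rate <= 0) abort2("learning_rate must be positive", "configuration_error")
  if (g$momentum < 0 || g$momentum >= 1) abort2("momentum must lie in [0, 1)", "configuration_error")
  if (g$epochs < 0) abort2("epochs must be >= 0", "configuration_error")
  invisible(g)
}

#' The genome search space
#'
#' @return Named list of admissible ranges for every gene.
#' @export
genome_space <- function() {
  list(
    n_hidden_layers = 1:2,
    hidden_range = c(2L, 64L),
    activations = c("logistic", "tanh", "relu"),
    lr_log10_range = c(-3, log10(0.3)),
    momentum_range = c(0, 0.95),
    epochs_range = c(40L, 250L),
    weight_seed_range = c(1L, 1000000L)
  )
}

#' Draw a random genome (uses the current RNG stream)
#' @param space a \code{\link{genome_space}}.
#' @return An \code{ann_genome}.
#' @export
random_genome <- function(space = genome_space()) {
  ann_genome(
    n_hidden_layers = sample(space$n_hidden_layers, 1L),
    hidden_sizes = sample(seq(space$hidden_range[1], space$hidden_range[2]), 2L,
                          replace = TRUE),
    activation = sample(space$activations, 1L),
    learning_rate = 10^runif(1, space$lr_log10_range[1], space$lr_log10_range[2]),
    momentum = runif(1, space$momentum_range[1], space$momentum_range[2]),
    epochs = sample(seq(space$epochs_range[1], space$epochs_range[2]), 1L),
    weight_seed = sample(seq(space$weight_seed_range[1], space$weight_seed_range[2]), 1L)
  )
}

#' The fixed baseline genome
#'
#' A sensible hand-chosen network; the GA must never end below it because
#' it is seeded into the initial population and protected by elitism.
#' @return An \code{ann_genome}.
#' @export
default_genome <- function() {
  ann_genome(n_hidden_layers = 1L, hidden_sizes = c(12L, 8L),
             activation = "tanh", learning_rate = 0.05, momentum = 0.8,
             epochs = 120L, weight_seed = 17L)
}

genome_key <- function(g) {
  paste(g$n_hidden_layers, paste(g$hidden_sizes, collapse = "x"), g$activation,
        signif(g$learning_rate, 8), signif(g$momentum, 8), g$epochs,
        g$weight_seed, sep = "|")
}

.act <- function(z, a) switch(a,
  logistic = 1 / (1 + exp(-z)),
  tanh = tanh(z),
  relu = pmax(z, 0))

.act_grad <- function(h, a) switch(a,
  logistic = h * (1 - h),
  tanh = 1 - h * h,
  relu = (h > 0) * 1)

ann_forward <- function(W, b, activation, X) {
  H <- list()
  A <- X
  nl <- length(W)
  for (l in seq_len(nl - 1L)) {
    A <- .act(A %*% W[[l]] + matrix(b[[l]], nrow(A), length(b[[l]]), byrow = TRUE),
              activation)
    H[[l]] <- A
  }
  Z <- A %*% W[[nl]] + matrix(b[[nl]], nrow(A), length(b[[nl]]), byrow = TRUE)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(hidden = H, probs = P)
}

#' Train the network described by a genome
#'
#' Mini-batch gradient descent with momentum on the softmax cross-entropy,
#' for exactly \code{genome$epochs} epochs. Inputs are z-scored with a
#' scaler fit on the supplied (training) rows and stored in the model; all
#' randomness (weight init, batch shuffling) derives from
#' \code{genome$weight_seed}, so retraining is bit-reproducible.
#'
#' @param genome an \code{\link{ann_genome}}.
#' @param X n x p numeric matrix of features (training rows only).
#' @param y integer grades in {1, 2, 3}.
#' @param batch_size mini-batch size (default 16).
#' @return Object of class \code{trained_ann}: genome, scaler, weights,
#'   biases, \code{train_loss_curve} (one mean cross-entropy per epoch),
#'   \code{input_dim}, \code{output_dim}.
#' @export
train_ann <- function(genome, X, y, batch_size = 16L) {
  validate_genome(genome)
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort2("X must be finite", "schema_error")
  if (!all(y %in% 1:3)) abort2("y must contain grades in {1, 2, 3}", "schema_error")
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  sg <- apply(X, 2L, stats::sd)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  Y <- matrix(0, n, 3L); Y[cbind(seq_len(n), as.integer(y))] <- 1

  sizes <- c(p, genome$hidden_sizes[seq_len(genome$n_hidden_layers)], 3L)
  nl <- length(sizes) - 1L

  model <- with_seed(genome$weight_seed, {
    W <- vector("list", nl); b <- vector("list", nl)
    vW <- vector("list", nl); vb <- vector("list", nl)
    for (l in seq_len(nl)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim), sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
      vW[[l]] <- W[[l]] * 0; vb[[l]] <- b[[l]] * 0
    }
    loss_curve <- numeric(0)
    if (genome$epochs > 0L) {
      lr <- genome$learning_rate; mo <- genome$momentum
      act <- genome$activation
      for (ep in seq_len(genome$epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        for (start in seq(1L, n, by = batch_size)) {
          bi <- ord[start:min(n, start + batch_size - 1L)]
          Xb <- Xs[bi, , drop = FALSE]; Yb <- Y[bi, , drop = FALSE]
          fw <- ann_forward(W, b, act, Xb)
          P <- fw$probs
          ep_loss <- ep_loss - sum(log(pmax(P[Yb == 1], 1e-300)))
          delta <- (P - Yb) / length(bi)
          for (l in rev(seq_len(nl))) {
            Ain <- if (l == 1L) Xb else fw$hidden[[l - 1L]]
            gW <- crossprod(Ain, delta)
            gb <- colSums(delta)
            if (l > 1L)
              delta <- (delta %*% t(W[[l]])) * .act_grad(fw$hidden[[l - 1L]], act)
            vW[[l]] <- mo * vW[[l]] - lr * gW
            vb[[l]] <- mo * vb[[l]] - lr * gb
            W[[l]] <- W[[l]] + vW[[l]]
            b[[l]] <- b[[l]] + vb[[l]]
          }
        }
        ep_loss <- ep_loss / n
        if (!is.finite(ep_loss))
          abort2(sprintf("training diverged (non-finite loss) at learning_rate %.4g",
                         lr), "divergence_error")
        loss_curve[ep] <- ep_loss
      }
    }
    list(W = W, b = b, loss_curve = loss_curve)
  })

  structure(list(
    genome = genome,
    scaler = list(mean = mu, sd = sg),
    weights = model$W,
    biases = model$b,
    activation = genome$activation,
    train_loss_curve = model$loss_curve,
    input_dim = p,
    output_dim = 3L
  ), class = "trained_ann")
}

#' Predict the grade of one or more feature vectors
#'
#' Applies the model's stored z-score scaler, runs the forward pass and
#' returns the argmax grade (exact probability ties resolve toward the
#' lower, i.e. better, grade) along with the softmax probabilities.
#'
#' @param model a \code{\link{train_ann}} result.
#' @param x numeric vector of length \code{input_dim}, or a matrix with
#'   that many columns.
#' @return For a vector: list(\code{grade}, \code{probabilities}). For a
#'   matrix: list(\code{grades}, \code{probabilities}) (n x 3).
#' @export
predict_grade <- function(model, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1L) else as.matrix(x)
  if (ncol(X) != model$input_dim)
    abort2(sprintf("expected %d features, got %d", model$input_dim, ncol(X)),
           "schema_error")
  Xs <- sweep(sweep(X, 2L, model$scaler$mean), 2L, model$scaler$sd, "/")
  P <- ann_forward(model$weights, model$biases, model$activation, Xs)$probs
  grades <- apply(P, 1L, which.max)  # first max == lowest grade on ties
  if (single) list(grade = as.integer(grades[1]), probabilities = as.numeric(P[1, ]))
  else list(grades = as.integer(grades), probabilities = P)
}

#' @export
print.trained_ann <- function(x, ...) {
  g <- x$genome
  cat(sprintf("<trained_ann> %d-%s-3 (%s), lr %.3g, momentum %.2f, %d epochs\n",
              x$input_dim,
              paste(g$hidden_sizes[seq_len(g$n_hidden_layers)], collapse = "-"),
              g$activation, g$learning_rate, g$momentum, g$epochs))
  invisible(x)
}

#' Blind-test evaluation against the examiner-consensus template
#'
#' @param model a \code{\link{train_ann}} result.
#' @param X_test feature matrix of held-out rows (never seen by training,
#'   evolution or reduction fitting).
#' @param y_test consensus grades of those rows.
#' @return Object of class \code{eval_report}: \code{exact_accuracy},
#'   \code{confusion} (3 x 3, rows = consensus, cols = predicted),
#'   \code{critical_errors} (predictions two grades off, i.e.
#'   excellent/good vs poor), \code{n_test}.
#' @export
evaluate_blind <- function(model, X_test, y_test) {
  pred <- predict_grade(model, as.matrix(X_test))$grades
  y <- as.integer(y_test)
  conf <- table(factor(y, levels = 1:3), factor(pred, levels = 1:3))
  conf <- matrix(as.integer(conf), 3L, 3L,
                 dimnames = list(consensus = 1:3, predicted = 1:3))
  structure(list(
    exact_accuracy = mean(pred == y),
    confusion = conf,
    critical_errors = sum(abs(pred - y) >= 2L),
    n_test = length(y)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> exact agreement %.1f%% (n = %d), critical errors %d\n",
              100 * x$exact_accuracy, x$n_test, x$critical_errors))
  print(x$confusion)
  invisible(x)
}
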