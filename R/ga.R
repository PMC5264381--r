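# Island-model genetic algorithm over network genomes. Fitness is exact
# validation accuracy of the trained genome; evolution uses tournament
# selection, per-gene uniform crossover, per-gene re-draw mutation,
# per-island elitism and ring migration.

#' GA settings
#'
#' Defaults are the reference configuration: 2 islands of 10 genomes
#' evolved for 20 generations with migration every 5 generations.
#'
#' @param n_islands number of islands (ring topology).
#' @param island_size genomes per island (>= 4).
#' @param generations number of generations (>= 1).
#' @param migration_interval every this many generations the best genome of
#'   each island replaces the worst of the next island.
#' @param tournament_k tournament size for parent selection.
#' @param crossover_p per-gene probability of inheriting from the second
#'   parent.
#' @param mutation_p per-gene probability of re-drawing within range.
#' @param include_default seed the baseline \code{\link{default_genome}}
#'   into the first island.
#' @param seed master seed for all GA randomness.
#' @return Object of class \code{ga_config}.
#' @export
ga_config <- function(n_islands = 2L, island_size = 10L, generations = 20L,
                      migration_interval = 5L, tournament_k = 3L,
                      crossover_p = 0.5, mutation_p = 0.1,
                      include_default = TRUE, seed = 42L) {
  if (island_size < 4L) abort2("island_size must be >= 4", "configuration_error")
  if (generations < 1L) abort2("generations must be >= 1", "configuration_error")
  structure(list(n_islands = as.integer(n_islands),
                 island_size = as.integer(island_size),
                 generations = as.integer(generations),
                 migration_interval = as.integer(migration_interval),
                 tournament_k = as.integer(tournament_k),
                 crossover_p = crossover_p, mutation_p = mutation_p,
                 include_default = include_default,
                 seed = as.integer(seed)), class = "ga_config")
}

.gene_names <- c("n_hidden_layers", "hidden1", "hidden2", "activation",
                 "learning_rate", "momentum", "epochs", "weight_seed")

# draw one gene value within range (uses current RNG stream)
draw_gene <- function(gene, space) {
  switch(gene,
    n_hidden_layers = sample(space$n_hidden_layers, 1L),
    hidden1 = ,
    hidden2 = sample(seq(space$hidden_range[1], space$hidden_range[2]), 1L),
    activation = sample(space$activations, 1L),
    learning_rate = 10^runif(1, space$lr_log10_range[1], space$lr_log10_range[2]),
    momentum = runif(1, space$momentum_range[1], space$momentum_range[2]),
    epochs = sample(seq(space$epochs_range[1], space$epochs_range[2]), 1L),
    weight_seed = sample(seq(space$weight_seed_range[1], space$weight_seed_range[2]), 1L)
  )
}

genome_get <- function(g, gene) switch(gene,
  hidden1 = g$hidden_sizes[1], hidden2 = g$hidden_sizes[2], g[[gene]])

genome_set <- function(g, gene, value) {
  if (gene == "hidden1") g$hidden_sizes[1] <- as.integer(value)
  else if (gene == "hidden2") g$hidden_sizes[2] <- as.integer(value)
  else if (gene %in% c("n_hidden_layers", "epochs", "weight_seed")) g[[gene]] <- as.integer(value)
  else g[[gene]] <- value
  g
}

crossover_genomes <- function(a, b, p) {
  out <- a
  for (gene in .gene_names)
    if (runif(1) < p) out <- genome_set(out, gene, genome_get(b, gene))
  out
}

mutate_genome <- function(g, p, space) {
  for (gene in .gene_names)
    if (runif(1) < p) g <- genome_set(g, gene, draw_gene(gene, space))
  g
}

#' Evolve a network genome by the island-model GA
#'
#' Every genome is trained on the training split and scored by exact
#' agreement on the validation split; elitism keeps the per-island best, so
#' the best fitness is non-decreasing across generations. The overall best
#' genome is retrained on the training split and returned with the history.
#'
#' @param X_train,y_train training features (reduced table) and consensus
#'   grades.
#' @param X_valid,y_valid validation rows for fitness.
#' @param config a \code{\link{ga_config}}.
#' @return Object of class \code{ga_result}: \code{best_genome},
#'   \code{best_model}, \code{best_fitness}, \code{history} (data.frame
#'   generation/best_fitness), \code{population} (final islands).
#' @export
ga_evolve <- function(X_train, y_train, X_valid, y_valid, config = ga_config()) {
  if (is.null(X_valid) || nrow(as.matrix(X_valid)) == 0L)
    abort2("validation split is empty", "configuration_error")
  X_train <- as.matrix(X_train); X_valid <- as.matrix(X_valid)
  space <- genome_space()
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(g) {
    key <- genome_key(g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    model <- train_ann(g, X_train, y_train)
    acc <- mean(predict_grade(model, X_valid)$grades == as.integer(y_valid))
    cache[[key]] <- acc
    acc
  }

  result <- with_seed(derive_seed(config$seed, 77L), {
    islands <- lapply(seq_len(config$n_islands), function(i) {
      pop <- lapply(seq_len(config$island_size), function(j) random_genome(space))
      if (i == 1L && config$include_default) pop[[1L]] <- default_genome()
      pop
    })
    fit <- lapply(islands, function(pop) vapply(pop, fitness_of, 0))
    history <- data.frame(generation = 0L, best_fitness = max(unlist(fit)))

    for (gen in seq_len(config$generations)) {
      for (i in seq_along(islands)) {
        pop <- islands[[i]]; f <- fit[[i]]
        elite <- pop[[which.max(f)]]
        nxt <- vector("list", config$island_size)
        nxt[[1L]] <- elite
        for (j in 2:config$island_size) {
          pick <- function() {
            cand <- sample.int(config$island_size, config$tournament_k, replace = TRUE)
            pop[[cand[which.max(f[cand])]]]
          }
          child <- crossover_genomes(pick(), pick(), config$crossover_p)
          nxt[[j]] <- mutate_genome(child, config$mutation_p, space)
        }
        islands[[i]] <- nxt
      }
      if (config$n_islands > 1L && gen %% config$migration_interval == 0L) {
        # evaluate, then best of island i replaces worst of island i+1 (ring)
        fit_now <- lapply(islands, function(pop) vapply(pop, fitness_of, 0))
        bests <- lapply(seq_along(islands), function(i)
          islands[[i]][[which.max(fit_now[[i]])]])
        for (i in seq_along(islands)) {
          dst <- if (i == config$n_islands) 1L else i + 1L
          worst <- which.min(fit_now[[dst]])
          islands[[dst]][[worst]] <- bests[[i]]
        }
      }
      fit <- lapply(islands, function(pop) vapply(pop, fitness_of, 0))
      history <- rbind(history,
                       data.frame(generation = gen, best_fitness = max(unlist(fit))))
    }

    allf <- unlist(fit)
    allg <- do.call(c, islands)
    best <- allg[[which.max(allf)]]
    list(best_genome = best, best_fitness = max(allf), history = history,
         population = islands, fitness = fit)
  })

  result$best_model <- train_ann(result$best_genome, X_train, y_train)
  structure(result, class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best validation accuracy %.3f after %d generations\n",
              x$best_fitness, max(x$history$generation)))
  print(x$best_genome)
  invisible(x)
}

#' @export
print.ann_genome <- function(x, ...) {
  cat(sprintf("<ann_genome> layers %s (%s), lr %.3g, momentum %.2f, epochs %d, seed %d\n",
              paste(x$hidden_sizes[seq_len(x$n_hidden_layers)], collapse = "-"),
              x$activation, x$learning_rate, x$momentum, x$epochs, x$weight_seed))
  invisible(x)
}
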