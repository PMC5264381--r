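# End-to-end experiment driver: synthetic dataset -> features -> reduction
# -> split -> GA-evolved network -> blind-test report, with all artifacts
# (and the fully resolved configuration) written to disk for replay.

#' Full pipeline configuration
#'
#' Materializes every stage's defaults so a run is reproducible from the
#' dumped configuration alone. Unknown keys in \code{...} overrides are
#' rejected.
#'
#' @param n dataset size (reference experiment: 126 images).
#' @param seed master seed; fans out deterministically to dataset
#'   generation, splitting and the GA.
#' @param synth a \code{\link{synth_config}}.
#' @param features a \code{\link{feature_params}}.
#' @param reduce list with \code{threshold} and \code{target_dim}.
#' @param split a \code{\link{split_spec}} (its seed is derived from the
#'   master seed at run time).
#' @param ga a \code{\link{ga_config}} (likewise).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n = 126L, seed = 42L,
                            synth = synth_config(),
                            features = feature_params(),
                            reduce = list(threshold = 0.9, target_dim = 24L),
                            split = split_spec(),
                            ga = ga_config()) {
  if (!setequal(names(reduce), c("threshold", "target_dim")))
    abort2("reduce section must have exactly threshold and target_dim",
           "configuration_error")
  structure(list(n = as.integer(n), seed = as.integer(seed), synth = synth,
                 features = features, reduce = reduce, split = split, ga = ga,
                 config_version = "1"), class = "pipeline_config")
}

config_as_list <- function(cfg) {
  rapply(unclass(cfg), function(x) x, how = "list")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the reference experiment end to end
#'
#' Generates (or accepts) a labeled dataset, extracts the 36-variable
#' descriptors, fits the collinearity reduction on the training rows only,
#' evolves the classifier on train/validation and evaluates it blind on the
#' untouched test rows. The consensus examiner grade is the learning
#' target throughout, mirroring the mode-template protocol.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param dataset optional pre-built list of \code{labeled_image}; when
#'   NULL the synthetic generator is run with the configured size and seed.
#' @param out_dir optional directory for artifacts (features.csv,
#'   reduction.json, model.json, report.json, config.json).
#' @param verbose print per-stage progress.
#' @return List: \code{features} (data.frame), \code{split},
#'   \code{reduction}, \code{ga}, \code{eval} (an \code{eval_report}),
#'   \code{config}, \code{config_hash}.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(dataset)) {
    say("synth: generating %d images (seed %d)", config$n, config$seed)
    dataset <- generate_dataset(config$synth, config$n,
                                seed = derive_seed(config$seed, 1L))
  }
  say("features: extracting %d x 36 descriptors", length(dataset))
  feats <- extract_features(dataset, config$features)
  y <- feats$consensus
  X <- as.matrix(feats[, feature_registry()$name])

  sp <- config$split
  sp$seed <- derive_seed(config$seed, 2L)
  split <- split_dataset(nrow(X), sp, labels = y)

  say("reduce: collinearity pruning on %d training rows", length(split$train))
  reduction <- fit_reduction(X[split$train, , drop = FALSE],
                             threshold = config$reduce$threshold,
                             target_dim = config$reduce$target_dim)
  Xr <- apply_reduction(X, reduction)

  ga_cfg <- config$ga
  ga_cfg$seed <- derive_seed(config$seed, 3L)
  say("gann: evolving (%d islands x %d genomes x %d generations)",
      ga_cfg$n_islands, ga_cfg$island_size, ga_cfg$generations)
  ga <- ga_evolve(Xr[split$train, , drop = FALSE], y[split$train],
                  Xr[split$valid, , drop = FALSE], y[split$valid], ga_cfg)
  eval_report <- evaluate_blind(ga$best_model, Xr[split$test, , drop = FALSE],
                                y[split$test])
  say("done in %.1f s: blind accuracy %.3f, critical errors %d",
      as.numeric(difftime(Sys.time(), t0, units = "secs")),
      eval_report$exact_accuracy, eval_report$critical_errors)

  out <- list(features = feats, split = split, reduction = reduction, ga = ga,
              eval = eval_report, config = config, config_hash = config_hash(config))
  if (!is.null(out_dir)) write_artifacts(out, out_dir)
  out
}

write_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config_hash = run$config_hash)
  write.csv(run$features, file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(meta, list(retained = run$reduction$retained,
                 dropped = run$reduction$dropped,
                 threshold = run$reduction$threshold,
                 target_dim = run$reduction$target_dim)),
    file.path(out_dir, "reduction.json"), auto_unbox = TRUE, digits = NA)
  save_model(run$ga$best_model, file.path(out_dir, "model.json"),
             extra = meta)
  jsonlite::write_json(
    c(meta, list(exact_accuracy = run$eval$exact_accuracy,
                 confusion = run$eval$confusion,
                 critical_errors = run$eval$critical_errors,
                 n_test = run$eval$n_test,
                 split_sizes = vapply(run$split, length, 0L))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(meta, config_as_list(run$config)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Serialize a trained network (plus its genome and scaler) to JSON
#'
#' @param model a \code{\link{train_ann}} result.
#' @param path output file.
#' @param extra named list merged into the JSON root.
#' @export
save_model <- function(model, path, extra = list()) {
  obj <- c(extra, list(
    genome = unclass(model$genome),
    scaler = model$scaler,
    weights = model$weights,
    biases = model$biases,
    activation = model$activation,
    input_dim = model$input_dim,
    output_dim = model$output_dim
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model written by \code{\link{save_model}}
#' @param path JSON file.
#' @return A \code{trained_ann}.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$genome
  genome <- ann_genome(g$n_hidden_layers, g$hidden_sizes, g$activation,
                       g$learning_rate, g$momentum, g$epochs, g$weight_seed)
  structure(list(
    genome = genome,
    scaler = list(mean = as.numeric(obj$scaler$mean), sd = as.numeric(obj$scaler$sd)),
    weights = lapply(obj$weights, function(w) {
      w <- as.matrix(w)
      storage.mode(w) <- "double"
      dimnames(w) <- NULL
      w
    }),
    biases = lapply(obj$biases, as.numeric),
    activation = obj$activation,
    train_loss_curve = numeric(0),
    input_dim = obj$input_dim,
    output_dim = obj$output_dim
  ), class = "trained_ann")
}

#' Grade a single raw micrograph with a trained model and reduction
#'
#' Runs the full image-to-grade chain: 36-variable extraction, reduction to
#' the model's inputs, prediction.
#'
#' @param image numeric matrix (0..255) or path to an 8-bit PNG.
#' @param model a \code{trained_ann}.
#' @param reduction the \code{reduction_report} the model was trained under.
#' @param params a \code{\link{feature_params}}.
#' @return list(\code{grade}, \code{probabilities}, \code{features}).
#' @export
grade_image <- function(image, model, reduction, params = feature_params()) {
  if (is.character(image)) {
    arr <- png::readPNG(image)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    image <- round(arr * 255)
  }
  fv <- assemble_vector(image, params)
  xr <- apply_reduction(fv, reduction)
  pred <- predict_grade(model, as.numeric(xr))
  list(grade = pred$grade, probabilities = pred$probabilities, features = fv)
}
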