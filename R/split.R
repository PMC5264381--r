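# Reproducible train/validation/test partitioning (70/15/15 by default)
# with largest-remainder rounding and optional label stratification.

#' Split specification
#'
#' @param train_fraction,valid_fraction,test_fraction positive fractions
#'   summing to 1 (defaults 0.70/0.15/0.15).
#' @param stratified balance the grade composition of the three splits.
#' @param seed integer seed for the shuffling.
#' @return Object of class \code{split_spec}.
#' @export
split_spec <- function(train_fraction = 0.70, valid_fraction = 0.15,
                       test_fraction = 0.15, stratified = TRUE, seed = 1L) {
  f <- c(train_fraction, valid_fraction, test_fraction)
  if (abs(sum(f) - 1) > 1e-9 || any(f <= 0))
    abort2("fractions must be positive and sum to 1", "configuration_error")
  structure(list(fractions = f, stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder rounding of n into parts proportional to fracs;
# remainder ties go to the earlier part.
largest_remainder <- function(n, fracs) {
  exact <- n * fracs
  base <- floor(exact)
  rem <- exact - base
  extra <- n - sum(base)
  if (extra > 0) {
    ord <- order(-rem, seq_along(fracs))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Partition sample indices into train/validation/test
#'
#' Global split sizes follow largest-remainder rounding of the fractions
#' (e.g. n = 126 at 0.70/0.15/0.15 gives 88/19/19). Under stratification the
#' per-class allocation also uses largest remainders, reconciled against the
#' global sizes; an error is raised if any class would be absent from a
#' split. Deterministic for a fixed seed.
#'
#' @param n number of samples (>= 10).
#' @param spec a \code{\link{split_spec}}.
#' @param labels integer grades (required when \code{spec$stratified}).
#' @return List of 1-based index vectors \code{train}, \code{valid},
#'   \code{test}; pairwise disjoint, covering \code{1..n}.
#' @export
split_dataset <- function(n, spec = split_spec(), labels = NULL) {
  if (n < 10L) abort2("need n >= 10 samples to split", "configuration_error")
  sizes <- largest_remainder(n, spec$fractions)
  if (!spec$stratified) {
    perm <- with_seed(spec$seed, sample.int(n))
    out <- list(train = sort(perm[seq_len(sizes[1])]),
                valid = sort(perm[sizes[1] + seq_len(sizes[2])]),
                test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
    return(out)
  }
  if (is.null(labels) || length(labels) != n)
    abort2("stratified split needs one label per sample", "configuration_error")
  classes <- sort(unique(labels))
  ncls <- length(classes)
  nc <- vapply(classes, function(cl) sum(labels == cl), 0L)
  # per-class floors, then reconcile remainders against the global sizes
  alloc <- matrix(0L, ncls, 3L)
  remf <- matrix(0, ncls, 3L)
  for (k in seq_len(ncls)) {
    exact <- nc[k] * spec$fractions
    alloc[k, ] <- floor(exact)
    remf[k, ] <- exact - floor(exact)
  }
  class_left <- nc - rowSums(alloc)
  split_left <- sizes - colSums(alloc)
  cells <- expand.grid(k = seq_len(ncls), s = 1:3)
  cells$rem <- remf[cbind(cells$k, cells$s)]
  cells <- cells[order(-cells$rem, cells$k, cells$s), ]
  for (i in seq_len(nrow(cells))) {
    k <- cells$k[i]; s <- cells$s[i]
    if (class_left[k] > 0L && split_left[s] > 0L) {
      alloc[k, s] <- alloc[k, s] + 1L
      class_left[k] <- class_left[k] - 1L
      split_left[s] <- split_left[s] - 1L
    }
  }
  # any leftovers (remainder pattern incompatible): deterministic sweep
  for (k in seq_len(ncls)) while (class_left[k] > 0L) {
    s <- which(split_left > 0L)[1]
    alloc[k, s] <- alloc[k, s] + 1L
    class_left[k] <- class_left[k] - 1L
    split_left[s] <- split_left[s] - 1L
  }
  if (any(alloc == 0L))
    abort2("a label class would be absent from a split (n too small to stratify)",
           "stratification_error")
  idx <- list(train = integer(), valid = integer(), test = integer())
  for (k in seq_len(ncls)) {
    members <- which(labels == classes[k])
    perm <- with_seed(derive_seed(spec$seed, 500L + k), sample(members))
    idx$train <- c(idx$train, perm[seq_len(alloc[k, 1])])
    idx$valid <- c(idx$valid, perm[alloc[k, 1] + seq_len(alloc[k, 2])])
    idx$test <- c(idx$test, perm[alloc[k, 1] + alloc[k, 2] + seq_len(alloc[k, 3])])
  }
  lapply(idx, sort)
}
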