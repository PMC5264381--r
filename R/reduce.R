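# Collinearity analysis: prune the 36-variable descriptor down to the
# neural network's input set (24 in the reference configuration).

#' Pearson correlation matrix of a feature table
#'
#' Constant columns get zero correlation to everything (diagonal stays 1).
#'
#' @param features numeric matrix or data.frame of n rows x p feature
#'   columns (n >= 3).
#' @return p x p symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 3L) abort2("need at least 3 rows for correlations", "insufficient_data_error")
  sds <- apply(X, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  cm[sds < 1e-12, ] <- 0
  cm[, sds < 1e-12] <- 0
  diag(cm) <- 1
  # enforce exact symmetry against floating-point asymmetry
  cm <- (cm + t(cm)) / 2
  cm
}

#' Greedy collinearity pruning
#'
#' While any retained pair has \code{|r| > threshold}, the pair with the
#' largest \code{|r|} is examined and the member with the larger mean
#' \code{|r|} to all other retained features is dropped. If
#' \code{target_dim} is set it is binding in both directions: the threshold
#' loop stops once \code{target_dim} features remain, and if more remain
#' after it, dropping continues by the same mean-|r| ranking until exactly
#' \code{target_dim} are left. All ties break deterministically by registry
#' (column) order, preferring to drop the later feature.
#'
#' @param corr correlation matrix with dimnames (from
#'   \code{\link{correlation_matrix}}).
#' @param threshold correlation magnitude in (0, 1].
#' @param target_dim exact number of features to retain, or \code{NULL} for
#'   purely threshold-driven pruning.
#' @return Object of class \code{reduction_report}: \code{retained} (ordered
#'   names), \code{dropped} (data.frame name/reason/partner/abs_r),
#'   \code{threshold}, \code{target_dim}.
#' @export
collinearity_prune <- function(corr, threshold = 0.9, target_dim = NULL) {
  if (threshold <= 0 || threshold > 1)
    abort2("threshold must lie in (0, 1]", "configuration_error")
  p <- nrow(corr)
  if (!is.null(target_dim) && (target_dim > p || target_dim < 1))
    abort2("target_dim must lie in [1, ncol]", "configuration_error")
  nm <- colnames(corr)
  if (is.null(nm)) nm <- paste0("f", seq_len(p))
  keep <- rep(TRUE, p)
  dropped <- list()
  a <- abs(corr); diag(a) <- 0

  mean_abs_r <- function(i) mean(a[i, keep & seq_len(p) != i])

  repeat {
    if (!is.null(target_dim) && sum(keep) <= target_dim) break
    ak <- a[keep, keep, drop = FALSE]
    if (max(ak) <= threshold) break
    ids <- which(keep)
    w <- which(ak == max(ak), arr.ind = TRUE)
    # earliest pair in registry order
    pr <- w[order(pmin(w[, 1], w[, 2]), pmax(w[, 1], w[, 2]))[1], ]
    i <- ids[min(pr)]; j <- ids[max(pr)]
    mi <- mean_abs_r(i); mj <- mean_abs_r(j)
    drop <- if (mi > mj) i else if (mj > mi) j else j  # tie: drop later
    keep[drop] <- FALSE
    dropped[[length(dropped) + 1L]] <- data.frame(
      name = nm[drop], reason = "threshold",
      partner = nm[if (drop == i) j else i], abs_r = a[i, j])
  }
  if (!is.null(target_dim)) {
    if (sum(keep) < target_dim)
      abort2("threshold pass retained fewer features than target_dim", "configuration_error")
    while (sum(keep) > target_dim) {
      ids <- which(keep)
      mr <- vapply(ids, mean_abs_r, 0)
      # drop largest mean |r|; tie -> later registry position
      drop <- ids[max(which(mr == max(mr)))]
      partner <- ids[which.max(a[drop, ids])]
      keep[drop] <- FALSE
      dropped[[length(dropped) + 1L]] <- data.frame(
        name = nm[drop], reason = "target_dim",
        partner = nm[partner], abs_r = max(a[drop, ids]))
    }
  }
  structure(list(
    retained = nm[keep],
    dropped = if (length(dropped)) do.call(rbind, dropped)
              else data.frame(name = character(), reason = character(),
                              partner = character(), abs_r = numeric()),
    threshold = threshold,
    target_dim = target_dim
  ), class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report> retained %d, dropped %d (threshold %.2f%s)\n",
              length(x$retained), nrow(x$dropped), x$threshold,
              if (is.null(x$target_dim)) "" else sprintf(", target %d", x$target_dim)))
  invisible(x)
}

#' Apply a reduction report to a feature vector or table
#'
#' Selects the retained features by name, in retained order.
#'
#' @param x named numeric vector (a \code{feature_vector}) or a
#'   data.frame/matrix with feature columns.
#' @param report a \code{\link{collinearity_prune}} result.
#' @return Reduced vector or table.
#' @export
apply_reduction <- function(x, report) {
  nms <- if (is.null(dim(x))) names(x) else colnames(x)
  missing <- setdiff(report$retained, nms)
  if (length(missing))
    abort2(paste("features missing from input:", paste(missing, collapse = ", ")),
           "schema_error")
  if (is.null(dim(x))) x[report$retained] else x[, report$retained, drop = FALSE]
}

#' Fit the reference reduction on a training feature table
#'
#' Convenience wrapper: correlation matrix plus greedy pruning.
#'
#' @param features n x p numeric table (training rows only, to avoid
#'   leakage into validation/test).
#' @inheritParams collinearity_prune
#' @return A \code{reduction_report}.
#' @export
fit_reduction <- function(features, threshold = 0.9, target_dim = 24L) {
  collinearity_prune(correlation_matrix(features), threshold, target_dim)
}
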