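# Internal helpers shared across modules.

## Labeled distance-matrix helpers ------------------------------------------

# Coerce a square symmetric matrix to a labeled `dist` and validate the
# DistanceMatrix contract: symmetric within 1e-10, zero diagonal, finite.
as_dist_checked <- function(m, labels = rownames(m), metric = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (any(!is.finite(m))) stop("distance matrix contains non-finite values")
  if (max(abs(m - t(m))) > 1e-10) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 0)) stop("distance matrix has a nonzero diagonal")
  d <- stats::as.dist(m)
  if (!is.null(metric)) attr(d, "metric") <- metric
  d
}

# Off-diagonal values of a dist (or square matrix) as a vector, in the
# fixed lower-triangle order used by all matrix-correlation tests.
dist_vec <- function(d) {
  if (inherits(d, "dist")) as.vector(d) else as.matrix(d)[lower.tri(as.matrix(d))]
}

dist_labels <- function(d) {
  if (inherits(d, "dist")) attr(d, "Labels") else rownames(as.matrix(d))
}

# Check that two distance objects cover the same labels in the same order.
check_conformable <- function(...) {
  labs <- lapply(list(...), dist_labels)
  n <- vapply(list(...), function(d) attr(stats::as.dist(as.matrix(d)), "Size"), 1L)
  if (length(unique(n)) != 1L) stop("distance matrices differ in dimension")
  ref <- labs[[1L]]
  for (l in labs[-1L]) {
    if (!is.null(ref) && !is.null(l) && !identical(ref, l))
      stop("distance matrices carry different or reordered labels")
  }
  invisible(TRUE)
}

## Permutation machinery -----------------------------------------------------

# "Add-one" permutation p-value: (1 + exceedances) / (1 + n_perm), never 0.
perm_pvalue <- function(exceed, n_perm) (1 + exceed) / (1 + n_perm)

#' Absolute-difference distance matrix over a sample covariate
#'
#' Pairwise `|x_i - x_j|` over a numeric per-sample covariate (elevation,
#' pH, ...), as a labeled `dist` for the Mantel family. Replicates at one
#' station legitimately get distance 0 and are kept.
#'
#' @param x numeric covariate, one value per sample, no missing values.
#' @param labels sample labels (default `names(x)`).
#' @param metric metric name stored on the result.
#' @return A labeled `dist`.
#' @export
covariate_distance <- function(x, labels = names(x), metric = "abs_difference") {
  if (any(!is.finite(x))) stop("covariate contains missing or non-finite values")
  as_dist_checked(abs(outer(x, x, "-")), labels = labels, metric = metric)
}
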