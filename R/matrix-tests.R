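# Matrix-correlation inference: ANOSIM, the Mantel family and the Mantel
# correlogram. All permutation p-values use the add-one estimator
# (1 + exceedances)/(1 + n_perm). ANOSIM is one-sided (its alternative is
# "between-group distances larger"); the Mantel family is two-sided by
# default because environmental correlations carry sign.

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' over midranked off-diagonal distances, with significance by permuting
#' group labels (via [vegan::anosim()]).
#'
#' @param dm sample distance matrix (`dist`).
#' @param groups group label per sample (>= 2 groups, each non-empty).
#' @param n_perm number of permutations (9,999 by default).
#' @param seed optional seed.
#' @return List of class `anosim_result`: `statistic` (R), `p`, `n_perm`.
#' @export
anosim <- function(dm, groups, n_perm = 9999, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("ANOSIM needs at least 2 groups")
  if (length(groups) != attr(stats::as.dist(dm), "Size"))
    stop("group vector length does not match the distance matrix")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(dm), droplevels(groups),
                       permutations = n_perm)
  structure(list(statistic = unname(fit$statistic), p = fit$signif,
                 n_perm = n_perm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

mantel_result <- function(statistic, p, n_perm, tail, method = "pearson") {
  structure(list(statistic = statistic, p = p, n_perm = n_perm,
                 tail = tail, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations, %s-sided, %s)\n",
              x$statistic, x$p, x$n_perm, x$tail, x$method))
  invisible(x)
}

tail_exceed <- function(obs, perm, tail) {
  switch(tail,
         two = sum(abs(perm) >= abs(obs) - 1e-12),
         greater = sum(perm >= obs - 1e-12),
         less = sum(perm <= obs + 1e-12))
}

#' Mantel test between two distance matrices
#'
#' Correlation of the off-diagonal vectors of two conformable distance
#' matrices, with significance by jointly permuting rows and columns of the
#' second matrix.
#'
#' @param dmA,dmB conformable distance matrices with matching labels.
#' @param n_perm permutations (999 by default).
#' @param seed optional seed.
#' @param method correlation method (`"pearson"` default, or
#'   `"spearman"`).
#' @param tail `"two"` (default), `"greater"` or `"less"`.
#' @return A `mantel_result`.
#' @export
mantel <- function(dmA, dmB, n_perm = 999, seed = NULL,
                   method = c("pearson", "spearman"),
                   tail = c("two", "greater", "less")) {
  method <- match.arg(method); tail <- match.arg(tail)
  check_conformable(dmA, dmB)
  if (!is.null(seed)) set.seed(seed)
  a <- dist_vec(dmA)
  bm <- as.matrix(dmB)
  lt <- lower.tri(bm)
  r_obs <- cor(a, bm[lt], method = method)
  n <- nrow(bm)
  perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(a, bm[p, p][lt], method = method)
  }, 1)
  mantel_result(r_obs, perm_pvalue(tail_exceed(r_obs, perm, tail), n_perm),
                n_perm, tail, method)
}

partial_cor <- function(rab, rac, rbc) {
  denom <- (1 - rac^2) * (1 - rbc^2)
  # controlling for a matrix collinear with A or B leaves nothing to
  # correlate; return 0 by convention instead of 0/0
  if (denom < 1e-12) return(0)
  (rab - rac * rbc) / sqrt(denom)
}

#' Partial Mantel test
#'
#' Correlation between `dmA` and `dmB` controlling for `dmC`, via the
#' first-order partial correlation of the off-diagonal vectors;
#' significance by permuting rows and columns of `dmB`.
#'
#' @inheritParams mantel
#' @param dmC conformable covariate distance matrix held constant.
#' @return A `mantel_result`.
#' @export
partial_mantel <- function(dmA, dmB, dmC, n_perm = 999, seed = NULL,
                           method = c("pearson", "spearman"),
                           tail = c("two", "greater", "less")) {
  method <- match.arg(method); tail <- match.arg(tail)
  check_conformable(dmA, dmB, dmC)
  if (!is.null(seed)) set.seed(seed)
  a <- dist_vec(dmA); cvec <- dist_vec(dmC)
  if (var(cvec) == 0)
    stop("covariate matrix is constant; use a plain Mantel test")
  bm <- as.matrix(dmB)
  lt <- lower.tri(bm)
  rac <- cor(a, cvec, method = method)
  b <- bm[lt]
  r_obs <- partial_cor(cor(a, b, method = method), rac,
                       cor(b, cvec, method = method))
  n <- nrow(bm)
  perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    bp <- bm[p, p][lt]
    partial_cor(cor(a, bp, method = method), rac,
                cor(bp, cvec, method = method))
  }, 1)
  mantel_result(r_obs, perm_pvalue(tail_exceed(r_obs, perm, tail), n_perm),
                n_perm, tail, method)
}

#' Mantel correlogram (distance-decay by distance class)
#'
#' Bins spatial distances into equal-width classes (Sturges' rule on the
#' number of pairs by default) and computes, per class, the Mantel
#' correlation between the community distance matrix and the class
#' membership indicator. The sign is flipped so positive r means
#' communities in that distance class are more similar than average —
#' distance decay shows as positive r in the nearest class. Class p-values
#' (two-sided permutation) are Holm-corrected.
#'
#' @param dm_community community distance matrix.
#' @param dm_space spatial (or other covariate) distance matrix.
#' @param n_classes integer, or `"sturges"` for `ceiling(log2(pairs) + 1)`.
#' @param n_perm permutations per class.
#' @param seed optional seed.
#' @return A `data.frame` per class: `class`, `midpoint`, `n_pairs`, `r`,
#'   `p`, `p_adj` (classes with fewer than 2 pairs get `NA` statistics).
#' @export
mantel_correlogram <- function(dm_community, dm_space, n_classes = "sturges",
                               n_perm = 999, seed = NULL) {
  check_conformable(dm_community, dm_space)
  if (!is.null(seed)) set.seed(seed)
  comm_m <- as.matrix(dm_community)
  lt <- lower.tri(comm_m)
  comm <- comm_m[lt]
  space <- as.matrix(dm_space)[lt]
  n_pairs <- length(space)
  if (identical(n_classes, "sturges"))
    n_classes <- ceiling(log2(n_pairs) + 1)
  breaks <- seq(min(space), max(space), length.out = n_classes + 1)
  cls <- cut(space, breaks, include.lowest = TRUE, labels = FALSE)
  n <- nrow(comm_m)
  out <- data.frame(class = seq_len(n_classes),
                    midpoint = (head(breaks, -1) + breaks[-1]) / 2,
                    n_pairs = as.vector(table(factor(cls, levels = seq_len(n_classes)))),
                    r = NA_real_, p = NA_real_, p_adj = NA_real_)
  if (stats::sd(comm) == 0) {
    out$r[out$n_pairs >= 2] <- 0
    out$p[out$n_pairs >= 2] <- 1
    out$p_adj <- out$p
    return(out)
  }
  for (k in seq_len(n_classes)) {
    if (out$n_pairs[k] < 2 || out$n_pairs[k] == n_pairs) next
    ind <- as.numeric(cls == k)
    r_obs <- -cor(comm, ind)
    perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      -cor(comm_m[p, p][lt], ind)
    }, 1)
    out$r[k] <- r_obs
    out$p[k] <- perm_pvalue(tail_exceed(r_obs, perm, "two"), n_perm)
  }
  ok <- !is.na(out$p)
  out$p_adj[ok] <- p.adjust(out$p[ok], method = "holm")
  out
}
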