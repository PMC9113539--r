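#' Indicator species analysis (IndVal)
#'
#' For OTU i and group g, specificity `A = mean abundance in g / sum of
#' group mean abundances` and fidelity `B = fraction of g's samples where i
#' is present`; `IndVal = sqrt(A * B)` and each OTU is assigned its best
#' group. Significance comes from permuting sample group labels and
#' counting permuted maximum IndVal values at least as large as the
#' observed one (add-one estimator). IndVal is NOT invariant to per-sample
#' rescaling (A uses group mean abundances), so normalize first when
#' library sizes differ.
#'
#' @param table an [otu_table()] (raw or normalized).
#' @param groups group label per sample (>= 2 groups, each non-empty).
#' @param n_perm label permutations (999 by default).
#' @param seed optional seed.
#' @param alpha significance level for the `significant` flag.
#' @return A `data.frame`, one row per OTU: `otu_id`, `group`, `A`, `B`,
#'   `indval`, `p`, `significant`. OTUs absent everywhere get `NA`
#'   statistics.
#' @export
indval <- function(table, groups, n_perm = 999, seed = NULL, alpha = 0.05) {
  x <- table$counts
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(x))
    stop("group vector length does not match the table")
  if (nlevels(groups) < 2) stop("IndVal needs at least 2 groups")
  if (any(table(groups) == 0)) stop("every group needs at least one sample")
  if (!is.null(seed)) set.seed(seed)
  ab <- function(g) {
    gm <- rowsum(x, g) / as.vector(table(g))
    list(A = sweep(gm, 2L, colSums(gm), "/"),
         B = rowsum((x > 0) + 0, g) / as.vector(table(g)))
  }
  stat <- function(g) { s <- ab(g); sqrt(s$A * s$B) }
  ab_obs <- ab(groups)
  iv_obs <- sqrt(ab_obs$A * ab_obs$B)
  best <- apply(iv_obs, 2L, function(v) if (all(is.na(v))) NA_integer_
                else which.max(v))
  obs <- vapply(seq_len(ncol(x)), function(i)
    if (is.na(best[i])) NA_real_ else iv_obs[best[i], i], 1)
  exceed <- numeric(ncol(x))
  for (r in seq_len(n_perm)) {
    ivp <- stat(sample(groups))
    mx <- suppressWarnings(apply(ivp, 2L, max, na.rm = TRUE))
    exceed <- exceed + (mx >= obs - 1e-12)
  }
  p <- ifelse(is.na(obs), NA_real_, perm_pvalue(exceed, n_perm))
  pick <- function(m) vapply(seq_len(ncol(x)), function(i)
    if (is.na(best[i])) NA_real_ else m[best[i], i], 1)
  data.frame(otu_id = colnames(x),
             group = levels(groups)[best],
             A = pick(ab_obs$A),
             B = pick(ab_obs$B),
             indval = obs, p = p,
             significant = !is.na(p) & p <= alpha,
             stringsAsFactors = FALSE)
}
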