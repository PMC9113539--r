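#' Bray-Curtis dissimilarity between samples
#'
#' `BC(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` on raw or
#' normalized abundances. A pair of all-zero samples has no defined
#' dissimilarity, so empty samples are an error.
#'
#' @param table an [otu_table()].
#' @return A labeled `dist` with values in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  x <- table$counts
  if (any(rowSums(x) == 0))
    stop("Bray-Curtis is undefined for empty sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Partition Sorensen dissimilarity into turnover and nestedness
#'
#' Presence/absence decomposition: with `a` shared OTUs and `b`, `c` unique
#' to each sample, total dissimilarity `bsor = (b + c)/(2a + b + c)` splits
#' into species turnover `bsim = min(b,c)/(a + min(b,c))` and the
#' richness-difference (nestedness) remainder `bsne = bsor - bsim`. The
#' summary turnover percentage is `mean(bsim)/mean(bsor) * 100` across all
#' pairs.
#'
#' @param table an [otu_table()]; presence is count > 0. A pair of empty
#'   samples is an error.
#' @return A list of class `beta_partition`: `beta_sor`, `beta_sim`,
#'   `beta_sne` (labeled `dist` objects), `turnover_percent`,
#'   `nestedness_percent`.
#' @export
sorensen_partition <- function(table) {
  p <- (table$counts > 0) + 0
  if (any(rowSums(p) == 0))
    stop("empty sample(s): ", paste(rownames(p)[rowSums(p) == 0], collapse = ", "))
  a <- p %*% t(p)
  rich <- rowSums(p)
  b <- outer(rich, rich, function(x, y) x) - a   # unique to row sample
  cc <- outer(rich, rich, function(x, y) y) - a  # unique to col sample
  mn <- pmin(b, cc)
  bsor <- (b + cc) / (2 * a + b + cc)
  bsim <- ifelse(a + mn == 0, 0, mn / (a + mn))
  bsne <- bsor - bsim
  diag(bsor) <- diag(bsim) <- diag(bsne) <- 0
  labs <- sample_ids(table)
  out <- list(beta_sor = as_dist_checked(bsor, labs, "sorensen"),
              beta_sim = as_dist_checked(bsim, labs, "simpson_turnover"),
              beta_sne = as_dist_checked(bsne, labs, "nestedness"))
  msor <- mean(dist_vec(out$beta_sor))
  out$turnover_percent <- if (msor > 0)
    mean(dist_vec(out$beta_sim)) / msor * 100 else NA_real_
  out$nestedness_percent <- if (msor > 0) 100 - out$turnover_percent else NA_real_
  class(out) <- "beta_partition"
  out
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("Sorensen partition over %d samples: turnover %.2f%%, nestedness %.2f%%\n",
              attr(x$beta_sor, "Size"), x$turnover_percent, x$nestedness_percent))
  invisible(x)
}

#' Unweighted UniFrac distance between samples
#'
#' Fraction of the branch length of the shared phylogeny that leads
#' exclusively to OTUs of one sample, out of the branch length leading to
#' OTUs of either; branches ancestral only to absent OTUs are excluded.
#' Presence/absence only.
#'
#' @param table an [otu_table()]; OTUs must all be tips of `tree`.
#' @param tree rooted `phylo` covering the table's OTUs.
#' @return A labeled `dist` with values in \[0, 1\].
#' @export
unweighted_unifrac <- function(table, tree) {
  if (!ape::is.rooted(tree))
    stop("UniFrac needs a rooted tree; midpoint-root it first (see read_tree)")
  lost <- setdiff(otu_ids(table), tree$tip.label)
  if (length(lost))
    stop("OTUs absent from the tree: ", paste(lost, collapse = ", "))
  if (any(rowSums(table$counts) == 0))
    stop("UniFrac is undefined for empty samples")
  if (length(setdiff(tree$tip.label, otu_ids(table))))
    tree <- ape::keep.tip(tree, otu_ids(table))
  d <- picante::unifrac(table$counts, tree)
  m <- as.matrix(d)[sample_ids(table), sample_ids(table)]
  as_dist_checked(m, metric = "unweighted_unifrac")
}
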