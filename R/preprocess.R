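#' Discard samples with low sequencing depth
#'
#' Removes samples whose library size is strictly less than the threshold,
#' so a sample sitting exactly at the cutoff is kept. `threshold = "q1"`
#' resolves to the first quartile of the library sizes using the
#' linear-interpolation (type 7) quantile — the definition matters, since a
#' printed cutoff like "first quartile = 18" depends on it.
#'
#' @param table raw-count [otu_table()].
#' @param threshold integer minimum library size, or `"q1"`.
#' @return The filtered `otu_table`; removed sample ids are recorded in
#'   `attr(, "removed_samples")`.
#' @export
filter_low_depth_samples <- function(table, threshold = "q1") {
  if (table$normalized) stop("depth filtering requires raw counts")
  sizes <- library_sizes(table)
  if (identical(threshold, "q1"))
    threshold <- unname(quantile(sizes, 0.25, type = 7))
  keep <- sizes >= threshold
  if (!any(keep)) stop("all samples fall below the depth threshold")
  out <- otu_table(table$counts[keep, , drop = FALSE])
  attr(out, "removed_samples") <- names(sizes)[!keep]
  attr(out, "depth_threshold") <- threshold
  out
}

#' Normalize a count table
#'
#' `tss` (total-sum scaling) divides each count by its sample's library
#' size, giving within-sample relative abundances. `css` (cumulative sum
#' scaling) divides each sample by the sum of its counts at or below the
#' sample's `css_quantile`-th quantile of nonzero counts, then rescales by
#' the median of those scaling factors across samples, damping the
#' influence of a few dominant OTUs on the effective library size.
#'
#' @param table raw-count [otu_table()] (zero-depth samples are an error;
#'   filter first).
#' @param method `"css"` (default) or `"tss"`.
#' @param css_quantile quantile used by CSS, default 0.5.
#' @return A normalized `otu_table` (`normalized = TRUE`, `method` set).
#' @export
normalize <- function(table, method = c("css", "tss"), css_quantile = 0.5) {
  method <- match.arg(method)
  if (table$normalized) stop("table is already normalized")
  sizes <- library_sizes(table)
  if (any(sizes == 0))
    stop("zero-depth sample(s): ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  x <- table$counts
  if (method == "tss") {
    out <- x / sizes
  } else {
    sf <- apply(x, 1L, function(v) {
      nz <- v[v > 0]
      q <- quantile(nz, css_quantile, type = 7)
      sum(nz[nz <= q])
    })
    out <- x / sf * median(sf)
  }
  otu_table(out, normalized = TRUE, method = method)
}

#' Observed OTU richness per sample
#'
#' Number of OTUs with nonzero count in each sample. Computed on raw
#' counts only — richness on a rescaled table is meaningless, so normalized
#' tables are refused.
#'
#' @param table raw-count [otu_table()].
#' @return Named integer vector, one entry per sample.
#' @export
observed_richness <- function(table) {
  if (table$normalized)
    stop("richness is computed on raw counts, not a normalized table")
  rowSums(table$counts > 0)
}

#' Rarefaction curves (analytic or Monte Carlo)
#'
#' Expected OTU richness at given subsampling depths. The analytic form is
#' the exact hypergeometric expectation
#' `E[S_d] = sum_i (1 - choose(N - n_i, d)/choose(N, d))` (via
#' [vegan::rarefy()]); `"montecarlo"` averages observed richness over
#' `n_reps` subsamples drawn without replacement. Depths exceeding a
#' sample's library size are reported as `NA`.
#'
#' @param table raw-count [otu_table()].
#' @param depths integer vector of subsampling depths.
#' @param method `"analytic"` (default) or `"montecarlo"`.
#' @param n_reps Monte Carlo replicates per depth.
#' @param seed optional seed for the Monte Carlo path.
#' @return A long `data.frame`: `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(table, depths, method = c("analytic", "montecarlo"),
                              n_reps = 100, seed = NULL) {
  method <- match.arg(method)
  if (table$normalized) stop("rarefaction requires raw counts")
  if (!is.null(seed)) set.seed(seed)
  sizes <- library_sizes(table)
  res <- expand.grid(sample_id = sample_ids(table), depth = depths,
                     stringsAsFactors = FALSE)
  res$richness <- NA_real_
  for (r in seq_len(nrow(res))) {
    s <- res$sample_id[r]; d <- res$depth[r]
    if (d > sizes[s]) next
    v <- table$counts[s, ]
    if (method == "analytic") {
      res$richness[r] <- unname(suppressWarnings(vegan::rarefy(v, sample = d)))
    } else {
      units <- rep.int(seq_along(v), v)
      res$richness[r] <- mean(vapply(seq_len(n_reps), function(i)
        length(unique(sample(units, d, replace = FALSE))), 1))
    }
  }
  res
}
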