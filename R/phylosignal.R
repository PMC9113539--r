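# Phylogenetic signal of elevational habitat preference: preferred
# elevation, bootstrap patristic-distance nulls for indicator sets, clade
# divergence contrasts, root-to-tip distances and effect sizes.

#' Preferred elevation per OTU
#'
#' Normalized abundance-weighted mean of the elevations of all samples in
#' which the OTU is detected: `PE_i = sum_s n_is e_s / sum_s n_is` over
#' samples with `n_is > 0`. Invariant to global count rescaling and always
#' bounded by the detection elevations.
#'
#' @param table an [otu_table()] (raw or normalized).
#' @param metadata metadata with `sample_id` and `elevation` covering the
#'   table's samples.
#' @return A `data.frame`: `otu_id`, `preferred_elevation`,
#'   `n_sites_detected`, `total_abundance` (undetected OTUs get `NA` with
#'   a warning).
#' @export
preferred_elevation <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  miss <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(miss))
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  e <- metadata$elevation[match(sample_ids(table), metadata$sample_id)]
  x <- table$counts
  tot <- colSums(x)
  pe <- as.vector(crossprod(x, e)) / tot
  if (any(tot == 0)) {
    warning(sum(tot == 0), " OTU(s) detected nowhere; preferred elevation NA")
    pe[tot == 0] <- NA_real_
  }
  data.frame(otu_id = otu_ids(table), preferred_elevation = pe,
             n_sites_detected = colSums(x > 0), total_abundance = tot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bootstrap null for indicator-set phylogenetic distances
#'
#' Compares a statistic (the mean by default) of all pairwise patristic
#' distances among an indicator set to a bootstrap distribution built by
#' repeatedly drawing, with replacement, the same number of distances from
#' the whole community's pairwise-distance pool. The draw unit is a SET of
#' distances matching the observed pair count, so the null is a sampling
#' distribution of set-level statistics and the 2.5/97.5 percentiles form a
#' 95% interval for the observed statistic. The empirical p is the add-one
#' fraction of draws at or below the observation ("more phylogenetically
#' similar than chance"); a plain two-sample t comparison of the indicator
#' distances against the pool is reported alongside.
#'
#' @param indicator_ids tip ids of the indicator set (>= 2), a subset of
#'   `community_ids`.
#' @param community_ids tip ids of the whole community (subset of the
#'   tree's tips).
#' @param tree `phylo` with branch lengths.
#' @param n_boot bootstrap draws (1,000 by default).
#' @param seed optional seed.
#' @param statistic function applied to each distance set (default `mean`).
#' @return List of class `bootstrap_pd_null`: `observed`, `null` (draws),
#'   `ci` (2.5/97.5 percentiles), `p`, `t_test`, `n_pairs`.
#' @export
bootstrap_pd_null <- function(indicator_ids, community_ids, tree,
                              n_boot = 1000, seed = NULL, statistic = mean) {
  if (length(indicator_ids) < 2) stop("need at least 2 indicator ids")
  if (!all(indicator_ids %in% community_ids))
    stop("indicator ids must be a subset of the community")
  if (!all(community_ids %in% tree$tip.label))
    stop("community ids must be tree tips")
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(patristic_matrix(tree))[community_ids, community_ids]
  pool <- D[lower.tri(D)]
  obs_d <- D[indicator_ids, indicator_ids]
  obs_d <- obs_d[lower.tri(obs_d)]
  n_pairs <- length(obs_d)
  observed <- statistic(obs_d)
  null <- vapply(seq_len(n_boot), function(i)
    statistic(sample(pool, n_pairs, replace = TRUE)), 1)
  tt <- if (n_pairs >= 2) t.test(obs_d, pool) else NULL
  structure(list(observed = observed, null = null,
                 ci = quantile(null, c(0.025, 0.975)),
                 p = perm_pvalue(sum(null <= observed + 1e-12), n_boot),
                 t_test = tt,
                 n_pairs = n_pairs),
            class = "bootstrap_pd_null")
}

#' @export
print.bootstrap_pd_null <- function(x, ...) {
  cat(sprintf(paste0("bootstrap patristic null: observed %s = %.4f over %d",
                     " pairs, 95%% null interval [%.4f, %.4f], p = %.4g\n"),
              "statistic", x$observed, x$n_pairs, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

# Maximal monophyletic groups whose tips are all labeled.
maximal_labeled_clades <- function(tree, labeled) {
  n <- ape::Ntip(tree)
  tips_of <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  ok <- vapply(tips_of, function(t) all(tree$tip.label[t] %in% labeled), TRUE)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n + 1L
  maximal <- which(ok & (seq_along(ok) == root | !ok[pmax(parent, 1L)]))
  lapply(maximal, function(nd) tree$tip.label[tips_of[[nd]]])
}

#' Clade-level divergence contrasts for indicator types
#'
#' Labels each clade by the elevation-preference types of its members
#' (`high_only`, `low_only`, `mixed`), measures its mean within-clade
#' pairwise patristic distance and mean root-to-tip distance, and contrasts
#' mean divergence between clade types with a permutation t-statistic
#' (shuffling type labels over clades), Bonferroni-corrected across the
#' comparisons. Clades default to the maximal monophyletic groups whose
#' tips are all labeled; size-1 clades have no within-clade distance and
#' are excluded from the contrasts with a warning.
#'
#' @param tree `phylo` with branch lengths.
#' @param elevation_labels named vector mapping tip ids to `"high"` or
#'   `"low"`.
#' @param clades optional list of tip-id vectors (disjoint); `NULL` derives
#'   them from the tree.
#' @param n_perm label permutations per contrast (1,000 by default).
#' @param seed optional seed.
#' @return List of class `clade_report`: `clades` (data frame per clade)
#'   and `comparisons` (data frame per contrast with Bonferroni-corrected
#'   p).
#' @export
clade_divergence_test <- function(tree, elevation_labels, clades = NULL,
                                  n_perm = 1000, seed = NULL) {
  if (is.null(names(elevation_labels)))
    stop("elevation_labels must be named by tip id")
  if (!all(names(elevation_labels) %in% tree$tip.label))
    stop("labels refer to tips absent from the tree")
  if (is.null(clades))
    clades <- maximal_labeled_clades(tree, names(elevation_labels))
  if (anyDuplicated(unlist(clades))) stop("clades must be disjoint tip sets")
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(patristic_matrix(tree))
  rtt <- root_to_tip(tree)$distances
  clade_type <- function(members) {
    t <- unique(elevation_labels[members])
    if (length(t) > 1) "mixed" else paste0(t, "_only")
  }
  df <- data.frame(
    clade = seq_along(clades),
    n_tips = lengths(clades),
    type = vapply(clades, clade_type, ""),
    mean_pairwise_distance = vapply(clades, function(m) {
      if (length(m) < 2) return(NA_real_)
      d <- D[m, m]; mean(d[lower.tri(d)])
    }, 1),
    mean_root_to_tip = vapply(clades, function(m) mean(rtt[m]), 1),
    stringsAsFactors = FALSE)
  df$members <- vapply(clades, paste, "", collapse = ",")
  if (any(df$n_tips < 2))
    warning(sum(df$n_tips < 2),
            " singleton clade(s) excluded from divergence contrasts")
  usable <- df[df$n_tips >= 2, , drop = FALSE]
  contrasts <- list(mixed_vs_pure = list(
                      g1 = usable$type == "mixed",
                      g2 = usable$type != "mixed"),
                    high_vs_low = list(
                      g1 = usable$type == "high_only",
                      g2 = usable$type == "low_only"))
  comp <- do.call(rbind, lapply(names(contrasts), function(nm) {
    g1 <- contrasts[[nm]]$g1; g2 <- contrasts[[nm]]$g2
    if (sum(g1) < 1 || sum(g2) < 1)
      return(data.frame(comparison = nm, delta = NA_real_, p = NA_real_))
    v <- usable$mean_pairwise_distance
    lab <- g1[g1 | g2]
    vv <- v[g1 | g2]
    obs <- mean(vv[lab]) - mean(vv[!lab])
    perm <- vapply(seq_len(n_perm), function(i) {
      pl <- sample(lab)
      mean(vv[pl]) - mean(vv[!pl])
    }, 1)
    data.frame(comparison = nm, delta = obs,
               p = perm_pvalue(sum(abs(perm) >= abs(obs) - 1e-12), n_perm))
  }))
  ntest <- sum(!is.na(comp$p))
  comp$p_bonferroni <- pmin(1, comp$p * max(1, ntest))
  structure(list(clades = df, comparisons = comp), class = "clade_report")
}

#' Root-to-tip distances and group contrast
#'
#' Sum of branch lengths from the root to each tip; when groups are given,
#' reports per-group mean and standard deviation and a Kruskal-Wallis test
#' (p = 1 when every distance is identical, as on an ultrametric tree).
#'
#' @param tree rooted `phylo`.
#' @param tip_ids tips to report (default all).
#' @param groups optional named vector mapping (a subset of) `tip_ids` to
#'   groups.
#' @return List: `distances` (named vector), and with groups `summary`
#'   (data frame) and `kruskal` (`statistic`, `p`).
#' @export
root_to_tip <- function(tree, tip_ids = NULL, groups = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(depths) <- tree$tip.label
  if (is.null(tip_ids)) tip_ids <- tree$tip.label
  unknown <- setdiff(tip_ids, tree$tip.label)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  out <- list(distances = depths[tip_ids])
  if (!is.null(groups)) {
    g <- factor(groups[tip_ids])
    d <- out$distances[!is.na(g)]
    g <- droplevels(g[!is.na(g)])
    out$summary <- data.frame(group = levels(g),
                              n = as.vector(table(g)),
                              mean = as.vector(tapply(d, g, mean)),
                              sd = as.vector(tapply(d, g, sd)),
                              stringsAsFactors = FALSE)
    if (stats::sd(d) < 1e-12 || nlevels(droplevels(g)) < 2) {
      out$kruskal <- list(statistic = 0, p = 1)
    } else {
      kw <- kruskal.test(d, g)
      out$kruskal <- list(statistic = unname(kw$statistic),
                          p = kw$p.value)
    }
  }
  out
}

#' Shared-OTU abundance test between two communities
#'
#' Counts OTUs present in both tables and asks whether their pooled
#' regional relative abundance is higher than for a random draw of the
#' same number of OTUs from the pooled meta-community list (add-one
#' permutation p; one-sided, "shared OTUs are more abundant").
#'
#' @param table_a,table_b [otu_table()]s over a shared OTU id space.
#' @param n_perm random draws (1,000 by default).
#' @param seed optional seed.
#' @return List: `n_shared`, `observed_mean_abundance`, `p` (`NA` when no
#'   OTU is shared), `shared_ids`.
#' @export
shared_otu_abundance_test <- function(table_a, table_b, n_perm = 1000,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tot_a <- colSums(table_a$counts); tot_b <- colSums(table_b$counts)
  pres_a <- names(tot_a)[tot_a > 0]; pres_b <- names(tot_b)[tot_b > 0]
  shared <- intersect(pres_a, pres_b)
  pool_ids <- union(pres_a, pres_b)
  pooled <- setNames(numeric(length(pool_ids)), pool_ids)
  pooled[names(tot_a)] <- pooled[names(tot_a)] + tot_a
  pooled[names(tot_b)] <- pooled[names(tot_b)] + tot_b
  pooled <- pooled[pool_ids] / sum(pooled[pool_ids])
  if (length(shared) == 0)
    return(list(n_shared = 0L, observed_mean_abundance = NA_real_,
                p = NA_real_, shared_ids = character(0)))
  obs <- mean(pooled[shared])
  null <- vapply(seq_len(n_perm), function(i)
    mean(pooled[sample(pool_ids, length(shared))]), 1)
  list(n_shared = length(shared), observed_mean_abundance = obs,
       p = perm_pvalue(sum(null >= obs - 1e-12), n_perm),
       shared_ids = shared)
}

#' Cohen's d with Welch's t-test
#'
#' Pooled-standard-deviation standardized mean difference
#' `d = (mean_a - mean_b)/s_pooled`; Welch's t-test reported alongside.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @return List: `d`, `t`, `p`, `mean_a`, `mean_b`.
#' @export
cohens_d <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * var(values_a) + (nb - 1) * var(values_b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance; effect size undefined")
  tt <- t.test(values_a, values_b)
  list(d = (mean(values_a) - mean(values_b)) / sqrt(sp2),
       t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b))
}
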