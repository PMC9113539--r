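# Null-model partition of community assembly (Stegen-style framework).
# Two complementary nulls per sample pair: a phylogenetic one (beta-NTI,
# tip-label shuffling of beta-MNTD) detects selection, and a taxonomic one
# (Raup-Crick on Bray-Curtis under a richness- and abundance-preserving
# null) separates dispersal limitation and homogenizing dispersal from
# drift among the pairs selection cannot explain.

#' Between-community mean nearest-taxon distance (beta-MNTD)
#'
#' For samples j, k:
#' `0.5 * (sum_i f_ij min_{i' in k} d(i, i') + sum_i' f_i'k min_{i in j} d(i, i'))`
#' with `f` the within-sample relative abundances (or `1/richness` when
#' unweighted) and `d` the patristic distance.
#'
#' @param table an [otu_table()] with no empty samples.
#' @param tree `phylo` covering the table's OTUs.
#' @param abundance_weighted weight by relative abundance (default) or
#'   presence only.
#' @return A labeled `dist` in tree branch-length units.
#' @export
pairwise_bmntd <- function(table, tree, abundance_weighted = TRUE) {
  prep <- bmntd_prepare(table, tree, abundance_weighted)
  m <- bmntd_core(prep$f, prep$D, prep$support, seq_len(ncol(prep$f)))
  as_dist_checked(m, labels = sample_ids(table), metric = "bmntd")
}

bmntd_prepare <- function(table, tree, abundance_weighted) {
  x <- table$counts
  if (any(rowSums(x) == 0))
    stop("beta-MNTD is undefined for empty sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  lost <- setdiff(colnames(x), tree$tip.label)
  if (length(lost))
    stop("OTUs absent from the tree: ", paste(lost, collapse = ", "))
  D <- as.matrix(patristic_matrix(tree))[colnames(x), colnames(x)]
  f <- if (abundance_weighted) x / rowSums(x) else {
    p <- (x > 0) + 0
    p / rowSums(p)
  }
  support <- apply(x > 0, 1L, which, simplify = FALSE)
  list(f = f, D = D, support = support)
}

# beta-MNTD for one tip relabeling `g` (a permutation of taxon indices;
# identity = observed). M[, k] = min over taxa of sample k (relabeled) of
# the distance to every taxon, evaluated at relabeled positions.
bmntd_core <- function(f, D, support, g) {
  n_s <- nrow(f)
  M <- vapply(support, function(idx) {
    rows <- g[idx]
    if (length(rows) == 1L) D[rows, ] else
      do.call(pmin, lapply(rows, function(r) D[r, ]))
  }, numeric(ncol(D)))
  Mg <- M[g, , drop = FALSE]
  A <- f %*% Mg
  m <- 0.5 * (A + t(A))
  diag(m) <- 0
  dimnames(m) <- list(rownames(f), rownames(f))
  m
}

#' Beta nearest-taxon index (beta-NTI)
#'
#' Standardized effect size of beta-MNTD against a null that shuffles tip
#' labels across the whole tree: `(obs - mean_null)/sd_null` per sample
#' pair. `|beta-NTI| > 2` indicates selection — variable selection when
#' positive (communities more phylogenetically distinct than chance),
#' homogeneous selection when negative. One seeded stream generates a
#' shared set of relabelings used for every pair, so results are
#' deterministic regardless of pair order.
#'
#' @inheritParams pairwise_bmntd
#' @param n_null number of tip relabelings (999 by default).
#' @param seed optional seed.
#' @return A labeled symmetric matrix of beta-NTI values (`NA` with a
#'   warning where the null is degenerate, sd = 0).
#' @export
bnti <- function(table, tree, n_null = 999, seed = NULL,
                 abundance_weighted = TRUE) {
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips for tip-label nulls")
  prep <- bmntd_prepare(table, tree, abundance_weighted)
  n_t <- ncol(prep$f)
  obs <- bmntd_core(prep$f, prep$D, prep$support, seq_len(n_t))
  if (!is.null(seed)) set.seed(seed)
  s1 <- matrix(0, nrow(obs), ncol(obs))
  s2 <- matrix(0, nrow(obs), ncol(obs))
  for (r in seq_len(n_null)) {
    g <- sample.int(n_t)
    nb <- bmntd_core(prep$f, prep$D, prep$support, g)
    s1 <- s1 + nb
    s2 <- s2 + nb^2
  }
  mu <- s1 / n_null
  sdv <- sqrt(pmax(0, (s2 - n_null * mu^2) / (n_null - 1)))
  out <- (obs - mu) / sdv
  degenerate <- sdv == 0 & upper.tri(sdv)
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) have a degenerate null (sd = 0); ",
            "beta-NTI reported as NA")
    out[sdv == 0] <- NA_real_
  }
  diag(out) <- 0
  dimnames(out) <- list(sample_ids(table), sample_ids(table))
  out
}

# One null community for the Raup-Crick model: draw the sample's observed
# richness of species without replacement with probability proportional to
# occupancy, give each one individual, then allocate the remaining reads
# multinomially with probability proportional to regional relative
# abundance.
rc_null_community <- function(n_taxa, richness, depth, occupancy, regional) {
  sp <- sample.int(n_taxa, richness, prob = occupancy, replace = FALSE)
  x <- numeric(n_taxa)
  x[sp] <- 1
  extra <- depth - richness
  if (extra > 0)
    x[sp] <- x[sp] + rmultinom(1L, extra, regional[sp])[, 1L]
  x
}

#' Raup-Crick dissimilarity on Bray-Curtis (RC-bray)
#'
#' Per sample pair, compares the observed Bray-Curtis dissimilarity to
#' `n_null` dissimilarities between null communities that preserve each
#' sample's observed richness and total reads, with species drawn by
#' occupancy and reads allocated by regional relative abundance. The rank
#' of the observation (ties at half weight) is rescaled to \[-1, 1\]:
#' values near +1 mean the pair is more dissimilar than the null expects
#' (dispersal limitation), near -1 less dissimilar (homogenizing
#' dispersal).
#'
#' @param table raw-count [otu_table()] with at least 2 samples.
#' @param n_null null replicates per pair (999 by default).
#' @param seed optional seed.
#' @param reference optional raw-count [otu_table()] over the same OTU ids
#'   from which occupancy and regional abundance are estimated (e.g. a
#'   larger survey of the metacommunity); defaults to `table` itself.
#' @return A labeled symmetric matrix of RC values in \[-1, 1\].
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = NULL,
                            reference = table) {
  if (table$normalized || reference$normalized)
    stop("RC-bray requires raw counts")
  x <- table$counts
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (any(rowSums(x) == 0))
    stop("empty sample(s): ", paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  if (!identical(colnames(reference$counts), colnames(x)))
    stop("reference must cover the same OTU ids in the same order")
  if (!is.null(seed)) set.seed(seed)
  occupancy <- colSums(reference$counts > 0)
  regional <- colSums(reference$counts) / sum(reference$counts)
  ## taxa never observed cannot enter a null community
  usable <- occupancy > 0
  occ_u <- occupancy[usable]; reg_u <- regional[usable]
  n_taxa <- sum(usable)
  rich <- rowSums(x > 0)
  if (any(rich > n_taxa))
    stop("a sample is richer than the reference pool; null is infeasible")
  depth <- round(rowSums(x))
  n_s <- nrow(x)
  out <- matrix(0, n_s, n_s, dimnames = list(rownames(x), rownames(x)))
  bc <- function(u, v) sum(abs(u - v)) / sum(u + v)
  for (j in seq_len(n_s - 1L)) {
    for (k in (j + 1L):n_s) {
      obs <- bc(x[j, ], x[k, ])
      nulls <- vapply(seq_len(n_null), function(i) {
        bc(rc_null_community(n_taxa, rich[j], depth[j], occ_u, reg_u),
           rc_null_community(n_taxa, rich[k], depth[k], occ_u, reg_u))
      }, 1)
      frac <- (sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null
      out[j, k] <- out[k, j] <- (frac - 0.5) * 2
    }
  }
  out
}

#' Classify assembly processes from beta-NTI and RC-bray
#'
#' Threshold table: beta-NTI > +2 is variable selection, < -2 homogeneous
#' selection; among pairs with |beta-NTI| <= 2, RC > +0.95 is dispersal
#' limitation (with drift), RC < -0.95 homogenizing dispersal, and the
#' remainder drift.
#'
#' @param bnti_m beta-NTI matrix from [bnti()].
#' @param rc_m RC matrix from [raup_crick_bray()], conformable.
#' @param bnti_threshold,rc_threshold classification thresholds (2, 0.95).
#' @return A `data.frame` of class `assembly_classification`, one row per
#'   unordered sample pair: `sample_1`, `sample_2`, `bnti`, `rc`,
#'   `process` (factor; `NA` where beta-NTI is missing).
#' @export
classify_processes <- function(bnti_m, rc_m, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  bnti_m <- as.matrix(bnti_m); rc_m <- as.matrix(rc_m)
  if (!identical(dim(bnti_m), dim(rc_m)))
    stop("beta-NTI and RC matrices are not conformable")
  if (!is.null(rownames(bnti_m)) && !is.null(rownames(rc_m)) &&
      !identical(rownames(bnti_m), rownames(rc_m)))
    stop("beta-NTI and RC matrices carry different sample orders")
  idx <- which(upper.tri(bnti_m), arr.ind = TRUE)
  b <- bnti_m[upper.tri(bnti_m)]
  r <- rc_m[upper.tri(rc_m)]
  lv <- c("variable_selection", "homogeneous_selection",
          "dispersal_limitation_drift", "homogenizing_dispersal", "drift")
  proc <- ifelse(is.na(b), NA_character_,
          ifelse(b > bnti_threshold, "variable_selection",
          ifelse(b < -bnti_threshold, "homogeneous_selection",
          ifelse(!is.na(r) & r > rc_threshold, "dispersal_limitation_drift",
          ifelse(!is.na(r) & r < -rc_threshold, "homogenizing_dispersal",
                 "drift")))))
  labs <- rownames(bnti_m)
  out <- data.frame(sample_1 = labs[idx[, 1L]], sample_2 = labs[idx[, 2L]],
                    bnti = b, rc = r,
                    process = factor(proc, levels = lv),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(bnti = bnti_threshold, rc = rc_threshold)
  attr(out, "n_missing") <- sum(is.na(proc))
  class(out) <- c("assembly_classification", "data.frame")
  out
}

#' Assign samples to elevation zones
#'
#' High above `high` (strictly), Low below `low` (strictly), Middle
#' otherwise — so samples at exactly 500 or 1,000 m are Middle.
#'
#' @param elevation numeric elevations, meters.
#' @param high,low zone boundaries (1,000 and 500 m).
#' @return Factor with levels Low, Middle, High.
#' @export
assign_zones <- function(elevation, high = 1000, low = 500) {
  factor(ifelse(elevation > high, "High",
                ifelse(elevation < low, "Low", "Middle")),
         levels = c("Low", "Middle", "High"))
}

#' Assembly-process fractions per zone pair
#'
#' For each unordered zone pair (including within-zone), the fraction of
#' sample pairs assigned to each process. Pairs with a missing process are
#' excluded from the fractions and counted in `n_excluded`.
#'
#' @param classification an `assembly_classification`.
#' @param zones named vector (or factor) mapping every sample to a zone.
#' @return A `data.frame`: `zone_pair`, `n_pairs`, one fraction column per
#'   process (rows sum to 1), `n_excluded`.
#' @export
zone_summary <- function(classification, zones) {
  zones <- setNames(as.character(zones), names(zones))
  miss <- setdiff(unique(c(classification$sample_1, classification$sample_2)),
                  names(zones))
  if (length(miss))
    stop("samples without a zone: ", paste(miss, collapse = ", "))
  z1 <- zones[classification$sample_1]
  z2 <- zones[classification$sample_2]
  pair <- ifelse(z1 <= z2, paste(z1, z2, sep = "-"), paste(z2, z1, sep = "-"))
  lv <- levels(classification$process)
  keep <- !is.na(classification$process)
  tab <- table(pair[keep], classification$process[keep])
  excl <- table(pair[!keep])
  out <- data.frame(zone_pair = rownames(tab),
                    n_pairs = as.vector(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (p in lv) out[[p]] <- as.vector(tab[, p]) / pmax(1, rowSums(tab))
  out$n_excluded <- as.vector(excl[match(out$zone_pair, names(excl))])
  out$n_excluded[is.na(out$n_excluded)] <- 0L
  out
}
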