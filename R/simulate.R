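# Synthetic community generator. Three layers, mirroring how elevation is
# thought to structure the communities: (1) a pure-birth phylogeny, (2)
# Brownian-motion evolution of a per-OTU elevation optimum on that
# phylogeny (habitat preference is heritable, so optima are phylogenetically
# conserved), (3) multinomial sampling of reads per sample from a regional
# log-normal pool filtered by a Gaussian kernel around each OTU's optimum,
# with optional dispersal mixing of expected compositions within dispersal
# pools. The knobs map onto assembly processes: filter width `filter_sigma`
# is selection strength, mixing fraction `dispersal_mix` is homogenizing
# dispersal, and an infinite filter with no mixing is pure drift.

#' Configuration for the synthetic community generator
#'
#' Defaults describe a regional pool of 300 OTUs whose elevation optima are
#' centred mid-gradient (800 m) and spread widely enough (Brownian sigma
#' 150 m per unit branch length on a tree of height ~log(n)) to span a
#' 400-1,200 m transect, sampled at 150 reads per sample — the shallow,
#' sparse-sampling regime typical of taxon-targeted amplicon libraries,
#' where each community realizes only a fraction of the regional pool.
#'
#' @param n_otus number of OTUs (tree tips) in the regional pool.
#' @param birth_rate Yule speciation rate (1/time).
#' @param bm_sigma Brownian-motion standard deviation of the elevation
#'   optimum, meters per square root of branch length.
#' @param root_optimum ancestral elevation optimum, meters.
#' @param filter_sigma Gaussian habitat-filter width, meters; `Inf` disables
#'   selection.
#' @param dispersal_mix fraction `m` in \[0, 1\] of each sample's expected
#'   composition replaced by its dispersal pool's mean composition.
#' @param mixing_pools how samples are pooled for dispersal mixing:
#'   `"zones"` (the High/Middle/Low analysis zones), `"merge_low_middle"`
#'   (Low and Middle share one pool, High separate — downslope transport),
#'   or `"all"` (one pool).
#' @param lognormal_mu,lognormal_sigma log-scale parameters of the regional
#'   abundance distribution.
#' @param depth reads per sample (multinomial total, exact).
#' @param seed integer seed; the full dataset is a deterministic function
#'   of the configuration including the seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_otus = 300, birth_rate = 1, bm_sigma = 150,
                             root_optimum = 800, filter_sigma = 150,
                             dispersal_mix = 0,
                             mixing_pools = c("zones", "merge_low_middle", "all"),
                             lognormal_mu = 0, lognormal_sigma = 1,
                             depth = 150, seed = 1) {
  mixing_pools <- match.arg(mixing_pools)
  if (filter_sigma <= 0) stop("filter_sigma must be > 0")
  if (dispersal_mix < 0 || dispersal_mix > 1)
    stop("dispersal_mix must lie in [0, 1]")
  if (depth < 1) stop("depth must be >= 1")
  if (bm_sigma < 0) stop("bm_sigma must be >= 0")
  structure(list(n_otus = n_otus, birth_rate = birth_rate,
                 bm_sigma = bm_sigma, root_optimum = root_optimum,
                 filter_sigma = filter_sigma, dispersal_mix = dispersal_mix,
                 mixing_pools = mixing_pools, lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma, depth = depth,
                 seed = seed),
            class = "synthetic_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Starts from the root split (two lineages) and waits
#' Exponential(k * birth_rate) between successive splits while k lineages
#' are extant; the lineage that splits is chosen uniformly. After the n-th
#' tip arises the tree grows for one further Exponential(n * birth_rate)
#' interval so every terminal branch has positive length. The tree is
#' ultrametric by construction.
#'
#' @param n_otus number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed optional integer seed (omit when the caller manages the RNG).
#' @return A rooted ultrametric `phylo` with tips `OTU_0001`, ...
#' @export
simulate_tree <- function(n_otus, birth_rate = 1, seed = NULL) {
  if (n_otus < 2) stop("n_otus must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_otus)
  ## provisional internal node ids in creation order; root is 1
  parent_of <- c(1L, 1L)      # pending parent node per active lineage
  time_of <- c(0, 0)          # time of that parent node
  node_count <- 1L
  edges <- matrix(0L, 2L * n - 2L, 2L)
  lengths <- numeric(2L * n - 2L)
  n_edge <- 0L
  t <- 0
  k <- 2L
  while (k < n) {
    t <- t + rexp(1L, rate = k * birth_rate)
    i <- sample.int(k, 1L)
    node_count <- node_count + 1L
    n_edge <- n_edge + 1L
    edges[n_edge, ] <- c(parent_of[i], node_count)
    lengths[n_edge] <- t - time_of[i]
    parent_of[i] <- node_count; time_of[i] <- t
    parent_of <- append(parent_of, node_count, after = i)
    time_of <- append(time_of, t, after = i)
    k <- k + 1L
  }
  t_end <- t + rexp(1L, rate = n * birth_rate)
  for (i in seq_len(n)) {
    n_edge <- n_edge + 1L
    edges[n_edge, ] <- c(parent_of[i], -i)   # negative = tip placeholder
    lengths[n_edge] <- t_end - time_of[i]
  }
  ## remap: tips 1..n, internals n+1 .. 2n-1 (creation order, root first)
  remap <- function(v) ifelse(v < 0L, -v, v + n)
  tree <- list(edge = cbind(remap(edges[, 1L]), remap(edges[, 2L])),
               edge.length = lengths,
               tip.label = sprintf("OTU_%04d", seq_len(n)),
               Nnode = n - 1L)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Evolve elevation optima along a tree by Brownian motion
#'
#' Each child node's optimum is its parent's plus a Normal(0,
#' bm_sigma^2 * branch_length) increment, so trait covariance between tips
#' equals shared path length times bm_sigma^2 — elevational preference is
#' phylogenetically conserved by construction.
#'
#' @param tree a `phylo` with branch lengths.
#' @param bm_sigma Brownian standard deviation (trait units per sqrt branch
#'   length); 0 returns the root optimum for every tip.
#' @param root_optimum trait value at the root, meters.
#' @param seed optional integer seed.
#' @return Named numeric vector of tip optima (meters).
#' @export
evolve_optima <- function(tree, bm_sigma, root_optimum = 800, seed = NULL) {
  if (bm_sigma < 0) stop("bm_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  vals <- numeric(n + tree$Nnode)
  vals[n + 1L] <- root_optimum
  inc <- rnorm(nrow(tree$edge), 0, bm_sigma * sqrt(tree$edge.length))
  for (e in seq_len(nrow(tree$edge)))
    vals[tree$edge[e, 2L]] <- vals[tree$edge[e, 1L]] + inc[e]
  setNames(vals[seq_len(n)], tree$tip.label)
}

# Dispersal pools for a vector of sample elevations.
mixing_pool_ids <- function(elevation, mixing_pools, high = 1000, low = 500) {
  z <- as.character(assign_zones(elevation, high = high, low = low))
  switch(mixing_pools,
         zones = z,
         merge_low_middle = ifelse(z == "High", "High", "LowMiddle"),
         all = rep("all", length(z)))
}

#' Assemble synthetic communities on a sampling design
#'
#' Expected weight of OTU i in sample s is its regional log-normal
#' abundance times a Gaussian habitat filter
#' `exp(-(e_s - opt_i)^2 / (2 filter_sigma^2))`. Dispersal mixing replaces
#' each sample's expected weight vector with
#' `(1 - m) * own + m * pool mean` before the multinomial draw, so library
#' sizes stay exactly `depth`. With `filter_sigma = Inf` and `m = 0` every
#' sample is a neutral multinomial draw from the regional pool.
#'
#' @param tree phylogeny whose tips are the OTU pool.
#' @param optima named per-OTU elevation optima covering all tips.
#' @param design a `sampling_design`.
#' @param config a [synthetic_config()]; its `seed` is NOT applied here —
#'   use [simulate_dataset()] for end-to-end seeded generation, or seed the
#'   RNG yourself.
#' @param regime_label free-text label stored with the dataset.
#' @return A list of class `synthetic_dataset`: `table` (raw counts),
#'   `metadata`, `tree`, `true_optima`, `regime`, `config`.
#' @export
assemble_communities <- function(tree, optima, design, config,
                                 regime_label = "custom") {
  if (!all(tree$tip.label %in% names(optima)))
    stop("optima must cover every tree tip")
  optima <- optima[tree$tip.label]
  meta <- design_samples(design)
  n_s <- nrow(meta)
  n_t <- length(optima)
  pool_abund <- rlnorm(n_t, config$lognormal_mu, config$lognormal_sigma)
  gauss <- if (is.finite(config$filter_sigma)) {
    exp(-outer(meta$elevation, optima, "-")^2 / (2 * config$filter_sigma^2))
  } else matrix(1, n_s, n_t)
  w <- sweep(gauss, 2L, pool_abund, "*")
  if (any(rowSums(w) == 0))
    stop("a sample has zero expected weight for every OTU; ",
         "increase filter_sigma")
  m <- config$dispersal_mix
  if (m > 0) {
    pools <- mixing_pool_ids(meta$elevation, config$mixing_pools)
    for (p in unique(pools)) {
      idx <- which(pools == p)
      pool_mean <- colMeans(w[idx, , drop = FALSE])
      w[idx, ] <- (1 - m) * w[idx, , drop = FALSE] +
        m * matrix(pool_mean, length(idx), n_t, byrow = TRUE)
    }
  }
  counts <- t(vapply(seq_len(n_s),
                     function(s) rmultinom(1L, config$depth, w[s, ])[, 1L],
                     integer(n_t)))
  dimnames(counts) <- list(meta$sample_id, names(optima))
  structure(list(table = otu_table(counts),
                 metadata = validate_metadata(meta),
                 tree = tree,
                 true_optima = optima,
                 regime = regime_label,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples x %d OTUs, regime '%s', seed %d\n",
              nrow(x$table$counts), ncol(x$table$counts), x$regime,
              x$config$seed))
  invisible(x)
}

#' Simulate a full synthetic dataset under a named regime
#'
#' One call generating tree, optima and counts under a single seed. The
#' regimes fix the assembly-process knobs: `"selection"` uses a strong
#' habitat filter (`filter_sigma` 100 m, no mixing), `"neutral"` disables
#' selection and mixing (pure drift), and `"dispersal"` combines a moderate
#' filter (200 m) with strong mixing (`dispersal_mix` 0.9) across a shared
#' Low+Middle pool, emulating downslope transport below the summit zone.
#'
#' @param design `"wm"`, `"wl"` or a `sampling_design`.
#' @param regime `"selection"`, `"neutral"`, `"dispersal"` or `"custom"`
#'   (take all knobs from `config`).
#' @param config a [synthetic_config()]; regime presets override its
#'   `filter_sigma`, `dispersal_mix` and `mixing_pools`.
#' @param seed integer seed overriding `config$seed` when given.
#' @return A `synthetic_dataset`.
#' @export
simulate_dataset <- function(design = c("wm", "wl"),
                             regime = c("selection", "neutral", "dispersal",
                                        "custom"),
                             config = synthetic_config(), seed = NULL) {
  regime <- match.arg(regime)
  if (is.character(design))
    design <- switch(match.arg(design), wm = make_wm_design(),
                     wl = make_wl_design())
  if (!is.null(seed)) config$seed <- as.integer(seed)
  preset <- switch(regime,
                   selection = list(filter_sigma = 100, dispersal_mix = 0),
                   neutral = list(filter_sigma = Inf, dispersal_mix = 0),
                   dispersal = list(filter_sigma = 200, dispersal_mix = 0.9,
                                    mixing_pools = "merge_low_middle"),
                   custom = list())
  config[names(preset)] <- preset
  set.seed(config$seed)
  tree <- simulate_tree(config$n_otus, config$birth_rate)
  optima <- evolve_optima(tree, config$bm_sigma, config$root_optimum)
  assemble_communities(tree, optima, design, config, regime_label = regime)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the count table and metadata as TSV, the tree as Newick, and a
#' JSON sidecar recording the configuration, regime and true optima so any
#' downstream result can be traced to its generating parameters.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$table, file.path(dir, "otu_table.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  sidecar <- list(regime = dataset$regime,
                  config = unclass(dataset$config),
                  note = paste("synthetic data; regime parameters are",
                               "generator settings, not estimates"),
                  true_optima = as.list(dataset$true_optima))
  jsonlite::write_json(sidecar, file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
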