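test_that("Yule simulator is deterministic, ultrametric and rate-faithful", {
  expect_error(simulate_tree(1), "n_otus")
  t2 <- simulate_tree(2, seed = 3)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(ape::is.ultrametric(t2))

  a <- ape::write.tree(simulate_tree(50, seed = 1))
  b <- ape::write.tree(simulate_tree(50, seed = 1))
  expect_identical(a, b)

  # log-lineage-through-time slope recovers the birth rate
  slopes <- vapply(1:100, function(s) {
    tr <- simulate_tree(200, birth_rate = 1, seed = 1000 + s)
    depth <- max(ape::node.depth.edgelength(tr))
    split_times <- sort(depth - ape::branching.times(tr))
    unname(coef(lm(log(seq_along(split_times) + 1) ~ split_times))[2])
  }, 1)
  expect_equal(mean(slopes), 1, tolerance = 0.2)
})

test_that("Brownian optima have the covariance structure of the tree", {
  tr <- read_tree(text = "(A:1,B:1);")
  expect_equal(unname(evolve_optima(tr, 0, 800, seed = 1)), c(800, 800))
  expect_error(evolve_optima(tr, -1), "bm_sigma")

  # tip variance on unit branches: Var = bm_sigma^2
  tips <- vapply(1:1000, function(s) evolve_optima(tr, 100, 0, seed = s)[1], 1)
  expect_equal(var(tips), 1e4, tolerance = 0.15)

  # deep split: between-clade variance dominates within
  deep <- read_tree(text = "((A:0.1,B:0.1):4.9,(C:0.1,D:0.1):4.9);")
  hits <- vapply(1:100, function(s) {
    o <- evolve_optima(deep, 100, 0, seed = 2000 + s)
    between <- var(c(mean(o[c("A", "B")]), mean(o[c("C", "D")])))
    within <- mean(c(var(o[c("A", "B")]), var(o[c("C", "D")])))
    between > within
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("community assembly respects depth, filtering and determinism", {
  cfg <- synthetic_config(n_otus = 50, depth = 200, seed = 9)
  ds1 <- simulate_dataset("wm", "selection", config = cfg)
  ds2 <- simulate_dataset("wm", "selection", config = cfg)
  expect_identical(ds1$table$counts, ds2$table$counts)
  expect_identical(ds1$true_optima, ds2$true_optima)
  expect_true(all(library_sizes(ds1$table) == 200))

  # a narrow filter forbids far-from-optimum OTUs in mixed communities
  tr <- simulate_tree(40, seed = 5)
  opt <- setNames(rep(c(1200, 400), 20), tr$tip.label)
  design <- make_wm_design()
  set.seed(11)
  narrow <- synthetic_config(n_otus = 40, filter_sigma = 50, depth = 500)
  ds <- assemble_communities(tr, opt, design, narrow)
  low <- ds$metadata$sample_id[ds$metadata$elevation == 400]
  high_pref <- names(opt)[opt == 1200]
  expect_equal(sum(ds$table$counts[low, high_pref]), 0)

  # all-zero expected weight errors with advice
  opt_far <- setNames(rep(1e6, 40), tr$tip.label)
  expect_error(assemble_communities(tr, opt_far, design, narrow),
               "filter_sigma")
})

test_that("neutral regime draws every sample from one shared pool", {
  # identical expected composition across samples: chi-square homogeneity
  # not rejected at alpha = 0.01 in >= 95/100 seeds
  design <- structure(data.frame(site_id = paste0("x", 1:6),
                                 elevation = c(400, 500, 700, 900, 1100, 1200),
                                 n_replicates = 1L),
                      class = c("sampling_design", "data.frame"))
  cfg <- synthetic_config(n_otus = 20, depth = 1000, filter_sigma = Inf)
  rejected <- vapply(1:100, function(s) {
    cfg$seed <- 5000 + s
    ds <- simulate_dataset(design, "neutral", config = cfg)
    x <- ds$table$counts[, colSums(ds$table$counts) > 0, drop = FALSE]
    suppressWarnings(chisq.test(x, simulate.p.value = TRUE,
                                B = 499)$p.value) < 0.01
  }, TRUE)
  expect_gte(sum(!rejected), 95)
})

test_that("full dispersal mixing homogenizes compositions within a pool", {
  hits <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_otus = 60, depth = 300, filter_sigma = 150,
                            dispersal_mix = 1, mixing_pools = "zones",
                            seed = 6000 + s)
    ds <- simulate_dataset("wm", "custom", config = cfg)
    bc <- as.matrix(bray_curtis(ds$table))
    z <- assign_zones(ds$metadata$elevation)
    same <- outer(z, z, "==")
    lt <- lower.tri(bc)
    mean(bc[lt & same]) < mean(bc[lt & !same])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("written datasets round-trip through the plain-text formats", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset("wl", "neutral",
                         config = synthetic_config(n_otus = 30, depth = 100),
                         seed = 77)
  write_dataset(ds, dir)
  tab <- read_otu_table(file.path(dir, "otu_table.tsv"))
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  tr <- read_tree(file.path(dir, "tree.nwk"))
  vd <- validate_dataset(tab, md, tr)
  expect_identical(tab$counts, ds$table$counts)
  side <- jsonlite::read_json(file.path(dir, "simulation.json"))
  expect_equal(side$regime, "neutral")
  expect_equal(side$config$seed, 77)
})
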