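test_that("bootstrap patristic null behaves at its fixed points", {
  tree <- simulate_tree(20, seed = 1)
  tips <- tree$tip.label
  # indicator set = whole community: observed equals the pool mean
  bp <- bootstrap_pd_null(tips, tips, tree, n_boot = 500, seed = 2)
  D <- as.matrix(patristic_matrix(tree))
  expect_equal(bp$observed, mean(D[lower.tri(D)]), tolerance = 1e-12)
  expect_gt(bp$p, 0.2); expect_lt(bp$p, 0.8)

  # determinism
  bp2 <- bootstrap_pd_null(tips[1:5], tips, tree, n_boot = 200, seed = 9)
  bp3 <- bootstrap_pd_null(tips[1:5], tips, tree, n_boot = 200, seed = 9)
  expect_identical(bp2$ci, bp3$ci)

  expect_error(bootstrap_pd_null(tips[1], tips, tree), "2 indicator")
  expect_error(bootstrap_pd_null(c("nope", "nah"), tips, tree), "subset")
})

test_that("clade divergence contrasts detect constructed structure", {
  # zero-length cherry has zero divergence; identical compositions give p = 1
  tree <- read_tree(text = "((A:0,B:0):1,((C:0,D:0):1,(E:1,F:1):1):1);")
  labels <- c(A = "high", B = "high", C = "low", D = "low",
              E = "high", F = "low")
  rep <- clade_divergence_test(tree, labels,
                               clades = list(c("A", "B"), c("C", "D"),
                                             c("E", "F")),
                               n_perm = 199, seed = 4)
  expect_equal(rep$clades$mean_pairwise_distance[1], 0)
  expect_equal(rep$clades$type, c("high_only", "low_only", "mixed"))

  same <- clade_divergence_test(tree, labels,
                                clades = list(c("A", "B"), c("C", "D")),
                                n_perm = 199, seed = 5)
  expect_equal(same$comparisons$p[same$comparisons$comparison == "high_vs_low"],
               1)

  # six deep mixed clades vs six shallow pure cherries, built as a ladder
  cherry <- function(i, len) sprintf("(t%d_1:%g,t%d_2:%g)", i, len, i, len)
  lens <- rep(c(2, 0.05), each = 6)  # clades 1-6 mixed/deep, 7-12 pure/shallow
  nw <- cherry(12, lens[12])
  for (i in 11:1) nw <- sprintf("(%s:1,%s:1)", cherry(i, lens[i]), nw)
  tr <- read_tree(text = paste0(nw, ";"))
  lab <- setNames(rep("high", 24), paste0("t", rep(1:12, each = 2),
                                          "_", rep(1:2, 12)))
  lab[paste0("t", 1:6, "_2")] <- "low"      # mixed clades
  lab[paste0("t", 7:9, "_1")] <- lab[paste0("t", 7:9, "_2")] <- "low"
  clades <- lapply(1:12, function(i) paste0("t", i, "_", 1:2))
  hits <- vapply(1:20, function(s) {
    rp <- clade_divergence_test(tr, lab, clades = clades, n_perm = 499,
                                seed = 6000 + s)
    cmp <- rp$comparisons[rp$comparisons$comparison == "mixed_vs_pure", ]
    cmp$delta > 0 && cmp$p_bonferroni <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("maximal labeled clades are found from the tree", {
  tree <- read_tree(text = "(((A:1,B:1):1,C:2):1,(D:1,E:1):2);")
  labels <- c(A = "high", B = "high", D = "low", E = "low")
  rep <- clade_divergence_test(tree, labels, n_perm = 49, seed = 6)
  members <- sort(rep$clades$members)
  expect_equal(members, c("A,B", "D,E"))
})

test_that("root-to-tip distances are path sums with a group contrast", {
  tree <- read_tree(text = "(A:1,(B:1,C:3):1);")
  rt <- root_to_tip(tree)
  expect_equal(unname(rt$distances[c("A", "B", "C")]), c(1, 2, 4))
  expect_error(root_to_tip(tree, "Z"), "unknown")

  # ultrametric: all equal, Kruskal-Wallis degenerates to p = 1
  ut <- simulate_tree(12, seed = 7)
  g <- setNames(rep(c("x", "y"), 6), ut$tip.label)
  rtu <- root_to_tip(ut, groups = g)
  expect_equal(rtu$kruskal$p, 1)
  expect_lt(diff(range(rtu$distances)), 1e-8)

  # stretching one group's terminal branches raises its mean
  st <- ut
  idx <- match(names(g)[g == "x"], st$tip.label)
  term <- st$edge[, 2] %in% idx
  st$edge.length[term] <- st$edge.length[term] * 2
  rts <- root_to_tip(st, groups = g)
  sm <- rts$summary
  expect_gt(sm$mean[sm$group == "x"], sm$mean[sm$group == "y"])
  expect_lt(rts$kruskal$p, 0.05)
})

test_that("shared-OTU abundance test counts and calibrates as defined", {
  a <- otu_table(rbind(s1 = c(x = 5, y = 0, z = 0),
                       s2 = c(x = 3, y = 2, z = 0)))   # presents x, y
  b <- otu_table(rbind(t1 = c(x = 1, y = 2, z = 0),
                       t2 = c(x = 4, y = 0, z = 3)))   # presents x, y, z
  res <- shared_otu_abundance_test(a, b, n_perm = 99, seed = 8)
  expect_equal(res$n_shared, 2L)  # x and y
  expect_setequal(res$shared_ids, c("x", "y"))

  # disjoint tables
  d1 <- otu_table(matrix(c(1, 1), 1, 2, dimnames = list("s", c("x", "y"))))
  d2 <- otu_table(matrix(c(0, 0, 3, 4), 1, 4,
                         dimnames = list("t", c("x", "y", "u", "v"))))
  res0 <- shared_otu_abundance_test(d1, d2)
  expect_equal(res0$n_shared, 0L)
  expect_true(is.na(res0$p))

  # sharing exactly the most abundant OTUs is detected
  set.seed(9)
  n <- 60
  abund <- sort(rlnorm(n, 0, 2), decreasing = TRUE)
  big <- matrix(round(abund * 10) + 1, 1, n,
                dimnames = list("s", paste0("o", 1:n)))
  top <- big; top[1, 11:n] <- 0
  res_top <- shared_otu_abundance_test(otu_table(big), otu_table(top),
                                       n_perm = 999, seed = 10)
  expect_equal(res_top$n_shared, 10L)
  expect_lte(res_top$p, 0.01)
})

test_that("Cohen's d matches its pooled-variance definition", {
  expect_error(cohens_d(c(1, 1, 1), c(1, 1)), "zero pooled variance")
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(cohens_d(a, b)$d, (mean(a) - mean(b)) / sp)
  expect_lt(cohens_d(c(0, 0, 0.001), c(1, 1, 1.001))$d, 0)  # sign
  same <- cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d, 0)
})
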