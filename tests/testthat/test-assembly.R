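test_that("beta-MNTD matches its formula, fixed points and picante", {
  tree <- read_tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  m <- matrix(0, 2, 4, dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  m[1, "A"] <- 5; m[2, "C"] <- 3
  b <- as.matrix(pairwise_bmntd(otu_table(m), tree))
  expect_equal(b["s1", "s2"], 3)  # single patristic path

  # identical samples -> 0
  m2 <- matrix(c(2, 1, 0, 4, 2, 1, 0, 4), 2, 4, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  expect_equal(as.matrix(pairwise_bmntd(otu_table(m2), tree))["s1", "s2"], 0)

  # adding to k an OTU already in j cannot increase j's term
  base <- matrix(0, 2, 4, dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  base[1, c("A", "B")] <- 1; base[2, "C"] <- 1
  grown <- base; grown[2, "A"] <- 1
  expect_lte(as.matrix(pairwise_bmntd(otu_table(grown), tree))["s1", "s2"],
             as.matrix(pairwise_bmntd(otu_table(base), tree))["s1", "s2"])

  # random tables: defining formula + picante cross-check
  for (seed in 1:3) {
    tr <- simulate_tree(10, seed = 500 + seed)
    tab <- random_table(5, 10, seed = seed)
    colnames(tab$counts) <- tr$tip.label
    tab <- otu_table(tab$counts)
    ours <- as.matrix(pairwise_bmntd(tab, tr))
    D <- as.matrix(patristic_matrix(tr))
    f <- tab$counts / rowSums(tab$counts)
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(ours[i, j], bf_bmntd_pair(f[i, ], f[j, ], D),
                   tolerance = 1e-10)
    ref <- as.matrix(picante::comdistnt(tab$counts, D,
                                        abundance.weighted = TRUE))
    expect_equal(ours, ref[rownames(ours), colnames(ours)],
                 tolerance = 1e-10)
  }
})

test_that("beta-NTI equals the exhaustive tip-relabeling null on 4 tips", {
  tree <- read_tree(text = "((A:1,B:2):0.5,(C:0.7,D:1.4):0.9);")
  m <- matrix(c(3, 1, 0, 0, 0, 0, 2, 5), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  tab <- otu_table(m)
  D <- as.matrix(patristic_matrix(tree))
  f <- m / rowSums(m)
  obs <- bf_bmntd_pair(f[1, ], f[2, ], D)
  perms <- all_perms(4)
  nulls <- apply(perms, 1, function(g)
    bf_bmntd_pair(f[1, ], f[2, ], D[g, g]))
  exact <- (obs - mean(nulls)) / sqrt(mean((nulls - mean(nulls))^2))
  mc <- bnti(tab, tree, n_null = 4999, seed = 7)["s1", "s2"]
  expect_lt(abs(mc - exact), 0.12)
})

test_that("beta-NTI is invariant to rescaling all branch lengths", {
  tr <- simulate_tree(15, seed = 71)
  tab <- random_table(6, 15, seed = 72)
  colnames(tab$counts) <- tr$tip.label
  tab <- otu_table(tab$counts)
  b1 <- bnti(tab, tr, n_null = 199, seed = 73)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.5
  b2 <- bnti(tab, tr2, n_null = 199, seed = 73)
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("Raup-Crick hits its boundaries and validates input", {
  # a reference pool dominated by a few shared OTUs makes null pairs
  # similar; two disjoint observed samples then exceed every null -> RC = +1
  n <- 40
  x <- matrix(0, 2, n, dimnames = list(c("s1", "s2"), paste0("o", 1:n)))
  x[1, 1:10] <- 20; x[2, 11:20] <- 20
  # dominants are both abundant and ubiquitous; the other OTUs occur in one
  # reference sample each, so null draws almost surely share dominants
  ref <- matrix(0, 6, n, dimnames = list(paste0("r", 1:6), paste0("o", 1:n)))
  ref[, 21:30] <- 100
  rare <- setdiff(1:n, 21:30)
  ref[cbind(rep(1:6, length.out = length(rare)), rare)] <- 1
  rc <- raup_crick_bray(otu_table(x), n_null = 99, seed = 82,
                        reference = otu_table(ref))
  expect_equal(rc["s1", "s2"], 1)

  # identical concentrated samples: observed 0 below every null -> RC = -1
  y <- matrix(0, 2, n, dimnames = list(c("s1", "s2"), paste0("o", 1:n)))
  y[, 1:10] <- 20
  rc2 <- raup_crick_bray(otu_table(y), n_null = 99, seed = 83,
                         reference = otu_table(ref))
  expect_equal(rc2["s1", "s2"], -1)

  single <- otu_table(matrix(1, 1, 2, dimnames = list("s1", c("a", "b"))))
  expect_error(raup_crick_bray(single), "2 samples")
  norm <- normalize(random_table(3, 4, seed = 84), "tss")
  expect_error(raup_crick_bray(norm), "raw counts")
})

test_that("process classification follows the threshold table exactly", {
  lab <- c("s1", "s2", "s3")
  bn <- matrix(0, 3, 3, dimnames = list(lab, lab))
  rc <- matrix(0, 3, 3, dimnames = list(lab, lab))
  bn[1, 2] <- bn[2, 1] <- 3.1;  rc[1, 2] <- rc[2, 1] <- 0.2
  bn[1, 3] <- bn[3, 1] <- 0.5;  rc[1, 3] <- rc[3, 1] <- -0.99
  bn[2, 3] <- bn[3, 2] <- 1.9;  rc[2, 3] <- rc[3, 2] <- 0.9
  cls <- classify_processes(bn, rc)
  got <- setNames(as.character(cls$process),
                  paste(cls$sample_1, cls$sample_2))
  expect_equal(unname(got["s1 s2"]), "variable_selection")
  expect_equal(unname(got["s1 s3"]), "homogenizing_dispersal")
  expect_equal(unname(got["s2 s3"]), "drift")

  bn[2, 1] <- bn[1, 2] <- -2.5
  expect_equal(as.character(classify_processes(bn, rc)$process[1]),
               "homogeneous_selection")
  bn[2, 1] <- bn[1, 2] <- 1; rc[1, 2] <- rc[2, 1] <- 0.97
  expect_equal(as.character(classify_processes(bn, rc)$process[1]),
               "dispersal_limitation_drift")

  # missing beta-NTI propagates to a missing label
  bn[1, 2] <- bn[2, 1] <- NA
  cls_na <- classify_processes(bn, rc)
  expect_true(is.na(cls_na$process[1]))
  expect_equal(attr(cls_na, "n_missing"), 1L)
})

test_that("zone fractions sum to one and handle boundaries as defined", {
  z <- assign_zones(c(400, 500, 750, 1000, 1001))
  expect_equal(as.character(z),
               c("Low", "Middle", "Middle", "Middle", "High"))

  lab <- paste0("s", 1:4)
  bn <- matrix(1, 4, 4, dimnames = list(lab, lab)); diag(bn) <- 0
  rc <- matrix(0, 4, 4, dimnames = list(lab, lab))
  cls <- classify_processes(bn, rc)
  zones <- setNames(c("Low", "Low", "High", "High"), lab)
  zs <- zone_summary(cls, zones)
  frac_cols <- c("variable_selection", "homogeneous_selection",
                 "dispersal_limitation_drift", "homogenizing_dispersal",
                 "drift")
  expect_equal(unname(rowSums(zs[, frac_cols])), rep(1, nrow(zs)))
  expect_equal(zs$drift[zs$zone_pair == "High-Low"], 1)  # all drift here
  expect_error(zone_summary(cls, zones[1:3]), "without a zone")
})
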