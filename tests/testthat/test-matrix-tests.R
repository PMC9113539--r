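test_that("Mantel statistic hits its fixed points", {
  dm <- random_dm(8, seed = 1)
  expect_equal(mantel(dm, dm, n_perm = 19, seed = 1)$statistic, 1)
  affine <- as.dist(0.3 + 2 * as.matrix(dm))
  expect_equal(mantel(dm, affine, n_perm = 19, seed = 1)$statistic, 1)
  expect_error(mantel(dm, random_dm(5, seed = 2)), "dimension")
})

test_that("Mantel permutation p equals exhaustive enumeration at n = 5", {
  dmA <- random_dm(5, seed = 11)
  dmB <- random_dm(5, seed = 12)
  a <- as.vector(dmA)
  bm <- as.matrix(dmB)
  lt <- lower.tri(bm)
  r_obs <- cor(a, bm[lt])
  perms <- all_perms(5)
  r_all <- apply(perms, 1, function(p) cor(a, bm[p, p][lt]))
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  fit <- mantel(dmA, dmB, n_perm = 9999, seed = 13)
  expect_equal(fit$statistic, r_obs)
  expect_lt(abs(fit$p - p_exact), 0.02)
})

test_that("partial Mantel matches the closed-form partial correlation", {
  dmA <- random_dm(12, seed = 21)
  dmB <- random_dm(12, seed = 22)
  dmC <- random_dm(12, seed = 23)
  a <- as.vector(dmA); b <- as.vector(dmB); cc <- as.vector(dmC)
  expected <- (cor(a, b) - cor(a, cc) * cor(b, cc)) /
    sqrt((1 - cor(a, cc)^2) * (1 - cor(b, cc)^2))
  fit <- partial_mantel(dmA, dmB, dmC, n_perm = 19, seed = 24)
  expect_equal(fit$statistic, expected, tolerance = 1e-12)

  # controlling for itself collapses the correlation
  self <- partial_mantel(dmA, dmB, dmA, n_perm = 19, seed = 25)
  expect_lt(abs(self$statistic), 0.3)

  # an independent covariate barely moves r
  plain <- mantel(dmA, dmB, n_perm = 19, seed = 26)$statistic
  for (s in 1:20) {
    pc <- partial_mantel(dmA, dmB, random_dm(12, seed = 300 + s),
                         n_perm = 0 + 19, seed = s)$statistic
    expect_lt(abs(pc - plain), 0.25)
  }

  const <- as.dist(matrix(1, 12, 12) - diag(12))
  expect_error(partial_mantel(dmA, dmB, const), "plain Mantel")
})

test_that("ANOSIM separates perfectly separable groups and matches
           exhaustive enumeration", {
  # all within < all between -> R = 1
  m <- matrix(2, 6, 6)
  m[1:3, 1:3] <- 0.5; m[4:6, 4:6] <- 0.5
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  fit <- anosim(as.dist(m), g, n_perm = 99, seed = 1)
  expect_equal(fit$statistic, 1)
  expect_error(anosim(as.dist(m), rep("a", 6)), "2 groups")

  # 4 samples: exhaustive over all 4! label orders
  dm <- random_dm(4, seed = 31)
  g4 <- c("a", "a", "b", "b")
  r_obs <- bf_anosim_R(dm, g4)
  perms <- all_perms(4)
  r_all <- apply(perms, 1, function(p) bf_anosim_R(dm, g4[p]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  fit4 <- anosim(dm, g4, n_perm = 9999, seed = 32)
  expect_equal(fit4$statistic, r_obs, tolerance = 1e-10)
  expect_lt(abs(fit4$p - p_exact), 0.02)
})

test_that("ANOSIM R is invariant under monotone distance transforms", {
  dm <- random_dm(9, seed = 41)
  g <- rep(c("a", "b", "c"), each = 3)
  r1 <- anosim(dm, g, n_perm = 19, seed = 1)$statistic
  r2 <- anosim(as.dist(as.matrix(dm)^3), g, n_perm = 19, seed = 1)$statistic
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_true(abs(r1) <= 1)
})

test_that("Mantel r agrees with the vegan implementation", {
  dmA <- random_dm(10, seed = 51)
  dmB <- random_dm(10, seed = 52)
  ours <- mantel(dmA, dmB, n_perm = 19, seed = 53)$statistic
  ref <- vegan::mantel(dmA, dmB, permutations = 19)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("the correlogram bins by Sturges and signs distance decay", {
  # 10 samples -> 45 pairs -> 7 classes
  set.seed(61)
  xy <- matrix(runif(20, 0, 1000), 10, 2)
  sp <- as.matrix(dist(xy))
  dimnames(sp) <- list(paste0("s", 1:10), paste0("s", 1:10))
  # community distance strictly increasing with space
  comm <- as.dist(sp * 0.001)
  cg <- mantel_correlogram(as.dist(comm), as.dist(sp), n_perm = 99, seed = 62)
  expect_equal(nrow(cg), ceiling(log2(45) + 1))
  ok <- !is.na(cg$r)
  first <- which(ok)[1]; last <- rev(which(ok))[1]
  expect_gt(cg$r[first], 0)
  expect_lt(cg$r[last], 0)

  # flat community distances: r = 0 everywhere it is defined
  flat <- as.dist(matrix(1, 10, 10) - diag(10))
  cg0 <- mantel_correlogram(flat, as.dist(sp), n_perm = 99, seed = 63)
  expect_true(all(cg0$r[!is.na(cg0$r)] == 0))
})

test_that("environmental covariate distances are absolute differences", {
  d <- covariate_distance(c(s1 = 400, s2 = 400, s3 = 1200))
  m <- as.matrix(d)
  expect_equal(m["s1", "s2"], 0)   # replicates at one station stay distinct
  expect_equal(m["s1", "s3"], 800)
  expect_error(covariate_distance(c(1, NA)), "finite")
})
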