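test_that("Bray-Curtis matches hand arithmetic and its axioms", {
  m <- mk_counts(rbind(c(2, 2), c(1, 3)))
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 0.25)     # (1+1)/(3+5)

  ident <- mk_counts(rbind(c(4, 1), c(4, 1)))
  expect_equal(bray_curtis(ident)["s1", "s2"], 0)
  disj <- mk_counts(rbind(c(5, 0), c(0, 7)))
  expect_equal(bray_curtis(disj)["s1", "s2"], 1)

  set.seed(13)
  for (rep in 1:5) {
    m2 <- mk_counts(matrix(rpois(8 * 15, 4) + 1, 8, 15))
    d2 <- bray_curtis(m2)
    expect_true(all(d2 >= 0 & d2 <= 1))
    expect_equal(d2, t(d2))
    expect_equal(unname(diag(d2)), rep(0, 8))
    # joint positive scaling of all samples leaves distances unchanged
    expect_equal(bray_curtis(m2 * 3.7), d2)
  }
  expect_error(bray_curtis(mk_counts(rbind(c(0, 0), c(1, 2)))), "zero total")
})

test_that("Bray-Curtis agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(14)
  m <- mk_counts(matrix(rpois(10 * 20, 6) + 1, 10, 20))
  expect_equal(bray_curtis(m),
               as.matrix(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PERMANOVA agrees with exhaustive enumeration at N = 6", {
  set.seed(15)
  m <- mk_counts(matrix(rpois(6 * 10, 8) + 1, 6, 10))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 3)
  p_exact <- exhaustive_p(d, g)
  res <- permanova(d, g, n_perm = 999, seed = 4)
  # with 999 draws the sampled p should sit within ~3 SE of the exact p
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 999)
  expect_equal(res$df, c(1L, 4L))
})

test_that("PERMANOVA pseudo-F matches vegan's adonis2", {
  skip_if_not_installed("vegan")
  set.seed(16)
  m <- mk_counts(matrix(rpois(15 * 12, 6) + 1, 15, 12))
  g <- rep(c("a", "b", "c"), each = 5)
  d <- bray_curtis(m)
  res <- permanova(d, g, n_perm = 9, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 9)
  expect_equal(res$f, ad$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ad$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates planted clusters and is seed-reproducible", {
  set.seed(17)
  a <- matrix(rpois(8 * 10, 3), 8, 10)
  b <- matrix(rpois(8 * 10, 3), 8, 10) + 40
  m <- mk_counts(rbind(a, b))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 8)
  res <- permanova(d, g, n_perm = 99, seed = 5)
  expect_gt(res$f, 10)
  expect_equal(res$p_value, 1 / 100)
  res2 <- permanova(d, g, n_perm = 99, seed = 5)
  expect_identical(res$p_value, res2$p_value)
})

test_that("pairwise PERMANOVA reduces to the omnibus test for two groups", {
  set.seed(18)
  m <- mk_counts(matrix(rpois(10 * 8, 5) + 1, 10, 8))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 5)
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 6)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$p_raw, pw$p_adj)
  expect_equal(pw$p_raw, permanova(d, g, n_perm = 99, seed = 7)$p_value)
})

test_that("pairwise PERMANOVA isolates a planted outlier group", {
  set.seed(19)
  base <- matrix(rpois(18 * 10, 5) + 1, 18, 10)
  base[13:18, ] <- base[13:18, ] + 60
  m <- mk_counts(base)
  d <- bray_curtis(m)
  g <- rep(c("a", "b", "c"), each = 6)
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 8)
  involving_c <- pw$group_a == "c" | pw$group_b == "c"
  expect_true(all(pw$p_adj[involving_c] < 0.05))
  expect_gt(pw$p_raw[!involving_c], 0.05)
})

test_that("dispersion matches the planar closed form and vegan", {
  # points in the plane: Euclidean distances embed exactly, so the
  # distance to the group centroid has a direct coordinate answer
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(10, 10), c(14, 10), c(10, 14))
  rownames(pts) <- paste0("s", 1:6)
  d <- as.matrix(stats::dist(pts))
  g <- rep(c("a", "b"), each = 3)
  out <- dispersion(d, g, n_perm = 9, seed = 1)
  direct <- c(
    sqrt(rowSums(sweep(pts[1:3, ], 2, colMeans(pts[1:3, ]))^2)),
    sqrt(rowSums(sweep(pts[4:6, ], 2, colMeans(pts[4:6, ]))^2))
  )
  expect_equal(unname(out$distances), unname(direct), tolerance = 1e-8)

  skip_if_not_installed("vegan")
  set.seed(20)
  m <- mk_counts(matrix(rpois(12 * 10, 5) + 1, 12, 10))
  db <- bray_curtis(m)
  g2 <- rep(c("a", "b", "c"), each = 4)
  out2 <- dispersion(db, g2, n_perm = 9, seed = 2)
  bd <- vegan::betadisper(stats::as.dist(db), g2, type = "centroid")
  expect_equal(unname(out2$distances), unname(bd$distances),
               tolerance = 1e-8)
})

test_that("dispersion is zero for identical samples and grows with spread", {
  m <- mk_counts(matrix(5, 6, 4))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 3)
  out <- suppressWarnings(dispersion(d, g, n_perm = 9, seed = 1))
  expect_equal(unname(out$distances), rep(0, 6), tolerance = 1e-10)

  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(7, 5), c(5, 7))
  rownames(pts) <- paste0("s", 1:6)
  d2 <- as.matrix(stats::dist(pts))
  out2 <- dispersion(d2, g, n_perm = 9, seed = 1)
  # group b is group a scaled by 2: dispersion doubles
  expect_equal(unname(out2$group_means["b"]),
               2 * unname(out2$group_means["a"]), tolerance = 1e-8)
  expect_error(dispersion(d2, c("a", rep("b", 5)), 9, 1), "at least 2")
})

test_that("observed richness counts taxa above threshold", {
  m <- mk_counts(rbind(c(0, 5, 0, 2), c(0, 0, 0, 0)))
  expect_equal(unname(observed_richness(m)), c(2, 0))
  set.seed(24)
  m2 <- mk_counts(matrix(rpois(6 * 30, 1), 6, 30))
  expect_equal(unname(observed_richness(m2)),
               unname(apply(m2, 1, function(x) sum(x >= 1))))
  out <- observed_richness(m2, groupby = rep(c("x", "y"), each = 3))
  expect_equal(out$summary$n, c(3L, 3L))
  expect_equal(out$summary$mean[1], mean(out$per_sample[1:3]))
})

test_that("environmental pruning removes correlated variables greedily", {
  set.seed(25)
  a <- rnorm(12)
  env <- cbind(A = a, B = 2 * a + 5, C = rnorm(12))
  rownames(env) <- month.abb
  out <- env_prune(env)
  expect_length(out$removed, 1)
  expect_true(out$removed %in% c("A", "B"))
  expect_true("C" %in% out$retained)

  # independent variables survive at defaults in nearly all runs
  keep <- vapply(1:40, function(s) {
    set.seed(100 + s)
    e <- matrix(rnorm(12 * 5), 12, 5,
                dimnames = list(month.abb, paste0("V", 1:5)))
    length(env_prune(e)$removed) == 0
  }, logical(1))
  expect_gte(mean(keep), 0.95)

  # constant variable flagged, treated as uncorrelated
  env2 <- cbind(env, K = rep(3, 12))
  out2 <- env_prune(env2)
  expect_equal(out2$constant, "K")
  expect_true("K" %in% out2$retained)
})
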