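# Independent coordinate-space oracle: one-way decomposition of squared
# deviations about group means, for points embedded in Euclidean space.
anova_ss_oracle <- function(x, labels) {
  x <- as.matrix(x)
  grand <- colMeans(x)
  ss_total <- sum(sweep(x, 2, grand)^2)
  ss_within <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(xg, 2, colMeans(xg))^2)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

test_that("the 4-point worked example gives F = 200", {
  x <- c(0, 0.1, 1, 1.1)
  lab <- c("a", "a", "b", "b")
  oracle <- anova_ss_oracle(x, lab)
  expect_equal(unname(oracle), c(1.01, 0.01, 1.00))

  res <- permanova(as.matrix(dist(x)), lab, exact = TRUE)
  expect_equal(res$SS_total, 1.01)
  expect_equal(res$SS_within, 0.01)
  expect_equal(res$F, 200)
  expect_equal(res$R2, 1 / 1.01)
  expect_equal(res$df, 1L)
})

test_that("distance SS decomposition matches coordinate ANOVA", {
  set.seed(31)
  for (i in 1:5) {
    x <- matrix(rnorm(18), ncol = 2)
    lab <- rep(c("a", "b", "c"), each = 3)
    res <- permanova(as.matrix(dist(x)), lab, n_perm = 9, seed = 1)
    oracle <- anova_ss_oracle(x, lab)
    expect_equal(res$SS_total, unname(oracle["total"]), tolerance = 1e-9)
    expect_equal(res$SS_within, unname(oracle["within"]), tolerance = 1e-9)
    expect_equal(res$SS, unname(oracle["between"]), tolerance = 1e-9)
  }
})

test_that("exact p equals brute-force enumeration on small samples", {
  x <- c(0, 0.3, 2.2, 2.5, 1.0, 4.0, 3.1, 0.6)
  lab <- rep(c("a", "b"), each = 4)
  # independent oracle: enumerate label assignments with combn and compute
  # F from coordinates each time
  f_of <- function(l) {
    ss <- anova_ss_oracle(x, l)
    (ss["between"] / 1) / (ss["within"] / (length(x) - 2))
  }
  picks <- combn(8, 4)
  f_all <- apply(picks, 2, function(idx) {
    l <- rep("b", 8); l[idx] <- "a"; f_of(l)
  })
  f_obs <- f_of(lab)
  p_oracle <- mean(f_all >= f_obs - 1e-12)

  res <- permanova(as.matrix(dist(x)), lab, exact = TRUE)
  expect_equal(res$F, unname(f_obs), tolerance = 1e-10)
  expect_equal(res$p, p_oracle)
  expect_equal(res$n_perm, 70L)
})

test_that("permanova agrees with an established implementation", {
  set.seed(5)
  x <- matrix(rnorm(30), ncol = 2)
  lab <- rep(c("a", "b", "c"), each = 5)
  res <- permanova(as.matrix(dist(x)), lab, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(dist(x) ~ lab, permutations = 99)
  expect_equal(res$F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(res$SS, ref$SumOfSqs[1], tolerance = 1e-10)
})

test_that("null-configuration data give small R2 and large p", {
  set.seed(17)
  x <- rnorm(20)
  lab <- rep(c("a", "b"), 10)   # labels interleaved, groups exchangeable
  res <- permanova(as.matrix(dist(x)), lab, n_perm = 199, seed = 3)
  expect_lt(res$R2, 0.2)
  expect_gt(res$p, 0.1)
})

test_that("F, R2 and p are invariant to relabeling, reordering, scaling", {
  set.seed(41)
  x <- matrix(rnorm(24), ncol = 2)
  lab <- rep(c("a", "b", "c"), each = 4)
  d <- as.matrix(dist(x))
  base <- permanova(d, lab, n_perm = 99, seed = 7)

  relab <- permanova(d, c(a = "z", b = "y", c = "x")[lab], n_perm = 99,
                     seed = 7)
  expect_equal(relab$F, base$F)
  expect_equal(relab$R2, base$R2)

  perm <- sample(nrow(d))
  reord <- permanova(d[perm, perm], lab[perm], n_perm = 99, seed = 7)
  expect_equal(reord$F, base$F, tolerance = 1e-10)
  expect_equal(reord$R2, base$R2, tolerance = 1e-10)

  scaled <- permanova(5 * d, lab, n_perm = 99, seed = 7)
  expect_equal(scaled$F, base$F, tolerance = 1e-10)
  expect_equal(scaled$R2, base$R2, tolerance = 1e-10)
  expect_equal(scaled$p, base$p)
})

test_that("pairwise permanova runs one test per unordered pair", {
  set.seed(19)
  x <- c(rnorm(5), rnorm(5, 3), rnorm(5, 6))
  lab <- rep(c("white", "yellow", "orange"), each = 5)
  d <- as.matrix(dist(x))
  res <- pairwise_permanova(d, lab, n_perm = 99, seed = 1)
  expect_equal(res$comparison,
               c("orange-white", "orange-yellow", "white-yellow"))
  expect_equal(res$p_adj, pmin(1, res$p * 3))

  none <- pairwise_permanova(d, lab, adjust = "none", n_perm = 99, seed = 1)
  expect_equal(none$p_adj, none$p)

  two <- pairwise_permanova(d[1:10, 1:10], lab[1:10], n_perm = 99, seed = 1)
  expect_equal(nrow(two), 1)
  expect_equal(two$p_adj, two$p)
})

test_that("dispersion test detects unequal spread and not mirror images", {
  # translated copies: identical internal geometry (with genuinely unequal
  # within-group distances-to-centroid), so the between-group dispersion
  # difference and hence F are exactly 0
  x1 <- c(0, 1, 3, 7)
  x2 <- x1 + 50
  d <- as.matrix(dist(c(x1, x2)))
  lab <- rep(c("a", "b"), each = 4)
  res <- dispersion_test(d, lab, n_perm = 99, seed = 1)
  expect_equal(res$F, 0, tolerance = 1e-10)
  expect_equal(unname(diff(res$group_dispersion)), 0, tolerance = 1e-10)

  # one tight, one dispersed group
  set.seed(8)
  y <- rbind(matrix(rnorm(40, sd = 0.05), ncol = 2),
             matrix(rnorm(40, sd = 3), ncol = 2))
  res2 <- dispersion_test(as.matrix(dist(y)), rep(c("a", "b"), each = 20),
                          n_perm = 199, seed = 2)
  expect_gt(res2$F, 10)
  expect_lt(res2$p, 0.05)
  expect_error(dispersion_test(matrix(0, 4, 4), rep(c("a", "b"), 2)),
               "all-zero")
})

test_that("bootstrap group distances: degenerate and identical groups", {
  e <- c(0.1, 0.1, 0.1, 0.05)
  # zero within-group variance: point = exact centroid distance, CI width 0
  f <- rbind(matrix(log(c(0.3, 0.4, 0.5, 0.6)), 3, 4, byrow = TRUE),
             matrix(log(c(0.5, 0.4, 0.3, 0.7)), 3, 4, byrow = TRUE))
  ct <- make_catch_table(f, c(rep(0, 3), rep(0.2, 3)), e = e)
  meta <- tiny_meta(ct$ids, rep(c("orange", "white"), each = 3))
  res <- boot_group_distance(ct, meta, B = 50, seed = 4)
  chr <- res[res$channel == "chromatic", ]
  expect_equal(chr$point, chromatic_distance(f[1, ], f[4, ], e))
  expect_equal(chr$hi - chr$lo, 0)
  ach <- res[res$channel == "achromatic", ]
  expect_equal(ach$point, 0.2 / 0.05)

  # two identical groups: point estimate 0, CI lower bound 0
  f2 <- rbind(f[1:3, ], f[1:3, ])
  ct2 <- make_catch_table(f2, rep(0, 6), e = e)
  res2 <- boot_group_distance(ct2, meta, B = 50, seed = 4)
  expect_equal(res2$point, rep(0, 2))
  expect_equal(res2$lo, rep(0, 2))

  expect_error(boot_group_distance(ct, meta, pairs = "orange-blue", B = 10,
                                   seed = 1), "unknown pair")
  meta_small <- tiny_meta(ct$ids, c("orange", rep("white", 5)))
  expect_error(boot_group_distance(ct, meta_small, B = 10, seed = 1),
               "fewer than 2")
})

test_that("bootstrap CIs narrow as group size grows", {
  widths <- vapply(c(5, 20, 80), function(n) {
    cfg <- study_config(c(orange.M = n, white.M = n), replicates = 2,
                        seed = 99)
    sim <- generate_dataset(cfg)
    proc <- process_spectra(sim$spectra, sim$metadata)
    ct <- quantum_catches(proc, toy_tetra_vs(), flat_illuminant())
    res <- boot_group_distance(ct, sim$metadata, B = 200, seed = 12)
    chr <- res[res$channel == "chromatic", ]
    chr$hi - chr$lo
  }, 0)
  expect_true(all(diff(widths) < 0))
})
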