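test_that("quantile normalization maps rows onto the mean quantile profile", {
  # hand-derivable 2x2 case: rows (1,3) and (2,8); sorted means (1.5, 5.5)
  m <- matrix(c(1, 2, 3, 8), nrow = 2)
  q <- quantile_normalize(m)
  expect_equal(sort(q[1, ]), c(1.5, 5.5))
  expect_equal(sort(q[2, ]), c(1.5, 5.5))

  # after normalization every subject has an identical sorted profile
  x <- withr::with_seed(1, matrix(rnorm(60), nrow = 5))
  qx <- quantile_normalize(x)
  profiles <- apply(qx, 1, sort)
  expect_true(all(abs(profiles - profiles[, 1]) < 1e-12))

  # identical rows are a fixed point; the map is idempotent
  same <- matrix(rep(c(2, 5, 9), each = 3), nrow = 3)
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  expect_equal(quantile_normalize(qx), qx, tolerance = 1e-9)

  expect_error(quantile_normalize(matrix(c(1, NA, 2, 3), 2)),
               "non-finite", class = "personet_error")
})

test_that("variable-gene selection ranks by variance with lexicographic ties", {
  x <- withr::with_seed(2, cbind(matrix(rnorm(50, sd = 3), 10),
                                 matrix(rnorm(150, sd = 0.5), 10)))
  colnames(x) <- sprintf("g%02d", 1:20)
  top <- select_variable_genes(x, 5)
  expect_true(all(top %in% sprintf("g%02d", 1:5)))

  const <- matrix(1, 4, 6, dimnames = list(NULL, c("b", "a", "d", "c", "f", "e")))
  expect_identical(select_variable_genes(const, 3), c("a", "b", "c"))

  expect_setequal(select_variable_genes(x, 20), colnames(x))
  expect_error(select_variable_genes(x, 0), "positive")
  expect_error(select_variable_genes(x, 21), "21")

  # invariance to subject order
  perm <- withr::with_seed(3, sample(nrow(x)))
  expect_identical(select_variable_genes(x[perm, ], 8),
                   select_variable_genes(x, 8))
})

test_that("one-way ANOVA matches the closed-form F on a hand-computable input", {
  vals <- c(1, 2, 2, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 2)
  res <- profile_anova(vals, g)
  # direct textbook computation, independent of aov()
  means <- tapply(vals, g, mean)
  grand <- mean(vals)
  ssb <- sum(2 * (means - grand)^2)
  ssw <- sum((vals - means[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 3)
  expect_equal(res$F, f_oracle, tolerance = 1e-12)
  expect_equal(res$p, pf(f_oracle, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$bonferroni_alpha, 0.05 / 3)
})

test_that("degenerate zero-within-variance input is flagged", {
  res <- profile_anova(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_true(res$degenerate)
  expect_identical(res$F, Inf)
  expect_identical(res$p, 0)
})

test_that("group-size preconditions are enforced", {
  expect_error(profile_anova(1:3, c("a", "a", "b")), "n >= 2",
               class = "personet_error")
  expect_error(profile_anova(1:4, rep("a", 4)), "two groups",
               class = "personet_error")
})

test_that("point-biserial effect size equals the Pearson formula and saturates", {
  vals <- withr::with_seed(4, rnorm(40))
  g <- rep(c("x", "y"), each = 20)
  ind <- as.numeric(g == "y")
  oracle <- sum((ind - mean(ind)) * (vals - mean(vals))) /
    sqrt(sum((ind - mean(ind))^2) * sum((vals - mean(vals))^2))
  expect_equal(pairwise_effect_size(vals, g), oracle, tolerance = 1e-12)

  # identical distributions: r near 0 (exactly 0 for mirrored samples)
  expect_lt(abs(pairwise_effect_size(c(1, 2, 3, 1, 2, 3),
                                     rep(c("x", "y"), each = 3))), 1e-12)
  # perfect separation: large effect
  sep <- pairwise_effect_size(c(0, 0.1, 0.2, 10, 10.1, 10.2),
                              rep(c("x", "y"), each = 3))
  expect_gt(abs(sep), 0.8)
  expect_warning(r0 <- pairwise_effect_size(rep(1, 4), c("x", "x", "y", "y")),
                 "constant")
  expect_identical(r0, 0)
})

test_that("bootstrap ANOVA separates null from planted ordered effects", {
  # pure null: neither profile effects nor planted biclusters (bicluster
  # structure genuinely induces profile-correlated expression by chance)
  cfg_null <- tiny_cfg(seed = 31, n_subjects = 60, n_genes = 150,
                       profile_sizes = c(creative = 20, organized = 25,
                                         unregulated = 15),
                       bicluster_genes = 15, bicluster_effect = 0,
                       responsive_frac = 0.2,
                       profile_effect = c(creative = 0, organized = 0,
                                          unregulated = 0))
  es0 <- gen_expression(cfg_null)
  b0 <- bootstrap_profile_anova(es0$values, es0$labels, n_boot = 30, seed = 1)
  expect_lt(b0$mean_F, 3)  # null range

  cfg_eff <- tiny_cfg(seed = 31, n_subjects = 60, n_genes = 150,
                      profile_sizes = c(creative = 20, organized = 25,
                                        unregulated = 15),
                      bicluster_genes = 15, bicluster_effect = 0,
                      responsive_frac = 0.2)
  es1 <- gen_expression(cfg_eff)
  b1 <- bootstrap_profile_anova(es1$values, es1$labels, n_boot = 30, seed = 1)
  expect_gt(b1$mean_F, qf(0.99, 2, 3 * ncol(es1$values) - 3))
  # ordered effect creative > organized > unregulated, measured on the
  # responsive genes (the analysis analogue: the selected variable genes)
  br <- bootstrap_profile_anova(es1$values, es1$labels,
                                genes = es1$truth$responsive_genes,
                                n_boot = 30, seed = 1)
  pw <- setNames(br$pairwise$mean_r, br$pairwise$pair)
  expect_gt(abs(pw[["creative-unregulated"]]),
            abs(pw[["organized-unregulated"]]))
  expect_gt(abs(pw[["organized-unregulated"]]), 0.2)

  # reproducible single replicate
  one_a <- bootstrap_profile_anova(es1$values, es1$labels, n_boot = 1, seed = 7)
  one_b <- bootstrap_profile_anova(es1$values, es1$labels, n_boot = 1, seed = 7)
  expect_identical(one_a$F, one_b$F)
})
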