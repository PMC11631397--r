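test_that("layer_index measures distance to the nearest plate edge", {
  # corner touches the edge; interior position is min of the four distances
  expect_identical(layer_index(1, 1), 0L)
  expect_identical(layer_index(16, 21), min(15L, 20L, 16L, 27L))
  expect_identical(layer_index(16, 21), 15L)
  # a 1536 plate (32 x 48) has 16 distinct layers
  layers <- outer(1:32, 1:48, function(r, c) layer_index(r, c, 32, 48))
  expect_identical(sort(unique(as.vector(layers))), 0:15)
  expect_error(layer_index(0, 1), "out of plate bounds")
  expect_error(layer_index(33, 1), "out of plate bounds")
})

test_that("edge normalization equalizes layer means and preserves the grand mean", {
  # uniform grid is unchanged
  u <- matrix(100, 16, 24)
  expect_equal(normalize_edges(u), u)

  # layer-0 cells inflated 1.5x: normalization restores equal layer means
  lay <- mutscreen:::layer_matrix(16, 24)
  g <- matrix(200, 16, 24)
  g[lay == 0] <- 300
  norm <- normalize_edges(g)
  layer_means <- tapply(as.vector(norm), as.vector(lay), mean)
  expect_equal(unname(diff(range(layer_means))), 0, tolerance = 1e-9)
  expect_equal(mean(norm), mean(g), tolerance = 1e-9)

  # idempotent: second application changes nothing
  set.seed(1)
  r <- matrix(rlnorm(16 * 24, meanlog = 5), 16, 24)
  once <- normalize_edges(r)
  expect_equal(normalize_edges(once), once, tolerance = 1e-9)
  expect_equal(mean(once), mean(r), tolerance = 1e-9)

  # missing cells: remaining members of the layer carry the mean
  g2 <- g
  g2[1, 1] <- NA
  n2 <- normalize_edges(g2)
  expect_true(is.na(n2[1, 1]))
  expect_false(anyNA(n2[-1]))
})

test_that("trapezoid AUC matches analytic areas", {
  conc <- seq(0, 0.8, length.out = 18)
  expect_equal(dose_auc(conc, rep(1, 18)), 0.8)
  expect_equal(dose_auc(conc, rep(0, 18)), 0)
  # linear decline 1 -> 0 is a triangle of area cmax/2
  expect_equal(dose_auc(conc, seq(1, 0, length.out = 18)), 0.4)
  # interior missing points are skipped, integrating the remaining grid
  y <- rep(1, 18)
  y[7] <- NA
  expect_equal(dose_auc(conc, y), 0.8)
  expect_error(dose_auc(conc, c(1, rep(NA, 17))), "at least 2")
})

test_that("escapee rule is mean + k sd with the boundary classed escapee", {
  anc <- c(0.08, 0.10, 0.12)   # mean 0.10
  thr <- 0.10 + 3 * sd(anc)
  expect_true(classify_escapee(thr - 0.01, anc))
  expect_false(classify_escapee(thr + 0.01, anc))
  expect_true(classify_escapee(thr, anc))     # tie -> escapee
  expect_error(classify_escapee(0.2, 0.1), ">= 2 ancestor")
  # fabricated ancestor with mean 0.10, sd 0.02: 0.15 escapee, 0.20 not
  anc2 <- c(0.08, 0.12)        # mean 0.10, sd ~0.0283
  anc2 <- 0.1 + (anc2 - 0.1) * 0.02 / sd(anc2)
  expect_equal(c(mean(anc2), sd(anc2)), c(0.10, 0.02))
  expect_true(classify_escapee(0.15, anc2))
  expect_false(classify_escapee(0.20, anc2))
})

test_that("delta AUC is the difference from the ancestral mean", {
  expect_equal(delta_auc(0.35, c(0.08, 0.12)), 0.25)
  expect_equal(delta_auc(0.10, c(0.08, 0.12)), 0)
})

test_that("cost profiles are ratios to the ancestor mean per condition", {
  conds <- c("MMD", "MMG", "CMD", "CMG", "YPD", "YPG")
  mut <- setNames(rep(list(c(a = 100, b = 50)), 6), conds)
  anc <- setNames(rep(list(c(100, 100)), 6), conds)
  cp <- cost_profile(mut, anc, strains = c("a", "b"))
  expect_equal(cp$mean_cost, c(1, 0.5))
  expect_true(all(as.matrix(cp[conds]) == c(1, 0.5)))
  # one condition missing for a strain: mean over the remaining 5
  mut2 <- mut
  mut2$YPG <- c(a = NA, b = 50)
  cp2 <- cost_profile(mut2, anc, strains = c("a", "b"))
  expect_equal(cp2$mean_cost, c(1, 0.5))
  # ancestor mean zero: condition dropped with a warning
  anc3 <- anc
  anc3$MMD <- c(0, 0)
  expect_warning(cp3 <- cost_profile(mut, anc3, strains = c("a", "b")),
                 "dropped")
  expect_equal(cp3$mean_cost, c(1, 0.5))
})

test_that("two-group rank test agrees with the exhaustive permutation null", {
  a <- c(1, 2, 3)
  b <- c(10, 11, 12)
  res <- compare_groups(a, b)
  # oracle: enumerate all 20 assignments of the 6 ranks to group a and
  # compute the Kruskal-Wallis statistic H from rank sums directly
  ranks <- rank(c(a, b))
  combos <- combn(6, 3)
  H <- function(ra) {
    n <- 6
    12 / (n * (n + 1)) * (sum(ra)^2 / 3 + (sum(1:6) - sum(ra))^2 / 3) -
      3 * (n + 1)
  }
  h_obs <- H(ranks[1:3])
  expect_equal(res$statistic, h_obs)
  p_exact <- mean(apply(combos, 2, function(ix) H(ranks[ix])) >= h_obs)
  # observed split is the most extreme: exact permutation p = 2/20
  expect_equal(p_exact, 0.1)
  # identical groups: statistic 0, p 1
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # Bonferroni arithmetic, capped at 1
  expect_equal(compare_groups(a, b, bonferroni_m = 6)$p_adjusted,
               min(1, res$p_value * 6))
})

test_that("correlations match hand-computed rank formulae", {
  x <- 1:5
  expect_equal(correlate(x, 2 * x, "pearson")$estimate, 1)
  y <- exp(x)   # monotone nonlinear
  expect_equal(correlate(x, y, "spearman")$estimate, 1)
  expect_lt(correlate(x, y, "pearson")$estimate, 1)
  # n = 5 vector against the classical 1 - 6*sum(d^2)/(n(n^2-1)) formula
  y2 <- c(2, 1, 4, 3, 5)
  d <- rank(x) - rank(y2)
  rho_hand <- 1 - 6 * sum(d^2) / (5 * 24)
  expect_equal(correlate(x, y2, "spearman")$estimate, rho_hand)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
})

test_that("escapees never appear in retained effect-size comparisons", {
  sc <- screen_scenario(n_mutants = 60, escapee_fraction = 0.4,
                        noise_cv = 0, seed = 77)
  p <- gen_plate_set(sc)
  scored <- score_plates(p)
  retained <- scored[scored$role == "mutant" & !scored$escapee, ]
  truth_esc <- p$truth$strain[p$truth$escapee]
  expect_length(intersect(retained$strain, truth_esc), 0)
})

test_that("AUC is monotone under pointwise increases of the dose series", {
  set.seed(8)
  conc <- seq(0, 0.8, length.out = 10)
  for (i in 1:20) {
    y <- runif(10)
    bump <- y + runif(10, 0, 0.2)
    expect_gte(dose_auc(conc, bump), dose_auc(conc, y))
    expect_gte(dose_auc(conc, pmin(y, 1)), 0)
    expect_lte(dose_auc(conc, pmin(y, 1)), 0.8)
  }
})
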