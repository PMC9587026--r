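test_that("Spearman correlation handles monotone, inverse and mixed
           rankings", {
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3))$rho, 0.6)
  expect_error(spearman_rho(1:2, 1:2), "3 complete pairs")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("Spearman correlation is invariant under monotone transforms
           and ignores missing pairs", {
  set.seed(51)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, r0)
  expect_equal(spearman_rho(x, y^3 + 5)$rho, r0)
  xm <- c(x, NA); ym <- c(y, 4)
  expect_equal(spearman_rho(xm, ym)$rho, r0)
})

test_that("Zou's interval for dependent overlapping correlations matches
           the published construction", {
  # bounds computed independently from the MOVER formulas
  z <- zou_ci_difference(0.5, 0.1, 0.2, 500)
  expect_equal(z$low, 0.2997175, tolerance = 1e-6)
  expect_equal(z$high, 0.4984913, tolerance = 1e-6)
  expect_true(z$different)

  # self-comparison: symmetric about zero, contains zero
  s <- zou_ci_difference(0.5, 0.5, 0.3, 100)
  expect_equal(s$low, -s$high, tolerance = 1e-12)
  expect_false(s$different)

  # smaller samples widen the interval
  s25 <- zou_ci_difference(0.5, 0.5, 0.3, 25)
  expect_gt(s25$high, s$high)

  expect_error(zou_ci_difference(1, 0.5, 0.3, 100), "inside")
})

test_that("group comparison reproduces the hand-ranked Kruskal-Wallis
           statistic and BH-adjusted pairwise tests", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b", "c"), each = 2)
  gc <- group_comparison(vals, grp)
  expect_equal(gc$kruskal$statistic, 4.5714, tolerance = 1e-4)
  expect_equal(gc$kruskal$df, 2)
  expect_equal(nrow(gc$pairwise), 3)
  expect_true(all(gc$pairwise$p_adjusted >= gc$pairwise$p))
  expect_true(all(gc$pairwise$p_adjusted <= 1))

  # two exchangeable samples cannot be told apart
  gc2 <- group_comparison(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(gc2$pairwise$p, 1)

  expect_error(group_comparison(1:3, c("a", "a", "b")), "b")
  expect_error(group_comparison(1:4, rep("a", 4)), "2 groups")
})

test_that("Bland-Altman analysis recovers bias, limits of agreement and
           proportional bias", {
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 4))
  expect_equal(ba$bias, -2 / 3, tolerance = 1e-9)
  expect_equal(ba$loa_low, -1.798, tolerance = 1e-3)
  expect_equal(ba$loa_high, 0.465, tolerance = 1e-3)

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  expect_equal(same$proportional_bias$slope, 0)

  offset <- bland_altman(c(2, 3, 4, 6), c(1, 2, 3, 5))
  expect_equal(offset$bias, 1)
  expect_equal(offset$proportional_bias$slope, 0, tolerance = 1e-12)

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("ergodicity decomposes variance with n-1 denominators and
           behaves at the limits", {
  vals <- c(10, 12, 20, 22, 30, 28)
  subj <- rep(c("A", "B", "C"), each = 2)
  e <- ergodicity(vals, subj)
  expect_equal(e$var_inter, 81.333, tolerance = 1e-4)
  expect_equal(e$var_intra, 2)
  expect_equal(e$e, 0.97600, tolerance = 1e-4)

  # identical repeats within subjects: pure individual set points, e = 1
  e1 <- ergodicity(c(1, 1, 5, 5, 9, 9), subj)
  expect_equal(e1$e, 1)

  # identical subject means, varying repeats: e collapses to 0
  e0 <- ergodicity(c(4, 6, 3, 7, 2, 8), subj)
  expect_equal(e0$e, 0)

  expect_warning(
    es <- ergodicity(c(10, 12, 20, 22, 5), c(subj[1:4], "D")),
    "excluded")
  expect_equal(es$n_subjects, 2)
  expect_error(suppressWarnings(ergodicity(c(1, 2), c("A", "B"))),
               "at least 2 subjects")
})

test_that("ergodicity is invariant under shift and scale", {
  set.seed(52)
  subj <- rep(sprintf("s%02d", 1:10), each = 3)
  vals <- rnorm(10)[rep(1:10, each = 3)] + rnorm(30, sd = 0.3)
  e <- ergodicity(vals, subj)$e
  expect_equal(ergodicity(vals + 100, subj)$e, e, tolerance = 1e-12)
  expect_equal(ergodicity(vals * 7, subj)$e, e, tolerance = 1e-12)
  expect_true(e >= 0 && e <= 1)
})

test_that("correlation edge lists cover all marker pairs with adjusted
           p-values", {
  set.seed(53)
  d <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  d$b <- d$a + rnorm(20, sd = 0.1)
  edges <- correlation_edges(d)
  expect_equal(nrow(edges), 3)
  ab <- edges[edges$marker_a == "a" & edges$marker_b == "b", ]
  expect_gt(ab$rho, 0.9)
  expect_true(all(edges$p_adjusted >= edges$p))
})
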