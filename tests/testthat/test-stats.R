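test_that("aggregation averages per animal and region, then per group", {
  rec <- data.frame(group = "g", animal = c("a", "a", "b", "c"),
                    region = "cortex", area = c(2, 4, 4, 6))
  agg <- aggregateMetrics(rec, meanMetrics = "area")
  ## animal means 3, 4, 6 -> these are the experimental units
  expect_equal(sort(agg$animalRegion$value), c(3, 4, 6))
  g <- agg$group
  expect_equal(g$mean, mean(c(3, 4, 6)))
  expect_equal(g$sem, stats::sd(c(3, 4, 6)) / sqrt(3))
  expect_identical(g$n_animals, 3L)
})

test_that("group SEM follows sd/sqrt(n) and is flagged NA for one animal", {
  rec <- data.frame(group = "g", animal = rep(c("a", "b", "c"), 1),
                    region = "r", v = c(2, 4, 6))
  g <- aggregateMetrics(rec, meanMetrics = "v")$group
  expect_equal(g$sem, 2 / sqrt(3))
  one <- data.frame(group = "g", animal = "a", region = "r", v = c(2, 4))
  g1 <- aggregateMetrics(one, meanMetrics = "v")$group
  expect_equal(g1$mean, 3)
  expect_true(is.na(g1$sem))
  expect_identical(g1$n_animals, 1L)
})

test_that("cumulative metrics are summed per animal, not averaged", {
  rec <- data.frame(group = "g", animal = "a", region = "r",
                    iod = c(10, 20))
  agg <- aggregateMetrics(rec, meanMetrics = character(0),
                          sumMetrics = "iod")
  expect_equal(agg$animalRegion$value, 30)
  expect_error(aggregateMetrics(data.frame(x = 1), meanMetrics = "x"),
               "key column")
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  av <- oneWayAnova(groups)
  ## SSB = 6, SSW = 6 -> MSB = 3, MSW = 1
  expect_equal(av$F, 3)
  expect_identical(av$df_between, 2L)
  expect_identical(av$df_within, 6L)
  expect_equal(av$mse, 1)
  expect_equal(av$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  ## permutation invariance
  av2 <- oneWayAnova(groups[c(3, 1, 2)])
  expect_equal(av2$F, av$F)
  ## degenerate and error paths
  same <- list(a = c(2, 2), b = c(2, 2), c = c(2, 2))
  avSame <- oneWayAnova(same)
  expect_equal(avSame$F, 0); expect_equal(avSame$p, 1)
  expect_error(oneWayAnova(list(a = 1:3)), "two groups")
  expect_error(oneWayAnova(list(a = 1:3, b = 2)), "two values")
})

test_that("two-group ANOVA F equals the pooled t-test statistic squared", {
  set.seed(11)
  for (k in 1:5) {
    x <- stats::rnorm(6 + k); y <- stats::rnorm(9, 1)
    av <- oneWayAnova(list(x = x, y = y))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(av$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher LSD reproduces the pooled-error pairwise t", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  lsd <- fisherLsd(groups)
  ac <- lsd[lsd$group1 == "a" & lsd$group2 == "c", ]
  ## means 2 vs 4, MSE = 1, n = 3 -> |t| = 2/sqrt(2/3) = 2.449
  expect_equal(abs(ac$t), 2.449, tolerance = 1e-3)
  expect_identical(ac$df, 6L)
  expect_equal(ac$p, 0.0499, tolerance = 1e-2)
  expect_identical(ac$stars, "*")
  ab <- lsd[lsd$group1 == "a" & lsd$group2 == "b", ]
  expect_identical(ab$stars, "")
  ## identical pair means give t = 0, p = 1 regardless of unbalanced n
  g0 <- list(a = c(1, 2, 3), b = c(0.5, 2, 3.5), c = c(5, 6, 7))
  l0 <- fisherLsd(g0)
  ab0 <- l0[l0$group1 == "a" & l0$group2 == "b", ]
  expect_equal(ab0$t, 0); expect_equal(ab0$p, 1)
  expect_error(fisherLsd(list(a = c(2, 2), b = c(2, 2))), "degenerate")
})

test_that("significance stars follow the journal convention", {
  expect_identical(significanceStars(c(0.2, 0.04, 0.009, 0.0005)),
                   c("", "*", "**", "***"))
})

test_that("Pearson correlation matches hand computations", {
  x <- c(1, 2, 3)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  r <- pearsonCorrelation(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5)
  expect_identical(r$n, 3L)
  expect_error(pearsonCorrelation(c(1, 1, 1), x), "constant")
  expect_error(pearsonCorrelation(c(1, 2), c(3, 4)), "n >= 3")
})

test_that("Fisher Z matches its closed form and is antisymmetric", {
  eq <- fisherZTest(0.4, 50, 0.4, 50, tail = "greater")
  expect_equal(eq$Z, 0)
  expect_equal(eq$p, 0.5)
  fz <- fisherZTest(0.5, 103, 0.3, 103, tail = "greater")
  zExp <- (atanh(0.5) - atanh(0.3)) / sqrt(2 / 100)
  expect_equal(fz$Z, zExp, tolerance = 1e-12)
  expect_equal(fz$Z, 1.696, tolerance = 1e-3)
  expect_equal(fz$p, 0.045, tolerance = 1e-3)
  ## swapping the samples negates Z and mirrors the tails
  sw <- fisherZTest(0.3, 103, 0.5, 103, tail = "less")
  expect_equal(sw$Z, -fz$Z)
  expect_equal(sw$p, fz$p)
  ## the matched-direction one-tailed p is half the two-tailed p
  two <- fisherZTest(0.5, 103, 0.3, 103, tail = "two.sided")
  expect_equal(fz$p, two$p / 2)
  expect_error(fisherZTest(1, 10, 0.5, 10), "infinite")
  expect_error(fisherZTest(0.2, 3, 0.5, 10), "n >= 4")
})

test_that("discrimination index reports both conventions", {
  di <- discriminationIndex(30, 30)
  expect_equal(di$fraction, 0.5); expect_equal(di$signed, 0)
  di <- discriminationIndex(45, 15)
  expect_equal(di$fraction, 0.75); expect_equal(di$signed, 0.5)
  di <- discriminationIndex(0, 20)
  expect_equal(di$fraction, 0); expect_equal(di$signed, -1)
  expect_error(discriminationIndex(0, 0), "zero total")
})

test_that("time in centre counts frames inside the zone", {
  full <- cbind(rep(5, 600), rep(5, 600))
  expect_equal(timeInCenter(full, c(0, 0, 10, 10), 1), 600)
  expect_equal(timeInCenter(full, c(20, 20, 30, 30), 1), 0)
  half <- cbind(c(rep(5, 3000), rep(50, 3000)), rep(5, 6000))
  expect_equal(timeInCenter(half, c(0, 0, 10, 10), 0.1), 300)
  expect_warning(z <- timeInCenter(matrix(numeric(0), 0, 2),
                                   c(0, 0, 1, 1), 1), "empty")
  expect_equal(z, 0)
})
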