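test_that("Welch t from summaries reproduces the printed data-quality statistics", {
  # group summaries as printed in the data-quality comparison table
  uk <- twoSampleT(list(mean = 95.3, sd = 3.0, n = 18),
                   list(mean = 99.9, sd = 0.3, n = 14))
  expect_equal(uk$statistic, -6.5, tolerance = 0.01)
  expect_equal(uk$effectSizeD, -2.04, tolerance = 0.01)

  gm <- twoSampleT(list(mean = 95.0, sd = 3.2, n = 22),
                   list(mean = 99.3, sd = 1.4, n = 16))
  expect_equal(gm$statistic, -5.6, tolerance = 0.01)
  expect_equal(gm$effectSizeD, -1.66, tolerance = 0.01)
})

test_that("sample-based t-tests agree with stats::t.test for both variants", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    w <- twoSampleT(a, b, "welch")
    ref <- t.test(a, b)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(w$pParametric, ref$p.value, tolerance = 1e-10)
    p <- twoSampleT(a, b, "pooled")
    refp <- t.test(a, b, var.equal = TRUE)
    expect_equal(p$statistic, unname(refp$statistic), tolerance = 1e-10)
    expect_equal(p$df, length(a) + length(b) - 2)
  }
  expect_error(twoSampleT(c(1, 1), c(1, 1)), "zero variance")
})

test_that("welch and pooled coincide when group sizes and SDs match", {
  a <- c(1.2, 0.3, -0.5, 2.0, 0.8)
  b <- a + 1   # same n, same sd
  w <- twoSampleT(a, b, "welch"); p <- twoSampleT(a, b, "pooled")
  expect_equal(w$statistic, p$statistic, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-9)
})

test_that("location tests match the closed-form oracle", {
  # x = {1,2,3}: t = mean/(sd/sqrt(n)) = 2/(1/sqrt(3)) = 2*sqrt(3)
  r <- locationTest(c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)

  sym <- locationTest(c(-1, 1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$pParametric, 1)

  x <- rnorm(10)
  expect_error(locationTest(x, x, mode = "paired"), "zero variance")

  set.seed(3)
  y <- rnorm(12); z <- rnorm(12)
  pr <- locationTest(y, z, mode = "paired")
  ref <- t.test(y, z, paired = TRUE)
  expect_equal(pr$statistic, unname(ref$statistic), tolerance = 1e-10)
})

test_that("BH adjustment matches the hand-enumerated step-up values", {
  r <- bhFdr(c(0.001, 0.01, 0.02, 0.5))
  expect_equal(r$adjusted, c(0.004, 0.02, 0.08 / 3, 0.5), tolerance = 1e-12)
  expect_equal(bhFdr(0.03)$adjusted, 0.03)
  expect_equal(bhFdr(rep(0.2, 5))$adjusted, rep(0.2, 5))
  expect_true(all(bhFdr(c(0.001, 0.01), alpha = 0.05)$significant))
})

test_that("IQR filtering follows the linear-interpolation quartile convention", {
  r <- iqrFilter(c(1, 2, 3, 4, 100))
  expect_equal(r$retained, c(1, 2, 3, 4))   # Q1=2, Q3=4, fences [-1, 7]
  expect_equal(r$dropped, 100)

  x <- c(2.8, 3.1, 2.9, 3.2, 3.0)
  expect_equal(iqrFilter(x)$retained, x)
  expect_equal(iqrFilter(rep(5, 6))$retained, rep(5, 6))
})

test_that("permutation tests enumerate exhaustively and flip signs exactly", {
  r <- permutationTest(c(0, 0), c(1, 1))
  expect_true(r$exhaustive)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)   # 2 of C(4,2)=6 assignments

  s <- permutationTest(c(1, 1, 1))
  expect_true(s$exhaustive)
  expect_equal(s$p, 0.25, tolerance = 1e-12)    # 2 of 2^3 sign patterns

  set.seed(7)
  x <- rnorm(8)
  same <- permutationTest(x, x)
  expect_gte(same$p, 0.9)

  # Monte-Carlo path is seeded and deterministic
  a <- rnorm(12); b <- rnorm(12) + 1
  p1 <- permutationTest(a, b, params = statsParams(nPermutations = 500, seed = 4))
  p2 <- permutationTest(a, b, params = statsParams(nPermutations = 500, seed = 4))
  expect_false(p1$exhaustive)
  expect_identical(p1$p, p2$p)
})

test_that("permutation p approximates the parametric p for normal samples", {
  set.seed(11)
  diffs <- replicate(30, {
    a <- rnorm(15); b <- rnorm(15, 0.4)
    pp <- permutationTest(a, b, params = statsParams(nPermutations = 2000))$p
    pt <- t.test(a, b)$p.value
    abs(pp - pt)
  })
  expect_lt(median(diffs), 0.02)
})

test_that("bootstrap CI for d is seeded, ordered, and covers null effects", {
  set.seed(13)
  a <- rnorm(25); b <- rnorm(25)
  ci <- bootstrapDCI(a, b, statsParams(nBootstrap = 1000, seed = 2))
  expect_lt(ci[1], ci[2])
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_identical(ci, bootstrapDCI(a, b, statsParams(nBootstrap = 1000, seed = 2)))
  d <- cohensD(a, b)
  expect_true(ci[1] <= d && d <= ci[2])
})

test_that("group comparison reports carry parametric and permutation results", {
  set.seed(17)
  a <- rnorm(16, 1); b <- rnorm(18)
  out <- compareGroups(a, b, "welch",
                       statsParams(nPermutations = 500, nBootstrap = 500))
  expect_true(all(c("statistic", "pParametric", "pPermutation",
                    "effectSizeD", "dCiLow", "dCiHigh", "shapiroA") %in%
                    names(out)))
  expect_equal(out$nA, 16)
  expect_true(out$dCiLow <= out$effectSizeD && out$effectSizeD <= out$dCiHigh)
})
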