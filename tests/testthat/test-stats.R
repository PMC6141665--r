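test_that("Kruskal-Wallis H matches the hand-computed rank-sum formula", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p.value, pchisq(7.2, 2, lower.tail = FALSE))

  # degenerate: all observations identical
  kw0 <- kruskalWallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)

  expect_error(kruskalWallis(list(1:3, numeric(0))), "at least one observation")
  expect_error(kruskalWallis(list(1:5)), "at least 2 groups")
})

test_that("tie-corrected H and p agree with the independent base-R implementation", {
  set.seed(41)
  for (i in 1:20) {
    x <- sample(round(rnorm(60, 10, 2), 1))  # rounding forces ties
    g <- factor(sample(rep(1:4, 15)))
    kw <- kruskalWallis(x, g)
    ref <- stats::kruskal.test(x, g)
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p.value, ref$p.value, tolerance = 1e-12)
  }
  # without ties the correction changes nothing
  x <- rnorm(30); g <- factor(rep(1:3, 10))
  expect_equal(kruskalWallis(x, g)$statistic,
               unname(stats::kruskal.test(x, g)$statistic), tolerance = 1e-12)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(42)
  x <- rnorm(80); g <- factor(rep(1:4, 20))
  h0 <- kruskalWallis(x, g)$statistic
  expect_equal(kruskalWallis(exp(x), g)$statistic, h0, tolerance = 1e-12)
  expect_equal(kruskalWallis(atan(x) * 5 - 2, g)$statistic, h0,
               tolerance = 1e-12)
})

test_that("the chi-square p approximates an exact sampled permutation null", {
  set.seed(43)
  x <- round(rnorm(36, 0, 1.5), 1)
  g <- factor(rep(1:3, each = 12))
  kw <- kruskalWallis(x, g)
  B <- 1e5
  r <- rank(x); n <- tabulate(g); N <- length(x)
  C <- 1 - sum(table(r)^3 - table(r)) / (N^3 - N)
  hPerm <- replicate(B, {
    rp <- sample(r)
    Rj <- rowsum(rp, g)[, 1]
    (12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)) / C
  })
  pPerm <- mean(hPerm >= kw$statistic - 1e-12)
  # chi-square approximation error at this n dominates the MC error
  expect_lt(abs(pPerm - kw$p.value), 0.015)
})

test_that("Dunn pairwise comparisons have the documented structure", {
  # two identical groups
  ph0 <- dunnPosthoc(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_equal(ph0$z, 0)
  expect_equal(ph0$p_raw, 1)

  set.seed(44)
  x <- rnorm(60); g <- factor(rep(c("S", "W", "SD", "CSR"), 15),
                              levels = c("S", "W", "SD", "CSR"))
  ph <- dunnPosthoc(x, g)
  expect_equal(nrow(ph), 6L)  # k = 4 -> 6 pairs
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  expect_true(all(ph$p_adj <= 1))
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 6), tolerance = 1e-12)
  phS <- dunnPosthoc(x, g, adjustment = "sidak")
  expect_equal(phS$p_adj, 1 - (1 - phS$p_raw)^6, tolerance = 1e-12)
  phN <- dunnPosthoc(x, g, adjustment = "none")
  expect_equal(phN$p_adj, phN$p_raw)
})

test_that("in the 2-group case Dunn z^2 reproduces the tie-corrected H", {
  set.seed(45)
  for (i in 1:10) {
    x <- round(rnorm(40, 0, 2), 1)
    g <- factor(rep(1:2, each = 20))
    z <- dunnPosthoc(x, g)$z
    h <- kruskalWallis(x, g)$statistic
    expect_equal(z^2, h, tolerance = 1e-9)
  }
})

test_that("Spearman rho handles perfect order, reversal and mid-rank ties", {
  x <- 1:10
  expect_equal(spearmanTest(x, x^3)$estimate, 1)
  expect_equal(spearmanTest(x, rev(x))$estimate, -1)

  xt <- c(1, 2, 2, 3); yt <- c(10, 20, 20, 40)
  st <- spearmanTest(xt, yt)
  expect_equal(st$estimate, cor(rank(xt), rank(yt)), tolerance = 1e-12)

  expect_error(spearmanTest(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearmanTest(1:2, 1:2), "at least 3")
})

test_that("Spearman agrees with the base-R cross-check and is rank-invariant", {
  set.seed(46)
  for (i in 1:10) {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
    st <- spearmanTest(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(st$estimate, unname(ref$estimate), tolerance = 1e-12)
    # antisymmetry and monotone invariance
    expect_equal(spearmanTest(x, -y)$estimate, -st$estimate, tolerance = 1e-12)
    expect_equal(spearmanTest(exp(x), y)$estimate, st$estimate,
                 tolerance = 1e-12)
  }
  # the t-approximation p matches the closed form
  x <- rnorm(30); y <- rnorm(30)
  st <- spearmanTest(x, y)
  tS <- st$estimate * sqrt(28 / (1 - st$estimate^2))
  expect_equal(st$p.value, 2 * pt(-abs(tS), 28), tolerance = 1e-12)
})
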