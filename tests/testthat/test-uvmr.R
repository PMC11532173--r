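test_that("Wald ratio is direct arithmetic with delta-method SE", {
  w <- waldRatio(0.1, 0.01, 0.02, 0.005)
  expect_equal(w@beta, 0.2)
  expect_equal(w@se, 0.05)
  expect_equal(waldRatio(0.1, 0.01, 0, 0.005)@beta, 0)
  # joint sign flip leaves the ratio unchanged
  expect_equal(waldRatio(-0.1, 0.01, -0.02, 0.005)@beta, 0.2)
  expect_error(waldRatio(0, 0.01, 0.02, 0.005), "beta_exp")
})

test_that("IVW equals the closed-form weighted mean of Wald ratios", {
  bx <- c(0.12, 0.2, 0.31)
  by <- c(0.03, 0.05, 0.055)
  sy <- c(0.01, 0.02, 0.015)
  h <- harmonizedSet(c("a", "b", "c"), bx, rep(0.01, 3), by, sy)
  est <- mrIVW(h, effects = "fixed")
  w <- 1 / sy^2
  expect_equal(est@beta, sum(w * bx * by) / sum(w * bx^2), tolerance = 1e-12)
  # identical to the inverse-variance weighted mean of ratios with
  # first-order ratio weights
  wr <- bx^2 / sy^2
  expect_equal(est@beta, sum(wr * by / bx) / sum(wr), tolerance = 1e-12)
  expect_equal(est@se, sqrt(1 / sum(w * bx^2)), tolerance = 1e-12)
})

test_that("equal Wald ratios give Q = 0 and coinciding fixed/random SEs", {
  bx <- c(0.1, 0.2, 0.3)
  h <- harmonizedSet(c("a", "b", "c"), bx, rep(0.01, 3), 0.4 * bx,
                     rep(0.02, 3))
  fx <- mrIVW(h, "fixed")
  rn <- mrIVW(h, "multiplicative_random")
  expect_equal(fx@beta, 0.4)
  expect_equal(fx@extras$Q, 0)
  expect_equal(fx@se, rn@se)
  expect_error(mrIVW(harmonizedSet("a", 0.1, 0.01, 0.1, 0.01)),
               "at least 2")
})

test_that("random-effects IVW inflates but never deflates the SE", {
  set.seed(5)
  for (i in 1:10) {
    h <- randomSet(12, beta = 0.1, seed = i)
    expect_gte(mrIVW(h)@se, mrIVW(h, "fixed")@se)
  }
})

test_that("Egger recovers an exact linear law and matches a WLS oracle", {
  bx <- c(0.05, 0.1, 0.18, 0.25, 0.3)
  a <- 0.02; b <- 0.35
  by <- a + b * bx
  sy <- c(0.01, 0.02, 0.012, 0.03, 0.015)
  h <- harmonizedSet(letters[1:5], bx, rep(0.01, 5), by, sy)
  e <- mrEgger(h)
  expect_equal(e$estimate@beta, b, tolerance = 1e-10)
  expect_equal(e$intercept@estimate, a, tolerance = 1e-10)

  # independent oracle: stats::lm weighted fit on noisy data
  set.seed(11)
  by2 <- a + b * bx + rnorm(5, 0, sy)
  h2 <- harmonizedSet(letters[1:5], bx, rep(0.01, 5), by2, sy)
  e2 <- mrEgger(h2, dispersion = "plain")
  fit <- lm(by2 ~ bx, weights = 1 / sy^2)
  expect_equal(unname(e2$estimate@beta), unname(coef(fit)[2]),
               tolerance = 1e-10)
  expect_equal(unname(e2$intercept@estimate), unname(coef(fit)[1]),
               tolerance = 1e-10)
  expect_equal(unname(e2$estimate@se),
               unname(summary(fit)$coefficients[2, 2]), tolerance = 1e-8)
  expect_error(mrEgger(randomSet(2)), "at least 3")
})

test_that("weighted median handles constant, unweighted and interpolated cases", {
  bx <- rep(0.2, 5)
  h <- harmonizedSet(letters[1:5], bx, rep(0.01, 5), 0.3 * bx,
                     rep(0.02, 5))
  expect_equal(mrWeightedMedian(h, nBoot = 100, seed = 1)@beta, 0.3)

  # odd number of equally weighted SNPs: the middle order statistic
  ratios <- c(0.1, 0.5, 0.3, 0.9, 0.2)
  h2 <- harmonizedSet(letters[1:5], rep(0.1, 5), rep(0.01, 5),
                      0.1 * ratios, rep(0.02, 5))
  expect_equal(mrWeightedMedian(h2, nBoot = 100, seed = 1)@beta,
               sort(ratios)[3])

  # bootstrap SE is reproducible under a fixed seed
  e1 <- mrWeightedMedian(h2, nBoot = 200, seed = 7)
  e2 <- mrWeightedMedian(h2, nBoot = 200, seed = 7)
  expect_identical(e1@se, e2@se)
  expect_warning(mrWeightedMedian(h2, nBoot = 50, seed = 1), "nBoot")
})

test_that("mode estimators find the majority mode, honouring weights", {
  ratios <- c(0.19, 0.2, 0.21, 0.2, 0.195, 0.205, 0.2, 0.89, 0.9, 0.91)
  bx <- rep(0.1, 10)
  h <- harmonizedSet(sprintf("s%d", 1:10), bx, rep(0.005, 10),
                     bx * ratios, rep(0.02, 10))
  simple <- mrMode(h, weighted = FALSE, nBoot = 100, seed = 1)
  expect_lt(abs(simple@beta - 0.2), 0.05)

  # grid-search density-argmax oracle
  grid <- seq(0, 1.2, by = 1e-3)
  s <- 0.9 * min(sd(ratios), mad(ratios)) * 10^(-1 / 5)
  dens <- vapply(grid, function(g)
    mean(dnorm((g - ratios) / s)), numeric(1))
  expect_lt(abs(simple@beta - grid[which.max(dens)]), 0.02)

  # upweighting the minority flips the mode
  sy <- c(rep(0.02, 7), rep(0.002, 3))
  h2 <- harmonizedSet(sprintf("s%d", 1:10), bx, rep(0.005, 10),
                      bx * ratios, sy)
  weighted <- mrMode(h2, weighted = TRUE, nBoot = 100, seed = 1)
  expect_lt(abs(weighted@beta - 0.9), 0.05)
  expect_error(mrMode(h, phi = 0, seed = 1), "phi")
})

test_that("estimators are equivariant under sign flips", {
  h <- randomSet(15, beta = 0.25, seed = 3)
  d <- h@data
  flipBoth <- harmonizedSet(d$snp, -d$beta_exp, d$se_exp, -d$beta_out,
                            d$se_out, d$eaf_exp)
  flipOut <- harmonizedSet(d$snp, d$beta_exp, d$se_exp, -d$beta_out,
                           d$se_out, d$eaf_exp)
  for (f in list(function(x) mrIVW(x)@beta,
                 function(x) mrEgger(x)$estimate@beta,
                 function(x) mrWeightedMedian(x, nBoot = 100,
                                              seed = 2)@beta,
                 function(x) mrMode(x, nBoot = 100, seed = 2)@beta,
                 function(x) mrMode(x, weighted = TRUE, nBoot = 100,
                                    seed = 2)@beta)) {
    expect_equal(f(flipBoth), f(h), tolerance = 1e-8)
    expect_equal(f(flipOut), -f(h), tolerance = 1e-8)
  }
})

test_that("homogeneous valid instruments give concordant estimates", {
  h <- randomSet(40, beta = 0.3, seed = 8, se_out = 0.01,
                 se_exp = 0.001)
  ests <- c(mrIVW(h)@beta, mrEgger(h)$estimate@beta,
            mrWeightedMedian(h, nBoot = 100, seed = 1)@beta,
            mrMode(h, nBoot = 100, seed = 1)@beta,
            mrMode(h, weighted = TRUE, nBoot = 100, seed = 1)@beta)
  expect_true(all(abs(ests - 0.3) < 0.05))
})

test_that("estimate tables mirror the reporting layout", {
  h <- randomSet(10, beta = 0.2, seed = 4)
  tab <- mrEstimateTable(h, seed = 1)
  expect_equal(tab$method, c("IVW", "MR-Egger", "WeightedMedian"))
  expect_true(all(c("exposure", "outcome", "nsnp", "or", "or_ci_low",
                    "or_ci_high", "pval") %in% names(tab)))
  expect_true(all(tab$or > 0))
})
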