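test_that("Cochran's Q is zero for perfectly consistent ratios", {
  bx <- c(0.1, 0.2, 0.3, 0.15)
  h <- harmonizedSet(letters[1:4], bx, rep(0.01, 4), 0.5 * bx,
                     rep(0.02, 4))
  q <- cochranQ(h)
  expect_equal(q@qStat, 0)
  expect_equal(q@pval, 1)
  expect_equal(q@df, 3)
  expect_equal(cochranQ(h, "egger")@df, 2)
  expect_equal(sum(q@contributions), q@qStat)
})

test_that("an injected outlier dominates Q and drives its p below 0.05", {
  h <- randomSet(15, beta = 0.2, seed = 13)
  d <- h@data
  j <- 5
  d$beta_out[j] <- d$beta_out[j] + 10 * d$se_out[j]
  h2 <- harmonizedSet(d$snp, d$beta_exp, d$se_exp, d$beta_out, d$se_out)
  q <- cochranQ(h2)
  expect_equal(names(which.max(q@contributions)), d$snp[j])
  expect_lt(q@pval, 0.05)
})

test_that("MR-PRESSO is deterministic and flags spiked SNPs only", {
  h <- randomSet(20, beta = 0.2, seed = 17)
  d <- h@data
  spike <- c(4, 11)
  d$beta_out[spike] <- d$beta_out[spike] + 10 * d$se_out[spike]
  h2 <- harmonizedSet(d$snp, d$beta_exp, d$se_exp, d$beta_out, d$se_out)

  p1 <- mrPresso(h2, nSim = 1000, seed = 99)
  p2 <- mrPresso(h2, nSim = 1000, seed = 99)
  expect_identical(p1@outlierPvals, p2@outlierPvals)
  expect_identical(p1@globalPval, p2@globalPval)

  expect_true(all(d$snp[spike] %in% outlierIds(p1)))
  expect_lt(p1@globalPval, 0.01)
  # after-removal estimate moves toward the generating slope
  expect_lt(abs(p1@estimateAfter@beta - 0.2),
            abs(p1@estimateBefore@beta - 0.2))

  clean <- mrPresso(h, nSim = 1000, seed = 99)
  expect_length(outlierIds(clean), 0)
  expect_gt(clean@globalPval, 0.05)
  expect_error(mrPresso(randomSet(3), nSim = 1000, seed = 1),
               "at least 4")
})

test_that("radial MR agrees with IVW in the clean limit and flags spikes", {
  # zero exposure SE: modified second-order weights reduce to first order
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  set.seed(23)
  sy <- runif(5, 0.01, 0.03)
  by <- 0.3 * bx + rnorm(5, 0, sy)
  h <- harmonizedSet(letters[1:5], bx, rep(1e-12, 5), by, sy)
  r <- radialMR(h)
  expect_equal(r@slope, mrIVW(h, "fixed")@beta, tolerance = 1e-6)
  expect_length(outlierIds(r), 0)

  # one 10-SE outlier among 20 has the top contribution and is flagged
  h2 <- randomSet(20, beta = 0.2, seed = 29)
  d <- h2@data
  d$beta_out[7] <- d$beta_out[7] + 10 * d$se_out[7]
  h3 <- harmonizedSet(d$snp, d$beta_exp, d$se_exp, d$beta_out, d$se_out)
  r2 <- radialMR(h3)
  expect_equal(names(which.max(r2@contributions)), d$snp[7])
  expect_true(d$snp[7] %in% outlierIds(r2))

  # removing flagged outliers restores homogeneity
  keep <- !(d$snp %in% outlierIds(r2))
  h4 <- harmonizedSet(d$snp[keep], d$beta_exp[keep], d$se_exp[keep],
                      d$beta_out[keep], d$se_out[keep])
  expect_gt(radialMR(h4)@qPval, 0.05)
})

test_that("leave-one-out is stable on homogeneous data and flags dominance", {
  h <- randomSet(10, beta = 0.3, seed = 37, se_out = 0.01,
                 se_exp = 0.001)
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo@estimates), 10)
  expect_false(any(loo@estimates$flag))

  # one SNP carrying all the signal: omitting it nulls the estimate
  bx <- c(1, rep(0.05, 4))
  by <- c(0.5, rnorm(4, 0, 0.001))
  h2 <- harmonizedSet(letters[1:5], bx, rep(0.01, 5), by, rep(0.02, 5))
  loo2 <- leaveOneOut(h2)
  expect_true(loo2@estimates$flag[1])
  expect_lt(abs(loo2@estimates$beta[1]), 0.1)

  expect_equal(nrow(leaveOneOut(randomSet(3))@estimates), 3)
})

test_that("Steiger supports the correct orientation and is antisymmetric", {
  sim <- simulateTwoSample(simScenario("clean", beta = 0.2, seed = 43))
  h <- simHarmonized(sim, "TOS_like", "DR_like")
  s <- steigerTest(h, nExp = 270000, nOut = 210000)
  expect_true(s@directionOk)
  expect_gt(s@r2Exposure, s@r2Outcome)

  # swapping exposure and outcome negates z and withdraws support
  d <- h@data
  hSwap <- harmonizedSet(d$snp, d$beta_out, d$se_out, d$beta_exp,
                         d$se_exp, d$eaf_exp)
  sSwap <- steigerTest(hSwap, nExp = 210000, nOut = 270000)
  expect_equal(sSwap@zStat, -s@zStat, tolerance = 1e-12)
  expect_false(sSwap@directionOk)

  dNA <- d; dNA$eaf_exp <- NA_real_
  hNA <- harmonizedSet(dNA$snp, dNA$beta_exp, dNA$se_exp, dNA$beta_out,
                       dNA$se_out)
  expect_error(steigerTest(hNA, 1000, 1000), "eaf")
})

test_that("power reduces to alpha at the null and is monotone", {
  expect_equal(as.numeric(powerBinary(10000, 0.1, 0.05, 0, alpha = 0.05)),
               0.05, tolerance = 1e-12)
  ns <- c(1e3, 1e4, 1e5, 1e6)
  pw <- vapply(ns, function(n)
    as.numeric(powerBinary(n, 0.1, 0.05, 0.1)), numeric(1))
  expect_true(all(diff(pw) >= 0))
  r2s <- seq(0.01, 0.2, by = 0.01)
  pw2 <- vapply(r2s, function(r)
    as.numeric(powerBinary(1e5, 0.1, r, 0.1)), numeric(1))
  expect_true(all(diff(pw2) >= 0))
  bs <- seq(0, 0.5, by = 0.05)
  pw3 <- vapply(bs, function(b)
    as.numeric(powerBinary(1e5, 0.1, 0.05, b)), numeric(1))
  expect_true(all(diff(pw3) >= 0))
  expect_error(powerBinary(1e4, 0.1, 0.05, 0.1, alpha = 1.2), "alpha")
})

test_that("closed-form power matches a Wald-test simulation at NCP 10.5", {
  # parameters chosen so NCP = n * r2 * K(1-K) * beta^2 = 10.5
  n <- 1e5; K <- 0.5; r2 <- 0.02; b <- sqrt(10.5 / (n * r2 * K * (1 - K)))
  pw <- as.numeric(powerBinary(n, K, r2, b))
  expect_equal(pw, 0.9, tolerance = 0.01)
  set.seed(7)
  z <- rnorm(2e5, sqrt(10.5), 1)
  sim <- mean(abs(z) > qnorm(0.975))
  expect_equal(pw, sim, tolerance = 0.01)
})

test_that("the consolidated battery assembles every diagnostic", {
  sim <- simulateTwoSample(simScenario("clean", beta = 0.2, seed = 53))
  h <- simHarmonized(sim, "TOS_like", "DR_like")
  b <- sensitivityBattery(h, nSim = 500, seed = 3, nExp = 270000,
                          nOut = 210000, caseFractionOut = 10413 / 210000)
  expect_s4_class(b$q_ivw, "QResult")
  expect_s4_class(b$q_egger, "QResult")
  expect_s4_class(b$egger_intercept, "EggerInterceptTest")
  expect_s4_class(b$presso, "PressoResult")
  expect_s4_class(b$radial, "RadialResult")
  expect_s4_class(b$loo, "LooTable")
  expect_s4_class(b$steiger, "SteigerResult")
  expect_true(b$power > 0 && b$power <= 1)
})
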