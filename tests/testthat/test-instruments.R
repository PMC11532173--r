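test_that("F statistic follows the printed formula exactly", {
  expect_equal(fStatistic(0.5, 1, 3), 1)
  expect_equal(fStatistic(0, 5, 100), 0)
  # independent arithmetic: (0.02/40) / (0.98/39959)
  expect_equal(fStatistic(0.02, 40, 40000), (0.02 / 40) / (0.98 / 39959))
  expect_gt(fStatistic(0.02, 40, 40000), 10)
  expect_error(fStatistic(0.5, 10, 11), "degrees of freedom")
})

test_that("F is strictly increasing in r2 and n at fixed k", {
  r2 <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(fStatistic(r2, 5, 1000)) > 0))
  n <- seq(100, 10000, by = 100)
  expect_true(all(diff(fStatistic(0.1, 5, n)) > 0))
})

test_that("per-SNP variance explained is 2p(1-p)beta^2", {
  expect_equal(perSnpR2(0.3, 0.2), 2 * 0.3 * 0.7 * 0.04)
  expect_equal(perSnpR2(0.5, 0), 0)
  # monotone in p(1-p): shrinking eaf toward 0 shrinks r2
  eafs <- c(0.4, 0.2, 0.1, 0.01)
  expect_true(all(diff(perSnpR2(eafs, 0.2)) < 0))
  expect_error(perSnpR2(NA, 0.2), "eaf")
})

test_that("clumping keeps independent SNPs and prunes perfect LD by p-value", {
  tab <- makeTable(c("rs1", "rs2", "rs3"), c(0.3, 0.2, 0.1),
                   rep(0.01, 3), pval = c(1e-20, 1e-10, 1e-8))
  ld0 <- diag(1, 3); dimnames(ld0) <- list(snpIds(tab), snpIds(tab))
  expect_equal(snpIds(clumpSnps(tab, ld0)), snpIds(tab))

  ld1 <- ld0; ld1["rs1", "rs2"] <- ld1["rs2", "rs1"] <- 1
  expect_equal(snpIds(clumpSnps(tab, ld1)), c("rs1", "rs3"))
  expect_error(clumpSnps(tab, ld0[1:2, 1:2]), "rs3")
})

test_that("greedy clumping matches a brute-force validity check", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- 8
    ids <- sprintf("rs%d", 1:k)
    tab <- makeTable(ids, runif(k, 0.05, 0.3), rep(0.01, k),
                     pval = runif(k, 1e-12, 1e-6))
    m <- matrix(runif(k * k), k, k)
    m <- (m + t(m)) / 2; diag(m) <- 1
    m[m < 0.5] <- 0                        # sparsify conflicts
    dimnames(m) <- list(ids, ids)
    kept <- snpIds(clumpSnps(tab, m, r2Max = 0.6))
    p <- setNames(tab@records$pval, ids)
    # no retained pair violates the threshold
    if (length(kept) > 1)
      expect_true(all(m[kept, kept][upper.tri(diag(length(kept)))] < 0.6))
    # every dropped SNP conflicts with a retained better-ranked SNP
    for (d in setdiff(ids, kept)) {
      conf <- kept[m[d, kept] >= 0.6]
      expect_true(any(p[conf] < p[d] |
                        (p[conf] == p[d] & conf < d)))
    }
  }
})

test_that("clump result is invariant to input row order", {
  set.seed(3)
  k <- 10
  ids <- sprintf("rs%d", 1:k)
  tab <- makeTable(ids, runif(k, 0.05, 0.3), rep(0.01, k),
                   pval = sample(c(1e-10, 1e-9, 1e-9, 1e-8), k, TRUE))
  m <- matrix(0.4, k, k); diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  ref <- snpIds(clumpSnps(tab, m, r2Max = 0.3))
  perm <- tab@records[sample(k), ]
  tab2 <- gwasTable(perm, "trait")
  expect_setequal(snpIds(clumpSnps(tab2, m, r2Max = 0.3)), ref)
})

test_that("the kb window limits which pairs are compared", {
  tab <- makeTable(c("rs1", "rs2"), c(0.2, 0.2), rep(0.01, 2),
                   pval = c(1e-10, 1e-9), chrom = c(1, 1),
                   pos = c(1e6, 2e7))  # 19 Mb apart
  m <- matrix(1, 2, 2); dimnames(m) <- list(snpIds(tab), snpIds(tab))
  expect_equal(length(snpIds(clumpSnps(tab, m, windowKb = 5000))), 2L)
  tab2 <- makeTable(c("rs1", "rs2"), c(0.2, 0.2), rep(0.01, 2),
                    pval = c(1e-10, 1e-9), chrom = c(1, 1),
                    pos = c(1e6, 2e6))
  expect_equal(snpIds(clumpSnps(tab2, m, windowKb = 5000)), "rs1")
})

test_that("selectInstruments applies the three filters in order", {
  k <- 50
  ids <- sprintf("rs%02d", 1:k)
  set.seed(9)
  exp <- makeTable(ids, runif(k, 0.1, 0.3), rep(0.01, k),
                   pval = rep(1e-10, k), eaf = runif(k, 0.2, 0.8),
                   n_total = 40000)
  out <- makeTable(ids, rnorm(k, 0, 0.01), rep(0.02, k),
                   pval = rep(0.5, k))
  ld <- diag(1, k); dimnames(ld) <- list(ids, ids)
  inst <- selectInstruments(exp, out, ld)
  expect_equal(nSnps(inst), k)          # no filter binds
  expect_true(inst@valid)
  expect_equal(inst@r2Total, sum(inst@r2PerSnp))

  # one SNP strongly associated with the outcome is excluded with audit
  out2 <- out@records
  out2$pval[out2$snp == "rs01"] <- 1e-9
  inst2 <- selectInstruments(exp, gwasTable(out2, "out"), ld)
  expect_false("rs01" %in% snpIds(inst2))
  a <- auditTrail(inst2)
  expect_equal(a$action[a$snp == "rs01"], "dropped-outcome-significant")
})

test_that("stage-by-stage hand application gives the same retained list", {
  ids <- sprintf("rs%d", 1:6)
  exp <- makeTable(ids, rep(0.2, 6), rep(0.01, 6),
                   pval = c(1e-10, 1e-9, 1e-3, 1e-12, 1e-11, 1e-9),
                   eaf = rep(0.4, 6), n_total = 30000)
  out <- makeTable(ids, rep(0, 6), rep(0.02, 6),
                   pval = c(0.5, 0.5, 0.5, 1e-10, 0.5, 0.5))
  ld <- diag(1, 6); dimnames(ld) <- list(ids, ids)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.9
  # by hand: rs3 fails significance; rs2 clumps against rs1 (worse p);
  # rs4 is outcome-significant -> retained = rs1, rs5, rs6
  inst <- selectInstruments(exp, out, ld)
  expect_setequal(snpIds(inst), c("rs1", "rs5", "rs6"))
  # selection output is a subset of the clump output which is a subset of
  # the significance-filtered input
  sig <- ids[exp@records$pval < 5e-8]
  clumped <- snpIds(clumpSnps(gwasTable(exp@records[exp@records$pval < 5e-8, ],
                                        "t"), ld))
  expect_true(all(snpIds(inst) %in% clumped))
  expect_true(all(clumped %in% sig))
})

test_that("emptying stages raise stage-specific errors", {
  ids <- c("rs1", "rs2")
  exp <- makeTable(ids, c(0.1, 0.1), c(0.01, 0.01), pval = c(0.5, 0.5))
  out <- makeTable(ids, c(0, 0), c(0.02, 0.02))
  ld <- diag(1, 2); dimnames(ld) <- list(ids, ids)
  expect_error(selectInstruments(exp, out, ld), "significance filter")
  exp2 <- makeTable(ids, c(0.1, 0.1), c(0.01, 0.01),
                    pval = c(1e-10, 1e-10))
  out2 <- makeTable(ids, c(0.5, 0.5), c(0.02, 0.02),
                    pval = c(1e-10, 1e-10))
  expect_error(selectInstruments(exp2, out2, ld),
               "outcome-significance")
})
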