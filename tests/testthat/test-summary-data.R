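test_that("TSV round trip preserves all retained fields", {
  tab <- makeTable(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                   se = c(0.01, 0.02, 0.03), ea = c("A", "C", "T"),
                   oa = c("G", "A", "C"), eaf = c(0.2, 0.5, 0.8),
                   chrom = c(1, 2, 3), pos = c(1e6, 2e6, 3e6))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGwas(tab, path)
  back <- readGwas(path, traitLabel = "trait")
  expect_equal(nSnps(back), 3L)
  expect_equal(back@records, tab@records)
})

test_that("rows violating record invariants are dropped with a warning", {
  df <- data.frame(snp = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "A", "A"),
                   other_allele = c("G", "G", "G"),
                   beta = c(0.1, 0.2, 0.3), se = c(0.01, 0, 0.02),
                   pval = c(0.01, 0.02, 1.5))
  expect_warning(tab <- gwasTable(df), "2 row")
  expect_equal(snpIds(tab), "rs1")
})

test_that("missing mandatory column is a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.1\t0.01"), path)
  expect_error(readGwas(path), "pval")
  writeLines("", path)
  expect_error(readGwas(path), "empty")
})

test_that("palindromic allele pairs are exactly A/T and C/G", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("C", "G"))
  expect_true(isPalindromic("G", "C"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("T", "C"))
  expect_error(isPalindromic("A", "A"), "identical")
})

test_that("harmonize flips swapped alleles and negates the outcome beta", {
  exp <- makeTable("rs1", 0.1, 0.01, ea = "A", oa = "G")
  out <- makeTable("rs1", 0.3, 0.02, ea = "G", oa = "A")
  h <- harmonize(exp, out)
  expect_equal(h@data$beta_out, -0.3)
  expect_equal(auditTrail(h)$action, "allele-flipped")
})

test_that("strand flips are recognised via reverse complement", {
  exp <- makeTable("rs1", 0.1, 0.01, ea = "A", oa = "G")
  outSame <- makeTable("rs1", 0.3, 0.02, ea = "T", oa = "C")  # A/G on - strand
  h <- harmonize(exp, outSame)
  expect_equal(h@data$beta_out, 0.3)
  expect_equal(auditTrail(h)$action, "kept")
  outSwap <- makeTable("rs1", 0.3, 0.02, ea = "C", oa = "T")
  h2 <- harmonize(exp, outSwap)
  expect_equal(h2@data$beta_out, -0.3)
})

test_that("palindromic SNPs are dropped under the default policy", {
  exp <- makeTable(c("rs1", "rs2"), c(0.1, 0.2), c(0.01, 0.01),
                   ea = c("A", "C"), oa = c("T", "A"))
  out <- makeTable(c("rs1", "rs2"), c(0.3, 0.1), c(0.02, 0.02),
                   ea = c("A", "C"), oa = c("T", "A"))
  h <- harmonize(exp, out)
  expect_equal(snpIds(h), "rs2")
  a <- auditTrail(h)
  expect_equal(a$action[a$snp == "rs1"], "dropped-palindromic")
})

test_that("infer_by_eaf keeps orientable palindromes and flips discordant ones", {
  exp <- makeTable(c("rs1", "rs2", "rs3"), c(0.1, 0.1, 0.1), rep(0.01, 3),
                   ea = rep("A", 3), oa = rep("T", 3),
                   eaf = c(0.2, 0.2, 0.5))
  out <- makeTable(c("rs1", "rs2", "rs3"), c(0.3, 0.3, 0.3), rep(0.02, 3),
                   ea = rep("A", 3), oa = rep("T", 3),
                   eaf = c(0.25, 0.75, 0.5))
  h <- harmonize(exp, out, palindromePolicy = "infer_by_eaf")
  a <- auditTrail(h)
  expect_equal(a$action[a$snp == "rs1"], "kept")           # same side
  expect_equal(a$action[a$snp == "rs2"], "allele-flipped") # opposite side
  expect_equal(a$action[a$snp == "rs3"], "dropped-palindromic") # ambiguous
  expect_equal(h@data$beta_out[h@data$snp == "rs2"], -0.3)
})

test_that("harmonizing identical tables keeps every non-palindromic SNP unchanged", {
  tab <- makeTable(sprintf("rs%d", 1:5), runif(5, -0.2, 0.2), rep(0.01, 5),
                   ea = c("A", "C", "T", "G", "A"),
                   oa = c("G", "T", "C", "A", "C"))
  h <- harmonize(tab, tab)
  expect_equal(nSnps(h), 5L)
  expect_equal(h@data$beta_out, h@data$beta_exp)
  expect_true(all(auditTrail(h)$action == "kept"))
})

test_that("harmonization is idempotent and orientation-invariant", {
  set.seed(42)
  exp <- makeTable(sprintf("rs%d", 1:8), rnorm(8, 0, 0.1), rep(0.01, 8),
                   ea = rep(c("A", "C"), 4), oa = rep(c("G", "T"), 4))
  out <- makeTable(sprintf("rs%d", 1:8), rnorm(8, 0, 0.1), rep(0.02, 8),
                   ea = rep(c("A", "C"), 4), oa = rep(c("G", "T"), 4))
  h1 <- harmonize(exp, out)

  # flipping the outcome's alleles and negating beta must change nothing
  flipped <- out@records
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h2 <- harmonize(exp, gwasTable(flipped, "trait"))
  expect_equal(h1@data, h2@data)

  # harmonizing an already-aligned pair changes nothing
  aligned <- out@records
  aligned$effect_allele <- exp@records$effect_allele
  aligned$other_allele <- exp@records$other_allele
  aligned$beta <- h1@data$beta_out[match(aligned$snp, h1@data$snp)]
  h3 <- harmonize(exp, gwasTable(aligned, "trait"))
  expect_equal(h3@data$beta_out, h1@data$beta_out)
})

test_that("audit actions partition the snp intersection", {
  exp <- makeTable(c("rs1", "rs2", "rs3", "rs4"), rep(0.1, 4), rep(0.01, 4),
                   ea = c("A", "A", "C", "A"), oa = c("T", "G", "G", "C"))
  out <- makeTable(c("rs2", "rs3", "rs4", "rs5"), rep(0.1, 4), rep(0.01, 4),
                   ea = c("A", "C", "C", "A"), oa = c("G", "G", "T", "G"))
  h <- harmonize(exp, out)
  a <- auditTrail(h)
  expect_setequal(a$snp, c("rs2", "rs3", "rs4"))  # the intersection
  retained <- sum(a$action %in% c("kept", "allele-flipped"))
  expect_equal(retained + sum(!a$action %in% c("kept", "allele-flipped")),
               length(a$snp))
  expect_equal(nSnps(h), retained)
})

test_that("outcome-significant SNPs can be excluded during harmonization", {
  exp <- makeTable(c("rs1", "rs2"), c(0.1, 0.1), c(0.01, 0.01))
  out <- makeTable(c("rs1", "rs2"), c(0.5, 0.01), c(0.02, 0.02),
                   pval = c(1e-9, 0.5))
  h <- harmonize(exp, out, pOutcome = 5e-8)
  expect_equal(snpIds(h), "rs2")
  a <- auditTrail(h)
  expect_equal(a$action[a$snp == "rs1"], "dropped-outcome-significant")
})

test_that("disjoint tables raise a no-overlap error", {
  exp <- makeTable("rs1", 0.1, 0.01)
  out <- makeTable("rs2", 0.1, 0.01)
  expect_error(harmonize(exp, out), "overlap")
})
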