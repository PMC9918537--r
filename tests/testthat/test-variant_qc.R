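test_that("VCF reading maps GT fields to dosages with documented missing rules", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_filter_fixture_vcf(path)
  rv <- read_vcf(path)
  expect_equal(dim(rv$genotypes), c(40, 20))
  expect_equal(rv$samples, sprintf("S%02d", 1:40))
  # ./. and half-missing calls become NA
  expect_true(all(is.na(rv$genotypes[1:10, "v14"])))
  # alleles beyond 1 (triallelic GTs) are missing under the documented rule
  expect_true(all(is.na(rv$genotypes[29:40, "v09"])))
  expect_false(rv$variants$biallelic[rv$variants$id == "v09"])
  # QUAL and MQ round-trip; absent MQ is NA
  expect_equal(rv$variants$qual[rv$variants$id == "v10"], 15)
  expect_true(is.na(rv$variants$mq[rv$variants$id == "v13"]))
  expect_error(read_vcf(file.path(tempdir(), "nope.vcf")), "no such")
})

test_that("exact HWE test agrees with full enumeration for all tables n <= 30", {
  # monomorphic sites have a single outcome
  expect_equal(hwe_exact_test(12, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  # sweep all genotype tables up to n = 30 against the enumeration oracle
  worst <- 0
  for (n in c(3, 7, 12, 19, 25, 30)) {
    for (nAA in 0:n) {
      for (nAa in 0:(n - nAA)) {
        naa <- n - nAA - nAa
        p1 <- hwe_exact_test(nAA, nAa, naa)
        p2 <- oracle_hwe(nAA, nAa, naa)
        worst <- max(worst, abs(p1 - p2))
      }
    }
  }
  expect_lt(worst, 1e-12)
  # extreme heterozygote excess is far below any conventional cutoff
  expect_lt(hwe_exact_test(0, 50, 0), 1e-10)
  expect_equal(hwe_exact_test(0, 50, 0), oracle_hwe(0, 50, 0), tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 2, 3), ">= 0")
})

test_that("HWE p-values under a binomial null are uniform to super-uniform", {
  set.seed(11)
  n <- 400
  ps <- replicate(600, {
    g <- rbinom(n, 2, 0.35)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  # exact conditional tests are conservative: the ECDF sits on or below the
  # diagonal (within sampling tolerance)
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_vals <- sapply(grid, function(q) mean(ps <= q))
  expect_true(all(ecdf_vals <= grid + 0.06))
})

test_that("filters remove hand-tallied variants in fixed order", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_filter_fixture_vcf(path)
  rv <- read_vcf(path)
  res <- apply_filters(rv$genotypes, rv$variants, filter_config())
  expect_equal(res$removed,
               c(biallelic = 1L, qual = 2L, mq = 2L, missingness = 1L,
                 maf = 4L, hwe = 1L))
  expect_equal(res$n_pass, 9)
  expect_setequal(res$variants$id, c(sprintf("v%02d", 1:8), "v15"))
  # the MAF = 0.05 variant fails the strict > 0.05 rule
  expect_false("v16" %in% res$variants$id)
})

test_that("disabling every threshold reproduces the input", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_filter_fixture_vcf(path)
  rv <- read_vcf(path)
  off <- filter_config(qual_min = -Inf, mq_min = -Inf,
                       max_missing_fraction = 1, maf_min = -Inf,
                       hwe_alpha = 0, biallelic_only = FALSE)
  res <- apply_filters(rv$genotypes, rv$variants, off)
  expect_equal(res$n_pass, res$n_input)
  expect_identical(unname(res$genotypes), unname(rv$genotypes))
})

test_that("the surviving set is invariant to filter order (attribution is not)", {
  # each filter's pass criterion is intrinsic to a variant, so survivors are
  # an intersection; emulate reorderings by toggling stages on/off in nested
  # applications and comparing against the all-at-once run
  cfg <- small_cohort_config(seed = 13, qual_range = c(10, 60),
                             mq_range = c(10, 60), missing_rate = 0.25)
  co <- simulate_cohort(cfg)
  v <- co$variants; v$biallelic <- TRUE
  full <- apply_filters(co$genotypes, v, filter_config())
  # apply MAF+HWE first, then QUAL/MQ/missingness on the survivors
  s1 <- apply_filters(co$genotypes, v,
                      filter_config(qual_min = -Inf, mq_min = -Inf,
                                    max_missing_fraction = 1))
  s2 <- apply_filters(s1$genotypes, s1$variants,
                      filter_config(maf_min = -Inf, hwe_alpha = 0))
  expect_setequal(s2$variants$id, full$variants$id)
})

test_that("mean imputation preserves allele frequencies exactly", {
  set.seed(3)
  G <- matrix(rbinom(300, 2, 0.3), 30, 10)
  G[sample(length(G), 60)] <- NA
  af_before <- colMeans(G, na.rm = TRUE)
  Gi <- impute_missing_mean(G)
  expect_false(anyNA(Gi))
  expect_equal(colMeans(Gi), af_before, tolerance = 1e-14)
  # frequency-0.25 variant with one missing call imputes dosage 0.5
  g <- c(1, 0, 1, 0, NA)  # af over 4 calls = 0.25
  expect_equal(impute_missing_mean(matrix(g))[5], 0.5)
  # no-missing input is untouched
  Gfull <- matrix(rbinom(40, 2, 0.5), 8, 5)
  expect_identical(impute_missing_mean(Gfull), Gfull)
  expect_error(impute_missing_mean(matrix(NA_real_, 3, 1)), "all calls missing")
})
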