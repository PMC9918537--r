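test_that("Balding-Nichols frequencies match the moment parameterization", {
  # fst = 0 collapses exactly to the ancestral frequency
  expect_identical(balding_nichols_freqs(0.5, 0, 2), c(0.5, 0.5))
  # Beta moments: mean p_anc, variance fst * p_anc * (1 - p_anc)
  set.seed(1)
  draws <- balding_nichols_freqs(rep(0.5, 10000), fst = 0.1, n_pops = 2)
  expect_equal(mean(draws), 0.5, tolerance = 0.01)
  expect_equal(var(draws), 0.025, tolerance = 0.002)
  # degenerate ancestral frequencies are rejected
  expect_error(balding_nichols_freqs(0.99999 + 1e-5, 0.1, 2))
  expect_error(balding_nichols_freqs(0, 0.1, 2), "strictly inside")
  expect_error(balding_nichols_freqs(0.5, 1, 2), "fst")
})

test_that("config validation catches inconsistent designs", {
  expect_error(sim_config(samples_per_pop = c(1, 86)), ">= 2")
  expect_error(sim_config(n_causal = 10000, n_loci = 100), "n_causal")
  expect_error(sim_config(target_pve = 1.2), "target_pve")
  expect_error(sim_config(sweep_region = list(scaffold = 1, start = 9e6,
                                              end = 11e6)),
               "within its scaffold")
})

test_that("genotype simulation honors missingness and is seed-deterministic", {
  cfg <- small_cohort_config(missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  expect_false(anyNA(sim$genotypes))
  expect_true(all(sim$genotypes %in% 0:2))
  # positions sorted within scaffold, loci in the sweep region flagged
  v <- sim$variants
  for (s in unique(v$scaffold)) {
    expect_false(is.unsorted(v$pos[v$scaffold == s]))
  }
  expect_true(all(v$pos[v$in_sweep] - 1 >= 5e5 &
                    v$pos[v$in_sweep] - 1 < 1e6))
  expect_true(all(v$scaffold[v$in_sweep] == "scaffold_1"))

  sim2 <- simulate_genotypes(cfg)
  expect_identical(sim$genotypes, sim2$genotypes)
  expect_identical(sim$variants, sim2$variants)

  cfg2 <- small_cohort_config(missing_rate = 0.2)
  sim3 <- simulate_genotypes(cfg2)
  expect_equal(mean(is.na(sim3$genotypes)), 0.2, tolerance = 0.02)
  expect_false(anyNA(sim3$genotypes_complete))
})

test_that("sweep loci are more differentiated and less diverse than background", {
  cfg <- small_cohort_config(seed = 21, missing_rate = 0, n_loci = 2000)
  sim <- simulate_genotypes(cfg)
  early <- which(sim$samples$population == "pop1")  # pop1 has the lower latitude
  late <- which(sim$samples$population == "pop2")
  sw <- sim$variants$in_sweep
  comp <- wc_fst_sites(sim$genotypes, early, late)
  fst_site <- (comp$a) / (comp$a + comp$b + comp$c)
  expect_gt(median(fst_site[sw], na.rm = TRUE),
            median(fst_site[!sw], na.rm = TRUE))
  # expected heterozygosity in the early population depressed inside the sweep
  p_early <- colMeans(sim$genotypes[early, ]) / 2
  het <- 2 * p_early * (1 - p_early)
  expect_lt(mean(het[sw]), mean(het[!sw]))
})

test_that("phenotype realizes the target PVE exactly and causal-free traits are noise", {
  cfg <- small_cohort_config(missing_rate = 0, target_pve = 0.7,
                             samples_per_pop = c(75, 75))
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim, cfg)
  vg <- var(ph$components$genetic)
  ve <- var(ph$components$noise)
  expect_equal(vg / (vg + ve), 0.7, tolerance = 1e-10)
  # with no cline/covariates the same ratio holds for var(y) directly
  cfg0 <- small_cohort_config(missing_rate = 0, target_pve = 0.7,
                              samples_per_pop = c(75, 75), cline_slope = 0,
                              covariate_effects = c(sex = 0, year = 0, age = 0))
  sim0 <- simulate_genotypes(cfg0)
  ph0 <- simulate_phenotype(sim0, cfg0)
  vy <- var(ph0$phenotypes$arrival_date_ordinal)
  expect_gte(var(ph0$components$genetic) / vy, 0.68)
  expect_lte(var(ph0$components$genetic) / vy, 0.72)

  # target_pve = 0: phenotype uncorrelated with any genotype column
  cfgz <- small_cohort_config(missing_rate = 0, target_pve = 0)
  simz <- simulate_genotypes(cfgz)
  phz <- simulate_phenotype(simz, cfgz)
  rs <- abs(cor(phz$components$genetic + phz$components$noise,
                simz$genotypes[, 1:50]))
  expect_true(all(rs < 4 / sqrt(nrow(simz$genotypes))))
})

test_that("a pure cline shifts population means by slope x latitude gap", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = c(30, 30),
                    pop_latitudes = c(30, 40), pop_longitudes = c(-80, -90),
                    cline_slope = 1, n_causal = 0, target_pve = 0,
                    covariate_effects = c(sex = 0, year = 0, age = 0),
                    missing_rate = 0, sweep_region = NULL, n_loci = 50,
                    seed = 5)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim, cfg)
  f <- ph$components$fixed
  gap <- mean(f[sim$samples$population == "pop2"]) -
    mean(f[sim$samples$population == "pop1"])
  expect_equal(gap, 10, tolerance = 1e-12)
})

test_that("cohort round-trips through VCF and plants the configured genes", {
  cfg <- small_cohort_config(seed = 9)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))

  rv <- read_vcf(paths[["vcf"]])
  expect_identical(unname(rv$genotypes), unname(co$genotypes))
  expect_identical(rv$variants$pos, co$variants$pos)
  expect_identical(rv$variants$qual, co$variants$qual)
  expect_identical(rv$variants$mq, co$variants$mq)

  genes <- read_bed(paths[["genes"]])
  expect_equal(nrow(genes), 13)
  expect_true(all(genes$start >= 5e5 & genes$end <= 1e6))

  prov <- yaml::read_yaml(paths[["provenance"]])
  expect_equal(prov$config$seed, 9)
})

test_that("an empty cohort writes a valid header-only VCF", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.vcf")
  write_vcf(matrix(numeric(0), 0, 0),
            data.frame(scaffold = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       qual = numeric(0), mq = numeric(0)),
            path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  expect_true(any(startsWith(lines, "#CHROM")))
  expect_equal(sum(!startsWith(lines, "#")), 0)
})
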