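test_that("marginal scan recovers exact effects and respects invariances", {
  set.seed(5)
  n <- 80; p <- 40
  G <- matrix(rbinom(n * p, 2, 0.4), n, p)
  W <- cbind(1, rnorm(n))
  y <- 0.5 * G[, 7]  # noiseless single-SNP signal
  st <- marginal_gwas(y, G, W)
  expect_equal(st$beta[7], 0.5, tolerance = 1e-10)
  expect_lt(st$p[7], 1e-200)

  # adding a constant to y leaves slopes unchanged (intercept absorbs it)
  y2 <- 3 + 0.5 * G[, 7] + rnorm(n, 0, 0.5)
  st_a <- marginal_gwas(y2, G, W)
  st_b <- marginal_gwas(y2 + 100, G, W)
  expect_equal(st_a$beta, st_b$beta, tolerance = 1e-10)
  expect_equal(st_a$p, st_b$p, tolerance = 1e-10)

  # monomorphic variants are flagged, not reported
  Gm <- cbind(G, 1)
  st_m <- marginal_gwas(y2, Gm, W)
  expect_true(is.na(st_m$beta[p + 1]) && is.na(st_m$p[p + 1]))
})

test_that("null p-values are uniform", {
  set.seed(6)
  n <- 150; p <- 400
  G <- matrix(rbinom(n * p, 2, 0.3), n, p)
  y <- rnorm(n)
  st <- marginal_gwas(y, G)
  ks <- suppressWarnings(ks.test(st$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clumping matches the brute-force all-pairs oracle", {
  set.seed(7)
  n <- 60; p <- 200
  base <- matrix(rbinom(n * p, 2, 0.4), n, p)
  # create LD blocks by copying columns with small perturbations
  for (j in seq(2, p, by = 5)) {
    flip <- rbinom(n, 1, 0.05)
    base[, j] <- ifelse(flip == 1, 2 - base[, j - 1], base[, j - 1])
  }
  variants <- data.frame(scaffold = rep(c("s1", "s2"), each = p / 2),
                         pos = rep(seq(1e4, by = 5e4, length.out = p / 2), 2))
  pvals <- runif(p)
  stats <- data.frame(p = pvals)
  got <- ld_clump(stats, base, variants, r2_cutoff = 0.2, window_kb = 250)
  want <- oracle_clump(pvals, base, variants$scaffold, variants$pos, 0.2, 250)
  expect_identical(got, want)

  # perfectly correlated neighbors: only the smaller-p one is indexed
  G2 <- cbind(base[, 1], base[, 1])
  v2 <- data.frame(scaffold = "s1", pos = c(1000, 2000))
  st2 <- data.frame(p = c(0.01, 0.5))
  expect_identical(ld_clump(st2, G2, v2, 0.1, 250), 1L)

  # r2_cutoff = 1 retains all distinct genotype vectors (strict inequality)
  G3 <- cbind(base[, 1], base[, 2], base[, 1])
  v3 <- data.frame(scaffold = "s1", pos = c(1, 2, 3) * 1000)
  st3 <- data.frame(p = c(0.01, 0.2, 0.5))
  got3 <- ld_clump(st3, G3, v3, r2_cutoff = 1, window_kb = 250)
  expect_identical(got3, c(1L, 2L, 3L))  # r^2 == 1 is not > 1: all retained
})

test_that("model building finds a planted causal SNP and scores sensibly", {
  set.seed(9)
  n <- 200; p <- 300
  G <- matrix(rbinom(n * p, 2, 0.4), n, p)
  colnames(G) <- paste0("v", 1:p)
  variants <- data.frame(scaffold = "s1",
                         pos = seq(1e4, by = 3e5, length.out = p),
                         id = colnames(G))
  y <- 2 * G[, 33] + rnorm(n)
  model <- build_pgs_model(y, G, variants = variants, seed = 2)
  expect_false(model$empty)
  expect_true(33 %in% model$variant_idx)
  # individual with all-zero dosages at model variants scores 0
  G0 <- G; G0[1, model$variant_idx] <- 0
  expect_equal(predict_pgs(model, G0)[1], 0)
  # all-noise phenotype: chosen model has ~no held-out predictive power
  yn <- rnorm(n)
  mn <- build_pgs_model(yn[1:150], G[1:150, ], variants = variants, seed = 3)
  r2 <- migrarch:::incremental_r2(predict_pgs(mn, G[151:200, ]), yn[151:200],
                                  matrix(1, 50, 1))
  expect_lt(r2, 0.15)
})

test_that("jackknife CV is seeded, leak-free, and handles degenerate reps", {
  cfg <- small_cohort_config(seed = 23, missing_rate = 0, n_loci = 300,
                             target_pve = 0.8, samples_per_pop = c(50, 50),
                             sweep_region = NULL)
  co <- simulate_cohort(cfg)
  G <- co$genotypes; colnames(G) <- co$variants$id
  y <- co$phenotypes$arrival_date_ordinal
  v <- co$variants

  cv1 <- suppressWarnings(jackknife_cv(y, G, variants = v, reps = 5, seed = 77))
  cv2 <- suppressWarnings(jackknife_cv(y, G, variants = v, reps = 5, seed = 77))
  expect_identical(cv1$rep_results, cv2$rep_results)
  expect_identical(cv1$partitions, cv2$partitions)
  expect_true(all(cv1$rep_results$r2 >= 0 & cv1$rep_results$r2 <= 1))

  # leak-freedom: perturbing phenotypes of rep-1 test individuals must not
  # change the model fitted in rep 1 (it only sees training rows)
  te <- setdiff(seq_along(y), cv1$partitions[[1]])
  y_pert <- y
  y_pert[te] <- y_pert[te] + rnorm(length(te), 0, 50)
  tr <- cv1$partitions[[1]]
  m_orig <- build_pgs_model(y[tr], G[tr, ], variants = v,
                            seed = derive_seed(77, 1))
  m_pert <- build_pgs_model(y_pert[tr], G[tr, ], variants = v,
                            seed = derive_seed(77, 1))
  expect_identical(m_orig$variant_idx, m_pert$variant_idx)
  expect_identical(m_orig$beta, m_pert$beta)
  expect_identical(m_orig$threshold, m_pert$threshold)

  # a single repetition is a valid degenerate run
  cv_one <- suppressWarnings(jackknife_cv(y, G, variants = v, reps = 1, seed = 5))
  expect_equal(nrow(cv_one$rep_results), 1)
  expect_error(jackknife_cv(y[1:10], G[1:10, ], variants = v), "n >= 20")
})

test_that("decile summary follows the documented remainder rule", {
  # strictly increasing phenotype in prediction order gives monotone means
  preds <- data.frame(index = 1:87, sample_id = sprintf("S%03d", 1:87),
                      mean_score = seq(-2, 2, length.out = 87),
                      n_heldout = 5)
  phen <- 100 + seq_len(87)
  d <- decile_summary(preds, phen)
  expect_equal(d$table$n, c(9, 9, 9, 9, 9, 9, 9, 8, 8, 8))
  expect_equal(sum(d$table$n), 87)
  expect_true(all(diff(d$table$mean_phenotype) > 0))
  expect_gt(d$spearman, 0.99)  # decile ties keep it just below 1
  expect_error(decile_summary(preds[1:5, ], phen[1:5]), ">= 10")
})
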