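test_that("extreme-group selection is stable and guarded", {
  ph <- data.frame(sample_id = sprintf("S%03d", 1:87),
                   arrival_date_ordinal = 1:87)
  g <- select_extremes(ph, k = 10)
  expect_equal(sort(g$early), sprintf("S%03d", 1:10))
  expect_equal(sort(g$late), sprintf("S%03d", 78:87))

  # tie at the boundary: lexicographically smaller sample id wins
  ph2 <- data.frame(sample_id = c("S002", "S001", "S003", "S004", "S005"),
                    arrival_date_ordinal = c(5, 5, 7, 8, 9))
  g2 <- select_extremes(ph2, k = 2)
  expect_equal(sort(g2$early), c("S001", "S002"))

  expect_error(select_extremes(ph, k = 44), "2k|overlap")
})

test_that("windowed FST matches the textbook variance-components oracle", {
  set.seed(31)
  G <- matrix(rbinom(20 * 50, 2, runif(50, 0.1, 0.9)), 20, 50, byrow = TRUE)
  G[sample(length(G), 50)] <- NA
  variants <- data.frame(scaffold = "s1", pos = sort(sample(1:4999, 50)))
  windows <- make_windows(c(s1 = 5000), size = 5000)
  scan <- wc_fst_window(G, variants, 1:10, 11:20, windows)
  expect_equal(scan$value[1], oracle_wc_fst_window(G, 1:10, 11:20),
               tolerance = 1e-12)

  # a fixed difference gives site FST exactly 1
  Gf <- rbind(matrix(0, 5, 1), matrix(2, 5, 1))
  comp <- wc_fst_sites(Gf, 1:5, 6:10)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)

  expect_error(wc_fst_window(G, variants, 1, 2:20, windows), ">= 2")
})

test_that("panmictic groups give mean window FST near zero", {
  set.seed(32)
  n <- 40; p <- 4000
  G <- matrix(rbinom(n * p, 2, rep(runif(p, 0.1, 0.9), each = n)), n, p)
  variants <- data.frame(scaffold = "s1",
                         pos = sort(sample(1:(2000 * 5000), p)))
  windows <- make_windows(c(s1 = 2000 * 5000), size = 5000)
  scan <- wc_fst_window(G, variants, 1:20, 21:40, windows)
  v <- scan$value[scan$valid]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v)), 3 * se)
  expect_true(any(v < 0))  # negatives retained, not clamped
})

test_that("delta-FST subtracts window-wise and propagates validity", {
  set.seed(33)
  G <- matrix(rbinom(30 * 60, 2, 0.4), 30, 60)
  variants <- data.frame(scaffold = "s1", pos = sort(sample(1:30000, 60)))
  windows <- make_windows(c(s1 = 30000), size = 5000)
  s1 <- wc_fst_window(G, variants, 1:10, 11:20, windows)
  d0 <- net_fst(s1, s1)
  expect_true(all(abs(d0$value[d0$valid]) == 0))

  s2 <- wc_fst_window(G, variants, 1:10, 21:30, windows)
  s2$valid[2] <- FALSE
  d <- net_fst(s1, s2)
  expect_false(d$valid[2])
  expect_true(is.na(d$value[2]))

  s3 <- s2[-1, ]
  expect_error(net_fst(s1, s3), "identical windows")
})

test_that("windowed diversity matches formula and all-pairs oracle", {
  # single site, allele counts 5/5 among 5 diploids, window span 5000
  G1 <- matrix(c(2, 2, 1, 0, 0), 5, 1)  # 5 alt alleles of 10
  v1 <- data.frame(scaffold = "s1", pos = 100)
  w1 <- make_windows(c(s1 = 5000), 5000)
  pw <- pi_window(G1, v1, 1:5, w1)
  expect_equal(pw$value[1], (2 * 0.5 * 0.5 * 10 / 9) / 5000, tolerance = 1e-14)

  # no variants: pi = 0
  w2 <- make_windows(c(s1 = 10000), 5000)
  pw2 <- pi_window(G1, v1, 1:5, w2)
  expect_equal(pw2$value[2], 0)

  # random fixture vs literal mean-pairwise-difference oracle
  set.seed(34)
  G <- matrix(rbinom(8 * 30, 2, 0.4), 8, 30)
  v <- data.frame(scaffold = "s1", pos = sort(sample(1:4999, 30)))
  w <- make_windows(c(s1 = 5000), 5000)
  got <- pi_window(G, v, 1:8, w)$value[1] * 5000
  expect_equal(got, oracle_pi_pairs(G, 1:8), tolerance = 1e-10)
})

test_that("Tajima's D matches an independently coded constants oracle", {
  set.seed(35)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    G <- matrix(rbinom(n * 40, 2, runif(40, 0.05, 0.95)), n, 40, byrow = TRUE)
    v <- data.frame(scaffold = "s1", pos = sort(sample(1:4999, 40)))
    w <- make_windows(c(s1 = 5000), 5000)
    got <- tajimas_d_window(G, v, 1:n, w)
    want <- oracle_tajimas_d(G, 1:n)
    if (is.na(want)) {
      expect_false(got$valid[1])
    } else {
      expect_equal(got$value[1], want, tolerance = 1e-10)
    }
  }
  # invariant windows are flagged, group of one diploid errors
  G0 <- matrix(0, 6, 3)
  v0 <- data.frame(scaffold = "s1", pos = c(10, 20, 30))
  w0 <- make_windows(c(s1 = 5000), 5000)
  expect_false(tajimas_d_window(G0, v0, 1:6, w0)$valid[1])
  expect_error(tajimas_d_window(G0, v0, 1, w0), "haplotypes")
})

test_that("sweeps depress diversity and Tajima's D in simulation", {
  cfg <- small_cohort_config(seed = 37, missing_rate = 0, n_loci = 4000,
                             sweep_diversity_factor = 0.2)
  sim <- simulate_genotypes(cfg)
  early <- which(sim$samples$population == "pop1")
  w <- make_windows(c(scaffold_1 = 2e6, scaffold_2 = 1e6), 5000)
  pi_s <- pi_window(sim$genotypes, sim$variants, early, w)
  td_s <- tajimas_d_window(sim$genotypes, sim$variants, early, w)
  in_sweep <- w$scaffold == "scaffold_1" & w$start >= 5e5 & w$end <= 1e6
  expect_lt(median(pi_s$value[in_sweep & pi_s$n_sites > 0]),
            median(pi_s$value[!in_sweep & pi_s$n_sites > 0]))
  expect_lt(median(td_s$value[in_sweep & td_s$valid], na.rm = TRUE),
            median(td_s$value[!in_sweep & td_s$valid], na.rm = TRUE))
})

test_that("region detection merges runs, ignores flat scans, and translates", {
  nw <- 400
  base <- data.frame(scaffold = "s1", start = (0:(nw - 1)) * 5000,
                     end = (1:nw) * 5000, n_sites = 5L, stat = "delta_fst",
                     value = 0, valid = TRUE, stringsAsFactors = FALSE)
  # flat scan: MAD = 0 -> no outliers by the documented fallback
  expect_equal(nrow(detect_region(base)), 0)

  set.seed(38)
  scan <- base
  scan$value <- rnorm(nw, 0, 0.01)
  scan$value[101:110] <- 0.5           # plant one
  scan$value[301:305] <- 0.4           # plant two, far away
  regs <- detect_region(scan, z_cutoff = 4, merge_gap_windows = 2)
  expect_equal(nrow(regs), 2)
  expect_true(regs$start[1] <= 101 * 5000 && regs$end[1] >= 110 * 5000 - 5000)

  # a small gap inside a run is bridged
  scan2 <- scan
  scan2$value[105] <- 0                # hole of one window
  regs2 <- detect_region(scan2, z_cutoff = 4, merge_gap_windows = 2)
  expect_equal(nrow(regs2), 2)

  # translation invariance
  scan3 <- scan
  shift <- 1e6
  scan3$start <- scan3$start + shift; scan3$end <- scan3$end + shift
  regs3 <- detect_region(scan3, z_cutoff = 4, merge_gap_windows = 2)
  expect_equal(regs3$start, regs$start + shift)
  expect_equal(regs3$end, regs$end + shift)
})

test_that("gene overlap uses half-open intervals", {
  regions <- data.frame(scaffold = "s1", start = 1000, end = 2000)
  ann <- data.frame(gene_id = c("left_touch", "inside", "spans", "right_touch"),
                    scaffold = "s1",
                    start = c(500, 1200, 900, 2000),
                    end = c(1000, 1300, 2100, 2500))
  hits <- genes_in_region(regions, ann)
  expect_setequal(hits[[1]], c("inside", "spans"))
  expect_equal(attr(hits, "counts"), 2L)

  # 13 genes planted in the sweep region are all recovered
  co <- simulate_cohort(small_cohort_config(seed = 39))
  region13 <- data.frame(scaffold = "scaffold_1", start = 5e5, end = 1e6)
  hits13 <- genes_in_region(region13, co$genes)
  expect_equal(attr(hits13, "counts"), 13L)

  empty <- genes_in_region(regions, co$genes[0, ])
  expect_equal(attr(empty, "counts"), 0L)
})
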