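# Programmatic fixtures shared across test files.

# A 20-variant, 40-sample VCF in which each variant either passes every
# filter or fails exactly one known stage. Hand-tallied expectations:
#   pass: v01-v08 and v15 (9 variants)
#   biallelic: v09; qual: v10 (QUAL 15), v11 (QUAL exactly 20);
#   mq: v12 (MQ 10), v13 (MQ absent); missingness: v14 (25% missing);
#   maf: v16 (MAF exactly 0.05), v17 (MAF 0.025), v19 (monomorphic ref),
#        v20 (monomorphic alt); hwe: v18 (all 40 heterozygous,
#   exact p ~ 4e-11 < 1e-6).
write_filter_fixture_vcf <- function(path) {
  n <- 40
  gt_clean <- c(rep("0/0", 16), rep("0/1", 16), rep("1/1", 8))
  gt_v15 <- c(rep("./.", 8), rep("0/0", 12), rep("0/1", 16), rep("1/1", 4))
  gt_v14 <- c(rep("./.", 10), rep("0/0", 10), rep("0/1", 16), rep("1/1", 4))
  gt_v16 <- c(rep("0/1", 4), rep("0/0", 36))   # MAF = 4/80 = 0.05
  gt_v17 <- c(rep("0/1", 2), rep("0/0", 38))   # MAF = 2/80 = 0.025
  gt_v18 <- rep("0/1", n)                      # extreme het excess
  gt_v19 <- rep("0/0", n)
  gt_v20 <- rep("1/1", n)
  gt_v09 <- c(rep("0/0", 16), rep("0/1", 12), rep("1/2", 8), rep("2/2", 4))

  row <- function(i, alt, qual, info, gts) {
    paste(c("chr1", i * 1000, sprintf("v%02d", i), "A", alt, qual, "PASS",
            info, "GT", gts), collapse = "\t")
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%02d", 1:n)), collapse = "\t")
  )
  body <- c(
    sapply(1:8, function(i) row(i, "G", 50, "MQ=50", gt_clean)),
    row(9, "G,T", 50, "MQ=50", gt_v09),
    row(10, "G", 15, "MQ=50", gt_clean),
    row(11, "G", 20, "MQ=50", gt_clean),
    row(12, "G", 50, "MQ=10", gt_clean),
    row(13, "G", 50, ".", gt_clean),
    row(14, "G", 50, "MQ=50", gt_v14),
    row(15, "G", 50, "MQ=50", gt_v15),
    row(16, "G", 50, "MQ=50", gt_v16),
    row(17, "G", 50, "MQ=50", gt_v17),
    row(18, "G", 50, "MQ=50", gt_v18),
    row(19, "G", 50, "MQ=50", gt_v19),
    row(20, "G", 50, "MQ=50", gt_v20)
  )
  writeLines(c(lines, body), path)
  path
}

# small cohort for fast end-to-end tests; any sim_config argument can be
# overridden through ...
small_cohort_config <- function(seed = 7L, ...) {
  args <- list(n_pops = 2, samples_per_pop = c(30, 30), n_scaffolds = 2,
               scaffold_lengths = c(2e6, 1e6), n_loci = 600,
               background_fst = 0.05,
               sweep_region = list(scaffold = 1L, start = 5e5, end = 1e6),
               sweep_fst = 0.5, sweep_diversity_factor = 0.3,
               n_causal = 20, target_pve = 0.5, missing_rate = 0.1,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
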