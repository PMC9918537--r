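#!/usr/bin/env Rscript
# Step 2: variant quality control.
#
# Reads the cohort VCF and applies the standard resequencing filters in fixed
# order -- biallelic sites, QUAL > 20, MQ > 20, per-variant missingness <= 20%,
# MAF > 0.05, exact Hardy-Weinberg p >= 1e-6 -- then mean-imputes the
# surviving dosages to a complete matrix for the linear models.

library(migrarch)

vcf <- "results/cohort/cohort.vcf"
if (!file.exists(vcf)) stop("run analysis/01_simulate_cohort.R first")

raw <- read_vcf(vcf)
qc <- apply_filters(raw$genotypes, raw$variants, filter_config())

report <- data.frame(stage = c("input", names(qc$removed), "pass"),
                     count = c(qc$n_input, as.integer(qc$removed), qc$n_pass))
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write.table(report, "results/qc/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(qc$genotypes, qc$variants, "results/qc/filtered.vcf")

cat("filter report:\n")
print(report, row.names = FALSE)
cat(sprintf("%d of %d variants pass; mean missingness among survivors %.3f\n",
            qc$n_pass, qc$n_input, mean(is.na(qc$genotypes))))
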