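# Variant QC: VCF reading (via vcfR), the standard resequencing filters
# (biallelic, QUAL > 20, MQ > 20, missingness <= 20%, MAF > 0.05, exact
# Hardy-Weinberg test), and mean-dosage imputation to a complete matrix.

#' Build a variant filter configuration
#'
#' Defaults follow common practice for low-coverage resequencing panels:
#' QUAL > 20, MQ > 20, per-variant missingness at most 20%, MAF strictly
#' above 0.05, exact Hardy-Weinberg p >= 1e-6, biallelic SNPs only. All
#' QUAL/MQ/MAF comparisons are strict inequalities.
#'
#' @param qual_min variants must have QUAL strictly above this (`-Inf`
#'   disables).
#' @param mq_min variants must have MQ strictly above this; records lacking
#'   an MQ INFO key fail the filter (`-Inf` disables, missing MQ then passes).
#' @param max_missing_fraction maximum fraction of missing calls (1 disables).
#' @param maf_min minor allele frequency must be strictly above this
#'   (computed on non-missing calls; `-Inf` disables).
#' @param hwe_alpha variants with exact HWE p-value below this are removed
#'   (0 disables).
#' @param biallelic_only drop records with more than one ALT allele.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qual_min = 20, mq_min = 20,
                          max_missing_fraction = 0.20, maf_min = 0.05,
                          hwe_alpha = 1e-6, biallelic_only = TRUE) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(qual_min = qual_min, mq_min = mq_min,
                 max_missing_fraction = max_missing_fraction,
                 maf_min = maf_min, hwe_alpha = hwe_alpha,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_config")
}

#' Read a VCF into a dosage matrix and variant table
#'
#' Dosage is the count of ALT alleles in the GT field. Calls with any missing
#' allele (`./.`, half-calls like `./0`) or any allele other than 0/1 are
#' recorded as missing; multiallelic records are retained in the table but
#' flagged `biallelic = FALSE` for the filter stage. Positions stay 1-based
#' as in the VCF.
#'
#' @param path VCF 4.x file with GT genotypes.
#' @return A list: `genotypes` (samples x variants dosage matrix, `NA` =
#'   missing), `variants` (scaffold, pos, id, ref, alt, qual, mq, biallelic,
#'   af), `samples` (character vector).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  p <- nrow(fix)
  if (p == 0) {
    return(list(genotypes = matrix(numeric(0), 0, 0),
                variants = data.frame(scaffold = character(0),
                                      pos = integer(0), id = character(0),
                                      ref = character(0), alt = character(0),
                                      qual = numeric(0), mq = numeric(0),
                                      biallelic = logical(0), af = numeric(0)),
                samples = character(0)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  mq <- suppressWarnings(vcfR::extract.info(vcf, "MQ", as.numeric = TRUE))
  if (is.null(mq)) mq <- rep(NA_real_, p)

  dosage_of <- function(calls) {
    # calls: character vector of GT strings for one variant
    a <- strsplit(calls, "[/|]")
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".") || any(is.na(al))) return(NA_real_)
      ai <- suppressWarnings(as.integer(al))
      if (anyNA(ai) || any(ai > 1L)) return(NA_real_)
      sum(ai)
    }, numeric(1))
  }
  gt[is.na(gt)] <- "./."
  G <- t(apply(gt, 1, dosage_of))          # variants x samples
  if (p == 1L) G <- matrix(G, nrow = 1L)
  G <- t(G)                                 # samples x variants
  rownames(G) <- colnames(gt)
  samples <- colnames(gt)

  variants <- data.frame(
    scaffold = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mq = as.numeric(mq),
    biallelic = !grepl(",", fix$ALT) & !is.na(fix$ALT) & fix$ALT != ".",
    stringsAsFactors = FALSE
  )
  variants$af <- colMeans(G, na.rm = TRUE) / 2
  colnames(G) <- variants$id
  list(genotypes = G, variants = variants, samples = samples)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the total probability, under the hypergeometric-type HWE null,
#' of all heterozygote counts (same parity, same allele totals) whose
#' probability does not exceed that of the observed count. Computed with the
#' standard stable recurrence over heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_bad_arg("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_bad_arg("need at least one genotyped individual")
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)  # monomorphic: single possible outcome

  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hets))
  # start at the largest feasible het count and recurse downward:
  # P(h-2)/P(h) = h(h-1) / (4 (n_hom_rare + 1)(n_hom_common + 1))
  m <- length(hets)
  probs[m] <- 1
  for (i in rev(seq_len(m - 1L))) {
    h <- hets[i + 1L]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i] <- probs[i + 1L] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
  }
  probs <- probs / sum(probs)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop_bad_arg("inconsistent genotype counts")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' Apply variant filters in fixed order
#'
#' Order: biallelic, QUAL, MQ, missingness, MAF, HWE. Each removed variant is
#' attributed to the first filter it fails; the surviving set is independent
#' of the order. MAF and the HWE test use non-missing calls only.
#'
#' @param G samples x variants dosage matrix (`NA` missing).
#' @param variants variant table from [read_vcf()] (needs qual, mq,
#'   biallelic).
#' @param cfg a [filter_config()].
#' @return A list: `genotypes`, `variants` (survivors, with `maf` and
#'   `hwe_p` columns), `removed` (named integer vector per filter stage),
#'   `n_input`, `n_pass`.
#' @export
apply_filters <- function(G, variants, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"), ncol(G) == nrow(variants))
  p <- ncol(G)
  n_nonmiss <- colSums(!is.na(G))
  af <- ifelse(n_nonmiss > 0, colMeans(G, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(af, 1 - af)
  miss_frac <- 1 - n_nonmiss / nrow(G)

  hwe_p <- rep(NA_real_, p)
  pass <- rep(TRUE, p)
  removed <- c(biallelic = 0L, qual = 0L, mq = 0L, missingness = 0L,
               maf = 0L, hwe = 0L)
  fail_stage <- function(bad, stage) {
    bad <- bad & pass
    removed[stage] <<- sum(bad)
    pass[bad] <<- FALSE
  }
  if (cfg$biallelic_only) fail_stage(!variants$biallelic, "biallelic")
  if (is.finite(cfg$qual_min)) {
    fail_stage(is.na(variants$qual) | variants$qual <= cfg$qual_min, "qual")
  }
  if (is.finite(cfg$mq_min)) {
    fail_stage(is.na(variants$mq) | variants$mq <= cfg$mq_min, "mq")
  }
  fail_stage(miss_frac > cfg$max_missing_fraction, "missingness")
  if (is.finite(cfg$maf_min)) {
    fail_stage(is.na(maf) | maf <= cfg$maf_min, "maf")
  }
  if (cfg$hwe_alpha > 0) {
    cand <- which(pass & n_nonmiss > 0)
    for (j in cand) {
      gj <- G[, j]
      n2 <- sum(gj == 2, na.rm = TRUE)
      n1 <- sum(gj == 1, na.rm = TRUE)
      n0 <- sum(gj == 0, na.rm = TRUE)
      hwe_p[j] <- hwe_exact_test(n0, n1, n2)
    }
    fail_stage(!is.na(hwe_p) & hwe_p < cfg$hwe_alpha, "hwe")
  }

  keep <- which(pass)
  v <- variants[keep, , drop = FALSE]
  v$maf <- maf[keep]
  v$af <- af[keep]
  v$hwe_p <- hwe_p[keep]
  rownames(v) <- NULL
  list(genotypes = G[, keep, drop = FALSE], variants = v,
       removed = removed, n_input = p, n_pass = length(keep))
}

#' Mean-dosage imputation
#'
#' Replaces each missing dosage with twice the ALT allele frequency of the
#' variant's non-missing calls, leaving per-variant allele frequencies (and
#' column means) exactly unchanged. A deliberately simple, deterministic
#' stand-in for haplotype-based imputation, adequate for the downstream
#' linear models.
#'
#' @param G samples x variants dosage matrix.
#' @return The complete matrix (no `NA`).
#' @export
impute_missing_mean <- function(G) {
  miss <- is.na(G)
  if (!any(miss)) return(G)
  cm <- colMeans(G, na.rm = TRUE)
  if (anyNA(cm) || any(is.nan(cm))) {
    stop_bad_arg("variant(s) with all calls missing cannot be mean-imputed")
  }
  idx <- which(miss, arr.ind = TRUE)
  G[miss] <- cm[idx[, 2]]
  G
}
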