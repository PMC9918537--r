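# Synthetic-cohort generator: structured populations under the Balding-Nichols
# model, an optional planted sweep (elevated differentiation + depressed
# diversity), a polygenic arrival-date phenotype with a latitudinal cline, and
# VCF/TSV/BED writers so every downstream stage runs without external data.

#' Build a simulation configuration
#'
#' Returns a validated configuration for the synthetic cohort generator. The
#' defaults emulate the study design this package targets: 87 geolocator-tracked
#' individuals split between a southern (early-arriving, low-latitude) and a
#' northern (late-arriving, high-latitude) breeding population, a ~5 day/degree
#' latitudinal cline in spring arrival date (the cohort spans roughly 131 days),
#' a 2 Mb high-differentiation/low-diversity sweep region, a polygenic phenotype
#' with PVE 0.74, and 20% missing genotypes.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop integer vector of per-population sample sizes.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_lengths scaffold lengths in bp.
#' @param n_loci total number of variant loci.
#' @param background_fst genome-background differentiation between populations,
#'   on the FST scale, in `[0, 1)`.
#' @param sweep_region `NULL`, or `list(scaffold =, start =, end =)` (0-based,
#'   half-open bp interval) marking the planted sweep.
#' @param sweep_fst differentiation at sweep loci, in `[0, 1)`.
#' @param sweep_diversity_factor multiplier in `(0, 1]` applied to the minor
#'   allele frequency of sweep loci in the "early" group, depressing
#'   heterozygosity, nucleotide diversity and Tajima's D there.
#' @param sweep_mode `"population"` (sweep differentiates the early vs late
#'   populations; a structure-driven signal) or `"phenotype"` (sweep
#'   differentiates a latent early/late timing morph assigned independently of
#'   population; a phenotype-linked signal).
#' @param sweep_phenotype_effect days added to the arrival date of the late
#'   timing morph when `sweep_mode = "phenotype"`.
#' @param n_sweep_genes number of genes planted inside the sweep region.
#' @param n_causal number of causal loci behind the polygenic phenotype.
#' @param target_pve realized proportion of phenotypic variance explained by
#'   the causal loci, relative to genetic + residual variance, in `[0, 1]`.
#' @param cline_slope arrival-date change per degree latitude (days/degree).
#' @param phen_intercept baseline arrival ordinal date at latitude 0.
#' @param covariate_effects named numeric vector of slopes for `sex`
#'   (0/1), `year` (centered) and `age` (years).
#' @param pop_latitudes,pop_longitudes per-population colony coordinates
#'   (degrees).
#' @param missing_rate fraction of genotype calls masked missing, in `[0, 1)`.
#' @param qual_range,mq_range ranges from which per-variant QUAL and MQ are
#'   drawn uniformly.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2L,
                       samples_per_pop = c(44L, 43L),
                       n_scaffolds = 2L,
                       scaffold_lengths = c(10e6, 5e6),
                       n_loci = 5000L,
                       background_fst = 0.05,
                       sweep_region = list(scaffold = 1L, start = 4e6, end = 6e6),
                       sweep_fst = 0.5,
                       sweep_diversity_factor = 0.3,
                       sweep_mode = c("population", "phenotype"),
                       sweep_phenotype_effect = 30,
                       n_sweep_genes = 13L,
                       n_causal = 50L,
                       target_pve = 0.74,
                       cline_slope = 5,
                       phen_intercept = -100,
                       covariate_effects = c(sex = 2, year = 0.5, age = -1),
                       pop_latitudes = c(27.8, 53.5),
                       pop_longitudes = c(-81.5, -113.5),
                       missing_rate = 0.2,
                       qual_range = c(30, 60),
                       mq_range = c(30, 60),
                       seed = 1L) {
  sweep_mode <- match.arg(sweep_mode)
  cfg <- list(
    n_pops = as.integer(n_pops),
    samples_per_pop = as.integer(samples_per_pop),
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_lengths = as.numeric(scaffold_lengths),
    n_loci = as.integer(n_loci),
    background_fst = background_fst,
    sweep_region = sweep_region,
    sweep_fst = sweep_fst,
    sweep_diversity_factor = sweep_diversity_factor,
    sweep_mode = sweep_mode,
    sweep_phenotype_effect = sweep_phenotype_effect,
    n_sweep_genes = as.integer(n_sweep_genes),
    n_causal = as.integer(n_causal),
    target_pve = target_pve,
    cline_slope = cline_slope,
    phen_intercept = phen_intercept,
    covariate_effects = covariate_effects,
    pop_latitudes = pop_latitudes,
    pop_longitudes = pop_longitudes,
    missing_rate = missing_rate,
    qual_range = qual_range,
    mq_range = mq_range,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (cfg$n_pops < 1L) add("n_pops must be >= 1")
  if (length(cfg$samples_per_pop) != cfg$n_pops) {
    add("samples_per_pop must have one entry per population")
  }
  if (any(cfg$samples_per_pop < 2L)) add("each population needs >= 2 samples")
  if (length(cfg$scaffold_lengths) != cfg$n_scaffolds) {
    add("scaffold_lengths must have one entry per scaffold")
  }
  if (any(cfg$scaffold_lengths <= 0)) add("scaffold lengths must be positive")
  if (cfg$n_loci < 1L) add("n_loci must be >= 1")
  if (cfg$background_fst < 0 || cfg$background_fst >= 1) {
    add("background_fst must lie in [0, 1)")
  }
  if (!is.null(cfg$sweep_region)) {
    sr <- cfg$sweep_region
    if (!all(c("scaffold", "start", "end") %in% names(sr))) {
      add("sweep_region needs scaffold, start, end")
    } else {
      if (sr$scaffold < 1L || sr$scaffold > cfg$n_scaffolds) {
        add("sweep_region scaffold out of range")
      } else if (sr$start < 0 || sr$end > cfg$scaffold_lengths[sr$scaffold] ||
                 sr$start >= sr$end) {
        add("sweep_region must lie within its scaffold with start < end")
      }
    }
    if (cfg$sweep_fst < 0 || cfg$sweep_fst >= 1) add("sweep_fst must lie in [0, 1)")
    if (cfg$sweep_diversity_factor <= 0 || cfg$sweep_diversity_factor > 1) {
      add("sweep_diversity_factor must lie in (0, 1]")
    }
  }
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_loci) {
    add("n_causal must lie in [0, n_loci]")
  }
  if (cfg$target_pve < 0 || cfg$target_pve > 1) add("target_pve must lie in [0, 1]")
  if (length(cfg$pop_latitudes) != cfg$n_pops ||
      length(cfg$pop_longitudes) != cfg$n_pops) {
    add("pop_latitudes/pop_longitudes must have one entry per population")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    add("missing_rate must lie in [0, 1)")
  }
  if (length(errs)) {
    stop_bad_arg("invalid simulation config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' Balding-Nichols population allele frequencies
#'
#' Draws one allele frequency per population from a Beta distribution with
#' mean `p_anc` and variance `fst * p_anc * (1 - p_anc)`, i.e. shape
#' parameters `p_anc * (1 - fst) / fst` and `(1 - p_anc) * (1 - fst) / fst`.
#' With `fst = 0` every population gets exactly the ancestral frequency.
#'
#' @param p_anc ancestral allele frequency, strictly inside (0, 1).
#' @param fst differentiation parameter in `[0, 1)`.
#' @param n_pops number of populations.
#' @return Numeric vector of length `n_pops`.
#' @export
balding_nichols_freqs <- function(p_anc, fst, n_pops) {
  if (any(p_anc <= 0) || any(p_anc >= 1)) {
    stop_bad_arg("p_anc must lie strictly inside (0, 1)")
  }
  if (fst < 0 || fst >= 1) stop_bad_arg("fst must lie in [0, 1)")
  if (fst == 0) return(rep(p_anc, each = n_pops))
  k <- (1 - fst) / fst
  n <- n_pops * length(p_anc)
  stats::rbeta(n, rep(p_anc, each = n_pops) * k, rep(1 - p_anc, each = n_pops) * k)
}

# Scale the minor allele towards fixation: freq p -> p * f if p <= 0.5,
# else 1 - (1 - p) * f. Models loss of diversity in a swept group.
shrink_minor_freq <- function(p, factor) {
  ifelse(p <= 0.5, p * factor, 1 - (1 - p) * factor)
}

#' Simulate a genotype matrix with population structure and a planted sweep
#'
#' Places `n_loci` loci uniformly on the configured scaffolds (sorted within
#' scaffold), draws per-population allele frequencies from the Balding-Nichols
#' model at `background_fst` (sweep loci at `sweep_fst`), shrinks the minor
#' allele frequency of sweep loci in the early group by
#' `sweep_diversity_factor`, and draws diploid dosages binomially. Missing
#' calls are masked at `missing_rate`; the unmasked (complete) matrix is also
#' returned so phenotypes can be simulated from true genotypes.
#'
#' The "early" group is the lowest-latitude population when
#' `sweep_mode = "population"`, or a latent timing morph assigned to each
#' individual with probability 1/2 (independently of population) when
#' `sweep_mode = "phenotype"`; in the latter case sweep loci are differentiated
#' between morphs rather than populations.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` (n x p dosage matrix with `NA`
#'   missing), `genotypes_complete` (same, pre-masking), `variants`
#'   (data.frame: scaffold, pos, ref, alt, qual, mq, in_sweep), `samples`
#'   (data.frame: sample_id, population, colony, latitude, longitude, sex,
#'   year, age, morph), and `config`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- sum(config$samples_per_pop)
    p <- config$n_loci
    pop <- rep(seq_len(config$n_pops), config$samples_per_pop)
    early_pop <- which.min(config$pop_latitudes)

    # loci: scaffolds proportional to length, distinct positions, sorted
    scaf <- sort(sample.int(config$n_scaffolds, p, replace = TRUE,
                            prob = config$scaffold_lengths /
                              sum(config$scaffold_lengths)))
    pos <- unlist(lapply(seq_len(config$n_scaffolds), function(k) {
      n_k <- sum(scaf == k)
      if (n_k == 0) return(integer(0))
      sort(sample.int(config$scaffold_lengths[k], n_k))  # 1-based, unique
    }))

    in_sweep <- rep(FALSE, p)
    if (!is.null(config$sweep_region)) {
      sr <- config$sweep_region
      in_sweep <- scaf == sr$scaffold & pos - 1 >= sr$start & pos - 1 < sr$end
    }

    p_anc <- stats::runif(p, 0.05, 0.95)
    # per-pop background frequencies (n_pops x p); draw order is
    # pop-major within locus, matching the matrix fill below
    bg <- balding_nichols_freqs(p_anc, config$background_fst, config$n_pops)
    freq_pop <- matrix(bg, nrow = config$n_pops)

    morph <- rep(NA_integer_, n)
    sweep_cols <- which(in_sweep)
    if (length(sweep_cols)) {
      if (config$sweep_mode == "population") {
        sw <- matrix(balding_nichols_freqs(p_anc[sweep_cols], config$sweep_fst,
                                           config$n_pops),
                     nrow = config$n_pops)
        sw[early_pop, ] <- shrink_minor_freq(sw[early_pop, ],
                                             config$sweep_diversity_factor)
        freq_pop[, sweep_cols] <- sw
      } else {
        morph <- stats::rbinom(n, 1L, 0.5)  # 0 = early morph, 1 = late morph
        sw <- matrix(balding_nichols_freqs(p_anc[sweep_cols], config$sweep_fst, 2L),
                     nrow = 2L)
        sw[1L, ] <- shrink_minor_freq(sw[1L, ], config$sweep_diversity_factor)
        freq_morph <- sw  # row 1 early morph, row 2 late morph
      }
    }

    G <- matrix(NA_real_, n, p)
    for (k in seq_len(config$n_pops)) {
      rows <- which(pop == k)
      G[rows, ] <- stats::rbinom(length(rows) * p, 2L,
                                 rep(freq_pop[k, ], each = length(rows)))
    }
    if (length(sweep_cols) && config$sweep_mode == "phenotype") {
      for (m in 0:1) {
        rows <- which(morph == m)
        G[rows, sweep_cols] <- stats::rbinom(length(rows) * length(sweep_cols), 2L,
                                             rep(freq_morph[m + 1L, ],
                                                 each = length(rows)))
      }
    }

    variants <- data.frame(
      scaffold = paste0("scaffold_", scaf),
      pos = as.integer(pos),
      ref = sample(c("A", "C", "G", "T"), p, replace = TRUE),
      alt = NA_character_,
      qual = round(stats::runif(p, config$qual_range[1], config$qual_range[2]), 2),
      mq = round(stats::runif(p, config$mq_range[1], config$mq_range[2]), 2),
      biallelic = TRUE,
      in_sweep = in_sweep,
      stringsAsFactors = FALSE
    )
    variants$alt <- vapply(variants$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1))
    variants$id <- paste0(variants$scaffold, ":", variants$pos)

    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      population = paste0("pop", pop),
      colony = paste0("colony", pop),
      latitude = config$pop_latitudes[pop],
      longitude = config$pop_longitudes[pop],
      sex = stats::rbinom(n, 1L, 0.5),
      year = sample(2008:2015, n, replace = TRUE),
      age = sample(1:3, n, replace = TRUE),
      morph = morph,
      stringsAsFactors = FALSE
    )
    rownames(G) <- samples$sample_id
    colnames(G) <- variants$id

    G_complete <- G
    if (config$missing_rate > 0) {
      mask <- stats::runif(n * p) < config$missing_rate
      G[mask] <- NA_real_
    }

    list(genotypes = G, genotypes_complete = G_complete, variants = variants,
         samples = samples, config = config)
  })
}

#' Simulate the arrival-date phenotype
#'
#' Builds `y = intercept + cline_slope * latitude + covariate terms +
#' (sweep morph effect) + sum(causal effects x dosage) + noise`, with causal
#' loci drawn from the complete genotype matrix and noise rescaled (and
#' orthogonalized against the genetic values) so that the realized genetic
#' variance fraction `var(g) / (var(g) + var(e))` equals `target_pve` exactly.
#' The fixed cline and covariate terms sit outside that ratio: they are the
#' structured part of the phenotype that the downstream models absorb with
#' covariates and PC1.
#'
#' @param sim output of [simulate_genotypes()].
#' @param config a [sim_config()]; defaults to the config stored in `sim`.
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return A list: `phenotypes` (the samples data.frame plus
#'   `arrival_date_ordinal`), `effects` (data.frame of causal loci and betas),
#'   `components` (list of the genetic, noise and fixed vectors).
#' @export
simulate_phenotype <- function(sim, config = sim$config, seed = config$seed + 1L) {
  G <- sim$genotypes_complete %||% sim$genotypes
  if (anyNA(G)) stop_bad_arg("phenotype simulation needs complete genotypes")
  n <- nrow(G); p <- ncol(G)
  with_seed(seed, {
    causal_idx <- integer(0)
    beta <- numeric(0)
    g <- rep(0, n)
    if (config$n_causal > 0L) {
      causal_idx <- sort(sample.int(p, config$n_causal))
      beta <- stats::rnorm(config$n_causal)
      g <- drop(G[, causal_idx, drop = FALSE] %*% beta)
    }
    var_g <- stats::var(g)
    pve <- config$target_pve
    if (pve == 1 && var_g == 0) {
      stop_bad_arg("target_pve = 1 requires non-zero genetic variance")
    }
    e <- stats::rnorm(n)
    if (var_g > 0) {
      # remove the sample correlation with g, then scale to the exact ratio
      e <- e - g * (stats::cov(e, g) / var_g)
      e <- e - mean(e)
      if (pve == 0) {
        g <- rep(0, n)
        beta <- rep(0, length(beta))
        e <- e / stats::sd(e) * 10  # days; arbitrary scale for a pure-noise trait
      } else if (pve == 1) {
        e <- rep(0, n)
      } else {
        e <- e / stats::sd(e) * sqrt(var_g * (1 - pve) / pve)
      }
    } else {
      e <- e / stats::sd(e) * 10
    }

    s <- sim$samples
    ce <- config$covariate_effects
    fixed <- config$phen_intercept + config$cline_slope * s$latitude +
      ce[["sex"]] * s$sex + ce[["year"]] * (s$year - mean(s$year)) +
      ce[["age"]] * s$age
    if (config$sweep_mode == "phenotype" && !all(is.na(s$morph))) {
      fixed <- fixed + config$sweep_phenotype_effect * s$morph
    }
    y <- fixed + g + e

    phen <- s
    phen$arrival_date_ordinal <- as.numeric(y)
    effects <- data.frame(
      variant = sim$variants$id[causal_idx],
      scaffold = sim$variants$scaffold[causal_idx],
      pos = sim$variants$pos[causal_idx],
      beta = beta,
      stringsAsFactors = FALSE
    )
    list(phenotypes = phen, effects = effects,
         components = list(fixed = fixed, genetic = g, noise = e))
  })
}

#' Simulate a full cohort (genotypes + phenotype + gene annotation)
#'
#' Convenience wrapper around [simulate_genotypes()], [simulate_phenotype()]
#' and a gene-planting step: `n_sweep_genes` non-overlapping genes are placed
#' uniformly inside the sweep region (when one is configured).
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_cohort` with `genotypes`,
#'   `genotypes_complete`, `variants`, `samples`, `phenotypes`, `effects`,
#'   `genes`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  sim <- simulate_genotypes(config)
  ph <- simulate_phenotype(sim, config)
  genes <- data.frame(gene_id = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (!is.null(config$sweep_region) && config$n_sweep_genes > 0L) {
    genes <- with_seed(config$seed + 2L, {
      sr <- config$sweep_region
      k <- config$n_sweep_genes
      span <- sr$end - sr$start
      gene_len <- max(1000, floor(span / (3 * k)))
      starts <- sort(sample.int(span - gene_len, k))
      data.frame(
        gene_id = sprintf("gene%02d", seq_len(k)),
        scaffold = paste0("scaffold_", sr$scaffold),
        start = sr$start + starts,
        end = pmin(sr$start + starts + gene_len, sr$end),
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE
      )
    })
  }
  out <- c(sim, list(phenotypes = ph$phenotypes, effects = ph$effects,
                     genes = genes))
  out$config <- config
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "loci;",
      sum(x$variants$in_sweep), "sweep loci;",
      nrow(x$genes), "planted genes\n")
  invisible(x)
}

#' Write a cohort to VCF / TSV / BED files
#'
#' Emits `cohort.vcf` (VCF 4.2 with QUAL column and `MQ` INFO key),
#' `phenotypes.tsv` (sample_id, arrival_date_ordinal, sex, year, age, colony,
#' population, latitude, longitude), `genes.bed` (BED3+name, 0-based
#' half-open) and `provenance.yaml` (config + seed).
#'
#' @param cohort a `synthetic_cohort` (or compatible list).
#' @param out_dir output directory, created if needed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_bad_arg("cannot create output dir: ", out_dir)
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    provenance = file.path(out_dir, "provenance.yaml")
  )
  write_vcf(cohort$genotypes, cohort$variants, paths[["vcf"]],
            scaffold_lengths = stats::setNames(
              cohort$config$scaffold_lengths,
              paste0("scaffold_", seq_len(cohort$config$n_scaffolds))))

  ph <- cohort$phenotypes
  cols <- c("sample_id", "arrival_date_ordinal", "sex", "year", "age",
            "colony", "population", "latitude", "longitude")
  utils::write.table(ph[, cols], paths[["phenotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  g <- cohort$genes
  utils::write.table(
    data.frame(g$scaffold, format(g$start, scientific = FALSE, trim = TRUE),
               format(g$end, scientific = FALSE, trim = TRUE), g$gene_id),
    paths[["genes"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  prov <- cohort$config
  class(prov) <- NULL
  prov$sweep_region <- if (is.null(prov$sweep_region)) "none" else prov$sweep_region
  yaml::write_yaml(list(tool = "migrarch", config = prov), paths[["provenance"]])
  invisible(paths)
}

#' Write a dosage matrix as VCF 4.2
#'
#' Dosages 0/1/2 become unphased GT `0/0`, `0/1`, `1/1`; `NA` becomes `./.`.
#' QUAL is written from `variants$qual` and mapping quality as the `MQ` INFO
#' key. A header-only VCF is valid output for zero variants.
#'
#' @param G n x p dosage matrix (rows = samples).
#' @param variants data.frame with scaffold, pos, ref, alt, qual, mq.
#' @param path output path.
#' @param scaffold_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, variants, path, scaffold_lengths = NULL) {
  n <- nrow(G); p <- ncol(G)
  stopifnot(p == nrow(variants))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=migrarch",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(scaffold_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(scaffold_lengths),
                          as.integer(scaffold_lengths)))
  }
  ids <- if (n > 0) rownames(G) %||% sprintf("S%03d", seq_len(n)) else character(0)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", ids), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (p > 0) {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    GT <- matrix("./.", n, p)
    ok <- !is.na(G)
    GT[ok] <- gt_code[as.character(G[ok])]
    body <- paste(
      variants$scaffold, variants$pos,
      variants$id %||% ".", variants$ref, variants$alt,
      format(variants$qual, trim = TRUE), "PASS",
      paste0("MQ=", format(variants$mq, trim = TRUE)), "GT",
      apply(GT, 2, paste, collapse = "\t"),
      sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
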