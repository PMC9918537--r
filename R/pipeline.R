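# End-to-end orchestration: simulate -> QC -> (geolocate) -> BSLMM -> PGS ->
# selection scans, with one global seed fanned out deterministically to the
# stages and a machine-readable run report.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Build a pipeline configuration
#'
#' Stage toggles plus per-stage parameter blocks. When `simulate` is off, the
#' inputs block must point at an existing VCF and phenotype (or groups)
#' table. Validation reports every problem at once, not just the first.
#'
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds derive from it.
#' @param stages character subset of
#'   `c("simulate", "qc", "geolocate", "bslmm", "pgs", "scan")`.
#' @param sim a [sim_config()] for the simulate stage.
#' @param filters a [filter_config()].
#' @param bslmm list of [fit_bslmm()] arguments (iterations, burnin, thin...).
#' @param pgs list of [jackknife_cv()] arguments (reps, train_frac...).
#' @param scan list: k (extreme-group size), window_size, z_cutoff,
#'   merge_gap_windows.
#' @param inputs list of paths used when simulate is off: `vcf`,
#'   `phenotypes`, `genes` (BED, optional), `twilights` (CSV, optional;
#'   enables the geolocate stage), `colony_sites` (optional TSV:
#'   colony, latitude, longitude).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "qc", "bslmm", "pgs", "scan"),
                            sim = sim_config(seed = derive_seed(seed, 1L)),
                            filters = filter_config(),
                            bslmm = list(),
                            pgs = list(),
                            scan = list(k = 10L, window_size = 5000,
                                        z_cutoff = 4, merge_gap_windows = 2L),
                            inputs = list()) {
  known <- c("simulate", "qc", "geolocate", "bslmm", "pgs", "scan")
  errs <- character()
  bad <- setdiff(stages, known)
  if (length(bad)) errs <- c(errs, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (!"simulate" %in% stages) {
    if (is.null(inputs$vcf)) {
      errs <- c(errs, "simulate disabled but no inputs$vcf given")
    } else if (!file.exists(inputs$vcf)) {
      errs <- c(errs, paste("inputs$vcf does not exist:", inputs$vcf))
    }
    needs_phen <- any(c("bslmm", "pgs", "scan") %in% stages)
    if (needs_phen && is.null(inputs$phenotypes) && is.null(inputs$groups) &&
        !"geolocate" %in% stages) {
      errs <- c(errs, "no phenotype source: need inputs$phenotypes, inputs$groups, or the geolocate stage")
    }
    if (!is.null(inputs$phenotypes) && !file.exists(inputs$phenotypes)) {
      errs <- c(errs, paste("inputs$phenotypes does not exist:", inputs$phenotypes))
    }
  }
  if ("geolocate" %in% stages && is.null(inputs$twilights) &&
      !"simulate" %in% stages) {
    errs <- c(errs, "geolocate stage needs inputs$twilights")
  }
  if (length(errs)) {
    stop_bad_arg("invalid pipeline config:\n  - ",
                 paste(errs, collapse = "\n  - "))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 sim = sim, filters = filters, bslmm = bslmm, pgs = pgs,
                 scan = scan, inputs = inputs),
            class = "pipeline_config")
}

stage_error <- function(stage, parent) {
  stop(structure(class = c("migrarch_stage_error", "error", "condition"),
                 list(message = paste0("stage '", stage, "' failed: ",
                                       conditionMessage(parent)),
                      call = NULL, stage = stage, parent = parent)))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing per-stage TSV
#' outputs under `out_dir` and a `run_report.json` with parameter provenance
#' and the headline metrics (PVE median and 89% ETI, PGS cross-validated mean
#' R-squared and full-sample R-squared, top delta-FST regions with gene
#' counts). A stage failure halts the run with a typed condition
#' (`migrarch_stage_error`); outputs of completed stages are preserved.
#'
#' @param cfg a [pipeline_config()].
#' @return The run report, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, stages = cfg$stages,
                 parameters = list(filters = unclass(cfg$filters),
                                   scan = cfg$scan, bslmm = cfg$bslmm,
                                   pgs = cfg$pgs),
                 metrics = list(), outputs = list())
  has <- function(s) s %in% cfg$stages
  cohort <- NULL; qc <- NULL; Gc <- NULL; phen <- NULL; genes <- NULL

  if (has("simulate")) {
    tryCatch({
      cohort <- simulate_cohort(cfg$sim)
      paths <- write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
      phen <- cohort$phenotypes
      genes <- cohort$genes
      report$outputs$cohort <- as.list(paths)
    }, error = function(e) stage_error("simulate", e))
  } else {
    phen <- if (!is.null(cfg$inputs$phenotypes)) {
      utils::read.delim(cfg$inputs$phenotypes, stringsAsFactors = FALSE)
    }
    genes <- if (!is.null(cfg$inputs$genes)) read_bed(cfg$inputs$genes)
  }

  if (has("geolocate") && !is.null(cfg$inputs$twilights)) {
    tryCatch({
      tw <- read_twilights(cfg$inputs$twilights)
      sites <- if (!is.null(cfg$inputs$colony_sites)) {
        utils::read.delim(cfg$inputs$colony_sites, stringsAsFactors = FALSE)
      }
      rows <- lapply(split(tw, tw$sample_id), function(ts) {
        track <- estimate_track(ts)
        site <- if (!is.null(sites)) {
          colony_site(sites$latitude[1], sites$longitude[1])
        } else {
          # default: last reliable position approximates the colony
          okr <- which(track$quality == "ok")
          colony_site(track$latitude[okr[length(okr)]],
                      track$longitude[okr[length(okr)]])
        }
        data.frame(sample_id = ts$sample_id[1],
                   arrival_date_ordinal = as.integer(derive_arrival_date(track, site)))
      })
      arr <- do.call(rbind, rows)
      write_tsv(arr, file.path(cfg$out_dir, "arrival_dates.tsv"))
      if (is.null(phen)) phen <- arr else {
        phen$arrival_date_ordinal <- NULL
        phen <- merge(phen, arr, by = "sample_id", sort = FALSE)
      }
      report$outputs$geolocate <- "arrival_dates.tsv"
    }, error = function(e) stage_error("geolocate", e))
  }

  if (has("qc")) {
    tryCatch({
      vcf_path <- cfg$inputs$vcf %||% file.path(cfg$out_dir, "cohort", "cohort.vcf")
      raw <- read_vcf(vcf_path)
      qc <- apply_filters(raw$genotypes, raw$variants, cfg$filters)
      Gc <- impute_missing_mean(qc$genotypes)
      rep_df <- data.frame(stage = c("input", names(qc$removed), "pass"),
                           count = c(qc$n_input, as.integer(qc$removed),
                                     qc$n_pass))
      write_tsv(rep_df, file.path(cfg$out_dir, "filter_report.tsv"))
      write_vcf(qc$genotypes, qc$variants,
                file.path(cfg$out_dir, "filtered.vcf"))
      report$metrics$n_snps_pass <- qc$n_pass
      report$outputs$qc <- c("filter_report.tsv", "filtered.vcf")
    }, error = function(e) stage_error("qc", e))
  }

  need_y <- function(stage) {
    if (is.null(phen) || is.null(phen$arrival_date_ordinal)) {
      stage_error(stage, simpleError("no phenotype table available"))
    }
    # align genotype rows with the phenotype table
    ord <- match(rownames(Gc), phen$sample_id)
    if (anyNA(ord)) stage_error(stage, simpleError(
      "sample ids in VCF and phenotype table do not match"))
    phen[ord, , drop = FALSE]
  }

  W <- NULL
  if (has("bslmm") || has("pgs")) {
    tryCatch({
      ph <- need_y("covariates")
      pc <- genotype_pca(Gc, n_pcs = 1L)
      W <- covariate_matrix(ph, pc$scores[, 1])
      phen <- ph
    }, error = function(e) stage_error("covariates", e))
  }

  if (has("bslmm")) {
    tryCatch({
      args <- c(list(y = phen$arrival_date_ordinal, G = Gc, W = W,
                     seed = derive_seed(cfg$seed, 2L)), cfg$bslmm)
      post <- do.call(fit_bslmm, args)
      s <- summarize_pve(post)
      write_tsv(post$samples, file.path(cfg$out_dir, "bslmm_samples.tsv"))
      write_tsv(data.frame(variant = post$variant_ids, pip = post$pip),
                file.path(cfg$out_dir, "bslmm_pip.tsv"))
      report$metrics$pve_median <- s$median
      report$metrics$pve_eti <- s$eti
      report$metrics$n_pip_candidates <- nrow(pip_candidates(post))
      report$outputs$bslmm <- c("bslmm_samples.tsv", "bslmm_pip.tsv")
    }, error = function(e) stage_error("bslmm", e))
  }

  if (has("pgs")) {
    tryCatch({
      args <- c(list(y = phen$arrival_date_ordinal, G = Gc, W = W,
                     variants = qc$variants,
                     seed = derive_seed(cfg$seed, 3L)), cfg$pgs)
      cv <- do.call(jackknife_cv, args)
      full <- build_pgs_model(phen$arrival_date_ordinal, Gc, W, qc$variants,
                              seed = derive_seed(cfg$seed, 4L))
      full_r2 <- incremental_r2(predict_pgs(full, Gc),
                                phen$arrival_date_ordinal, W)
      dec <- decile_summary(cv, phen$arrival_date_ordinal)
      write_tsv(cv$rep_results, file.path(cfg$out_dir, "pgs_cv_r2.tsv"))
      write_tsv(cv$predictions, file.path(cfg$out_dir, "pgs_predictions.tsv"))
      write_tsv(dec$table, file.path(cfg$out_dir, "pgs_deciles.tsv"))
      report$metrics$pgs_cv_mean_r2 <- mean(cv$rep_results$r2)
      report$metrics$pgs_full_r2 <- full_r2
      report$metrics$pgs_decile_spearman <-
        stats::cor(dec$table$decile, dec$table$mean_phenotype,
                   method = "spearman")
      report$outputs$pgs <- c("pgs_cv_r2.tsv", "pgs_predictions.tsv",
                              "pgs_deciles.tsv")
    }, error = function(e) stage_error("pgs", e))
  }

  if (has("scan")) {
    tryCatch({
      if (is.null(qc)) {
        raw <- read_vcf(cfg$inputs$vcf %||%
                          file.path(cfg$out_dir, "cohort", "cohort.vcf"))
        G <- raw$genotypes; variants <- raw$variants
      } else {
        G <- qc$genotypes  # scans handle missingness site-wise; no imputation
        variants <- qc$variants
      }
      lens <- tapply(variants$pos, variants$scaffold, max)
      if (!is.null(cohort)) {
        lens <- stats::setNames(cohort$config$scaffold_lengths,
                                paste0("scaffold_",
                                       seq_len(cohort$config$n_scaffolds)))
      }
      windows <- make_windows(lens, cfg$scan$window_size %||% 5000)

      if (!is.null(cfg$inputs$groups)) {
        gr <- utils::read.delim(cfg$inputs$groups, stringsAsFactors = FALSE)
        early <- gr$sample_id[gr$group == "early"]
        late <- gr$sample_id[gr$group == "late"]
        popA <- gr$sample_id[gr$group == "popA"]
        popB <- gr$sample_id[gr$group == "popB"]
      } else {
        ph <- if (is.null(phen$sample_id)) need_y("scan") else phen
        ext <- select_extremes(ph, cfg$scan$k %||% 10L)
        early <- ext$early; late <- ext$late
        lat_by_pop <- tapply(ph$latitude, ph$population, mean)
        popA <- ph$sample_id[ph$population == names(which.min(lat_by_pop))]
        popB <- ph$sample_id[ph$population == names(which.max(lat_by_pop))]
      }
      scan_ph <- wc_fst_window(G, variants, early, late, windows)
      scan_pop <- wc_fst_window(G, variants, popA, popB, windows)
      dfst <- net_fst(scan_ph, scan_pop)
      pi_e <- pi_window(G, variants, early, windows)
      td_e <- tajimas_d_window(G, variants, early, windows)
      regions <- detect_region(dfst, cfg$scan$z_cutoff %||% 4,
                               cfg$scan$merge_gap_windows %||% 2L)
      write_tsv(scan_ph, file.path(cfg$out_dir, "fst_phenotype.tsv"))
      write_tsv(scan_pop, file.path(cfg$out_dir, "fst_population.tsv"))
      write_tsv(dfst, file.path(cfg$out_dir, "delta_fst.tsv"))
      write_tsv(pi_e, file.path(cfg$out_dir, "pi_early.tsv"))
      write_tsv(td_e, file.path(cfg$out_dir, "tajimas_d_early.tsv"))
      gene_hits <- NULL
      if (nrow(regions) && !is.null(genes) && nrow(genes)) {
        gl <- genes_in_region(regions, genes)
        regions$n_genes <- attr(gl, "counts")
        regions$genes <- vapply(gl, paste, character(1), collapse = ",")
      } else if (nrow(regions)) {
        regions$n_genes <- 0L; regions$genes <- ""
      }
      write_tsv(regions, file.path(cfg$out_dir, "delta_fst_regions.tsv"))
      report$metrics$n_regions <- nrow(regions)
      if (nrow(regions)) {
        top <- regions[which.max(regions$peak_value), ]
        report$metrics$top_region <- list(
          scaffold = top$scaffold, start = top$start, end = top$end,
          span_bp = top$end - top$start, n_genes = top$n_genes)
      }
      report$outputs$scan <- c("fst_phenotype.tsv", "fst_population.tsv",
                               "delta_fst.tsv", "pi_early.tsv",
                               "tajimas_d_early.tsv", "delta_fst_regions.tsv")
    }, error = function(e) stage_error("scan", e))
  }

  report$status <- "success"
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
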