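# Polygenic scores by clumping + p-value thresholding, evaluated with
# jackknife cross-validation (default 100 random 85/15 partitions) and
# summarized by decile. All model choices (summary statistics, clumping,
# threshold selection) use training individuals only.

#' Per-SNP marginal association scan
#'
#' Covariate-adjusted simple regression per variant via Frisch-Waugh:
#' phenotype and dosages are residualized on `W`, then slope, standard error
#' and two-sided p-value are computed per column. Monomorphic variants get
#' `NA` effect and p-value and are excluded downstream.
#'
#' @param y phenotype vector.
#' @param G complete samples x variants dosage matrix.
#' @param W covariate matrix with intercept (default intercept only).
#' @return data.frame: beta, se, t, p, effect allele is the ALT/dosage allele.
#' @export
marginal_gwas <- function(y, G, W = NULL) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  stopifnot(nrow(G) == n, nrow(W) == n)
  q <- qr(W)
  ry <- qr.resid(q, y)
  RG <- qr.resid(q, G)
  sxx <- colSums(RG^2)
  sxy <- drop(crossprod(RG, ry))
  syy <- sum(ry^2)
  df <- n - q$rank - 1L
  if (df < 1) stop_bad_arg("not enough residual degrees of freedom")
  beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
  ssr <- syy - beta^2 * sxx
  se <- sqrt(pmax(ssr, 0) / df / sxx)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  pval[!is.finite(pval)] <- NA_real_
  data.frame(beta = beta, se = se, t = tval, p = pval)
}

#' Greedy p-value-ordered LD clumping
#'
#' Variants are processed in ascending p-value order (ties broken by position
#' then column index); a variant becomes an index unless it lies within
#' `window_kb` of an already-chosen index on the same scaffold with squared
#' genotype correlation strictly above `r2_cutoff`.
#'
#' @param stats data.frame from [marginal_gwas()] (needs `p`).
#' @param G complete dosage matrix (columns aligned to `stats`).
#' @param variants data.frame with `scaffold` and `pos` aligned to columns.
#' @param r2_cutoff squared-correlation cutoff (default 0.1).
#' @param window_kb clumping window in kb (default 250).
#' @return Integer vector of index-variant column positions.
#' @export
ld_clump <- function(stats, G, variants, r2_cutoff = 0.1, window_kb = 250) {
  stopifnot(nrow(stats) == ncol(G), nrow(variants) == ncol(G))
  usable <- which(!is.na(stats$p))
  ord <- usable[order(stats$p[usable], variants$pos[usable], usable)]
  window_bp <- window_kb * 1000
  idx <- integer(0)
  for (j in ord) {
    keep <- TRUE
    if (length(idx)) {
      near <- idx[variants$scaffold[idx] == variants$scaffold[j] &
                    abs(variants$pos[idx] - variants$pos[j]) <= window_bp]
      for (i in near) {
        r <- suppressWarnings(stats::cor(G[, j], G[, i]))
        if (!is.na(r) && r^2 > r2_cutoff) { keep <- FALSE; break }
      }
    }
    if (keep) idx <- c(idx, j)
  }
  sort(idx)
}

default_threshold_grid <- function() {
  c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

# squared Pearson correlation between a score and the covariate-residualized
# phenotype; 0 when the score is degenerate
incremental_r2 <- function(score, y, W) {
  if (length(unique(score)) < 2) return(0)
  ry <- qr.resid(qr(W), y)
  r <- suppressWarnings(stats::cor(score, ry))
  if (is.na(r)) 0 else r^2
}

#' Build a clumping + thresholding PGS model on training data
#'
#' Summary statistics and clumping are computed on an internal training split;
#' each p-value threshold in the grid is scored on the internal validation
#' split, and the threshold with the highest incremental R-squared (over a
#' covariates-only model) wins. The final model re-estimates summary
#' statistics and clumping on the full training set at the winning threshold.
#' Tuning never touches data outside `y`/`G`/`W` as passed (the evaluation
#' fold of an outer cross-validation must not be included).
#'
#' @param y,G,W training phenotype, complete dosages, covariates.
#' @param variants variant table aligned to `G` columns.
#' @param thresholds p-value threshold grid.
#' @param r2_cutoff,window_kb clumping parameters.
#' @param internal_frac fraction of the training set used for internal
#'   summary-statistic estimation (rest tunes the threshold).
#' @param seed RNG seed for the internal split.
#' @return A list of class `pgs_model`: `variant_idx` (columns of `G`),
#'   `variant_id`, `beta`, `threshold`, `r2_cutoff`, `window_kb`, `empty`,
#'   `tuning` (per-threshold internal R-squared).
#' @export
build_pgs_model <- function(y, G, W = NULL, variants,
                            thresholds = default_threshold_grid(),
                            r2_cutoff = 0.1, window_kb = 250,
                            internal_frac = 0.75, seed = 1L) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  itrain <- with_seed(seed, sort(sample.int(n, max(2, round(internal_frac * n)))))
  ival <- setdiff(seq_len(n), itrain)
  if (length(ival) < 3) { itrain <- seq_len(n); ival <- seq_len(n) }

  st_int <- marginal_gwas(y[itrain], G[itrain, , drop = FALSE],
                          W[itrain, , drop = FALSE])
  idx_int <- ld_clump(st_int, G[itrain, , drop = FALSE], variants,
                      r2_cutoff, window_kb)
  tuning <- vapply(thresholds, function(thr) {
    sel <- idx_int[!is.na(st_int$p[idx_int]) & st_int$p[idx_int] <= thr]
    if (!length(sel)) return(0)
    sc <- drop(G[ival, sel, drop = FALSE] %*% st_int$beta[sel])
    incremental_r2(sc, y[ival], W[ival, , drop = FALSE])
  }, numeric(1))
  best <- thresholds[which.max(tuning)]

  st <- marginal_gwas(y, G, W)
  idx <- ld_clump(st, G, variants, r2_cutoff, window_kb)
  sel <- idx[!is.na(st$p[idx]) & st$p[idx] <= best]
  model <- list(variant_idx = sel,
                variant_id = variants$id[sel] %||% as.character(sel),
                beta = st$beta[sel],
                threshold = best, r2_cutoff = r2_cutoff,
                window_kb = window_kb,
                empty = length(sel) == 0,
                tuning = data.frame(threshold = thresholds, r2 = tuning))
  class(model) <- "pgs_model"
  model
}

#' Score individuals with a PGS model
#'
#' Weighted sum of effect-allele (ALT) dosages over the model's index
#' variants; an empty model scores everyone 0.
#'
#' @param model a `pgs_model`.
#' @param G complete dosage matrix with the same column order the model was
#'   built against.
#' @return Numeric score vector.
#' @export
predict_pgs <- function(model, G) {
  stopifnot(inherits(model, "pgs_model"))
  if (model$empty) return(rep(0, nrow(G)))
  drop(G[, model$variant_idx, drop = FALSE] %*% model$beta)
}

#' Jackknife cross-validation of the PGS pipeline
#'
#' Repeats `reps` random train/test partitions (default 100 at 85%/15%; at
#' n = 87 that is 74 training and 13 test individuals). Each repetition runs
#' the full pipeline -- marginal scan, clumping, threshold selection -- on the
#' training fold only, then reports the incremental R-squared of the score on
#' the held-out fold. Held-out scores are standardized against the training
#' fold's score distribution so per-individual predictions are comparable
#' across repetitions, and averaged per individual.
#'
#' @param y,G,W phenotype, complete dosages, covariates for all n individuals.
#' @param variants variant table aligned to `G`.
#' @param reps number of partitions.
#' @param train_frac training fraction.
#' @param seed RNG seed (partitions and internal splits derive from it).
#' @param ... passed to [build_pgs_model()] (thresholds, clumping).
#' @return A list of class `pgs_cv`: `rep_results` (rep, r2, threshold,
#'   n_snps, fingerprint), `predictions` (sample index, mean standardized
#'   score, n_heldout), `never_heldout` (indices, if any), `partitions`.
#' @export
jackknife_cv <- function(y, G, W = NULL, variants, reps = 100L,
                         train_frac = 0.85, seed = 1L, ...) {
  n <- length(y)
  if (n < 20) stop_bad_arg("jackknife CV needs n >= 20")
  if (is.null(W)) W <- matrix(1, n, 1)
  n_train <- round(train_frac * n)
  partitions <- with_seed(seed, {
    lapply(seq_len(reps), function(r) sort(sample.int(n, n_train)))
  })
  pred_sum <- numeric(n); pred_n <- integer(n)
  rep_results <- data.frame(rep = seq_len(reps), r2 = NA_real_,
                            threshold = NA_real_, n_snps = NA_integer_,
                            fingerprint = NA_real_)
  for (r in seq_len(reps)) {
    tr <- partitions[[r]]
    te <- setdiff(seq_len(n), tr)
    model <- build_pgs_model(y[tr], G[tr, , drop = FALSE],
                             W[tr, , drop = FALSE], variants,
                             seed = derive_seed(seed, r), ...)
    sc_tr <- predict_pgs(model, G[tr, , drop = FALSE])
    sc_te <- predict_pgs(model, G[te, , drop = FALSE])
    rep_results$r2[r] <- incremental_r2(sc_te, y[te], W[te, , drop = FALSE])
    rep_results$threshold[r] <- model$threshold
    rep_results$n_snps[r] <- length(model$variant_idx)
    rep_results$fingerprint[r] <- sum(abs(model$beta)) +
      1e-9 * sum(model$variant_idx)
    s_tr <- stats::sd(sc_tr)
    z <- if (is.na(s_tr) || s_tr == 0) rep(0, length(te)) else {
      (sc_te - mean(sc_tr)) / s_tr
    }
    pred_sum[te] <- pred_sum[te] + z
    pred_n[te] <- pred_n[te] + 1L
  }
  never <- which(pred_n == 0)
  if (length(never)) {
    warning(length(never), " individual(s) never held out; predictions missing",
            call. = FALSE)
  }
  out <- list(
    rep_results = rep_results,
    predictions = data.frame(
      index = seq_len(n),
      sample_id = rownames(G) %||% as.character(seq_len(n)),
      mean_score = ifelse(pred_n > 0, pred_sum / pmax(pred_n, 1), NA_real_),
      n_heldout = pred_n),
    never_heldout = never,
    partitions = partitions)
  class(out) <- "pgs_cv"
  out
}

#' Decile summary of predicted polygenic scores
#'
#' Ranks individuals by mean held-out predicted score (ties broken by sample
#' id) and cuts them into 10 groups: decile 1 holds the lowest scores. When n
#' is not divisible by 10, the `n mod 10` extra members go to the lowest
#' deciles (sizes are determined before ranking, so the rule is
#' deterministic).
#'
#' @param cv a `pgs_cv` (or a data.frame with `mean_score` and `sample_id`).
#' @param phenotype phenotype vector aligned to the cv individuals.
#' @return A list: `table` (decile, n, mean_score, mean_phenotype,
#'   median_phenotype), `assignment` (per-individual decile),
#'   `spearman` (rank correlation between decile index and individual
#'   phenotype).
#' @export
decile_summary <- function(cv, phenotype) {
  preds <- if (inherits(cv, "pgs_cv")) cv$predictions else cv
  ok <- which(!is.na(preds$mean_score))
  if (length(ok) < 10) stop_bad_arg("need >= 10 individuals with predictions")
  n <- length(ok)
  sizes <- rep(n %/% 10, 10)
  extra <- n %% 10
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- ok[order(preds$mean_score[ok], preds$sample_id[ok])]
  dec <- rep(NA_integer_, nrow(preds))
  dec[ord] <- rep(seq_len(10), times = sizes)
  tab <- do.call(rbind, lapply(seq_len(10), function(d) {
    i <- which(dec == d)
    data.frame(decile = d, n = length(i),
               mean_score = mean(preds$mean_score[i]),
               mean_phenotype = mean(phenotype[i]),
               median_phenotype = stats::median(phenotype[i]))
  }))
  sp <- suppressWarnings(
    stats::cor(dec[ok], phenotype[ok], method = "spearman"))
  list(table = tab, assignment = dec, spearman = sp)
}

#' @export
print.pgs_cv <- function(x, ...) {
  cat(sprintf("PGS jackknife CV: %d reps, mean test R2 = %.3f (sd %.3f)\n",
              nrow(x$rep_results), mean(x$rep_results$r2),
              stats::sd(x$rep_results$r2)))
  invisible(x)
}
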