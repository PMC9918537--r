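# Bayesian sparse linear mixed model for PVE and posterior inclusion
# probabilities, with GRM/PCA utilities for covariate construction.
#
# Model (after absorbing covariates W):
#   y = X beta + u + eps,  u ~ N(0, sigma^2 lambda_u K),  eps ~ N(0, sigma^2 I)
# with spike-and-slab beta: each SNP included independently with probability
# pi_sparsity, included effects ~ N(0, sigma^2 lambda_beta). Hyperparameters
# are expressed as h (total genetic variance fraction) and rho (sparse share),
# both uniform on (0,1); log pi_sparsity is uniform on [log(1/p), 0].
# beta, u and sigma^2 are integrated analytically, so the chain moves only
# over (gamma, h, rho, log pi) -- a collapsed Metropolis-Hastings sampler.

#' Genomic relatedness matrix from a complete dosage matrix
#'
#' Columns are mean-centered and (by default) scaled to unit sample variance,
#' then `K = X Xᵀ / p`. Zero-variance columns contribute nothing. The
#' standardized form weights all loci equally regardless of allele frequency;
#' `scale = "centered"` keeps raw centered dosages.
#'
#' @param G complete samples x variants dosage matrix.
#' @param scale `"standardized"` (default) or `"centered"`.
#' @return Symmetric PSD n x n matrix.
#' @export
compute_grm <- function(G, scale = c("standardized", "centered")) {
  scale <- match.arg(scale)
  if (is.null(dim(G)) || ncol(G) == 0) stop_bad_arg("need at least one variant")
  if (anyNA(G)) stop_bad_arg("GRM needs complete genotypes; impute first")
  X <- scale_genotypes(G, standardize = scale == "standardized")
  K <- tcrossprod(X) / ncol(G)
  (K + t(K)) / 2
}

scale_genotypes <- function(G, standardize = TRUE) {
  X <- sweep(G, 2, colMeans(G), "-")
  if (standardize) {
    s <- apply(G, 2, stats::sd)
    s[s == 0 | is.na(s)] <- Inf  # monomorphic columns vanish
    X <- sweep(X, 2, s, "/")
  }
  X
}

#' Principal components of genetic variation
#'
#' Eigendecomposition of the GRM; scores are eigenvectors scaled by the
#' square root of their (non-negative) eigenvalues. Sign convention: within
#' each PC the largest-magnitude score is positive.
#'
#' @param G complete dosage matrix (or a precomputed GRM via `grm =`).
#' @param n_pcs number of components to return.
#' @param grm optional precomputed GRM.
#' @return A list: `scores` (n x n_pcs), `explained` (fractions summing to 1
#'   over all components), `values` (all eigenvalues).
#' @export
genotype_pca <- function(G, n_pcs = 10L, grm = NULL) {
  K <- grm %||% compute_grm(G)
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  n_pcs <- min(n_pcs, ncol(K))
  scores <- e$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_pcs)]), n_pcs)
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(K) %||% rownames(G)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  list(scores = scores, explained = vals / sum(vals), values = e$values)
}

#' Build the standard covariate matrix
#'
#' Intercept, sex, year (centered), age, and PC1 of the genotype data.
#'
#' @param phenotypes data.frame with sex, year, age columns.
#' @param pc1 numeric vector (first genotype principal component).
#' @return Numeric matrix with full column rank.
#' @export
covariate_matrix <- function(phenotypes, pc1) {
  W <- cbind(intercept = 1, sex = phenotypes$sex,
             year = phenotypes$year - mean(phenotypes$year),
             age = phenotypes$age, PC1 = pc1)
  if (qr(W)$rank < ncol(W)) {
    keep <- qr(W)$pivot[seq_len(qr(W)$rank)]
    W <- W[, sort(keep), drop = FALSE]
  }
  W
}

# --- collapsed sampler engine -----------------------------------------------
# The engine keeps, for the current (hyperparameters, gamma), the caches
#   AXg = diag(1/Lambda) %*% Xt[, gam],  XtLX = Xg' L^-1 Xg,  XtLy = Xg' L^-1 y
# updated incrementally on add/remove, so a gamma move costs O(k m) plus one
# k x k Cholesky instead of a fresh O(k^2 m) cross-product.

bslmm_env <- function(d, Xt, yt, vbar, kbar, p, m, max_k, calibration = "inclusion") {
  env <- new.env(parent = emptyenv())
  env$d <- d; env$Xt <- Xt; env$yt <- yt
  env$vbar <- vbar; env$kbar <- kbar; env$p <- p; env$m <- m
  env$max_k <- max_k
  env$calibration <- calibration
  env$gam <- integer(0)
  # preallocated caches (columns/rows 1..k are live)
  env$Xg <- matrix(0, m, max_k)
  env$AXg <- matrix(0, m, max_k)
  env$XtLX <- matrix(0, max_k, max_k)
  env$XtLy <- numeric(max_k)
  env
}

env_set_hypers <- function(env, h, rho, logpi) {
  env$h <- h; env$rho <- rho; env$logpi <- logpi
  pip_n <- exp(logpi) * env$p
  env$eff_k <- switch(env$calibration,
    inclusion = function(k) max(k, 1),
    pi = function(k) pip_n,
    hybrid = function(k) max(k, pip_n))
  env$lam_u <- h * (1 - rho) / ((1 - h) * env$kbar)
  # sparse-effect variance calibrated to the realized inclusion set: with k
  # SNPs included, lam_beta = h rho / ((1 - h) k vbar), so the included set is
  # expected to carry the sparse share of variance regardless of k
  env$hr_s <- h * rho / (1 - h)
  lam <- env$lam_u * env$d + 1
  env$inv_lam <- 1 / lam
  env$logdet_lam <- sum(log(lam))
  env$yL <- env$yt * env$inv_lam
  env$yLy <- sum(env$yt * env$yL)
  env_rebuild_gamma(env)
}

env_rebuild_gamma <- function(env) {
  k <- length(env$gam)
  if (k == 0L) return(invisible(env))
  ix <- seq_len(k)
  Xg <- env$Xt[, env$gam, drop = FALSE]
  AXg <- Xg * env$inv_lam
  env$Xg[, ix] <- Xg
  env$AXg[, ix] <- AXg
  env$XtLX[ix, ix] <- crossprod(Xg, AXg)
  env$XtLy[ix] <- drop(crossprod(AXg, env$yt))
  invisible(env)
}

env_add <- function(env, j) {
  xj <- env$Xt[, j]
  axj <- xj * env$inv_lam
  k <- length(env$gam)
  kk <- k + 1L
  env$Xg[, kk] <- xj
  env$AXg[, kk] <- axj
  if (k > 0L) {
    ix <- seq_len(k)
    v <- drop(crossprod(env$Xg[, ix, drop = FALSE], axj))
    env$XtLX[ix, kk] <- v
    env$XtLX[kk, ix] <- v
  }
  env$XtLX[kk, kk] <- sum(xj * axj)
  env$XtLy[kk] <- sum(axj * env$yt)
  env$gam <- c(env$gam, j)
  invisible(env)
}

env_remove <- function(env, j) {
  # swap the removed slot with the last live slot, then shrink
  i <- match(j, env$gam)
  k <- length(env$gam)
  if (i < k) {
    env$Xg[, i] <- env$Xg[, k]
    env$AXg[, i] <- env$AXg[, k]
    ix <- seq_len(k)
    row_k <- env$XtLX[k, ix]
    row_k[i] <- env$XtLX[k, k]
    env$XtLX[i, ix] <- row_k
    env$XtLX[ix, i] <- row_k
    env$XtLy[i] <- env$XtLy[k]
    env$gam[i] <- env$gam[k]
  }
  env$gam <- env$gam[-k]
  invisible(env)
}

# collapsed log marginal likelihood at the current caches; also stores the
# Cholesky and S for reuse by the conditional draw
env_logml <- function(env) {
  k <- length(env$gam)
  base <- -0.5 * env$logdet_lam
  if (k == 0L) {
    env$S <- env$yLy
    return(base - 0.5 * env$m * log(env$yLy))
  }
  ix <- seq_len(k)
  lam_beta <- env$hr_s / (env$eff_k(k) * env$vbar)
  env$lam_beta <- lam_beta
  B <- lam_beta * env$XtLX[ix, ix, drop = FALSE]
  diag(B) <- diag(B) + 1
  R <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  quad <- lam_beta * sum(backsolve(R, env$XtLy[ix], transpose = TRUE)^2)
  S <- env$yLy - quad
  if (S <= 0) return(-Inf)
  env$S <- S
  base - sum(log(diag(R))) - 0.5 * env$m * log(S)
}

# conditional draw of sigma^2, beta, u given (gamma, hypers); PVE on the
# realized covariate-adjusted sample
env_draw <- function(env) {
  m <- env$m
  k <- length(env$gam)
  if (k == 0L) {
    S <- env$yLy
    sigma2 <- S / stats::rchisq(1, df = m)
    g <- numeric(m)
  } else {
    ix <- seq_len(k)
    lam_beta <- env$hr_s / (env$eff_k(k) * env$vbar)
    P <- env$XtLX[ix, ix, drop = FALSE] + diag(1 / lam_beta, k)
    Rp <- chol(P)
    XtLy <- env$XtLy[ix]
    mu <- backsolve(Rp, backsolve(Rp, XtLy, transpose = TRUE))
    S <- env$yLy - sum(XtLy * mu)
    sigma2 <- S / stats::rchisq(1, df = m)
    beta <- mu + sqrt(sigma2) * backsolve(Rp, stats::rnorm(k))
    g <- drop(env$Xg[, ix, drop = FALSE] %*% beta)
  }
  r <- env$yt - g
  ci <- 1 - env$inv_lam  # lam_u d / (lam_u d + 1)
  u <- ci * r + stats::rnorm(m, 0, sqrt(pmax(sigma2 * ci, 0)))
  gv <- g + u
  var_g <- sum((gv - mean(gv))^2) / (m - 1)
  list(pve = var_g / (var_g + sigma2), sigma2 = sigma2)
}

#' Fit the Bayesian sparse linear mixed model
#'
#' Estimates the proportion of phenotypic variance explained (PVE) and
#' per-SNP posterior inclusion probabilities (PIP). Covariates are absorbed
#' by rotating the model onto an orthonormal basis of the complement of
#' `col(W)` (equivalent to a flat prior on the covariate coefficients); the
#' polygenic term is handled in the eigenbasis of the rotated GRM, and sparse
#' effects, the polygenic vector and the residual variance are integrated
#' analytically, so the Metropolis-Hastings chain moves only over the
#' inclusion indicators and (h, rho, log pi). Inclusion proposals mix uniform
#' draws with draws weighted toward SNPs ranked high by marginal association
#' (weight proportional to 1/rank), with the exact Hastings correction.
#'
#' Per retained sample, PVE is computed on the realized (covariate-adjusted)
#' sample: draw sigma^2, beta and u from their conditionals, then
#' `PVE = var(g) / (var(g) + sigma^2)` with `g = X beta + u`.
#'
#' @param y phenotype vector.
#' @param G complete samples x variants dosage matrix.
#' @param W covariate matrix (with intercept), full column rank.
#' @param iterations,burnin,thin MCMC controls; retained samples =
#'   `(iterations - burnin) / thin`.
#' @param gamma_moves inclusion-indicator updates per iteration.
#' @param max_included hard cap on the sparse-set size.
#' @param seed RNG seed; chains are exactly reproducible.
#' @return A list of class `bslmm_posterior`: `samples` (data.frame with h,
#'   rho, log_pi, n_included, pve, sigma2), `pip` (per-variant posterior
#'   inclusion probabilities), `inclusion_counts`, `n_retained`,
#'   `diagnostics` (split-chain R-hat for PVE and h, acceptance rates),
#'   `variant_ids`.
#' @export
fit_bslmm <- function(y, G, W = NULL,
                      iterations = 8000L, burnin = 2000L, thin = 6L,
                      gamma_moves = 10L, max_included = 75L, seed = 1L,
                      calibration = c("hybrid", "inclusion", "pi")) {
  calibration <- match.arg(calibration)
  n <- length(y)
  stopifnot(nrow(G) == n, iterations > burnin, thin >= 1)
  if (anyNA(G)) stop_bad_arg("BSLMM needs complete genotypes; impute first")
  if (is.null(W)) W <- matrix(1, n, 1)
  q <- qr(W)
  if (q$rank < ncol(W)) stop_bad_arg("covariate matrix W is rank deficient")
  p <- ncol(G)
  m <- n - q$rank

  X <- scale_genotypes(G, standardize = TRUE)
  Qfull <- qr.Q(q, complete = TRUE)
  Q2 <- Qfull[, (q$rank + 1):n, drop = FALSE]
  y2 <- drop(crossprod(Q2, y))
  X2 <- crossprod(Q2, X)                # m x p
  K2 <- tcrossprod(X2) / p
  e <- eigen((K2 + t(K2)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  yt <- drop(crossprod(U, y2))
  Xt <- crossprod(U, X2)                # m x p
  kbar <- mean(d)
  vbar <- sum(X2^2) / (p * max(m - 1, 1))
  if (kbar <= 0) stop_bad_arg("degenerate GRM (no genetic variance)")

  # guided add-proposal: SNP weights 1 / marginal-association rank, mixed
  # half-and-half with a uniform component; during burn-in the ranks are
  # refreshed from residual associations (finite adaptation: the proposal is
  # frozen before any retained sample is drawn)
  xy <- abs(drop(crossprod(X2, y2)))
  rank_order <- order(-xy)              # rank_order[r] = SNP with rank r
  rank_of <- integer(p); rank_of[rank_order] <- seq_len(p)
  wts <- 1 / seq_len(p)                 # weight by rank
  cum_w <- cumsum(wts)
  Zw <- cum_w[p]
  w_of <- wts[rank_of]                  # weight of SNP j

  n_keep <- (iterations - burnin) %/% thin
  samples <- matrix(NA_real_, n_keep, 6,
                    dimnames = list(NULL, c("h", "rho", "log_pi",
                                            "n_included", "pve", "sigma2")))
  incl_counts <- numeric(p)

  env <- bslmm_env(d, Xt, yt, vbar, kbar, p, m, max_included, calibration)

  with_seed(seed, {
    h <- 0.5; rho <- 0.5; logpi <- log(1 / p)  # start at the sparse corner
    env_set_hypers(env, h, rho, logpi)
    cur_ml <- env_logml(env)
    log_prior_gam <- function(k, lp) k * lp + (p - k) * log1p(-exp(lp))
    acc_g <- 0L; tot_g <- 0L; acc_h <- 0L; tot_h <- 0L
    kept <- 0L
    logpi_lo <- log(1 / p)
    in_gam <- logical(p)
    w_gam <- 0  # sum of rank weights of included SNPs

    draw_add <- function() {
      # sample an excluded SNP from the mixture proposal
      repeat {
        j <- if (stats::runif(1) < 0.5) {
          rank_order[findInterval(stats::runif(1, 0, Zw), cum_w) + 1L]
        } else {
          sample.int(p, 1L)
        }
        if (!in_gam[j]) return(j)
      }
    }
    q_add <- function(j, k_excl, w_excl) {
      0.5 * w_of[j] / w_excl + 0.5 / k_excl
    }

    for (it in seq_len(iterations)) {
      for (g_it in seq_len(gamma_moves)) {
        tot_g <- tot_g + 1L
        k <- length(env$gam)
        move <- if (k == 0L) "add" else {
          c("add", "remove", "swap")[sample.int(3L, 1L,
                                                prob = c(0.4, 0.4, 0.2))]
        }
        if (move == "add" && k >= min(max_included, p - 1L)) next
        k_excl <- p - k
        w_excl <- Zw - w_gam
        if (move == "add") {
          j <- draw_add()
          p_fwd <- if (k == 0L) 1 else 0.4
          q_fwd <- log(p_fwd * q_add(j, k_excl, w_excl))
          q_rev <- log(0.4 / (k + 1))
          dlp <- logpi - log1p(-exp(logpi))  # binomial prior ratio for k+1 vs k
          env_add(env, j)
          new_ml <- env_logml(env)
          log_a <- (new_ml - cur_ml) + dlp + (q_rev - q_fwd)
          if (is.finite(log_a) && log(stats::runif(1)) < log_a) {
            cur_ml <- new_ml; acc_g <- acc_g + 1L
            in_gam[j] <- TRUE; w_gam <- w_gam + w_of[j]
          } else {
            env_remove(env, j)
          }
        } else if (move == "remove") {
          j <- env$gam[sample.int(k, 1L)]
          p_rev <- if (k == 1L) 1 else 0.4
          w_excl2 <- w_excl + w_of[j]
          q_fwd <- log(0.4 / k)
          q_rev <- log(p_rev * q_add(j, k_excl + 1L, w_excl2))
          dlp <- log1p(-exp(logpi)) - logpi
          env_remove(env, j)
          new_ml <- env_logml(env)
          log_a <- (new_ml - cur_ml) + dlp + (q_rev - q_fwd)
          if (is.finite(log_a) && log(stats::runif(1)) < log_a) {
            cur_ml <- new_ml; acc_g <- acc_g + 1L
            in_gam[j] <- FALSE; w_gam <- w_gam - w_of[j]
          } else {
            env_add(env, j)
          }
        } else {
          i_out <- env$gam[sample.int(k, 1L)]
          j_in <- draw_add()
          # forward: remove i_out (1/k), add j_in from current excluded set
          q_fwd <- log(q_add(j_in, k_excl, w_excl))
          # reverse: remove j_in (1/k), add i_out from the post-move excluded
          w_excl2 <- w_excl + w_of[i_out] - w_of[j_in]
          q_rev <- log(q_add(i_out, k_excl, w_excl2))
          env_remove(env, i_out); env_add(env, j_in)
          new_ml <- env_logml(env)
          log_a <- (new_ml - cur_ml) + (q_rev - q_fwd)
          if (is.finite(log_a) && log(stats::runif(1)) < log_a) {
            cur_ml <- new_ml; acc_g <- acc_g + 1L
            in_gam[i_out] <- FALSE; in_gam[j_in] <- TRUE
            w_gam <- w_gam - w_of[i_out] + w_of[j_in]
          } else {
            env_remove(env, j_in); env_add(env, i_out)
          }
        }
      }

      # hyperparameter update: random walk on (logit h, logit rho, log pi),
      # mixed with an independence proposal on (h, rho) so the chain can jump
      # between the small-effect and large-effect regimes
      tot_h <- tot_h + 1L
      indep <- stats::runif(1) < 0.25
      if (indep) {
        h2 <- stats::runif(1); r2 <- stats::runif(1)
        lp2 <- logpi
        jac <- 0  # uniform independence proposal on uniform priors
      } else {
        h2 <- stats::plogis(stats::qlogis(h) + stats::rnorm(1, 0, 0.5))
        r2 <- stats::plogis(stats::qlogis(rho) + stats::rnorm(1, 0, 0.5))
        lp2 <- logpi + stats::rnorm(1, 0, 0.4)
        jac <- log(h2 * (1 - h2)) + log(r2 * (1 - r2)) -
          log(h * (1 - h)) - log(rho * (1 - rho))
      }
      if (lp2 >= logpi_lo && lp2 <= 0) {
        old <- list(h = env$h, rho = env$rho, logpi = env$logpi)
        env_set_hypers(env, h2, r2, lp2)
        new_ml <- env_logml(env)
        k <- length(env$gam)
        dlp <- log_prior_gam(k, lp2) - log_prior_gam(k, logpi)
        log_a <- (new_ml - cur_ml) + dlp + jac
        if (is.finite(log_a) && log(stats::runif(1)) < log_a) {
          h <- h2; rho <- r2; logpi <- lp2
          cur_ml <- new_ml; acc_h <- acc_h + 1L
        } else {
          env_set_hypers(env, old$h, old$rho, old$logpi)
        }
      }

      if (it < burnin && it %% max(250L, burnin %/% 4L) == 0L) {
        # refresh proposal ranks from the residual associations
        k <- length(env$gam)
        resid_t <- env$yt
        if (k > 0L) {
          ix <- seq_len(k)
          lam_beta <- env$hr_s / (env$eff_k(k) * env$vbar)
          P <- env$XtLX[ix, ix, drop = FALSE] + diag(1 / lam_beta, k)
          bhat <- tryCatch(solve(P, env$XtLy[ix]), error = function(e) NULL)
          if (!is.null(bhat)) {
            resid_t <- env$yt - drop(env$Xg[, ix, drop = FALSE] %*% bhat)
          }
        }
        xy <- abs(drop(crossprod(Xt, resid_t * env$inv_lam)))
        rank_order <- order(-xy)
        rank_of[rank_order] <- seq_len(p)
        w_of <- wts[rank_of]
        w_gam <- sum(w_of[env$gam])
      }

      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        dr <- env_draw(env)
        samples[kept, ] <- c(h, rho, logpi, length(env$gam), dr$pve, dr$sigma2)
        if (length(env$gam)) {
          incl_counts[env$gam] <- incl_counts[env$gam] + 1
        }
      }
    }

    diagnostics <- list(
      rhat_pve = split_rhat(samples[, "pve"]),
      rhat_h = split_rhat(samples[, "h"]),
      accept_gamma = acc_g / max(tot_g, 1),
      accept_hyper = acc_h / max(tot_h, 1)
    )
    if (is.finite(diagnostics$rhat_pve) && diagnostics$rhat_pve > 1.2) {
      warning("BSLMM chain may not have converged: split R-hat for PVE = ",
              round(diagnostics$rhat_pve, 3), call. = FALSE)
    }
    out <- list(samples = as.data.frame(samples),
                pip = incl_counts / n_keep,
                inclusion_counts = incl_counts,
                n_retained = n_keep,
                diagnostics = diagnostics,
                variant_ids = colnames(G) %||% as.character(seq_len(p)))
    class(out) <- "bslmm_posterior"
    out
  })
}

split_rhat <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) return(NA_real_)
  half <- n %/% 2
  a <- x[seq_len(half)]; b <- x[(n - half + 1):n]
  W <- (stats::var(a) + stats::var(b)) / 2
  mu <- c(mean(a), mean(b))
  B <- half * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Summarize the PVE posterior
#'
#' @param post a `bslmm_posterior`.
#' @param level credible level for the equal-tailed interval (default 0.89:
#'   the 5.5% and 94.5% quantiles).
#' @return A list: `median`, `eti` (length-2 vector), `level`.
#' @export
summarize_pve <- function(post, level = 0.89) {
  stopifnot(inherits(post, "bslmm_posterior"))
  pve <- post$samples$pve
  if (!length(pve)) stop_bad_arg("empty posterior")
  a <- (1 - level) / 2
  list(median = stats::median(pve),
       eti = unname(stats::quantile(pve, c(a, 1 - a))),
       level = level)
}

#' SNPs with high posterior inclusion probability
#'
#' @param post a `bslmm_posterior`.
#' @param threshold PIP must be strictly above this (default 0.1).
#' @return data.frame (variant, pip) sorted by decreasing PIP; possibly empty.
#' @export
pip_candidates <- function(post, threshold = 0.1) {
  stopifnot(inherits(post, "bslmm_posterior"))
  sel <- which(post$pip > threshold)
  out <- data.frame(variant = post$variant_ids[sel], pip = post$pip[sel],
                    stringsAsFactors = FALSE)
  out[order(-out$pip), , drop = FALSE]
}

#' @export
print.bslmm_posterior <- function(x, ...) {
  s <- summarize_pve(x)
  cat("BSLMM posterior:", x$n_retained, "retained samples\n")
  cat(sprintf("  PVE median %.3f, 89%% ETI [%.3f, %.3f]\n",
              s$median, s$eti[1], s$eti[2]))
  cat(sprintf("  split R-hat (PVE) %.3f; %d SNPs with PIP > 0.1\n",
              x$diagnostics$rhat_pve, sum(x$pip > 0.1)))
  invisible(x)
}
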