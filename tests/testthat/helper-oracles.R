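# Independent brute-force oracles used to validate the package estimators.
# These are deliberately naive (loops, full enumeration) and share no code
# with the implementations they check.

# Exact HWE p-value by direct enumeration: for every possible heterozygote
# count with the observed allele totals, compute the conditional probability
# from log-factorials and sum those no more probable than the observed.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  })
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Weir-Cockerham (1984) two-group variance components, scalar textbook form,
# one site at a time.
oracle_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(c(a = NA, b = NA, c = NA))
  r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_fst_window <- function(G, rows1, rows2) {
  comps <- sapply(seq_len(ncol(G)), function(j) {
    oracle_wc_site(G[rows1, j], G[rows2, j])
  })
  num <- sum(comps["a", ], na.rm = TRUE)
  den <- sum(colSums(comps), na.rm = TRUE)
  num / den
}

# Nucleotide diversity as literal mean pairwise difference over haplotypes:
# expand each site's allele counts into haplotype alleles and loop over all
# haplotype pairs.
oracle_pi_pairs <- function(G, rows) {
  Gg <- G[rows, , drop = FALSE]
  total <- 0
  for (j in seq_len(ncol(Gg))) {
    g <- Gg[!is.na(Gg[, j]), j]
    m <- length(g)
    if (m < 2) next
    hap <- c(rep(1, sum(g)), rep(0, 2 * m - sum(g)))
    nh <- length(hap)
    diffs <- 0; pairs <- 0
    for (i in 1:(nh - 1)) for (l in (i + 1):nh) {
      diffs <- diffs + (hap[i] != hap[l]); pairs <- pairs + 1
    }
    total <- total + diffs / pairs
  }
  total
}

# Tajima's D computed directly from a complete haplotype expansion with the
# 1989 constants written out longhand.
oracle_tajimas_d <- function(G, rows) {
  Gg <- G[rows, , drop = FALSE]
  if (anyNA(Gg)) stop("oracle expects complete data")
  m <- length(rows)
  nh <- 2 * m
  ac <- colSums(Gg)
  seg <- ac > 0 & ac < 2 * m
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_hat <- 0
  for (j in which(seg)) {
    c_j <- ac[j]
    pi_hat <- pi_hat + c_j * (nh - c_j) / choose(nh, 2)
  }
  a1 <- sum(1 / (1:(nh - 1)))
  a2 <- sum(1 / (1:(nh - 1))^2)
  b1 <- (nh + 1) / (3 * (nh - 1))
  b2 <- 2 * (nh^2 + nh + 3) / (9 * nh * (nh - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nh + 2) / (a1 * nh) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# O(p^2) reference clumping: for each variant in ascending p-value order,
# compare against every already-chosen index.
oracle_clump <- function(pvals, G, scaffold, pos, r2_cutoff, window_kb) {
  ord <- order(pvals, pos, seq_along(pvals))
  ord <- ord[!is.na(pvals[ord])]
  idx <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (i in idx) {
      if (scaffold[i] == scaffold[j] &&
          abs(pos[i] - pos[j]) <= window_kb * 1000) {
        r <- suppressWarnings(stats::cor(G[, i], G[, j]))
        if (!is.na(r) && r^2 > r2_cutoff) { ok <- FALSE; break }
      }
    }
    if (ok) idx <- c(idx, j)
  }
  sort(idx)
}
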