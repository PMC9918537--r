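# Windowed differentiation and diversity scans: Weir-Cockerham FST between
# phenotype-extreme groups, net differentiation (delta-FST) after subtracting
# a population contrast, nucleotide diversity and Tajima's D, robust-Z
# outlier-region detection, and gene overlap. Window coordinates are 0-based
# half-open; VCF positions are 1-based.

#' Tile scaffolds into non-overlapping windows
#'
#' Windows start at coordinate 0 of each scaffold; the terminal window may be
#' shorter and is retained.
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths (bp).
#' @param size window size in bp (default 5000).
#' @return data.frame: scaffold, start, end (0-based half-open).
#' @export
make_windows <- function(scaffold_lengths, size = 5000) {
  stopifnot(size > 0, !is.null(names(scaffold_lengths)))
  do.call(rbind, lapply(names(scaffold_lengths), function(s) {
    len <- scaffold_lengths[[s]]
    starts <- seq(0, len - 1e-9, by = size)
    data.frame(scaffold = s, start = starts,
               end = pmin(starts + size, len), stringsAsFactors = FALSE)
  }))
}

#' Select phenotype-extreme groups
#'
#' The k earliest and k latest arrival dates; ties at the group boundary are
#' broken by the lexicographically smaller sample id (stable rule).
#'
#' @param phenotypes data.frame with `sample_id` and `arrival_date_ordinal`.
#' @param k group size (default 10).
#' @return A list of class `group_assignment`: `early`, `late` (sample ids).
#' @export
select_extremes <- function(phenotypes, k = 10L) {
  n <- nrow(phenotypes)
  if (n < 2 * k) stop_bad_arg("need at least 2k phenotyped individuals")
  if (k < 2) stop_bad_arg("k must be >= 2")
  ord_early <- order(phenotypes$arrival_date_ordinal, phenotypes$sample_id)
  ord_late <- order(-phenotypes$arrival_date_ordinal, phenotypes$sample_id)
  early <- phenotypes$sample_id[ord_early[seq_len(k)]]
  late <- phenotypes$sample_id[ord_late[seq_len(k)]]
  if (length(intersect(early, late))) {
    stop_bad_arg("early and late groups overlap; reduce k")
  }
  structure(list(early = early, late = late), class = "group_assignment")
}

#' Per-site Weir-Cockerham variance components for two groups
#'
#' Computes the among-group (a), among-individual-within-group (b) and
#' within-individual (c) components per site from genotype counts, excluding
#' missing genotypes site-wise. Sites where either group has fewer than two
#' genotyped individuals are flagged unusable.
#'
#' @param G samples x variants dosage matrix (`NA` missing).
#' @param rows1,rows2 row indices (or names) of the two groups.
#' @return data.frame: a, b, c, usable (one row per variant).
#' @export
wc_fst_sites <- function(G, rows1, rows2) {
  G1 <- G[rows1, , drop = FALSE]
  G2 <- G[rows2, , drop = FALSE]
  grp_stats <- function(Gi) {
    m <- colSums(!is.na(Gi))
    ac <- colSums(Gi, na.rm = TRUE)
    het <- colSums(Gi == 1, na.rm = TRUE)
    list(n = m, p = ifelse(m > 0, ac / (2 * m), NA_real_),
         h = ifelse(m > 0, het / m, NA_real_))
  }
  s1 <- grp_stats(G1); s2 <- grp_stats(G2)
  usable <- s1$n >= 2 & s2$n >= 2
  r <- 2
  nbar <- (s1$n + s2$n) / r
  sum_n <- s1$n + s2$n
  nc <- (sum_n - (s1$n^2 + s2$n^2) / sum_n) / (r - 1)
  pbar <- (s1$n * s1$p + s2$n * s2$p) / sum_n
  s2v <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (s1$n * s1$h + s2$n * s2$h) / sum_n
  inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2v
  a <- (nbar / nc) * (s2v - (inner - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (inner - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!usable] <- NA; b[!usable] <- NA; cc[!usable] <- NA
  data.frame(a = a, b = b, c = cc, usable = usable)
}

assign_windows <- function(variants, windows) {
  # returns, per variant, the row of `windows` containing it (NA if none);
  # VCF positions are 1-based, windows 0-based half-open
  widx <- rep(NA_integer_, nrow(variants))
  for (s in unique(windows$scaffold)) {
    wr <- which(windows$scaffold == s)
    vr <- which(variants$scaffold == s)
    if (!length(vr)) next
    pos0 <- variants$pos[vr] - 1
    j <- findInterval(pos0, windows$start[wr])
    ok <- j >= 1 & pos0 < windows$end[wr][pmax(j, 1)]
    widx[vr[ok]] <- wr[j[ok]]
  }
  widx
}

sum_by_window <- function(x, widx, n_windows) {
  out <- numeric(n_windows)
  ok <- !is.na(widx) & !is.na(x)
  if (any(ok)) {
    t <- tapply(x[ok], widx[ok], sum)
    out[as.integer(names(t))] <- t
  }
  out
}

#' Windowed Weir-Cockerham FST between two groups
#'
#' Ratio-of-sums ("weighted") window estimate: `sum(a) / sum(a + b + c)` over
#' usable sites in each window. Windows with no usable site, or an all-
#' monomorphic zero denominator, are flagged invalid. Negative window values
#' are retained (the estimator is unbiased around zero under panmixia).
#'
#' @param G samples x variants dosage matrix.
#' @param variants data.frame with `scaffold`, `pos` aligned to `G` columns.
#' @param rows1,rows2 row indices/names of the two groups.
#' @param windows from [make_windows()].
#' @return data.frame: scaffold, start, end, n_sites, stat = "fst", value,
#'   valid.
#' @export
wc_fst_window <- function(G, variants, rows1, rows2, windows) {
  if (length(rows1) < 2 || length(rows2) < 2) {
    stop_bad_arg("each group needs >= 2 individuals")
  }
  comp <- wc_fst_sites(G, rows1, rows2)
  widx <- assign_windows(variants, windows)
  nw <- nrow(windows)
  num <- sum_by_window(ifelse(comp$usable, comp$a, NA), widx, nw)
  den <- sum_by_window(ifelse(comp$usable, comp$a + comp$b + comp$c, NA),
                       widx, nw)
  n_sites <- sum_by_window(as.numeric(comp$usable), widx, nw)
  valid <- n_sites >= 1 & den != 0
  data.frame(scaffold = windows$scaffold, start = windows$start,
             end = windows$end, n_sites = as.integer(n_sites),
             stat = "fst", value = ifelse(valid, num / den, NA_real_),
             valid = valid, stringsAsFactors = FALSE)
}

#' Net differentiation (delta-FST) between two window scans
#'
#' Per window, the phenotype-contrast FST minus the population-contrast FST,
#' removing differentiation driven by population structure and shared
#' background processes. Windows must tile identically; a window is valid
#' only where both inputs are valid. Negative values are retained.
#'
#' @param scan_pheno,scan_pop window scans from [wc_fst_window()].
#' @return data.frame like the inputs with stat = "delta_fst".
#' @export
net_fst <- function(scan_pheno, scan_pop) {
  same <- identical(scan_pheno$scaffold, scan_pop$scaffold) &&
    identical(scan_pheno$start, scan_pop$start) &&
    identical(scan_pheno$end, scan_pop$end)
  if (!same) stop_bad_arg("scans are not tiled on identical windows")
  valid <- scan_pheno$valid & scan_pop$valid
  data.frame(scaffold = scan_pheno$scaffold, start = scan_pheno$start,
             end = scan_pheno$end,
             n_sites = pmin(scan_pheno$n_sites, scan_pop$n_sites),
             stat = "delta_fst",
             value = ifelse(valid, scan_pheno$value - scan_pop$value, NA_real_),
             valid = valid, stringsAsFactors = FALSE)
}

#' Windowed nucleotide diversity
#'
#' Per-site unbiased heterozygosity `2p(1-p) * 2m/(2m-1)` over the group's m
#' genotyped diploids, summed across variant sites and divided by the window
#' span in bp (non-variant positions contribute zero to the numerator and
#' full length to the denominator).
#'
#' @param G dosage matrix; @param variants aligned variant table.
#' @param rows group row indices/names (>= 2 individuals).
#' @param windows from [make_windows()].
#' @return data.frame: scaffold, start, end, n_sites, stat = "pi", value,
#'   valid.
#' @export
pi_window <- function(G, variants, rows, windows) {
  if (length(rows) < 2) stop_bad_arg("group needs >= 2 individuals")
  Gg <- G[rows, , drop = FALSE]
  m <- colSums(!is.na(Gg))
  ac <- colSums(Gg, na.rm = TRUE)
  p <- ifelse(m > 0, ac / (2 * m), NA_real_)
  het <- ifelse(m >= 2, 2 * p * (1 - p) * (2 * m) / (2 * m - 1), NA_real_)
  widx <- assign_windows(variants, windows)
  nw <- nrow(windows)
  num <- sum_by_window(het, widx, nw)
  n_sites <- sum_by_window(as.numeric(!is.na(het) & het > 0), widx, nw)
  data.frame(scaffold = windows$scaffold, start = windows$start,
             end = windows$end, n_sites = as.integer(n_sites),
             stat = "pi", value = num / (windows$end - windows$start),
             valid = TRUE, stringsAsFactors = FALSE)
}

tajima_constants <- function(nh) {
  i <- seq_len(nh - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (nh + 1) / (3 * (nh - 1))
  b2 <- 2 * (nh^2 + nh + 3) / (9 * nh * (nh - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nh + 2) / (a1 * nh) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' `D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S-1))` with the 1989 constants
#' computed at the haplotype sample size. Haplotypes are derived from diploid
#' genotypes (2m per site, no phasing, Hardy-Weinberg within group assumed);
#' with missing data the constants use the rounded mean number of genotyped
#' haplotypes over the window's segregating sites. Windows with no
#' segregating site are flagged invalid.
#'
#' @inheritParams pi_window
#' @return data.frame: scaffold, start, end, n_sites (segregating sites),
#'   stat = "tajimas_d", value, valid.
#' @export
tajimas_d_window <- function(G, variants, rows, windows) {
  if (2 * length(rows) < 4) stop_bad_arg("need >= 4 haplotypes (2 diploids)")
  Gg <- G[rows, , drop = FALSE]
  m <- colSums(!is.na(Gg))
  ac <- colSums(Gg, na.rm = TRUE)
  seg <- m >= 2 & ac > 0 & ac < 2 * m
  # mean pairwise differences per site: c(2m - c) / C(2m, 2)
  pw <- ifelse(seg, ac * (2 * m - ac) / (m * (2 * m - 1)), NA_real_)
  widx <- assign_windows(variants, windows)
  nw <- nrow(windows)
  S <- sum_by_window(as.numeric(seg), widx, nw)
  pi_hat <- sum_by_window(pw, widx, nw)
  nh_sum <- sum_by_window(ifelse(seg, 2 * m, NA_real_), widx, nw)
  value <- rep(NA_real_, nw)
  valid <- S >= 1
  for (w in which(valid)) {
    nh <- max(4L, as.integer(round(nh_sum[w] / S[w])))
    k <- tajima_constants(nh)
    vr <- k$e1 * S[w] + k$e2 * S[w] * (S[w] - 1)
    if (vr <= 0) { valid[w] <- FALSE; next }
    value[w] <- (pi_hat[w] - S[w] / k$a1) / sqrt(vr)
  }
  data.frame(scaffold = windows$scaffold, start = windows$start,
             end = windows$end, n_sites = as.integer(S),
             stat = "tajimas_d", value = value, valid = valid,
             stringsAsFactors = FALSE)
}

#' Detect elevated regions in a window scan
#'
#' Windows whose robust Z-score `(value - median) / (1.4826 * MAD)` exceeds
#' `z_cutoff` are outliers; runs of outliers separated by at most
#' `merge_gap_windows` non-outlier windows (same scaffold) are merged, and a
#' merged run must contain at least `min_windows` outlier windows to be
#' reported -- a region is a sustained elevation, not a single-window spike.
#' A zero MAD (e.g. a flat scan) yields no outliers by definition.
#'
#' @param scan a window scan data.frame (needs value, valid).
#' @param z_cutoff robust Z threshold (default 4).
#' @param merge_gap_windows maximum gap, in windows, bridged when merging
#'   (default 2).
#' @param min_windows minimum number of outlier windows per region
#'   (default 3).
#' @return data.frame of regions: scaffold, start, end, n_windows,
#'   peak_start, peak_value, mean_value.
#' @export
detect_region <- function(scan, z_cutoff = 4, merge_gap_windows = 2L,
                          min_windows = 3L) {
  v <- scan$value[scan$valid]
  if (!length(v)) stop_bad_arg("scan has no valid windows")
  med <- stats::median(v)
  mad <- stats::mad(v)
  empty <- data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      peak_start = numeric(0), peak_value = numeric(0),
                      mean_value = numeric(0), stringsAsFactors = FALSE)
  if (mad == 0) return(empty)
  z <- (scan$value - med) / mad
  out_rows <- which(scan$valid & z > z_cutoff)
  if (!length(out_rows)) return(empty)
  regions <- list()
  for (s in unique(scan$scaffold[out_rows])) {
    srows <- which(scan$scaffold == s)
    srows <- srows[order(scan$start[srows])]
    flag <- srows %in% out_rows
    pos <- which(flag)
    grp <- cumsum(c(1, diff(pos) > merge_gap_windows + 1))
    for (g in unique(grp)) {
      wr <- srows[pos[grp == g]]
      if (length(wr) < min_windows) next
      pk <- wr[which.max(scan$value[wr])]
      regions[[length(regions) + 1L]] <- data.frame(
        scaffold = s, start = min(scan$start[wr]), end = max(scan$end[wr]),
        n_windows = length(wr), peak_start = scan$start[pk],
        peak_value = scan$value[pk],
        mean_value = mean(scan$value[wr], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) return(empty)
  do.call(rbind, regions)
}

#' Genes overlapping detected regions
#'
#' Half-open interval intersection: a gene overlaps a region when it shares
#' at least 1 bp (a gene ending exactly at the region start does not).
#'
#' @param regions data.frame from [detect_region()].
#' @param annotation data.frame with gene_id, scaffold, start, end (0-based
#'   half-open).
#' @return A list, one element per region: character vector of gene ids; the
#'   counts are attached as a `counts` attribute.
#' @export
genes_in_region <- function(regions, annotation) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- annotation$scaffold == r$scaffold &
      annotation$start < r$end & annotation$end > r$start
    annotation$gene_id[hit]
  })
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}

#' Read a BED3+name gene annotation
#'
#' @param path BED file (tab-separated, no header): chrom, start, end, name;
#'   extra columns are ignored.
#' @return data.frame: gene_id, scaffold, start, end.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such BED: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    return(data.frame(gene_id = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0)))
  }
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  data.frame(gene_id = if (ncol(b) >= 4) b[[4]] else paste0("feat", seq_len(nrow(b))),
             scaffold = b[[1]], start = as.numeric(b[[2]]),
             end = as.numeric(b[[3]]), stringsAsFactors = FALSE)
}
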