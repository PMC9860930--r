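# Sliding-window selective-sweep scan: per-site Weir-Cockerham (1984) Fst
# variance components, window-weighted Fst (ratio of sums), per-population
# nucleotide diversity, the pi-ratio contrast, top-quantile window calls
# and the two-method overlap with gene annotation.

#' Site filters for the sweep scan
#'
#' Keeps biallelic sites whose overall minor-allele frequency (over the
#' union of both populations) is at least `maf_min` and whose genotype
#' call rate is at least `max_missing` (so a `max_missing` of 0.9 means at
#' most 10% missing genotypes).
#'
#' @param panel A `variant_panel`.
#' @param maf_min Minimum overall minor-allele frequency (default 0.05).
#' @param max_missing Minimum call-rate, VCFtools-style (default 0.9).
#' @return Filtered [site_counts()] tibble.
#' @export
filter_sites <- function(panel, maf_min = 0.05, max_missing = 0.9) {
  sc <- site_counts(panel)
  pops <- unique(panel$pops$population)
  n_cols <- paste0("n_", pops); alt_cols <- paste0("alt_", pops)
  n_tot <- rowSums(as.matrix(sc[n_cols]))
  alt_tot <- rowSums(as.matrix(sc[alt_cols]))
  n_samples <- ncol(panel$geno)
  call_rate <- (n_tot / 2) / n_samples
  af <- ifelse(n_tot > 0, alt_tot / n_tot, 0)
  maf <- pmin(af, 1 - af)
  sc[sc$biallelic & maf >= maf_min & call_rate >= max_missing, ]
}

#' Weir-Cockerham variance components for one biallelic site
#'
#' Computes the among-population (a), among-individual (b) and
#' within-individual (c) components of the Weir-Cockerham (1984) diploid
#' estimator from per-population called-allele counts, alt counts and
#' heterozygote counts.
#'
#' @param n Called allele counts per population (length 2, in alleles).
#' @param alt Alt allele counts per population.
#' @param het Observed heterozygote counts per population.
#' @return Named numeric vector `c(a =, b =, c =)`, or `NA`s when a
#'   population has no called diploids.
#' @export
wc_fst_components <- function(n, alt, het) {
  r <- 2
  nd <- n / 2                     # diploid counts
  if (any(nd < 1)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  p <- alt / n
  h <- het / nd
  nbar <- mean(nd)
  nc <- (r * nbar - sum(nd^2) / (r * nbar)) / (r - 1)
  pbar <- sum(nd * p) / (r * nbar)
  s2 <- sum(nd * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(nd * h) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# vectorized WC components over a site_counts tibble (two populations)
wc_components_table <- function(sc, pops) {
  n1 <- sc[[paste0("n_", pops[1])]]; n2 <- sc[[paste0("n_", pops[2])]]
  a1 <- sc[[paste0("alt_", pops[1])]]; a2 <- sc[[paste0("alt_", pops[2])]]
  h1 <- sc[[paste0("het_", pops[1])]]; h2 <- sc[[paste0("het_", pops[2])]]
  r <- 2
  nd1 <- n1 / 2; nd2 <- n2 / 2
  ok <- nd1 >= 1 & nd2 >= 1
  p1 <- ifelse(n1 > 0, a1 / n1, 0); p2 <- ifelse(n2 > 0, a2 / n2, 0)
  hh1 <- ifelse(nd1 > 0, h1 / nd1, 0); hh2 <- ifelse(nd2 > 0, h2 / nd2, 0)
  nbar <- (nd1 + nd2) / 2
  nc <- (r * nbar - (nd1^2 + nd2^2) / (r * nbar)) / (r - 1)
  pbar <- (nd1 * p1 + nd2 * p2) / (r * nbar)
  s2 <- (nd1 * (p1 - pbar)^2 + nd2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nd1 * hh1 + nd2 * hh2) / (r * nbar)
  ok <- ok & nbar > 1 & nc > 0
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  sc$wc_a <- ifelse(ok, a, NA_real_)
  sc$wc_b <- ifelse(ok, b, NA_real_)
  sc$wc_c <- ifelse(ok, cc, NA_real_)
  sc
}

#' Sliding-window tiling of a chromosome
#'
#' @param chrom_length_bp Chromosome length.
#' @param window_size_bp Window size (default 50000).
#' @param window_step_bp Step (default 20000); must not exceed the size.
#' @param chrom Chromosome name.
#' @return Tibble of 0-based half-open windows.
#' @export
make_windows <- function(chrom_length_bp, window_size_bp = 50000,
                         window_step_bp = 20000, chrom = "chr1") {
  stopifnot(window_step_bp <= window_size_bp)
  starts <- seq(0, max(0, chrom_length_bp - 1), by = window_step_bp)
  starts <- starts[starts < chrom_length_bp]
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(pmin(starts + window_size_bp,
                                       chrom_length_bp)))
}

#' Window statistics: weighted Fst, per-population pi, pi-ratio
#'
#' Window Fst is the Weir-Cockerham ratio of sums `sum(a)/sum(a+b+c)`
#' (not a mean of per-site ratios). Per-site pi is
#' `2*c_ref*c_alt/(n*(n-1))` on called alleles; window pi is the per-site
#' sum divided by the window length in bp. The pi-ratio is
#' reference-population pi over selected-population pi, so sweeps in the
#' selected population appear in the upper tail.
#'
#' @param sc Filtered [site_counts()] (from [filter_sites()]).
#' @param windows Window tiling from [make_windows()].
#' @param ref_pop,sel_pop Population names (reference = non-cashmere).
#' @param ratio_cap Cap applied when only the denominator pi is zero.
#' @return `windows` with `n_sites`, `fst`, `fst_clamped`, `pi_<pops>`,
#'   `pi_ratio` columns (NA where undefined).
#' @export
window_stats <- function(sc, windows, ref_pop = "reference",
                         sel_pop = "cashmere", ratio_cap = 1000) {
  sc <- wc_components_table(sc, c(ref_pop, sel_pop))
  site_pi <- function(n, alt) ifelse(n > 1, 2 * alt * (n - alt) / (n * (n - 1)), 0)
  pi_ref_site <- site_pi(sc[[paste0("n_", ref_pop)]],
                         sc[[paste0("alt_", ref_pop)]])
  pi_sel_site <- site_pi(sc[[paste0("n_", sel_pop)]],
                         sc[[paste0("alt_", sel_pop)]])
  res <- windows
  n <- nrow(windows)
  n_sites <- integer(n); fst <- pi_r <- pi_s <- numeric(n)
  for (i in seq_len(n)) {
    inw <- which(sc$chrom == windows$chrom[i] &
                   sc$pos >= windows$start[i] & sc$pos < windows$end[i])
    n_sites[i] <- length(inw)
    if (length(inw) == 0) { fst[i] <- NA; pi_r[i] <- 0; pi_s[i] <- 0; next }
    a <- sum(sc$wc_a[inw], na.rm = TRUE)
    abc <- sum(sc$wc_a[inw] + sc$wc_b[inw] + sc$wc_c[inw], na.rm = TRUE)
    fst[i] <- if (abc > 0) a / abc else NA_real_
    len <- windows$end[i] - windows$start[i]
    pi_r[i] <- sum(pi_ref_site[inw]) / len
    pi_s[i] <- sum(pi_sel_site[inw]) / len
  }
  res$n_sites <- n_sites
  res$fst <- fst
  res$fst_clamped <- pmax(fst, 0)
  res[[paste0("pi_", ref_pop)]] <- pi_r
  res[[paste0("pi_", sel_pop)]] <- pi_s
  res$pi_ratio <- pi_ratio(pi_r, pi_s, ratio_cap)
  res$pi_ratio[res$n_sites == 0] <- NA_real_
  res
}

#' Pi-ratio of two window diversity values
#'
#' Reference-population pi over selected-population pi: sweeps in the
#' selected population give large ratios. Undefined (NA) when both are
#' zero; capped when only the denominator is zero.
#'
#' @param pi_ref Reference-population window pi (per bp).
#' @param pi_sel Selected-population window pi (per bp).
#' @param cap Value used when only `pi_sel` is zero (default 1000).
#' @return Numeric vector of ratios.
#' @export
pi_ratio <- function(pi_ref, pi_sel, cap = 1000) {
  dplyr::case_when(pi_ref == 0 & pi_sel == 0 ~ NA_real_,
                   pi_sel == 0 ~ cap,
                   TRUE ~ pi_ref / pi_sel)
}

#' Top-fraction window calling
#'
#' The threshold is the k-th largest order statistic with k = ceiling of
#' `top_fraction * n` over the non-missing values; windows at or above that
#' threshold are flagged (ties kept, so the flagged count can exceed
#' `ceiling(top_fraction * n)`).
#'
#' @param values Numeric vector of window statistics (NA allowed).
#' @param top_fraction Upper-tail fraction (default 0.01).
#' @return List with `threshold` and logical `flag` (NA values unflagged).
#' @export
top_windows <- function(values, top_fraction = 0.01) {
  ok <- !is.na(values)
  if (!any(ok)) return(list(threshold = NA_real_, flag = rep(FALSE, length(values))))
  # k-th largest order statistic with k = ceiling(top_fraction * n): flags
  # exactly k windows in the absence of ties, more when tied
  k <- max(1L, ceiling(top_fraction * sum(ok)))
  thr <- sort(values[ok], decreasing = TRUE)[k]
  if (all(values[ok] == values[ok][1]))
    warning("all window values equal; every window is tie-flagged")
  flag <- !is.na(values) & values >= thr
  list(threshold = thr, flag = flag)
}

# merge bookended/overlapping intervals (tibble chrom,start,end)
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$chrom, iv$start), ]
  out <- list()
  cur <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$chrom[i] == cur$chrom && iv$start[i] <= cur$end) {
      cur$end <- max(cur$end, iv$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- iv[i, ]
    }
  }
  out[[length(out) + 1]] <- cur
  dplyr::bind_rows(out)
}

# intersection of two merged interval sets
intersect_intervals <- function(x, y) {
  x <- merge_intervals(x); y <- merge_intervals(y)
  rows <- list()
  for (i in seq_len(nrow(x))) {
    yy <- y[y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i], ]
    if (nrow(yy) == 0) next
    for (j in seq_len(nrow(yy))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = x$chrom[i],
        start = max(x$start[i], yy$start[j]),
        end = min(x$end[i], yy$end[j]))
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0)))
  dplyr::bind_rows(rows)
}

# genes (tibble chrom,start,end,gene) overlapping >=1 bp with any interval
genes_overlapping <- function(genes, iv) {
  hits <- character(0)
  for (i in seq_len(nrow(iv))) {
    sel <- genes$chrom == iv$chrom[i] & genes$start < iv$end[i] &
      genes$end > iv$start[i]
    hits <- c(hits, genes$gene[sel])
  }
  sort(unique(hits))
}

#' Overlap the two methods' top windows and annotate genes
#'
#' Candidate regions are the interval intersection of the merged Fst-top
#' and pi-ratio-top window sets. Genes are assigned to each method by
#' >= 1 bp overlap with that method's flagged windows; the final
#' candidate list is the intersection of the two per-method gene lists.
#'
#' @param windows Output of [window_stats()] with logical columns
#'   `top_fst` and `top_pi_ratio`.
#' @param gene_intervals Tibble `chrom`, `start`, `end`, `gene` (0-based
#'   half-open).
#' @return List: `regions` (merged common intervals), `n_window_overlaps`
#'   (count before merging), `genes_fst`, `genes_pi_ratio`,
#'   `genes_overlap`.
#' @export
overlap_and_annotate <- function(windows, gene_intervals) {
  fw <- windows[windows$top_fst, c("chrom", "start", "end")]
  pw <- windows[windows$top_pi_ratio, c("chrom", "start", "end")]
  common <- intersect_intervals(fw, pw)
  regions <- merge_intervals(common)
  list(regions = regions,
       n_window_overlaps = nrow(common),
       genes_fst = genes_overlapping(gene_intervals, fw),
       genes_pi_ratio = genes_overlapping(gene_intervals, pw),
       genes_overlap = intersect(genes_overlapping(gene_intervals, fw),
                                 genes_overlapping(gene_intervals, pw)))
}

#' Full selective-sweep scan
#'
#' Filters sites, computes window statistics, flags the top fraction per
#' method and annotates candidate genes.
#'
#' @param panel A `variant_panel` with populations `reference` and
#'   `cashmere` (names configurable).
#' @param gene_intervals Gene interval tibble (may be NULL).
#' @param chrom_length_bp Chromosome length for the tiling.
#' @param window_size_bp,window_step_bp Window geometry (50 kb / 20 kb).
#' @param top_fraction Upper-tail fraction per method (0.01).
#' @param maf_min,max_missing Site filters.
#' @param ref_pop,sel_pop Population names.
#' @return List: `windows` tibble (stats + `top_fst`, `top_pi_ratio`,
#'   `top_both` flags), `thresholds`, and the [overlap_and_annotate()]
#'   fields when gene intervals are given.
#' @export
sweep_scan <- function(panel, gene_intervals = NULL,
                       chrom_length_bp = max(panel$sites$pos) + 1,
                       window_size_bp = 50000, window_step_bp = 20000,
                       top_fraction = 0.01, maf_min = 0.05,
                       max_missing = 0.9, ref_pop = "reference",
                       sel_pop = "cashmere") {
  sc <- filter_sites(panel, maf_min, max_missing)
  win <- make_windows(chrom_length_bp, window_size_bp, window_step_bp,
                      chrom = panel$sites$chrom[1])
  ws <- window_stats(sc, win, ref_pop, sel_pop)
  tf <- top_windows(ws$fst, top_fraction)
  tp <- top_windows(ws$pi_ratio, top_fraction)
  ws$top_fst <- tf$flag
  ws$top_pi_ratio <- tp$flag
  ws$top_both <- tf$flag & tp$flag
  out <- list(windows = ws,
              thresholds = c(fst = tf$threshold, pi_ratio = tp$threshold))
  if (!is.null(gene_intervals))
    out <- c(out, overlap_and_annotate(ws, gene_intervals))
  out
}
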