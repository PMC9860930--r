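# Site filters, Weir-Cockerham components, window statistics, top-window
# calling and the two-method overlap.

panel_from_geno <- function(geno1, geno2, pos = NULL) {
  # geno: sites x samples dosage matrices per population
  geno <- cbind(geno1, geno2)
  n1 <- ncol(geno1); n2 <- ncol(geno2)
  colnames(geno) <- c(sprintf("r%02d", seq_len(n1)),
                      sprintf("c%02d", seq_len(n2)))
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 10L
  sites <- tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                          ref = "A", alt = "G", biallelic = TRUE)
  cashmere:::new_variant_panel(
    sites, geno,
    tibble::tibble(sample = colnames(geno),
                   population = rep(c("reference", "cashmere"),
                                    c(n1, n2))))
}

test_that("site filters apply MAF, call-rate and biallelic rules", {
  # 10 + 10 diploids; site 1: MAF 0.04 (dropped); site 2: common
  g1 <- matrix(0L, 2, 10); g2 <- matrix(0L, 2, 10)
  g2[1, 1] <- 1L          # 1 alt of 40 alleles: MAF 0.025
  g1[2, 1:4] <- 1L; g2[2, 1:4] <- 1L
  p <- panel_from_geno(g1, g2)
  kept <- filter_sites(p, maf_min = 0.05, max_missing = 0.9)
  expect_equal(kept$pos, 20L)

  # 20 samples with 3 missing -> call rate 0.85 < 0.9 -> dropped
  g1b <- matrix(1L, 1, 10); g2b <- matrix(0L, 1, 10)
  g1b[1, 1:3] <- NA
  pb <- panel_from_geno(g1b, g2b)
  expect_equal(nrow(filter_sites(pb)), 0)

  # triallelic flag drops the site
  pc <- panel_from_geno(matrix(1L, 1, 10), matrix(0L, 1, 10))
  pc$sites$biallelic <- FALSE
  expect_equal(nrow(filter_sites(pc)), 0)
})

test_that("WC components reach the fixed-difference limit", {
  n <- c(200, 200); alt <- c(0, 200); het <- c(0, 0)
  comp <- wc_fst_components(n, alt, het)
  fst <- comp["a"] / sum(comp)
  expect_gt(fst, 0.99)
  # identical monomorphic populations contribute nothing
  comp0 <- wc_fst_components(c(20, 20), c(0, 0), c(0, 0))
  expect_equal(unname(comp0), c(0, 0, 0))
})

test_that("WC components match an independent transcription", {
  # n1=n2=4 diploids, p1=0.5 (4 hets), p2=0.25 (2 hets)
  comp <- wc_fst_components(n = c(8, 8), alt = c(4, 2), het = c(4, 2))
  # independent direct transcription of the 1984 definitions
  r <- 2; n_i <- c(4, 4); p_i <- c(0.5, 0.25); h_i <- c(1, 0.5)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a_o <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b_o <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
  c_o <- hbar / 2
  expect_equal(unname(comp), c(a_o, b_o, c_o), tolerance = 1e-12)
  # vectorized path agrees with the scalar path
  sc <- tibble::tibble(chrom = "chr1", pos = 0L, biallelic = TRUE,
                       n_reference = 8, alt_reference = 4, het_reference = 4,
                       n_cashmere = 8, alt_cashmere = 2, het_cashmere = 2)
  v <- cashmere:::wc_components_table(sc, c("reference", "cashmere"))
  expect_equal(c(v$wc_a, v$wc_b, v$wc_c), c(a_o, b_o, c_o),
               tolerance = 1e-12)
})

test_that("window Fst is a ratio of sums, not a mean of ratios", {
  # two sites with very different information content
  g1 <- rbind(c(rep(2L, 10)), c(rep(0L, 9), 1L))
  g2 <- rbind(c(rep(0L, 10)), c(rep(0L, 9), 1L))
  p <- panel_from_geno(g1, g2, pos = c(10L, 20L))
  sc <- site_counts(p)
  win <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  ws <- window_stats(sc, win)
  scc <- cashmere:::wc_components_table(sc, c("reference", "cashmere"))
  ratio_of_sums <- sum(scc$wc_a) / sum(scc$wc_a + scc$wc_b + scc$wc_c)
  mean_of_ratios <- mean(scc$wc_a / (scc$wc_a + scc$wc_b + scc$wc_c))
  expect_equal(ws$fst, ratio_of_sums, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ratio_of_sums, mean_of_ratios)))
})

test_that("window pi matches the hand computation and scales with size", {
  # 100 bp window, n=8 alleles, alt counts 4 and 2:
  # pi = (2*4*4/56 + 2*2*6/56)/100 = 0.01 per bp
  g1 <- rbind(c(2L, 2L, 0L, 0L), c(1L, 1L, 0L, 0L))
  g2 <- matrix(0L, 2, 4)
  p <- panel_from_geno(g1, g2, pos = c(10L, 50L))
  sc <- site_counts(p)
  win <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  ws <- window_stats(sc, win)
  expect_equal(ws$pi_reference, 0.01, tolerance = 1e-12)
  win2 <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L)
  ws2 <- window_stats(sc, win2)
  expect_equal(ws2$pi_reference, 0.005, tolerance = 1e-12)
  # monomorphic population: pi = 0
  expect_equal(ws$pi_cashmere, 0)
})

test_that("pi-ratio orientation flags sweeps in the selected population", {
  expect_equal(
    window_stats(site_counts(panel_from_geno(matrix(1L, 1, 8),
                                             matrix(1L, 1, 8))),
                 tibble::tibble(chrom = "chr1", start = 0L, end = 20L)
    )$pi_ratio, 1, tolerance = 1e-12)
})

test_that("top-window calling uses the order-statistic quantile with ties", {
  vals <- c(1:99, 100)
  tw <- top_windows(vals, 0.01)
  expect_equal(sum(tw$flag), 1)
  expect_equal(which(tw$flag), 100)
  expect_warning(top_windows(rep(1, 50), 0.01), "tie")
})

test_that("permuted labels give near-zero mean window Fst", {
  vp <- sim_sweep()
  panel <- vp$panel
  set.seed(1)
  perm <- sample(panel$pops$population)
  panel$pops$population <- perm
  res <- sweep_scan(panel, chrom_length_bp = 5e6)
  expect_lt(abs(mean(res$windows$fst, na.rm = TRUE)), 0.01)
})

test_that("overlap handles disjoint and identical flag sets", {
  w <- tibble::tibble(chrom = "chr1",
                      start = c(0L, 100L, 200L, 300L),
                      end = c(100L, 200L, 300L, 400L))
  genes <- tibble::tibble(chrom = "chr1", start = c(10L, 210L),
                          end = c(20L, 220L), gene = c("g1", "g2"))
  w$top_fst <- c(TRUE, FALSE, FALSE, FALSE)
  w$top_pi_ratio <- c(FALSE, FALSE, TRUE, FALSE)
  ov <- overlap_and_annotate(w, genes)
  expect_equal(nrow(ov$regions), 0)
  expect_equal(ov$genes_overlap, character(0))

  w$top_pi_ratio <- w$top_fst
  ov2 <- overlap_and_annotate(w, genes)
  expect_equal(nrow(ov2$regions), 1)
  expect_equal(ov2$regions$start, 0L)
  expect_equal(ov2$genes_overlap, "g1")
})

test_that("planted sweeps are recovered by both methods exactly", {
  vp <- sim_sweep()
  ann <- simulate_annotation_and_pathways(5e6, 100, vp$truth, seed = 2)
  res <- sweep_scan(vp$panel, ann$gene_intervals, chrom_length_bp = 5e6)
  sw <- vp$truth$sweep_windows
  hit_both <- vapply(seq_len(nrow(sw)), function(i)
    any(res$windows$top_both & res$windows$start < sw$end[i] &
          res$windows$end > sw$start[i]), NA)
  expect_true(all(hit_both))
  expect_setequal(res$genes_overlap, ann$sweep_genes)
  expect_true(all(res$windows$fst <= 1 + 1e-9, na.rm = TRUE))
  expect_true(all(res$windows$fst >= -0.5, na.rm = TRUE))
})

test_that("null planting yields null double-top rates", {
  vp0 <- simulate_variant_panel(
    n_per_pop = 15, chrom_length_bp = 2e7, snp_density = 0.001,
    sweep_windows = tibble::tibble(start = 1e6L, end = 1050000L),
    reduction = 1, divergence = 0, missing_rate = 0, seed = 17)
  res <- sweep_scan(vp0$panel, chrom_length_bp = 2e7)
  n <- sum(!is.na(res$windows$fst))
  # expected double-top fraction is top_fraction^2 = 1e-4 under
  # independence; with ~1000 windows the count should be tiny
  expect_lte(sum(res$windows$top_both), 3)
})
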