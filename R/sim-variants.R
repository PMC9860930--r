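# Two-population genotype simulation with planted selective-sweep windows.
# Sites are simulated independently (Beta-distributed shared frequencies
# with per-population jitter), which keeps windows exchangeable and the
# planted pi/Fst contrasts analytic; linkage is not needed by any
# downstream window statistic.

#' Simulate a two-population variant panel with planted sweeps
#'
#' Background sites draw a shared allele frequency from a symmetric Beta
#' and jitter per-population frequencies around it (Balding-Nichols style,
#' background differentiation `fst_background`). Inside planted sweep
#' windows the second ("cashmere") population's heterozygosity is shrunk
#' by `reduction` (frequencies pushed toward the boundary away from the
#' reference population) and pushed further toward fixation by
#' `divergence`, so window pi drops and differentiation rises. Diploid
#' genotypes are binomial draws; missingness is applied uniformly.
#'
#' @param n_per_pop Diploid samples per population.
#' @param chrom_length_bp Chromosome length (bp).
#' @param snp_density Expected SNPs per bp (e.g. 0.005).
#' @param sweep_windows Tibble/data frame with `start`, `end` (0-based
#'   half-open) of planted sweeps; NULL or empty for none.
#' @param reduction Sweep heterozygosity reduction factor in (0, 1]; 1
#'   means no reduction (null planting).
#' @param divergence Extra push toward fixation in [0, 1); 0 disables.
#' @param missing_rate Per-genotype missing probability.
#' @param fst_background Background differentiation of the jitter.
#' @param chrom Chromosome name.
#' @param seed Integer RNG seed.
#' @return List with `panel` (a `variant_panel`) and `truth` (a
#'   `sweep_truth` list: sweep windows, factors, per-pop expected
#'   background pi per bp).
#' @export
simulate_variant_panel <- function(n_per_pop = 20, chrom_length_bp = 5e6,
                                   snp_density = 0.002,
                                   sweep_windows = NULL,
                                   reduction = 0.1, divergence = 0.6,
                                   missing_rate = 0.02,
                                   fst_background = 0.02,
                                   chrom = "chr1", seed = 1) {
  stopifnot(reduction > 0, reduction <= 1, divergence >= 0, divergence < 1,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  if (is.null(sweep_windows))
    sweep_windows <- tibble::tibble(start = integer(0), end = integer(0))
  sweep_windows <- tibble::as_tibble(sweep_windows)
  if (nrow(sweep_windows) > 0) {
    if (any(sweep_windows$start < 0 | sweep_windows$end > chrom_length_bp))
      stop("sweep window outside chromosome", call. = FALSE)
    ov <- order(sweep_windows$start)
    sw <- sweep_windows[ov, ]
    if (nrow(sw) > 1 && any(sw$start[-1] < sw$end[-nrow(sw)]))
      stop("sweep windows must be disjoint", call. = FALSE)
  }

  n_sites <- stats::rpois(1, chrom_length_bp * snp_density)
  pos <- sort(sample.int(chrom_length_bp, n_sites)) - 1L
  # shared ancestral frequency, folded to keep minor alleles common enough
  p_anc <- stats::rbeta(n_sites, 0.8, 0.8)
  p_anc <- pmin(pmax(p_anc, 0.01), 0.99)
  jitter <- function(p) {
    f <- fst_background
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  p1 <- jitter(p_anc)
  p2 <- jitter(p_anc)

  in_sweep <- rep(FALSE, n_sites)
  if (nrow(sweep_windows) > 0) {
    for (i in seq_len(nrow(sweep_windows))) {
      in_sweep <- in_sweep | (pos >= sweep_windows$start[i] &
                                pos < sweep_windows$end[i])
    }
  }
  if (any(in_sweep) && (reduction < 1 || divergence > 0)) {
    ps <- p2[in_sweep]
    h_target <- reduction * ps * (1 - ps)
    disc <- pmax(0.25 - h_target, 0)
    # push away from the reference population's frequency
    up <- ps >= p1[in_sweep]
    ps_new <- ifelse(up, 0.5 + sqrt(disc), 0.5 - sqrt(disc))
    boundary <- ifelse(up, 1, 0)
    ps_new <- ps_new + divergence * (boundary - ps_new)
    p2[in_sweep] <- pmin(pmax(ps_new, 0), 1)
  }

  draw <- function(p, n) {
    g <- matrix(stats::rbinom(length(p) * n, 2, rep(p, n)),
                nrow = length(p))
    if (missing_rate > 0)
      g[matrix(stats::runif(length(g)) < missing_rate, nrow = nrow(g))] <- NA
    g
  }
  g1 <- draw(p1, n_per_pop)
  g2 <- draw(p2, n_per_pop)
  geno <- cbind(g1, g2)
  samples <- c(sprintf("ref_%02d", seq_len(n_per_pop)),
               sprintf("cash_%02d", seq_len(n_per_pop)))
  colnames(geno) <- samples
  pops <- tibble::tibble(
    sample = samples,
    population = rep(c("reference", "cashmere"), each = n_per_pop))
  sites <- tibble::tibble(chrom = chrom, pos = pos,
                          ref = "A", alt = "G",
                          biallelic = TRUE)
  panel <- new_variant_panel(sites, geno, pops)
  truth <- structure(list(
    sweep_windows = sweep_windows |>
      dplyr::mutate(chrom = chrom, .before = 1),
    reduction = reduction,
    divergence = divergence,
    # E[2p(1-p)] per segregating site times density approximates pi/bp
    background_pi_bp = 2 * mean(p_anc * (1 - p_anc)) * snp_density,
    fst_background = fst_background,
    site_in_sweep = in_sweep
  ), class = "sweep_truth")
  list(panel = panel, truth = truth)
}
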