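# Synthetic skin-transcriptome data: a normalized matrix with planted
# stage-linked coexpression modules (for the network analysis) and a
# negative-binomial count matrix with planted fold-changes between two
# breeds (for differential expression).

STAGE_LEVELS <- c("anagen", "catagen", "telogen", "late_telogen")
STAGE_MONTHS <- list(anagen = 4:9, catagen = 10:12, telogen = 1:2,
                     late_telogen = 3)

#' Simulate expression data with planted modules and fold-changes
#'
#' The normalized matrix covers samples spread over the four hair-follicle
#' stages (anagen, catagen, telogen, late-telogen). Each planted module is
#' driven by a latent factor tied to one stage's indicator; module genes
#' are `sqrt(module_cor) * latent + sqrt(1-module_cor) * noise` scaled to
#' pass the standard-deviation filter, so the expected within-module
#' gene-gene correlation is `module_cor`. The count matrix covers two
#' breed groups with `n_de` genes carrying a planted log2 fold-change of
#' +/- `lfc` (half up, half down in the cashmere group) under a negative
#' binomial with gene-wise dispersion.
#'
#' @param n_genes Total genes.
#' @param samples_per_stage Samples in each of the four stages.
#' @param n_modules Planted modules.
#' @param module_size Genes per module.
#' @param module_cor Target within-module correlation, in (0,1).
#' @param n_de Number of DE genes in the count matrix.
#' @param lfc Planted |log2 fold-change|.
#' @param dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param samples_per_group Samples per breed group in the count matrix.
#' @param seed Integer RNG seed.
#' @return List: `normalized` (gene x sample matrix), `counts` (gene x
#'   sample integer matrix), `traits` (sample/month/stage tibble),
#'   `groups` (sample/group tibble for counts), `truth` (`expr_truth`).
#' @export
simulate_expression <- function(n_genes = 2000, samples_per_stage = 15,
                                n_modules = 4, module_size = 50,
                                module_cor = 0.8, n_de = 100, lfc = 2,
                                dispersion = 0.2, samples_per_group = 10,
                                seed = 1) {
  stopifnot(module_cor > 0, module_cor < 1, dispersion > 0)
  if (n_modules * module_size > n_genes)
    stop("module_size x n_modules exceeds n_genes", call. = FALSE)
  set.seed(seed)
  n_samples <- samples_per_stage * 4
  stage <- rep(STAGE_LEVELS, each = samples_per_stage)
  month <- vapply(stage, function(s) sample(STAGE_MONTHS[[s]], 1), 0)
  samples <- sprintf("S%03d", seq_len(n_samples))
  traits <- tibble::tibble(sample = samples, month = month, stage = stage)

  genes <- sprintf("G%04d", seq_len(n_genes))
  module_assignment <- stats::setNames(rep(0L, n_genes), genes)
  latent <- matrix(0, n_modules, n_samples,
                   dimnames = list(paste0("M", seq_len(n_modules)), samples))
  expr <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(genes, samples))
  for (m in seq_len(n_modules)) {
    st <- STAGE_LEVELS[(m - 1) %% 4 + 1]
    ind <- as.numeric(stage == st)
    lat <- scale(ind + stats::rnorm(n_samples, sd = 0.3))[, 1]
    latent[m, ] <- lat
    rows <- ((m - 1) * module_size + 1):(m * module_size)
    module_assignment[rows] <- m
    # per-gene loadings spread connectivity within the module, as in real
    # coexpression data; E[loading^2] = module_cor
    l <- sqrt(module_cor) * stats::runif(module_size, 0.85, 1.14)
    l <- pmin(l, 0.995)
    expr[rows, ] <- l * matrix(lat, module_size, n_samples, byrow = TRUE) +
      sqrt(1 - l^2) * matrix(stats::rnorm(module_size * n_samples),
                             module_size)
  }
  # weak shared sample factor over all genes (library/batch-like), giving
  # the low-correlation background real data shows
  shared <- stats::rnorm(n_samples)
  bg_load <- stats::runif(n_genes, 0, 0.3)
  expr <- expr * sqrt(1 - bg_load^2) + bg_load * matrix(shared, n_genes,
                                                        n_samples,
                                                        byrow = TRUE)
  # scale to clear the SD filter and give genes distinct baselines
  expr <- expr * 2 + stats::rnorm(n_genes, mean = 8, sd = 1)

  # count matrix: two breed groups
  grp_samples <- c(sprintf("black_%02d", seq_len(samples_per_group)),
                   sprintf("cash_%02d", seq_len(samples_per_group)))
  groups <- tibble::tibble(
    sample = grp_samples,
    group = rep(c("black", "cashmere"), each = samples_per_group))
  base_mu <- 2^stats::rnorm(n_genes, mean = 6, sd = 1.5)
  de_lfc <- stats::setNames(rep(0, n_genes), genes)
  if (n_de > 0) {
    de_idx <- sample.int(n_genes, n_de)
    de_lfc[de_idx] <- rep(c(lfc, -lfc), length.out = n_de)
  }
  mu1 <- matrix(base_mu, n_genes, samples_per_group)
  mu2 <- matrix(base_mu * 2^de_lfc, n_genes, samples_per_group)
  mu <- cbind(mu1, mu2)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / dispersion),
                   n_genes, dimnames = list(genes, grp_samples))

  truth <- structure(list(
    de_genes = de_lfc[de_lfc != 0],
    module_assignment = module_assignment,
    module_latent = latent,
    trait_table = traits,
    nb_dispersion = stats::setNames(rep(dispersion, n_genes), genes),
    module_cor = module_cor
  ), class = "expr_truth")
  list(normalized = expr, counts = counts, traits = traits,
       groups = groups, truth = truth)
}

#' Stage indicator matrix from a trait table
#'
#' Encodes the four hair-follicle stages as binary indicator columns for
#' module-trait correlation.
#'
#' @param traits Tibble with `sample` and `stage`.
#' @return Sample x stage 0/1 matrix.
#' @export
stage_indicators <- function(traits) {
  out <- vapply(STAGE_LEVELS, function(s) as.numeric(traits$stage == s),
                numeric(nrow(traits)))
  rownames(out) <- traits$sample
  out
}
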