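# Negative-binomial differential expression between two groups:
# median-of-ratios size factors, method-of-moments dispersion, per-gene NB
# GLM (log link, group indicator, size-factor offsets) with a Wald test
# and Benjamini-Hochberg FDR.

#' Median-of-ratios size factors
#'
#' `factor_j = median_g count_gj / geomean_g` over genes positive in all
#' samples. Falls back to total-count ratios (with a warning) when no
#' gene is positive everywhere.
#'
#' @param counts Nonnegative integer gene x sample matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene positive in all samples; using total-count ratios")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, stats::median)
}

#' Method-of-moments NB dispersion per gene
#'
#' On the size-factor-normalized scale:
#' `alpha = max((s^2 - mu) / mu^2, alpha_floor)` with no shrinkage.
#'
#' @param counts Count matrix.
#' @param sf Size factors from [size_factors()].
#' @param alpha_floor Lower bound (default 1e-8).
#' @return Numeric vector of dispersions named by gene.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                alpha_floor = 1e-8) {
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  s2 <- apply(norm, 1, stats::var)
  alpha <- (s2 - mu) / mu^2
  alpha[!is.finite(alpha)] <- alpha_floor
  stats::setNames(pmax(alpha, alpha_floor), rownames(counts))
}

# per-gene NB GLM with design (1, group) and log size-factor offsets;
# IRLS on two coefficients with closed-form 2x2 solves
nb_glm_gene <- function(y, g, log_sf, alpha, effect_cap = 10 * log(2),
                        max_iter = 50, tol = 1e-10) {
  # initialize from group means on the normalized scale
  ynorm <- y / exp(log_sf)
  m0 <- mean(ynorm[g == 0]); m1 <- mean(ynorm[g == 1])
  b0 <- log(max(m0, 0.1))
  b1 <- log(max(m1, 0.1)) - b0
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * g + log_sf
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (y - mu) / mu
    # normal equations for delta: (X'WX) d = X'W z_resid (score form)
    s0 <- sum(w * z); s1 <- sum(w * z * g)
    a11 <- sum(w); a12 <- sum(w * g); a22 <- sum(w * g)
    det <- a11 * a22 - a12^2
    if (!is.finite(det) || abs(det) < 1e-12) break
    d0 <- (a22 * s0 - a12 * s1) / det
    d1 <- (a11 * s1 - a12 * s0) / det
    b0 <- b0 + d0
    b1 <- min(max(b1 + d1, -effect_cap), effect_cap)
    if (max(abs(c(d0, d1))) < tol) { conv <- TRUE; break }
  }
  eta <- b0 + b1 * g + log_sf
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  a11 <- sum(w); a12 <- sum(w * g); a22 <- sum(w * g)
  det <- a11 * a22 - a12^2
  se <- if (det > 0) sqrt(a11 / det) else NA_real_
  capped <- abs(abs(b1) - effect_cap) < 1e-9
  c(b0 = b0, b1 = b1, se = se, converged = as.numeric(conv || capped),
    capped = as.numeric(capped), base_mean = mean(mu / exp(log_sf)))
}

#' NB Wald differential-expression test
#'
#' Per gene, maximizes the NB likelihood in (intercept, group effect) with
#' fixed dispersion and log size-factor offsets; reports the log2
#' fold-change (group2 vs group1), its SE from the observed Fisher
#' information, the Wald z and two-sided normal p, and BH q-values over
#' the tested genes. All-zero genes are excluded from testing and from
#' the BH denominator. One-group-all-zero genes (separation) have the
#' effect capped and are flagged.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Data frame `sample`, `group` (two levels; the second
#'   level in sort order is "group2") or a vector along columns.
#' @param sf Size factors (computed if missing).
#' @param dispersions Per-gene dispersions (computed if missing).
#' @return Tibble: gene, base_mean, log2fc, se_log2fc, wald_z, p_value,
#'   q_value, capped, direction.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL, dispersions = NULL) {
  if (is.data.frame(groups)) {
    grp <- groups$group[match(colnames(counts), groups$sample)]
  } else grp <- groups
  lev <- sort(unique(as.character(grp)))
  stopifnot(length(lev) == 2)
  g <- as.numeric(grp == lev[2])
  if (sum(g == 0) < 2 || sum(g == 1) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, sf)
  keep <- rowSums(counts) > 0
  res <- t(vapply(which(keep), function(i)
    nb_glm_gene(counts[i, ], g, log(sf), dispersions[i]),
    numeric(6)))
  log2fc <- res[, "b1"] / log(2)
  se2 <- res[, "se"] / log(2)
  z <- res[, "b1"] / res[, "se"]
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  conv <- res[, "converged"] == 1
  q <- rep(NA_real_, length(p))
  q[conv] <- stats::p.adjust(p[conv], method = "BH")
  tibble::tibble(
    gene = rownames(counts)[keep],
    base_mean = res[, "base_mean"],
    log2fc = log2fc,
    se_log2fc = se2,
    wald_z = z,
    p_value = p,
    q_value = q,
    converged = conv,
    capped = res[, "capped"] == 1,
    group2 = lev[2])
}

#' Call differentially expressed genes
#'
#' DEG iff `|log2FC| > lfc_threshold` and `q < fdr_threshold` (both
#' strict). Up/down direction is relative to group2.
#'
#' @param results Tibble from [nb_wald_test()].
#' @param lfc_threshold log2 fold-change threshold (default 1.0).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return `results` filtered to DEGs with a `direction` column;
#'   attributes `n_up` / `n_down` carry the counts.
#' @export
call_degs <- function(results, lfc_threshold = 1.0, fdr_threshold = 0.05) {
  deg <- results |>
    dplyr::filter(!is.na(.data$q_value),
                  abs(.data$log2fc) > lfc_threshold,
                  .data$q_value < fdr_threshold) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
  attr(deg, "n_up") <- sum(deg$direction == "up")
  attr(deg, "n_down") <- sum(deg$direction == "down")
  deg
}
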