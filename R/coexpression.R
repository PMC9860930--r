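# Weighted coexpression network core: variance filter, sample outlier
# screen, scale-free soft-threshold selection, topological overlap,
# static-height module cutting, eigengenes, module merging, module-trait
# correlation and GS/MM hub-gene screening.

#' Remove low-variance genes
#'
#' Keeps genes whose sample standard deviation is at least `sd_min`
#' (`>=` semantics; the boundary gene is kept).
#'
#' @param expr Gene x sample numeric matrix.
#' @param sd_min Minimum SD (default 0.5).
#' @return Row-subset of `expr`.
#' @export
filter_by_sd <- function(expr, sd_min = 0.5) {
  sds <- apply(expr, 1, stats::sd)
  expr[sds >= sd_min, , drop = FALSE]
}

#' Sample outlier screen by hierarchical clustering
#'
#' Average-linkage clustering on Euclidean distances between samples.
#' With a finite `cut_height`, clusters of size < 2 above the cut are
#' flagged as outliers and dropped; the default (`NULL`) is report-only
#' and never drops samples.
#'
#' @param expr Gene x sample matrix.
#' @param cut_height Dendrogram cut height, or `NULL` for report-only.
#' @return List: `retained` (sample names), `outliers`, `hclust`.
#' @export
detect_sample_outliers <- function(expr, cut_height = NULL) {
  stopifnot(ncol(expr) >= 3)
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  if (is.null(cut_height))
    return(list(retained = colnames(expr), outliers = character(0),
                hclust = hc))
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  out <- names(cl)[cl %in% as.integer(names(sizes)[sizes < 2])]
  list(retained = setdiff(colnames(expr), out), outliers = out, hclust = hc)
}

#' Soft-threshold power selection for a scale-free network
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed,
#' connectivities are binned (10 bins) and the scale-free fit index is the
#' R-squared of `log10(freq) ~ log10(mean k)` signed by the slope. The
#' chosen power is the smallest one reaching `target_r2`; if none does,
#' the argmax is returned with a warning.
#'
#' @param expr Gene x sample matrix (filtered).
#' @param powers Candidate integer powers.
#' @param target_r2 Scale-free fit target (default 0.85).
#' @param signed Use a signed network (`((1+cor)/2)^beta`)? Default
#'   unsigned.
#' @return List: `power`, `fit_table` (power, signed R2, slope, mean k).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.85,
                                signed = FALSE) {
  cm <- stats::cor(t(expr))
  sim <- if (signed) (1 + cm) / 2 else abs(cm)
  diag(sim) <- 0
  rows <- purrr::map(powers, function(b) {
    k <- rowSums(sim^b)
    brk <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- table(bin)
    keep <- freq > 0
    if (sum(keep) < 3)
      return(tibble::tibble(power = b, r2 = NA_real_, slope = NA_real_,
                            mean_k = mean(k)))
    mk <- tapply(k, bin, mean)[keep]
    lf <- log10(as.numeric(freq[keep]))
    lk <- log10(pmax(as.numeric(mk), .Machine$double.eps))
    fit <- stats::lm(lf ~ lk)
    # scale-free topology has a negative slope; the fit index is positive
    # exactly then (WGCNA convention)
    r2 <- -summary(fit)$r.squared * sign(stats::coef(fit)[2])
    tibble::tibble(power = b, r2 = unname(r2),
                   slope = unname(stats::coef(fit)[2]), mean_k = mean(k))
  })
  tab <- dplyr::bind_rows(rows)
  hit <- which(!is.na(tab$r2) & tab$r2 >= target_r2)
  if (length(hit) > 0) {
    power <- tab$power[hit[1]]
  } else {
    power <- tab$power[which.max(tab$r2)]
    warning("no power reaches target R2 ", target_r2,
            "; using argmax power ", power)
  }
  list(power = power, fit_table = tab)
}

#' Unsigned (or signed) adjacency matrix
#'
#' @param expr Gene x sample matrix.
#' @param power Soft-threshold power beta.
#' @param signed Signed network? Default unsigned `|cor|^beta`.
#' @return Gene x gene adjacency in `[0,1]` with unit diagonal.
#' @export
adjacency_matrix <- function(expr, power, signed = FALSE) {
  cm <- stats::cor(t(expr))
  a <- if (signed) ((1 + cm) / 2)^power else abs(cm)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i,j` and `k_i = sum_{j != i} a_ij`;
#' the diagonal is 1.
#'
#' @param adjacency Symmetric adjacency in `[0,1]`.
#' @return TOM matrix in `[0,1]`.
#' @export
tom_matrix <- function(adjacency) {
  a0 <- adjacency
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  tom
}

#' Module detection by static tree cut
#'
#' Average-linkage clustering of `dissTOM = 1 - TOM`, cut at a fixed
#' height (`cut_height_frac` of the maximum merge height); branches with
#' at least `min_module_size` genes become modules, everything else gets
#' label 0. Labels are ordered by decreasing module size.
#'
#' @param diss_tom Dissimilarity matrix `1 - TOM`.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height_frac Fraction of the max merge height for the cut.
#' @return Integer vector of module labels named by gene (0 = unassigned).
#' @export
cut_modules <- function(diss_tom, min_module_size = 30,
                        cut_height_frac = 0.99) {
  hc <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h <- cut_height_frac * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  sizes <- sort(table(cl), decreasing = TRUE)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(length(cl))
  for (i in seq_along(keep)) labels[cl == keep[i]] <- i
  names(labels) <- rownames(diss_tom)
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-gene z-scored submatrix across samples, sign-aligned so that its
#' correlation with the module's mean expression profile is non-negative,
#' and scaled to unit variance.
#'
#' @param expr Gene x sample matrix.
#' @param labels Module labels from [cut_modules()].
#' @return Module x sample matrix (rownames `ME1`, `ME2`, ...).
#' @export
module_eigengene <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  stopifnot(length(mods) >= 1)
  me <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  for (i in seq_along(mods)) {
    sub <- expr[labels == mods[i], , drop = FALSE]
    z <- t(scale(t(sub)))
    z[is.na(z)] <- 0                       # constant gene: no contribution
    if (nrow(z) < 2) {
      v <- z[1, ]
    } else {
      v <- svd(z, nu = 0, nv = 1)$v[, 1]
    }
    if (stats::sd(v) > 0) v <- as.numeric(scale(v))
    if (sum(v * colMeans(z)) < 0) v <- -v
    me[i, ] <- v
  }
  me
}

#' Merge similar modules by eigengene correlation
#'
#' Average-linkage clustering of `1 - cor(ME_i, ME_j)`; clusters below
#' `me_diss_threshold` are merged, eigengenes recomputed, and the step
#' iterated to a fixed point.
#'
#' @param expr Gene x sample matrix.
#' @param labels Module labels.
#' @param me_diss_threshold Dissimilarity threshold (default 0.25, i.e.
#'   modules over 75% similar are merged).
#' @return List: `labels` (relabeled by decreasing size), `eigengenes`.
#' @export
merge_modules <- function(expr, labels, me_diss_threshold = 0.25) {
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) <= 1) break
    me <- module_eigengene(expr, labels)
    diss <- 1 - stats::cor(t(me))
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    cl <- stats::cutree(hc, h = me_diss_threshold)
    if (length(unique(cl)) == length(mods)) break
    map <- stats::setNames(cl, mods)
    labels[labels > 0] <- map[as.character(labels[labels > 0])]
  }
  # relabel by decreasing size
  mods <- names(sort(table(labels[labels > 0]), decreasing = TRUE))
  relab <- integer(length(labels)); names(relab) <- names(labels)
  for (i in seq_along(mods)) relab[labels == as.integer(mods[i])] <- i
  list(labels = relab,
       eigengenes = if (any(relab > 0)) module_eigengene(expr, relab)
                    else NULL)
}

# correlation + two-sided p via t = r sqrt(n-2)/sqrt(1-r^2)
cor_with_p <- function(x, y) {
  r <- stats::cor(x, y)
  n <- nrow(as.matrix(x))
  tt <- r * sqrt(pmax(n - 2, 1)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

#' Module-trait correlation and hub-gene screening
#'
#' Pearson correlations (with t-distribution p-values) between module
#' eigengenes and trait indicator columns, gene significance
#' (GS = gene-trait correlation) and module membership (MM = gene-
#' eigengene correlation). Hub genes are genes of the key modules passing
#' `|GS| > gs_cut` and `|MM| > mm_cut` for the selected trait and their
#' own module's eigengene.
#'
#' @param expr Gene x sample matrix.
#' @param eigengenes Module x sample eigengene matrix.
#' @param labels Module labels.
#' @param traits Sample x trait numeric matrix (e.g.
#'   [stage_indicators()]), samples in `colnames(expr)` order.
#' @param trait Trait column for hub screening (default `"anagen"`).
#' @param key_modules Modules of interest (default: the module with the
#'   largest `|r|` against `trait`).
#' @param gs_cut,mm_cut Hub thresholds (defaults 0.2 and 0.8).
#' @return List: `module_trait` tibble (module, trait, r, p), `gs`, `mm`
#'   matrices, `hubs` tibble, `key_modules`.
#' @export
module_trait_and_hubs <- function(expr, eigengenes, labels, traits,
                                  trait = "anagen", key_modules = NULL,
                                  gs_cut = 0.2, mm_cut = 0.8) {
  stopifnot(all(colnames(expr) == rownames(traits)))
  zv <- apply(traits, 2, stats::sd) == 0
  if (any(zv)) warning("zero-variance trait column(s): ",
                       paste(colnames(traits)[zv], collapse = ","))
  mt <- cor_with_p(t(eigengenes), traits)
  module_trait <- tibble::as_tibble(as.table(mt$r), .name_repair = "minimal")
  names(module_trait) <- c("module", "trait", "r")
  module_trait$p <- as.vector(mt$p)
  gs <- cor_with_p(t(expr), traits)
  mm <- cor_with_p(t(expr), t(eigengenes))
  if (is.null(key_modules)) {
    sub <- module_trait[module_trait$trait == trait & !is.na(module_trait$r), ]
    key_modules <- sub$module[which.max(abs(sub$r))]
  }
  gene_me <- paste0("ME", labels)
  own_mm <- rep(NA_real_, length(labels))
  ok <- gene_me %in% colnames(mm$r)
  own_mm[ok] <- mm$r[cbind(which(ok), match(gene_me[ok], colnames(mm$r)))]
  gs_trait <- gs$r[, trait]
  hub_tbl <- tibble::tibble(
    gene = rownames(expr),
    module = gene_me,
    gs = gs_trait,
    mm = own_mm,
    hub = !is.na(own_mm) & gene_me %in% key_modules &
      abs(gs_trait) > gs_cut & abs(own_mm) > mm_cut)
  list(module_trait = module_trait, gs = gs$r, mm = mm$r,
       hubs = hub_tbl, key_modules = key_modules)
}

#' Full coexpression workflow
#'
#' SD filter, outlier screen (report-only by default), soft-threshold
#' pick, TOM, static-cut modules, eigengene merge, module-trait
#' correlation and hub screening.
#'
#' @param expr Normalized gene x sample matrix.
#' @param traits Trait table (`sample`, `stage`) or indicator matrix.
#' @param sd_min,min_module_size,me_diss_threshold,gs_cut,mm_cut,target_r2
#'   Thresholds (defaults 0.5, 30, 0.25, 0.2, 0.8, 0.85).
#' @param trait Trait for hub screening.
#' @param signed Signed network? Default unsigned.
#' @return List with all intermediate products: `power`, `labels`,
#'   `eigengenes`, `module_trait`, `hubs`, ...
#' @export
run_coexpression <- function(expr, traits, sd_min = 0.5,
                             min_module_size = 30,
                             me_diss_threshold = 0.25, gs_cut = 0.2,
                             mm_cut = 0.8, target_r2 = 0.85,
                             trait = "anagen", signed = FALSE) {
  if (is.data.frame(traits)) traits <- stage_indicators(traits)
  expr <- filter_by_sd(expr, sd_min)
  outl <- detect_sample_outliers(expr)
  st <- pick_soft_threshold(expr, target_r2 = target_r2, signed = signed)
  adj <- adjacency_matrix(expr, st$power, signed = signed)
  tom <- tom_matrix(adj)
  labels <- cut_modules(1 - tom, min_module_size)
  if (!any(labels > 0))
    return(list(power = st$power, fit_table = st$fit_table,
                labels = labels, eigengenes = NULL, module_trait = NULL,
                hubs = NULL, outliers = outl$outliers))
  merged <- merge_modules(expr, labels, me_diss_threshold)
  traits <- traits[colnames(expr), , drop = FALSE]
  mth <- module_trait_and_hubs(expr, merged$eigengenes, merged$labels,
                               traits, trait = trait, gs_cut = gs_cut,
                               mm_cut = mm_cut)
  c(list(power = st$power, fit_table = st$fit_table,
         labels = merged$labels, eigengenes = merged$eigengenes,
         outliers = outl$outliers, expr_filtered = expr), mth)
}
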