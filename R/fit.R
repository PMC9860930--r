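# Maximum-likelihood fitting of GY94 codon models and the two
# likelihood-ratio tests: branch model (rapidly evolving genes, REG) and
# branch-site model (positively selected genes, PSG).
#
# Branch lengths are taken from the input tree up to one free per-gene rate
# scalar; kappa, omega(s), site-class weights and that scalar are estimated
# by ML. Parameters live on unconstrained transformed scales inside the
# optimizer.

# mixture log-likelihood: classes = list of list(weight, omega_by_edge).
# `cache` (an environment) memoizes per-class site log-likelihood vectors
# across optimizer iterations; hits are exact (keyed on all parameters).
mixture_loglik <- function(ctx, kappa, rate_scale, classes, codon_freqs,
                           cache = NULL) {
  class_ll <- function(cl) {
    key <- if (!is.null(cache))
      paste(signif(c(kappa, rate_scale, cl$omega_by_edge), 14),
            collapse = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    plist <- edge_prob_matrices(ctx, kappa, cl$omega_by_edge, codon_freqs,
                                rate_scale)
    out <- site_loglik_pruning(ctx, plist, codon_freqs)
    if (!is.null(cache)) cache[[key]] <- out
    out
  }
  site_ll <- vapply(classes, class_ll, numeric(ctx$n_sites))
  if (!is.matrix(site_ll)) site_ll <- matrix(site_ll, nrow = ctx$n_sites)
  w <- vapply(classes, `[[`, 0, "weight")
  m <- apply(site_ll, 1, max)
  sum(ctx$pattern_weight * (m + log(colSums(w * t(exp(site_ll - m))))))
}

logistic <- function(x) 1 / (1 + exp(-x))

# model definitions: map transformed parameter vector -> (kappa, scale,
# classes); init vectors; parameter names
codon_model_def <- function(model, ctx, foreground_edges, fixed = list()) {
  n_edge <- nrow(ctx$edge)
  fg <- rep(FALSE, n_edge); fg[foreground_edges] <- TRUE
  one_class <- function(omega_by_edge) list(list(weight = 1,
                                                omega_by_edge = omega_by_edge))
  switch(model,
    one_ratio = list(
      npar = 3,
      init = function(kappa0, omega0) c(log(kappa0), log(omega0), 0),
      unpack = function(x) list(
        kappa = exp(x[1]), scale = exp(x[3]),
        classes = one_class(rep(exp(x[2]), n_edge)),
        omega = c(all = exp(x[2])))
    ),
    two_ratio = list(
      npar = 4,
      init = function(kappa0, omega0) c(log(kappa0), log(omega0),
                                        log(omega0), 0),
      unpack = function(x) list(
        kappa = exp(x[1]), scale = exp(x[4]),
        classes = one_class(ifelse(fg, exp(x[3]), exp(x[2]))),
        omega = c(background = exp(x[2]), foreground = exp(x[3])))
    ),
    free_ratio = list(
      npar = 2 + n_edge,
      init = function(kappa0, omega0) c(log(kappa0), 0,
                                        rep(log(omega0), n_edge)),
      unpack = function(x) list(
        kappa = exp(x[1]), scale = exp(x[2]),
        classes = one_class(exp(x[3:(2 + n_edge)])),
        omega = exp(x[3:(2 + n_edge)]))
    ),
    branch_site_null = {
      free_k <- is.null(fixed$kappa); free_s <- is.null(fixed$scale)
      list(
        npar = 2 + free_k + free_s,
        init = function(kappa0, omega0)
          c(if (free_k) log(kappa0), if (free_s) 0,
            stats::qlogis(min(omega0, 0.9)), 1),
        unpack = function(x) {
          i <- 0
          kappa <- if (free_k) exp(x[(i <- i + 1)]) else fixed$kappa
          scl <- if (free_s) exp(x[(i <- i + 1)]) else fixed$scale
          w0 <- logistic(x[(i <- i + 1)]); p0 <- logistic(x[(i <- i + 1)])
          list(kappa = kappa, scale = scl,
               classes = list(
                 list(weight = p0, omega_by_edge = rep(w0, n_edge)),
                 list(weight = 1 - p0, omega_by_edge = rep(1, n_edge))),
               omega = c(omega0 = w0, omega2 = 1, p0 = p0, p1 = 1 - p0,
                         p2 = 0))
        })
    },
    branch_site_alt = {
      free_k <- is.null(fixed$kappa); free_s <- is.null(fixed$scale)
      list(
        npar = 4 + free_k + free_s,
        init = function(kappa0, omega0)
          c(if (free_k) log(kappa0), if (free_s) 0,
            stats::qlogis(min(omega0, 0.9)), 1, -1, -6.9),
        unpack = function(x) {
          i <- 0
          kappa <- if (free_k) exp(x[(i <- i + 1)]) else fixed$kappa
          scl <- if (free_s) exp(x[(i <- i + 1)]) else fixed$scale
          w0 <- logistic(x[(i <- i + 1)])
          ew <- exp(c(x[i + 1], x[i + 2], 0))
          p <- ew / sum(ew)                     # (p0, p1, p2) softmax
          w2 <- 1 + 999 * logistic(x[i + 3])   # omega2 in [1, 1000)
          list(kappa = kappa, scale = scl,
               classes = list(
                 list(weight = p[1], omega_by_edge = rep(w0, n_edge)),
                 list(weight = p[2], omega_by_edge = rep(1, n_edge)),
                 list(weight = p[3],
                      omega_by_edge = ifelse(fg, w2, 1))),
               omega = c(omega0 = w0, omega2 = w2, p0 = p[1], p1 = p[2],
                         p2 = p[3]))
        })
    },
    stop("unknown model: ", model, call. = FALSE))
}

#' Fit a GY94 codon model by maximum likelihood
#'
#' Supported models: `one_ratio` (single dN/dS), `two_ratio` (separate
#' foreground dN/dS; the branch model), `free_ratio` (per-branch dN/dS),
#' `branch_site_null` / `branch_site_alt` (site-class mixtures where a
#' proportion of sites on the foreground branch evolves at omega2, fixed
#' to 1 under the null, free >= 1 under the alternative).
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths.
#' @param alignment Codon alignment.
#' @param model Model name (see Details).
#' @param foreground Branch spec (child-node label or leaf set) for models
#'   that need one.
#' @param codon_freqs Equilibrium codon frequencies; defaults to F1x4
#'   frequencies estimated from the alignment's observed nucleotides.
#' @param n_starts Number of optimizer starts (perturbed initial values).
#' @param tol Convergence tolerance on the log-likelihood.
#' @return A `codon_fit` object: list with `model`, `lnL`, `kappa`,
#'   `omega` (named estimates), `scale`, `convergence`, `n_sites`.
#' @export
fit_model <- function(tree, alignment, model = "one_ratio",
                      foreground = NULL, codon_freqs = NULL,
                      n_starts = if (grepl("branch_site", model)) 3 else 1,
                      tol = 1e-6, starts = NULL, fixed = list()) {
  codon_mat <- as_codon_matrix(alignment)
  if (is.null(codon_freqs)) codon_freqs <- observed_f1x4(codon_mat)
  ctx <- codon_pruning_context(tree, codon_indices(codon_mat))
  fg_edges <- integer(0)
  if (model %in% c("two_ratio", "branch_site_null", "branch_site_alt")) {
    if (is.null(foreground))
      stop("model '", model, "' requires a foreground branch", call. = FALSE)
    fg_edges <- resolve_branch(ctx$tree, foreground)
  }
  def <- codon_model_def(model, ctx, fg_edges, fixed)
  cache <- new.env(parent = emptyenv())
  negll <- function(x) {
    u <- def$unpack(x)
    ll <- tryCatch(mixture_loglik(ctx, u$kappa, u$scale, u$classes,
                                  codon_freqs, cache = cache),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  if (is.null(starts)) {
    starts <- list(def$init(2, 0.5))
    extra <- list(c(1, 0.1), c(4, 1.5))
    k <- 2
    while (length(starts) < n_starts && k - 1 <= length(extra)) {
      starts[[k]] <- def$init(extra[[k - 1]][1], extra[[k - 1]][2])
      k <- k + 1
    }
  }
  best <- NULL
  conv_ok <- FALSE
  for (st in starts) {
    opt <- stats::optim(st, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = tol / 10))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) conv_ok <- TRUE
  }
  u <- def$unpack(best$par)
  structure(list(model = model, lnL = -best$value, kappa = u$kappa,
                 omega = u$omega, scale = u$scale, par = best$par,
                 convergence = conv_ok && best$convergence == 0,
                 foreground = foreground, n_sites = ctx$n_real_sites,
                 n_dropped = ctx$n_dropped),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("<codon_fit %s: lnL %.3f, kappa %.3f, %d sites>\n",
              x$model, x$lnL, x$kappa, x$n_sites))
  print(round(x$omega, 4))
  invisible(x)
}

# F1x4 frequencies from observed nucleotide composition of the alignment
observed_f1x4 <- function(codon_mat) {
  valid <- codon_mat[codon_mat %in% codon_alphabet()]
  nts <- unlist(strsplit(valid, ""))
  tab <- table(factor(nts, levels = c("A", "C", "G", "T"))) + 1
  codon_freqs_f1x4(stats::setNames(as.numeric(tab) / sum(tab),
                                   names(tab)))
}

lrt_row <- function(gene, fit_null, fit_alt, extra = list()) {
  stat <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  tibble::tibble(
    gene = gene,
    lnL_null = fit_null$lnL, lnL_alt = fit_alt$lnL,
    statistic = stat, df = 1L, p_value = p,
    converged = fit_null$convergence && fit_alt$convergence,
    !!!extra
  )
}

#' Branch-model likelihood-ratio test (rapidly evolving genes)
#'
#' Compares the one-ratio model to the two-ratio model with a separate
#' foreground dN/dS. The candidate verdict requires `p < lrt_alpha` and an
#' *elevated* foreground estimate; a `direction` column records whether the
#' foreground estimate exceeds the background so the directionless rule
#' can be recovered.
#'
#' @inheritParams fit_model
#' @param gene Gene identifier carried into the result row.
#' @param lrt_alpha Significance level (default 0.05).
#' @return One-row tibble (an LRT result).
#' @export
branch_model_test <- function(tree, alignment, foreground, gene = "gene",
                              lrt_alpha = 0.05, ...) {
  f0 <- fit_model(tree, alignment, "one_ratio", ...)
  # warm-start the nested alternative from the one-ratio optimum
  w <- unname(f0$omega["all"])
  s1 <- c(log(f0$kappa), log(w), log(w), log(f0$scale))
  f1 <- fit_model(tree, alignment, "two_ratio", foreground = foreground,
                  starts = list(s1), ...)
  if (f1$lnL < f0$lnL - 1e-4) {
    f1b <- fit_model(tree, alignment, "two_ratio", foreground = foreground,
                     starts = list(s1 + c(0, 0, log(3), 0)), ...)
    if (f1b$lnL > f1$lnL) f1 <- f1b
  }
  row <- lrt_row(gene, f0, f1, list(
    omega_background = unname(f1$omega["background"]),
    omega_foreground = unname(f1$omega["foreground"])))
  row$direction <- ifelse(row$omega_foreground > row$omega_background,
                          "elevated", "reduced")
  row$candidate <- row$converged & row$p_value < lrt_alpha &
    row$direction == "elevated"
  row$test <- "branch"
  row
}

#' Branch-site likelihood-ratio test (positively selected genes)
#'
#' Compares the branch-site null (foreground site class at omega2 = 1) to
#' the alternative (omega2 >= 1 free). The p-value uses a plain
#' chi-square(1) reference; `boundary_mix = TRUE` switches to the 50:50
#' point-mass/chi-square boundary mixture.
#'
#' @inheritParams branch_model_test
#' @param boundary_mix Use the 50:50 boundary mixture null distribution?
#' @return One-row tibble.
#' @export
branch_site_test <- function(tree, alignment, foreground, gene = "gene",
                             lrt_alpha = 0.05, boundary_mix = FALSE, ...) {
  # kappa and the branch-length scale are profiled out at their one-ratio
  # estimates; the branch-site fits then optimize the site-class mixture
  fr <- fit_model(tree, alignment, "one_ratio", ...)
  fixed <- list(kappa = fr$kappa, scale = fr$scale)
  w0 <- stats::qlogis(min(max(unname(fr$omega["all"]), 0.01), 0.85))
  s0 <- c(w0, stats::qlogis(0.8))
  f0 <- fit_model(tree, alignment, "branch_site_null",
                  foreground = foreground, starts = list(s0),
                  fixed = fixed, ...)
  # alt starts branch out from the null optimum at several omega2 values
  pn <- f0$par
  p0 <- logistic(pn[2])
  base <- c(pn[1],
            log(max(p0 * 0.9, 1e-3) / 0.1),
            log(max((1 - p0) * 0.9, 1e-3) / 0.1),
            stats::qlogis(1 / 999))            # omega2 start ~2
  alt_starts <- list(base,
                     replace(base, 4, stats::qlogis(3 / 999)),   # ~4
                     replace(base, 4, -3))                       # ~47
  f1 <- fit_model(tree, alignment, "branch_site_alt",
                  foreground = foreground, starts = alt_starts,
                  fixed = fixed, ...)
  if (f1$lnL < f0$lnL) f1$lnL <- f0$lnL  # boundary: alt nests the null
  row <- lrt_row(gene, f0, f1, list(
    omega2 = unname(f1$omega["omega2"]),
    p2 = unname(f1$omega["p2"])))
  if (boundary_mix) row$p_value <- row$p_value / 2
  row$candidate <- row$converged & row$p_value < lrt_alpha
  row$test <- "branch_site"
  row
}

#' Run a selection test over a set of genes
#'
#' Applies [branch_model_test()] or [branch_site_test()] to every gene and
#' adds Benjamini-Hochberg adjusted q-values over the converged tests.
#'
#' @param tree Rooted tree.
#' @param alignments Named list of codon alignments.
#' @param foreground Foreground branch spec.
#' @param test `"branch"` (REG) or `"branch_site"` (PSG).
#' @param lrt_alpha Significance level for the candidate verdict.
#' @param ... Passed to the per-gene test.
#' @return Tibble with one row per gene, including `q_value`.
#' @export
run_selection_tests <- function(tree, alignments, foreground,
                                test = c("branch", "branch_site"),
                                lrt_alpha = 0.05, ...) {
  test <- match.arg(test)
  fun <- if (test == "branch") branch_model_test else branch_site_test
  res <- purrr::imap(alignments, function(aln, id)
    fun(tree, aln, foreground = foreground, gene = id,
        lrt_alpha = lrt_alpha, ...))
  res <- dplyr::bind_rows(res)
  res$q_value <- NA_real_
  res$q_value[res$converged] <- stats::p.adjust(res$p_value[res$converged],
                                                method = "BH")
  res
}
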