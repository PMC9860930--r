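# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a codon model fit
#'
#' @param x A `codon_fit` from [fit_model()].
#' @param ... Unused.
#' @return One row per estimated quantity: `term`, `estimate`.
#' @method tidy codon_fit
#' @export
tidy.codon_fit <- function(x, ...) {
  est <- c(kappa = x$kappa, scale = x$scale, x$omega)
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' @rdname tidy.codon_fit
#' @return For `glance`: one row with `model`, `lnL`, `n_sites`,
#'   `n_dropped`, `converged`.
#' @method glance codon_fit
#' @export
glance.codon_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lnL = x$lnL, n_sites = x$n_sites,
                 n_dropped = x$n_dropped, converged = x$convergence)
}

#' Tidy an expression-truth object
#'
#' @param x An `expr_truth` from [simulate_expression()].
#' @param ... Unused.
#' @return Tibble with one row per gene: module assignment and planted
#'   log2 fold-change.
#' @method tidy expr_truth
#' @export
tidy.expr_truth <- function(x, ...) {
  genes <- names(x$module_assignment)
  tibble::tibble(gene = genes,
                 module = unname(x$module_assignment),
                 log2fc = unname(ifelse(genes %in% names(x$de_genes),
                                        x$de_genes[genes], 0)))
}

#' Tidy a sweep-truth object
#'
#' @param x A `sweep_truth` from [simulate_variant_panel()].
#' @param ... Unused.
#' @return The planted sweep-window tibble with the reduction and
#'   divergence factors attached.
#' @method tidy sweep_truth
#' @export
tidy.sweep_truth <- function(x, ...) {
  out <- x$sweep_windows
  out$reduction <- x$reduction
  out$divergence <- x$divergence
  out
}
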