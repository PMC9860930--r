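# Gene-set bookkeeping across pipeline stages, hypergeometric pathway
# enrichment with BH correction, and the bipartite gene-pathway edge list.

#' Create a gene-set ledger
#'
#' A named collection of gene sets (PSGs, REGs, convergent genes, sweep
#' candidates, module genes, DEGs, ...) over one declared gene universe.
#'
#' @param universe Character vector of all gene identifiers.
#' @return A `gene_set_ledger`.
#' @export
gene_set_ledger <- function(universe) {
  structure(list(universe = unique(universe), sets = list(),
                 provenance = list()),
            class = "gene_set_ledger")
}

#' Add a named gene set to a ledger
#'
#' Genes outside the universe are dropped with a warning; sets are
#' deduplicated.
#'
#' @param ledger A `gene_set_ledger`.
#' @param name Set name.
#' @param genes Character vector.
#' @param stage Producing pipeline stage (provenance).
#' @return The updated ledger.
#' @export
add_gene_set <- function(ledger, name, genes, stage = NA_character_) {
  genes <- unique(genes)
  out <- setdiff(genes, ledger$universe)
  if (length(out) > 0) {
    warning(length(out), " genes of set '", name, "' outside the universe")
    genes <- intersect(genes, ledger$universe)
  }
  ledger$sets[[name]] <- genes
  ledger$provenance[[name]] <- stage
  ledger
}

#' @export
print.gene_set_ledger <- function(x, ...) {
  cat(sprintf("<gene_set_ledger: %d sets over %d genes>\n",
              length(x$sets), length(x$universe)))
  for (nm in names(x$sets))
    cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Intersect named sets with Venn-style pairwise counts
#'
#' @param ledger A `gene_set_ledger`.
#' @param ... Set names (character).
#' @return List: `intersection` (character vector), `sizes` (per-set),
#'   `pairwise` (tibble of all pairwise overlap counts).
#' @export
intersect_sets <- function(ledger, ...) {
  names_ <- c(...)
  unknown <- setdiff(names_, names(ledger$sets))
  if (length(unknown) > 0)
    stop("unknown set name(s): ", paste(unknown, collapse = ","),
         call. = FALSE)
  sets <- ledger$sets[names_]
  inter <- Reduce(intersect, sets)
  pairs <- if (length(names_) >= 2) utils::combn(names_, 2, simplify = FALSE)
           else list()
  pairwise <- purrr::map_dfr(pairs, function(p)
    tibble::tibble(set1 = p[1], set2 = p[2],
                   overlap = length(intersect(sets[[p[1]]], sets[[p[2]]]))))
  list(intersection = sort(inter),
       sizes = vapply(sets, length, 0L),
       pairwise = pairwise)
}

#' Hypergeometric pathway enrichment
#'
#' For each pathway with `K` genes in a universe of `N`, and a query set
#' of `m` genes overlapping it in `k`, the p-value is the upper tail
#' `P[X >= k]` of Hypergeometric(N, K, m). BH q-values are computed over
#' pathways; the significance flag uses raw `p < alpha`.
#'
#' @param set Character vector of query genes.
#' @param pathways Tibble `pathway`, `gene`.
#' @param universe Character vector of all genes.
#' @param alpha Raw-p significance level (default 0.05).
#' @return Tibble sorted by p: pathway, k, m, K, N, p_value, q_value,
#'   significant, genes (comma-separated overlap).
#' @export
hypergeom_enrich <- function(set, pathways, universe, alpha = 0.05) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  set <- intersect(unique(set), universe)
  m <- length(set)
  pathways <- pathways[pathways$gene %in% universe, ]
  rows <- pathways |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene),
      k = length(intersect(.data$gene, set)),
      genes = paste(sort(intersect(.data$gene, set)), collapse = ","),
      .groups = "drop")
  n_univ <- length(universe)
  rows$m <- m
  rows$N <- n_univ
  rows$p_value <- stats::phyper(rows$k - 1, rows$K, n_univ - rows$K, m,
                                lower.tail = FALSE)
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$p_value < alpha
  rows[order(rows$p_value),
       c("pathway", "k", "m", "K", "N", "p_value", "q_value",
         "significant", "genes")]
}

#' Bipartite gene-pathway edge list for significant pathways
#'
#' @param enrichment Tibble from [hypergeom_enrich()].
#' @return Tibble of edges `gene`, `pathway` (one per overlap member of
#'   each significant pathway), with a `nodes` attribute holding the node
#'   table (`node`, `type`).
#' @export
gene_pathway_network <- function(enrichment) {
  sig <- enrichment[enrichment$significant & enrichment$k > 0, ]
  edges <- if (nrow(sig) == 0) {
    tibble::tibble(gene = character(0), pathway = character(0))
  } else {
    sig |>
      dplyr::select("pathway", "genes") |>
      dplyr::mutate(gene = strsplit(.data$genes, ",")) |>
      tidyr::unnest("gene") |>
      dplyr::select("gene", "pathway")
  }
  attr(edges, "nodes") <- tibble::tibble(
    node = c(unique(edges$gene), unique(edges$pathway)),
    type = rep(c("gene", "pathway"),
               c(length(unique(edges$gene)),
                 length(unique(edges$pathway)))))
  edges
}
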