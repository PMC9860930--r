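# Synthetic gene annotation and pathway tables consistent with planted
# sweep signals: gene intervals tile the chromosome, designated genes sit
# inside sweep windows, and one pathway is enriched for a designated set.

#' Simulate gene intervals and pathway membership
#'
#' Genes tile the chromosome as disjoint intervals. For every planted
#' sweep window one gene is relocated to sit inside it (these are the
#' planted sweep genes). Pathways partition genes at random except one
#' designated pathway that is loaded with `enriched_pathway_genes`.
#'
#' @param chrom_length_bp Chromosome length.
#' @param n_genes Number of genes.
#' @param sweep_truth `sweep_truth` from [simulate_variant_panel()] (or
#'   NULL for no planted placement).
#' @param n_pathways Number of pathways.
#' @param enriched_pathway_genes Character vector of gene ids to
#'   concentrate in the first pathway (defaults to the planted sweep
#'   genes).
#' @param pathway_size Mean genes per pathway.
#' @param chrom Chromosome name.
#' @param seed Integer RNG seed.
#' @return List: `gene_intervals` tibble, `pathways` tibble,
#'   `sweep_genes` (ids placed in sweep windows), `enriched_pathway` id.
#' @export
simulate_annotation_and_pathways <- function(chrom_length_bp, n_genes,
                                             sweep_truth = NULL,
                                             n_pathways = 10,
                                             enriched_pathway_genes = NULL,
                                             pathway_size = 15,
                                             chrom = "chr1", seed = 1) {
  set.seed(seed)
  gene_len <- 2000L
  if (n_genes * gene_len * 2 > chrom_length_bp)
    stop("genes do not fit on the chromosome without overlap", call. = FALSE)
  slot <- floor(chrom_length_bp / n_genes)
  starts <- as.integer((seq_len(n_genes) - 1) * slot)
  genes <- tibble::tibble(chrom = chrom, start = starts,
                          end = starts + gene_len,
                          gene = sprintf("G%04d", seq_len(n_genes)))
  sweep_genes <- character(0)
  if (!is.null(sweep_truth) && nrow(sweep_truth$sweep_windows) > 0) {
    sw <- sweep_truth$sweep_windows
    for (i in seq_len(nrow(sw))) {
      mid <- as.integer((sw$start[i] + sw$end[i]) / 2)
      # relocate the gene whose slot covers the window center
      gi <- min(n_genes, mid %/% slot + 1)
      genes$start[gi] <- pmax(sw$start[i], mid - gene_len %/% 2)
      genes$end[gi] <- genes$start[gi] + gene_len
      sweep_genes <- c(sweep_genes, genes$gene[gi])
    }
    genes <- genes[order(genes$start), ]
  }
  if (is.null(enriched_pathway_genes)) enriched_pathway_genes <- sweep_genes
  pw_names <- sprintf("path%02d", seq_len(n_pathways))
  rows <- list()
  if (length(enriched_pathway_genes) > 0) {
    pad <- sample(setdiff(genes$gene, enriched_pathway_genes),
                  max(0, pathway_size - length(enriched_pathway_genes)))
    rows[[1]] <- tibble::tibble(pathway = pw_names[1],
                                gene = c(enriched_pathway_genes, pad))
  } else {
    rows[[1]] <- tibble::tibble(pathway = pw_names[1],
                                gene = sample(genes$gene, pathway_size))
  }
  for (k in seq_len(n_pathways)[-1]) {
    rows[[k]] <- tibble::tibble(
      pathway = pw_names[k],
      gene = sample(setdiff(genes$gene, enriched_pathway_genes),
                    min(pathway_size, n_genes - length(enriched_pathway_genes))))
  }
  list(gene_intervals = genes,
       pathways = dplyr::distinct(dplyr::bind_rows(rows)),
       sweep_genes = sort(unique(sweep_genes)),
       enriched_pathway = pw_names[1])
}
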