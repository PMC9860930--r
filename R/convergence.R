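# Convergent amino-acid substitution detection between two focal lineages,
# and the conservative-site (CCS) filter: the derived residue must appear
# only in the two convergent lineages while all other lineages share a
# single different residue.

#' Detect convergent substitutions between two focal branches
#'
#' A site is convergent when, on both focal branches, the child state
#' differs from the parent ("most recent common ancestor" side) state, and
#' the two derived (child) states are identical. All four reconstructed
#' states must reach `posterior_min`. Sites where the two parent states
#' are themselves identical are flagged `parallel` (they are reported, not
#' excluded).
#'
#' @param anc `ancestral_states` from [marginal_reconstruction()].
#' @param focal_pair Character vector of two branch child-node labels (or
#'   leaf-set specs resolvable by the tree).
#' @param posterior_min Posterior gate applied to the two parent and two
#'   derived states (default 0.8).
#' @param gene Gene id carried into the result.
#' @return Tibble: one row per convergent site with parent/derived states,
#'   the background residue set and a `parallel` flag.
#' @export
detect_convergent_substitutions <- function(anc, focal_pair,
                                            posterior_min = 0.8,
                                            gene = "gene") {
  tree <- anc$tree
  stopifnot(length(focal_pair) == 2)
  edges <- vapply(focal_pair, function(f) resolve_branch(tree, f), 0L)
  ch <- tree$edge[edges, 2]; pa <- tree$edge[edges, 1]
  if (ch[1] %in% path_to_root_nodes(tree, ch[2]) ||
      ch[2] %in% path_to_root_nodes(tree, ch[1]))
    stop("focal branches must not be ancestrally nested", call. = FALSE)
  ntip <- ape::Ntip(tree)
  focal_tips <- sort(unique(c(edge_descendant_tips(tree, edges[1]),
                              edge_descendant_tips(tree, edges[2]))))
  bg_tips <- setdiff(seq_len(ntip), focal_tips)

  n_sites <- ncol(anc$states)
  d1 <- anc$states[ch[1], ]; d2 <- anc$states[ch[2], ]
  p1 <- anc$states[pa[1], ]; p2 <- anc$states[pa[2], ]
  post_ok <- anc$posterior[ch[1], ] >= posterior_min &
    anc$posterior[ch[2], ] >= posterior_min &
    anc$posterior[pa[1], ] >= posterior_min &
    anc$posterior[pa[2], ] >= posterior_min
  hit <- which(d1 == d2 & d1 != p1 & d2 != p2 & post_ok)
  if (length(hit) == 0) {
    return(tibble::tibble(gene = character(0), site = integer(0),
                          derived = character(0), parent1 = character(0),
                          parent2 = character(0), background = character(0),
                          parallel = logical(0), min_posterior = numeric(0)))
  }
  bg_set <- vapply(hit, function(s) {
    res <- anc$states[bg_tips, s]
    res <- res[anc$posterior[bg_tips, s] == 1]   # valid observed leaves only
    paste(sort(unique(res)), collapse = ",")
  }, character(1))
  min_post <- pmin(anc$posterior[ch[1], hit], anc$posterior[ch[2], hit],
                   anc$posterior[pa[1], hit], anc$posterior[pa[2], hit])
  tibble::tibble(gene = gene, site = unname(hit),
                 derived = unname(d1[hit]),
                 parent1 = unname(p1[hit]), parent2 = unname(p2[hit]),
                 background = bg_set,
                 parallel = unname(p1[hit] == p2[hit]),
                 min_posterior = unname(min_post))
}

#' Conservative-site (CCS) filter
#'
#' Keeps convergent sites where (i) every valid non-focal leaf carries one
#' single residue, (ii) that residue differs from the focal derived
#' residue, and (iii) every leaf of both focal lineages carries the
#' derived residue.
#'
#' @param sites Output of [detect_convergent_substitutions()].
#' @param alignment The protein alignment.
#' @param tree The tree used for detection.
#' @param focal_pair The same focal branch pair.
#' @return `sites` with a logical `ccs_pass` column.
#' @export
ccs_filter <- function(sites, alignment, tree, focal_pair) {
  if (nrow(sites) == 0) {
    sites$ccs_pass <- logical(0)
    return(sites)
  }
  edges <- vapply(focal_pair, function(f) resolve_branch(tree, f), 0L)
  ntip <- ape::Ntip(tree)
  focal_tips <- sort(unique(c(edge_descendant_tips(tree, edges[1]),
                              edge_descendant_tips(tree, edges[2]))))
  bg_tips <- setdiff(seq_len(ntip), focal_tips)
  aa <- alignment$aa_matrix[tree$tip.label, , drop = FALSE]
  sites$ccs_pass <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites$site[i]; d <- sites$derived[i]
    bg <- aa[bg_tips, s]
    bg <- bg[bg %in% VALID_AA]
    if (length(bg) == 0) return(FALSE)
    if (length(unique(bg)) != 1) return(FALSE)   # background not conserved
    if (unique(bg) == d) return(FALSE)           # derived leaks to background
    all(aa[focal_tips, s] == d)                  # focal lineages fixed
  }, NA)
  sites
}

#' Gene-level convergence report
#'
#' Summarizes per-site evidence to the genes carrying at least one
#' CCS-passing convergent site, formatting each substitution like `K136R`
#' (parent residue, 1-based site, derived residue).
#'
#' @param site_table Row-bound site tables (with `ccs_pass`) across genes.
#' @return Tibble: `gene`, `n_sites`, `substitutions` (comma-separated).
#' @export
converge_report <- function(site_table) {
  if (nrow(site_table) == 0 || !any(site_table$ccs_pass)) {
    return(tibble::tibble(gene = character(0), n_sites = integer(0),
                          substitutions = character(0)))
  }
  site_table |>
    dplyr::filter(.data$ccs_pass) |>
    dplyr::mutate(label = paste0(
      ifelse(.data$parent1 == .data$parent2, .data$parent1,
             paste0(.data$parent1, "/", .data$parent2)),
      .data$site, .data$derived)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     substitutions = paste(.data$label, collapse = ","),
                     .groups = "drop")
}

#' Run the full convergence scan over a set of genes
#'
#' Applies the validity filter, marginal reconstruction, convergence
#' detection and the CCS filter to every protein alignment.
#'
#' @param tree Rooted tree.
#' @param alignments Named list of protein alignments (codon alignments
#'   are translated automatically).
#' @param focal_pair Two branch child-node labels.
#' @param posterior_min Posterior gate for reconstructed states.
#' @param min_valid Validity threshold for the gene filter.
#' @return List with `sites` (all convergent sites, `ccs_pass` flagged),
#'   `genes` (gene-level CCS report), `skipped` (genes failing validity).
#' @export
run_convergence_scan <- function(tree, alignments, focal_pair,
                                 posterior_min = 0.8, min_valid = 0.75) {
  skipped <- character(0)
  tabs <- list()
  for (id in names(alignments)) {
    aln <- alignments[[id]]
    if (aln$kind == "codon") aln <- translate_codon_alignment(aln)
    vf <- validity_filter(aln, min_valid)
    if (!vf$pass) { skipped <- c(skipped, id); next }
    anc <- marginal_reconstruction(tree, aln)
    st <- detect_convergent_substitutions(anc, focal_pair, posterior_min,
                                          gene = id)
    tabs[[id]] <- ccs_filter(st, aln, anc$tree, focal_pair)
  }
  sites <- dplyr::bind_rows(tabs)
  if (nrow(sites) == 0) {
    sites <- tibble::tibble(gene = character(0), site = integer(0),
                            derived = character(0), parent1 = character(0),
                            parent2 = character(0), background = character(0),
                            parallel = logical(0), min_posterior = numeric(0),
                            ccs_pass = logical(0))
  }
  list(sites = sites, genes = converge_report(sites), skipped = skipped)
}
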