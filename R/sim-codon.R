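# Synthetic codon alignments evolved on a fixed tree under GY94, with
# planted foreground omega shifts and (optionally) planted convergent
# amino-acid substitutions. The simulator uses the same rate-matrix code
# path as the estimator, so recovery tests are free of model mismatch.

#' Simulate codon alignments on a tree with planted omega shifts
#'
#' Evolves `n_genes` codon alignments root-to-tips under the GY94 process.
#' Root codons are drawn from the equilibrium frequencies; designated
#' foreground branches evolve at `foreground_omega` while all others use
#' `base_omega`. The full internal-node state history is recorded as
#' ground truth.
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths in expected
#'   substitutions per codon.
#' @param n_genes Number of genes to simulate.
#' @param n_codons Codon sites per gene.
#' @param kappa Transition/transversion ratio.
#' @param base_omega Background dN/dS.
#' @param foreground_branches Character vector of branch child-node labels
#'   evolving at `foreground_omega` (NULL for none).
#' @param foreground_omega dN/dS on the foreground branches.
#' @param codon_freqs Equilibrium codon frequencies.
#' @param seed Integer RNG seed.
#' @return A list with `alignments` (named list of codon
#'   `cashmere_alignment`s) and `truth` (a `phylo_truth` list: the tree,
#'   per-branch omega map, per-gene node-state matrices, and gene table).
#' @export
simulate_codon_data <- function(tree, n_genes, n_codons, kappa = 2,
                                base_omega = 0.2,
                                foreground_branches = NULL,
                                foreground_omega = base_omega,
                                codon_freqs = codon_freqs_f1x4(),
                                seed = 1) {
  stopifnot(base_omega > 0, foreground_omega > 0)
  set.seed(seed)
  tree <- validate_tree(tree)
  trp <- stats::reorder(tree, "postorder")
  br <- tree_branches(trp)
  if (!is.null(foreground_branches) &&
      !all(foreground_branches %in% br$child_label))
    stop("foreground branches not in tree: ",
         paste(setdiff(foreground_branches, br$child_label), collapse = ","),
         call. = FALSE)
  omega_by_edge <- rep(base_omega, nrow(br))
  omega_by_edge[br$child_label %in% foreground_branches] <- foreground_omega

  # transition matrices are parameter-only: build once, reuse per gene
  uo <- unique(omega_by_edge)
  edecs <- lapply(uo, function(w)
    gy94_eigen(gy94_rate_matrix(kappa, w, codon_freqs), codon_freqs))
  names(edecs) <- as.character(uo)
  plist <- lapply(seq_len(nrow(br)), function(e)
    gy94_prob(edecs[[as.character(omega_by_edge[e])]], br$length[e]))

  ntip <- ape::Ntip(trp)
  nnode <- ntip + trp$Nnode
  labs <- node_labels(trp)
  root <- trp$edge[nrow(trp$edge), 1]
  codons <- codon_alphabet()
  # preorder = reversed postorder edge list
  edge_order <- rev(seq_len(nrow(trp$edge)))

  alignments <- vector("list", n_genes)
  node_states <- vector("list", n_genes)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  for (g in seq_len(n_genes)) {
    states <- matrix(NA_integer_, nnode, n_codons)
    states[root, ] <- sample.int(61, n_codons, replace = TRUE,
                                 prob = codon_freqs)
    for (e in edge_order) {
      parent <- trp$edge[e, 1]; child <- trp$edge[e, 2]
      p <- plist[[e]]
      ps <- states[parent, ]
      cs <- integer(n_codons)
      for (s in unique(ps)) {
        sel <- which(ps == s)
        cs[sel] <- sample.int(61, length(sel), replace = TRUE, prob = p[s, ])
      }
      states[child, ] <- cs
    }
    rownames(states) <- labs
    node_states[[g]] <- states
    leaf_mat <- matrix(codons[states[seq_len(ntip), ]], nrow = ntip,
                       dimnames = list(labs[seq_len(ntip)], NULL))
    alignments[[g]] <- new_alignment("codon", leaf_mat)
  }
  names(alignments) <- gene_ids
  names(node_states) <- gene_ids

  truth <- list(
    tree = trp,
    branch_omega = stats::setNames(omega_by_edge, br$child_label),
    foreground_branches = foreground_branches,
    kappa = kappa,
    codon_freqs = codon_freqs,
    node_states = node_states,
    genes = tibble::tibble(
      gene = gene_ids,
      selected = rep(!is.null(foreground_branches) &&
                       foreground_omega != base_omega, n_genes)
    ),
    convergent_sites = tibble::tibble(
      gene = character(0), site = integer(0), derived = character(0),
      background = character(0), conservative = logical(0)
    )
  )
  class(truth) <- "phylo_truth"
  list(alignments = alignments, truth = truth)
}

#' Plant convergent amino-acid substitutions on two focal branches
#'
#' Overwrites selected alignment columns so that both focal branches carry
#' an identical derived residue that differs from each parent's state.
#' With `conservative = TRUE` every non-focal leaf is forced to a single
#' shared background residue (the conservative-site condition); otherwise
#' the simulated background variation is left untouched. Recorded
#' node-state truth is updated in step with the leaves.
#'
#' @param sim Output of [simulate_codon_data()].
#' @param focal_pair Character vector of two branch child-node labels.
#' @param n_sites Number of convergent sites to plant per designated gene.
#' @param genes Genes to plant in (default: first gene).
#' @param conservative Plant conservative (CCS-passing) sites?
#' @param seed Integer RNG seed.
#' @return `sim` with modified alignments and augmented truth.
#' @export
plant_convergent_sites <- function(sim, focal_pair, n_sites,
                                   genes = names(sim$alignments)[1],
                                   conservative = TRUE, seed = 1) {
  stopifnot(length(focal_pair) == 2, n_sites >= 0)
  set.seed(seed)
  if (n_sites == 0) return(sim)
  tree <- sim$truth$tree
  br <- tree_branches(tree)
  edges <- vapply(focal_pair, function(f) resolve_branch(tree, f), 0L)
  if (tree$edge[edges[1], 2] %in% path_to_root_nodes(tree, tree$edge[edges[2], 2]) ||
      tree$edge[edges[2], 2] %in% path_to_root_nodes(tree, tree$edge[edges[1], 2]))
    stop("focal branches must not be ancestrally nested", call. = FALSE)
  codons <- codon_alphabet()
  aa <- codon_amino_acids()
  ntip <- ape::Ntip(tree)
  # deterministic representative codon for each amino acid (highest freq)
  rep_codon <- vapply(unique(aa), function(a) {
    cand <- which(aa == a)
    cand[which.max(sim$truth$codon_freqs[cand])]
  }, 0L)

  focal_nodes <- lapply(edges, function(e) {
    tips <- edge_descendant_tips(tree, e)
    c(tree$edge[e, 2], setdiff(clade_nodes(tree, tree$edge[e, 2]), tree$edge[e, 2]))
  })
  focal_tips <- sort(unique(unlist(lapply(edges, function(e)
    edge_descendant_tips(tree, e)))))
  parents <- tree$edge[edges, 1]

  for (g in genes) {
    states <- sim$truth$node_states[[g]]
    mat <- sim$alignments[[g]]$codon_matrix
    n_codons <- ncol(mat)
    available <- sample(seq_len(n_codons))
    planted <- 0; k <- 0
    while (planted < n_sites && k < length(available)) {
      k <- k + 1
      site <- available[k]
      # skip sites already substituting on a focal branch (resample rule)
      sub_on_focal <- any(vapply(edges, function(e)
        aa[states[tree$edge[e, 1], site]] != aa[states[tree$edge[e, 2], site]],
        NA))
      if (isTRUE(sub_on_focal)) {
        message("site ", site, " in ", g,
                " already variable on a focal branch; resampled")
        next
      }
      if (conservative) {
        bg_aa <- sample(names(rep_codon), 1)
        derived_aa <- sample(setdiff(names(rep_codon), bg_aa), 1)
        states[, site] <- rep_codon[[bg_aa]]
      } else {
        parent_aas <- aa[states[parents, site]]
        choices <- setdiff(names(rep_codon), parent_aas)
        derived_aa <- sample(choices, 1)
        bg_aa <- NA_character_
      }
      for (fn in focal_nodes) states[fn, site] <- rep_codon[[derived_aa]]
      mat[, site] <- codons[states[seq_len(ntip), site]]
      sim$truth$convergent_sites <- dplyr::bind_rows(
        sim$truth$convergent_sites,
        tibble::tibble(gene = g, site = site, derived = derived_aa,
                       background = bg_aa, conservative = conservative))
      planted <- planted + 1
    }
    if (planted < n_sites)
      warning("only planted ", planted, " of ", n_sites, " sites in ", g)
    sim$truth$node_states[[g]] <- states
    sim$alignments[[g]] <- new_alignment("codon", mat)
  }
  sim$truth$focal_pair <- focal_pair
  sim
}

# all nodes (internal + tips) in the clade rooted at `node`
clade_nodes <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- node
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ntip])
  }
  unique(out)
}

# node numbers on the path from `node` to the root (exclusive of node)
path_to_root_nodes <- function(tree, node) {
  out <- integer(0)
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    node <- tree$edge[e, 1]
    out <- c(out, node)
  }
  out
}
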