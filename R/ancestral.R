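# Ancestral protein-state reconstruction: alignment validity gating, Fitch
# parsimony state sets, and marginal ML reconstruction under a Poisson-type
# amino-acid model with observed frequencies.

#' Alignment validity filter
#'
#' A gene passes when the fraction of alignment cells holding one of the
#' 20 canonical residues is at least `min_valid` (default 0.75, with `>=`
#' semantics). Per-column validity fractions are retained for site-level
#' gating.
#'
#' @param alignment Protein `cashmere_alignment`.
#' @param min_valid Minimum overall valid fraction.
#' @return List with `pass`, `validity` (overall fraction) and
#'   `column_validity` (per-site fractions).
#' @export
validity_filter <- function(alignment, min_valid = 0.75) {
  stopifnot(alignment$kind == "protein")
  v <- alignment$valid
  list(pass = mean(v) >= min_valid,
       validity = mean(v),
       column_validity = colMeans(v))
}

#' Fitch parsimony state sets for one site
#'
#' Bottom-up Fitch pass: leaves contribute their observed residue (or the
#' full residue set when invalid); intersections propagate upward, with a
#' union and a unit count increment on empty intersections.
#'
#' @param tree Rooted tree.
#' @param alignment Protein alignment.
#' @param site 1-based site index.
#' @return List with `state_sets` (list per node, ape node order) and
#'   `count` (parsimony substitution count), or `NULL` (with a warning)
#'   for an all-invalid column.
#' @export
fitch_states <- function(tree, alignment, site) {
  stopifnot(alignment$kind == "protein")
  col <- alignment$aa_matrix[tree$tip.label, site]
  valid <- col %in% VALID_AA
  if (!any(valid)) {
    warning("site ", site, " has no valid residue; skipped")
    return(NULL)
  }
  trp <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(trp)
  nnode <- ntip + trp$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    res <- alignment$aa_matrix[trp$tip.label[i], site]
    sets[[i]] <- if (res %in% VALID_AA) res else VALID_AA
  }
  count <- 0
  # postorder edges: children of each internal node appear consecutively
  for (e in seq_len(nrow(trp$edge))) {
    parent <- trp$edge[e, 1]; child <- trp$edge[e, 2]
    if (is.null(sets[[parent]])) {
      sets[[parent]] <- sets[[child]]
    } else {
      inter <- intersect(sets[[parent]], sets[[child]])
      if (length(inter) > 0) {
        sets[[parent]] <- inter
      } else {
        sets[[parent]] <- union(sets[[parent]], sets[[child]])
        count <- count + 1
      }
    }
  }
  names(sets) <- node_labels(trp)
  list(state_sets = sets, count = count)
}

# Poisson-type amino-acid generator: q_ij = freq_j (i != j), rescaled to
# unit mean rate. A user-supplied 20x20 exchangeability matrix may replace
# the uniform exchangeabilities.
aa_rate_matrix <- function(freqs, exchange = NULL) {
  stopifnot(length(freqs) == 20, abs(sum(freqs) - 1) < 1e-8)
  if (is.null(exchange)) exchange <- matrix(1, 20, 20)
  q <- exchange * rep(freqs, each = 20)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(freqs * diag(q))
  q <- q / mu
  dimnames(q) <- list(VALID_AA, VALID_AA)
  q
}

# observed amino-acid frequencies with a pseudocount
observed_aa_freqs <- function(alignment, pseudo = 0.5) {
  tab <- table(factor(alignment$aa_matrix[alignment$valid],
                      levels = VALID_AA)) + pseudo
  as.numeric(tab) / sum(tab)
}

#' Marginal ancestral reconstruction of protein states
#'
#' Up-down pruning under a Poisson-type replacement model with
#' alignment-wide observed frequencies (a user 20x20 exchangeability
#' matrix may be supplied). For every internal node and site the marginal
#' posterior over the 20 residues is computed; the reported state is the
#' argmax, with ties broken toward the residue observed in more leaves
#' and then lexicographically.
#'
#' @param tree Rooted tree with branch lengths (expected replacements per
#'   site).
#' @param alignment Protein alignment covering the tree's tips.
#' @param exchange Optional 20x20 exchangeability matrix.
#' @return An `ancestral_states` list: `states` (node x site character
#'   matrix, leaves included), `posterior` (node x site matrix of the
#'   reported state's posterior; 1 for valid leaf cells), `tree`.
#' @export
marginal_reconstruction <- function(tree, alignment, exchange = NULL) {
  stopifnot(alignment$kind == "protein")
  if (!all(tree$tip.label %in% alignment$taxa))
    stop("alignment is missing taxa: ",
         paste(setdiff(tree$tip.label, alignment$taxa), collapse = ","),
         call. = FALSE)
  trp <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(trp)
  nnode <- ntip + trp$Nnode
  n_sites <- alignment$n_sites
  aa_mat <- alignment$aa_matrix[trp$tip.label, , drop = FALSE]
  freqs <- observed_aa_freqs(alignment)
  q <- aa_rate_matrix(freqs, exchange)
  edec <- gy94_eigen(q, freqs)     # same reversible-eigen machinery
  pmats <- lapply(trp$edge.length, function(t) gy94_prob(edec, t))

  # leaf conditionals: unit vector for valid residues, ones for missing
  partial <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    m <- matrix(0, 20, n_sites)
    idx <- match(aa_mat[i, ], VALID_AA)
    ok <- !is.na(idx)
    m[cbind(idx[ok], which(ok))] <- 1
    m[, !ok] <- 1
    partial[[i]] <- m
  }
  edge <- trp$edge
  # upward (postorder) pass; store per-edge child-message for reuse
  edge_msg <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    edge_msg[[e]] <- pmats[[e]] %*% partial[[child]]
    partial[[parent]] <- if (is.null(partial[[parent]])) edge_msg[[e]]
                         else partial[[parent]] * edge_msg[[e]]
  }
  root <- edge[nrow(edge), 1]
  # downward pass: outside[v] excludes the subtree below v
  outside <- vector("list", nnode)
  outside[[root]] <- matrix(freqs, 20, n_sites)
  for (e in rev(seq_len(nrow(edge)))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    sibs <- setdiff(which(edge[, 1] == parent), e)
    above <- outside[[parent]]
    for (s in sibs) above <- above * edge_msg[[s]]
    outside[[child]] <- crossprod(pmats[[e]], above)
  }

  labs <- node_labels(trp)
  states <- matrix(NA_character_, nnode, n_sites, dimnames = list(labs, NULL))
  posterior <- matrix(NA_real_, nnode, n_sites, dimnames = list(labs, NULL))
  # leaf counts per residue per site, for the tie-break
  leaf_counts <- apply(aa_mat, 2, function(col)
    tabulate(match(col, VALID_AA), 20))
  for (v in seq_len(nnode)) {
    post <- partial[[v]] * outside[[v]]
    norm <- colSums(post)
    norm[norm == 0] <- 1
    post <- post / rep(norm, each = 20)
    # argmax with deterministic tie-break: leaf support, then alphabet
    pick <- apply(rbind(post, leaf_counts), 2, function(x) {
      p <- x[1:20]; cnt <- x[21:40]
      cand <- which(p >= max(p) - 1e-12)
      if (length(cand) > 1) cand <- cand[order(-cnt[cand], VALID_AA[cand])]
      cand[1]
    })
    states[v, ] <- VALID_AA[pick]
    posterior[v, ] <- post[cbind(pick, seq_len(n_sites))]
  }
  # leaves report their observed residue where valid
  for (i in seq_len(ntip)) {
    ok <- aa_mat[i, ] %in% VALID_AA
    states[i, ok] <- aa_mat[i, ok]
    posterior[i, ok] <- 1
  }
  structure(list(states = states, posterior = posterior, tree = trp),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("<ancestral_states: %d nodes x %d sites>\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}
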