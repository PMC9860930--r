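# Felsenstein pruning likelihood for codon alignments under GY94.
#
# The core computes per-site log-likelihood vectors so that single-class
# models and branch-site mixtures share one code path.

# Convert a taxa x site codon character matrix to 1..61 indices (NA for
# anything outside the sense-codon alphabet: gaps, ambiguity, stops).
codon_indices <- function(codon_mat) {
  codons <- codon_alphabet()
  idx <- match(codon_mat, codons)
  dim(idx) <- dim(codon_mat)
  rownames(idx) <- rownames(codon_mat)
  idx
}

# Pruning context: everything about (tree, data) that is invariant across
# parameter values. Complete-case sites: columns with any NA codon are
# dropped gene-wide before fitting.
codon_pruning_context <- function(tree, codon_idx, drop_incomplete = TRUE) {
  if (!all(tree$tip.label %in% rownames(codon_idx)))
    stop("alignment is missing taxa: ",
         paste(setdiff(tree$tip.label, rownames(codon_idx)), collapse = ", "),
         call. = FALSE)
  codon_idx <- codon_idx[tree$tip.label, , drop = FALSE]
  n_total <- ncol(codon_idx)
  if (drop_incomplete) {
    keep <- colSums(is.na(codon_idx)) == 0
    codon_idx <- codon_idx[, keep, drop = FALSE]
  }
  tr <- stats::reorder(tree, "postorder")
  # site-pattern compression: identical columns are computed once
  keys <- apply(codon_idx, 2, paste0, collapse = "_")
  first <- !duplicated(keys)
  pattern_index <- match(keys, keys[first])
  pat <- codon_idx[, first, drop = FALSE]
  list(tree = tr,
       codon_idx = pat,
       pattern_weight = as.numeric(tabulate(pattern_index, sum(first))),
       pattern_index = pattern_index,
       n_sites = ncol(pat),
       n_real_sites = length(keys),
       n_dropped = n_total - length(keys),
       ntip = ape::Ntip(tr),
       edge = tr$edge,
       edge_length = tr$edge.length,
       root = tr$edge[nrow(tr$edge), 1])
}

# Per-site log-likelihood under a single set of branch transition matrices.
# plist: list of 61x61 P matrices indexed by edge row (postorder order).
site_loglik_pruning <- function(ctx, plist, codon_freqs) {
  ntip <- ctx$ntip
  n_sites <- ctx$n_sites
  nnode <- ntip + ctx$tree$Nnode
  partial <- vector("list", nnode)
  logscale <- rep(0, n_sites)
  edge <- ctx$edge
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    p <- plist[[e]]
    contrib <- if (child <= ntip) {
      p[, ctx$codon_idx[child, ], drop = FALSE]
    } else {
      p %*% partial[[child]]
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
    }
    # periodic rescaling: partial-likelihood magnitudes decay roughly
    # geometrically in merge count, so rescaling every 16 merges keeps
    # doubles far from underflow on any desk-scale tree
    if (e %% 16L == 0L) {
      mx <- apply(partial[[parent]], 2, max)
      mx[mx == 0] <- 1
      partial[[parent]] <- partial[[parent]] / rep(mx, each = nrow(partial[[parent]]))
      logscale <- logscale + log(mx)
    }
  }
  lik <- colSums(codon_freqs * partial[[ctx$root]])
  log(lik) + logscale
}

# Build per-edge transition matrices given kappa, per-edge omega vector
# (length nrow(edge)), codon freqs and a branch-length scale multiplier.
edge_prob_matrices <- function(ctx, kappa, omega_by_edge, codon_freqs,
                               rate_scale = 1) {
  uo <- unique(omega_by_edge)
  edecs <- lapply(uo, function(w)
    gy94_eigen(gy94_rate_matrix(kappa, w, codon_freqs), codon_freqs))
  names(edecs) <- as.character(uo)
  lapply(seq_along(omega_by_edge), function(e)
    gy94_prob(edecs[[as.character(omega_by_edge[e])]],
              ctx$edge_length[e] * rate_scale))
}

#' Codon-alignment log-likelihood under GY94
#'
#' Felsenstein pruning over a rooted tree. `omega` may be a single value
#' (one-ratio), or a named vector mapping branch child-node labels to
#' branch-specific dN/dS values (unnamed branches fall back to
#' `omega[["background"]]` or the first element).
#'
#' @param tree `ape::phylo` tree whose tip labels match the alignment.
#' @param alignment A codon alignment from [read_alignment()] or
#'   [simulate_codon_data()], or a taxa x site codon character matrix.
#' @param kappa Transition/transversion ratio.
#' @param omega dN/dS, scalar or named per-branch vector (see Details).
#' @param codon_freqs Equilibrium codon frequencies.
#' @param rate_scale Multiplier applied to all tree branch lengths.
#' @return Total log-likelihood (numeric scalar) with attribute
#'   `"site_loglik"` holding the per-site vector.
#' @export
log_likelihood <- function(tree, alignment, kappa = 2, omega = 1,
                           codon_freqs = codon_freqs_f1x4(),
                           rate_scale = 1) {
  codon_mat <- as_codon_matrix(alignment)
  ctx <- codon_pruning_context(tree, codon_indices(codon_mat))
  omega_by_edge <- expand_branch_omega(ctx$tree, omega)
  plist <- edge_prob_matrices(ctx, kappa, omega_by_edge, codon_freqs,
                              rate_scale)
  sl <- site_loglik_pruning(ctx, plist, codon_freqs)
  out <- sum(ctx$pattern_weight * sl)
  attr(out, "site_loglik") <- sl[ctx$pattern_index]
  out
}

# omega spec -> per-edge vector (postorder edge order of ctx$tree)
expand_branch_omega <- function(tree, omega) {
  br <- tree_branches(tree)
  if (is.null(names(omega))) {
    if (length(omega) == 1) return(rep(omega, nrow(br)))
    if (length(omega) == nrow(br)) return(omega)
    stop("unnamed omega must be scalar or one per edge", call. = FALSE)
  }
  bg <- if ("background" %in% names(omega)) omega[["background"]]
        else omega[[1]]
  out <- rep(bg, nrow(br))
  named <- setdiff(names(omega), "background")
  for (nm in named) {
    hit <- which(br$child_label == nm)
    if (length(hit) != 1)
      stop("omega names a branch not in the tree: ", nm, call. = FALSE)
    out[hit] <- omega[[nm]]
  }
  out
}

# Accept several alignment representations and return the codon character
# matrix (taxa x sites of 3-letter codons).
as_codon_matrix <- function(alignment) {
  if (is.matrix(alignment) && is.character(alignment)) {
    if (all(nchar(alignment[!is.na(alignment)]) == 3)) return(alignment)
    stop("character matrix must contain 3-letter codons", call. = FALSE)
  }
  if (inherits(alignment, "cashmere_alignment")) {
    if (alignment$kind != "codon")
      stop("codon alignment required", call. = FALSE)
    return(alignment$codon_matrix)
  }
  stop("unsupported alignment representation", call. = FALSE)
}
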