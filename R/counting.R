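# Counting-based per-branch dN/dS (Nei-Gojobori style) over reconstructed
# or recorded ancestral codon states: a fast surrogate for free-ratio ML
# omega on large trees.

# NG86 nonsynonymous/synonymous site counts per codon; changes to stop
# codons are excluded from the denominator.
ng86_site_counts <- function() {
  if (!is.null(.cashmere_env$ng86_sites)) return(.cashmere_env$ng86_sites)
  codons <- codon_alphabet()
  aa <- codon_amino_acids()
  nts <- c("A", "C", "G", "T")
  n_sites <- s_sites <- numeric(length(codons))
  for (i in seq_along(codons)) {
    chars <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      alts <- setdiff(nts, chars[pos])
      fates <- vapply(alts, function(a) {
        mut <- chars; mut[pos] <- a
        mc <- paste0(mut, collapse = "")
        j <- match(mc, codons)
        if (is.na(j)) return(NA_character_)          # stop codon
        if (aa[j] == aa[i]) "syn" else "nonsyn"
      }, character(1))
      fates <- fates[!is.na(fates)]
      if (length(fates) == 0) next
      s_sites[i] <- s_sites[i] + sum(fates == "syn") / length(fates)
      n_sites[i] <- n_sites[i] + sum(fates == "nonsyn") / length(fates)
    }
  }
  out <- list(nonsyn = n_sites, syn = s_sites)
  .cashmere_env$ng86_sites <- out
  out
}

# Average nonsyn/syn difference counts between two codons over all
# minimal single-step paths (paths through stop codons are excluded).
codon_path_counts <- function(i, j) {
  codons <- codon_alphabet()
  aa <- codon_amino_acids()
  if (i == j) return(c(nonsyn = 0, syn = 0))
  walk <- function(a, b) {
    ca <- strsplit(codons[a], "")[[1]]; cb <- strsplit(codons[b], "")[[1]]
    diff <- which(ca != cb)
    if (length(diff) == 1) {
      return(list(c(nonsyn = as.numeric(aa[a] != aa[b]),
                    syn = as.numeric(aa[a] == aa[b]))))
    }
    paths <- list()
    for (d in diff) {
      mid <- ca; mid[d] <- cb[d]
      m <- match(paste0(mid, collapse = ""), codons)
      if (is.na(m)) next                           # via stop: disallowed
      step <- c(nonsyn = as.numeric(aa[a] != aa[m]),
                syn = as.numeric(aa[a] == aa[m]))
      for (rest in walk(m, b)) paths[[length(paths) + 1]] <- step + rest
    }
    paths
  }
  paths <- walk(i, j)
  if (length(paths) == 0) {
    # all paths pass through stops; fall back to counting positions
    return(c(nonsyn = sum(strsplit(codons[i], "")[[1]] !=
                            strsplit(codons[j], "")[[1]]), syn = 0))
  }
  Reduce(`+`, paths) / length(paths)
}

#' Per-branch dN, dS and omega by substitution counting
#'
#' Given codon states at every node (recorded simulation truth or an
#' ancestral reconstruction), counts nonsynonymous and synonymous
#' differences between the endpoint codons of every branch (averaging over
#' minimal mutational paths for multi-hit codons), normalizes by
#' Nei-Gojobori site counts, and reports per-branch dN/dS. `omega` is `NA`
#' (flagged) where dS = 0.
#'
#' @param tree Rooted tree.
#' @param node_states Node x site matrix of codon indices (1..61), rows in
#'   ape node-number order (as produced by [simulate_codon_data()] truth),
#'   or of 3-letter codon strings.
#' @return Tibble: one row per branch with `dN`, `dS`, `omega`,
#'   `omega_defined`.
#' @export
counting_omega_per_branch <- function(tree, node_states) {
  if (is.character(node_states)) {
    idx <- match(node_states, codon_alphabet())
    dim(idx) <- dim(node_states); rownames(idx) <- rownames(node_states)
    node_states <- idx
  }
  sites <- ng86_site_counts()
  br <- tree_branches(tree)
  pair_cache <- new.env(parent = emptyenv())
  counts <- function(i, j) {
    key <- paste0(min(i, j), "_", max(i, j))
    if (is.null(pair_cache[[key]])) pair_cache[[key]] <- codon_path_counts(i, j)
    pair_cache[[key]]
  }
  rows <- lapply(seq_len(nrow(br)), function(e) {
    ps <- node_states[br$parent[e], ]; cs <- node_states[br$child[e], ]
    ok <- !is.na(ps) & !is.na(cs)
    nd <- sd <- 0
    for (k in which(ok & ps != cs)) {
      cc <- counts(ps[k], cs[k])
      nd <- nd + cc[["nonsyn"]]; sd <- sd + cc[["syn"]]
    }
    # site counts from the parent sequence
    n_sites_tot <- sum(sites$nonsyn[ps[ok]])
    s_sites_tot <- sum(sites$syn[ps[ok]])
    dn <- if (n_sites_tot > 0) nd / n_sites_tot else 0
    ds <- if (s_sites_tot > 0) sd / s_sites_tot else 0
    tibble::tibble(branch = br$child_label[e], dN = dn, dS = ds,
                   omega = if (ds > 0) dn / ds else NA_real_,
                   omega_defined = ds > 0)
  })
  dplyr::bind_rows(rows)
}
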