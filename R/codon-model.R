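# Goldman-Yang (GY94) codon substitution model: 61-codon sense alphabet,
# rate matrix construction, and eigen-decomposed transition probabilities.

#' The 61 sense codons of the standard genetic code
#'
#' Stop codons (TAA, TAG, TGA) are excluded from the state space.
#'
#' @return Character vector of 61 codons in fixed lexicographic order.
#' @export
codon_alphabet <- function() {
  nts <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(nts, nts, paste0), nts,
                           function(ab, c) paste0(ab, c)))
  all64 <- sort(all64)
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

# translation table for the 61 sense codons (standard code)
codon_amino_acids <- function() {
  codons <- codon_alphabet()
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# Pairwise structure of the codon space, computed once per session.
# For each ordered pair differing at exactly one position: records whether
# the nucleotide change is a transition and whether it is nonsynonymous.
codon_pair_structure <- function() {
  if (!is.null(.cashmere_env$pair_struct)) return(.cashmere_env$pair_struct)
  codons <- codon_alphabet()
  aa <- codon_amino_acids()
  n <- length(codons)
  mat <- matrix(unlist(strsplit(codons, "")), nrow = n, byrow = TRUE)
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  ii <- integer(0); jj <- integer(0); ts <- logical(0); ns <- logical(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(mat[i, ] != mat[j, ])
      if (length(diff) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, is_transition(mat[i, diff], mat[j, diff]))
      ns <- c(ns, aa[i] != aa[j])
    }
  }
  out <- list(i = ii, j = jj, transition = ts, nonsyn = ns, n = n)
  .cashmere_env$pair_struct <- out
  out
}

.cashmere_env <- new.env(parent = emptyenv())

#' F1x4 equilibrium codon frequencies
#'
#' Codon frequencies are products of position-independent nucleotide
#' frequencies, renormalized over the 61 sense codons.
#'
#' @param nt_freqs Named numeric vector of A/C/G/T frequencies (summing to 1).
#' @return Numeric 61-vector summing to 1, named by codon.
#' @export
codon_freqs_f1x4 <- function(nt_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(nt_freqs)))
  nt_freqs <- nt_freqs / sum(nt_freqs)
  codons <- codon_alphabet()
  mat <- matrix(unlist(strsplit(codons, "")), ncol = 3, byrow = TRUE)
  f <- nt_freqs[mat[, 1]] * nt_freqs[mat[, 2]] * nt_freqs[mat[, 3]]
  f <- as.numeric(f) / sum(f)
  names(f) <- codons
  f
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61x61 codon generator with entries
#' `q[i,j] = pi_j * kappa^[transition] * omega^[nonsynonymous]` for codon
#' pairs differing at exactly one nucleotide, zero otherwise. Rows sum to
#' zero and the matrix is rescaled so the expected substitution rate at
#' equilibrium is one per codon, so branch lengths are expected
#' substitutions per codon site.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param codon_freqs Equilibrium codon frequencies (61-vector summing to 1),
#'   e.g. from [codon_freqs_f1x4()].
#' @param scale If `TRUE` (default) rescale to unit mean rate.
#' @return 61x61 numeric matrix with codon dimnames.
#' @export
gy94_rate_matrix <- function(kappa, omega,
                             codon_freqs = codon_freqs_f1x4(),
                             scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(codon_freqs) == 61,
            abs(sum(codon_freqs) - 1) < 1e-8)
  ps <- codon_pair_structure()
  q <- matrix(0, ps$n, ps$n)
  rate <- codon_freqs[ps$j] * ifelse(ps$transition, kappa, 1) *
    ifelse(ps$nonsyn, omega, 1)
  q[cbind(ps$i, ps$j)] <- rate
  diag(q) <- -rowSums(q)
  if (scale) {
    mu <- -sum(codon_freqs * diag(q))
    if (mu > 0) q <- q / mu
  }
  dimnames(q) <- list(codon_alphabet(), codon_alphabet())
  q
}

# Eigen-decomposition of a reversible generator Q with stationary
# distribution pi. Returns components from which P(t) is assembled cheaply
# for any t:  P(t) = inv_left %*% diag(exp(lambda t)) %*% right.
gy94_eigen <- function(q, codon_freqs) {
  d <- sqrt(codon_freqs)
  b <- q * (d %o% (1 / d))            # D^{1/2} Q D^{-1/2}, symmetric
  b <- (b + t(b)) / 2                 # guard against rounding asymmetry
  eig <- eigen(b, symmetric = TRUE)
  list(values = eig$values,
       left = eig$vectors * (1 / d),  # D^{-1/2} U
       right = t(eig$vectors * d))    # U^T D^{1/2}
}

# Transition probability matrix P(t) = exp(Qt) from a gy94_eigen object.
gy94_prob <- function(edec, t) {
  if (t <= 0) return(diag(length(edec$values)))
  p <- edec$left %*% (exp(edec$values * t) * edec$right)
  p[p < 0] <- 0
  p
}
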