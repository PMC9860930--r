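# FASTA alignment input/output. Codon alignments are stored as taxa x site
# matrices of 3-letter codons; protein alignments as taxa x site matrices
# of single-letter residues with a parallel validity mask.

VALID_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")

new_alignment <- function(kind, mat) {
  out <- list(kind = kind)
  if (kind == "codon") {
    out$codon_matrix <- mat
    out$n_sites <- ncol(mat)
  } else {
    out$aa_matrix <- mat
    out$valid <- matrix(mat %in% VALID_AA, nrow = nrow(mat),
                        dimnames = dimnames(mat))
    out$n_sites <- ncol(mat)
  }
  out$taxa <- rownames(mat)
  class(out) <- "cashmere_alignment"
  out
}

#' @export
print.cashmere_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment: %d taxa x %d sites>\n", x$kind,
              length(x$taxa), x$n_sites))
  invisible(x)
}

#' Read a codon or protein alignment from FASTA
#'
#' All sequences must have equal length; codon alignments must have length
#' divisible by three. Gaps and ambiguity codes are preserved and treated
#' as missing downstream.
#'
#' @param path FASTA file path.
#' @param kind `"codon"` or `"protein"`.
#' @return A `cashmere_alignment` object.
#' @export
read_alignment <- function(path, kind = c("codon", "protein")) {
  kind <- match.arg(kind)
  set <- if (kind == "codon") Biostrings::readBStringSet(path)
         else Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  alignment_from_strings(seqs, kind)
}

# Shared constructor from named sequence strings (used by readers and the
# simulator).
alignment_from_strings <- function(seqs, kind) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(unique(lens), collapse = ","), call. = FALSE)
  len <- lens[[1]]
  if (kind == "codon") {
    if (len %% 3 != 0)
      stop("codon alignment length ", len, " is not divisible by 3",
           call. = FALSE)
    n_codons <- len / 3
    mat <- t(vapply(seqs, function(s)
      substring(s, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons)),
      character(n_codons)))
    if (n_codons == 1) {
      mat <- matrix(mat, ncol = 1, dimnames = list(names(seqs), NULL))
    }
    rownames(mat) <- names(seqs)
  } else {
    mat <- t(vapply(seqs, function(s)
      strsplit(s, "")[[1]], character(len)))
    if (len == 1) mat <- matrix(mat, ncol = 1)
    rownames(mat) <- names(seqs)
  }
  new_alignment(kind, mat)
}

#' Write an alignment to FASTA
#'
#' @param alignment A `cashmere_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  mat <- if (alignment$kind == "codon") alignment$codon_matrix
         else alignment$aa_matrix
  seqs <- apply(mat, 1, paste0, collapse = "")
  writeLines(paste0(">", rownames(mat), "\n", seqs), path)
  invisible(path)
}

# Protein view of a codon alignment: translate sense codons, mark
# everything else (gap/ambiguous/stop) as "X".
translate_codon_alignment <- function(alignment) {
  stopifnot(alignment$kind == "codon")
  codons <- codon_alphabet()
  aa <- codon_amino_acids()
  mat <- alignment$codon_matrix
  idx <- match(mat, codons)
  out <- matrix(ifelse(is.na(idx), "X", aa[idx]), nrow = nrow(mat),
                dimnames = dimnames(mat))
  new_alignment("protein", out)
}
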