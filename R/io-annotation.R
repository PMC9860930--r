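# Gene intervals (BED / GFF3), expression matrices and pathway tables.
# Internal genomic coordinates are 0-based half-open everywhere;
# conversion happens only at the file boundary.

#' Read gene intervals from BED or GFF3
#'
#' Format is auto-detected from the extension (`.bed` vs `.gff`/`.gff3`).
#' BED is 0-based half-open and used as-is; GFF3 (1-based closed) is
#' shifted so both representations of an interval coincide internally.
#'
#' @param path Annotation file.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `gene`.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    out <- tibble::tibble(chrom = as.character(df[[1]]),
                          start = as.integer(df[[2]]),
                          end = as.integer(df[[3]]),
                          gene = as.character(df[[4]]))
  } else if (ext %in% c("gff", "gff3")) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    attr_field <- as.character(df[[9]])
    gene <- stringr::str_match(attr_field, "(?:ID|Name|gene_id)=([^;]+)")[, 2]
    gene[is.na(gene)] <- paste0("feature", which(is.na(gene)))
    out <- tibble::tibble(chrom = as.character(df[[1]]),
                          start = as.integer(df[[4]]) - 1L,
                          end = as.integer(df[[5]]),
                          gene = gene)
  } else {
    stop("unrecognized annotation extension: ", ext, call. = FALSE)
  }
  bad <- out$end <= out$start
  if (any(bad))
    stop("interval with end <= start after normalization: line ",
         which(bad)[1], call. = FALSE)
  out
}

#' Write gene intervals to BED
#'
#' @param intervals Tibble `chrom`, `start`, `end`, `gene`.
#' @param path Output path.
#' @export
write_annotation_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column = gene ids, header row = sample ids; all cells numeric.
#'
#' @param path TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cell in expression matrix '", path, "'", call. = FALSE)
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path Output path.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pathway membership table
#'
#' Two-column TSV (`pathway`, `gene`), one gene per row.
#'
#' @param path TSV file.
#' @return Tibble `pathway`, `gene`, deduplicated.
#' @export
read_pathways <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "gene") %in% names(df)))
  dplyr::distinct(tibble::as_tibble(df[, c("pathway", "gene")]))
}

#' Write a pathway membership table
#'
#' @param pathways Tibble `pathway`, `gene`.
#' @param path Output path.
#' @export
write_pathways <- function(pathways, path) {
  utils::write.table(pathways, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
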