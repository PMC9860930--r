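# Variant panel container and VCF v4.2 input/output. Internally positions
# are 0-based; conversion to the VCF's 1-based coordinates happens only at
# the file boundary. Missing genotypes are never imputed: they reduce the
# called-allele denominator downstream.

new_variant_panel <- function(sites, geno, pops) {
  stopifnot(nrow(sites) == nrow(geno),
            all(colnames(geno) %in% pops$sample))
  structure(list(sites = sites, geno = geno,
                 pops = pops[match(colnames(geno), pops$sample), ]),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel: %d sites x %d samples (%s)>\n",
              nrow(x$sites), ncol(x$geno),
              paste(sprintf("%s:%d", names(table(x$pops$population)),
                            table(x$pops$population)), collapse = ", ")))
  invisible(x)
}

#' Read a VCF into a variant panel
#'
#' Parses GT fields into alt-allele dosages (0/1/2, `NA` for missing).
#' Multiallelic records are retained but flagged not-biallelic.
#'
#' @param path VCF v4.2 file (plain or gzipped text).
#' @param pop_table Data frame mapping `sample` to `population`; every
#'   sample listed must be present in the VCF.
#' @return A `variant_panel`: `sites` tibble (`chrom`, `pos` 0-based,
#'   `ref`, `alt`, `biallelic`), `geno` dosage matrix (sites x samples),
#'   `pops` tibble.
#' @export
read_vcf <- function(path, pop_table) {
  pop_table <- tibble::as_tibble(pop_table)
  stopifnot(all(c("sample", "population") %in% names(pop_table)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(pop_table$sample, samples)
  if (length(missing) > 0)
    stop("samples in pop_table absent from VCF: ",
         paste(missing, collapse = ","), call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, pop_table$sample, drop = FALSE]
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dim(dos) <- dim(gt); colnames(dos) <- colnames(gt)
  fix <- vcfR::getFIX(v)
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    biallelic = !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1
  )
  new_variant_panel(sites, dos, pop_table)
}

#' Write a variant panel to VCF v4.2
#'
#' @param panel A `variant_panel`.
#' @param path Output path.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(panel$geno)),
                     collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[panel$geno + 1L],
                   nrow = nrow(panel$geno))
  gt_str[is.na(panel$geno)] <- "./."
  lines <- paste(panel$sites$chrom, panel$sites$pos + 1L, ".",
                 panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Per-population allele counts at every site
#'
#' @param panel A `variant_panel`.
#' @return Tibble: one row per site with, per population, called allele
#'   count `n_<pop>`, alt count `alt_<pop>` and observed heterozygote
#'   count `het_<pop>`.
#' @export
site_counts <- function(panel) {
  out <- panel$sites
  for (p in unique(panel$pops$population)) {
    g <- panel$geno[, panel$pops$population == p, drop = FALSE]
    out[[paste0("n_", p)]] <- 2L * rowSums(!is.na(g))
    out[[paste0("alt_", p)]] <- rowSums(g, na.rm = TRUE)
    out[[paste0("het_", p)]] <- rowSums(g == 1L, na.rm = TRUE)
  }
  out
}
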