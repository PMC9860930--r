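# Run configuration: one structured object holding every pipeline
# threshold, validated on construction, round-trippable through YAML so a
# run can log its resolved configuration and seed.

#' Pipeline configuration
#'
#' Defaults mirror the study's stated thresholds: 50 kb windows with a
#' 20 kb step, top 1% per sweep method, MAF 0.05, at most 10% missing
#' genotypes, LRT alpha 0.05, |log2FC| > 1 with FDR < 0.05 for DEGs,
#' SD >= 0.5 expression filter, scale-free fit target 0.85, minimum
#' module size 30, eigengene-dissimilarity merge threshold 0.25, and hub
#' cuts |GS| > 0.2, |MM| > 0.8.
#'
#' @param window_size_bp,window_step_bp Sweep window geometry.
#' @param top_fraction Upper-tail fraction per sweep method.
#' @param maf_min Minimum minor-allele frequency.
#' @param max_missing Maximum fraction of missing genotypes per site.
#' @param lrt_alpha LRT significance level.
#' @param lfc_threshold DEG |log2FC| threshold.
#' @param fdr_threshold DEG FDR threshold.
#' @param sd_min Expression SD filter.
#' @param soft_power_target_r2 Scale-free fit target.
#' @param min_module_size Minimum module size.
#' @param me_diss_threshold Module-eigengene merge threshold.
#' @param gs_cut,mm_cut Hub-gene cut-offs.
#' @param posterior_min Ancestral-state posterior gate.
#' @param rng_seed Seed logged with every run.
#' @return A validated `cashmere_config` list.
#' @export
cashmere_config <- function(window_size_bp = 50000L,
                            window_step_bp = 20000L,
                            top_fraction = 0.01,
                            maf_min = 0.05,
                            max_missing = 0.10,
                            lrt_alpha = 0.05,
                            lfc_threshold = 1.0,
                            fdr_threshold = 0.05,
                            sd_min = 0.5,
                            soft_power_target_r2 = 0.85,
                            min_module_size = 30L,
                            me_diss_threshold = 0.25,
                            gs_cut = 0.2,
                            mm_cut = 0.8,
                            posterior_min = 0.8,
                            rng_seed = 1L) {
  cfg <- list(window_size_bp = as.integer(window_size_bp),
              window_step_bp = as.integer(window_step_bp),
              top_fraction = top_fraction, maf_min = maf_min,
              max_missing = max_missing, lrt_alpha = lrt_alpha,
              lfc_threshold = lfc_threshold,
              fdr_threshold = fdr_threshold, sd_min = sd_min,
              soft_power_target_r2 = soft_power_target_r2,
              min_module_size = as.integer(min_module_size),
              me_diss_threshold = me_diss_threshold,
              gs_cut = gs_cut, mm_cut = mm_cut,
              posterior_min = posterior_min,
              rng_seed = as.integer(rng_seed))
  props <- c("top_fraction", "maf_min", "max_missing", "lrt_alpha",
             "fdr_threshold", "soft_power_target_r2", "me_diss_threshold",
             "gs_cut", "mm_cut", "posterior_min")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("config '", p, "' must be a proportion in [0,1]", call. = FALSE)
  }
  if (cfg$window_step_bp > cfg$window_size_bp)
    stop("window_step_bp must not exceed window_size_bp", call. = FALSE)
  class(cfg) <- "cashmere_config"
  cfg
}

#' Read / write a configuration as YAML
#'
#' Keys present in the file override the defaults; unknown keys error.
#'
#' @param path YAML file.
#' @return A `cashmere_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(cashmere_config)))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ","),
         call. = FALSE)
  do.call(cashmere_config, vals)
}

#' @rdname read_config
#' @param config A `cashmere_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.cashmere_config <- function(x, ...) {
  cat("<cashmere_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
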