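# Shared fixtures, built in code. Expensive simulations are memoized in a
# session-local environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# six-taxon balanced-ish tree used throughout the codon tests
six_taxon_tree <- function() {
  read_tree_text(
    "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05,(E:0.1,F:0.1):0.05);")
}

# eight-taxon tree with two non-sister focal tips (A and E)
eight_taxon_tree <- function() {
  read_tree_text(paste0(
    "(((A:0.05,B:0.05):0.03,(C:0.05,D:0.05):0.03):0.02,",
    "((E:0.05,F:0.05):0.03,(G:0.05,H:0.05):0.03):0.02);"))
}

# codon simulation at omega 0.2, 2000 codons (recovery tests)
sim_omega02 <- function() {
  fixture("sim_omega02", function()
    simulate_codon_data(six_taxon_tree(), n_genes = 1, n_codons = 2000,
                        kappa = 2, base_omega = 0.2, seed = 42))
}

# expression simulation used by coexpression + DE tests
sim_expr <- function() {
  fixture("sim_expr", function()
    simulate_expression(n_genes = 600, samples_per_stage = 15,
                        n_modules = 4, module_size = 50, module_cor = 0.8,
                        n_de = 60, lfc = 2, dispersion = 0.2,
                        samples_per_group = 10, seed = 4))
}

# sweep simulation with three planted windows
sim_sweep <- function() {
  fixture("sim_sweep", function() {
    sw <- tibble::tibble(start = c(1000000L, 2500000L, 4000000L),
                         end = c(1050000L, 2550000L, 4050000L))
    simulate_variant_panel(n_per_pop = 20, chrom_length_bp = 5e6,
                           snp_density = 0.002, sweep_windows = sw,
                           reduction = 0.1, divergence = 0.6,
                           missing_rate = 0.02, seed = 9)
  })
}

# independent GY94 rate-matrix transcription used as an oracle: built
# directly from codon strings and the genetic code, no shared code path
# with the package internals beyond the alphabet definition
oracle_gy94 <- function(kappa, omega, freqs) {
  codons <- codon_alphabet()
  gc <- Biostrings::GENETIC_CODE
  n <- length(codons)
  q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- strsplit(codons[i], "")[[1]]; cj <- strsplit(codons[j], "")[[1]]
      d <- which(ci != cj)
      if (length(d) != 1) next
      ts <- paste0(sort(c(ci[d], cj[d])), collapse = "") %in% c("AG", "CT")
      ns <- gc[[codons[i]]] != gc[[codons[j]]]
      q[i, j] <- freqs[j] * (if (ts) kappa else 1) * (if (ns) omega else 1)
    }
  }
  diag(q) <- -rowSums(q)
  q / (-sum(freqs * diag(q)))
}
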