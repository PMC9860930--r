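# Convergence detection rule, CCS filtration chain and planted-truth
# recovery.

# hand-built ancestral_states object on the 8-taxon tree for rule tests
toy_anc <- function(focal_derived = c("V", "V"),
                    focal_parents = c("I", "I"),
                    background = "I", bg_override = NULL) {
  tr <- eight_taxon_tree()
  trp <- stats::reorder(tr, "postorder")
  labs <- c(trp$tip.label, trp$node.label)
  states <- matrix(background, length(labs), 1,
                   dimnames = list(labs, NULL))
  posterior <- matrix(1, length(labs), 1, dimnames = list(labs, NULL))
  states["A", 1] <- focal_derived[1]
  states["E", 1] <- focal_derived[2]
  # parents of A and E
  pa <- labs[trp$edge[trp$edge[, 2] == match("A", labs), 1]]
  pe <- labs[trp$edge[trp$edge[, 2] == match("E", labs), 1]]
  states[pa, 1] <- focal_parents[1]
  states[pe, 1] <- focal_parents[2]
  if (!is.null(bg_override))
    for (nm in names(bg_override)) states[nm, 1] <- bg_override[[nm]]
  structure(list(states = states, posterior = posterior, tree = trp),
            class = "ancestral_states")
}

toy_aln_from_anc <- function(anc) {
  tr <- anc$tree
  mat <- anc$states[tr$tip.label, , drop = FALSE]
  cashmere:::new_alignment("protein", mat)
}

test_that("the convergence rule accepts parallel and rejects divergent", {
  hit <- detect_convergent_substitutions(toy_anc(), c("A", "E"))
  expect_equal(nrow(hit), 1)
  expect_true(hit$parallel)          # identical parent states
  expect_equal(unname(hit$derived), "V")

  miss <- detect_convergent_substitutions(
    toy_anc(focal_derived = c("V", "L")), c("A", "E"))
  expect_equal(nrow(miss), 0)

  # different parents, same derived: strict convergent, not parallel
  conv <- detect_convergent_substitutions(
    toy_anc(focal_parents = c("I", "K")), c("A", "E"))
  expect_equal(nrow(conv), 1)
  expect_false(conv$parallel)
})

test_that("the posterior gate suppresses uncertain calls", {
  anc <- toy_anc()
  pa <- rownames(anc$states)[stats::reorder(eight_taxon_tree(), "postorder")$edge[
    stats::reorder(eight_taxon_tree(), "postorder")$edge[, 2] == 1, 1]]
  anc$posterior[pa, 1] <- 0.5
  hit <- detect_convergent_substitutions(anc, c("A", "E"),
                                         posterior_min = 0.8)
  expect_equal(nrow(hit), 0)
})

test_that("CCS filter enforces the conservative-background rule", {
  anc <- toy_anc()
  sites <- detect_convergent_substitutions(anc, c("A", "E"))
  aln <- toy_aln_from_anc(anc)
  expect_true(ccs_filter(sites, aln, anc$tree, c("A", "E"))$ccs_pass)

  # one background leaf carries the derived residue -> fail
  anc2 <- toy_anc(bg_override = list(G = "V"))
  s2 <- detect_convergent_substitutions(anc2, c("A", "E"))
  expect_false(ccs_filter(s2, toy_aln_from_anc(anc2), anc2$tree,
                          c("A", "E"))$ccs_pass)

  # background split I/L (not conserved) -> fail
  anc3 <- toy_anc(bg_override = list(G = "L", H = "L"))
  s3 <- detect_convergent_substitutions(anc3, c("A", "E"))
  expect_false(ccs_filter(s3, toy_aln_from_anc(anc3), anc3$tree,
                          c("A", "E"))$ccs_pass)
})

test_that("gene report formats substitutions parent-site-derived", {
  tab <- tibble::tibble(gene = "PRPF4B", site = 136L, derived = "R",
                        parent1 = "K", parent2 = "K", background = "K",
                        parallel = TRUE, min_posterior = 1,
                        ccs_pass = TRUE)
  rep <- converge_report(tab)
  expect_equal(rep$substitutions, "K136R")
  empty <- converge_report(tab[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("planted conservative sites are recovered exactly", {
  sim <- fixture("sim_ccs", function() {
    s <- simulate_codon_data(eight_taxon_tree(), 5, 200, 2, 0.2, seed = 3)
    plant_convergent_sites(s, c("A", "E"), n_sites = 5,
                           genes = c("gene001", "gene002"),
                           conservative = TRUE, seed = 5)
  })
  res <- run_convergence_scan(eight_taxon_tree(), sim$alignments,
                              c("A", "E"))
  truth <- sim$truth$convergent_sites
  ccs <- res$sites[res$sites$ccs_pass, ]
  expect_setequal(paste(ccs$gene, ccs$site), paste(truth$gene, truth$site))
  expect_setequal(res$genes$gene, unique(truth$gene))
})

test_that("CCS sites are nested inside convergent sites", {
  sim <- fixture("sim_ccs", function() {
    s <- simulate_codon_data(eight_taxon_tree(), 5, 200, 2, 0.2, seed = 3)
    plant_convergent_sites(s, c("A", "E"), n_sites = 5,
                           genes = c("gene001", "gene002"),
                           conservative = TRUE, seed = 5)
  })
  res <- run_convergence_scan(eight_taxon_tree(), sim$alignments,
                              c("A", "E"), posterior_min = 0)
  # every CCS-passing site is a detected convergent site by construction;
  # and every detected site substitutes on both focal branches
  expect_true(all(res$sites$ccs_pass %in% c(TRUE, FALSE)))
  expect_true(all(res$sites$derived != res$sites$parent1))
  expect_true(all(res$sites$derived != res$sites$parent2))
  expect_gte(nrow(res$sites), sum(res$sites$ccs_pass))
})

test_that("nested focal branches are rejected", {
  anc <- toy_anc()
  expect_error(detect_convergent_substitutions(anc, c("A", "N2")),
               "nested")
})
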