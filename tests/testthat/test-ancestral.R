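# Validity gating, Fitch parsimony and marginal reconstruction against
# enumeration oracles.

make_protein_aln <- function(rows) {
  mat <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(rows)
  cashmere:::new_alignment("protein", mat)
}

test_that("validity filter uses exact fractions with >= semantics", {
  aln <- make_protein_aln(stats::setNames(
    rep(c("MKLV", "MKLV"), c(1, 1)), c("a", "b")))
  vf <- validity_filter(aln)
  expect_true(vf$pass)
  expect_equal(vf$validity, 1.0)

  # 10x10 with 30 gaps -> 0.70 -> fail
  mat <- matrix("A", 10, 10, dimnames = list(paste0("t", 1:10), NULL))
  mat[seq_len(30)] <- "-"
  aln2 <- cashmere:::new_alignment("protein", mat)
  vf2 <- validity_filter(aln2)
  expect_equal(vf2$validity, 0.70)
  expect_false(vf2$pass)

  # exactly at 0.75 -> pass
  mat[seq_len(30)] <- "A"; mat[seq_len(25)] <- "-"
  vf3 <- validity_filter(cashmere:::new_alignment("protein", mat))
  expect_equal(vf3$validity, 0.75)
  expect_true(vf3$pass)
})

test_that("Fitch counts match textbook cases", {
  tr <- read_tree_text("((A:1,B:1):1,(C:1,D:1):1);")
  aln <- make_protein_aln(c(A = "V", B = "V", C = "I", D = "I"))
  fs <- fitch_states(tr, aln, 1)
  expect_equal(fs$count, 1)
  inv <- make_protein_aln(c(A = "V", B = "V", C = "V", D = "V"))
  fs2 <- fitch_states(tr, inv, 1)
  expect_equal(fs2$count, 0)
  expect_equal(fs2$state_sets[["N1"]], "V")
})

test_that("Fitch count equals the minimum over enumerated labelings", {
  set.seed(11)
  tr <- ape::rtree(8)
  tr <- read_tree_text(ape::write.tree(tr))
  resid <- c("A", "V", "I")
  for (rep in 1:5) {
    col <- stats::setNames(sample(resid, 8, replace = TRUE),
                            tr$tip.label)
    aln <- make_protein_aln(stats::setNames(col, tr$tip.label))
    fs <- fitch_states(tr, aln, 1)
    # brute force: enumerate internal labelings over the observed residues
    states <- unique(col)
    n_int <- tr$Nnode
    ntip <- ape::Ntip(tr)
    combos <- expand.grid(rep(list(states), n_int),
                          stringsAsFactors = FALSE)
    costs <- apply(combos, 1, function(lab) {
      full <- c(col[match(tr$tip.label, names(col))], unlist(lab))
      sum(full[tr$edge[, 1]] != full[tr$edge[, 2]])
    })
    expect_equal(fs$count, min(costs))
  }
})

test_that("marginal reconstruction matches a four-taxon enumeration", {
  tr <- read_tree_text("((A:0.1,B:0.15):0.07,(C:0.12,D:0.09):0.05);")
  aln <- make_protein_aln(c(A = "VK", B = "IK", C = "IR", D = "IR"))
  anc <- marginal_reconstruction(tr, aln)
  freqs <- cashmere:::observed_aa_freqs(aln)
  q <- cashmere:::aa_rate_matrix(freqs)
  edec <- cashmere:::gy94_eigen(q, freqs)
  pm <- function(t) cashmere:::gy94_prob(edec, t)
  trp <- anc$tree
  labs <- c(trp$tip.label, trp$node.label)
  # enumerate the three internal states (20^3) site by site
  aa <- cashmere:::VALID_AA
  p_e <- lapply(trp$edge.length, pm)
  for (site in 1:2) {
    obs <- match(aln$aa_matrix[trp$tip.label, site], aa)
    joint <- array(0, c(20, 20, 20))   # root, int1, int2 in edge order
    # identify node numbers
    root <- trp$edge[nrow(trp$edge), 1]
    ints <- setdiff(unique(trp$edge[, 1]), root)
    for (r in 1:20) for (i1 in 1:20) for (i2 in 1:20) {
      full <- integer(7)
      full[seq_along(trp$tip.label)] <- obs
      full[root] <- r; full[ints[1]] <- i1; full[ints[2]] <- i2
      pr <- freqs[r]
      for (e in seq_len(nrow(trp$edge)))
        pr <- pr * p_e[[e]][full[trp$edge[e, 1]], full[trp$edge[e, 2]]]
      joint[r, i1, i2] <- pr
    }
    post_root <- apply(joint, 1, sum) / sum(joint)
    post_i1 <- apply(joint, 2, sum) / sum(joint)
    post_i2 <- apply(joint, 3, sum) / sum(joint)
    # compare reported argmax states and posteriors
    expect_equal(unname(anc$states[root, site]), aa[which.max(post_root)])
    expect_equal(unname(anc$posterior[root, site]), unname(max(post_root)),
                 tolerance = 1e-9)
    expect_equal(unname(anc$states[ints[1], site]), aa[which.max(post_i1)])
    expect_equal(unname(anc$posterior[ints[1], site]), unname(max(post_i1)),
                 tolerance = 1e-9)
    expect_equal(unname(anc$states[ints[2], site]), aa[which.max(post_i2)])
    expect_equal(unname(anc$posterior[ints[2], site]), unname(max(post_i2)),
                 tolerance = 1e-9)
  }
})

test_that("invariant columns reconstruct to the shared residue", {
  tr <- eight_taxon_tree()
  aln <- make_protein_aln(stats::setNames(rep("KV", 8), tr$tip.label))
  anc <- marginal_reconstruction(tr, aln)
  expect_true(all(anc$states[, 1] == "K"))
  expect_true(all(anc$states[, 2] == "V"))
  expect_true(all(anc$posterior >= cashmere:::observed_aa_freqs(aln)[1]))
})

test_that("Fitch and marginal ML agree on zero-homoplasy data", {
  sim <- simulate_codon_data(eight_taxon_tree(), 1, 60, 2, 0.2, seed = 15)
  aln <- translate_codon_alignment(sim$alignments[[1]])
  anc <- marginal_reconstruction(eight_taxon_tree(), aln)
  trp <- anc$tree
  agree <- 0; total <- 0
  for (site in seq_len(aln$n_sites)) {
    fs <- fitch_states(trp, aln, site)
    # zero-homoplasy columns: parsimony count equals number of distinct
    # residues minus one
    if (fs$count != length(unique(aln$aa_matrix[, site])) - 1) next
    for (nd in trp$node.label) {
      if (length(fs$state_sets[[nd]]) == 1) {
        total <- total + 1
        if (fs$state_sets[[nd]] == anc$states[nd, site]) agree <- agree + 1
      }
    }
  }
  expect_gt(total, 20)
  expect_equal(agree, total)
})
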