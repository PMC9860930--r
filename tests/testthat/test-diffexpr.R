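# Size factors, dispersion, the NB Wald test and DEG calling.

test_that("size factors match hand-computed medians and scaling", {
  m <- matrix(c(10, 20, 30, 40,
                20, 40, 60, 80,
                5, 10, 15, 20,
                100, 200, 300, 400,
                8, 16, 24, 32), 5, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  sf <- size_factors(m)
  # every gene has the same cross-sample profile 1:2:3:4
  geo <- exp(rowMeans(log(m)))
  expect_equal(unname(sf),
               unname(apply(m / geo, 2, stats::median)), tolerance = 1e-12)
  # identical samples -> all factors 1
  m2 <- matrix(rep(c(3, 7, 11), 4), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m2)), rep(1, 4))
  # doubling one sample doubles its factor
  m3 <- cbind(m2, s5 = 2 * m2[, 1])
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3["s5"] / sf3["s1"]), 2, tolerance = 1e-12)
})

test_that("dispersion estimates hit the floor for Poisson-like genes", {
  set.seed(3)
  pois <- matrix(rpois(200 * 50, 100), 200, 50,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  alpha <- estimate_dispersion(pois, rep(1, 50))
  expect_lt(stats::median(alpha), 0.01)
  const <- matrix(5, 2, 10, dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(estimate_dispersion(const, rep(1, 10))),
               rep(1e-8, 2))
})

test_that("dispersion recovery brackets the simulated value", {
  set.seed(7)
  mu <- 200
  nb <- matrix(rnbinom(500 * 100, mu = mu, size = 1 / 0.2), 500, 100,
               dimnames = list(sprintf("g%03d", 1:500), NULL))
  alpha <- estimate_dispersion(nb, rep(1, 100))
  expect_gt(stats::median(alpha), 0.1)
  expect_lt(stats::median(alpha), 0.3)
})

test_that("planted fold-changes are recovered with correct sign", {
  se <- sim_expr()
  de <- fixture("de_run", function() nb_wald_test(se$counts, se$groups))
  truth <- se$truth$de_genes
  est <- de$log2fc[match(names(truth), de$gene)]
  expect_equal(stats::median(abs(est)), 2, tolerance = 0.15)
  expect_true(all(sign(est) == sign(truth)))
  degs <- call_degs(de)
  expect_gte(sum(degs$gene %in% names(truth)), 0.9 * length(truth))
  # empirical FDR among calls stays controlled
  fdr <- mean(!degs$gene %in% names(truth))
  expect_lte(fdr, 0.1)
})

test_that("label swap negates fold-changes and keeps p-values", {
  se <- sim_expr()
  de <- fixture("de_run", function() nb_wald_test(se$counts, se$groups))
  swapped <- se$groups
  swapped$group <- ifelse(swapped$group == "black", "zeta", "black")
  de2 <- nb_wald_test(se$counts, swapped)
  ix <- match(de$gene, de2$gene)
  expect_equal(de2$log2fc[ix], -de$log2fc, tolerance = 1e-6)
  expect_equal(de2$p_value[ix], de$p_value, tolerance = 1e-6)
})

test_that("scaling one sample leaves fold-changes invariant", {
  se <- sim_expr()
  counts2 <- se$counts
  counts2[, 1] <- counts2[, 1] * 3L
  de <- fixture("de_run", function() nb_wald_test(se$counts, se$groups))
  sf1 <- size_factors(se$counts); sf2 <- size_factors(counts2)
  # relative to another sample, the scaled sample's factor triples
  expect_equal(unname((sf2[1] / sf2[2]) / (sf1[1] / sf1[2])), 3,
               tolerance = 0.02)
  de2 <- nb_wald_test(counts2, se$groups)
  ix <- match(de$gene, de2$gene)
  expect_equal(de2$log2fc[ix], de$log2fc, tolerance = 0.1)
})

test_that("all-zero genes are excluded and q-values are BH-monotone", {
  se <- sim_expr()
  counts <- se$counts
  counts["G0001", ] <- 0L
  de <- nb_wald_test(counts, se$groups)
  expect_false("G0001" %in% de$gene)
  ord <- order(de$p_value[de$converged])
  q <- de$q_value[de$converged][ord]
  expect_true(all(diff(q) >= -1e-12))
  expect_true(all(q >= de$p_value[de$converged][ord] - 1e-12))
})

test_that("DEG calling uses strict inequalities at both boundaries", {
  res <- tibble::tibble(gene = c("a", "b", "c"),
                        base_mean = 10, log2fc = c(1.0, 1.5, -2),
                        se_log2fc = 0.1, wald_z = 5,
                        p_value = c(0.001, 0.001, 0.001),
                        q_value = c(0.01, 0.05, 0.01),
                        converged = TRUE, capped = FALSE,
                        group2 = "cashmere")
  deg <- call_degs(res, lfc_threshold = 1.0, fdr_threshold = 0.05)
  expect_equal(deg$gene, "c")          # a: lfc not > 1; b: q not < 0.05
  expect_equal(deg$direction, "down")
  expect_equal(attr(deg, "n_down"), 1)
})

test_that("the NB Wald test agrees with an established NB GLM fitter", {
  skip_if_not_installed("DESeq2")
  se <- sim_expr()
  counts <- se$counts[1:80, ]
  cd <- data.frame(condition = factor(se$groups$group,
                                      levels = c("black", "cashmere")))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, cd, ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, fitType = "mean")
  rr <- DESeq2::results(dds)
  de <- nb_wald_test(counts, se$groups)
  ix <- match(de$gene, rownames(rr))
  # same model family, different dispersion treatment: estimates track
  r <- stats::cor(de$log2fc, rr$log2FoldChange[ix])
  expect_gt(r, 0.98)
  expect_lt(stats::median(abs(de$log2fc - rr$log2FoldChange[ix])), 0.15)
})
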