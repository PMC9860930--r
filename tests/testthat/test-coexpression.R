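# WGCNA-core operations: filters, soft threshold, TOM, module detection,
# eigengenes, merging, module-trait correlation and hubs.

test_that("SD filter keeps the boundary gene", {
  m <- rbind(a = rep(1, 10), b = seq(0, 3, length.out = 10))
  m <- rbind(m, c = scale(rnorm(10))[, 1] * 0.5)   # SD exactly 0.5
  expect_equal(rownames(filter_by_sd(m, 0.5)), c("b", "c"))
})

test_that("outlier screen is report-only by default and flags shifts", {
  se <- sim_expr()
  expr <- se$normalized[1:100, ]
  out <- detect_sample_outliers(expr)
  expect_equal(out$retained, colnames(expr))
  expect_equal(out$outliers, character(0))
  # one sample shifted far away gets flagged below its merge height
  expr2 <- expr
  expr2[, 1] <- expr2[, 1] + 50
  hc <- detect_sample_outliers(expr2)$hclust
  cut <- max(hc$height) * 0.5
  out2 <- detect_sample_outliers(expr2, cut_height = cut)
  expect_equal(out2$outliers, colnames(expr)[1])
})

test_that("soft threshold selection reaches the scale-free target", {
  se <- sim_expr()
  expr <- filter_by_sd(se$normalized, 0.5)
  st <- pick_soft_threshold(expr, target_r2 = 0.85)
  expect_true(is.finite(st$power))
  expect_gte(st$fit_table$r2[st$fit_table$power == st$power], 0.85)
  # degenerate target: power 1 always qualifies when r2 >= 0
  st0 <- pick_soft_threshold(expr, target_r2 = 0)
  expect_equal(st0$power, 1)
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # two connected nodes only: TOM = 1
  a <- diag(2); a[1, 2] <- a[2, 1] <- 1
  expect_equal(tom_matrix(a)[1, 2], 1)
  # empty adjacency: off-diagonal zero
  expect_equal(tom_matrix(diag(3))[1, 2], 0)
  # random 5-node adjacency vs direct triple loop
  set.seed(2)
  a5 <- matrix(runif(25), 5); a5 <- (a5 + t(a5)) / 2; diag(a5) <- 1
  tom <- tom_matrix(a5)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    l <- sum(vapply(setdiff(1:5, c(i, j)), function(u)
      a5[i, u] * a5[u, j], 0))
    k_i <- sum(a5[i, -i]); k_j <- sum(a5[j, -j])
    expect_equal(tom[i, j], (l + a5[i, j]) / (min(k_i, k_j) + 1 - a5[i, j]),
                 tolerance = 1e-12)
  }
})

test_that("TOM stays in [0,1] for random adjacencies", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    a <- matrix(runif(n * n), n); a <- (a + t(a)) / 2; diag(a) <- 1
    tom <- tom_matrix(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("module cutting recovers planted blocks and ignores noise", {
  set.seed(31)
  lat1 <- rnorm(40); lat2 <- rnorm(40)
  block <- function(lat, n) t(replicate(n, sqrt(0.9) * lat +
                                          sqrt(0.1) * rnorm(40)))
  expr <- rbind(block(lat1, 50), block(lat2, 50))
  rownames(expr) <- paste0("g", 1:100)
  tom <- tom_matrix(adjacency_matrix(expr, 6))
  labels <- cut_modules(1 - tom, 30)
  truth <- rep(1:2, each = 50)
  expect_equal(length(unique(labels[labels > 0])), 2)
  expect_equal(mclust::adjustedRandIndex(labels, truth), 1)

  # independent noise genes produce no module at min size 30
  noise <- matrix(rnorm(20 * 40), 20, dimnames = list(paste0("n", 1:20),
                                                      NULL))
  tn <- tom_matrix(adjacency_matrix(noise, 6))
  expect_true(all(cut_modules(1 - tn, 30) == 0))
})

test_that("eigengenes are stable to gene sign flips and track latents", {
  se <- sim_expr()
  expr <- se$normalized[1:50, ]          # planted module 1
  labels <- stats::setNames(rep(1L, 50), rownames(expr))
  me <- module_eigengene(expr, labels)
  expect_equal(nrow(me), 1)
  expect_equal(stats::sd(me[1, ]), 1, tolerance = 1e-9)
  r <- abs(stats::cor(me[1, ], se$truth$module_latent[1, ]))
  expect_gt(r, 0.9)
  # flipping every gene leaves the aligned eigengene direction usable
  me2 <- module_eigengene(-expr, labels)
  expect_gt(abs(stats::cor(me[1, ], me2[1, ])), 0.999)
})

test_that("module merging respects the dissimilarity threshold", {
  set.seed(41)
  lat <- rnorm(30)
  blockA <- t(replicate(40, lat + 0.35 * rnorm(30)))
  blockB <- t(replicate(40, lat + 0.35 * rnorm(30)))   # same driver
  blockC <- t(replicate(40, -lat + 0.35 * rnorm(30)))  # anti-correlated
  expr <- rbind(blockA, blockB, blockC)
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  labels <- stats::setNames(rep(1:3, each = 40), rownames(expr))
  merged <- merge_modules(expr, labels, 0.25)
  # A and B merge (cor ~ 0.9 -> diss ~ 0.1); C stays (diss ~ 1.8)
  expect_equal(length(unique(merged$labels[merged$labels > 0])), 2)
  m_ab <- unique(merged$labels[1:80])
  expect_length(m_ab, 1)
  expect_false(unique(merged$labels[81:120]) == m_ab)
  # idempotence
  again <- merge_modules(expr, merged$labels, 0.25)
  expect_identical(again$labels, merged$labels)
})

test_that("module-trait correlation reproduces the closed-form t test", {
  # n = 50, r = 0.28 -> p ~ 0.049
  tt <- 0.28 * sqrt(48) / sqrt(1 - 0.28^2)
  p <- 2 * stats::pt(tt, df = 48, lower.tail = FALSE)
  expect_equal(p, 0.0488, tolerance = 0.01)
  # ME identical to the trait: r = 1, p -> 0
  me <- matrix(rnorm(20), 1, dimnames = list("ME1", sprintf("s%02d", 1:20)))
  traits <- matrix(me[1, ], 20, 1,
                   dimnames = list(colnames(me), "anagen"))
  expr <- matrix(rnorm(40), 2, 20,
                 dimnames = list(c("g1", "g2"), colnames(me)))
  res <- module_trait_and_hubs(expr, me, stats::setNames(c(1L, 1L),
                                                         c("g1", "g2")),
                               traits, trait = "anagen")
  row <- res$module_trait[res$module_trait$trait == "anagen", ]
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_lt(row$p, 1e-12)
})

test_that("the full workflow recovers planted modules and hubs", {
  se <- sim_expr()
  cx <- fixture("coexpr_run", function()
    run_coexpression(se$normalized, se$traits))
  truth <- se$truth$module_assignment[names(cx$labels)]
  planted <- truth > 0
  ari <- mclust::adjustedRandIndex(truth[planted], cx$labels[planted])
  expect_gte(ari, 0.9)
  cors <- abs(stats::cor(t(cx$eigengenes), t(se$truth$module_latent)))
  expect_true(all(apply(cors, 2, max) > 0.9))
  # hub genes concentrate in the planted anagen-linked module (module 1)
  hub_genes <- cx$hubs$gene[cx$hubs$hub]
  expect_gt(length(hub_genes), 0)
  expect_true(all(truth[hub_genes] == 1))
  # determinism: identical input, identical labels
  cx2 <- run_coexpression(se$normalized, se$traits)
  expect_identical(cx$labels, cx2$labels)
})
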