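test_that("probe collapse takes per-gene medians and shares probes", {
  pm <- matrix(c(3, 5, 9, 2, 4, 8), nrow = 3,
               dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("gA", "gA", "gA"))
  out <- collapse_probes(pm, map)
  expect_equal(unname(out["gA", ]), c(5, 4))  # odd-count median

  map2 <- data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
  expect_warning(out2 <- collapse_probes(pm, map2), "unmapped")
  expect_equal(unname(out2["gA", "s1"]), 4)   # even-count median

  # one probe shared by two genes: identical rows
  map3 <- data.frame(probe_id = c("p1", "p1"), gene_id = c("gA", "gB"))
  out3 <- suppressWarnings(collapse_probes(pm, map3))
  expect_equal(out3["gA", ], out3["gB", ])
  expect_equal(unname(out3["gA", ]), unname(pm["p1", ]))  # single probe: identity
})

test_that("gene-wise normalization gives zero-mean unit-SD rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(10, 0, 20))
  colnames(m) <- c("s1", "s2", "s3")
  expect_message(norm <- genewise_normalize(m), "constant")
  expect_equal(unname(norm["a", ]), c(-1, 0, 1))
  expect_equal(unname(norm["b", ]), c(0, 0, 0))
  expect_equal(mean(norm["c", ]), 0)
  expect_equal(sd(norm["c", ]), 1)
  expect_error(genewise_normalize(m[, 1, drop = FALSE]), "two samples")
})

test_that("clustering merges perfectly correlated profiles first", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1))
  colnames(m) <- c("s1", "s2", "s3")
  hc <- cluster_genes(m)
  first <- sort(-hc$merge[1, ])
  expect_equal(first, c(1, 2))              # g1, g2 at r = 1
  expect_equal(hc$height[1], 0)

  two <- cluster_genes(m[1:2, ])
  expect_equal(nrow(two$merge), 1L)
  expect_equal(two$height, 1 - cor(m[1, ], m[2, ]))
})

test_that("average-linkage merges equal the naive agglomeration oracle", {
  set.seed(910)
  for (rep in 1:8) {
    m <- matrix(rnorm(5 * 6), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    hc <- cluster_genes(m)
    oracle <- naive_upgma(m)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
    expect_identical(hclust_members(hc), oracle$members)
  }
})

test_that("clustering is invariant to positive per-row affine transforms", {
  set.seed(911)
  m <- matrix(rnorm(5 * 6), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  scaled <- m * runif(5, 0.5, 4) + rnorm(5)
  expect_equal(cluster_genes(m)$merge, cluster_genes(scaled)$merge)
  expect_equal(cluster_genes(m)$height, cluster_genes(scaled)$height)
})

test_that("expressed sets threshold normalized values at tau", {
  m <- rbind(g1 = c(-1, 0, 1), g2 = c(0, 0, 0))
  colnames(m) <- c("Rt", "YL", "XL")
  sets <- expressed_sets(m)
  expect_equal(sets$g1, "XL")
  expect_equal(sets$g2, character(0))
  expect_equal(expressed_sets(m, tau = -2)$g1, c("Rt", "YL", "XL"))
})

test_that("pair categories encode the four set relations", {
  expect_equal(categorize_pair(c("Rt", "XL"), "YL")$category, 1L)
  expect_equal(categorize_pair(c("Rt", "XL"), c("XL", "Rt"))$category, 2L)
  expect_equal(categorize_pair("Rt", c("Rt", "XL"))$category, 3L)
  expect_equal(categorize_pair(c("Rt", "YL"), c("Rt", "XL"))$category, 4L)
  both_empty <- categorize_pair(character(0), character(0))
  expect_equal(both_empty$category, 2L)
  expect_match(both_empty$note, "empty")
  # symmetric up to subset direction
  ab <- categorize_pair("Rt", c("Rt", "XL"))
  ba <- categorize_pair(c("Rt", "XL"), "Rt")
  expect_equal(ab$category, ba$category)
  expect_equal(ab$subset_direction, "A_in_B")
  expect_equal(ba$subset_direction, "B_in_A")
  set.seed(912)
  labels <- c("Rt", "ML", "YL", "FC", "MC", "XL")
  for (rep in 1:20) {
    A <- sample(labels, sample(0:5, 1))
    B <- sample(labels, sample(0:5, 1))
    expect_equal(categorize_pair(A, B)$category,
                 categorize_pair(B, A)$category)
  }
})

test_that("highest tissue is the argmax with first-label tie-breaking", {
  m <- rbind(g1 = c(0.1, 5.0, 2.0), g2 = c(5, 5, 1))
  colnames(m) <- c("Rt", "YL", "XL")
  expect_message(top <- highest_tissue(m), "tied")
  expect_equal(unname(top["g1"]), "YL")
  expect_equal(unname(top["g2"]), "Rt")
})

test_that("relative expression follows the delta-Ct closed form", {
  expect_equal(relative_expression(25, 20), 0.03125)
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(20, 25), 32)
  expect_error(relative_expression(-1, 20))
})

test_that("planted expression categories are recovered exactly at zero noise", {
  sim <- gen_expression(pair_categories = rep(1:4, 3), noise_sd = 0,
                        seed = 21L)
  norm <- genewise_normalize(sim$matrix)
  sets <- expressed_sets(norm)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    got <- categorize_pair(sets[[truth$gene1[i]]], sets[[truth$gene2[i]]])
    expect_equal(got$category, truth$category[i],
                 info = paste("pair", truth$pair_id[i]))
  }
})
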