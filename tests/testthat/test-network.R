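test_that("adjacency is |cor|^power with unsigned handling and zero diagonal", {
  x <- withr::with_seed(1, matrix(rnorm(40), 4, 10,
                                  dimnames = list(paste0("P", 1:4), NULL)))
  x[2, ] <- 2 * x[1, ] + 3           # r = 1 with probe 1
  x[3, ] <- -x[1, ]                  # r = -1
  a <- adjacency_matrix(x, power = 8)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 1)           # unsigned: |-1|^8
  expect_equal(diag(a), rep(0, 4), ignore_attr = TRUE)
  ## beta = 1 gives |r| exactly; 0.5^8 spot value
  r <- stats::cor(t(x))
  expect_equal(adjacency_matrix(x, power = 1)[1, 4], abs(r[1, 4]))
  expect_equal(0.5^8, 0.00390625)
  ## affine rescaling of a probe profile leaves adjacency unchanged
  y <- x; y[4, ] <- 5 * x[4, ] - 7
  expect_equal(adjacency_matrix(y), a, tolerance = 1e-12)
  ## constant probes correlate 0 with everything
  z <- x; z[4, ] <- 1
  expect_equal(adjacency_matrix(z)[4, ], rep(0, 4), ignore_attr = TRUE)
  expect_error(adjacency_matrix(x[, 1:2]), ">= 3 samples")
})

test_that("TOM formula: saturated and empty graphs, symmetry guard", {
  a1 <- matrix(1, 3, 3); diag(a1) <- 0
  expect_equal(tom_similarity(a1), matrix(1, 3, 3))   # (1+1)/(2+1-1) = 1
  a0 <- matrix(0, 4, 4)
  t0 <- tom_similarity(a0)
  expect_equal(diag(t0), rep(1, 4))
  expect_equal(t0[upper.tri(t0)], rep(0, 6))
  bad <- matrix(runif(9), 3, 3)
  expect_error(tom_similarity(bad), "asymmetric")
})

test_that("TOM equals the naive O(n^3) oracle on random matrices", {
  for (s in 1:3) {
    a <- withr::with_seed(s, {
      m <- matrix(stats::runif(50 * 50), 50, 50); m <- (m + t(m)) / 2
      diag(m) <- 0; m
    })
    fast <- tom_similarity(a)
    expect_lt(max(abs(fast - naive_tom(a))), 1e-12)
    expect_true(all(fast >= 0 & fast <= 1 + 1e-12))
    expect_equal(fast, t(fast))
  }
})

test_that("average-linkage dendrogram separates blocks and has monotone heights", {
  n <- 20
  d <- matrix(1, n, n)
  d[1:10, 1:10] <- 0; d[11:20, 11:20] <- 0; diag(d) <- 0
  tree <- cluster_dendrogram(d)
  expect_true(all(diff(tree$height) >= -1e-12))
  top <- stats::cutree(tree, k = 2)
  expect_equal(length(unique(top[1:10])), 1)
  expect_equal(length(unique(top[11:20])), 1)
  expect_error(cluster_dendrogram(matrix(NaN, 2, 2)), "non-finite")
})

test_that("dendrogram is invariant to probe permutation (up to relabelling)", {
  d <- 1 - random_sym(30, seed = 5)
  diag(d) <- 0
  tree <- cluster_dendrogram(d)
  perm <- withr::with_seed(6, sample(30))
  tree_p <- cluster_dendrogram(d[perm, perm])
  expect_equal(sort(tree$height), sort(tree_p$height), tolerance = 1e-12)
  ## partitions at a mid height agree after undoing the permutation
  h <- stats::median(tree$height)
  c1 <- stats::cutree(tree, h = h)
  c2 <- stats::cutree(tree_p, h = h)[order(perm)]
  expect_equal(ari_of(c1, c2), 1)
})

block_diss <- function(sizes, within = 0.05, between = 0.95, seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  withr::with_seed(seed, {
    d <- matrix(stats::runif(n * n, between - 0.03, between + 0.03), n, n)
    for (g in seq_along(sizes)) {
      idx <- which(lab == g)
      d[idx, idx] <- stats::runif(length(idx)^2, within, within + 0.05)
    }
    d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(sprintf("P%03d", 1:n), sprintf("P%03d", 1:n))
    list(d = d, lab = lab)
  })
}

test_that("dynamic cut recovers planted blocks and dissolves small/noise structure", {
  bl <- block_diss(c(50, 50), seed = 11)
  part <- dynamic_tree_cut(cluster_dendrogram(bl$d), bl$d)
  expect_equal(length(setdiff(unique(part$module), "grey")), 2)
  expect_gte(ari_of(part$module, bl$lab), 0.9)
  ## all-noise dissimilarity: most probes grey
  nz <- withr::with_seed(12, {
    m <- matrix(stats::runif(200 * 200, 0.9, 1), 200, 200)
    m <- (m + t(m)) / 2; diag(m) <- 0; m
  })
  pnz <- dynamic_tree_cut(cluster_dendrogram(nz), nz)
  expect_gt(mean(pnz$module == "grey"), 0.5)
  ## a tight 5-probe cluster below min_size dissolves into grey
  bl5 <- block_diss(c(5, 40), seed = 13)
  p5 <- dynamic_tree_cut(cluster_dendrogram(bl5$d), bl5$d, min_size = 8)
  expect_true(all(p5$module[1:5] == "grey"))
})

test_that("deep_split = FALSE only cuts at the static ceiling", {
  bl <- block_diss(c(30, 30), within = 0.2, between = 0.7, seed = 14)
  ## both blocks join below the ceiling: without deep split they stay together
  part <- dynamic_tree_cut(cluster_dendrogram(bl$d), bl$d, cut_height = 0.995,
                           deep_split = FALSE, tightness = 0.99)
  expect_equal(length(setdiff(unique(part$module), "grey")), 1)
  part2 <- dynamic_tree_cut(cluster_dendrogram(bl$d), bl$d, cut_height = 0.995,
                            deep_split = TRUE, tightness = 0.99)
  expect_equal(length(setdiff(unique(part2$module), "grey")), 2)
})

test_that("module eigengene is PC1: reproduces shared profiles, optimal, sign-fixed", {
  prof <- sin(seq(0, 3, length.out = 12))
  x <- withr::with_seed(2, {
    m <- t(vapply(1:15, function(i) 2 + i * prof, numeric(12)))
    m + matrix(rnorm(15 * 12, 0, 1e-6), 15, 12)
  })
  dimnames(x) <- list(sprintf("P%02d", 1:15), sprintf("s%02d", 1:12))
  part <- tibble::tibble(probe = rownames(x), module = "M1")
  me <- module_eigengenes(x, part)
  expect_equal(abs(stats::cor(me[, 1], prof)), 1, tolerance = 1e-6)
  expect_gte(stats::cor(me[, 1], colMeans(x)), 0)       # sign convention
  ## PC1 optimality: explains at least as much variance as any single probe
  z <- t(scale(t(x)))
  var_me <- sum((z %*% me[, 1])^2)
  var_probe <- max(vapply(seq_len(nrow(z)), function(i) {
    v <- z[i, ] / sqrt(sum(z[i, ]^2)); sum((z %*% v)^2)
  }, numeric(1)))
  expect_gte(var_me + 1e-8, var_probe)
})

test_that("eigengene merging collapses similar modules and never raises the count", {
  prof1 <- seq(0, 1, length.out = 12)
  prof2 <- rev(prof1)
  x <- withr::with_seed(3, rbind(
    t(vapply(1:12, function(i) i * prof1 + rnorm(12, 0, 0.01), numeric(12))),
    t(vapply(1:12, function(i) i * prof1 + rnorm(12, 0, 0.01), numeric(12))),
    t(vapply(1:12, function(i) i * prof2 + rnorm(12, 0, 0.01), numeric(12)))))
  dimnames(x) <- list(sprintf("P%02d", 1:36), sprintf("s%02d", 1:12))
  part <- tibble::tibble(probe = rownames(x),
                         module = rep(c("M1", "M2", "M3"), each = 12))
  merged <- merge_modules(x, part, merge_cut = 0.2)
  mods <- setdiff(unique(merged$module), "grey")
  expect_equal(length(mods), 2)                       # M1/M2 merged, M3 apart
  expect_equal(length(unique(merged$module[1:24])), 1)
  expect_false(unique(merged$module[25:36]) %in% merged$module[1:24])
  ## anticorrelated eigengenes (diss ~ 2) are never merged
  expect_lte(length(mods), 3)
  ## grey untouched
  part$module[1] <- "grey"
  merged2 <- merge_modules(x, part, merge_cut = 0.2)
  expect_equal(merged2$module[1], "grey")
})

test_that("intramodular connectivity sums adjacency within the module", {
  a <- matrix(1, 3, 3); diag(a) <- 0
  dimnames(a) <- list(paste0("P", 1:3), paste0("P", 1:3))
  part <- tibble::tibble(probe = paste0("P", 1:3), module = "M1")
  expect_equal(intramodular_connectivity(a, part)$k_within, rep(2, 3))
  part$module <- c("M1", "M2", "M3")                  # singletons
  expect_equal(intramodular_connectivity(a, part)$k_within, rep(0, 3))
  ## brute-force oracle on a random instance
  n <- 25
  a2 <- random_sym(n, seed = 7); diag(a2) <- 0
  labs <- withr::with_seed(8, sample(c("M1", "M2", "grey"), n, replace = TRUE))
  part2 <- tibble::tibble(probe = rownames(a2), module = labs)
  got <- intramodular_connectivity(a2, part2)
  want <- vapply(seq_len(n), function(i)
    sum(a2[i, setdiff(which(labs == labs[i]), i)]), numeric(1))
  expect_equal(got$k_within, want, tolerance = 1e-12)
})

test_that("top_edges returns the strongest pairs, each once, sorted", {
  tom <- random_sym(4, seed = 9)
  edges <- top_edges(tom, budget = 3)
  expect_equal(nrow(edges), 3)
  expect_true(all(edges$from < edges$to))
  expect_true(all(diff(edges$weight) <= 0))
  all6 <- top_edges(tom, budget = 100)
  expect_equal(nrow(all6), 6)
  expect_equal(edges$weight, sort(tom[upper.tri(tom)], decreasing = TRUE)[1:3])
})

test_that("betweenness: path, complete graph, star, and BFS oracle", {
  path <- tibble::tibble(from = c("A", "B"), to = c("B", "C"))
  b <- node_betweenness(path)
  expect_equal(b$betweenness[b$probe == "B"], 1)
  expect_equal(sum(b$betweenness[b$probe != "B"]), 0)
  ## complete graph: all zero
  cg <- t(utils::combn(LETTERS[1:5], 2))
  bc <- node_betweenness(tibble::tibble(from = cg[, 1], to = cg[, 2]))
  expect_true(all(bc$betweenness == 0))
  ## star with 4 leaves: center carries C(4,2) = 6
  star <- tibble::tibble(from = "hub", to = paste0("L", 1:4))
  bs <- node_betweenness(star)
  expect_equal(bs$betweenness[bs$probe == "hub"], 6)
  ## random-graph battery against the path-counting oracle
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(8:20, 1))
    adj <- withr::with_seed(s + 100, {
      m <- matrix(stats::runif(n * n) < 0.25, n, n)
      m <- m | t(m); diag(m) <- FALSE; m
    })
    ids <- sprintf("N%02d", seq_len(n))
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(idx)) next
    edges <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]])
    got <- node_betweenness(edges)
    want <- oracle_betweenness(adj)
    present <- ids %in% c(edges$from, edges$to)
    expect_equal(got$betweenness[match(ids[present], got$probe)],
                 want[present], tolerance = 1e-9)
  }
})
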