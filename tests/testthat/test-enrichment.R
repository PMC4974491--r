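test_that("annotation propagation reaches every ancestor over is_a/part_of", {
  onto <- list(
    terms = tibble::tibble(id = c("A", "B", "C"), name = c("root", "mid", "leaf")),
    edges = tibble::tibble(child = c("B", "C"), parent = c("A", "B"),
                           relation = "is_a"))
  annot <- tibble::tibble(gene = "g1", term = "C")
  db <- propagate_annotations(onto, annot)
  expect_setequal(db$set[db$gene == "g1"], c("A", "B", "C"))
  ## diamond: two paths to the root, gene counted once (set semantics)
  onto2 <- list(
    terms = tibble::tibble(id = c("R", "P1", "P2", "L"), name = NA),
    edges = tibble::tibble(child = c("P1", "P2", "L", "L"),
                           parent = c("R", "R", "P1", "P2"),
                           relation = c("is_a", "is_a", "is_a", "part_of")))
  db2 <- propagate_annotations(onto2, tibble::tibble(gene = "g", term = "L"))
  expect_equal(sum(db2$set == "R" & db2$gene == "g"), 1)
  ## unknown terms are dropped with a warning
  expect_warning(propagate_annotations(onto, tibble::tibble(gene = "g", term = "ZZ")),
                 "unknown")
})

test_that("propagated sets grow monotonically toward the root", {
  truth <- tibble::tibble(probe = sprintf("P%03d", 1:80),
                          module = rep(c("m1", "m2", "background"), c(30, 20, 30)))
  sim <- simulate_ontology(truth, depth = 4, seed = 2)
  db <- propagate_annotations(sim$ontology, sim$annotations)
  sizes <- table(db$set)
  for (i in seq_len(nrow(sim$ontology$edges))) {
    ch <- sim$ontology$edges$child[i]; pa <- sim$ontology$edges$parent[i]
    expect_gte(sizes[pa], sizes[ch])
  }
  ## the root's set is the union of all annotated genes
  expect_equal(unname(sizes["T:0000000"]), length(unique(sim$annotations$gene)))
  ## a leaf with 10+ genes keeps at least as many at the root
  expect_gte(unname(sizes["T:0000000"]), 10)
})

test_that("hypergeometric enrichment: exact single-tail case and expectation case", {
  pop <- sprintf("G%02d", 1:20)
  sig <- pop[1:5]
  res <- hypergeom_enrich(pop[1:5], sig, pop)       # k = 5 of 5
  expect_equal(res$p_enrich, 1 / choose(20, 5), tolerance = 1e-12)
  expect_gt(res$z, 3)
  ## k at expectation with symmetric distribution: z near 0
  pop2 <- sprintf("G%02d", 1:40)
  res2 <- hypergeom_enrich(pop2[1:20], pop2[11:30], pop2)  # k = 10 = n*K/N
  expect_lt(abs(res2$z), 0.5)
  expect_error(hypergeom_enrich(c("G01", "NOPE"), sig, pop), "outside")
})

test_that("hypergeometric tails match enumeration; tails overlap at k", {
  withr::with_seed(7, {
    for (rep in 1:30) {
      N <- sample(10:60, 1)
      pop <- sprintf("G%03d", seq_len(N))
      K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
      sig <- sample(pop, K); lst <- sample(pop, n)
      res <- hypergeom_enrich(lst, sig, pop)
      k <- res$k
      expect_equal(res$p_enrich, enum_hyper_tail(k, N, K, n, TRUE), tolerance = 1e-10)
      expect_equal(res$p_deplete, enum_hyper_tail(k, N, K, n, FALSE), tolerance = 1e-10)
      expect_gte(res$p_enrich + res$p_deplete, 1)   # both tails include P(X = k)
    }
  })
})

test_that("trend split sums consecutive differences and applies SD/size filters", {
  ## profile [1, 3, 2] over three timepoints, one donor
  x <- matrix(c(1, 3, 2,
                5, 5, 5,
                4, 3, 1), 3, 3, byrow = TRUE)
  dimnames(x) <- list(c("Pup", "Pflat", "Pdn"),
                      sprintf("none_t%03d_d1", c(0, 2, 4)))
  part <- tibble::tibble(probe = rownames(x), module = "M1")
  tl <- trend_split(part, x, "none", sd_min = 0.2, min_genes = 1)
  expect_equal(tl$trend[tl$probe == "Pup"], 1)        # (3-1) + (2-3)
  expect_equal(tl$direction[tl$probe == "Pup"], "up")
  expect_equal(tl$direction[tl$probe == "Pdn"], "down")
  expect_false("Pflat" %in% tl$probe)                 # SD = 0 <= 0.2 dropped
  ## telescoping: trend equals last minus first, exactly
  expect_equal(tl$trend, x[tl$probe, 3] - x[tl$probe, 1], ignore_attr = TRUE)
  ## lists below min_genes are discarded
  tl5 <- trend_split(part, x, "none", sd_min = 0.2, min_genes = 5)
  expect_equal(nrow(tl5), 0)
  expect_error(trend_split(part, x[, 1, drop = FALSE], "none"), "2 time points")
})

test_that("trend telescoping identity holds on simulated data", {
  mods <- tibble::tibble(
    name = c("m_dn", "m_up"), size = c(40L, 30L),
    kind = c("monotone_down", "monotone_up"), amplitude = c(4, 4),
    conditions = list(c("none", "ifn_alpha", "ifn_gamma"),
                      c("none", "ifn_alpha", "ifn_gamma")))
  sim <- simulate_timecourse(simulation_config(n_probes = 150, seed = 6,
                                               modules = mods))
  part <- tibble::tibble(probe = sim$truth$probe,
                         module = ifelse(sim$truth$module == "background",
                                         "grey", sim$truth$module))
  tl <- trend_split(part, sim$exprs, "ifn_alpha")
  sel <- sim$samples[sim$samples$condition == "ifn_alpha", ]
  tps <- range(sel$timepoint)
  first <- rowMeans(sim$exprs[tl$probe, sel$sample[sel$timepoint == tps[1]]])
  last <- rowMeans(sim$exprs[tl$probe, sel$sample[sel$timepoint == tps[2]]])
  expect_equal(tl$trend, unname(last - first), tolerance = 1e-12)
  expect_true(all(tl$sd > 0.2))
  expect_true(all(table(tl$list) >= 5))
  ## up and down lists are disjoint
  expect_equal(length(intersect(tl$probe[tl$direction == "up"],
                                tl$probe[tl$direction == "down"])), 0)
})

test_that("enrichment matrix zeroes weak evidence and drops empty columns", {
  pop <- sprintf("G%03d", 1:400)
  lists <- tibble::tibble(
    module = rep(c("M1", "M2"), each = 20),
    direction = "up",
    list = rep(c("M1_up", "M2_up"), each = 20),
    probe = c(pop[1:20], pop[201:220]),
    trend = 1, sd = 1)
  db <- tibble::tibble(set = rep(c("HIT", "NULL20"), c(25, 20)),
                       gene = c(pop[1:25], pop[381:400]))
  z <- enrichment_matrix(lists, db, pop)
  expect_gt(z["HIT", "M1_up"], 2)
  ## NULL20 vs M1_up: overlap 0, expectation 1 -> neither tail significant -> 0
  ## then the all-zero row is removed
  expect_false("NULL20" %in% rownames(z))
  expect_true(all(abs(z[z != 0]) >= stats::qnorm(0.95) - 1e-9))
  ## a list with no enrichment at all is dropped as a column
  lists2 <- dplyr::bind_rows(lists, tibble::tibble(
    module = "M3", direction = "up", list = "M3_up",
    probe = pop[301:320], trend = 1, sd = 1))
  z2 <- enrichment_matrix(lists2, db, pop)
  expect_false("M3_up" %in% colnames(z2))
  expect_equal(ncol(z2), ncol(z))
})

test_that("GMT round-trip, deduplication and empty-line handling", {
  db <- tibble::tibble(set = rep(c("S1", "S2", "S3"), each = 3),
                       gene = c("a", "b", "c", "d", "e", "f", "g", "h", "i"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  back <- read_gmt(path)
  expect_equal(length(unique(back$set)), 3)
  expect_setequal(back$gene[back$set == "S1"], c("a", "b", "c"))
  ## duplicated member within a line collapses
  writeLines("DUP\tdesc\tx\tx\ty", path)
  expect_equal(read_gmt(path)$gene, c("x", "y"))
  ## empty set line skipped with warning; duplicate names suffixed
  writeLines(c("A\td\tx", "A\td\ty", "BAD\tdesc"), path)
  expect_warning(out <- read_gmt(path), "skipped")
  expect_setequal(unique(out$set), c("A", "A.1"))
})
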