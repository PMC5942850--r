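test_that("gene hit probabilities are length-proportional and normalised", {
  eq <- gene_table(data.frame(gene_id = letters[1:10],
                              start = (0:9) * 100 + 1, end = (0:9) * 100 + 100))
  expect_equal(unname(gene_hit_probability(eq)), rep(0.1, 10))
  g3 <- gene_table(data.frame(gene_id = c("a", "b", "c"),
                              start = c(1, 101, 401),
                              end = c(100, 400, 1000)))
  expect_equal(unname(gene_hit_probability(g3)), c(0.1, 0.3, 0.6))
  expect_equal(sum(gene_hit_probability(g3)), 1)
})

test_that("replicate-subset counts are binomial coefficients", {
  expect_equal(count_replicate_subsets(32, 2), 496)
  expect_equal(count_replicate_subsets(32, 1), 32)
  # enumeration oracle for a small case
  expect_equal(count_replicate_subsets(5, 3), ncol(utils::combn(5, 3)))
})

test_that("enrichment probability reproduces hand-evaluated cases", {
  # single subset: n_r = {1,1}, n_g = 2, p = 0.5 -> 1*1*0.25*0.5^0
  expect_equal(enrichment_probability(c(1, 1), 2, 0.5), 0.25)
  # three subsets of size 2 over n_r = {1,1,1}: 3 * 0.25 * 0.5
  expect_equal(enrichment_probability(c(1, 1, 1), 2, 0.5), 0.375)
  # n_r = {2,1}: 2*1 * 0.1^2 * 0.9^0
  expect_equal(enrichment_probability(c(2, 1), 2, 0.1), 0.02)
  # p_g = 0 with a hit is impossible under the null
  expect_equal(enrichment_probability(c(1, 1), 1, 0), 0)
})

test_that("with unit replicate counts the statistic is the binomial pmf", {
  for (R in c(3, 5, 8, 10)) {
    for (p in c(0.01, 0.1, 0.3, 0.49)) {
      for (ng in seq_len(R)) {
        expect_equal(enrichment_probability(rep(1, R), ng, p),
                     stats::dbinom(ng, R, p), tolerance = 1e-12)
      }
    }
  }
})

test_that("dynamic program equals enumeration wherever both run", {
  set.seed(4)
  for (i in 1:25) {
    R <- sample(3:9, 1)
    n_r <- sample(0:5, R, replace = TRUE)
    ng_max <- sum(n_r > 0)
    if (ng_max == 0) next
    ng <- sample(seq_len(min(ng_max, R)), 1)
    p <- stats::runif(1, 0.001, 0.6)
    a <- enrichment_probability(n_r, ng, p, method = "enumerate")
    b <- enrichment_probability(n_r, ng, p, method = "dp")
    expect_equal(b, a, tolerance = 1e-12)
  }
})

test_that("statistic grows with p_g below the mode and ignores label order", {
  n_r <- c(3, 1, 2, 4, 1, 2)
  ps <- c(0.001, 0.005, 0.02, 0.05)
  vals <- vapply(ps, function(p) enrichment_probability(n_r, 2, p),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(n_r)
    expect_equal(enrichment_probability(perm, 3, 0.01),
                 enrichment_probability(n_r, 3, 0.01))
  }
})

test_that("replicates with no mutant genes contribute nothing", {
  # subsets containing an n_r = 0 replicate have product 0
  expect_equal(enrichment_probability(c(0, 1, 1), 2, 0.5),
               enrichment_probability(c(1, 1), 2, 0.5))
})

test_that("significance calls use a strict threshold", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    P_g = c(0, 5e-5, 4.9e-5))
  out <- call_significant(res, alpha = 5e-5)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE))
})

test_that("Monte-Carlo null agrees with the closed form for unit counts", {
  R <- 6; p <- 0.2; ng <- 2
  mc <- monte_carlo_null(rep(1, R), ng, p, n_sims = 2e4, seed = 8)
  expect_lt(abs(mc$p_exact - stats::dbinom(ng, R, p)), 3 * mc$se_exact)
  expect_lt(abs(mc$p_tail - stats::pbinom(ng - 1, R, p,
                                          lower.tail = FALSE)),
            3 * mc$se_tail)
  # p_g -> 0 drives the estimate to 0
  expect_equal(monte_carlo_null(rep(1, 4), 1, 0, n_sims = 1000,
                                seed = 1)$p_exact, 0)
})

test_that("hit matrix counts distinct mutant genes per replicate", {
  genes <- demo_genes(5, gene_len = 100, gap = 0)
  # replicate a: two qualifying mutations in g01 (counts once) + one in g02;
  # replicate b: one in g03; sub-threshold and intergenic records ignored
  vt <- variant_table(data.frame(
    population_id = c("a", "a", "a", "a", "b", "b"),
    generation = 10L,
    position = c(10L, 20L, 150L, 180L, 250L, 720L),
    ref_base = "A", derived_base = "G",
    frequency = c(0.9, 0.8, 0.7, 0.3, 0.95, 0.9),
    depth = 100L, majority_reads = 90L,
    gene_id = "x", effect_class = "nonsynonymous"))
  hm <- hit_matrix(vt, genes, threshold = 0.5)
  expect_equal(hm$n_r[["a"]], 2L)   # g01, g02 (g01 deduplicated)
  expect_equal(hm$n_r[["b"]], 1L)   # g03; position 720 is intergenic
  expect_equal(unname(hm$intergenic[["b"]]), 1)
  expect_equal(hm$n_tot, sum(hm$n_r))
  expect_equal(as.integer(hm$n_g[["g01"]]), 1L)
})

test_that("a planted convergent gene is flagged, background genes are not", {
  genes <- demo_genes(20, gene_len = 300, gap = 200)
  genes$end[5] <- genes$start[5] + 59  # the planted gene is short (60 bp)
  genes$length <- genes$end - genes$start + 1
  set.seed(9)
  # 8 replicates: short planted gene g05 hit in 6; each replicate also
  # carries 3 background hits placed length-proportionally
  rows <- list()
  for (r in 1:8) {
    hits <- sprintf("g%02d", sample(20, 3, prob = genes$length))
    if (r <= 6) hits <- union(hits, "g05")
    pos <- vapply(hits, function(g) {
      gi <- genes[genes$gene_id == g, ]
      as.integer(sample(gi$start:gi$end, 1))
    }, integer(1))
    rows[[r]] <- data.frame(
      population_id = paste0("r", r), generation = 100L,
      position = pos, ref_base = "A", derived_base = "C",
      frequency = 0.8, depth = 200L, majority_reads = 160L,
      gene_id = hits, effect_class = "nonsynonymous")
  }
  vt <- variant_table(do.call(rbind, rows))
  hm <- hit_matrix(vt, genes, threshold = 0.5)
  res <- beneficial_scan(hm, genes, alpha = 5e-5)
  expect_true(res$significant[res$gene_id == "g05"])
  expect_equal(res$gene_id[1], "g05")  # top hit
  background <- res[res$gene_id != "g05", ]
  expect_true(all(!background$significant))
})

test_that("an ancestral mask removes shared pre-existing mutations", {
  genes <- demo_genes(3, gene_len = 100, gap = 0)
  vt <- variant_table(data.frame(
    population_id = rep(c("a", "b"), each = 1),
    generation = 10L, position = c(50L, 50L),
    ref_base = "A", derived_base = "G", frequency = 0.9,
    depth = 100L, majority_reads = 90L, gene_id = "g01",
    effect_class = "nonsynonymous"))
  hm <- hit_matrix(vt, genes)
  expect_equal(as.integer(hm$n_g[["g01"]]), 2L)
  hm_masked <- hit_matrix(vt, genes,
                          ancestral_mask = data.frame(position = 50L))
  expect_equal(length(hm_masked$n_g), 0L)
})
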