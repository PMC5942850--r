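test_that("cycle arithmetic matches the serial-dilution design", {
  expect_equal(generations_per_cycle(1e5), log2(1e5))
  expect_equal(complete_doublings(1e5), 16L)
  expect_equal(generations_per_cycle(1), 0)
  # day -> generation conversions used throughout the experiment design
  expect_equal(generations_at_day(28), 465)
  expect_equal(generations_at_day(175), 2907)
  expect_equal(generations_at_day(0), 0)
})

test_that("mutation-free simulation stays monomorphic for many cycles", {
  cfg <- sim_config(genome_length = 1000, U = 0, n_max = 1e4,
                    dilution = 100, days = 10)
  tr <- simulate_replicate(cfg, 3, snapshot_cycles = 1:10)
  for (s in tr$snapshots) {
    expect_equal(nrow(s$freqs), 0)
    expect_equal(s$n_haplotypes, 1L)
    expect_equal(s$mean_fitness, 1)
  }
})

test_that("trajectories are bit-identical under the same seed", {
  cfg <- sim_config(genome_length = 5000, U = 0.02, n_max = 1e4,
                    dilution = 100, days = 5)
  a <- simulate_replicate(cfg, 123, snapshot_cycles = c(2, 5))
  b <- simulate_replicate(cfg, 123, snapshot_cycles = c(2, 5))
  expect_identical(a$snapshots, b$snapshots)
  c <- simulate_replicate(cfg, 124, snapshot_cycles = c(2, 5))
  expect_false(identical(a$snapshots, c$snapshots))
})

test_that("cycle structure: stage sizes, final census and bottleneck", {
  cfg <- sim_config(genome_length = 1000, U = 0.01, n_max = 1e4,
                    dilution = 100, days = 3)
  tr <- simulate_replicate(cfg, 1, snapshot_cycles = 1:3)
  # stationary-phase census is exactly n_max every day
  for (s in tr$snapshots) expect_equal(s$n_cells, 1e4)
  # internal size ladder equals the analytic ladder
  expect_equal(tr$size_ladder, size_ladder(1e4, 100))
  expect_length(tr$size_ladder, complete_doublings(100) + 2)
})

test_that("mean fitness is non-decreasing with beneficial-only mutations", {
  cfg <- sim_config(genome_length = 5000,
                    dfe = dfe_spec(fraction_beneficial = 0.5,
                                   s_beneficial = 0.1,
                                   fraction_deleterious = 0),
                    U = 0.02, n_max = 1e4, dilution = 100, days = 12)
  fits <- sapply(1:6, function(r) {
    tr <- simulate_replicate(cfg, 100 + r, snapshot_cycles = c(4, 8, 12))
    vapply(tr$snapshots, function(s) s$mean_fitness, numeric(1))
  })
  means <- rowMeans(fits)
  expect_true(all(diff(means) >= 0))
  expect_gt(means[length(means)], 1)
})

test_that("higher mutation rate yields higher mean pairwise diversity", {
  mk <- function(U, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(genome_length = 5000, U = U, n_max = 5e3,
                        dilution = 100, days = 15)
      tr <- simulate_replicate(cfg, s)
      snap <- tr$snapshots[[1]]
      # true mean pairwise diversity per covered site, from frequencies
      sum(2 * snap$freqs$frequency * (1 - snap$freqs$frequency)) / 5000
    }, numeric(1))
  }
  seeds <- 1:10
  expect_gt(mean(mk(0.01, seeds)), mean(mk(0.0001, seeds)))
})

test_that("mutator locus raises the lineage mutation rate", {
  cfg <- sim_config(genome_length = 100, U = 0.2, n_max = 2e3,
                    dilution = 100, days = 8,
                    dfe = dfe_spec(fraction_beneficial = 0,
                                   fraction_deleterious = 0),
                    mutator_locus = list(position = c(1, 100),
                                         rate_multiplier = 10))
  tr <- simulate_replicate(cfg, 5, snapshot_cycles = 8)
  # every mutation hits the mutator window, so the population mean rate
  # must exceed the ancestral rate once any mutation segregates
  expect_gt(tr$snapshots[[1]]$mean_mutrate, cfg$U)
})

test_that("sample_reads reports frequencies per the read model", {
  # fixed sites: frequency 1 survives, frequency 0 is absent
  tf <- data.frame(position = c(10L, 20L), frequency = c(1, 0))
  vt <- sample_reads(tf, depth = 200, detection_threshold = 0.05, seed = 1)
  expect_equal(vt$position, 10L)
  expect_equal(vt$frequency, 1)
  # unbiasedness: mean reported frequency ~ 0.5 within 3 s.e.
  n <- 1e4
  tf2 <- data.frame(position = seq_len(n), frequency = rep(0.5, n))
  vt2 <- sample_reads(tf2, depth = 300, detection_threshold = 0, seed = 42)
  se <- sqrt(0.25 / 300) / sqrt(n)
  expect_lt(abs(mean(vt2$frequency) - 0.5), 3 * se)
  # depths are recorded and plausible
  expect_true(all(vt2$depth > 0))
  expect_lt(abs(mean(vt2$depth) - 300), 3 * sqrt(300 / n) + 1)
})

test_that("sample_reads suppresses sub-threshold alleles and logs coverage", {
  tf <- data.frame(position = 1:500, frequency = rep(0.01, 500))
  vt <- sample_reads(tf, depth = 100, detection_threshold = 0.05, seed = 7,
                     genome_length = 1000)
  expect_true(all(vt$frequency >= 0.05))
  rep <- attr(vt, "coverage_report")
  expect_true(is.list(rep))
  expect_true(rep$L_covered <= 1000)
})

test_that("fluctuation cultures follow the Luria-Delbruck law", {
  expect_true(all(simulate_fluctuation(0, 1e8, 20, seed = 1)$mutant_count == 0))
  # P(0) = exp(-m): m = 1 via mu*n_final
  fe <- simulate_fluctuation(1e-5, 1e5, 2e4, seed = 2)
  p0 <- mean(fe$mutant_count == 0)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 2e4)
  expect_lt(abs(p0 - exp(-1)), 3 * se)
})

test_that("growth-curve generator hits the logistic limits", {
  gc0 <- simulate_growth_curve(0.5, 1, 0.02, times = c(0, 100),
                               noise_sd = 0, seed = 1)
  expect_equal(gc0$od600[1], 0.02)
  expect_equal(gc0$od600[2], 1, tolerance = 1e-8)
})

test_that("simulate_plate recovers planted effects exactly at zero noise", {
  eff <- expand.grid(sample_id = c("anc", "evo"), compound = "cmpA",
                     well = 1:4, stringsAsFactors = FALSE)
  eff$effect <- ifelse(eff$sample_id == "evo", 0.4, 0.2)
  pl <- simulate_plate(eff, baseline = 0.1, noise_sd = 0, seed = 1)
  b <- biolog_score(pl)
  expect_equal(b$B[b$sample_id == "evo"], rep(0.4, 4))
  expect_equal(b$B[b$sample_id == "anc"], rep(0.2, 4))
})

test_that("plate noise sets the 99th percentile of baseline differences", {
  # |A_i - A_j| at 10 min is half-normal with scale sqrt(2)*sigma; its 99th
  # percentile is the distributional oracle for the noise threshold
  sigma <- 0.02
  eff <- data.frame(sample_id = paste0("s", 1:60),
                    compound = "c1", well = 1, effect = 0.3)
  pl <- simulate_plate(eff, baseline = 0.1, noise_sd = sigma, seed = 9)
  thr <- noise_threshold(pl, quantile = 0.99)
  oracle <- sqrt(2) * sigma * stats::qnorm(1 - 0.01 / 2)
  expect_equal(thr, oracle, tolerance = 0.25)
})

test_that("experiment-level seeds derive deterministically per replicate", {
  expect_equal(child_seed(1, 1), child_seed(1, 1))
  expect_false(child_seed(1, 1) == child_seed(1, 2))
  expect_true(all(vapply(1:100, function(i) child_seed(7, i), numeric(1)) <
                    2^31))
})
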