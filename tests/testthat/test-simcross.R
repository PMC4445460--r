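# Synthetic cross simulator: segregation invariants, viability, pools,
# sequencing counts, screen tables, growth curves.

test_that("cross designs are reproducible and validate their loci", {
  g <- tiny_genome(16)
  d1 <- make_cross(g, two_locus_model(), seed = 3)
  d2 <- make_cross(g, two_locus_model(), seed = 3)
  expect_identical(d1, d2)
  d3 <- make_cross(g, two_locus_model(), seed = 4)
  expect_false(identical(d1$markers$p1_allele, d3$markers$p1_allele))
  # model loci absent from the marker set are merged in
  expect_true(all(c("chr05_75500", "chr10_75500") %in% d1$markers$id))
  bad <- incompatibility_model(
    "two_locus_unlinked",
    lethal_loci = data.frame(chrom = c("chrV", "chrX"), pos = c(1L, 1L),
                             lethal_parent = c("P2", "P1")))
  expect_error(make_cross(g, bad), "unknown chromosome")
})

test_that("every simulated tetrad segregates 2:2 at every marker", {
  design <- make_cross(tiny_genome(16), two_locus_model(), seed = 1)
  ts <- simulate_tetrads(design, 1e4, seed = 2)
  per_tetrad_sums <- rowsum(ts$genotype, ts$tetrad)
  expect_true(all(per_tetrad_sums == 6))  # 1+1+2+2 at every marker
})

test_that("viability matches the model: none kills nobody, two-locus kills the lethal combination", {
  d0 <- make_cross(tiny_genome(), incompatibility_model("none"), seed = 1)
  ts0 <- simulate_tetrads(d0, 500, seed = 2)
  expect_true(all(ts0$viability))
  d2 <- make_cross(tiny_genome(16), two_locus_model(), seed = 1)
  ts2 <- simulate_tetrads(d2, 500, seed = 2)
  li <- d2$lethal_idx
  lethal <- ts2$genotype[, li[1]] == 2 & ts2$genotype[, li[2]] == 1
  expect_identical(unname(ts2$viability[, "restrictive"]), !lethal)
  expect_true(all(ts2$viability[, "permissive"]))
})

test_that("simulated tetrad class frequencies match analytic distributions", {
  set.seed(NULL)
  n <- 1e5
  cases <- list(
    list(model = two_locus_model(), genome = tiny_genome(16)),
    list(model = k_locus_model(3), genome = tiny_genome(16)),
    list(model = linked_model(r_from_bp(40000)), genome = tiny_genome(4)))
  for (cs in cases) {
    design <- make_cross(cs$genome, cs$model, seed = 1)
    ts <- simulate_tetrads(design, n, seed = 99)
    obs <- table(factor(viable_counts(ts, "restrictive"), levels = 4:0))
    exp_p <- expected_tetrad_distribution(cs$model)$probs
    keep <- exp_p > 0
    p <- suppressWarnings(
      stats::chisq.test(as.integer(obs)[keep], p = exp_p[keep]))$p.value
    expect_gt(p, 0.001, label = paste("kind", cs$model$kind))
  }
})

test_that("two-locus spore inviability converges to one-fourth", {
  design <- make_cross(tiny_genome(16), two_locus_model(), seed = 1)
  n <- 25000  # 1e5 spores
  ts <- simulate_tetrads(design, n, seed = 7)
  phat <- mean(!ts$viability[, "restrictive"])
  se <- sqrt(0.25 * 0.75 / (4 * n))
  expect_lt(abs(phat - 0.25), 3 * se)
})

test_that("spore pools honour the viability filter, one spore per tetrad", {
  design <- make_cross(make_genome(10, 150000, 5000), two_locus_model(),
                       seed = 1)
  pool <- simulate_spore_pool(design, "restrictive", 80, "inviable",
                              seed = 5)
  li <- design$lethal_idx
  expect_equal(nrow(pool$genotype), 80)
  expect_true(all(pool$genotype[, li[1]] == 2))
  expect_true(all(pool$genotype[, li[2]] == 1))
  pv <- simulate_spore_pool(design, "restrictive", 200, "viable", seed = 6)
  # per-marker P1 frequency ~ 0.5 away from the incompatibility loci
  far <- design$markers$chrom == "chr03"
  expect_lt(abs(mean(pv$genotype[, far] == 1) - 0.5), 0.03)
})

test_that("an impossible pool filter raises a no-progress error", {
  design <- make_cross(tiny_genome(), incompatibility_model("none"), seed = 1)
  expect_error(
    simulate_spore_pool(design, "permissive", 10, "inviable",
                        seed = 1, max_tetrads = 200),
    "no progress")
})

test_that("sequencing counts reflect pool composition, coverage and error", {
  design <- make_cross(tiny_genome(16), two_locus_model(), seed = 1)
  pool <- simulate_spore_pool(design, "restrictive", 30, "inviable", seed = 2)
  # force a pool fixed for P1 everywhere to test the error-free extreme
  fixed <- pool
  fixed$genotype[] <- 1L
  cnt <- simulate_bsa_counts(fixed, coverage = 40, error_rate = 0, seed = 3)
  expect_true(all(cnt$alt_count == 0))
  af <- allele_frequencies(cnt, min_depth = 1)
  expect_true(all(af$af_ref[af$depth > 0] == 1))
  # depth is Poisson around the requested coverage
  cnt2 <- simulate_bsa_counts(pool, coverage = 50, error_rate = 0.002,
                              seed = 4)
  depth <- cnt2$ref_count + cnt2$alt_count
  expect_lt(abs(mean(depth) - 50), 3 * sqrt(50 / nrow(cnt2)))
  expect_error(simulate_bsa_counts(pool, coverage = 0), "positive")
})

test_that("generators are deterministic under a fixed seed", {
  design <- make_cross(tiny_genome(16), two_locus_model(), seed = 1)
  expect_identical(simulate_tetrads(design, 50, seed = 8),
                   simulate_tetrads(design, 50, seed = 8))
  p1 <- simulate_spore_pool(design, "restrictive", 20, "inviable", seed = 9)
  p2 <- simulate_spore_pool(design, "restrictive", 20, "inviable", seed = 9)
  expect_identical(p1$genotype, p2$genotype)
  expect_identical(simulate_bsa_counts(p1, seed = 10),
                   simulate_bsa_counts(p2, seed = 10))
  s1 <- simulate_screen(n_crosses = 5, n_conditions = 4, seed = 11)
  s2 <- simulate_screen(n_crosses = 5, n_conditions = 4, seed = 11)
  expect_identical(s1, s2)
  g1 <- simulate_growth_curve(0.3, noise_sd = 0.01, seed = 12)
  g2 <- simulate_growth_curve(0.3, noise_sd = 0.01, seed = 12)
  expect_identical(g1, g2)
})

test_that("screen simulation emits the requested instance grid", {
  scr <- simulate_screen(n_crosses = 27, n_conditions = 20,
                         n_parent_failures = 59, seed = 21)
  expect_equal(nrow(scr$instances), 540)
  expect_equal(sum(!(scr$instances$p1_viable & scr$instances$p2_viable)), 59)
  expect_equal(nrow(scr$spores), 540 * 80)
  # spore records are consistent with the instance counts
  agg <- stats::aggregate(viable_condition ~ cross_id + condition,
                          scr$spores, sum)
  m <- merge(agg, scr$instances)
  expect_equal(m$viable_condition, m$spores_viable_condition)
  # pure 'none' mix is fully viable
  s0 <- simulate_screen(n_crosses = 3, n_conditions = 3, mix = c(none = 1),
                        n_parent_failures = 0, seed = 1)
  expect_true(all(s0$instances$spores_viable_condition == 80))
})

test_that("growth curves follow the exact logistic in the noiseless limit", {
  tt <- seq(0, 20, by = 0.5)
  cv <- simulate_growth_curve(0.3, lag_h = 0, carrying_capacity = 1.2,
                              noise_sd = 0, times = tt, od0 = 0.05)
  K <- 1.2
  expected <- K * 0.05 / (0.05 + (K - 0.05) * exp(-0.3 * tt))
  expect_equal(cv$od, expected)
  # lag shifts the trajectory without altering the plateau
  cl <- simulate_growth_curve(0.3, lag_h = 4, carrying_capacity = 1.2,
                              noise_sd = 0, times = tt, od0 = 0.05)
  expect_equal(cl$od[tt <= 4], rep(0.05, sum(tt <= 4)))
  expect_error(simulate_growth_curve(-1), "rate > 0")
})
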