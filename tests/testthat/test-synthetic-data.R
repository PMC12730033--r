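test_that("fixed seed gives bit-identical simulated tables", {
  cfg <- simulation_config(5, 4, list(trait_spec("y", 10, 1, 1)),
                           rng_seed = 42)
  expect_identical(simulate_trait_table(cfg), simulate_trait_table(cfg))
  expect_identical(simulate_germination(cfg), simulate_germination(cfg))
  cfg2 <- simulation_config(5, 4, list(trait_spec("y", 10, 1, 1)),
                            rng_seed = 43)
  expect_false(identical(simulate_trait_table(cfg),
                         simulate_trait_table(cfg2)))
})

test_that("trait simulation follows the additive two-component model", {
  # variance of genotype means converges to sigma2_g + sigma2_e/k
  cfg <- simulation_config(2000, 4, list(trait_spec("y", 5, 2, 4)),
                           rng_seed = 11)
  tab <- simulate_trait_table(cfg)
  vm <- var(tapply(tab$value, tab$genotype, mean))
  expect_lt(abs(vm - (2 + 4 / 4)) / (2 + 4 / 4), 0.05)
  expect_lt(abs(mean(tab$value) - 5), 0.1)
})

test_that("no-signal traits mostly truncate the genetic variance to zero", {
  truncated <- vapply(1:60, function(s) {
    cfg <- simulation_config(20, 4, list(trait_spec("y", 10, 0, 1)),
                             rng_seed = 1000 + s)
    a <- anova_crd(simulate_trait_table(cfg), "y")
    genetic_parameters(a)$Vg == 0
  }, logical(1))
  expect_gte(mean(truncated), 0.4)
})

test_that("degenerate germination settings behave as limits", {
  gm <- germination_model(seeds_per_replicate = 50, n_days = 21,
                          p_germ_mean = 1 - 1e-12, p_germ_genotype_sd = 0,
                          time_mean = 5, time_sd = 0, time_genotype_sd = 0)
  cfg <- simulation_config(3, 4, list(trait_spec("y", 1, 0, 1)),
                           germination = gm, rng_seed = 2)
  course <- simulate_germination(cfg)
  expect_true(all(course$count[course$day == 5] == 50))
  expect_true(all(course$count[course$day != 5] == 0))

  gm0 <- germination_model(p_germ_mean = 1e-12, p_germ_genotype_sd = 0)
  cfg0 <- simulation_config(3, 4, list(trait_spec("y", 1, 0, 1)),
                            germination = gm0, rng_seed = 2)
  expect_true(all(simulate_germination(cfg0)$count == 0))
})

test_that("per-replicate germination fraction is binomial around p", {
  gm <- germination_model(p_germ_mean = 0.8, p_germ_genotype_sd = 0,
                          time_mean = 6, time_sd = 1.5, time_genotype_sd = 0)
  cfg <- simulation_config(20, 4, list(trait_spec("y", 1, 0, 1)),
                           germination = gm, rng_seed = 3)
  course <- simulate_germination(cfg)
  tot <- aggregate(count ~ genotype + replicate, course, sum)
  # counts per replicate never exceed seeds sown
  expect_true(all(tot$count <= 50))
  # pooled total within 4 binomial SDs of n*p
  n <- 50 * nrow(tot)
  expect_lt(abs(sum(tot$count) - n * 0.8), 4 * sqrt(n * 0.8 * 0.2))
})

test_that("ground truth matches closed-form algebra", {
  cfg <- simulation_config(
    3, 4,
    list(trait_spec("zero", 10, 0, 1),
         trait_spec("threeq", 10, 3 * 2 / 4, 2),
         trait_spec("cv", 50, 4, 1)),
    rng_seed = 1)
  gt <- ground_truth(cfg)
  expect_equal(gt$h2_pct[gt$trait == "zero"], 0)
  expect_equal(gt$h2_pct[gt$trait == "threeq"], 75)
  expect_equal(gt$CVg_pct[gt$trait == "cv"], 100 * sqrt(4) / 50)
})

test_that("invalid configurations are rejected", {
  expect_error(trait_spec("y", 1, -1, 1), "sigma2_g")
  expect_error(trait_spec("y", 1, 1, 0), "sigma2_e")
  expect_error(simulation_config(1, 4, list(trait_spec("y", 1, 1, 1))),
               "n_genotypes")
  expect_error(germination_model(p_germ_mean = 0), "p_germ_mean")
})
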