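test_that("seed indices match hand-worked values", {
  expect_equal(thousand_seed_weight(8, 1000), 8)
  expect_equal(thousand_seed_weight(1, 500), 2)
  expect_equal(thousand_seed_weight(0.35, 250), 1.4)
  expect_error(thousand_seed_weight(1, 0), "sample_count")

  expect_equal(germination_percentage(c(25, 25), 50), 100)
  expect_equal(germination_percentage(c(0, 0), 50), 0)
  expect_equal(germination_percentage(c(10, 5), 50), 30)
  expect_error(germination_percentage(c(1), 0), "seeds_sown")

  expect_equal(germination_speed_index(50, days = 5), 10)
  expect_equal(germination_speed_index(c(10, 5), days = c(2, 4)), 6.25)
  expect_equal(germination_speed_index(rep(0, 21)), 0)

  expect_equal(mean_germination_time(7, days = 3), 3)
  expect_equal(mean_germination_time(c(10, 5), days = c(2, 4)), 40 / 15)
  expect_equal(mean_germination_time(c(1, 1), days = c(1, 21)), 11)
  expect_true(is.na(mean_germination_time(c(0, 0), days = c(1, 2))))

  expect_equal(biomass_density(10, 5), 2)
  expect_equal(biomass_density(0, 3), 0)
  expect_equal(biomass_density(1.25, 2.5), 0.5)
  expect_error(biomass_density(1, 0), "length")

  expect_equal(seed_vigor_index(100, 3), 300)
  expect_equal(seed_vigor_index(0, 2), 0)
  expect_equal(seed_vigor_index(84, 2.5), 210)
})

test_that("GSI and MGT obey their bounds and monotonicity", {
  set.seed(9)
  for (i in 1:25) {
    n_days <- sample(5:21, 1)
    counts <- rpois(n_days, 2)
    ng <- sum(counts)
    gsi <- germination_speed_index(counts)
    expect_gte(gsi, ng / n_days)
    expect_lte(gsi, ng)
    if (ng > 0) {
      mgt <- mean_germination_time(counts)
      expect_gte(mgt, 1)
      expect_lte(mgt, n_days)
      # moving one germination event one day earlier lowers MGT
      late <- which(counts > 0 & seq_len(n_days) > 1)
      if (length(late)) {
        d <- max(late)
        shifted <- counts
        shifted[d] <- shifted[d] - 1
        shifted[d - 1] <- shifted[d - 1] + 1
        expect_lt(mean_germination_time(shifted), mgt)
      }
    }
  }
})

test_that("germination_traits yields one replicate-level row per index", {
  course <- germination_course(data.frame(
    genotype = rep(c("A", "B"), each = 6),
    replicate = rep(rep(1:2, each = 3), 2),
    day = rep(1:3, 4),
    count = c(5, 3, 2, 4, 4, 0, 0, 0, 0, 1, 0, 9),
    seeds_sown = 10))
  expect_warning(tab <- germination_traits(course), "no germination")
  expect_s3_class(tab, "phenotype_table")
  expect_equal(nrow(tab), 2 * 2 * 3)
  a1 <- tab[tab$genotype == "A" & tab$replicate == 1, ]
  expect_equal(a1$value[a1$trait == "G"], 100)
  expect_equal(a1$value[a1$trait == "GSI"], 5 / 1 + 3 / 2 + 2 / 3)
  expect_equal(a1$value[a1$trait == "MGT"], (5 + 6 + 6) / 10)
  # replicate with zero germination -> missing MGT, G = 0
  b1 <- tab[tab$genotype == "B" & tab$replicate == 1, ]
  expect_equal(b1$value[b1$trait == "G"], 0)
  expect_true(is.na(b1$value[b1$trait == "MGT"]))
})

test_that("germination course validation catches bad inputs", {
  base <- data.frame(genotype = "A", replicate = 1, day = 1:2,
                     count = c(6, 6), seeds_sown = 10)
  expect_error(germination_course(base), "exceed")
  base$count <- c(-1, 2)
  expect_error(germination_course(base), "negative")
  base$count <- c(1, 2)
  base$day <- c(0, 1)
  expect_error(germination_course(base), "positive integers")
})
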