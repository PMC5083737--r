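test_that("feature cohort has the declared schema and composition", {
  cfg <- cohort_config(seed = 1)
  coh <- gen_feature_cohort(cfg)
  expect_equal(nrow(coh), 44)
  expect_equal(names(coh), c("tissue_id", "class", feature_names(cfg)))
  expect_equal(as.integer(table(coh$class)), c(12, 16, 16))
  expect_false(anyNA(coh))
})

test_that("all-zero cohort yields an empty table with the full header", {
  coh <- gen_feature_cohort(cohort_config(n_per_class = c(0, 0, 0)))
  expect_equal(nrow(coh), 0)
  expect_equal(names(coh), c("tissue_id", "class", feature_names()))
})

test_that("generation is deterministic given the config seed", {
  cfg <- cohort_config(seed = 99)
  expect_identical(gen_feature_cohort(cfg), gen_feature_cohort(cfg))
  cfg_small <- cohort_config(n_per_class = c(2, 2, 2), nuclei_mean = 10,
                             nuclei_sd = 2, n_noise_features = 4, seed = 7)
  a <- gen_nucleus_cohort(cfg_small)
  b <- gen_nucleus_cohort(cfg_small)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$tissues, b$tissues)
  expect_false(identical(
    gen_feature_cohort(cfg),
    gen_feature_cohort(cohort_config(seed = 100))))
})

test_that("informative features recover their generative moments", {
  cfg <- cohort_config(n_per_class = c(2000, 0, 0), seed = 1)
  coh <- gen_feature_cohort(cfg)
  tab <- informative_defaults()
  for (f in unique(tab$feature)) {
    par <- tab[tab$feature == f & tab$class == "CP", ]
    expect_lt(abs(mean(coh[[f]]) - par$mean), 3 * par$sd / sqrt(2000))
    expect_lt(abs(sd(coh[[f]]) - par$sd), 3 * par$sd / sqrt(2000))
  }
  # and for a second class at the other end of the table
  cfg_pc <- cohort_config(n_per_class = c(0, 0, 2000), seed = 2)
  coh_pc <- gen_feature_cohort(cfg_pc)
  for (f in c("run_percentage", "n_light_pixels")) {
    par <- tab[tab$feature == f & tab$class == "PC", ]
    expect_lt(abs(mean(coh_pc[[f]]) - par$mean), 3 * par$sd / sqrt(2000))
  }
})

test_that("noise features carry no between-class signal", {
  cfg <- cohort_config(n_per_class = c(500, 0, 500), seed = 3)
  coh <- gen_feature_cohort(cfg)
  pvals <- vapply(sprintf("noise_%03d", 1:87), function(f)
    stats::t.test(coh[[f]][coh$class == "CP"],
                  coh[[f]][coh$class == "PC"])$p.value, numeric(1))
  expect_lte(mean(pvals < 0.01), 0.05)
})

test_that("nuclei-per-tissue counts follow the cohort distribution", {
  cfg <- cohort_config(n_per_class = c(34, 33, 33), n_noise_features = 0,
                       seed = 4)
  coh <- gen_nucleus_cohort(cfg)
  expect_lt(abs(mean(coh$tissues$n_nuclei) - 180), 3 * 22 / sqrt(100))
  expect_true(all(coh$tissues$n_nuclei >= 1))
  expect_equal(nrow(coh$nuclei), sum(coh$tissues$n_nuclei))

  fixed <- gen_nucleus_cohort(cohort_config(
    n_per_class = c(2, 2, 2), nuclei_mean = 5, nuclei_sd = 0,
    n_noise_features = 0, seed = 5))
  expect_true(all(fixed$tissues$n_nuclei == 5))
})

test_that("tissue latent means are recovered by pooling nuclei", {
  cfg <- cohort_config(n_per_class = c(1, 0, 0), nuclei_mean = 1000,
                       nuclei_sd = 0, n_noise_features = 2, seed = 6)
  coh <- gen_nucleus_cohort(cfg)
  pooled <- pool_tissue(coh$nuclei)
  tab <- informative_defaults()
  for (f in feature_names(cfg)) {
    latent <- coh$tissues[[f]][1]
    base_sd <- if (f %in% tab$feature)
      tab$sd[tab$feature == f & tab$class == "CP"] else 1
    tol <- 3 * cfg$nucleus_dispersion * base_sd / sqrt(1000)
    expect_lt(abs(pooled[[f]] - latent), tol)
  }
  # pooling the cohort table agrees with pool_tissue on the same nuclei
  tl <- pool_cohort(coh$nuclei)
  expect_equal(unlist(tl[1, feature_names(cfg)]), pooled[feature_names(cfg)])
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_class = c(-1, 2, 2)), "non-negative")
  expect_error(cohort_config(nuclei_sd = -1), "nuclei_sd")
  bad <- informative_defaults()
  bad$sd[1] <- 0
  expect_error(cohort_config(informative_params = bad), "sd must be > 0")
  expect_error(
    gen_nucleus_cohort(cohort_config(nuclei_mean = -5)), "nuclei_mean")
  expect_error(
    gen_nucleus_cohort(cohort_config(n_per_class = c(0, 0, 0))), "empty")
})
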