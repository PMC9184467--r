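test_that("effect sampling follows the hyper-distribution", {
  h <- group_hyper(mu_a = -2.49, sigma_a = 0, mu_b = -0.032, sigma_b = 0,
                   mu_c = 149, sigma_c = 0, mu_d = -10.8, sigma_d = 0)
  e <- sample_individual_effects(h, 5, seed = 1)
  expect_equal(e$a, rep(-2.49, 5))
  expect_equal(e$c, rep(149, 5))

  # law of large numbers at the study's gaussian-intercept hypers
  h2 <- default_scenario()$hyper$virus_free
  e2 <- sample_individual_effects(h2, 100000, seed = 2)
  expect_lt(abs(mean(e2$c) - 149), 3 * 75.1 / sqrt(100000))
  expect_lt(abs(sd(e2$c) - 75.1), 3 * 75.1 / sqrt(2 * 100000))

  expect_error(group_hyper(0, -1, 0, 1, 0, 1, 0, 1), "sigma_a")
  expect_error(sample_individual_effects(h, 0), ">= 1")
})

test_that("default scenario encodes the study design", {
  scen <- default_scenario()
  expect_equal(scen$hyper$virus_free$mu_a, -2.49)
  expect_equal(scen$hyper$virus_free$sigma_a, 2.20)
  expect_equal(scen$hyper$infected$mu_c, 284)
  expect_equal(scen$hyper$infected$sigma_d, 26.1)
  expect_equal(sum(scen$design$n_per_group_sex), 87)
  expect_equal(unname(scen$design$n_per_group_sex["virus_free_male"]), 26)
  expect_equal(scen$design$trials_per_individual, 8)
  expect_equal(scen$design$observation_limit_s, 600)
})

test_that("simulated trials follow the hurdle data-generating process", {
  des <- study_design(n_per_group_sex = c(virus_free_male = 2,
                                          virus_free_female = 2,
                                          infected_male = 2,
                                          infected_female = 2),
                      trials_per_individual = 5, residual_sd = 1e-9)
  eff <- function(a, b, c, d, n = 4) data.frame(a = rep(a, n), b = b,
                                                c = c, d = d)
  # saturating stay-logit: nobody emerges, no latencies recorded
  ds <- simulate_trials(list(virus_free = eff(20, 0, 300, 0),
                             infected = eff(20, 0, 300, 0)), des, seed = 1)
  expect_false(any(ds$emerged))
  expect_true(all(is.na(ds$latency_s)))

  # noise-free limit: everyone emerges at exactly round(c + d x)
  ds2 <- simulate_trials(list(virus_free = eff(-30, 0, 300, -12),
                              infected = eff(-30, 0, 300, -12)), des,
                         seed = 2)
  expect_true(all(ds2$emerged))
  x <- ds2$trial_index - mean(ds2$trial_index)
  expect_equal(ds2$latency_s, round(300 - 12 * x))

  # fair-coin stay process at a_i = b_i = 0
  des10k <- study_design(n_per_group_sex = c(virus_free_male = 625,
                                             virus_free_female = 625,
                                             infected_male = 0,
                                             infected_female = 0),
                         trials_per_individual = 8)
  ds3 <- simulate_trials(list(virus_free = eff(0, 0, 300, 0, 1250),
                              infected = eff(1, 1, 1, 1, 1)[0, ]),
                         des10k, seed = 3)
  expect_equal(nrow(ds3), 10000L)
  expect_lt(abs(mean(!ds3$emerged) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("simulation is deterministic given seed and config", {
  s1 <- simulate_emergence(seed = 9)
  s2 <- simulate_emergence(seed = 9)
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$effects, s2$effects)
  s3 <- simulate_emergence(seed = 10)
  expect_false(identical(s1$dataset, s3$dataset))
})

test_that("latencies always respect the censoring window", {
  scen <- default_scenario()
  scen$design <- study_design(n_per_group_sex = c(virus_free_male = 5,
                                                  virus_free_female = 5,
                                                  infected_male = 5,
                                                  infected_female = 5),
                              trials_per_individual = c(7, 10),
                              residual_sd = 200)
  for (seed in 1:5) {
    ds <- simulate_emergence(scen, seed = seed)$dataset
    lat <- ds$latency_s[ds$emerged]
    expect_true(all(lat >= 1 & lat <= 599))
    expect_true(all(is.na(ds$latency_s[!ds$emerged])))
    n_trials <- table(ds$individual_id)
    expect_true(all(n_trials >= 7 & n_trials <= 10))
  }
})

test_that("mortality replaces infected individuals with same-sex recruits", {
  scen <- default_scenario()
  scen$design <- study_design(n_per_group_sex = c(virus_free_male = 3,
                                                  virus_free_female = 3,
                                                  infected_male = 10,
                                                  infected_female = 10),
                              trials_per_individual = 8,
                              mortality_per_trial = 0.15)
  sim <- simulate_emergence(scen, seed = 4)
  ds <- sim$dataset
  expect_equal(nrow(validate_dataset(ds)), 0L)
  info <- individuals(ds)
  repl <- info[grepl("_r\\d+$", info$individual_id), ]
  expect_gt(nrow(repl), 0L)  # hazard 0.15 over 8 trials: replacements occur
  # a replacement keeps its predecessor's sex and restarts its experience
  for (i in seq_len(nrow(repl))) {
    orig_id <- sub("_r\\d+$", "", repl$individual_id[i])
    orig <- info[info$individual_id == orig_id, ]
    expect_equal(as.character(repl$sex[i]), as.character(orig$sex))
    expect_equal(as.character(repl$group[i]), "infected")
    expect_equal(min(ds$trial_index[ds$individual_id ==
                                      repl$individual_id[i]]), 1L)
  }
  # virus-free animals are never replaced
  expect_false(any(grepl("_r", info$individual_id[info$group ==
                                                    "virus_free"])))
})

test_that("scenario configs round-trip through YAML", {
  scen <- default_scenario()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scen, f)
  back <- read_scenario(f)
  expect_equal(back$hyper$virus_free$mu_a, scen$hyper$virus_free$mu_a)
  expect_equal(back$hyper$infected$sigma_d, scen$hyper$infected$sigma_d)
  expect_equal(back$design$n_per_group_sex, scen$design$n_per_group_sex)
  # simulating from the round-tripped scenario matches exactly
  expect_identical(simulate_emergence(back, seed = 3)$dataset,
                   simulate_emergence(scen, seed = 3)$dataset)
})
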