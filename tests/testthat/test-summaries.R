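test_that("group differences and exceedance follow their definitions", {
  n <- 2000
  set.seed(51)
  vf <- rnorm(n, 0, 1)
  fit <- fake_fit(list(`mu_c[virus_free]` = vf, `mu_c[infected]` = vf))
  gc <- group_difference(fit, "mu_c")
  expect_true(all(gc$draws == 0))
  expect_equal(gc$exceedance, 0.5)  # exact ties count one half

  fit2 <- fake_fit(list(`mu_c[virus_free]` = vf,
                        `mu_c[infected]` = vf + 10))
  gc2 <- group_difference(fit2, "mu_c")
  expect_equal(gc2$mean, -10)
  expect_equal(gc2$sd, 0)
  expect_equal(gc2$exceedance, 1)

  expect_error(group_difference(fit, "mu_q"), "unknown parameter")

  # difference mean decomposes into the group means
  set.seed(52)
  inf <- rnorm(n, 3, 2)
  fit3 <- fake_fit(list(`sigma_a[virus_free]` = abs(vf),
                        `sigma_a[infected]` = abs(inf)))
  gc3 <- group_difference(fit3, "sigma_a")
  expect_equal(gc3$mean, mean(abs(vf)) - mean(abs(inf)), tolerance = 1e-12)

  # exceedance + reverse exceedance = 1 under the tie convention
  for (p in c("mu_c", "sigma_a")) {
    f <- if (p == "mu_c") fit2 else fit3
    expect_equal(exceedance_probability(f, p) +
                   exceedance_probability(f, p, reference = "infected",
                                          other = "virus_free"), 1)
  }
})

test_that("personality scores are posterior means with metadata", {
  ids <- c("u1", "u2")
  info <- data.frame(individual_id = ids,
                     group = factor(c("virus_free", "infected"),
                                    levels = c("virus_free", "infected")),
                     sex = factor(c("male", "female"),
                                  levels = c("male", "female")),
                     n_trials = c(3L, 3L), n_emerged = c(2L, 1L))
  pars <- list()
  for (k in c("a", "b", "c", "d")) {
    for (i in seq_along(ids)) {
      pars[[sprintf("%s[%s]", k, ids[i])]] <- rep(i * 10, 100)
    }
  }
  fit <- fake_fit(pars, individuals = info)
  sc <- personality_scores(fit)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$a, c(10, 20))  # zero-variance draws: score equals value
  expect_equal(sc$d, c(10, 20))

  ds <- tiny_dataset()
  expect_error(personality_scores(fit, ds), "missing from posterior")
})

test_that("sex disaggregation summarises the four strata", {
  sc <- data.frame(
    individual_id = c("m1"), group = "virus_free", sex = "male",
    a = 1.5, b = 0, c = 100, d = -2, stringsAsFactors = FALSE)
  class(sc) <- c("personality_scores", "data.frame")
  out <- disaggregate_by_sex(sc)
  expect_equal(out$summary$n, c(1L, 0L, 0L, 0L))
  expect_equal(out$summary$a_mean[1], 1.5)  # single member: mean = score
  expect_equal(out$summary$n_positive_d, c(0L, 0L, 0L, 0L))

  sc$sex <- NA
  class(sc) <- c("personality_scores", "data.frame")
  expect_error(disaggregate_by_sex(sc), "m1")
})

test_that("sex-structured slopes are recovered through the full pipeline", {
  # infected males drift later with experience (+8 s/trial), everyone else
  # gets faster (-10 s/trial); the stratum means must come out ordered
  des <- study_design(n_per_group_sex = c(virus_free_male = 8,
                                          virus_free_female = 8,
                                          infected_male = 8,
                                          infected_female = 8),
                      trials_per_individual = 8, residual_sd = 30)
  set.seed(81)
  mk_eff <- function(n, d_mean) {
    data.frame(a = rnorm(n, -2, 0.5), b = rnorm(n, 0, 0.1),
               c = rnorm(n, 250, 40), d = rnorm(n, d_mean, 2))
  }
  effects <- list(virus_free = mk_eff(16, -10),
                  infected = rbind(mk_eff(8, 8),    # males first by design
                                   mk_eff(8, -10)))
  ds <- simulate_trials(effects, des, seed = 82)
  fit <- suppressWarnings(fit_hurdle(ds, chains = 2L, iter = 600L,
                                     warmup = 600L, seed = 83L,
                                     force = TRUE))
  out <- disaggregate_by_sex(personality_scores(fit, ds))
  s <- out$summary
  im <- s$d_mean[s$group == "infected" & s$sex == "male"]
  others <- s$d_mean[!(s$group == "infected" & s$sex == "male")]
  expect_true(all(im > others + 5))
  expect_gt(s$n_positive_d[s$group == "infected" & s$sex == "male"], 6)
  expect_true(all(s$n_positive_d[!(s$group == "infected" &
                                     s$sex == "male")] <= 1))
})

test_that("scores shrink towards the group mean", {
  # all-emerge design with flat slopes: the no-pooling estimate of c is the
  # individual's mean latency, and partial pooling must land each score
  # between that estimate and the population intercept
  des <- study_design(n_per_group_sex = c(virus_free_male = 10,
                                          virus_free_female = 10,
                                          infected_male = 0,
                                          infected_female = 0),
                      trials_per_individual = 6, residual_sd = 50)
  set.seed(91)
  effects <- list(virus_free = data.frame(a = rep(-15, 20), b = 0,
                                          c = rnorm(20, 300, 60), d = 0),
                  infected = data.frame(a = numeric(), b = numeric(),
                                        c = numeric(), d = numeric()))
  ds <- simulate_trials(effects, des, seed = 92)
  fit <- suppressWarnings(fit_hurdle(
    ds, chains = 2L, iter = 600L, warmup = 600L, seed = 93L, force = TRUE,
    fixed = list(mu_b = c(virus_free = 0), sigma_b = c(virus_free = 0),
                 mu_d = c(virus_free = 0), sigma_d = c(virus_free = 0))))
  sc <- personality_scores(fit, ds)
  mu_c_hat <- mean(extract_draws(fit, "mu_c", "virus_free"))
  no_pool <- tapply(ds$latency_s, ds$individual_id, mean)
  no_pool <- no_pool[sc$individual_id]
  lo <- pmin(no_pool, mu_c_hat); hi <- pmax(no_pool, mu_c_hat)
  slack <- 0.05 * (hi - lo) + 2
  expect_true(all(sc$c >= lo - slack & sc$c <= hi + slack))
  # and the shrinkage is strict for the extreme individuals
  extreme <- which.max(abs(no_pool - mu_c_hat))
  expect_lt(abs(sc$c[extreme] - mu_c_hat), abs(no_pool[extreme] - mu_c_hat))
})

test_that("prediction curves have coherent intervals", {
  n <- 1000
  set.seed(55)
  pars <- list(`mu_a[virus_free]` = rnorm(n, -2, 0.3),
               `mu_b[virus_free]` = rep(0, n),
               `mu_c[virus_free]` = rnorm(n, 150, 10),
               `mu_d[virus_free]` = rep(0, n))
  fit <- fake_fit(pars)
  pc <- predict_curves(fit, "virus_free", 1:8)
  # flat hyper-slopes give flat curves
  expect_equal(diff(range(pc$emergence_prob)), 0)
  expect_equal(diff(range(pc$latency)), 0)
  expect_true(all(pc$emergence_lo <= pc$emergence_prob &
                    pc$emergence_prob <= pc$emergence_hi))
  expect_true(all(pc$emergence_prob >= 0 & pc$emergence_prob <= 1))
  expect_true(all(pc$latency_lo <= pc$latency & pc$latency <= pc$latency_hi))

  # a deterministic posterior collapses the interval onto the mean
  pars1 <- lapply(pars, function(v) rep(v[1], 2))
  fit1 <- fake_fit(pars1)
  pc1 <- predict_curves(fit1, "virus_free", 1:5)
  expect_equal(pc1$emergence_lo, pc1$emergence_prob)
  expect_equal(pc1$latency_hi, pc1$latency)

  expect_error(predict_curves(fit, "martian"), "martian")
})
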