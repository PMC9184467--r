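# Shared fixture builders; all data are generated in code.

# small deterministic two-group dataset
tiny_dataset <- function() {
  trial_dataset(data.frame(
    individual_id = rep(c("v1", "v2", "i1"), each = 3),
    group = rep(c("virus_free", "virus_free", "infected"), each = 3),
    sex = rep(c("male", "female", "male"), each = 3),
    trial_index = rep(1:3, 3),
    emerged = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                FALSE, FALSE, TRUE),
    latency_s = c(100, NA, 140, 220, 180, NA, NA, NA, 560)))
}

# random small dataset for property loops
random_dataset <- function(seed, n_ind = 6L, n_trials = 4L) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n_ind))
  grp <- rep(c("virus_free", "infected"), length.out = n_ind)
  rows <- do.call(rbind, lapply(seq_len(n_ind), function(i) {
    emg <- stats::runif(n_trials) < 0.6
    data.frame(individual_id = ids[i], group = grp[i],
               sex = sample(c("male", "female"), 1L),
               trial_index = seq_len(n_trials), emerged = emg,
               latency_s = ifelse(emg, sample(1:599, n_trials, TRUE), NA))
  }))
  trial_dataset(rows)
}

random_effects_for <- function(ds, seed) {
  set.seed(seed)
  info <- individuals(ds)
  data.frame(individual_id = info$individual_id, group = info$group,
             a = stats::rnorm(nrow(info), 0, 1.5),
             b = stats::rnorm(nrow(info), 0, 0.4),
             c = stats::rnorm(nrow(info), 250, 70),
             d = stats::rnorm(nrow(info), 0, 10),
             stringsAsFactors = FALSE)
}

# independent per-record log-likelihood oracle (deliberately naive)
brute_loglik <- function(ds, effects, residual_sd, centring) {
  total <- 0
  for (r in seq_len(nrow(ds))) {
    e <- effects[effects$individual_id == ds$individual_id[r], ]
    x <- ds$trial_index[r] - centring
    p_stay <- stats::plogis(e$a + e$b * x)
    stay <- !ds$emerged[r]
    total <- total + stats::dbinom(as.integer(stay), 1L, p_stay, log = TRUE)
    if (ds$emerged[r]) {
      total <- total + stats::dnorm(ds$latency_s[r], e$c + e$d * x,
                                    residual_sd, log = TRUE)
    }
  }
  total
}

# minimal hurdle_fit for derived-quantity tests: `pars` is a named list of
# equal-length draw vectors; chains are formed by halving each vector
fake_fit <- function(pars, individuals = NULL, centring_constant = 4.5,
                     groups = c("virus_free", "infected")) {
  n <- length(pars[[1L]])
  stopifnot(n %% 2L == 0L)
  arr <- array(NA_real_, c(n / 2L, 2L, length(pars)),
               dimnames = list(NULL, NULL, names(pars)))
  for (p in seq_along(pars)) arr[, , p] <- pars[[p]]
  if (is.null(individuals)) {
    individuals <- data.frame(individual_id = character(),
                              group = factor(character(),
                                             levels = c("virus_free",
                                                        "infected")),
                              sex = factor(character(),
                                           levels = c("male", "female")),
                              n_trials = integer(), n_emerged = integer())
  }
  structure(list(draws = arr, parameters = names(pars), groups = groups,
                 individuals = individuals,
                 centring_constant = centring_constant,
                 hyper_parameters = character()),
            class = "hurdle_fit")
}

# a small fitted model shared by summary/ppc tests (built once per run)
small_fit_cache <- new.env(parent = emptyenv())
small_fitted <- function() {
  if (!is.null(small_fit_cache$value)) return(small_fit_cache$value)
  scen <- default_scenario()
  scen$design <- study_design(
    n_per_group_sex = c(virus_free_male = 6, virus_free_female = 6,
                        infected_male = 6, infected_female = 6),
    trials_per_individual = 6)
  sim <- simulate_emergence(scen, seed = 77)
  fit <- suppressWarnings(fit_hurdle(sim$dataset, chains = 2L, iter = 600L,
                                     warmup = 600L, seed = 11L,
                                     force = TRUE))
  small_fit_cache$value <- list(fit = fit, dataset = sim$dataset,
                                scenario = scen)
  small_fit_cache$value
}
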