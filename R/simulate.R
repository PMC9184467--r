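#' Group-level hyperparameters of the hurdle hierarchy
#'
#' Means and standard deviations of the four independent normal
#' random-effect distributions: binomial (stay-logit) intercept `a` and
#' slope `b`, gaussian latency intercept `c` (seconds) and slope `d`
#' (seconds per trial of experience). The binomial linear predictor is the
#' logit of *staying* in the tube, so a larger `mu_a` means a lower
#' emergence probability.
#'
#' @param mu_a,sigma_a mean and SD of binomial intercepts (logit scale).
#' @param mu_b,sigma_b mean and SD of binomial slopes (logit per trial).
#' @param mu_c,sigma_c mean and SD of gaussian intercepts (seconds).
#' @param mu_d,sigma_d mean and SD of gaussian slopes (seconds per trial).
#' @return A `group_hyper` list of the eight values.
#' @export
group_hyper <- function(mu_a, sigma_a, mu_b, sigma_b,
                        mu_c, sigma_c, mu_d, sigma_d) {
  h <- list(mu_a = mu_a, sigma_a = sigma_a, mu_b = mu_b, sigma_b = sigma_b,
            mu_c = mu_c, sigma_c = sigma_c, mu_d = mu_d, sigma_d = sigma_d)
  for (nm in names(h)) {
    if (!is.numeric(h[[nm]]) || length(h[[nm]]) != 1L || !is.finite(h[[nm]]))
      stop(nm, " must be a single finite number", call. = FALSE)
  }
  for (nm in grep("^sigma_", names(h), value = TRUE)) {
    if (h[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  structure(h, class = "group_hyper")
}

#' Study design for the trial simulator
#'
#' Defaults emulate the study: 50 virus-free (26 M, 24 F) and 37 infected
#' (19 M, 18 F) individuals, tested for 7-10 trials each with a 10-minute
#' (600 s) observation limit, and dead infected individuals replaced by new
#' same-sex individuals.
#'
#' @param n_per_group_sex named integer vector with entries
#'   `virus_free_male`, `virus_free_female`, `infected_male`,
#'   `infected_female`.
#' @param trials_per_individual single count or length-2 range in
#'   \[1, 50\]; a range is sampled uniformly per individual.
#' @param observation_limit_s observation window (s); latencies are recorded
#'   in \[1, observation_limit_s - 1\].
#' @param residual_sd residual latency SD (s) around the individual's mean.
#' @param mortality_per_trial per-trial death hazard applied to infected
#'   individuals after each trial (geometric waiting time); 0 disables.
#' @param replacement whether a dead infected individual is replaced by a
#'   fresh same-sex individual that performs the remaining trials.
#' @return A `study_design` list.
#' @export
study_design <- function(n_per_group_sex = c(virus_free_male = 26,
                                             virus_free_female = 24,
                                             infected_male = 19,
                                             infected_female = 18),
                         trials_per_individual = 8,
                         observation_limit_s = 600,
                         residual_sd = 60,
                         mortality_per_trial = 0,
                         replacement = TRUE) {
  need <- c("virus_free_male", "virus_free_female", "infected_male",
            "infected_female")
  if (!all(need %in% names(n_per_group_sex)))
    stop("n_per_group_sex must name ", paste(need, collapse = ", "),
         call. = FALSE)
  tpi <- trials_per_individual
  if (!length(tpi) %in% 1:2 || any(tpi < 1 | tpi > 50))
    stop("trials_per_individual must be a count or range within [1, 50]",
         call. = FALSE)
  if (observation_limit_s <= 1) stop("observation_limit_s must be > 1",
                                     call. = FALSE)
  if (residual_sd <= 0) stop("residual_sd must be > 0", call. = FALSE)
  if (mortality_per_trial < 0 || mortality_per_trial >= 1)
    stop("mortality_per_trial must be in [0, 1)", call. = FALSE)
  structure(list(n_per_group_sex = n_per_group_sex[need],
                 trials_per_individual = tpi,
                 observation_limit_s = observation_limit_s,
                 residual_sd = residual_sd,
                 mortality_per_trial = mortality_per_trial,
                 replacement = isTRUE(replacement)),
            class = "study_design")
}

#' The default simulation scenario
#'
#' Hyperparameters are the posterior means reported for the study's two
#' groups, so simulated data mimic the real experiment: virus-free animals
#' mostly emerge (stay-logit mean -2.49) with latencies around 149 s that
#' shorten with experience (-10.8 s/trial); infected animals mostly stay
#' (0.845), and those that emerge do so late (284 s) with no consistent
#' experience effect (+2.52 s/trial) but large between-individual slope
#' variation (SD 26.1).
#'
#' @return List with elements `hyper` (named list of [group_hyper()] for
#'   `virus_free` and `infected`) and `design` (a [study_design()]).
#' @export
default_scenario <- function() {
  list(
    hyper = list(
      virus_free = group_hyper(mu_a = -2.49, sigma_a = 2.20,
                               mu_b = -0.032, sigma_b = 0.382,
                               mu_c = 149,   sigma_c = 75.1,
                               mu_d = -10.8, sigma_d = 5.33),
      infected   = group_hyper(mu_a = 0.845, sigma_a = 0.661,
                               mu_b = -0.046, sigma_b = 0.328,
                               mu_c = 284,   sigma_c = 64.3,
                               mu_d = 2.52,  sigma_d = 26.1)
    ),
    design = study_design()
  )
}

#' Draw per-individual effects from a group's hyper-distribution
#'
#' The four effects are mutually independent normals (no intercept-slope
#' correlation is modelled).
#'
#' @param hyper a [group_hyper()].
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return Data frame with `n` rows and columns `a`, `b`, `c`, `d`.
#' @export
sample_individual_effects <- function(hyper, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data.frame(a = stats::rnorm(n, hyper$mu_a, hyper$sigma_a),
             b = stats::rnorm(n, hyper$mu_b, hyper$sigma_b),
             c = stats::rnorm(n, hyper$mu_c, hyper$sigma_c),
             d = stats::rnorm(n, hyper$mu_d, hyper$sigma_d))
}

## Truncated-normal latencies by rejection, rounded to whole seconds, as the
## observer records them. The fitted likelihood stays untruncated gaussian.
rtrunc_latency <- function(mean, sd, lower, upper) {
  n <- length(mean)
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  if (sd == 0) {
    return(round(pmin(pmax(mean, lower), upper)))
  }
  for (tries in 1:10000) {
    draw <- stats::rnorm(length(todo), mean[todo], sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (length(todo) == 0L) break
  }
  if (length(todo) > 0L) {
    # pathological mean far outside the window: fall back to the boundary
    out[todo] <- pmin(pmax(mean[todo], lower), upper)
  }
  round(out)
}

#' Simulate emergence trials from given individual effects
#'
#' For individual i at experience t with centred covariate
#' x_t = t - mean(all trial indices in the schedule): the stay indicator is
#' Bernoulli(plogis(a_i + b_i x_t)); on emergence, latency is
#' Normal(c_i + d_i x_t, residual_sd) truncated by rejection to
#' \[1, observation_limit_s - 1\] and rounded to whole seconds. With a
#' positive mortality hazard, infected individuals may die after a trial
#' and (if `replacement`) are replaced by a fresh same-sex individual with
#' newly drawn effects that performs the remaining trials of the slot.
#'
#' @param effects named list with data frames `virus_free` and `infected`
#'   as from [sample_individual_effects()]; each must have at least as many
#'   rows as the design's group size, plus spare rows for replacements when
#'   mortality is on (replacement effects are drawn internally from `hyper`
#'   if provided in `...` via `hyper`).
#' @param design a [study_design()].
#' @param seed optional integer seed.
#' @param sex optional named list of sex vectors per group (recycled from
#'   the design's counts by default).
#' @param hyper optional named list of [group_hyper()] used to draw effects
#'   for replacement individuals (required if mortality > 0 and
#'   replacement).
#' @return A valid [trial_dataset()].
#' @export
simulate_trials <- function(effects, design, seed = NULL, sex = NULL,
                            hyper = NULL) {
  if (!all(c("virus_free", "infected") %in% names(effects)))
    stop("effects must be a named list with virus_free and infected",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  counts <- design$n_per_group_sex
  n_group <- c(virus_free = sum(counts[1:2]), infected = sum(counts[3:4]))
  if (sum(n_group) == 0L) stop("effects must be nonempty", call. = FALSE)
  for (g in names(n_group)) {
    if (nrow(effects[[g]]) < n_group[[g]])
      stop(sprintf("effects$%s has %d rows; design needs %d", g,
                   nrow(effects[[g]]), n_group[[g]]), call. = FALSE)
  }
  if (is.null(sex)) {
    sex <- list(
      virus_free = rep(c("male", "female"), counts[c("virus_free_male",
                                                     "virus_free_female")]),
      infected = rep(c("male", "female"), counts[c("infected_male",
                                                   "infected_female")]))
  }

  # trial schedule per individual (fixed count or uniform over a range)
  tpi <- design$trials_per_individual
  draw_T <- function(n) {
    if (length(tpi) == 1L) rep(as.integer(tpi), n)
    else sample(seq(tpi[1], tpi[2]), n, replace = TRUE)
  }

  rows <- list()
  for (g in c("virus_free", "infected")) {
    eff <- effects[[g]]
    n_i <- n_group[[g]]
    Ts <- draw_T(n_i)
    repl_counter <- 0L
    for (i in seq_len(n_i)) {
      id <- sprintf("%s_%02d", g, i)
      e <- eff[i, ]
      t_start <- 1L
      Ttot <- Ts[i]
      sx <- sex[[g]][i]
      repeat {
        died_at <- NA_integer_
        if (g == "infected" && design$mortality_per_trial > 0) {
          surv <- stats::rgeom(1L, design$mortality_per_trial)  # trials survived after each
          if (surv < Ttot - t_start + 1L) died_at <- t_start + surv
        }
        t_end <- if (is.na(died_at)) Ttot else died_at
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = id, group = g, sex = sx,
          trial_index = seq.int(1L, t_end - t_start + 1L),
          slot_trial = seq.int(t_start, t_end),
          a = e$a, b = e$b, c = e$c, d = e$d,
          stringsAsFactors = FALSE)
        if (is.na(died_at) || !design$replacement || died_at >= Ttot) break
        # same-sex replacement with fresh effects, new identity, restarts
        # its own experience count for the remaining trials of the slot
        if (is.null(hyper) || is.null(hyper[[g]]))
          stop("hyper must be supplied to draw replacement effects",
               call. = FALSE)
        repl_counter <- repl_counter + 1L
        id <- sprintf("%s_%02d_r%d", g, i, repl_counter)
        e <- sample_individual_effects(hyper[[g]], 1L)
        t_start <- died_at + 1L
      }
    }
  }
  sched <- do.call(rbind, rows)
  # experience covariate centred at the dataset-wide mean trial index
  xc <- mean(sched$trial_index)
  x <- sched$trial_index - xc

  p_stay <- stats::plogis(sched$a + sched$b * x)
  stay <- stats::runif(nrow(sched)) < p_stay
  emerged <- !stay
  latency <- rep(NA_real_, nrow(sched))
  if (any(emerged)) {
    latency[emerged] <- rtrunc_latency(
      sched$c[emerged] + sched$d[emerged] * x[emerged],
      design$residual_sd, lower = 1, upper = design$observation_limit_s - 1)
  }
  trial_dataset(data.frame(
    individual_id = sched$individual_id, group = sched$group,
    sex = sched$sex, trial_index = sched$trial_index,
    emerged = emerged, latency_s = latency, stringsAsFactors = FALSE))
}

#' Simulate a complete dataset from a scenario
#'
#' Convenience wrapper: draws individual effects from each group's
#' hyper-distribution, then simulates trials.
#'
#' @param scenario list with `hyper` and `design` as from
#'   [default_scenario()].
#' @param seed integer seed governing both the effect draws and the trials.
#' @return List with `dataset` (a [trial_dataset()]) and `effects` (the true
#'   per-individual effects, for parameter-recovery work).
#' @export
simulate_emergence <- function(scenario = default_scenario(), seed = 1L) {
  set.seed(seed)
  counts <- scenario$design$n_per_group_sex
  effects <- list(
    virus_free = sample_individual_effects(scenario$hyper$virus_free,
                                           sum(counts[1:2])),
    infected = sample_individual_effects(scenario$hyper$infected,
                                         sum(counts[3:4])))
  ds <- simulate_trials(effects, scenario$design, hyper = scenario$hyper)
  list(dataset = ds, effects = effects)
}

#' Read/write a scenario config
#'
#' Serialises the two [group_hyper()] objects and the [study_design()] to a
#' YAML file, so simulations are reproducible from a config + seed alone.
#'
#' @param scenario list with `hyper` and `design`.
#' @param path YAML file path.
#' @return `read_scenario` returns the scenario list; `write_scenario`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  obj <- list(hyper = lapply(scenario$hyper, unclass),
              design = unclass(scenario$design))
  obj$design$n_per_group_sex <- as.list(obj$design$n_per_group_sex)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  list(hyper = lapply(obj$hyper, function(h) do.call(group_hyper, h)),
       design = {
         d <- obj$design
         d$n_per_group_sex <- unlist(d$n_per_group_sex)
         d$trials_per_individual <- unlist(d$trials_per_individual)
         do.call(study_design, d)
       })
}
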