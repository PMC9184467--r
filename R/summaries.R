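#' Posterior of a group difference
#'
#' Computes the draw-wise difference (virus-free minus infected) of one
#' hyperparameter and the exceedance probability
#' P(infected > virus-free), the two derived columns of the study's summary
#' table. Ties count 0.5.
#'
#' @param fit a `hurdle_fit` containing both groups.
#' @param parameter bare hyperparameter name: one of `mu_a`, `sigma_a`,
#'   `mu_b`, `sigma_b`, `mu_c`, `sigma_c`, `mu_d`, `sigma_d`.
#' @param reference,other group labels forming the difference
#'   `reference - other` (defaults `virus_free - infected`).
#' @return A `group_comparison` list: `parameter`, `draws` (difference
#'   draws, aligned by chain and iteration), `mean`, `sd`,
#'   `exceedance` = P(other > reference).
#' @export
group_difference <- function(fit, parameter, reference = "virus_free",
                             other = "infected") {
  ref <- extract_draws(fit, parameter, reference)
  oth <- extract_draws(fit, parameter, other)
  d <- ref - oth
  structure(list(parameter = parameter, reference = reference,
                 other = other, draws = d, mean = mean(d),
                 sd = stats::sd(d),
                 exceedance = mean((oth > ref) + 0.5 * (oth == ref))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s - %s = %.3g +/- %.3g; P(%s > %s) = %.3f\n",
              x$parameter, x$reference, x$other, x$mean, x$sd,
              x$other, x$reference, x$exceedance))
  invisible(x)
}

#' Exceedance probability for one hyperparameter
#'
#' Fraction of aligned posterior draws in which the infected group's value
#' exceeds the virus-free group's (ties counted 0.5).
#'
#' @inheritParams group_difference
#' @return Probability in \[0, 1\].
#' @export
exceedance_probability <- function(fit, parameter,
                                   reference = "virus_free",
                                   other = "infected") {
  group_difference(fit, parameter, reference, other)$exceedance
}

#' Table-style summary of all hyperparameters
#'
#' One row per hyperparameter (four effect means and four effect SDs):
#' posterior mean +/- SD per group, the virus-free-minus-infected
#' difference, and the exceedance probability.
#'
#' @param fit a `hurdle_fit` with two groups.
#' @param reference,other group labels (see [group_difference()]).
#' @return Data frame with columns `parameter`, `<reference>_mean`,
#'   `<reference>_sd`, `<other>_mean`, `<other>_sd`, `difference_mean`,
#'   `difference_sd`, `p_exceed`.
#' @export
hyper_summary <- function(fit, reference = "virus_free", other = "infected") {
  pars <- c("mu_a", "sigma_a", "mu_b", "sigma_b", "mu_c", "sigma_c",
            "mu_d", "sigma_d")
  rows <- lapply(pars, function(p) {
    gc <- group_difference(fit, p, reference, other)
    ref <- extract_draws(fit, p, reference)
    oth <- extract_draws(fit, p, other)
    out <- data.frame(parameter = p,
                      ref_mean = mean(ref), ref_sd = stats::sd(ref),
                      oth_mean = mean(oth), oth_sd = stats::sd(oth),
                      difference_mean = gc$mean, difference_sd = gc$sd,
                      p_exceed = gc$exceedance, stringsAsFactors = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0(reference, c("_mean", "_sd")),
                       paste0(other, c("_mean", "_sd")))
  out
}

#' Per-individual personality scores
#'
#' Posterior mean of each individual's four effects: the binomial
#' (stay-logit) intercept and slope and the gaussian latency intercept and
#' slope. These are the partially pooled ("shrunk") individual estimates.
#'
#' @param fit a `hurdle_fit`.
#' @param ds optional [trial_dataset()]; when given, every individual in
#'   `ds` must be present in the posterior (error otherwise) and rows follow
#'   `ds`'s individual order.
#' @return Data frame (class `personality_scores`) with one row per
#'   individual: `individual_id`, `group`, `sex`, `a`, `b`, `c`, `d`.
#' @export
personality_scores <- function(fit, ds = NULL) {
  info <- fit$individuals
  if (!is.null(ds)) {
    want <- individuals(ds)
    missing_ids <- setdiff(want$individual_id, info$individual_id)
    if (length(missing_ids) > 0L) {
      stop("individual(s) missing from posterior: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    info <- info[match(want$individual_id, info$individual_id), ]
  }
  score <- function(k) {
    vapply(info$individual_id, function(id)
      mean(fit$draws[, , sprintf("%s[%s]", k, id)]), numeric(1L))
  }
  out <- data.frame(individual_id = info$individual_id,
                    group = info$group, sex = info$sex,
                    a = score("a"), b = score("b"), c = score("c"),
                    d = score("d"), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("personality_scores", "data.frame")
  out
}

#' Sex-disaggregated personality-score summaries
#'
#' Splits a personality-score table into the four group-by-sex strata and
#' summarises each trait per stratum, including the count of individuals
#' whose mean gaussian slope is positive (latency increasing with
#' experience).
#'
#' @param scores a [personality_scores()] table; sex must be known for all
#'   rows.
#' @return List with `scores` (per-stratum row subsets) and `summary`, a
#'   data frame with one row per (group, sex): `n`, per-trait mean and SD,
#'   and `n_positive_d`.
#' @export
disaggregate_by_sex <- function(scores) {
  if (anyNA(scores$sex)) {
    stop("sex unknown for individual(s): ",
         paste(scores$individual_id[is.na(scores$sex)], collapse = ", "),
         call. = FALSE)
  }
  strata <- expand.grid(group = group_levels(), sex = sex_levels(),
                        stringsAsFactors = FALSE)
  subsets <- list()
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    s <- scores[scores$group == strata$group[i] &
                  scores$sex == strata$sex[i], , drop = FALSE]
    subsets[[paste(strata$group[i], strata$sex[i], sep = "_")]] <<- s
    stat <- function(v, f) if (nrow(s) == 0L) NA_real_ else f(v)
    data.frame(group = strata$group[i], sex = strata$sex[i], n = nrow(s),
               a_mean = stat(s$a, mean), a_sd = stat(s$a, stats::sd),
               b_mean = stat(s$b, mean), b_sd = stat(s$b, stats::sd),
               c_mean = stat(s$c, mean), c_sd = stat(s$c, stats::sd),
               d_mean = stat(s$d, mean), d_sd = stat(s$d, stats::sd),
               n_positive_d = sum(s$d > 0), stringsAsFactors = FALSE)
  })
  list(scores = subsets, summary = do.call(rbind, rows))
}

#' Population prediction curves over experience
#'
#' For each trial in the grid and each posterior draw, evaluates the
#' population-level (hyper-mean plug-in) emergence probability
#' 1 - plogis(mu_a + mu_b x) and expected latency given emergence
#' mu_c + mu_d x, with x centred using the fit's stored constant; returns
#' pointwise posterior means and equal-tailed 95\% intervals. For stay
#' probabilities marginalised over individual heterogeneity see
#' [marginal_stay_probability()].
#'
#' @param fit a `hurdle_fit`.
#' @param group group label present in the fit.
#' @param trial_grid integer trial numbers (default 1:10).
#' @return Data frame (class `prediction_curve`) with columns `group`,
#'   `trial`, `emergence_prob`, `emergence_lo`, `emergence_hi`, `latency`,
#'   `latency_lo`, `latency_hi`.
#' @export
predict_curves <- function(fit, group, trial_grid = 1:10) {
  if (!group %in% fit$groups) stop("group not in posterior: ", group,
                                   call. = FALSE)
  mu_a <- extract_draws(fit, "mu_a", group)
  mu_b <- extract_draws(fit, "mu_b", group)
  mu_c <- extract_draws(fit, "mu_c", group)
  mu_d <- extract_draws(fit, "mu_d", group)
  q <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  rows <- lapply(trial_grid, function(tr) {
    x <- tr - fit$centring_constant
    p <- 1 - stats::plogis(mu_a + mu_b * x)
    lat <- mu_c + mu_d * x
    qp <- q(p); ql <- q(lat)
    data.frame(group = group, trial = tr,
               emergence_prob = mean(p), emergence_lo = qp[1L],
               emergence_hi = qp[2L],
               latency = mean(lat), latency_lo = ql[1L],
               latency_hi = ql[2L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prediction_curve", "data.frame")
  out
}
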