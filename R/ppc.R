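#' Built-in test statistics for posterior predictive checks
#'
#' Each statistic maps a [trial_dataset()] to one number; `NA` (e.g. the
#' latency SD of a replicate with no emergences) causes the replicate to be
#' skipped and counted. The set probes both hurdle parts: the binary
#' stay/emerge process and the location, spread, shape and tail of the
#' observed latencies.
#'
#' @return Named list of functions.
#' @export
ppc_statistics <- function() {
  lat <- function(ds) ds$latency_s[ds$emerged]
  list(
    stay_fraction = function(ds) mean(!ds$emerged),
    latency_mean = function(ds) {
      y <- lat(ds); if (length(y) == 0L) NA_real_ else mean(y)
    },
    latency_sd = function(ds) {
      y <- lat(ds); if (length(y) < 2L) NA_real_ else stats::sd(y)
    },
    latency_skewness = function(ds) {
      y <- lat(ds)
      if (length(y) < 3L || stats::sd(y) == 0) return(NA_real_)
      mean((y - mean(y))^3) / stats::sd(y)^3
    },
    latency_frac_gt_300 = function(ds) {
      y <- lat(ds); if (length(y) == 0L) NA_real_ else mean(y > 300)
    },
    n_records = function(ds) nrow(ds)
  )
}

## simulate one replicate dataset at the observed design from one draw
simulate_replicate <- function(fit, ds, draw_idx, observation_limit_s = 600) {
  d <- dim(fit$draws)
  it <- (draw_idx - 1L) %% d[1L] + 1L
  ch <- (draw_idx - 1L) %/% d[1L] + 1L
  ids_u <- fit$individuals$individual_id
  ind <- match(ds$individual_id, ids_u)
  ids <- ds$individual_id
  x <- ds$trial_index - fit$centring_constant
  pos <- function(k) match(sprintf("%s[%s]", k, ids_u), fit$parameters)
  a <- fit$draws[it, ch, pos("a")][ind]
  b <- fit$draws[it, ch, pos("b")][ind]
  cc <- fit$draws[it, ch, pos("c")][ind]
  dd <- fit$draws[it, ch, pos("d")][ind]
  sres <- fit$draws[it, ch, "sigma_res"]
  stay <- stats::runif(nrow(ds)) < stats::plogis(a + b * x)
  emerged <- !stay
  latency <- rep(NA_real_, nrow(ds))
  if (any(emerged)) {
    latency[emerged] <- rtrunc_latency(cc[emerged] + dd[emerged] * x[emerged],
                                       sres, 1, observation_limit_s - 1)
  }
  trial_dataset(data.frame(
    individual_id = ids, group = ds$group, sex = ds$sex,
    trial_index = ds$trial_index, emerged = emerged, latency_s = latency,
    stringsAsFactors = FALSE))
}

#' Posterior predictive check
#'
#' For each of `draws` posterior draws (evenly spaced through the pooled
#' chains), simulates a replicate dataset under the fitted model at the
#' observed design — same individuals, same trial indices, same centring,
#' conditioning on that draw's individual effects — computes the statistic
#' on the replicate, and compares with the observed value. The Bayesian
#' p-value is P(T_rep >= T_obs) over usable replicates.
#'
#' @param fit a `hurdle_fit`.
#' @param ds the observed [trial_dataset()] (every individual must be in
#'   the posterior).
#' @param statistic name of a built-in (see [ppc_statistics()]) or a
#'   function of a dataset.
#' @param draws number of posterior draws to use (default 500).
#' @param seed integer seed for the replicate simulations.
#' @param observation_limit_s censoring window for replicate latencies.
#' @return A `ppc_result`: `statistic`, `observed`, `replicates`,
#'   `p_value`, `n_skipped`.
#' @export
posterior_predictive_check <- function(fit, ds, statistic = "latency_mean",
                                       draws = 500L, seed = 1L,
                                       observation_limit_s = 600) {
  if (is.character(statistic)) {
    stats_all <- ppc_statistics()
    if (!statistic %in% names(stats_all)) {
      stop("unknown statistic: ", statistic, "; built-ins: ",
           paste(names(stats_all), collapse = ", "), call. = FALSE)
    }
    stat_name <- statistic
    stat_fun <- stats_all[[statistic]]
  } else {
    stat_name <- deparse(substitute(statistic))
    stat_fun <- match.fun(statistic)
  }
  missing_ids <- setdiff(unique(ds$individual_id),
                         fit$individuals$individual_id)
  if (length(missing_ids) > 0L) {
    stop("individual(s) missing from posterior: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  n_total <- dim(fit$draws)[1L] * dim(fit$draws)[2L]
  use <- unique(round(seq(1L, n_total, length.out = min(draws, n_total))))
  observed <- stat_fun(ds)
  if (is.na(observed)) {
    stop("statistic '", stat_name, "' is not computable on the observed ",
         "dataset", call. = FALSE)
  }
  reps <- vapply(use, function(i)
    stat_fun(simulate_replicate(fit, ds, i, observation_limit_s)),
    numeric(1L))
  skipped <- sum(is.na(reps))
  reps_ok <- reps[!is.na(reps)]
  structure(list(statistic = stat_name, observed = observed,
                 replicates = reps_ok,
                 p_value = mean(reps_ok >= observed),
                 n_skipped = skipped), class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("PPC %s: observed %.4g, %d replicates (%d skipped), p = %.3f\n",
              x$statistic, x$observed, length(x$replicates), x$n_skipped,
              x$p_value))
  invisible(x)
}

#' Run all built-in PPC statistics
#'
#' @inheritParams posterior_predictive_check
#' @return Data frame with one row per statistic: `statistic`, `observed`,
#'   `p_value`, `n_replicates`, `n_skipped`.
#' @export
ppc_all <- function(fit, ds, draws = 500L, seed = 1L,
                    observation_limit_s = 600) {
  out <- lapply(seq_along(ppc_statistics()), function(i) {
    nm <- names(ppc_statistics())[i]
    r <- posterior_predictive_check(fit, ds, nm, draws = draws,
                                    seed = seed + i - 1L,
                                    observation_limit_s = observation_limit_s)
    data.frame(statistic = nm, observed = r$observed, p_value = r$p_value,
               n_replicates = length(r$replicates),
               n_skipped = r$n_skipped, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
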