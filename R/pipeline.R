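#' End-to-end analysis pipeline
#'
#' Chains the full workflow: obtain trial data (read a CSV or simulate from
#' a scenario), fit the hurdle model, write the posterior, the
#' hyperparameter summary table, the personality-score table, prediction
#' curves, the posterior predictive checks, and a JSON manifest recording
#' configuration, seeds and package version.
#'
#' @param config a named list (or path to a YAML file) with entries
#'   \describe{
#'     \item{data}{path to a trial CSV, or `NULL` to simulate}
#'     \item{dialect}{optional path to a dialect YAML (see
#'       [read_dialect()])}
#'     \item{scenario}{optional path to a scenario YAML (see
#'       [read_scenario()]); defaults to [default_scenario()]}
#'     \item{out}{output directory (required)}
#'     \item{seed}{top-level integer seed; stage seeds are derived from it}
#'     \item{chains, iter, warmup, thin}{sampler settings}
#'     \item{ppc_draws}{posterior draws used per PPC statistic}
#'     \item{force}{pass convergence failures through as warnings}
#'   }
#' @return Invisibly, a list with the fitted model and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out)) stop("config$out is required", call. = FALSE)
  if (!is.null(config$data) && !is.null(config$simulate) &&
      isTRUE(config$simulate)) {
    stop("give either data or simulate, not both", call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  # deterministic stage seeds derived from the single top-level seed
  stage_seed <- function(k) (seed * 97L + k * 1009L) %% 900000000L + 1L

  if (!is.null(config$data)) {
    dialect <- if (is.null(config$dialect)) trial_dialect() else
      read_dialect(config$dialect)
    ds <- read_trials(config$data, dialect)
    data_path <- config$data
  } else {
    scenario <- if (is.null(config$scenario)) default_scenario() else
      read_scenario(config$scenario)
    sim <- simulate_emergence(scenario, seed = stage_seed(1L))
    ds <- sim$dataset
    data_path <- file.path(out, "trials.csv")
    write_trials(ds, data_path)
  }
  viol <- validate_dataset(ds)
  if (nrow(viol) > 0L) {
    utils::write.csv(viol, file.path(out, "validation.csv"),
                     row.names = FALSE)
    stop("stage 'validate': dataset has ", nrow(viol),
         " violation(s); see validation.csv", call. = FALSE)
  }

  num <- function(x, default) if (is.null(x)) default else as.integer(x)
  fit <- tryCatch(
    fit_hurdle(ds, chains = num(config$chains, 4L),
               iter = num(config$iter, 4000L),
               warmup = num(config$warmup, 1500L),
               thin = num(config$thin, 1L),
               seed = stage_seed(2L),
               force = isTRUE(config$force)),
    error = function(e) stop("stage 'fit': ", conditionMessage(e),
                             call. = FALSE))
  write_posterior(fit, file.path(out, "posterior"))
  utils::write.csv(fit$diagnostics, file.path(out, "diagnostics.csv"),
                   row.names = FALSE)
  utils::write.csv(hyper_summary(fit), file.path(out, "hyper_summary.csv"),
                   row.names = FALSE)
  scores <- personality_scores(fit, ds)
  utils::write.csv(as.data.frame(scores),
                   file.path(out, "personality_scores.csv"),
                   row.names = FALSE)
  if (!anyNA(scores$sex)) {
    utils::write.csv(disaggregate_by_sex(scores)$summary,
                     file.path(out, "scores_by_sex.csv"), row.names = FALSE)
  }
  curves <- do.call(rbind, lapply(fit$groups, function(g)
    predict_curves(fit, g, 1:10)))
  utils::write.csv(as.data.frame(curves),
                   file.path(out, "prediction_curves.csv"),
                   row.names = FALSE)
  ppc <- ppc_all(fit, ds, draws = num(config$ppc_draws, 200L),
                 seed = stage_seed(3L))
  utils::write.csv(ppc, file.path(out, "ppc.csv"), row.names = FALSE)

  manifest <- list(
    package = "crickemerge",
    version = as.character(utils::packageVersion("crickemerge")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    stage_seeds = list(simulate = stage_seed(1L), fit = stage_seed(2L),
                       ppc = stage_seed(3L)),
    config = config[setdiff(names(config), "out")],
    data = data_path,
    centring_constant = fit$centring_constant,
    chain_seeds = fit$seeds)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, dataset = ds, out = out))
}
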