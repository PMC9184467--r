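#' Persist and restore a fitted posterior
#'
#' A fit is stored as a self-describing plain-text container: a directory
#' holding `draws.csv` (columns `chain`, `iteration`, then one column per
#' parameter) and `meta.json` (parameter names, groups, individual index,
#' centring constant, seeds, sampler settings, priors, fixed parameters and
#' the diagnostics table).
#'
#' @param fit a `hurdle_fit`.
#' @param path directory to create/overwrite.
#' @return `write_posterior` returns `path` invisibly; `read_posterior`
#'   returns the reconstructed `hurdle_fit`.
#' @export
write_posterior <- function(fit, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(fit$draws)
  flat <- do.call(rbind, lapply(seq_len(d[2L]), function(ch) {
    cbind(chain = ch, iteration = seq_len(d[1L]), fit$draws[, ch, ])
  }))
  utils::write.csv(as.data.frame(flat), file.path(path, "draws.csv"),
                   row.names = FALSE)
  meta <- list(parameters = fit$parameters, groups = fit$groups,
               individuals = fit$individuals,
               centring_constant = fit$centring_constant,
               prior = unclass(fit$prior),
               fixed = list(value = as.data.frame(fit$fixed$value),
                            groups = rownames(fit$fixed$value),
                            sigma_res = fit$fixed$sigma_res),
               seeds = fit$seeds, chains = fit$chains, iter = fit$iter,
               warmup = fit$warmup, thin = fit$thin,
               hyper_parameters = fit$hyper_parameters,
               accept = as.list(fit$accept),
               diagnostics = fit$diagnostics)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  flat <- utils::read.csv(file.path(path, "draws.csv"), check.names = FALSE)
  chains <- max(flat$chain)
  n_iter <- max(flat$iteration)
  pars <- meta$parameters
  draws <- array(NA_real_, c(n_iter, chains, length(pars)),
                 dimnames = list(iteration = NULL, chain = NULL,
                                 parameter = pars))
  for (ch in seq_len(chains)) {
    draws[, ch, ] <- as.matrix(flat[flat$chain == ch, pars, drop = FALSE])
  }
  ind <- as.data.frame(meta$individuals)
  ind$group <- factor(ind$group, levels = group_levels())
  ind$sex <- factor(ind$sex, levels = sex_levels())
  fxv <- as.matrix(meta$fixed$value)
  rownames(fxv) <- meta$fixed$groups
  structure(list(
    draws = draws, parameters = pars, groups = meta$groups,
    individuals = ind, centring_constant = meta$centring_constant,
    prior = do.call(prior_config, meta$prior),
    fixed = list(value = fxv,
                 sigma_res = if (is.null(meta$fixed$sigma_res))
                   NA_real_ else meta$fixed$sigma_res),
    seeds = meta$seeds, chains = meta$chains, iter = meta$iter,
    warmup = meta$warmup, thin = meta$thin,
    hyper_parameters = meta$hyper_parameters,
    accept = unlist(meta$accept),
    diagnostics = as.data.frame(meta$diagnostics)), class = "hurdle_fit")
}
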