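#' Fit the hierarchical binomial-gaussian hurdle model
#'
#' Samples the joint posterior of the group hyperparameters (mean and SD of
#' the four individual-level effect distributions per group), the shared
#' residual latency SD, and all per-individual effects, using an adaptive
#' Metropolis-within-Gibbs scheme:
#' \itemize{
#'   \item binomial effects `a_i`, `b_i`: per-individual random-walk
#'     Metropolis, step sizes adapted during warmup toward 44\% acceptance;
#'   \item gaussian effects `(c_i, d_i)`: exact bivariate conjugate Gibbs;
#'   \item hyper-means: exact conjugate Gibbs given the effects;
#'   \item hyper-SDs and residual SD: random-walk Metropolis on the log
#'     scale (half-normal priors).
#' }
#' The experience covariate is centred at the dataset-wide mean trial index
#' (stored with the fit). The binomial linear predictor models the logit of
#' *staying* in the tube.
#'
#' @param ds a valid, nonempty [trial_dataset()].
#' @param chains number of chains (>= 2).
#' @param iter post-warmup iterations per chain.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param seed integer seed; per-chain seeds are derived as
#'   `seed + 1000 * (chain - 1)` unless `chain_seeds` is given.
#' @param chain_seeds optional explicit per-chain seeds (must be distinct).
#' @param thin keep every `thin`-th post-warmup draw.
#' @param prior a [prior_config()].
#' @param fixed named list of parameters to hold fixed, e.g.
#'   `list(mu_b = c(virus_free = 0), sigma_b = c(virus_free = 0),
#'   sigma_res = 50)`. Fixing a `sigma_*` at 0 clamps the corresponding
#'   effects to the (then also required to be fixed) hyper-mean.
#' @param force if `TRUE`, convergence failures (R-hat > `rhat_max` or
#'   bulk ESS < `ess_min` on any free hyperparameter) warn instead of
#'   erroring.
#' @param rhat_max,ess_min convergence gates applied to the reported
#'   hyperparameters.
#' @return A `hurdle_fit` object: draws array
#'   `[iteration, chain, parameter]` with named parameters
#'   (`mu_a[group]`, `sigma_a[group]`, ..., `sigma_res`, `a[id]`, ...),
#'   the per-individual index, centring constant, seeds, prior, and a
#'   diagnostics table.
#' @export
fit_hurdle <- function(ds, chains = 4L, iter = 4000L, warmup = 1500L,
                       seed = 1L, chain_seeds = NULL, thin = 1L,
                       prior = prior_config(), fixed = list(),
                       force = FALSE, rhat_max = 1.01, ess_min = 400) {
  if (nrow(ds) == 0L) stop("dataset is empty", call. = FALSE)
  bad <- validate_dataset(ds)
  if (nrow(bad) > 0L) {
    stop("dataset fails validation (", nrow(bad), " violation(s)); first: ",
         bad$message[1L], " at row ", bad$row[1L], call. = FALSE)
  }
  if (chains < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (is.null(chain_seeds)) chain_seeds <- seed + 1000L * (seq_len(chains) - 1L)
  if (length(chain_seeds) != chains || anyDuplicated(chain_seeds)) {
    stop("chains must have distinct seeds", call. = FALSE)
  }

  centring_constant <- centre_experience(ds)
  prep <- prepare_model_data(ds, centring_constant)
  groups <- as.character(unique(prep$info$group))
  fx <- parse_fixed(fixed, groups)

  # a group whose animals never emerged has no gaussian data; only allowed
  # when its gaussian hyperparameters are all held fixed
  for (g in groups) {
    g_idx <- which(as.character(prep$info$group) == g)
    if (!any(prep$e_ind %in% g_idx)) {
      gauss_fixed <- all(!is.na(c(fx$value[g, c("mu_c", "sigma_c",
                                                "mu_d", "sigma_d")])))
      if (!gauss_fixed) {
        stop("group '", g, "' has zero emergences; the gaussian part is ",
             "unidentifiable (fix its gaussian hyperparameters to proceed)",
             call. = FALSE)
      }
    }
  }

  ctrl <- list(iter = as.integer(iter), warmup = as.integer(warmup),
               thin = as.integer(thin))
  res <- lapply(seq_len(chains), function(k) {
    run_hurdle_chain(prep, groups, prior, fx, ctrl, chain_seeds[k])
  })

  n_save <- nrow(res[[1L]]$draws)
  par_names <- colnames(res[[1L]]$draws)
  draws <- array(NA_real_, dim = c(n_save, chains, length(par_names)),
                 dimnames = list(iteration = NULL, chain = NULL,
                                 parameter = par_names))
  for (k in seq_len(chains)) draws[, k, ] <- res[[k]]$draws

  fit <- structure(list(
    draws = draws, parameters = par_names, groups = groups,
    individuals = prep$info, centring_constant = centring_constant,
    prior = prior, fixed = fx, seeds = chain_seeds,
    chains = chains, iter = ctrl$iter, warmup = ctrl$warmup,
    thin = ctrl$thin,
    hyper_parameters = hyper_par_names(groups),
    accept = res[[1L]]$accept), class = "hurdle_fit")
  fit$diagnostics <- diagnostics(fit)

  free_hyper <- setdiff(fit$hyper_parameters, fixed_par_names(fx, groups))
  dg <- fit$diagnostics[fit$diagnostics$parameter %in% free_hyper, ]
  bad <- dg[!is.na(dg$rhat) & (dg$rhat > rhat_max | dg$ess_bulk < ess_min), ]
  if (nrow(bad) > 0L) {
    msg <- paste0("convergence failure on: ",
                  paste(sprintf("%s (R-hat %.3f, ESS %.0f)", bad$parameter,
                                bad$rhat, bad$ess_bulk), collapse = "; "))
    if (force) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  fit
}

hyper_par_names <- function(groups) {
  c(as.vector(t(outer(groups, c("mu_a", "sigma_a", "mu_b", "sigma_b",
                                "mu_c", "sigma_c", "mu_d", "sigma_d"),
                      function(g, p) sprintf("%s[%s]", p, g)))),
    "sigma_res")
}

## fixed-parameter request -> matrix of values (NA = free)
parse_fixed <- function(fixed, groups) {
  hp <- c("mu_a", "sigma_a", "mu_b", "sigma_b", "mu_c", "sigma_c",
          "mu_d", "sigma_d")
  value <- matrix(NA_real_, nrow = length(groups), ncol = length(hp),
                  dimnames = list(groups, hp))
  sigma_res <- NA_real_
  for (nm in names(fixed)) {
    if (nm == "sigma_res") {
      sigma_res <- as.numeric(fixed[[nm]])
      if (sigma_res <= 0) stop("fixed sigma_res must be > 0", call. = FALSE)
    } else if (nm %in% hp) {
      v <- fixed[[nm]]
      if (is.null(names(v)) || !all(names(v) %in% groups)) {
        stop("fixed$", nm, " must be a named vector over groups",
             call. = FALSE)
      }
      value[names(v), nm] <- as.numeric(v)
    } else {
      stop("unknown fixed parameter: ", nm, call. = FALSE)
    }
  }
  for (g in groups) {
    for (k in c("a", "b", "c", "d")) {
      sg <- value[g, paste0("sigma_", k)]
      if (!is.na(sg) && sg == 0 && is.na(value[g, paste0("mu_", k)])) {
        stop("sigma_", k, " fixed at 0 requires mu_", k,
             " fixed too (group ", g, ")", call. = FALSE)
      }
    }
  }
  list(value = value, sigma_res = sigma_res)
}

fixed_par_names <- function(fx, groups) {
  out <- character()
  for (g in groups) {
    set <- colnames(fx$value)[!is.na(fx$value[g, ])]
    out <- c(out, sprintf("%s[%s]", set, g))
  }
  if (!is.na(fx$sigma_res)) out <- c(out, "sigma_res")
  out
}

## one MCMC chain; prep is from prepare_model_data()
run_hurdle_chain <- function(prep, groups, prior, fx, ctrl, chain_seed) {
  set.seed(chain_seed)
  n_ind <- prep$n_ind
  gi <- match(as.character(prep$info$group), groups)  # group index per ind
  ind <- prep$ind; x <- prep$x; stay <- prep$stay
  e_ind <- prep$e_ind; e_x <- prep$e_x; e_y <- prep$e_y
  n_e <- length(e_y)

  # per-individual aggregation that keeps empty individuals (rowsum drops
  # groups with no rows)
  agg <- function(v, idx) {
    out <- numeric(n_ind)
    if (length(v) > 0L) {
      r <- rowsum(v, idx)
      out[as.integer(rownames(r))] <- r
    }
    out
  }
  # per-individual gaussian sufficient statistics
  m_i <- tabulate(e_ind, nbins = n_ind)
  Sx <- agg(e_x, e_ind)
  Sxx <- agg(e_x^2, e_ind)
  Sy <- agg(e_y, e_ind)
  Sxy <- agg(e_x * e_y, e_ind)

  llbin_i <- function(a, b) {
    eta <- a[ind] + b[ind] * x
    as.vector(rowsum(stay * eta - log1pexp(eta), ind))
  }

  G <- length(groups)
  hp_names <- colnames(fx$value)
  mu <- matrix(0, G, 4, dimnames = list(groups, c("a", "b", "c", "d")))
  sg <- matrix(1, G, 4, dimnames = list(groups, c("a", "b", "c", "d")))

  # data-informed initial values, jittered per chain
  n_i <- tabulate(ind, nbins = n_ind)
  s_i <- agg(stay, ind)
  a <- stats::qlogis((s_i + 0.5) / (n_i + 1)) + stats::rnorm(n_ind, 0, 0.3)
  b <- stats::rnorm(n_ind, 0, 0.1)
  cbar_i <- ifelse(m_i > 0, Sy / pmax(m_i, 1), NA)
  for (g in seq_len(G)) {
    here <- gi == g
    gc <- mean(cbar_i[here], na.rm = TRUE)
    if (!is.finite(gc)) gc <- if (!is.na(fx$value[g, "mu_c"]))
      fx$value[g, "mu_c"] else 300
    cbar_i[here & is.na(cbar_i)] <- gc
    mu[g, "a"] <- mean(a[here]) + stats::rnorm(1, 0, 0.3)
    mu[g, "b"] <- stats::rnorm(1, 0, 0.1)
    mu[g, "c"] <- gc + stats::rnorm(1, 0, 15)
    mu[g, "d"] <- stats::rnorm(1, 0, 3)
    sg[g, "a"] <- max(stats::sd(a[here]), 0.5) * exp(stats::rnorm(1, 0, 0.2))
    sg[g, "b"] <- 0.3 * exp(stats::rnorm(1, 0, 0.2))
    sg[g, "c"] <- max(stats::sd(cbar_i[here]), 20, na.rm = TRUE) *
      exp(stats::rnorm(1, 0, 0.2))
    sg[g, "d"] <- 10 * exp(stats::rnorm(1, 0, 0.2))
  }
  c_eff <- cbar_i + stats::rnorm(n_ind, 0, 5)
  d_eff <- stats::rnorm(n_ind, 0, 2)
  sigma_res <- 50 * exp(stats::rnorm(1, 0, 0.2))

  # apply fixed values
  mu_fixed <- !is.na(fx$value[, c("mu_a", "mu_b", "mu_c", "mu_d"),
                              drop = FALSE])
  sg_fixed <- !is.na(fx$value[, c("sigma_a", "sigma_b", "sigma_c",
                                  "sigma_d"), drop = FALSE])
  for (g in seq_len(G)) for (k in 1:4) {
    if (mu_fixed[g, k]) mu[g, k] <- fx$value[g, paste0("mu_", c("a", "b", "c", "d")[k])]
    if (sg_fixed[g, k]) sg[g, k] <- fx$value[g, paste0("sigma_", c("a", "b", "c", "d")[k])]
  }
  res_fixed <- !is.na(fx$sigma_res)
  if (res_fixed) sigma_res <- fx$sigma_res
  # effects clamped wherever their sigma is fixed at zero
  clamp <- sg[gi, , drop = FALSE] == 0
  a[clamp[, "a"]] <- mu[gi, "a"][clamp[, "a"]]
  b[clamp[, "b"]] <- mu[gi, "b"][clamp[, "b"]]
  c_eff[clamp[, "c"]] <- mu[gi, "c"][clamp[, "c"]]
  d_eff[clamp[, "d"]] <- mu[gi, "d"][clamp[, "d"]]
  free_a <- !clamp[, "a"]; free_b <- !clamp[, "b"]

  # prior scales aligned with mu/sg matrices
  mu_prior_sd <- c(prior$mu_a_sd, prior$mu_b_sd, prior$mu_c_sd, prior$mu_d_sd)
  sg_prior_sd <- c(prior$sigma_a_sd, prior$sigma_b_sd, prior$sigma_c_sd,
                   prior$sigma_d_sd)

  step_a <- rep(1, n_ind); step_b <- rep(0.3, n_ind)
  step_sg <- matrix(0.3, G, 4); step_res <- 0.1
  # step sizes for the joint translation/scaling moves
  step_tr <- matrix(c(0.5, 0.2, 10, 3), G, 4, byrow = TRUE)
  step_sc <- matrix(0.2, G, 4)
  ll_i <- llbin_i(a, b)

  # record subsets per group (binomial: all records; gaussian: emerged)
  rec_g <- lapply(seq_len(G), function(g) which(gi[ind] == g))
  erec_g <- lapply(seq_len(G), function(g) which(gi[e_ind] == g))

  total <- ctrl$warmup + ctrl$iter
  n_save <- ctrl$iter %/% ctrl$thin
  par_names <- c(hyper_par_names(groups),
                 sprintf("a[%s]", prep$info$individual_id),
                 sprintf("b[%s]", prep$info$individual_id),
                 sprintf("c[%s]", prep$info$individual_id),
                 sprintf("d[%s]", prep$info$individual_id))
  draws <- matrix(NA_real_, n_save, length(par_names),
                  dimnames = list(NULL, par_names))
  acc_a <- acc_b <- 0
  save_row <- 0L

  for (it in seq_len(total)) {
    adapting <- it <= ctrl$warmup
    gam <- 2 / (20 + it)^0.6   # Robbins-Monro adaptation rate

    # --- binomial intercepts (vectorised RW Metropolis over individuals)
    if (any(free_a)) {
      a_prop <- a + step_a * stats::rnorm(n_ind)
      a_prop[!free_a] <- a[!free_a]
      ll_prop <- llbin_i(a_prop, b)
      lr <- ll_prop - ll_i +
        stats::dnorm(a_prop, mu[gi, "a"], sg[gi, "a"], log = TRUE) -
        stats::dnorm(a, mu[gi, "a"], sg[gi, "a"], log = TRUE)
      lr[!free_a] <- -Inf
      ok <- log(stats::runif(n_ind)) < lr
      a[ok] <- a_prop[ok]; ll_i[ok] <- ll_prop[ok]
      if (adapting) {
        alpha <- pmin(1, exp(lr)); alpha[!free_a] <- 0.44
        step_a <- step_a * exp(gam * (alpha - 0.44))
      } else acc_a <- acc_a + mean(ok[free_a])
    }
    # --- binomial slopes
    if (any(free_b)) {
      b_prop <- b + step_b * stats::rnorm(n_ind)
      b_prop[!free_b] <- b[!free_b]
      ll_prop <- llbin_i(a, b_prop)
      lr <- ll_prop - ll_i +
        stats::dnorm(b_prop, mu[gi, "b"], sg[gi, "b"], log = TRUE) -
        stats::dnorm(b, mu[gi, "b"], sg[gi, "b"], log = TRUE)
      lr[!free_b] <- -Inf
      ok <- log(stats::runif(n_ind)) < lr
      b[ok] <- b_prop[ok]; ll_i[ok] <- ll_prop[ok]
      if (adapting) {
        alpha <- pmin(1, exp(lr)); alpha[!free_b] <- 0.44
        step_b <- step_b * exp(gam * (alpha - 0.44))
      } else acc_b <- acc_b + mean(ok[free_b])
    }

    # --- gaussian effects: exact bivariate conjugate update
    s2 <- sigma_res^2
    free_c <- !clamp[, "c"]; free_d <- !clamp[, "d"]
    pc <- 1 / sg[gi, "c"]^2; pd <- 1 / sg[gi, "d"]^2
    both <- free_c & free_d
    if (any(both)) {
      p11 <- m_i / s2 + pc; p12 <- Sx / s2; p22 <- Sxx / s2 + pd
      r1 <- Sy / s2 + mu[gi, "c"] * pc
      r2 <- Sxy / s2 + mu[gi, "d"] * pd
      det <- p11 * p22 - p12^2
      mc <- (p22 * r1 - p12 * r2) / det
      md <- (p11 * r2 - p12 * r1) / det
      # covariance = inverse precision; sample via its Cholesky factor
      v11 <- p22 / det; v21 <- -p12 / det; v22 <- p11 / det
      L11 <- sqrt(v11); L21 <- v21 / L11; L22 <- sqrt(pmax(v22 - L21^2, 0))
      z1 <- stats::rnorm(n_ind); z2 <- stats::rnorm(n_ind)
      c_new <- mc + L11 * z1
      d_new <- md + L21 * z1 + L22 * z2
      c_eff[both] <- c_new[both]; d_eff[both] <- d_new[both]
    }
    only_c <- free_c & !free_d
    if (any(only_c)) {
      prec <- m_i / s2 + pc
      mn <- ((Sy - d_eff * Sx) / s2 + mu[gi, "c"] * pc) / prec
      cc <- mn + stats::rnorm(n_ind) / sqrt(prec)
      c_eff[only_c] <- cc[only_c]
    }
    only_d <- free_d & !free_c
    if (any(only_d)) {
      prec <- Sxx / s2 + pd
      mn <- ((Sxy - c_eff * Sx) / s2 + mu[gi, "d"] * pd) / prec
      dd <- mn + stats::rnorm(n_ind) / sqrt(prec)
      d_eff[only_d] <- dd[only_d]
    }

    # --- hyper-means: conjugate given effects
    eff_mat <- cbind(a = a, b = b, c = c_eff, d = d_eff)
    for (g in seq_len(G)) {
      here <- gi == g; ng <- sum(here)
      for (k in 1:4) {
        if (mu_fixed[g, k]) next
        prec <- ng / sg[g, k]^2 + 1 / mu_prior_sd[k]^2
        mn <- (sum(eff_mat[here, k]) / sg[g, k]^2) / prec
        mu[g, k] <- mn + stats::rnorm(1) / sqrt(prec)
      }
    }

    # --- hyper-SDs: RW Metropolis on log(sigma), half-normal prior
    for (rep_sg in 1:3) for (g in seq_len(G)) {
      here <- gi == g; ng <- sum(here)
      for (k in 1:4) {
        if (sg_fixed[g, k]) next
        e <- eff_mat[here, k]
        SSk <- sum((e - mu[g, k])^2)
        cur <- sg[g, k]
        prop <- cur * exp(step_sg[g, k] * stats::rnorm(1))
        ltarget <- function(s) -ng * log(s) - SSk / (2 * s^2) -
          s^2 / (2 * sg_prior_sd[k]^2) + log(s)
        lr1 <- ltarget(prop) - ltarget(cur)
        if (log(stats::runif(1)) < lr1) sg[g, k] <- prop
        if (adapting) {
          step_sg[g, k] <- step_sg[g, k] *
            exp(gam * (min(1, exp(lr1)) - 0.44))
        }
      }
    }

    # --- joint moves along the hierarchical funnel: translate
    # (mu, effects) together, or rescale (sigma, effects - mu) together.
    # The random-effects prior term is invariant under both, so the
    # acceptance ratio reduces to the data-likelihood change plus the
    # hyper-prior change (the scaling Jacobian cancels exactly).
    bin_ll_g <- function(g, av, bv) {
      r <- rec_g[[g]]
      eta <- av[ind[r]] + bv[ind[r]] * x[r]
      sum(stay[r] * eta - log1pexp(eta))
    }
    touched_bin <- FALSE
    for (rep_f in 1:2) for (g in seq_len(G)) {
      here <- gi == g
      llg <- bin_ll_g(g, a, b)  # cached; updated on accepted binomial moves
      for (k in 1:4) {
        if (sg[g, k] == 0) next
        gauss <- k >= 3L
        if (gauss && length(erec_g[[g]]) == 0L) next
        if (gauss) {
          r <- erec_g[[g]]
          resid <- e_y[r] - c_eff[e_ind[r]] - d_eff[e_ind[r]] * e_x[r]
          w <- if (k == 3L) rep(1, length(r)) else e_x[r]
        }
        # translation move
        if (!mu_fixed[g, k]) {
          dl <- step_tr[g, k] * stats::rnorm(1)
          if (gauss) {
            dll <- (2 * dl * sum(resid * w) - dl^2 * sum(w^2)) /
              (2 * sigma_res^2)
          } else {
            av <- a; bv <- b
            if (k == 1L) av[here] <- a[here] + dl else
              bv[here] <- b[here] + dl
            dll <- bin_ll_g(g, av, bv) - llg
          }
          dpr <- stats::dnorm(mu[g, k] + dl, 0, mu_prior_sd[k], log = TRUE) -
            stats::dnorm(mu[g, k], 0, mu_prior_sd[k], log = TRUE)
          acc_p <- min(1, exp(dll + dpr))
          if (stats::runif(1) < acc_p) {
            mu[g, k] <- mu[g, k] + dl
            if (k == 1L) a[here] <- a[here] + dl
            else if (k == 2L) b[here] <- b[here] + dl
            else if (k == 3L) c_eff[here] <- c_eff[here] + dl
            else d_eff[here] <- d_eff[here] + dl
            if (gauss) resid <- resid - dl * w
            else { touched_bin <- TRUE; llg <- llg + dll }
          }
          if (adapting) step_tr[g, k] <- step_tr[g, k] *
              exp(gam * (acc_p - 0.44))
        }
        # scaling move
        if (!sg_fixed[g, k]) {
          kf <- exp(step_sc[g, k] * stats::rnorm(1))
          eff_cur <- switch(k, a, b, c_eff, d_eff)
          dev <- eff_cur[here] - mu[g, k]
          if (gauss) {
            u <- dev[match(e_ind[r], which(here))] * w
            dll <- (2 * (kf - 1) * sum(resid * u) -
                      (kf - 1)^2 * sum(u^2)) / (2 * sigma_res^2)
          } else {
            av <- a; bv <- b
            if (k == 1L) av[here] <- mu[g, k] + kf * dev else
              bv[here] <- mu[g, k] + kf * dev
            dll <- bin_ll_g(g, av, bv) - llg
          }
          sg_new <- kf * sg[g, k]
          # half-normal prior change plus the log k Jacobian left over
          # after the effects' Jacobian cancels their prior shift
          dpr <- (-sg_new^2 + sg[g, k]^2) / (2 * sg_prior_sd[k]^2) + log(kf)
          acc_p <- min(1, exp(dll + dpr))
          if (stats::runif(1) < acc_p) {
            sg[g, k] <- sg_new
            if (k == 1L) a[here] <- mu[g, k] + kf * dev
            else if (k == 2L) b[here] <- mu[g, k] + kf * dev
            else if (k == 3L) c_eff[here] <- mu[g, k] + kf * dev
            else d_eff[here] <- mu[g, k] + kf * dev
            if (!gauss) { touched_bin <- TRUE; llg <- llg + dll }
          }
          if (adapting) step_sc[g, k] <- step_sc[g, k] *
              exp(gam * (acc_p - 0.44))
        }
      }
    }
    if (touched_bin) ll_i <- llbin_i(a, b)

    # --- residual SD: RW Metropolis on log scale
    if (!res_fixed && n_e > 0) {
      resid <- e_y - c_eff[e_ind] - d_eff[e_ind] * e_x
      SSr <- sum(resid^2)
      cur <- sigma_res
      prop <- cur * exp(step_res * stats::rnorm(1))
      ltarget <- function(s) -n_e * log(s) - SSr / (2 * s^2) -
        s^2 / (2 * prior$residual_sd_sd^2) + log(s)
      lr1 <- ltarget(prop) - ltarget(cur)
      if (log(stats::runif(1)) < lr1) sigma_res <- prop
      if (adapting) step_res <- step_res * exp(gam * (min(1, exp(lr1)) - 0.44))
    }

    # --- store
    if (!adapting) {
      post_it <- it - ctrl$warmup
      if (post_it %% ctrl$thin == 0L) {
        save_row <- save_row + 1L
        draws[save_row, ] <- c(
          as.vector(t(cbind(mu[, "a"], sg[, "a"], mu[, "b"], sg[, "b"],
                            mu[, "c"], sg[, "c"], mu[, "d"], sg[, "d"]))),
          sigma_res, a, b, c_eff, d_eff)
      }
    }
  }

  list(draws = draws,
       accept = c(a = acc_a / ctrl$iter, b = acc_b / ctrl$iter))
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf(paste0("<hurdle_fit> %d chains x %d draws, %d individuals ",
                     "(groups: %s)\ncentring constant: %.3f\n"),
              x$chains, dim(x$draws)[1L], nrow(x$individuals),
              paste(x$groups, collapse = ", "), x$centring_constant))
  dg <- x$diagnostics[x$diagnostics$parameter %in% x$hyper_parameters, ]
  cat(sprintf("hyperparameter R-hat range: [%.3f, %.3f]; min bulk ESS: %.0f\n",
              min(dg$rhat, na.rm = TRUE), max(dg$rhat, na.rm = TRUE),
              min(dg$ess_bulk, na.rm = TRUE)))
  invisible(x)
}

#' Extract draws for one parameter
#'
#' @param fit a `hurdle_fit`.
#' @param parameter full parameter name (e.g. `"mu_c[infected]"`) or a bare
#'   hyperparameter name plus `group`.
#' @param group optional group label combined with a bare name.
#' @return Numeric vector of pooled post-warmup draws (all chains,
#'   chain-major order preserved by iteration so draws align across
#'   parameters).
#' @export
extract_draws <- function(fit, parameter, group = NULL) {
  if (!is.null(group)) parameter <- sprintf("%s[%s]", parameter, group)
  if (!parameter %in% fit$parameters) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  as.vector(fit$draws[, , parameter])
}
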