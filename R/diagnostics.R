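## Convergence diagnostics: split-chain rank-normalised R-hat and bulk
## effective sample size, following the modern (rank-based) formulation.

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  if (half < 2L) stop("need at least 4 iterations per chain", call. = FALSE)
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[seq.int(n - half + 1L, n), , drop = FALSE])
}

rank_normalise <- function(mat) {
  S <- length(mat)
  z <- stats::qnorm((rank(mat, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

## classic potential-scale-reduction on a [iteration x chain] matrix
rhat_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  W <- mean(apply(mat, 2L, stats::var))
  B <- n * stats::var(colMeans(mat))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

## FFT autocovariance (biased, as used for ESS estimation)
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2L^ceiling(log2(2L * n))
  f <- stats::fft(c(x, rep(0, npad - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)]
  ac / npad / n  # biased autocovariance estimate at lags 0..n-1
}

ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  acov <- vapply(seq_len(m), function(j) autocov_fft(mat[, j]), numeric(n))
  chain_var <- acov[1L, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- (n - 1) / n * W +
    if (m > 1L) stats::var(colMeans(mat)) else 0
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1L] <- 1
  # Geyer initial monotone positive sequence on paired sums
  max_t <- (n - 2L) %/% 2L
  tau <- 0; prev <- Inf
  for (t in 0:max_t) {
    P <- rho[2L * t + 1L] + rho[2L * t + 2L]
    if (!is.finite(P) || P <= 0) break
    P <- min(P, prev)
    prev <- P
    tau <- tau + P
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m + 10))
  min(n * m / tau, n * m * log10(n * m))
}

## single-parameter diagnostics on an [iteration x chain] matrix
rhat_ess <- function(mat) {
  if (ncol(mat) < 2L) stop("at least 2 chains are required", call. = FALSE)
  sp <- split_chains(mat)
  if (all(abs(sp - sp[1L]) < 1e-12)) {
    return(c(rhat = NA_real_, ess_bulk = NA_real_))
  }
  z <- rank_normalise(sp)
  c(rhat = rhat_basic(z), ess_bulk = ess_basic(z))
}

#' Convergence diagnostics table
#'
#' Split-chain rank-normalised R-hat and bulk effective sample size for
#' every parameter. Chains are split in half (so non-stationarity within a
#' chain inflates R-hat), pooled draws are rank-normalised, and the ESS uses
#' FFT autocovariances with Geyer's initial monotone positive-sequence
#' truncation. Parameters with (numerically) constant draws yield `NA`.
#'
#' @param x a `hurdle_fit` or a 3-d draws array `[iteration, chain,
#'   parameter]` (a matrix is treated as one parameter,
#'   `[iteration, chain]`).
#' @param ... unused.
#' @return Data frame with columns `parameter`, `rhat`, `ess_bulk`.
#' @export
diagnostics <- function(x, ...) UseMethod("diagnostics")

#' @rdname diagnostics
#' @export
diagnostics.hurdle_fit <- function(x, ...) diagnostics(x$draws)

#' @rdname diagnostics
#' @export
diagnostics.default <- function(x, ...) {
  if (is.matrix(x)) {
    x <- array(x, dim = c(dim(x), 1L),
               dimnames = list(NULL, NULL, "parameter"))
  }
  if (length(dim(x)) != 3L) {
    stop("x must be [iteration, chain, parameter]", call. = FALSE)
  }
  if (dim(x)[2L] < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (dim(x)[1L] < 4L) stop("need at least 4 iterations per chain",
                            call. = FALSE)
  pn <- dimnames(x)[[3L]]
  if (is.null(pn)) pn <- sprintf("parameter_%d", seq_len(dim(x)[3L]))
  res <- vapply(seq_len(dim(x)[3L]),
                function(p) rhat_ess(x[, , p, drop = TRUE]), numeric(2L))
  data.frame(parameter = pn, rhat = res[1L, ], ess_bulk = res[2L, ],
             stringsAsFactors = FALSE)
}
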