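#' Catastrophe-time dataset
#'
#' Observed catastrophe times together with the observation window `[a, b]`
#' (imaging captures only a truncated subset of the full distribution; the
#' window defaults to the observed range).
#'
#' @param times Catastrophe times in seconds (positive).
#' @param window Length-2 numeric `(min, max)` or `NULL` for the data range.
#' @export
catastrophe_dataset <- function(times, window = NULL) {
  stopifnot(length(times) > 0, all(is.finite(times)), all(times > 0))
  if (is.null(window)) window <- range(times)
  stopifnot(length(window) == 2L, window[1] < window[2],
            all(times >= window[1]), all(times <= window[2]))
  structure(list(times = as.numeric(times), window = as.numeric(window)),
            class = "catastrophe_dataset")
}

#' Gamma log-likelihood of catastrophe times
#'
#' Sum of log gamma densities, evaluated through the log-gamma function so
#' non-integer step parameters are exact.
#'
#' @param data A [catastrophe_dataset()].
#' @param shape Step parameter `N` (> 0).
#' @param scale Timescale `T` in seconds (> 0).
#' @export
gamma_log_likelihood <- function(data, shape, scale) {
  stopifnot(inherits(data, "catastrophe_dataset"), shape > 0, scale > 0)
  if (any(data$times <= 0)) stop("catastrophe times must be positive")
  sum(dgamma(data$times, shape = shape, scale = scale, log = TRUE))
}

#' Maximum-likelihood gamma fit
#'
#' Maximizes the gamma log-likelihood over `(shape, scale)`, started from the
#' moment estimates (and from the exponential submodel as a second start), on
#' the log-parameter scale. Deterministic given the data.
#'
#' @param data A [catastrophe_dataset()] with at least 10 observations.
#' @return List with `shape`, `scale`, `loglik`, `convergence` (0 = ok).
#' @export
mle_fit <- function(data) {
  stopifnot(inherits(data, "catastrophe_dataset"), length(data$times) >= 10)
  t <- data$times
  m <- mean(t); v <- var(t)
  starts <- list(c(m^2 / max(v, 1e-12), v / m), c(1, m))
  nll <- function(p) -gamma_log_likelihood(data, exp(p[1]), exp(p[2]))
  fits <- lapply(starts, function(s)
    tryCatch(optim(log(s), nll, method = "BFGS",
                   control = list(maxit = 500)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("gamma MLE failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (best$convergence != 0)
    stop("gamma MLE did not converge (code ", best$convergence, ")")
  list(shape = exp(best$par[1]), scale = exp(best$par[2]),
       loglik = -best$value, convergence = best$convergence)
}

#' Inference grid over the gamma parameters
#'
#' Regular grid on the support `N in [1, 10]`, `T in [10, 500]` s (default
#' steps 0.05 and 1 s).
#'
#' @param shape_step,scale_step Grid steps.
#' @param shape_range,scale_range Grid supports.
#' @export
catastrophe_grid <- function(shape_step = 0.05, scale_step = 1,
                             shape_range = c(1, 10),
                             scale_range = c(10, 500)) {
  structure(list(shape = seq(shape_range[1], shape_range[2], by = shape_step),
                 scale = seq(scale_range[1], scale_range[2], by = scale_step)),
            class = "catastrophe_param_grid")
}

#' Log-likelihood surface on the inference grid
#'
#' Matrix of gamma log-likelihoods (rows: shape, columns: scale). With
#' `truncated = TRUE` the likelihood of each observation is the
#' window-renormalized density (a documented deviation from the default
#' full-distribution likelihood).
#'
#' @param data A [catastrophe_dataset()].
#' @param grid A [catastrophe_grid()].
#' @param truncated Use the window-truncated likelihood?
#' @export
grid_log_likelihood <- function(data, grid = catastrophe_grid(),
                                truncated = FALSE) {
  stopifnot(inherits(data, "catastrophe_dataset"),
            inherits(grid, "catastrophe_param_grid"))
  t <- data$times
  n <- length(t)
  s1 <- sum(log(t)); s0 <- sum(t)
  ll <- outer(grid$shape, grid$scale, function(N, T)
    (N - 1) * s1 - s0 / T - n * (N * log(T) + lgamma(N)))
  if (truncated) {
    lmass <- outer(grid$shape, grid$scale, function(N, T)
      log(pgamma(data$window[2], N, scale = T) -
            pgamma(data$window[1], N, scale = T)))
    ll <- ll - n * lmass
  }
  dimnames(ll) <- list(shape = grid$shape, scale = grid$scale)
  ll
}

#' Informative prior anchored on the Mal3 likelihood surface
#'
#' Mixes the normalized anchor likelihood surface `p(N, T | O)` with a uniform
#' table, choosing the mixture weight so the ratio of the maximum to the
#' minimum prior probability over the grid equals `target_ratio` (default 10).
#' The weight solves a monotone one-parameter equation and is obtained in
#' closed form.
#'
#' @param anchor_loglik Log-likelihood matrix over the grid (from
#'   [grid_log_likelihood()] on the anchor dataset).
#' @param target_ratio Desired max/min prior ratio (> 1).
#' @return Prior matrix summing to one, with attributes `weight` (mixture
#'   weight on the likelihood component) and `ratio` (achieved ratio).
#' @export
build_informative_prior <- function(anchor_loglik, target_ratio = 10) {
  stopifnot(is.matrix(anchor_loglik), all(is.finite(anchor_loglik)),
            target_ratio > 1)
  lik <- exp(anchor_loglik - max(anchor_loglik))
  lik <- lik / sum(lik)
  u <- 1 / length(lik)
  lmax <- max(lik); lmin <- min(lik)
  max_ratio <- lmax / max(lmin, .Machine$double.xmin)
  if (max_ratio < target_ratio)
    stop(sprintf(
      "target ratio %g unreachable: the likelihood surface only supports ratios in [1, %g]",
      target_ratio, max_ratio))
  # ratio(w) = (w lmax + (1-w) u) / (w lmin + (1-w) u) is monotone in w;
  # solving ratio(w) = R gives:
  R <- target_ratio
  w <- (R - 1) * u / (lmax - R * lmin + (R - 1) * u)
  prior <- w * lik + (1 - w) * u
  achieved <- max(prior) / min(prior)
  if (abs(achieved / R - 1) > 0.01)
    stop("prior ratio solver failed: achieved ", achieved)
  attr(prior, "weight") <- w
  attr(prior, "ratio") <- achieved
  prior
}

#' Grid posterior over the gamma parameters
#'
#' Posterior `p(N, T | O)` proportional to `exp(log-likelihood) * prior`,
#' normalized on the grid with a log-sum-exp shift so it never underflows.
#' Also reports the maximizing `(N, T)` pair.
#'
#' @param data A [catastrophe_dataset()].
#' @param prior Prior matrix over the grid (e.g. from
#'   [build_informative_prior()]), or `NULL` for a flat prior.
#' @param grid A [catastrophe_grid()].
#' @param truncated Use the window-truncated likelihood?
#' @return Object of class `posterior_grid`: `shape_grid`, `scale_grid`,
#'   `log_likelihood`, `prior`, `posterior`, `mode` (named vector `shape`,
#'   `scale`).
#' @export
grid_posterior <- function(data, prior = NULL, grid = catastrophe_grid(),
                           truncated = FALSE) {
  ll <- grid_log_likelihood(data, grid, truncated = truncated)
  if (is.null(prior)) prior <- matrix(1 / length(ll), nrow(ll), ncol(ll))
  stopifnot(all(dim(prior) == dim(ll)), all(prior > 0))
  lp <- ll + log(prior)
  lp <- lp - max(lp)
  post <- exp(lp)
  post <- post / sum(post)
  ij <- which(post == max(post), arr.ind = TRUE)[1, ]
  structure(list(shape_grid = grid$shape, scale_grid = grid$scale,
                 log_likelihood = ll, prior = prior, posterior = post,
                 mode = c(shape = grid$shape[ij[1]],
                          scale = grid$scale[ij[2]])),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf(paste0("posterior grid %d x %d (N in [%g, %g], T in [%g, %g] s)\n",
                     "  mode: N = %g, T = %g s\n"),
              length(x$shape_grid), length(x$scale_grid),
              min(x$shape_grid), max(x$shape_grid),
              min(x$scale_grid), max(x$scale_grid),
              x$mode["shape"], x$mode["scale"]))
  invisible(x)
}

#' Size of the highest-posterior credible region
#'
#' Number of grid cells in the smallest set carrying at least `level`
#' posterior mass.
#'
#' @param pg A `posterior_grid`.
#' @param level Coverage (default 0.95).
#' @export
credible_region_size <- function(pg, level = 0.95) {
  stopifnot(inherits(pg, "posterior_grid"))
  p <- sort(as.numeric(pg$posterior), decreasing = TRUE)
  which(cumsum(p) >= level)[1]
}

#' Anchor likelihood surface from the synthetic Mal3 calibration
#'
#' The informative prior is anchored on the likelihood surface of a Mal3
#' catastrophe dataset. The experimental event list is not distributed with
#' the package, so by default the anchor is generated from the synthetic Mal3
#' calibration (gamma `N = 3.6`, `T = 35` s observed through a `(10, 400)` s
#' window).
#'
#' @param n Number of synthetic anchor events.
#' @param seed Seed of the synthetic anchor sample.
#' @param grid A [catastrophe_grid()].
#' @return Log-likelihood matrix over the grid.
#' @export
mal3_anchor_loglik <- function(n = 200, seed = 1, grid = catastrophe_grid()) {
  anchor <- gen_catastrophe_times(n = n, seed = seed)
  grid_log_likelihood(anchor, grid)
}

#' Goodness of fit of the window-truncated model
#'
#' Builds the truncated gamma distribution on the dataset's observation
#' window and compares it with the empirical distribution: the
#' Kolmogorov-Smirnov distance plus a parametric-bootstrap p value obtained by
#' resampling datasets of the same size from the truncated model.
#'
#' @param data A [catastrophe_dataset()].
#' @param shape,scale Gamma parameters of the candidate model.
#' @param n_boot Parametric bootstrap replicates.
#' @param seed Optional seed for the bootstrap.
#' @return List with `ks`, `p_value`, `n_boot`.
#' @export
truncated_fit_check <- function(data, shape, scale, n_boot = 199,
                                seed = NULL) {
  stopifnot(inherits(data, "catastrophe_dataset"), shape > 0, scale > 0)
  model <- catastrophe_model(shape, scale, tau0 = 0)
  a <- data$window[1]; b <- data$window[2]
  ks_stat <- function(t) {
    t <- sort(t); n <- length(t)
    Ft <- catastrophe_cdf_truncated(t, model, a, b)
    max(max(seq_len(n) / n - Ft), max(Ft - (seq_len(n) - 1) / n))
  }
  obs <- ks_stat(data$times)
  n <- length(data$times)
  pl <- pgamma(a, shape, scale = scale)
  pu <- pgamma(b, shape, scale = scale)
  draw <- function() qgamma(pl + runif(n) * (pu - pl), shape, scale = scale)
  boot <- with_seed_(seed, vapply(seq_len(n_boot), function(i)
    ks_stat(draw()), numeric(1)))
  list(ks = obs, p_value = (1 + sum(boot >= obs)) / (n_boot + 1),
       n_boot = n_boot)
}
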