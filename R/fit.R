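# Bounded least-squares calibration of the network against time-course
# observations.

.fit_observables <- function(sim, times) {
  idx <- match(times, sim$times)
  if (any(is.na(idx))) stop("observation times must lie on the simulation grid")
  list(
    pink1d = sim$trajectory[idx, "PINK1d"],
    ps65ub = ps65ub_readout(sim$trajectory)[idx],
    atg8pe = sim$atg8pe[idx]
  )
}

#' Fit network parameters to time-course observations
#'
#' Bounded least squares (Levenberg-Marquardt, [minpack.lm::nls.lm]) over a
#' configurable set of free parameters, optimized in log10 space within the
#' class bounds of [parameter_bounds()]. Residuals are computed per
#' observable after normalization to each observed series' maximum, so that
#' observables of different magnitude contribute comparably.
#'
#' @param net A `mito_network` supplying the fixed parameters and protocol.
#' @param observations Data frame with a `time` column (s, on a grid
#'   compatible with `dt`) and at least one of `pink1d`, `ps65ub`,
#'   `atg8pe` columns (nM).
#' @param free Names of the parameters allowed to vary (association
#'   constants and catalytic/velocity constants by default; degradation
#'   constants stay fixed).
#' @param start Optional named start values for the free parameters
#'   (defaults to the network's current values).
#' @param dt Simulation output spacing (s); must divide the observation
#'   times.
#' @param maxiter Maximum optimizer iterations.
#' @return A `fit_result`: `params` (full updated set), `free`, `rss`,
#'   `residuals` (per observable), `converged`, and the raw optimizer
#'   object.
#' @export
fit_parameters <- function(net, observations,
                           free = c("r1_v", "r7_kc", "r16_kc"),
                           start = NULL, dt = 60, maxiter = 40) {
  if (!is.data.frame(observations) || nrow(observations) == 0 ||
      !"time" %in% names(observations)) {
    stop("observations must be a non-empty data frame with a 'time' column")
  }
  obs_cols <- intersect(c("pink1d", "ps65ub", "atg8pe"), names(observations))
  if (length(obs_cols) == 0) {
    stop("observations must contain at least one of: pink1d, ps65ub, atg8pe")
  }
  stopifnot(all(free %in% names(net$params)))
  times <- observations$time
  t_end <- max(times)
  scales <- lapply(obs_cols, function(cl) max(abs(observations[[cl]]), 1e-12))
  names(scales) <- obs_cols

  bounds <- parameter_bounds()
  lower <- log10(vapply(free, function(nm) bounds[[.param_kind(nm)]][1], numeric(1)))
  upper <- log10(vapply(free, function(nm) bounds[[.param_kind(nm)]][2], numeric(1)))
  if (is.null(start)) start <- net$params[free]
  theta0 <- pmin(pmax(log10(unlist(start)), lower), upper)

  resid_fun <- function(theta) {
    p <- net$params
    p[free] <- 10^theta
    trial <- net
    trial$params <- p
    sim <- try(suppressWarnings(simulate_mitophagy(trial, t_end = t_end, dt = dt)),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e3, nrow(observations) * length(obs_cols)))
    mod <- .fit_observables(sim, times)
    unlist(lapply(obs_cols, function(cl) {
      (mod[[cl]] - observations[[cl]]) / scales[[cl]]
    }))
  }

  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = maxiter))
  params <- net$params
  params[free] <- 10^fit$par
  res <- resid_fun(fit$par)
  per_obs <- split(res, rep(obs_cols, each = nrow(observations)))
  structure(list(
    params = params,
    free = free,
    rss = sum(res^2),
    residuals = per_obs,
    converged = fit$info %in% 1:3,
    optimizer = fit
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> rss = %.4g, converged = %s\n", x$rss, x$converged))
  print(round(10^x$optimizer$par, 6))
  invisible(x)
}
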