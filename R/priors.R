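## The nine trajectory prior models, each a log-density / ancestral-sampler
## pair over the per-interval population sizes rho and their latent
## hyperparameters.  All densities are with respect to the natural (rho)
## scale: models stated on the log scale ("ln rho_{i+1} ~ Normal(...)")
## therefore appear as lognormal densities in rho.

SKYLINE_MODELS <- c("constant", "skyline", "bsp", "ebsp", "skyride",
                    "skygrid", "gmrf", "hsmrf", "skyfish")

#' Lognormal spread constant for a given prior span
#'
#' The standard deviation (on the natural-log scale) for which the central
#' `coverage` interval of a lognormal distribution spans `orders` orders of
#' magnitude is `orders * log(10) / (2 * qnorm((1 + coverage)/2))`.  The
#' Skyfish model uses half of this value, `H = 0.587405`, so that a
#' lognormal with sd `2 H` places 95% prior probability across two orders
#' of magnitude.
#'
#' @param orders orders of magnitude to span (default 2).
#' @param coverage central probability mass (default 0.95).
#' @return `H`, half the lognormal sd with the stated span.
#' @export
#' @examples
#' skyfish_h()  # 0.587405
skyfish_h <- function(orders = 2, coverage = 0.95) {
  orders * log(10) / (2 * stats::qnorm((1 + coverage) / 2)) / 2
}

#' Default hyperparameters of a skyline prior model
#'
#' Returns the standard constants of each model: `Uniform(0, 1e8)` bounds on
#' uncorrelated population sizes, `Loguniform(1e-2, 1e8)` on first interval
#' sizes of the autocorrelated chains, `Gamma(0.001, 0.001)` on the
#' precision `tau` (Skyride/Skygrid), `Half-Cauchy(0, 1)` on the global
#' scale `gamma` and local scales `sigma_i` (GMRF/HSMRF), smoothing
#' constants `zeta = 0.0195` (GMRF) and `zeta = 0.0051` (HSMRF) — calibrated
#' for 50 intervals and not re-derived for other interval counts — and for
#' Skyfish a `Poisson(10)` prior on the number of change-points,
#' `sigma ~ Exponential(rate = t_max/8)`, and
#' `rho_1 ~ Lognormal(median t_max/4, sd 2H)` with `H = 0.587405`.
#'
#' @param model one of `r paste0('"', SKYLINE_MODELS, '"', collapse = ", ")`.
#' @param n_intervals number of intervals (grid models; also the number of
#'   groups for events-based models when known up front).
#' @param t_max upper end of the modeled period (grid models and Skyfish).
#' @return a named list of hyperparameters.
#' @export
default_hyperparams <- function(model, n_intervals = NULL, t_max = NULL) {
  model <- match.arg(model, SKYLINE_MODELS)
  h <- list(
    uniform_max = 1e8,          # Uniform(0, 1e8) population-size bound
    logunif_min = 1e-2,         # Loguniform(1e-2, 1e8)
    logunif_max = 1e8)
  switch(model,
    constant = h,
    skyline = c(h, list(events_per_group = 5)),
    bsp = c(h, list(events_per_group = 5)),
    ebsp = c(h, list(alpha_eq = 0.5)),
    skyride = c(h, list(tau_shape = 0.001, tau_rate = 0.001)),
    skygrid = c(h, list(tau_shape = 0.001, tau_rate = 0.001)),
    gmrf = c(h, list(zeta = 0.0195, cauchy_scale = 1)),
    hsmrf = c(h, list(zeta = 0.0051, cauchy_scale = 1)),
    skyfish = {
      if (is.null(t_max)) stop("skyfish requires t_max")
      c(h, list(poisson_mean = 10, H = 0.587405, t_max = t_max,
                sigma_rate = t_max / 8))
    })
}

#' Specification of a skyline prior model
#'
#' Bundles a model name, its hyperparameters and its change-point scheme.
#' Events-based models (`skyline`, `bsp`, `ebsp`, `skyride`) derive their
#' change-points from the genealogy at inference time; grid models
#' (`skygrid`, `gmrf`, `hsmrf`) use `n_intervals` equally sized intervals on
#' `[0, t_max]`; `skyfish` estimates the number and position of its
#' change-points on `[0, t_max]`.
#'
#' @param model model name.
#' @param n_intervals number of intervals (grid models; default 50).
#' @param t_max modeled period (grid models and skyfish).
#' @param mode per-interval demographic function, `"constant"` or
#'   `"linear"`.
#' @param hyper named list of hyperparameter overrides.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(model, n_intervals = NULL, t_max = NULL,
                       mode = c("constant", "linear"), hyper = list()) {
  model <- match.arg(model, SKYLINE_MODELS)
  mode <- match.arg(mode)
  if (model %in% c("skygrid", "gmrf", "hsmrf")) {
    if (is.null(n_intervals)) n_intervals <- 50
    if (is.null(t_max)) stop(model, " requires t_max for its equal grid")
  }
  h <- utils::modifyList(default_hyperparams(model, n_intervals, t_max), hyper)
  structure(list(model = model, n_intervals = n_intervals, t_max = t_max,
                 mode = mode, hyper = h),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec: %s (%s mode)\n", x$model, x$mode))
  if (!is.null(x$n_intervals)) cat("  intervals:", x$n_intervals, "\n")
  if (!is.null(x$t_max)) cat("  t_max:", x$t_max, "\n")
  invisible(x)
}

## ---- helper densities -----------------------------------------------------

dloguniform <- function(x, a, b) {
  ifelse(x < a | x > b, -Inf, -log(x) - log(log(b / a)))
}

rloguniform <- function(n, a, b) exp(stats::runif(n, log(a), log(b)))

dhalfcauchy <- function(x, scale = 1) {
  ifelse(x <= 0, -Inf, log(2 / pi) - log(scale) - log1p((x / scale)^2))
}

rhalfcauchy <- function(n, scale = 1) abs(stats::rcauchy(n, 0, scale))

## ---- log prior ------------------------------------------------------------

#' Log prior density of a model state
#'
#' The sum of all component log densities of the model's generative
#' construction, including hyperprior terms; `-Inf` outside the support.
#' States are named lists as produced by [sample_prior()]; the number of
#' intervals is taken from `length(state$rho)`.
#'
#' @param spec a [prior_spec].
#' @param state a model state (see [sample_prior()]).
#' @return the log prior density.
#' @export
log_prior <- function(spec, state) {
  stopifnot(inherits(spec, "prior_spec"))
  h <- spec$hyper
  rho <- state$rho
  L <- length(rho)
  if (any(!is.finite(rho)) || any(rho <= 0)) return(-Inf)
  switch(spec$model,
    constant = {
      if (L != 1) stop("constant model has a single interval")
      stats::dunif(rho, 0, h$uniform_max, log = TRUE)
    },
    skyline = sum(stats::dunif(rho, 0, h$uniform_max, log = TRUE)),
    bsp = {
      lp <- dloguniform(rho[1], h$logunif_min, h$logunif_max)
      if (L > 1)
        lp <- lp + sum(stats::dexp(rho[-1], rate = 1 / rho[-L], log = TRUE))
      lp
    },
    ebsp = log_prior_ebsp(h, state),
    skyride = ,
    skygrid = {
      tau <- state$tau
      if (!is.finite(tau) || tau <= 0) return(-Inf)
      lp <- stats::dgamma(tau, shape = h$tau_shape, rate = h$tau_rate, log = TRUE) +
        dloguniform(rho[1], h$logunif_min, h$logunif_max)
      if (L > 1)
        lp <- lp + sum(stats::dlnorm(rho[-1], meanlog = log(rho[-L]),
                                     sdlog = 1 / sqrt(tau), log = TRUE))
      lp
    },
    gmrf = {
      gam <- state$gamma
      if (!is.finite(gam) || gam <= 0) return(-Inf)
      lp <- dhalfcauchy(gam, h$cauchy_scale) +
        stats::dunif(rho[1], 0, h$uniform_max, log = TRUE)
      if (L > 1)
        lp <- lp + sum(stats::dlnorm(rho[-1], meanlog = log(rho[-L]),
                                     sdlog = gam * h$zeta, log = TRUE))
      lp
    },
    hsmrf = {
      gam <- state$gamma; sig <- state$sigma_local
      if (!is.finite(gam) || gam <= 0) return(-Inf)
      if (length(sig) != L - 1 || any(!is.finite(sig)) || any(sig <= 0))
        return(-Inf)
      lp <- dhalfcauchy(gam, h$cauchy_scale) +
        sum(dhalfcauchy(sig, h$cauchy_scale)) +
        stats::dunif(rho[1], 0, h$uniform_max, log = TRUE)
      if (L > 1)
        lp <- lp + sum(stats::dlnorm(rho[-1], meanlog = log(rho[-L]),
                                     sdlog = sig * gam * h$zeta, log = TRUE))
      lp
    },
    skyfish = log_prior_skyfish(h, state))
}

log_prior_ebsp <- function(h, state) {
  rho <- state$rho; act <- state$active; mu <- state$mu
  L <- length(rho)
  if (length(act) != L || !act[1]) return(-Inf)
  if (!is.finite(mu) || mu <= 0) return(-Inf)
  ## ties must be materialized: an inactive interval repeats its predecessor
  if (L > 1 && any(!act[-1] & rho[-1] != rho[-L])) return(-Inf)
  lp <- dloguniform(mu, h$logunif_min, h$logunif_max) +
    stats::dexp(rho[1], rate = 1 / mu, log = TRUE)
  if (L > 1) {
    free <- which(act[-1]) + 1L
    n_act <- sum(act[-1]); n_tie <- L - 1 - n_act
    lp <- lp + sum(stats::dexp(rho[free], rate = 1 / mu, log = TRUE))
    ## guard 0 * log(0) at the degenerate equality probabilities 0 and 1
    if (n_act > 0) lp <- lp + n_act * log(h$alpha_eq)
    if (n_tie > 0) lp <- lp + n_tie * log(1 - h$alpha_eq)
  }
  lp
}

log_prior_skyfish <- function(h, state) {
  kappa <- state$kappa; xi <- state$xi; sigma <- state$sigma; rho <- state$rho
  if (length(xi) != kappa || length(rho) != kappa + 1) return(-Inf)
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  if (kappa > 0 && (is.unsorted(xi, strictly = TRUE) ||
                    any(xi <= 0) || any(xi >= h$t_max))) return(-Inf)
  lp <- stats::dpois(kappa, h$poisson_mean, log = TRUE) +
    stats::dexp(sigma, rate = h$sigma_rate, log = TRUE) +
    stats::dlnorm(rho[1], meanlog = log(h$t_max / 4), sdlog = 2 * h$H,
                  log = TRUE)
  if (kappa > 0) {
    ## sorted change-points: order-statistics density kappa! / t_max^kappa
    lp <- lp + lfactorial(kappa) - kappa * log(h$t_max)
    gaps <- diff(c(0, xi))
    lp <- lp + sum(stats::dlnorm(rho[-1], meanlog = log(rho[-(kappa + 1)]),
                                 sdlog = sigma * gaps, log = TRUE))
  }
  lp
}

## ---- sampling -------------------------------------------------------------

## forward lognormal autocorrelation chain; once a draw leaves the range of
## doubles (possible under the heavy-tailed hyperpriors) the remainder is
## pinned there, yielding a state of zero posterior density to be redrawn
lognormal_chain <- function(rho1, sdlogs) {
  rho <- c(rho1, rep(NA_real_, length(sdlogs)))
  for (i in seq_along(sdlogs)) {
    if (!is.finite(rho[i]) || rho[i] <= 0 || !is.finite(sdlogs[i])) {
      rho[(i + 1):length(rho)] <- Inf
      break
    }
    rho[i + 1] <- stats::rlnorm(1, meanlog = log(rho[i]), sdlog = sdlogs[i])
  }
  rho
}

#' Draw a model state from its prior
#'
#' Exact ancestral sampling in generative order (hyperparameters first, then
#' `rho[1]`, then forward along the autocorrelation chain).  Uses R's global
#' RNG stream; seed with [set.seed()].
#'
#' @param spec a [prior_spec].
#' @param n_intervals number of intervals to draw (defaults to
#'   `spec$n_intervals`; ignored by `constant` and `skyfish`).
#' @return a model state: a named list with element `rho` plus
#'   model-specific hyperparameters (`tau`, `gamma`, `sigma_local`, `mu`,
#'   `active`, `kappa`, `xi`, `sigma`).
#' @export
sample_prior <- function(spec, n_intervals = spec$n_intervals) {
  stopifnot(inherits(spec, "prior_spec"))
  h <- spec$hyper
  L <- n_intervals
  if (spec$model %in% c("skyline", "bsp", "ebsp", "skyride", "skygrid",
                        "gmrf", "hsmrf") && is.null(L))
    stop("n_intervals is required for ", spec$model)
  switch(spec$model,
    constant = list(rho = stats::runif(1, 0, h$uniform_max)),
    skyline = list(rho = stats::runif(L, 0, h$uniform_max)),
    bsp = {
      rho <- numeric(L)
      rho[1] <- rloguniform(1, h$logunif_min, h$logunif_max)
      for (i in seq_len(L - 1))
        rho[i + 1] <- stats::rexp(1, rate = 1 / rho[i])
      list(rho = rho)
    },
    ebsp = {
      mu <- rloguniform(1, h$logunif_min, h$logunif_max)
      active <- c(TRUE, stats::runif(L - 1) < h$alpha_eq)
      rho <- numeric(L)
      rho[1] <- stats::rexp(1, rate = 1 / mu)
      for (i in seq_len(L - 1))
        rho[i + 1] <- if (active[i + 1]) stats::rexp(1, rate = 1 / mu) else rho[i]
      list(rho = rho, active = active, mu = mu)
    },
    skyride = ,
    skygrid = {
      tau <- stats::rgamma(1, shape = h$tau_shape, rate = h$tau_rate)
      rho <- lognormal_chain(rloguniform(1, h$logunif_min, h$logunif_max),
                             rep(1 / sqrt(tau), L - 1))
      list(rho = rho, tau = tau)
    },
    gmrf = {
      gam <- rhalfcauchy(1, h$cauchy_scale)
      rho <- lognormal_chain(stats::runif(1, 0, h$uniform_max),
                             rep(gam * h$zeta, L - 1))
      list(rho = rho, gamma = gam)
    },
    hsmrf = {
      gam <- rhalfcauchy(1, h$cauchy_scale)
      sig <- rhalfcauchy(max(L - 1, 0), h$cauchy_scale)
      rho <- lognormal_chain(stats::runif(1, 0, h$uniform_max),
                             sig * gam * h$zeta)
      list(rho = rho, gamma = gam, sigma_local = sig)
    },
    skyfish = {
      kappa <- stats::rpois(1, h$poisson_mean)
      xi <- sort(stats::runif(kappa, 0, h$t_max))
      sigma <- stats::rexp(1, rate = h$sigma_rate)
      rho <- lognormal_chain(
        stats::rlnorm(1, meanlog = log(h$t_max / 4), sdlog = 2 * h$H),
        sigma * diff(c(0, xi)))
      list(rho = rho, kappa = kappa, xi = xi, sigma = sigma)
    })
}

#' Demographic trajectory implied by a Skyfish state
#'
#' Change-points are `{0} U xi`, giving `kappa + 1` intervals.
#'
#' @param state a skyfish model state.
#' @param t_max modeled period (the `xi` must lie in `[0, t_max]`).
#' @param mode interpolation mode.
#' @return a [trajectory].
#' @export
skyfish_trajectory_from_state <- function(state, t_max, mode = "constant") {
  if (length(state$xi) != state$kappa)
    stop("kappa must equal length(xi)")
  if (state$kappa > 0 && (any(state$xi < 0) || any(state$xi > t_max)))
    stop("xi outside [0, t_max]")
  trajectory(c(0, state$xi), state$rho, mode = mode)
}
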