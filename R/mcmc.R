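#' MCMC settings
#'
#' Defaults follow the reference analysis design: 100,000 iterations,
#' sampling every 10th, a burn-in of 10% and two replicate runs (yielding
#' 18,000 retained samples).
#'
#' @param iterations number of MCMC iterations (> 0).
#' @param thinning record every `thinning`-th iteration (`>= 1`).
#' @param burn_in_fraction fraction of recorded samples discarded per
#'   replicate (`0 <= b < 1`).
#' @param n_replicates number of independent replicate runs.
#' @param seed integer seed; replicate `r` uses `seed + r - 1`.
#' @param likelihood set to `FALSE` to target the prior alone (the log
#'   likelihood is forced to 0).
#' @param tuning named list of proposal tunings: `rho_scale`, `hyper_scale`
#'   (multiplier window widths), `xi_window` (slide half-width, as a
#'   fraction of `t_max`), `birth_sd` (lognormal sd of reversible-jump
#'   birth proposals).
#' @param auto_tune adapt proposal scales toward 0.44 acceptance during
#'   burn-in only (frozen afterwards to preserve detailed balance).
#' @return a list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 100000, thinning = 10,
                          burn_in_fraction = 0.1, n_replicates = 2,
                          seed = 1, likelihood = TRUE,
                          tuning = list(), auto_tune = TRUE) {
  if (iterations <= 0) stop("iterations must be > 0")
  if (thinning < 1) stop("thinning must be >= 1")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("need 0 <= burn_in_fraction < 1")
  if (n_replicates < 1) stop("need n_replicates >= 1")
  tun <- utils::modifyList(
    list(rho_scale = 1, hyper_scale = 1.5, xi_window = 0.1, birth_sd = 1),
    tuning)
  structure(list(iterations = as.integer(iterations),
                 thinning = as.integer(thinning),
                 burn_in_fraction = burn_in_fraction,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), likelihood = likelihood,
                 tuning = tun, auto_tune = auto_tune),
            class = "mcmc_settings")
}

#' Sample bookkeeping of an MCMC design
#'
#' `retained_sample_count()` gives the number of samples kept after
#' recording every `thinning`-th iteration, discarding a burn-in fraction
#' per replicate and pooling replicates:
#' `n_replicates * (floor(iterations/thinning) -
#'  floor(burn_in_fraction * floor(iterations/thinning)))`.
#' `raw_sample_count()` gives the per-replicate record count before
#' burn-in removal.
#'
#' @inheritParams mcmc_settings
#' @return an integer count.
#' @export
#' @examples
#' retained_sample_count(100000, 10, 0.1, 2)  # 18000
#' raw_sample_count(25000000, 1000)           # 25000
retained_sample_count <- function(iterations, thinning, burn_in_fraction,
                                  n_replicates) {
  per_rep <- raw_sample_count(iterations, thinning)
  n_replicates * (per_rep - floor(burn_in_fraction * per_rep))
}

#' @rdname retained_sample_count
#' @export
raw_sample_count <- function(iterations, thinning) {
  floor(iterations / thinning)
}

## ---- elementary proposals -------------------------------------------------

#' Multiplier (scale) proposal for a positive parameter
#'
#' Proposes `value * exp(tuning * (u - 0.5))` with `u ~ Uniform(0, 1)`;
#' the log Hastings ratio is `log(proposal / value)`.  The proposal is
#' always positive and reduces to the identity as `tuning -> 0`.
#'
#' @param value current (positive) value.
#' @param tuning window width.
#' @return list with `value` (the proposal) and `log_hastings`.
#' @export
scale_move <- function(value, tuning) {
  lf <- tuning * (stats::runif(1) - 0.5)
  list(value = value * exp(lf), log_hastings = lf)
}

## reflected sliding proposal on [lo, hi]; symmetric, so log Hastings = 0
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Reversible-jump birth/death proposal for the Skyfish model
#'
#' A birth draws a new change-point `xi* ~ Uniform(0, t_max)`, splits the
#' containing interval and draws the new interval's population size from a
#' lognormal centered on the current `log Ne(xi*)` with sd `birth_sd`; a
#' death removes a uniformly chosen change-point together with its
#' population size.  Both directions are attempted with probability 1/2; a
#' death at `kappa = 0` is auto-rejected.  The returned `log_hastings` is
#' `log q(reverse) - log q(forward)`; the prior ratio (Poisson term,
#' order-statistics term, population-size increments) is obtained by the
#' caller from [log_prior()] differences, and the dimension-matching
#' Jacobian of this identity parameterization is 1.
#'
#' @param state a skyfish model state.
#' @param t_max modeled period.
#' @param birth_sd lognormal sd of the birth proposal for the new
#'   population size.
#' @param mode interpolation mode used to evaluate `Ne(xi*)`.
#' @return list with `state` (the proposal, or the input when
#'   auto-rejected), `log_hastings`, and `type` (`"birth"`, `"death"` or
#'   `"reject"`).
#' @export
rj_birth_death_move <- function(state, t_max, birth_sd = 1,
                                mode = "constant") {
  kappa <- state$kappa
  birth <- stats::runif(1) < 0.5
  if (!birth && kappa == 0)
    return(list(state = state, log_hastings = -Inf, type = "reject"))
  traj <- skyfish_trajectory_from_state(state, t_max, mode = mode)
  if (birth) {
    xi_star <- stats::runif(1, 0, t_max)
    ne_here <- ne_at(traj, xi_star)
    p <- findInterval(xi_star, c(0, state$xi))   # containing interval
    rho_new <- stats::rlnorm(1, meanlog = log(ne_here), sdlog = birth_sd)
    new <- state
    new$kappa <- kappa + 1L
    new$xi <- append(state$xi, xi_star, after = p - 1L)
    new$rho <- append(state$rho, rho_new, after = p)
    lqf <- -log(t_max) +
      stats::dlnorm(rho_new, log(ne_here), birth_sd, log = TRUE)
    lqr <- -log(kappa + 1)
    list(state = new, log_hastings = lqr - lqf, type = "birth")
  } else {
    j <- sample.int(kappa, 1)
    new <- state
    new$kappa <- kappa - 1L
    new$xi <- state$xi[-j]
    new$rho <- state$rho[-(j + 1L)]
    traj_red <- skyfish_trajectory_from_state(new, t_max, mode = mode)
    ne_here <- ne_at(traj_red, state$xi[j])
    lqf <- -log(kappa)
    lqr <- -log(t_max) +
      stats::dlnorm(state$rho[j + 1L], log(ne_here), birth_sd, log = TRUE)
    list(state = new, log_hastings = lqr - lqf, type = "death")
  }
}

#' Reversible-jump tie toggle for the EBSP model
#'
#' Switches one candidate change-point between "tied to its predecessor"
#' and "free, exponentially distributed".  Activation draws the new
#' population size from its `Exponential(1/mu)` prior (so prior and
#' proposal densities cancel, leaving the `alpha_eq` prior odds and the
#' likelihood ratio); deactivation is deterministic, with the reverse
#' exponential density entering the Hastings ratio.  Downstream tied
#' intervals are re-materialized.
#'
#' @param state an ebsp model state (`rho`, `active`, `mu`).
#' @param index candidate interval to toggle (`2..L`); a uniform draw when
#'   `NULL`.
#' @return list with `state`, `log_hastings`, `index`.
#' @export
ebsp_toggle_move <- function(state, index = NULL) {
  L <- length(state$rho)
  if (L < 2) return(list(state = state, log_hastings = -Inf, index = NA))
  j <- if (is.null(index)) sample(2:L, 1) else as.integer(index)
  new <- state
  if (state$active[j]) {
    old_val <- state$rho[j]
    new$active[j] <- FALSE
    new$rho[j] <- new$rho[j - 1]
    new$rho <- ebsp_materialize(new$rho, new$active)
    lh <- stats::dexp(old_val, rate = 1 / state$mu, log = TRUE)
  } else {
    val <- stats::rexp(1, rate = 1 / state$mu)
    new$active[j] <- TRUE
    new$rho[j] <- val
    new$rho <- ebsp_materialize(new$rho, new$active)
    lh <- -stats::dexp(val, rate = 1 / state$mu, log = TRUE)
  }
  list(state = new, log_hastings = lh, index = j)
}

## repeat each tied interval's nearest active predecessor value
ebsp_materialize <- function(rho, active) {
  for (i in seq_along(rho)[-1]) if (!active[i]) rho[i] <- rho[i - 1]
  rho
}

## ---- inference context ----------------------------------------------------

## Classify the data argument and build a fast log-likelihood closure.
## Fixed change-point models in constant mode use a precomputed sufficient
## structure: per-interval hazard weights W_i = sum over segments of
## k(k-1)/2 * width, and per-interval coalescent counts m_i, giving
## loglik(rho) = -sum(W/rho) - sum(m log rho).
likelihood_structure <- function(g, x) {
  tl <- build_timeline(g, x[x > 0])
  nr <- nrow(tl)
  a <- tl$time[-nr]; b <- tl$time[-1]; k <- tl$k_after[-nr]
  kk2 <- ifelse(k < 2, 0, k * (k - 1) / 2)
  idx <- findInterval(a, x)
  L <- length(x)
  W <- vapply(seq_len(L), function(i) sum(kk2[idx == i] * (b - a)[idx == i]),
              numeric(1))
  m <- tabulate(findInterval(g$coal_times, x), nbins = L)
  list(W = W, m = m)
}

## Piecewise-linear cumulative pair-hazard profile of a genealogy:
## F(t) = integral_0^t k(u)(k(u)-1)/2 du, precomputed at event boundaries so
## that the constant-mode log likelihood for arbitrary change-points x is
## -sum_i (F(x_{i+1}) - F(x_i)) / rho_i - sum_coal log rho(interval of coal).
hazard_profile <- function(g) {
  tl <- build_timeline(g)
  b <- tl$time
  k <- tl$k_after
  kk2 <- c(ifelse(k[-length(k)] < 2, 0, k[-length(k)] * (k[-length(k)] - 1) / 2), 0)
  cumF <- c(0, cumsum(kk2[-length(kk2)] * diff(b)))
  list(b = b, cumF = cumF, kk2 = kk2, coal = g$coal_times)
}

profile_F <- function(pr, t) {
  idx <- findInterval(t, pr$b)
  idx0 <- pmax(idx, 1L)
  out <- pr$cumF[idx0] + pr$kk2[idx0] * (t - pr$b[idx0])
  out[idx == 0] <- 0
  out[!is.finite(t)] <- pr$cumF[length(pr$cumF)]
  out
}

profile_loglik <- function(pr, x, rho) {
  Fx <- profile_F(pr, c(x, Inf))
  -sum(diff(Fx) / rho) - sum(log(rho[findInterval(pr$coal, x)]))
}

inference_context <- function(spec, data, settings) {
  model <- spec$model
  h <- spec$hyper
  mode <- spec$mode

  kind <- if (is.null(data)) "none"
    else if (inherits(data, "genealogy")) "single"
    else if (is.list(data) && !is.null(data$genealogies)) "sequential"
    else if (is.list(data) && all(vapply(data, inherits, logical(1), "genealogy")))
      "multilocus"
    else stop("unrecognized data: give a genealogy, a list of genealogies, ",
              "or list(genealogies=, ref_log_density=)")
  if (kind == "none" && isTRUE(settings$likelihood))
    stop("no data supplied; use likelihood = FALSE for prior-only runs")

  events_based <- model %in% c("skyline", "bsp", "ebsp", "skyride")
  if (events_based && kind %in% c("multilocus", "sequential"))
    stop("coalescent-event-based change-points are genealogy-specific; ",
         model, " supports a single genealogy only")

  g1 <- switch(kind, single = data, multilocus = data[[1]],
               sequential = data$genealogies[[1]], NULL)

  ## fixed change-points and interval count
  x <- NULL; L <- spec$n_intervals
  if (model == "constant") { x <- 0; L <- 1L }
  else if (events_based) {
    if (!is.null(g1)) {
      n1 <- length(g1$coal_times)
      epi <- if (model %in% c("skyline", "bsp"))
        group_events(n1, h$events_per_group) else rep(1L, n1)
      x <- changepoints_from_events(g1, epi)
      L <- length(x)
    } else if (is.null(L))
      stop("prior-only runs of ", model, " need n_intervals")
  } else if (model %in% c("skygrid", "gmrf", "hsmrf")) {
    x <- equal_grid(spec$t_max, L)
  } else if (model == "skyfish") {
    if (is.null(spec$t_max)) stop("skyfish requires t_max")
  }

  ## log-likelihood closure over a model state
  loglik <-
    if (!isTRUE(settings$likelihood)) {
      function(state) 0
    } else if (model == "skyfish" && mode == "constant") {
      prs <- switch(kind,
        single = list(hazard_profile(data)),
        multilocus = lapply(data, hazard_profile),
        sequential = lapply(data$genealogies, hazard_profile))
      if (kind == "sequential") {
        ref <- data$ref_log_density
        if (length(ref) != length(prs))
          stop("need one reference log density per genealogy sample")
        function(state) {
          x <- c(0, state$xi)
          ld <- vapply(prs, profile_loglik, numeric(1), x = x, rho = state$rho)
          log_mean_exp(ld - ref)
        }
      } else {
        function(state) {
          x <- c(0, state$xi)
          sum(vapply(prs, profile_loglik, numeric(1), x = x, rho = state$rho))
        }
      }
    } else if (model == "skyfish") {
      dens <- switch(kind,
        single = function(traj) coalescent_log_density(data, traj),
        multilocus = function(traj) multilocus_log_density(data, traj),
        sequential = function(traj)
          sequential_log_likelihood(data$genealogies, data$ref_log_density, traj))
      function(state) {
        traj <- trajectory(c(0, state$xi), state$rho, mode = mode)
        dens(traj)
      }
    } else if (mode == "constant" && kind == "single") {
      st <- likelihood_structure(data, x)
      function(state) -sum(st$W / state$rho) - sum(st$m * log(state$rho))
    } else if (mode == "constant" && kind == "multilocus") {
      sts <- lapply(data, likelihood_structure, x = x)
      W <- Reduce(`+`, lapply(sts, `[[`, "W"))
      m <- Reduce(`+`, lapply(sts, `[[`, "m"))
      function(state) -sum(W / state$rho) - sum(m * log(state$rho))
    } else if (mode == "constant" && kind == "sequential") {
      sts <- lapply(data$genealogies, likelihood_structure, x = x)
      Wm <- do.call(rbind, lapply(sts, `[[`, "W"))
      mm <- do.call(rbind, lapply(sts, `[[`, "m"))
      ref <- data$ref_log_density
      if (length(ref) != nrow(Wm))
        stop("need one reference log density per genealogy sample")
      function(state) {
        ld <- -as.vector(Wm %*% (1 / state$rho)) -
          as.vector(mm %*% log(state$rho))
        log_mean_exp(ld - ref)
      }
    } else {  # linear mode, generic path
      dens <- switch(kind,
        single = function(traj) coalescent_log_density(data, traj),
        multilocus = function(traj) multilocus_log_density(data, traj),
        sequential = function(traj)
          sequential_log_likelihood(data$genealogies, data$ref_log_density, traj))
      function(state) dens(trajectory(x, state$rho, mode = mode))
    }

  list(kind = kind, x = x, L = L, loglik = loglik,
       t_max = spec$t_max, events_based = events_based)
}

## ---- the chain ------------------------------------------------------------

## One Metropolis sweep.  env holds state, lp (log prior), ll (log lik),
## tun (tuning scalars), acc/try counters, power.
mh_step <- function(env, spec, ctx, new_state, log_hastings, lik_changed,
                    class) {
  lp_new <- log_prior(spec, new_state)
  ok <- FALSE
  if (is.finite(lp_new) && is.finite(log_hastings)) {
    ll_new <- if (lik_changed) ctx$loglik(new_state) else env$ll
    if (is.finite(ll_new)) {
      dlog <- (lp_new + env$power * ll_new) - (env$lp + env$power * env$ll) +
        log_hastings
      if (log(stats::runif(1)) < dlog) {
        env$state <- new_state; env$lp <- lp_new; env$ll <- ll_new
        ok <- TRUE
      }
    }
  }
  env$try[class] <- env$try[class] + 1
  env$acc[class] <- env$acc[class] + ok
  invisible(ok)
}

mcmc_sweep <- function(env, spec, ctx) {
  model <- spec$model
  st <- env$state
  tun <- env$tun

  ## scale moves on every free population size
  free <- if (model == "ebsp") which(st$active) else seq_along(st$rho)
  for (j in free) {
    st <- env$state
    pr <- scale_move(st$rho[j], tun["rho_scale"])
    st$rho[j] <- pr$value
    if (model == "ebsp") st$rho <- ebsp_materialize(st$rho, st$active)
    mh_step(env, spec, ctx, st, pr$log_hastings, TRUE, "rho_scale")
  }

  ## scale moves on positive hyperparameters (prior-only likelihood impact)
  for (fld in intersect(names(env$state), c("tau", "gamma", "mu", "sigma"))) {
    st <- env$state
    pr <- scale_move(st[[fld]], tun["hyper_scale"])
    st[[fld]] <- pr$value
    mh_step(env, spec, ctx, st, pr$log_hastings, FALSE, "hyper_scale")
  }
  if (model == "hsmrf") {
    for (j in seq_along(env$state$sigma_local)) {
      st <- env$state
      pr <- scale_move(st$sigma_local[j], tun["hyper_scale"])
      st$sigma_local[j] <- pr$value
      mh_step(env, spec, ctx, st, pr$log_hastings, FALSE, "hyper_scale")
    }
  }

  if (model == "skyfish") {
    ## reflected sliding moves on each change-point
    w <- tun["xi_window"] * ctx$t_max
    for (j in seq_len(env$state$kappa)) {
      st <- env$state
      st$xi[j] <- reflect_into(st$xi[j] + stats::runif(1, -w, w), 0, ctx$t_max)
      mh_step(env, spec, ctx, st, 0, TRUE, "xi_slide")
    }
    ## one reversible-jump birth/death move per sweep
    pr <- rj_birth_death_move(env$state, ctx$t_max, tun["birth_sd"], spec$mode)
    mh_step(env, spec, ctx, pr$state, pr$log_hastings, TRUE, "rj")
  }
  if (model == "ebsp" && ctx$L > 1) {
    pr <- ebsp_toggle_move(env$state)
    mh_step(env, spec, ctx, pr$state, pr$log_hastings, TRUE, "rj")
  }
  invisible(NULL)
}

init_state <- function(spec, ctx, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    st <- sample_prior(spec, n_intervals = ctx$L)
    lp <- log_prior(spec, st)
    if (!is.finite(lp)) next
    ll <- ctx$loglik(st)
    if (is.finite(ll)) return(list(state = st, lp = lp, ll = ll))
  }
  stop("could not find a starting state with positive posterior probability ",
       "after ", max_tries, " prior draws")
}

num_str <- function(v) paste(sprintf("%.17g", v), collapse = ",")

record_row <- function(env, spec, ctx, iter, rep) {
  st <- env$state
  x <- if (spec$model == "skyfish") c(0, st$xi) else ctx$x
  row <- list(iteration = iter, replicate = rep,
              log_posterior = env$lp + env$ll, log_likelihood = env$ll,
              log_prior = env$lp, n_intervals = length(st$rho),
              times = num_str(x), rho = num_str(st$rho))
  for (fld in intersect(names(st), c("tau", "gamma", "mu", "sigma", "kappa")))
    row[[fld]] <- st[[fld]]
  if (!is.null(st$sigma_local)) row$sigma_local <- num_str(st$sigma_local)
  if (!is.null(st$active)) row$active <- paste(as.integer(st$active),
                                               collapse = ",")
  row
}

run_chain <- function(spec, ctx, n_iter, thinning, tune_iters, settings,
                      power = 1, state0 = NULL, rep_id = 1L,
                      record = TRUE) {
  env <- new.env()
  env$power <- power
  env$tun <- unlist(settings$tuning[c("rho_scale", "hyper_scale",
                                      "xi_window", "birth_sd")])
  names(env$tun) <- c("rho_scale", "hyper_scale", "xi_window", "birth_sd")
  classes <- c("rho_scale", "hyper_scale", "xi_slide", "rj")
  env$acc <- stats::setNames(numeric(4), classes)
  env$try <- stats::setNames(numeric(4), classes)

  ini <- if (is.null(state0)) init_state(spec, ctx) else state0
  env$state <- ini$state; env$lp <- ini$lp; env$ll <- ini$ll

  rows <- vector("list", n_iter %/% thinning)
  nrec <- 0L
  window <- 0L
  lls <- numeric(n_iter %/% thinning)
  for (it in seq_len(n_iter)) {
    mcmc_sweep(env, spec, ctx)
    ## Robbins-Monro style adaptation toward 0.44 acceptance, burn-in only
    if (settings$auto_tune && it <= tune_iters && it %% 50 == 0) {
      window <- window + 1L
      delta <- min(0.25, 1 / sqrt(window))
      map <- c(rho_scale = "rho_scale", hyper_scale = "hyper_scale",
               xi_slide = "xi_window")
      for (cl in names(map)) {
        if (env$try[cl] > 0) {
          rate <- env$acc[cl] / env$try[cl]
          env$tun[map[cl]] <- env$tun[map[cl]] * exp(delta * sign(rate - 0.44))
        }
      }
      env$tun["xi_window"] <- min(env$tun["xi_window"], 0.5)
      env$acc[] <- 0; env$try[] <- 0
    }
    if (it %% thinning == 0) {
      nrec <- nrec + 1L
      lls[nrec] <- env$ll
      if (record) rows[[nrec]] <- record_row(env, spec, ctx, it, rep_id)
    }
  }
  list(rows = if (record) rows[seq_len(nrec)] else NULL,
       loglik_samples = lls[seq_len(nrec)],
       final = list(state = env$state, lp = env$lp, ll = env$ll),
       acceptance = ifelse(env$try > 0, env$acc / env$try, NA),
       tuning = env$tun)
}

#' Run MCMC (or RJ-MCMC) for a skyline prior model
#'
#' Samples the posterior `likelihood x prior` over trajectory parameters
#' and hyperparameters.  Data may be a single [genealogy], a list of
#' genealogies (multi-locus, coalescent-event-independent models only), or
#' `list(genealogies = ..., ref_log_density = ...)` for sequential
#' inference from a posterior sample of genealogies.  Seeded runs are
#' reproducible; per-move acceptance rates are attached as an attribute.
#'
#' @param spec a [prior_spec].
#' @param data the data (see above); may be `NULL` for prior-only runs
#'   (`likelihood = FALSE` in the settings).
#' @param settings an [mcmc_settings] list.
#' @return a data frame of class `skyline_trace`: one row per retained
#'   sample with columns `iteration`, `replicate`, `log_posterior`,
#'   `log_likelihood`, `log_prior`, `n_intervals`, `times` and `rho`
#'   (comma-joined change-points and population sizes), plus model-specific
#'   hyperparameter columns.  Attributes: `model`, `mode`, `spec`,
#'   `settings`, `acceptance`.
#' @export
run_mcmc <- function(spec, data = NULL, settings = mcmc_settings()) {
  stopifnot(inherits(spec, "prior_spec"))
  if (!inherits(settings, "mcmc_settings"))
    settings <- do.call(mcmc_settings, settings)
  ctx <- inference_context(spec, data, settings)

  per_rep <- raw_sample_count(settings$iterations, settings$thinning)
  drop <- floor(settings$burn_in_fraction * per_rep)
  tune_iters <- floor(settings$burn_in_fraction * settings$iterations)

  all_rows <- list()
  acc <- NULL
  for (rep in seq_len(settings$n_replicates)) {
    set.seed(settings$seed + rep - 1L)
    res <- run_chain(spec, ctx, settings$iterations, settings$thinning,
                     tune_iters, settings, rep_id = rep)
    keep <- res$rows[(drop + 1L):per_rep]
    all_rows <- c(all_rows, keep)
    acc <- rbind(acc, res$acceptance)
  }
  cols <- names(all_rows[[1]])
  tr <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn)
    unlist(lapply(all_rows, `[[`, cn), use.names = FALSE)),
    stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  attr(tr, "model") <- spec$model
  attr(tr, "mode") <- spec$mode
  attr(tr, "spec") <- spec
  attr(tr, "settings") <- settings
  attr(tr, "acceptance") <- acc
  class(tr) <- c("skyline_trace", class(tr))
  tr
}

#' Write / read a trace as a tab-separated file
#'
#' One header row, one row per retained sample; numeric values are written
#' with full (17 significant digit) precision, so identically seeded runs
#' produce byte-identical files.
#'
#' @param trace a trace from [run_mcmc()].
#' @param path file path.
#' @return [read_trace()] returns the trace data frame;
#'   [write_trace()] returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(tr) <- c("skyline_trace", class(tr))
  tr
}

## ---- convergence ----------------------------------------------------------

ks_statistic <- function(x, y) {
  xs <- sort(x); ys <- sort(y)
  v <- c(xs, ys)
  max(abs(findInterval(v, xs) / length(xs) -
            findInterval(v, ys) / length(ys)))
}

#' Replicate convergence check on the demographic history
#'
#' Compares two replicate traces of the same model by the
#' Kolmogorov-Smirnov distance between their samples of `log Ne` at each
#' grid time; the check fails if any grid point exceeds the threshold.
#'
#' @param trace1,trace2 traces of the same model (e.g. single replicates
#'   split out of a [run_mcmc()] result).
#' @param grid time grid (see [exponential_grid()]).
#' @param threshold maximal tolerated KS distance (default 0.05).
#' @return list with `times`, `statistic` (per grid point), `threshold`
#'   and `pass`.
#' @export
check_convergence <- function(trace1, trace2, grid, threshold = 0.05) {
  if (nrow(trace1) < 100 || nrow(trace2) < 100)
    stop("need at least 100 samples per replicate")
  m1 <- log(trace_ne_matrix(trace1, grid))
  m2 <- log(trace_ne_matrix(trace2, grid))
  stat <- vapply(seq_along(grid),
                 function(i) ks_statistic(m1[, i], m2[, i]), numeric(1))
  list(times = grid, statistic = stat, threshold = threshold,
       pass = all(stat <= threshold))
}

## ---- marginal likelihoods -------------------------------------------------

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Runs a ladder of power posteriors `likelihood^beta x prior` with powers
#' `beta_i = (i/(n_stones - 1))^(1/0.3)` (quantiles of a Beta(0.3, 1),
#' the customary spacing, concentrating stones near the prior) and
#' assembles the log marginal likelihood from stone-wise importance
#' ratios: `sum_k log mean_j exp((beta_{k+1} - beta_k) * loglik_jk)` with
#' samples taken at power `beta_k`.  Chains are warm-started from the
#' previous stone.  Only proper priors are accepted.
#'
#' @param spec a [prior_spec].
#' @param data as in [run_mcmc()].
#' @param n_stones number of powers including the `beta = 0` prior stone
#'   and the `beta = 1` posterior stone (default 128, i.e. 127 power
#'   posteriors beyond the prior).
#' @param iterations_per_stone MCMC iterations per stone (default 5000).
#' @param seed integer seed.
#' @param tuning,auto_tune forwarded to [mcmc_settings()].
#' @param burn_in_fraction fraction of each stone's samples discarded.
#' @return list of class `stepping_stone` with `log_ml`, `betas`,
#'   `per_stone` (stone-wise log ratio contributions).
#' @export
stepping_stone <- function(spec, data, n_stones = 128,
                           iterations_per_stone = 5000, seed = 1,
                           tuning = list(), auto_tune = TRUE,
                           burn_in_fraction = 0.1) {
  stopifnot(inherits(spec, "prior_spec"))
  h <- spec$hyper
  if (!is.finite(h$uniform_max) || !is.finite(h$logunif_max) ||
      h$logunif_min <= 0)
    stop("improper prior: uniform and log-uniform bounds must be finite ",
         "and positive for marginal-likelihood estimation")
  settings <- mcmc_settings(iterations = iterations_per_stone, thinning = 1,
                            burn_in_fraction = burn_in_fraction,
                            n_replicates = 1, seed = seed,
                            likelihood = !is.null(data),
                            tuning = tuning, auto_tune = auto_tune)
  ctx <- inference_context(spec, data, settings)
  betas <- (seq_len(n_stones) - 1)^(1 / 0.3) / (n_stones - 1)^(1 / 0.3)
  set.seed(seed)
  drop <- floor(burn_in_fraction * iterations_per_stone)
  tune_iters <- drop
  state0 <- NULL
  contrib <- numeric(n_stones - 1)
  for (k in seq_len(n_stones - 1)) {
    res <- run_chain(spec, ctx, iterations_per_stone, 1L, tune_iters,
                     settings, power = betas[k], state0 = state0,
                     record = FALSE)
    ll <- res$loglik_samples[(drop + 1L):iterations_per_stone]
    contrib[k] <- log_mean_exp((betas[k + 1] - betas[k]) * ll)
    if (!is.finite(contrib[k])) stop("non-finite stepping-stone estimate at ",
                                     "stone ", k)
    state0 <- res$final
  }
  structure(list(log_ml = sum(contrib), betas = betas, per_stone = contrib),
            class = "stepping_stone")
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat(sprintf("stepping-stone log marginal likelihood: %.4f (%d stones)\n",
              x$log_ml, length(x$betas)))
  invisible(x)
}

#' Log Bayes factor between two models
#'
#' @param log_ml_a,log_ml_b log marginal likelihoods (numbers or
#'   [stepping_stone()] results).
#' @return `log BF = log_ml_a - log_ml_b`.
#' @export
bayes_factor <- function(log_ml_a, log_ml_b) {
  val <- function(x) if (inherits(x, "stepping_stone")) x$log_ml else x
  a <- val(log_ml_a); b <- val(log_ml_b)
  if (!is.finite(a) || !is.finite(b))
    stop("log marginal likelihoods must be finite")
  a - b
}
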