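test_that("default hyperparameters carry the standard constants", {
  expect_equal(default_hyperparams("gmrf", 50)$zeta, 0.0195)
  expect_equal(default_hyperparams("hsmrf", 50)$zeta, 0.0051)
  sf <- default_hyperparams("skyfish", t_max = 1e6)
  expect_equal(sf$H, 0.587405)
  expect_equal(sf$poisson_mean, 10)
  expect_equal(sf$sigma_rate, 1e6 / 8)
  expect_equal(default_hyperparams("bsp")$logunif_min, 1e-2)
  expect_equal(default_hyperparams("constant")$uniform_max, 1e8)
  expect_equal(default_hyperparams("skyride")$tau_shape, 0.001)
  expect_error(default_hyperparams("skynet"), "arg")
})

test_that("log prior matches closed-form component densities", {
  expect_equal(log_prior(prior_spec("constant"), list(rho = 5e7)),
               -log(1e8))
  expect_equal(log_prior(prior_spec("constant"), list(rho = 2e8)), -Inf)

  bsp <- prior_spec("bsp")
  expect_equal(log_prior(bsp, list(rho = 100)),
               -log(100) - log(log(1e10)))
  expect_equal(log_prior(bsp, list(rho = c(100, 100))),
               -log(100) - log(log(1e10)) + stats::dexp(100, 1 / 100, log = TRUE))
})

test_that("log prior equals an independent factorized computation", {
  ## the generative factorization recomputed from scratch per model
  set.seed(41)
  dlu <- function(x) -log(x) - log(log(1e8 / 1e-2))
  dhc <- function(x) log(2 / pi) - log1p(x^2)
  ## heavy-tailed hyperpriors occasionally push rho past double range, where
  ## both sides are degenerate; compare densities on representable draws
  draw_finite <- function(spec, L = NULL) {
    repeat {
      st <- sample_prior(spec, L)
      if (all(is.finite(st$rho)) && all(st$rho > 0)) return(st)
    }
  }

  for (i in 1:50) {
    L <- sample(2:4, 1)

    st <- sample_prior(prior_spec("skyline"), L)
    expect_equal(log_prior(prior_spec("skyline"), st), L * -log(1e8))

    st <- sample_prior(prior_spec("bsp"), L)
    expect_equal(log_prior(prior_spec("bsp"), st),
                 dlu(st$rho[1]) +
                   sum(stats::dexp(st$rho[-1], 1 / st$rho[-L], log = TRUE)))

    st <- draw_finite(prior_spec("skyride"), L)
    expect_equal(log_prior(prior_spec("skyride"), st),
                 stats::dgamma(st$tau, 0.001, 0.001, log = TRUE) +
                   dlu(st$rho[1]) +
                   sum(stats::dnorm(log(st$rho[-1]), log(st$rho[-L]),
                                    1 / sqrt(st$tau), log = TRUE) -
                         log(st$rho[-1])))

    st <- draw_finite(prior_spec("gmrf", t_max = 1), L)
    expect_equal(log_prior(prior_spec("gmrf", t_max = 1), st),
                 dhc(st$gamma) - log(1e8) +
                   sum(stats::dnorm(log(st$rho[-1]), log(st$rho[-L]),
                                    st$gamma * 0.0195, log = TRUE) -
                         log(st$rho[-1])))

    st <- draw_finite(prior_spec("hsmrf", t_max = 1), L)
    expect_equal(log_prior(prior_spec("hsmrf", t_max = 1), st),
                 dhc(st$gamma) + sum(dhc(st$sigma_local)) - log(1e8) +
                   sum(stats::dnorm(log(st$rho[-1]), log(st$rho[-L]),
                                    st$sigma_local * st$gamma * 0.0051,
                                    log = TRUE) - log(st$rho[-1])))

    st <- sample_prior(prior_spec("ebsp"), L)
    nact <- sum(st$active[-1])
    expect_equal(log_prior(prior_spec("ebsp"), st),
                 dlu(st$mu) +
                   sum(stats::dexp(st$rho[st$active], 1 / st$mu, log = TRUE)) +
                   nact * log(0.5) + (L - 1 - nact) * log(0.5))

    sf <- prior_spec("skyfish", t_max = 1e6)
    st <- draw_finite(sf)
    kap <- st$kappa
    manual <- stats::dpois(kap, 10, log = TRUE) +
      stats::dexp(st$sigma, 1e6 / 8, log = TRUE) +
      stats::dlnorm(st$rho[1], log(1e6 / 4), 2 * 0.587405, log = TRUE)
    if (kap > 0)
      manual <- manual + lfactorial(kap) - kap * log(1e6) +
        sum(stats::dlnorm(st$rho[-1], log(st$rho[-(kap + 1)]),
                          st$sigma * diff(c(0, st$xi)), log = TRUE))
    expect_equal(log_prior(sf, st), manual)
  }
})

test_that("one-interval restrictions integrate to one", {
  ## quadrature check of the first-interval density of each model family
  lu_norm <- stats::integrate(function(x) exp(-log(x) - log(log(1e10))),
                              1e-2, 1e8, rel.tol = 1e-10)$value
  expect_equal(lu_norm, 1, tolerance = 1e-6)
  un_norm <- stats::integrate(function(x) rep(1 / 1e8, length(x)),
                              0, 1e8)$value
  expect_equal(un_norm, 1, tolerance = 1e-10)
  ## lognormal first-interval density, integrated on the log scale
  sf_norm <- stats::integrate(function(y)
    stats::dnorm(y, log(1e6 / 4), 2 * 0.587405), -Inf, Inf,
    rel.tol = 1e-10)$value
  expect_equal(sf_norm, 1, tolerance = 1e-6)
  ## conditional increment densities integrate to one given the predecessor
  inc_norm <- stats::integrate(function(x) stats::dexp(x, 1 / 350), 0, Inf,
                               rel.tol = 1e-10)$value
  expect_equal(inc_norm, 1, tolerance = 1e-6)
})

test_that("prior draws reproduce their stated moments", {
  set.seed(42)
  n <- 20000
  rho <- replicate(n, sample_prior(prior_spec("constant"))$rho)
  expect_lt(abs(mean(rho) - 5e7) / (stats::sd(rho) / sqrt(n)), 3)

  sf <- prior_spec("skyfish", t_max = 1e6)
  kap <- replicate(n, sample_prior(sf)$kappa)
  expect_lt(abs(mean(kap) - 10) / (stats::sd(kap) / sqrt(n)), 3)

  gm <- prior_spec("gmrf", t_max = 1)
  inc <- replicate(5000, {
    st <- sample_prior(gm, 3)
    diff(log(st$rho))
  })
  expect_lt(abs(mean(inc)) / (stats::sd(inc) / sqrt(length(inc))), 3)
})

test_that("the number of free EBSP intervals is binomial", {
  set.seed(43)
  L <- 11
  n <- 5000
  nint <- replicate(n, sum(sample_prior(prior_spec("ebsp"), L)$active))
  ## 1 + Binomial(L - 1, 0.5) distinct intervals
  expect_lt(abs(mean(nint) - (1 + (L - 1) * 0.5)) /
              (stats::sd(nint) / sqrt(n)), 3)
})

test_that("skyfish states map to valid trajectories", {
  st0 <- list(rho = 42, kappa = 0L, xi = numeric(), sigma = 1)
  tr0 <- skyfish_trajectory_from_state(st0, 1e3)
  expect_equal(tr0$x, 0)
  expect_equal(ne_at(tr0, 999), 42)

  st2 <- list(rho = c(1, 2, 3), kappa = 2L, xi = c(100, 200), sigma = 1)
  tr2 <- skyfish_trajectory_from_state(st2, 1e3)
  expect_equal(tr2$x, c(0, 100, 200))
  expect_equal(ne_at(tr2, c(0, 150, 5000)), c(1, 2, 3))
  expect_error(skyfish_trajectory_from_state(
    list(rho = c(1, 2), kappa = 1L, xi = 2e3, sigma = 1), 1e3), "t_max")
})
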