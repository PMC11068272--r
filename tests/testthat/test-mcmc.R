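test_that("scale proposals are positive multipliers with the right Hastings ratio", {
  set.seed(51)
  pr <- scale_move(3, 0)
  expect_equal(pr$value, 3)
  expect_equal(pr$log_hastings, 0)
  for (i in 1:200) {
    pr <- scale_move(stats::runif(1, 0, 10), stats::runif(1, 0, 3))
    expect_gt(pr$value, 0)
  }
})

test_that("a pure scale-move chain leaves an exponential target invariant", {
  set.seed(52)
  x <- 1
  n <- 1e5
  out <- numeric(n)
  for (i in seq_len(n)) {
    pr <- scale_move(x, 2.5)
    if (log(stats::runif(1)) <
        stats::dexp(pr$value, log = TRUE) - stats::dexp(x, log = TRUE) +
        pr$log_hastings)
      x <- pr$value
    out[i] <- x
  }
  ks <- suppressWarnings(stats::ks.test(out[seq(1, n, by = 10)], stats::pexp))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("reversible-jump birth and death are exact inverses", {
  set.seed(53)
  st <- list(rho = c(10, 20), kappa = 1L, xi = 300, sigma = 1e-3)
  ## a birth followed by removing the same change-point restores the state
  repeat {
    pr <- rj_birth_death_move(st, 1000, birth_sd = 0.5)
    if (pr$type == "birth") break
  }
  j <- which(!(pr$state$xi %in% st$xi))
  back <- pr$state
  back$kappa <- back$kappa - 1L
  back$xi <- back$xi[-j]
  back$rho <- back$rho[-(j + 1)]
  expect_equal(back, st)

  ## death at kappa = 0 is auto-rejected
  st0 <- list(rho = 5, kappa = 0L, xi = numeric(), sigma = 1e-3)
  reject_seen <- FALSE
  for (i in 1:50) {
    pr <- rj_birth_death_move(st0, 1000)
    if (pr$type == "reject") {
      reject_seen <- TRUE
      expect_identical(pr$state, st0)
      expect_identical(pr$log_hastings, -Inf)
    }
  }
  expect_true(reject_seen)
})

test_that("EBSP toggles re-materialize ties and invert themselves", {
  set.seed(54)
  st <- list(rho = c(5, 5, 9), active = c(TRUE, FALSE, TRUE), mu = 10)
  pr <- ebsp_toggle_move(st, index = 2)     # activate
  expect_true(pr$state$active[2])
  back <- ebsp_toggle_move(pr$state, index = 2)  # deactivate again
  expect_equal(back$state, st)

  ## deactivating an interval propagates its predecessor's value downstream
  st2 <- list(rho = c(5, 7, 7), active = c(TRUE, TRUE, FALSE), mu = 10)
  pr2 <- ebsp_toggle_move(st2, index = 2)
  expect_equal(pr2$state$rho, c(5, 5, 5))

  ## alpha_eq = 1 puts zero prior mass on any tied candidate
  spec1 <- prior_spec("ebsp", hyper = list(alpha_eq = 1))
  expect_equal(log_prior(spec1, st2), -Inf)
  st_all <- list(rho = c(5, 7, 8), active = rep(TRUE, 3), mu = 10)
  expect_true(is.finite(log_prior(spec1, st_all)))
})

test_that("trace bookkeeping matches the replicate/thinning/burn-in arithmetic", {
  g <- two_tip(1500)
  sett <- mcmc_settings(iterations = 1000, thinning = 10,
                        burn_in_fraction = 0.1, n_replicates = 2, seed = 5)
  tr <- run_mcmc(prior_spec("constant"), g, sett)
  expect_equal(nrow(tr), retained_sample_count(1000, 10, 0.1, 2))
  expect_equal(nrow(tr), 180)
  expect_equal(sort(unique(tr$replicate)), c(1, 2))
})

test_that("identically seeded runs produce byte-identical trace files", {
  g <- two_tip(1500)
  sett <- mcmc_settings(iterations = 500, thinning = 5, n_replicates = 1,
                        seed = 99)
  f1 <- tempfile(); f2 <- tempfile()
  write_trace(run_mcmc(prior_spec("constant"), g, sett), f1)
  write_trace(run_mcmc(prior_spec("constant"), g, sett), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("prior-only chains recover the sampled prior per model", {
  set.seed(55)
  n_direct <- 1e4

  ## constant: uniform population size
  tr <- run_mcmc(prior_spec("constant"), NULL,
                 mcmc_settings(iterations = 20000, thinning = 2,
                               burn_in_fraction = 0.1, n_replicates = 1,
                               seed = 1, likelihood = FALSE))
  direct <- stats::runif(n_direct, 0, 1e8)
  expect_lt(ks_between(as.numeric(tr$rho), direct), 0.05)

  ## bsp: log-uniform first interval
  tr <- run_mcmc(prior_spec("bsp", n_intervals = 3), NULL,
                 mcmc_settings(iterations = 80000, thinning = 8,
                               burn_in_fraction = 0.1, n_replicates = 1,
                               seed = 2, likelihood = FALSE))
  rho1 <- vapply(strsplit(tr$rho, ","), function(v) as.numeric(v[1]),
                 numeric(1))
  direct <- exp(stats::runif(n_direct, log(1e-2), log(1e8)))
  expect_lt(ks_between(log(rho1), log(direct)), 0.05)

  ## gmrf with the global scale held fixed: increments are centered normals
  tr <- run_mcmc(prior_spec("gmrf", n_intervals = 2, t_max = 1,
                            hyper = list()), NULL,
                 mcmc_settings(iterations = 20000, thinning = 2,
                               burn_in_fraction = 0.1, n_replicates = 1,
                               seed = 3, likelihood = FALSE))
  rhom <- do.call(rbind, lapply(strsplit(tr$rho, ","),
                                function(v) as.numeric(v)))
  inc <- log(rhom[, 2]) - log(rhom[, 1])
  gam <- tr$gamma
  expect_lt(suppressWarnings(unname(stats::ks.test(
    inc / (gam * 0.0195), stats::pnorm)$statistic)), 0.05)

  ## ebsp: binomial number of free intervals
  tr <- run_mcmc(prior_spec("ebsp", n_intervals = 9), NULL,
                 mcmc_settings(iterations = 30000, thinning = 3,
                               burn_in_fraction = 0.1, n_replicates = 1,
                               seed = 4, likelihood = FALSE))
  nact <- vapply(strsplit(tr$active, ","),
                 function(v) sum(as.integer(v)), numeric(1))
  se <- stats::sd(nact) / sqrt(neff_batch(nact))
  expect_lt(abs(mean(nact) - (1 + 8 * 0.5)), 3 * pmax(se, 0.02))
})

test_that("skyline posteriors factorize per interval and match quadrature", {
  ## fixed three-tip genealogy, one coalescent event per interval: the
  ## posterior of each interval's size is independent with density
  ## proportional to exp(-W_i/r) r^(-m_i) times the uniform prior.  Both
  ## coalescent events (at 400 and 1300) fall in the older interval under
  ## the left-closed convention, so rho_2 | data ~ inv-gamma-like with
  ## hazard weight W_2 = 2(2-1)/2 * (1300 - 400) = 900 and m_2 = 2.
  set.seed(56)
  g <- three_tip(400, 1300)
  spec <- prior_spec("skyline", hyper = list(events_per_group = 1))
  tr <- run_mcmc(spec, g,
                 mcmc_settings(iterations = 40000, thinning = 4,
                               burn_in_fraction = 0.1, n_replicates = 2,
                               seed = 6))
  rhom <- do.call(rbind, lapply(strsplit(tr$rho, ","), as.numeric))
  f2 <- function(r) exp(-900 / r) / r^2
  oracle <- stats::integrate(function(r) log(r) * f2(r), 0, 1e8,
                             rel.tol = 1e-10)$value /
    stats::integrate(f2, 0, 1e8, rel.tol = 1e-10)$value
  expect_equal(mean(log(rhom[, 2])), oracle, tolerance = 0.05)
})

test_that("replicate convergence is diagnosed via grid-wise KS distances", {
  set.seed(57)
  g <- two_tip(1500)
  tr <- run_mcmc(prior_spec("constant"), g,
                 mcmc_settings(iterations = 20000, thinning = 5,
                               burn_in_fraction = 0.1, n_replicates = 2,
                               seed = 7))
  r1 <- tr[tr$replicate == 1, ]; r2 <- tr[tr$replicate == 2, ]
  grid <- exponential_grid(3000, 10)
  cv <- check_convergence(r1, r2, grid)
  expect_true(cv$pass)
  expect_equal(length(cv$statistic), 10)
  ## identical traces give statistic zero
  cv0 <- check_convergence(r1, r1, grid)
  expect_true(all(cv0$statistic == 0))
  ## disjoint supports fail
  fake1 <- r1; fake1$rho <- sprintf("%.17g", rep(1e3, nrow(r1)))
  fake2 <- r2; fake2$rho <- sprintf("%.17g", rep(1e4, nrow(r2)))
  expect_false(check_convergence(fake1, fake2, grid)$pass)
  expect_error(check_convergence(r1[1:10, ], r2, grid), "100")
})

test_that("stepping-stone estimates agree with brute-force benchmarks", {
  set.seed(58)
  ## likelihood identically one: the marginal of a normalized prior is one
  ss0 <- stepping_stone(prior_spec("constant"), NULL, n_stones = 8,
                        iterations_per_stone = 200, seed = 1)
  expect_equal(ss0$log_ml, 0, tolerance = 1e-12)

  ## two stones degenerate to the prior arithmetic-mean estimator
  g <- two_tip(1500)
  B <- 1e5
  spec <- prior_spec("constant", hyper = list(uniform_max = B))
  ss2 <- stepping_stone(spec, g, n_stones = 2,
                        iterations_per_stone = 20000, seed = 2)
  set.seed(101)
  rho <- stats::runif(50000, 0, B)
  naive <- log(mean(exp(-1500 / rho) / rho))
  expect_equal(ss2$log_ml, naive, tolerance = 0.2)

  ## improper priors are refused
  expect_error(stepping_stone(prior_spec("constant",
                                         hyper = list(uniform_max = Inf)),
                              g, n_stones = 4, iterations_per_stone = 100),
               "improper")
})

test_that("log Bayes factors subtract and antisymmetrize", {
  expect_equal(bayes_factor(-10, -12), 2)
  expect_equal(bayes_factor(-3, -3), 0)
  expect_equal(bayes_factor(-7, -2), -bayes_factor(-2, -7))
  expect_error(bayes_factor(NaN, 0), "finite")
})
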