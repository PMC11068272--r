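## Shared fixtures and independent oracles used across the suite.

## a two-tip genealogy with given coalescent time and tip ages
two_tip <- function(t1, age_a = 0, age_b = 0) {
  read_genealogy(sprintf("(A:%.12g,B:%.12g);", t1 - age_a, t1 - age_b),
                 c(A = age_a, B = age_b))
}

## a three-tip isochronous genealogy from its two coalescent times
three_tip <- function(t2, t1) {
  read_genealogy(sprintf("((A:%.12g,B:%.12g):%.12g,C:%.12g);",
                         t2, t2, t1 - t2, t1),
                 c(A = 0, B = 0, C = 0))
}

## adaptive-quadrature oracle for the integrated coalescent rate over (a, b)
quad_rate <- function(a, b, k, traj) {
  if (a == b) return(0)
  stats::integrate(function(t) coalescent_rate(rep(k, length(t)), ne_at(traj, t)),
                   a, b, rel.tol = 1e-11, abs.tol = 0)$value
}

## random positive piecewise trajectory for property tests
random_trajectory <- function(L = NULL, mode = "constant", t_span = 1000) {
  if (is.null(L)) L <- sample(1:5, 1)
  x <- c(0, sort(stats::runif(L - 1, 0, t_span)))
  trajectory(x, exp(stats::rnorm(L, log(500), 1)), mode = mode)
}

## two-sample Kolmogorov-Smirnov statistic without ks.test tie warnings
ks_between <- function(x, y) {
  n <- length(x); m <- length(y)
  o <- order(c(x, y))
  max(abs(cumsum(ifelse(o <= n, 1 / n, -1 / m))))
}

## crude effective sample size via batch means (for MCMC standard errors)
neff_batch <- function(x, n_batch = 50) {
  bs <- floor(length(x) / n_batch)
  bm <- vapply(seq_len(n_batch),
               function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  v_batch <- stats::var(bm) * bs
  max(10, length(x) * stats::var(x) / max(v_batch, 1e-300))
}

## thinning (rejection) sampler for the pairwise coalescent time of two
## isochronous lineages under a piecewise-constant trajectory: an
## independent check of the inversion sampler
thinning_pair_time <- function(traj) {
  lambda_max <- 1 / min(traj$rho)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, lambda_max)
    if (stats::runif(1) < (1 / ne_at(traj, t)) / lambda_max) return(t)
  }
}
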