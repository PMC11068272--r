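#' Instantaneous coalescent rate
#'
#' With `k` active lineages and effective population size `ne`, each of the
#' `k(k-1)/2` lineage pairs coalesces at rate `1/ne`, giving a total rate
#' `k(k-1)/(2 ne)`; the rate is 0 when fewer than two lineages are active.
#'
#' @param k number of active lineages (non-negative integer, vectorized).
#' @param ne effective population size (> 0, vectorized).
#' @return the coalescent rate.
#' @export
coalescent_rate <- function(k, ne) {
  if (any(ne <= 0)) stop("ne must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  ifelse(k < 2, 0, k * (k - 1) / (2 * ne))
}

#' Integrated coalescent rate over a segment
#'
#' Cumulative hazard `integral_a^b k(k-1) / (2 Ne(t)) dt` for a segment
#' `(a, b)` lying within a single trajectory interval.  Constant mode gives
#' `k(k-1)(b-a) / (2 rho_i)`; linear mode with slope `alpha != 0` gives
#' `k(k-1)/(2 alpha) * log(Ne(b)/Ne(a))`, falling back to the constant
#' formula as `alpha -> 0`.
#'
#' @param a,b segment bounds, `0 <= a <= b`, within one trajectory interval.
#' @param k active lineage count on the segment.
#' @param traj a [trajectory].
#' @return the cumulative hazard over `(a, b)`.
#' @export
integrated_rate <- function(a, b, k, traj) {
  stopifnot(inherits(traj, "demographic_trajectory"))
  if (a > b) stop("need a <= b")
  L <- length(traj$x)
  i <- findInterval(a, traj$x)
  if (i < L && b > traj$x[i + 1])
    stop("segment straddles a change-point; split it first")
  if (k < 2 || a == b) return(0)
  kk2 <- k * (k - 1) / 2
  if (traj$mode == "constant" || i >= L) {
    kk2 * (b - a) / traj$rho[i]
  } else {
    alpha <- (traj$rho[i + 1] - traj$rho[i]) / (traj$x[i + 1] - traj$x[i])
    ne_a <- traj$rho[i] + (a - traj$x[i]) * alpha
    if (alpha == 0) {
      kk2 * (b - a) / ne_a
    } else {
      ## log1p keeps the alpha -> 0 limit exact (no cancellation)
      kk2 / alpha * log1p(alpha * (b - a) / ne_a)
    }
  }
}

## Vectorized hazard over segments (a, b) with lineage counts k, each segment
## guaranteed to lie within one trajectory interval (the caller splits at
## change-points).  Core of the log density and of the simulator oracle.
segment_hazards <- function(a, b, k, traj) {
  kk2 <- ifelse(k < 2, 0, k * (k - 1) / 2)
  i <- findInterval(a, traj$x)
  L <- length(traj$x)
  if (traj$mode == "constant" || L == 1) {
    kk2 * (b - a) / traj$rho[i]
  } else {
    alpha_all <- interval_slope_all(traj)
    il <- pmin(i, L - 1)
    alpha <- ifelse(i >= L, 0, alpha_all[il])
    ne_a <- ifelse(i >= L, traj$rho[L],
                   traj$rho[il] + (a - traj$x[il]) * alpha)
    ifelse(alpha == 0, kk2 * (b - a) / ne_a,
           kk2 / ifelse(alpha == 0, 1, alpha) *
             log1p(alpha * (b - a) / ne_a))
  }
}

#' Log probability density of a genealogy under the coalescent
#'
#' The heterochronous coalescent log density of the genealogy's coalescent
#' times given a piecewise demographic trajectory.  All sampling events,
#' coalescent events and trajectory change-points are merged into one
#' ordered timeline; each inter-event segment contributes minus its
#' integrated coalescent rate (the log probability of no coalescence), and
#' each coalescent event contributes the log point-mass factor
#' `log[2 / (k(k-1)) * c(u)] = -log Ne(u)`.  A coalescent event lying
#' exactly on a change-point uses the older interval's population size
#' (left-closed convention).
#'
#' @param g a [genealogy].
#' @param traj a [trajectory].  Under the `events` scheme the trajectory's
#'   change-points are re-derived from the genealogy's coalescent times.
#' @param scheme a [changepoint_scheme]; `NULL` (default) uses the
#'   trajectory's change-points as specified.
#' @return the log density (finite for all valid inputs).
#' @export
#' @examples
#' g <- read_genealogy("(A:1.5,B:1.5);", c(A = 0, B = 0))
#' coalescent_log_density(g, trajectory(0, 1))  # dexp(1.5, log = TRUE) = -1.5
coalescent_log_density <- function(g, traj, scheme = NULL) {
  stopifnot(inherits(g, "genealogy"), inherits(traj, "demographic_trajectory"))
  if (!is.null(scheme) && scheme$method == "events") {
    x <- changepoints_from_events(g, scheme$events_per_interval)
    if (length(x) != length(traj$rho))
      stop("events scheme implies ", length(x), " intervals but trajectory has ",
           length(traj$rho))
    traj <- trajectory(x, traj$rho, mode = traj$mode)
  }
  tl <- build_timeline(g, traj$x[traj$x > 0])
  k_at_coal <- tl$k_after[tl$type == "coalescent"]
  if (any(k_at_coal < 1))
    stop("malformed timeline: fewer than two lineages at a coalescent event")

  a <- tl$time[-nrow(tl)]
  b <- tl$time[-1]
  k <- tl$k_after[-nrow(tl)]
  ld <- -sum(segment_hazards(a, b, k, traj)) -
    sum(log(ne_at(traj, g$coal_times)))
  if (!is.finite(ld)) stop("non-finite coalescent log density")
  ld
}

#' Multi-locus coalescent log density under a shared trajectory
#'
#' Gene trees from different loci are independent realizations of the
#' coalescent given the demographic history, so the joint log density is the
#' sum of per-locus log densities.  Only change-points specified
#' independently of coalescent events are allowed: event-based change-points
#' are locus-specific and would imply a different demographic history per
#' locus.
#'
#' @param gs a list of [genealogy] objects.
#' @param traj a [trajectory].
#' @param scheme optional [changepoint_scheme]; must not be `events`.
#' @return the summed log density.
#' @export
multilocus_log_density <- function(gs, traj, scheme = NULL) {
  if (!is.null(scheme) && scheme$method == "events")
    stop("event-based change-points are locus-specific; use method = \"specified\"")
  if (!length(gs)) stop("empty genealogy list")
  sum(vapply(gs, coalescent_log_density, numeric(1), traj = traj))
}

#' Sequential (importance-averaged) log likelihood over genealogy samples
#'
#' When genealogies sampled from the posterior of a first analysis are used
#' as data, the likelihood of a new demographic model is the average of the
#' per-sample density ratios against the coalescent prior density each
#' sample had in the original analysis:
#' `log mean_j exp(log p(g_j | traj) - ref_j)`, computed stably with a
#' max-shift.
#'
#' @param gs list of [genealogy] samples.
#' @param ref_log_density numeric, one reference log density per sample.
#' @param traj a [trajectory].
#' @return the log pseudo-likelihood.
#' @export
sequential_log_likelihood <- function(gs, ref_log_density, traj) {
  if (!length(gs)) stop("empty genealogy sample set")
  if (length(gs) != length(ref_log_density))
    stop("need one reference log density per genealogy sample")
  ld <- vapply(gs, coalescent_log_density, numeric(1), traj = traj)
  log_mean_exp(ld - ref_log_density)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}
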