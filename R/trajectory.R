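#' Piecewise demographic trajectories
#'
#' A demographic trajectory describes the effective population size
#' `Ne(t)` backward in time as a piecewise function over `L` intervals
#' delimited by change-points `x[1] = 0 < x[2] < ... < x[L]`.  In
#' `constant` mode `Ne(t) = rho[i]` on `[x[i], x[i+1])`; in `linear` mode
#' `Ne` interpolates linearly between `rho[i]` at `x[i]` and `rho[i+1]` at
#' `x[i+1]`.  Beyond the last change-point (`t >= x[L]`) both modes are
#' constant at `rho[L]`.  Intervals are left-closed/right-open so that
#' `Ne(0) = rho[1]` is always defined.
#'
#' @param x change-point times, strictly increasing, `x[1] = 0`.
#' @param rho positive population sizes, one per interval (`length(x)`).
#' @param mode `"constant"` or `"linear"`.
#' @return an object of class `demographic_trajectory`.
#' @export
#' @examples
#' tr <- trajectory(c(0, 100), c(100, 200), mode = "linear")
#' ne_at(tr, c(0, 50, 100, 250))  # 100 150 200 200
trajectory <- function(x, rho, mode = c("constant", "linear")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); rho <- as.numeric(rho)
  if (length(x) != length(rho))
    stop("x and rho must have one entry per interval")
  if (length(x) < 1) stop("need at least one interval")
  if (x[1] != 0) stop("the first change-point must be 0 (the present)")
  if (length(x) > 1 && any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (any(!is.finite(rho)) || any(rho <= 0)) stop("all rho must be finite and > 0")
  structure(list(x = x, rho = rho, mode = mode),
            class = "demographic_trajectory")
}

#' @export
print.demographic_trajectory <- function(x, ...) {
  cat(sprintf("demographic trajectory: %d interval(s), %s mode\n",
              length(x$x), x$mode))
  print(data.frame(change_point_time = x$x, pop_size = x$rho))
  invisible(x)
}

#' Evaluate the population size of a trajectory
#'
#' @param traj a [trajectory].
#' @param t times before present (vectorized, `>= 0`).
#' @return `Ne(t)` for each `t`.
#' @export
ne_at <- function(traj, t) {
  stopifnot(inherits(traj, "demographic_trajectory"))
  if (any(t < 0)) stop("t must be >= 0")
  i <- findInterval(t, traj$x)           # left-closed: t == x[i] -> interval i
  L <- length(traj$x)
  if (traj$mode == "constant" || L == 1) {
    traj$rho[i]
  } else {
    a <- interval_slope_all(traj)        # length L-1
    ne <- ifelse(i >= L, traj$rho[L],
                 traj$rho[pmin(i, L - 1)] +
                   (t - traj$x[pmin(i, L - 1)]) * a[pmin(i, L - 1)])
    ne
  }
}

interval_slope_all <- function(traj) {
  L <- length(traj$x)
  if (L < 2) return(numeric())
  diff(traj$rho) / diff(traj$x)
}

#' Slope of a linear-mode trajectory on interval `i`
#'
#' `alpha[i] = (rho[i+1] - rho[i]) / (x[i+1] - x[i])`.
#'
#' @param traj a [trajectory] in linear mode.
#' @param i interval index, `1 <= i < L`.
#' @return the slope.
#' @export
interval_slope <- function(traj, i) {
  stopifnot(inherits(traj, "demographic_trajectory"))
  if (traj$mode != "linear") stop("slopes are defined for linear mode only")
  L <- length(traj$x)
  if (any(i < 1 | i >= L)) stop("need 1 <= i < L")
  w <- traj$x[i + 1] - traj$x[i]
  if (any(w == 0)) stop("zero-length interval")
  (traj$rho[i + 1] - traj$rho[i]) / w
}

#' Change-points tied to coalescent events
#'
#' For coalescent-event-based skyline models the interval change-points
#' co-occur with coalescent times: the `n - 1` coalescent events are grouped
#' (most recent first) and change-point `i` is placed at the coalescent time
#' ending group `i`; the first interval starts at 0 and the last group's end
#' (the root) is covered by the constant tail of the trajectory.
#'
#' @param g a [genealogy].
#' @param events_per_interval integer counts per interval, each `>= 1`,
#'   summing to `n - 1`.
#' @return change-point times: `c(0, ...)`, one entry per interval.
#' @export
changepoints_from_events <- function(g, events_per_interval) {
  stopifnot(inherits(g, "genealogy"))
  epi <- as.integer(events_per_interval)
  if (any(epi < 1)) stop("events_per_interval must all be >= 1")
  n1 <- length(g$coal_times)
  if (sum(epi) != n1)
    stop(sprintf("events_per_interval must sum to n - 1 = %d", n1))
  ends <- cumsum(epi)
  c(0, g$coal_times[ends[-length(ends)]])
}

#' Grouping of coalescent events with a fixed group size
#'
#' `n - 1` events are split into `ceiling((n - 1)/g)` groups of `g` with the
#' final group absorbing the remainder (the layout used by the Bayesian
#' skyline plot with an expected five coalescent events per interval).
#'
#' @param n_events number of coalescent events (`n - 1`).
#' @param group_size events per group (default 5).
#' @return integer vector of group sizes summing to `n_events`.
#' @export
group_events <- function(n_events, group_size = 5) {
  n_events <- as.integer(n_events)
  group_size <- as.integer(group_size)
  if (n_events < 1 || group_size < 1) stop("need n_events >= 1 and group_size >= 1")
  k <- max(1L, n_events %/% group_size)
  epi <- rep(group_size, k)
  epi[k] <- n_events - group_size * (k - 1L)
  stopifnot(sum(epi) == n_events, all(epi >= 1))
  epi
}

#' Equally sized interval change-points
#'
#' @param t_max end of the modeled period (> 0).
#' @param L number of intervals (`>= 1`).
#' @return `L` change-point times `0, t_max/L, ..., t_max (L-1)/L`.
#' @export
equal_grid <- function(t_max, L) {
  if (t_max <= 0) stop("t_max must be > 0")
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  t_max * (seq_len(L) - 1) / L
}

#' Change-point scheme of a skyline model
#'
#' Two schemes are supported: `events`, where change-points co-occur with
#' coalescent events (grouped via `events_per_interval`), and `specified`,
#' where change-point `times` are fixed independently of the genealogy.
#'
#' @param method `"events"` or `"specified"`.
#' @param events_per_interval integer counts (events method).
#' @param times change-point times (specified method), sorted, `>= 0`.
#' @return an object of class `changepoint_scheme`.
#' @export
changepoint_scheme <- function(method = c("events", "specified"),
                               events_per_interval = NULL, times = NULL) {
  method <- match.arg(method)
  if (method == "events") {
    if (is.null(events_per_interval))
      stop("events method requires events_per_interval")
    if (any(events_per_interval < 1))
      stop("events_per_interval must all be >= 1")
  } else {
    if (is.null(times)) stop("specified method requires times")
    if (is.unsorted(times)) stop("times must be sorted")
    if (any(times < 0)) stop("times must be >= 0")
  }
  structure(list(method = method,
                 events_per_interval = events_per_interval,
                 times = times),
            class = "changepoint_scheme")
}

#' Read / write a trajectory as a two-column tab-separated table
#'
#' Columns: `change_point_time`, `pop_size`.
#'
#' @param path file path.
#' @param mode interpolation mode for the trajectory read back.
#' @return [read_trajectory()] returns a [trajectory];
#'   [write_trajectory()] returns `path` invisibly.
#' @export
read_trajectory <- function(path, mode = "constant") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  trajectory(tab$change_point_time, tab$pop_size, mode = mode)
}

#' @rdname read_trajectory
#' @param traj a [trajectory].
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(
    data.frame(change_point_time = traj$x, pop_size = traj$rho),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
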