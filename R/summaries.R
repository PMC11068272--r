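#' Exponentially spaced time grid
#'
#' Grid points `g_i = exp(log(1 + t_max) * i/(n_points - 1)) - 1`,
#' `i = 0 ... n_points - 1`: equally spaced in `log(1 + t)` (plain
#' log-spacing is undefined at 0), including both 0 and `t_max`.
#'
#' @param t_max end of the grid (> 0).
#' @param n_points number of grid points (`>= 2`, default 500).
#' @return strictly increasing times from 0 to `t_max`.
#' @export
exponential_grid <- function(t_max, n_points = 500) {
  if (t_max <= 0) stop("t_max must be > 0")
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("n_points must be >= 2")
  expm1(log1p(t_max) * (seq_len(n_points) - 1) / (n_points - 1))
}

## comma-joined numeric columns come back as plain numerics for
## single-interval models read from disk
str_num <- function(s) {
  if (is.numeric(s)) return(as.numeric(s))
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
}

## samples x grid matrix of Ne evaluated per trace row
trace_ne_matrix <- function(trace, grid, mode = NULL) {
  if (nrow(trace) == 0) stop("empty trace")
  if (is.null(mode)) mode <- attr(trace, "mode")
  if (is.null(mode)) mode <- "constant"
  xs <- lapply(trace$times, str_num)
  rs <- lapply(trace$rho, str_num)
  out <- matrix(NA_real_, nrow = nrow(trace), ncol = length(grid))
  if (mode == "constant") {
    for (i in seq_len(nrow(trace)))
      out[i, ] <- rs[[i]][findInterval(grid, xs[[i]])]
  } else {
    for (i in seq_len(nrow(trace)))
      out[i, ] <- ne_at(trajectory(xs[[i]], rs[[i]], mode = "linear"), grid)
  }
  out
}

#' Summarize a trace as a population-size envelope on a time grid
#'
#' For each grid time, every retained sample's trajectory is evaluated via
#' [ne_at()] and the median and central 95% credible interval of `Ne`
#' are computed (type-7 quantiles, i.e. linear interpolation of order
#' statistics).  Quantiles are taken of the population size itself,
#' sample-wise, which is how skyline envelopes are drawn.
#'
#' @param trace a trace from [run_mcmc()] or [read_trace()].
#' @param grid time grid, e.g. [exponential_grid()].
#' @param mode interpolation mode override (defaults to the trace's).
#' @return a data frame with columns `time`, `ne_median`,
#'   `ne_lower_2.5`, `ne_upper_97.5`.
#' @export
summarize_trace <- function(trace, grid, mode = NULL) {
  m <- trace_ne_matrix(trace, grid, mode)
  q <- apply(m, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE, type = 7)
  data.frame(time = grid, ne_median = q[2, ],
             ne_lower_2.5 = q[1, ], ne_upper_97.5 = q[3, ],
             check.names = FALSE)
}

#' Write a trajectory summary as a tab-separated file
#'
#' @param summary data frame from [summarize_trace()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
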