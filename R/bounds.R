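#' Closed-form convergence-time lower bounds
#'
#' Order-of-magnitude expressions (evaluated with constant 1) for the
#' minimum number of rounds any rumor-spreading protocol needs in a
#' well-mixed population of n agents with s sources under delta-uniform
#' noise over an alphabet of size k:
#'
#' * `pull_round_bound()`: `n * delta / (s^2 * (1 - delta * k)^2)` rounds
#'   of the parallel-PULL model.
#' * `detectable_pull_round_bound()`: the cube root of the same
#'   expression — the weaker bound that survives when sources can be
#'   identified reliably on sight.
#'
#' Both return `Inf` at `delta * k = 1`, where observations carry no
#' information at all. These are guides for scaling comparisons, not sharp
#' constants; simulations are compared against them only one-sidedly.
#'
#' @param n population size.
#' @param s number of sources (1 <= s < n).
#' @param delta noise-uniformity level, 0 < delta <= 1/k.
#' @param k alphabet size (>= 2).
#' @return rounds (numeric; possibly `Inf`).
#' @examples
#' pull_round_bound(1000, 1, 0.2, 2)  # ~555.6
#' @export
pull_round_bound <- function(n, s, delta, k) {
  check_bound_inputs(n, s, delta, k)
  denom <- (1 - delta * k)^2
  if (denom == 0) return(Inf)
  n * delta / (s^2 * denom)
}

#' @rdname pull_round_bound
#' @export
detectable_pull_round_bound <- function(n, s, delta, k) {
  pull_round_bound(n, s, delta, k)^(1 / 3)
}

check_bound_inputs <- function(n, s, delta, k) {
  stopifnot(k >= 2, s >= 1, s < n, delta > 0)
  if (delta > 1 / k + 1e-12) stop("delta must not exceed 1/k")
  invisible(NULL)
}

#' Theoretical per-observation process gap
#'
#' The l1 distance between the two hypotheses' next-observation
#' distributions is driven by the chance that the observed agent is a
#' source (s/n) times the fraction of its signal that noise does not
#' flatten (1 - delta k): `eps = s (1 - delta k) / n` (constant 1; the
#' static-display broadcast mixtures realise exactly `2 * eps` as their l1
#' gap).
#'
#' @inheritParams pull_round_bound
#' @return the gap scale (unitless).
#' @export
process_gap_theory <- function(n, s, delta, k) {
  check_bound_inputs(n, s, delta, k)
  s * (1 - delta * k) / n
}

#' Observations needed to distinguish at fixed error
#'
#' The sample-complexity scale `delta / eps^2`: with per-step gap eps and
#' attainability floor delta, of the order of this many observations are
#' required before the error of any distinguishing rule can drop below a
#' constant (e.g. 1/3).
#'
#' @param delta attainability floor (> 0).
#' @param eps per-observation l1 gap.
#' @return observation count scale (`Inf` when `eps` = 0).
#' @export
sample_complexity <- function(delta, eps) {
  stopifnot(delta > 0, eps >= 0)
  if (eps == 0) return(Inf)
  delta / eps^2
}

#' Convergence-time scaling experiment
#'
#' Measures how a convergence/certainty time grows with population size:
#' runs `time_fun(n)` `reps` times for every n in `n_grid`, tabulates
#' means and standard errors, and fits the log-log slope of mean time
#' versus n by ordinary least squares. Runs that return `NA` (never
#' converged within their step budget) are censored: they are excluded
#' from the means with a warning, and the slope is not fitted if any grid
#' point is fully censored.
#'
#' @param n_grid increasing vector of population sizes.
#' @param reps simulation repetitions per grid point (>= 30).
#' @param time_fun `function(n)` returning one measured time (steps or
#'   rounds), or `NA` if censored.
#' @param seed optional seed set once before all runs.
#' @return object of class `scaling_experiment`: list with `table` (a
#'   data.frame: n, mean_time, sem, reps, censored) and `slope` (log-log
#'   OLS slope, or `NA`).
#' @export
scaling_experiment <- function(n_grid, reps, time_fun, seed = NULL) {
  stopifnot(reps >= 30, length(n_grid) >= 2)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(n_grid, function(n) {
    times <- vapply(seq_len(reps), function(i) as.numeric(time_fun(n)),
                    numeric(1))
    cens <- sum(is.na(times))
    times <- times[!is.na(times)]
    data.frame(n = n,
               mean_time = if (length(times)) mean(times) else NA_real_,
               sem = if (length(times) > 1) stats::sd(times) / sqrt(length(times)) else NA_real_,
               reps = reps, censored = cens)
  })
  tab <- do.call(rbind, rows)
  if (any(tab$censored > 0)) {
    warning(sum(tab$censored), " runs were censored (never converged)")
  }
  slope <- NA_real_
  if (!anyNA(tab$mean_time) && all(tab$mean_time > 0)) {
    slope <- unname(stats::coef(stats::lm(log(mean_time) ~ log(n),
                                          data = tab))[2L])
  }
  structure(list(table = tab, slope = slope), class = "scaling_experiment")
}

#' @export
print.scaling_experiment <- function(x, ...) {
  cat("scaling experiment; log-log slope =", format(x$slope, digits = 4), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
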