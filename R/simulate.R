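# Simulation settings and the power/size experiment runner.
#
# Seven study conditions, two nonparallel-pattern families on the base curve
# 2.5 sin(3 pi x)(1 - x):
#   1  constant magnitude difference        (delta1)
#   2  frequency difference                 (delta2)
#   3  magnitude and frequency difference   (delta1, delta2)
#   4  non-constant magnitude difference    (delta3, exponent on (1 - x))
#   5  parallel shift only (null model)     (delta4)
#   6  magnitude difference, evenly spaced positions, AR(1) noise
#                                           (delta1, rho)
#   7  non-smooth piecewise truth with a change point at x = 0.5 (delta5)
# Settings 1-5 draw positions iid U(0, 1), independently for each subject;
# settings 6-7 use a shared evenly spaced grid.

#' Define a simulation setting
#'
#' @param setting Integer setting id, 1-7.
#' @param n Positions per subject (>= 10).
#' @param s Number of subjects (even; default 2, one curve per group).
#' @param delta1,delta2,delta3,delta4,delta5 Nonparallelism / shift
#'   parameters; all default 0 (every setting is then null).
#' @param rho AR(1) parameter of the setting-6 noise, in (-1, 1).
#' @param sigma Noise standard deviation.
#' @param design `"quasi_uniform"` (positions iid U(0,1)) or `"uniform"`
#'   (evenly spaced).  Defaults to the setting's own convention.
#' @param shared_positions Should all subjects share one set of positions?
#'   Defaults to `FALSE` for the U(0,1) designs and `TRUE` for evenly
#'   spaced ones.
#' @param seed Base seed for [simulate_setting()] and [empirical_power()].
#' @return An object of class `"sim_setting"`.
#' @examples
#' st <- sim_setting(1, n = 100, delta1 = 1)
#' d <- simulate_setting(st)
#' @export
sim_setting <- function(setting, n, s = 2, delta1 = 0, delta2 = 0, delta3 = 0,
                        delta4 = 0, delta5 = 0, rho = 0.5, sigma = 1,
                        design = NULL, shared_positions = NULL, seed = 1) {
  if (!setting %in% 1:7) stop("'setting' must be 1..7", call. = FALSE)
  if (n < 10) stop("'n' must be at least 10", call. = FALSE)
  if (s < 2 || s %% 2 != 0) stop("'s' must be an even number >= 2", call. = FALSE)
  if (abs(rho) >= 1) stop("'rho' must lie in (-1, 1)", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (is.null(design)) design <- if (setting <= 5) "quasi_uniform" else "uniform"
  design <- match.arg(design, c("quasi_uniform", "uniform"))
  if (is.null(shared_positions)) shared_positions <- design == "uniform"
  structure(list(setting = as.integer(setting), n = as.integer(n),
                 s = as.integer(s), delta1 = delta1, delta2 = delta2,
                 delta3 = delta3, delta4 = delta4, delta5 = delta5,
                 rho = rho, sigma = sigma, design = design,
                 shared_positions = shared_positions, seed = as.integer(seed)),
            class = "sim_setting")
}

#' @export
print.sim_setting <- function(x, ...) {
  deltas <- unlist(x[paste0("delta", 1:5)])
  deltas <- deltas[deltas != 0]
  cat(sprintf("Simulation setting %d: n = %d, s = %d, %s design%s, sigma = %g%s\n",
              x$setting, x$n, x$s, x$design,
              if (x$shared_positions) " (shared positions)" else "",
              x$sigma,
              if (x$setting == 6) sprintf(", AR(1) rho = %g", x$rho) else ""))
  cat("  ", if (length(deltas)) paste(names(deltas), "=", deltas, collapse = ", ")
      else "all deltas 0 (null)", "\n")
  invisible(x)
}

#' True mean function of a simulation setting
#'
#' @param x Positions in \eqn{[0, 1]}.
#' @param group Group labels 0/1 (recycled against `x`).
#' @param setting A [sim_setting()].
#' @return Numeric vector \eqn{f(x, group)}.
#' @export
truth_function <- function(x, group, setting) {
  stopifnot(inherits(setting, "sim_setting"))
  len <- max(length(x), length(group))
  x <- rep_len(x, len)
  g <- rep_len(as.integer(group), len)
  base <- 2.5 * sin(3 * pi * x) * (1 - x)
  id <- setting$setting
  if (id %in% 1:4)       # one family; the deltas pick the pattern
    ifelse(g == 0, base,
           (2.5 + setting$delta1) * sin((3 + setting$delta2) * pi * x) *
             (1 - x)^(1 + setting$delta3))
  else if (id == 5) base + setting$delta4 * (g == 1)
  else if (id == 6) (2.5 + setting$delta1 * (g == 1)) * sin(3 * pi * x) * (1 - x)
  else 2.5 * sin(2 * pi * x) * (x > 0 & x < 0.5) +
    (1 + setting$delta5 * (g == 1)) * (x - 1) * (x >= 0.5 & x < 1)
}

#' Draw one data set from a simulation setting
#'
#' Positions are iid U(0, 1) (independently per subject, unless
#' `shared_positions`) or an evenly spaced grid \eqn{(i - 1/2)/n}; noise is
#' iid \eqn{N(0, \sigma^2)} except in setting 6, where each subject's noise
#' vector is a stationary AR(1) Gaussian series with marginal variance
#' \eqn{\sigma^2} and autocorrelation \eqn{\rho^{|i - i'|}} along the
#' position index.
#'
#' @param setting A [sim_setting()].
#' @param seed Seed (default: the setting's base seed).  The caller's RNG
#'   state is untouched.
#' @return A [design_points()] object.
#' @export
simulate_setting <- function(setting, seed = setting$seed) {
  stopifnot(inherits(setting, "sim_setting"))
  n <- setting$n; s <- setting$s
  .with_seed(seed, {
    position <- if (setting$design == "uniform") rep((seq_len(n) - 0.5) / n, s)
      else if (setting$shared_positions) rep(stats::runif(n), s)
      else stats::runif(n * s)
    subject <- rep(seq_len(s), each = n)
    group <- as.integer(subject > s / 2)
    eps <- if (setting$setting == 6) {
      unlist(lapply(seq_len(s), function(j) {
        z <- stats::rnorm(n)
        e <- numeric(n); e[1] <- z[1]
        for (i in seq_len(n)[-1])
          e[i] <- setting$rho * e[i - 1] + sqrt(1 - setting$rho^2) * z[i]
        e
      }))
    } else stats::rnorm(n * s)
    value <- truth_function(position, group, setting) + setting$sigma * eps
    design_points(position, group, value, subject = subject)
  })
}

#' Empirical power (or size) of a test under a simulation setting
#'
#' Repeatedly draws data from the setting with replicate seeds
#' `seed + 1, ..., seed + reps`, applies the requested test at level
#' `alpha`, and returns the rejection fraction together with its
#' Monte-Carlo standard error.  When every delta is zero this estimates the
#' empirical size.
#'
#' @param setting A [sim_setting()].
#' @param reps Number of Monte-Carlo replicates (>= 50).
#' @param alpha Nominal level.
#' @param method `"wald"` (default) or `"permutation"`.
#' @param B Permutations per replicate when `method = "permutation"`.
#' @param seed Base seed (default: the setting's).
#' @param ... Further arguments passed to [parallelism_test()] or
#'   [permutation_test()].
#' @return An object of class `"power_estimate"`: list with `power`, `se`,
#'   `reps`, `alpha`, `method`, `rejections`.
#' @examples
#' \donttest{
#' st <- sim_setting(1, n = 100, delta1 = 1, seed = 11)
#' empirical_power(st, reps = 50)
#' }
#' @export
empirical_power <- function(setting, reps = 200, alpha = 0.05,
                            method = c("wald", "permutation"), B = 500,
                            seed = setting$seed, ...) {
  stopifnot(inherits(setting, "sim_setting"))
  method <- match.arg(method)
  if (reps < 50) stop("'reps' must be at least 50", call. = FALSE)
  rej <- vapply(seq_len(reps), function(r) {
    d <- simulate_setting(setting, seed = seed + r)
    res <- tryCatch(
      if (method == "wald") parallelism_test(d, alpha = alpha, ...)
      else permutation_test(d, B = B, seed = seed + r, alpha = alpha, ...),
      error = function(e) stop("replicate ", r, " (seed ", seed + r,
                               ") failed: ", conditionMessage(e),
                               call. = FALSE))
    res$reject
  }, logical(1))
  p <- mean(rej)
  structure(list(power = p, se = sqrt(p * (1 - p) / reps), reps = reps,
                 alpha = alpha, method = method, setting = setting,
                 rejections = rej),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Empirical rejection rate: %.3f (MC se %.3f; %d replicates, %s test, alpha = %g)\n",
              x$power, x$se, x$reps, x$method, x$alpha))
  invisible(x)
}

#' Power/size table over delta configurations and sample sizes
#'
#' Runs [empirical_power()] on a grid of delta configurations (rows) and
#' per-group sample sizes (columns), mirroring the layout of the package's
#' simulation study tables.
#'
#' @param setting_id Setting id 1-7.
#' @param deltas Named list; each element is a named list/vector of delta
#'   (and optionally `rho`) values defining one row.
#' @param n_values Integer vector of per-group sample sizes.
#' @param reps,alpha,method,seed,... Passed to [empirical_power()].
#' @return Data frame with one row per delta configuration and one column
#'   per sample size.
#' @export
power_table <- function(setting_id, deltas, n_values, reps = 200,
                        alpha = 0.05, method = "wald", seed = 1, ...) {
  rows <- lapply(seq_along(deltas), function(i) {
    cfg <- as.list(deltas[[i]])
    vals <- vapply(n_values, function(n) {
      st <- do.call(sim_setting,
                    c(list(setting = setting_id, n = n, seed = seed), cfg))
      empirical_power(st, reps = reps, alpha = alpha, method = method, ...)$power
    }, numeric(1))
    stats::setNames(as.data.frame(t(vals)), paste0("n", n_values))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(deltas) %||%
    paste0("config", seq_along(deltas))
  cbind(configuration = rownames(out), out, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
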