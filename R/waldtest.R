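# The Wald-type parallelism test: statistic, exact-trace null moments,
# decision rule, data-adaptive smoothing parameter, and multiplicity control.

#' Wald-type test statistic
#'
#' The squared empirical norm of the estimated interaction component,
#' \eqn{T_{n,\lambda} = \|\hat f_{11}\|_2^2 / (ns)}.
#'
#' @param f11_hat Interaction component evaluated at the `ns` data points.
#' @return Nonnegative scalar.
#' @export
test_statistic <- function(f11_hat) {
  sum(f11_hat^2) / length(f11_hat)
}

#' Null moments of the test statistic
#'
#' Mean and standard deviation of the asymptotic Gaussian null distribution:
#' \eqn{\mu_{n,\lambda} = \sigma^2 tr(\Delta)/(ns)} and
#' \eqn{\sigma^2_{n,\lambda} = 2 \sigma^4 tr(\Delta^2)/(ns)^2} with
#' \eqn{\Delta = M^{-1} K_{11}^2 M^{-1}}.  The traces are computed from a
#' Cholesky factorization of `M`; no explicit inverse is formed.  Because the
#' moments depend only on the design, \eqn{\lambda} and \eqn{\sigma^2} —
#' never on the nuisance components of the mean — the resulting test enjoys
#' the Wilks phenomenon.
#'
#' @param grams A [assemble_grams()] result.
#' @param sigma2 Noise variance (estimated or known).
#' @return An object of class `"null_moments"`: list with `mu`, `sigma`,
#'   `trace_delta`, `trace_delta2`, `lambda`, `sigma2`.
#' @export
null_moments <- function(grams, sigma2) {
  stopifnot(inherits(grams, "gram_set"))
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be positive", call. = FALSE)
  R <- tryCatch(chol(grams$M), error = function(e)
    stop("conditioning error: Cholesky of M failed: ", conditionMessage(e),
         call. = FALSE))
  X <- backsolve(R, forwardsolve(t(R), grams$K11))   # M^-1 K11
  trD <- sum(X^2)               # ||M^-1 K11||_F^2 = tr(Delta)
  trD2 <- sum((crossprod(X))^2) # ||X^T X||_F^2 = tr(Delta^2)
  ns <- grams$ns
  structure(list(mu = sigma2 * trD / ns,
                 sigma = sqrt(2 * trD2) * sigma2 / ns,
                 trace_delta = trD, trace_delta2 = trD2,
                 lambda = grams$lambda, sigma2 = sigma2),
            class = "null_moments")
}

#' @export
print.null_moments <- function(x, ...) {
  cat(sprintf("Null moments: mu = %.4g, sigma = %.4g (tr(Delta) = %.4g, tr(Delta^2) = %.4g, lambda = %.3g)\n",
              x$mu, x$sigma, x$trace_delta, x$trace_delta2, x$lambda))
  invisible(x)
}

#' Testing decision from statistic and null moments
#'
#' Standardizes the statistic, \eqn{z = (T - \mu_{n,\lambda}) /
#' \sigma_{n,\lambda}}, and applies the two-sided Gaussian rule
#' \eqn{|z| \ge z_{\alpha/2}} (the rule as stated; a one-sided variant for
#' the nonnegative statistic is available via `alternative = "greater"`).
#'
#' @param statistic Observed test statistic.
#' @param moments A [null_moments()] object.
#' @param alpha Nominal level in (0, 1).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return List with `z`, `p_value`, `reject`.
#' @export
decide <- function(statistic, moments, alpha = 0.05,
                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  z <- (statistic - moments$mu) / moments$sigma
  p <- if (alternative == "two.sided") 2 * stats::pnorm(-abs(z))
       else stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p_value = p, reject = p <= alpha)
}

#' Grid of candidate smoothing parameters
#'
#' @param n_points Number of grid points.
#' @param range Two-element range; log-spaced points are placed on it.
#' @return Increasing numeric vector.
#' @export
lambda_grid <- function(n_points = 50, range = c(1e-8, 1)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = n_points)
}

#' Data-adaptive smoothing parameter for testing
#'
#' Chooses the smoothing parameter by the testing-optimality rule
#' \eqn{\lambda^* \approx \sigma_{n,\lambda}}: since
#' \eqn{\sigma_{n,\lambda}} is nonincreasing in \eqn{\lambda}, the rule
#' returns the largest grid value still satisfying
#' \eqn{\lambda < \sigma_{n,\lambda}}, i.e. the grid point at the crossing
#' of the penalty scale and the null standard deviation.  This balances the
#' squared bias of the interaction estimate against the standard deviation
#' of the statistic (rather than its variance, which is the estimation-
#' optimal tradeoff).
#'
#' @param points A [design_points()] object.
#' @param config A [kernel_config()].
#' @param sigma2 Noise variance; `NULL` estimates it at the pilot
#'   \eqn{\lambda = n^{-4m/(4m+1)}}.
#' @param grid Candidate values, sorted increasing ([lambda_grid()]).
#' @return Selected \eqn{\lambda^*}, with attribute `table` (a data frame
#'   with the grid, \eqn{\sigma_{n,\lambda}} and the qualifying indicator).
#' @export
select_lambda <- function(points, config = kernel_config(), sigma2 = NULL,
                          grid = lambda_grid()) {
  points <- as.design_points(points)
  if (is.unsorted(grid) || any(grid <= 0))
    stop("'grid' must be positive and sorted increasing", call. = FALSE)
  eng <- .pt_engine(points, config$m)
  if (is.null(sigma2))
    sigma2 <- .eng_fit(eng, points$value, .pilot_lambda(eng))$sigma2
  sig <- .eng_sigma_nl(eng, grid, sigma2)
  ok <- grid < sig
  if (!any(ok))
    stop("no qualifying lambda on the grid (lambda >= sigma_{n,lambda} ",
         "everywhere); expand the grid toward smaller values", call. = FALSE)
  if (all(ok))
    stop("all grid points satisfy lambda < sigma_{n,lambda}; expand the ",
         "grid toward larger values to bracket the crossing", call. = FALSE)
  out <- max(grid[ok])
  attr(out, "table") <- data.frame(lambda = grid, sigma_nl = sig,
                                   qualifies = ok)
  out
}

#' Effective dimension of the kernel at a smoothing parameter
#'
#' \eqn{\hat\tau_\lambda = \max\{i : \hat\mu_i \ge \lambda\}}, the number of
#' empirical kernel eigenvalues at least \eqn{\lambda}.  This measures how
#' many directions the statistic effectively aggregates and drives its null
#' variance (\eqn{\tau_\lambda \asymp \lambda^{-1/(2m)}} for the
#' Bernoulli-polynomial kernels).
#'
#' @param eigenvalues Nonnegative eigenvalues sorted decreasing (see
#'   [k1_spectrum()]).
#' @param lambda Threshold.
#' @return Integer count (0 if none qualify).
#' @export
effective_dimension <- function(eigenvalues, lambda) {
  if (any(diff(eigenvalues) > 0))
    stop("'eigenvalues' must be sorted decreasing", call. = FALSE)
  sum(eigenvalues >= lambda)
}

#' Empirical spectrum of the continuous-margin kernel
#'
#' Eigenvalues (sorted decreasing) of the n-by-n matrix with entries
#' \eqn{K_1(x_i, x_j)/n}, the scaled Gram of the penalized continuous-margin
#' kernel; the input to [effective_dimension()].
#'
#' @param positions Numeric vector in \eqn{[0, 1]}.
#' @param m Spline order.
#' @return Numeric vector of eigenvalues.
#' @export
k1_spectrum <- function(positions, m = 2) {
  n <- length(positions)
  G <- outer(positions, positions, k1_continuous, m = m) / n
  sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Nonparametric parallelism test
#'
#' Tests whether the case and control curves are parallel, i.e. whether the
#' interaction component of the smoothing spline ANOVA decomposition
#' \eqn{f = f_{00} + f_{10}(x) + f_{01}(g) + f_{11}(x, g)} vanishes.  The
#' full pipeline: trace-equalize the kernel scales, estimate the noise
#' variance at a pilot smoothing parameter, select \eqn{\lambda^*} by the
#' testing-optimal rule (unless `lambda` is supplied), re-estimate the
#' variance at \eqn{\lambda^*}, evaluate the closed-form interaction
#' estimate, and compare \eqn{T_{n,\lambda} = \|\hat f_{11}\|^2/(ns)} with
#' its exact-trace Gaussian null moments.  Deterministic given the input.
#'
#' @param points A [design_points()] object (or data frame coercible to one).
#' @param alpha Nominal level.
#' @param m Spline order of the continuous margin (default 2, cubic
#'   analogue).
#' @param lambda Optional fixed smoothing parameter overriding the adaptive
#'   rule.
#' @param sigma2 Optional known noise variance; when supplied it is used
#'   as-is (no pilot estimation) — this also makes the null moments depend
#'   on nothing but the design and \eqn{\lambda}.
#' @param grid Candidate grid for the adaptive rule.
#' @param alternative Rejection region; see [decide()].
#' @return An object of class `"parallelism_test"`: list with `statistic`,
#'   `z`, `p_value`, `reject`, `alpha`, `lambda_star`, `sigma2_used`,
#'   `moments` ([null_moments()]-like), `edf`, `f11_hat`, `fitted`, `ns`,
#'   `m`.
#' @examples
#' set.seed(7)
#' x <- runif(200); g <- rep(0:1, each = 100)
#' y <- sin(2 * pi * x) + 0.8 * g * (x - 0.5) + rnorm(200, sd = 0.3)
#' parallelism_test(design_points(x, g, y))
#' @export
parallelism_test <- function(points, alpha = 0.05, m = 2, lambda = NULL,
                             sigma2 = NULL, grid = lambda_grid(),
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  points <- as.design_points(points)
  eng <- .pt_engine(points, m)
  y <- points$value

  s2 <- sigma2
  if (is.null(s2)) s2 <- .eng_fit(eng, y, .pilot_lambda(eng))$sigma2

  if (is.null(lambda)) {
    sig <- .eng_sigma_nl(eng, grid, s2)
    ok <- grid < sig
    if (!any(ok))
      stop("no qualifying lambda on the grid; expand it toward smaller values",
           call. = FALSE)
    if (all(ok))
      stop("all grid points qualify; expand the grid toward larger values",
           call. = FALSE)
    lambda <- max(grid[ok])
  }

  ft <- .eng_fit(eng, y, lambda)
  if (is.null(sigma2)) s2 <- ft$sigma2      # one refresh at lambda*
  tr <- .eng_traces(eng, lambda)
  mom <- structure(list(mu = s2 * tr[["trace_delta"]] / eng$ns,
                        sigma = sqrt(2 * tr[["trace_delta2"]]) * s2 / eng$ns,
                        trace_delta = tr[["trace_delta"]],
                        trace_delta2 = tr[["trace_delta2"]],
                        lambda = lambda, sigma2 = s2),
                   class = "null_moments")
  Tn <- test_statistic(ft$f11)
  dec <- decide(Tn, mom, alpha, alternative)
  structure(list(statistic = Tn, z = dec$z, p_value = dec$p_value,
                 reject = dec$reject, alpha = alpha, lambda_star = lambda,
                 sigma2_used = s2, moments = mom, edf = ft$edf,
                 f11_hat = ft$f11, fitted = ft$fitted, ns = eng$ns,
                 s = eng$s, m = m, alternative = alternative),
            class = "parallelism_test")
}

#' @export
print.parallelism_test <- function(x, ...) {
  cat("Nonparametric parallelism test (Wald-type, SSANOVA)\n")
  cat(sprintf("  ns = %d obs, %d subject(s); m = %d; lambda* = %.3g; sigma^2 = %.4f\n",
              x$ns, x$s, x$m, x$lambda_star, x$sigma2_used))
  cat(sprintf("  T = %.4g, null mean %.4g, null sd %.4g\n",
              x$statistic, x$moments$mu, x$moments$sigma))
  cat(sprintf("  z = %.3f, p = %.4g  ->  %s parallelism (H0: f11 = 0) at alpha = %g\n",
              x$z, x$p_value, if (x$reject) "REJECT" else "do not reject",
              x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across a family of parallelism
#' tests (e.g. one per genomic region); a validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Vector of adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}
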