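# Penalized least-squares fitting of the two-way SSANOVA model.
#
# Two equivalent computational routes are provided.  The dense route works
# from an assembled gram_set and mirrors the printed linear algebra
# (coefficient solve, closed-form interaction estimator, smoother-matrix
# variance estimate); it is the reference used by the oracle tests.  The
# fitting wrapper ssanova_fit() goes through the block eigen-engine, which
# gives identical numbers (see the test suite) at a fraction of the cost.

#' Penalized least-squares coefficient solve
#'
#' Returns the minimizer of
#' \deqn{\|y - ns K \alpha\|_2^2 + ns \lambda \alpha^T Q \alpha}
#' over \eqn{\alpha \in R^{ns}} via the symmetric linear system
#' \eqn{(ns K^2 + \lambda Q) \alpha = K y}.
#'
#' @param y Numeric response vector of length `ns`, in the observation order
#'   of the points the Gram set was assembled from.
#' @param grams A [assemble_grams()] result.
#' @return Coefficient vector \eqn{\hat\alpha} with attributes `fitted`
#'   (\eqn{ns K \hat\alpha}) and `residual_norm` (relative normal-equation
#'   residual).
#' @export
solve_alpha <- function(y, grams) {
  stopifnot(inherits(grams, "gram_set"))
  ns <- grams$ns
  if (length(y) != ns) stop("'y' must have length ns", call. = FALSE)
  K <- grams$K; Q <- grams$Q
  A <- ns * (K %*% K) + grams$lambda * Q
  diag(A) <- diag(A) + grams$jitter / ns
  b <- K %*% y
  alpha <- tryCatch(solve(A, b), error = function(e)
    stop("conditioning error in coefficient solve: ", conditionMessage(e),
         call. = FALSE))
  rel <- sqrt(sum((A %*% alpha - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
  if (rel > 1e-8)
    stop(sprintf("conditioning error: normal-equation residual %.2e > 1e-8", rel),
         call. = FALSE)
  alpha <- as.vector(alpha)
  attr(alpha, "fitted") <- as.vector(ns * K %*% alpha)
  attr(alpha, "residual_norm") <- rel
  alpha
}

# shared dense machinery: M^-1 y, M^-1 S, the S-annihilating projector action
.dense_proj <- function(y, grams) {
  R <- chol(grams$M)
  Minv <- function(v) backsolve(R, forwardsolve(t(R), v))
  W <- Minv(grams$S)
  StW <- crossprod(grams$S, W)
  if (rcond(StW) < 1e-12)
    stop("invalid design: S' M^-1 S is singular", call. = FALSE)
  dcoef <- solve(StW, crossprod(W, y))
  cc <- Minv(y) - W %*% dcoef
  list(c = as.vector(cc), d = as.vector(dcoef), W = W, StW = StW, Minv = Minv)
}

#' Closed-form interaction (nonparallel) component
#'
#' Evaluates the penalized least-squares estimate of the interaction
#' component at the `ns` data points via the closed form
#' \deqn{\hat f_{11} = K_{11} M^{-1} (I - S (S^T M^{-1} S)^{-1} S^T M^{-1}) y,}
#' the estimator the Wald statistic is built on.  The projector annihilates
#' the unpenalized subspace exactly, so purely parallel data give an exact
#' zero.  The evaluation uses the plain product kernel (`K11`), i.e. it is
#' not normalized by the scale parameter \eqn{\theta_{11}}.
#'
#' @inheritParams solve_alpha
#' @return Numeric vector \eqn{\hat f_{11}} of length `ns` with attribute
#'   `coef` (the representer coefficients \eqn{M^{-1} P y}).
#' @export
fit_f11 <- function(y, grams) {
  stopifnot(inherits(grams, "gram_set"))
  if (length(y) != grams$ns) stop("'y' must have length ns", call. = FALSE)
  pr <- .dense_proj(y, grams)
  f11 <- as.vector(grams$K11 %*% pr$c)
  attr(f11, "coef") <- pr$c
  f11
}

#' Noise-variance estimate
#'
#' Estimates \eqn{\sigma^2} from the smoothing residuals,
#' \eqn{\hat\sigma^2 = y^T (I - A(\lambda))^2 y / tr(I - A(\lambda))}.
#' With `method = "fit"` (default) the smoother is the penalized
#' least-squares fit used everywhere else in the package,
#' \eqn{A y = S\hat d + \Xi \hat c}; with `method = "alpha"` it is the
#' coefficient-path smoother \eqn{A(\lambda) = ns K (ns K^2 + \lambda Q)^{-1} K}.
#' Both are consistent; they differ by a lower-order term.
#'
#' @inheritParams solve_alpha
#' @param method Smoother used to form residuals, `"fit"` or `"alpha"`.
#' @return \eqn{\hat\sigma^2} with attribute `edf` (trace of the smoother).
#' @export
estimate_sigma2 <- function(y, grams, method = c("fit", "alpha")) {
  stopifnot(inherits(grams, "gram_set"))
  method <- match.arg(method)
  ns <- grams$ns
  if (length(y) != ns) stop("'y' must have length ns", call. = FALSE)
  if (method == "alpha") {
    alpha <- solve_alpha(y, grams)
    # A(lambda) is symmetric, so y'(I-A)^2 y = ||(I-A)y||^2
    K <- grams$K; Q <- grams$Q
    A <- ns * (K %*% K) + grams$lambda * Q
    diag(A) <- diag(A) + grams$jitter / ns
    Smat <- ns * K %*% solve(A, K)
    edf <- sum(diag(Smat))
    resid <- y - attr(alpha, "fitted")
  } else {
    pr <- .dense_proj(y, grams)
    Xi <- ns * grams$Q
    resid <- y - as.vector(grams$S %*% pr$d) - as.vector(Xi %*% pr$c)
    XiW <- Xi %*% pr$W
    edf <- 2 + sum(diag(Xi %*% pr$Minv(diag(ns)))) -
      sum(diag(solve(pr$StW, crossprod(pr$W, XiW))))
  }
  if (ns - edf <= 0)
    stop("oversmoothing/undersmoothing error: tr(I - A(lambda)) <= 0",
         call. = FALSE)
  out <- sum(resid^2) / (ns - edf)
  attr(out, "edf") <- edf
  out
}

#' Fit the two-way SSANOVA model
#'
#' Penalized least-squares fit of the paired-curve model at a given (or
#' pilot) smoothing parameter: scale parameters by trace equalization,
#' representer coefficient solve, interaction component, fitted values,
#' effective degrees of freedom and noise variance.
#'
#' @param points A [design_points()] object.
#' @param config A [kernel_config()]; if `lambda` is `NULL` the pilot value
#'   \eqn{n^{-4m/(4m+1)}} (with `n` the per-subject number of positions) is
#'   used.
#' @param compute_alpha Also solve the coefficient system [solve_alpha()]
#'   (dense, O(ns^3)); off by default.
#' @return An object of class `"ssanova_fit"`: list with `f11_hat`, `fitted`,
#'   `residuals`, `sigma2_hat`, `edf`, `lambda_used`, `theta_used`, `m`,
#'   and optionally `alpha_hat`.
#' @examples
#' set.seed(1)
#' d <- design_points(runif(60), rep(0:1, each = 30), rnorm(60))
#' f <- ssanova_fit(d)
#' f$sigma2_hat
#' @export
ssanova_fit <- function(points, config = kernel_config(), compute_alpha = FALSE) {
  points <- as.design_points(points)
  eng <- .pt_engine(points, config$m)
  lambda <- config$lambda
  if (is.null(lambda)) lambda <- .pilot_lambda(eng)
  ft <- .eng_fit(eng, points$value, lambda)
  out <- list(f11_hat = ft$f11, fitted = ft$fitted, residuals = ft$resid,
              sigma2_hat = ft$sigma2, edf = ft$edf, lambda_used = lambda,
              theta_used = c(theta10 = eng$theta, theta11 = eng$theta),
              m = config$m, ns = eng$ns)
  if (compute_alpha) {
    cfg <- config; cfg$lambda <- lambda
    out$alpha_hat <- as.vector(solve_alpha(points$value,
                                           assemble_grams(points, cfg)))
  }
  class(out) <- "ssanova_fit"
  out
}

.pilot_lambda <- function(eng) {
  m <- eng$m
  (eng$ns / eng$s)^(-4 * m / (4 * m + 1))
}

#' @export
print.ssanova_fit <- function(x, ...) {
  cat("Two-way SSANOVA fit\n")
  cat(sprintf("  ns = %d, lambda = %.3g, edf = %.2f, sigma^2 = %.4f\n",
              x$ns, x$lambda_used, x$edf, x$sigma2_hat))
  cat(sprintf("  ||f11_hat||^2/ns = %.4g\n", mean(x$f11_hat^2)))
  invisible(x)
}
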