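# Reproducing kernels of the tensor-product space.
#
# The continuous margin is the m-th order homogeneous (periodic) Sobolev
# space on [0, 1]; its penalized subspace has reproducing kernel
# (-1)^(m-1) k_{2m}(z - x) with k_r the r-th scaled Bernoulli polynomial
# B_r(.)/r! extended periodically.  The binary margin is R^2 with the
# averaging decomposition: constant kernel 1/2 and contrast kernel
# 1(equal) - 1/2.  Products of the marginal kernels give the four ANOVA
# blocks 00, 01, 10, 11.

# closed forms of B_r(x)/r! on [0, 1); r = 2m for m = 1, 2, 3 plus r = 1
.bernoulli_scaled <- list(
  "1" = function(x) x - 0.5,
  "2" = function(x) (x^2 - x + 1/6) / 2,
  "4" = function(x) (x^4 - 2 * x^3 + x^2 - 1/30) / 24,
  "6" = function(x) (x^6 - 3 * x^5 + 2.5 * x^4 - 0.5 * x^2 + 1/42) / 720
)

#' Scaled Bernoulli polynomial
#'
#' Evaluates \eqn{k_r(x) = B_r(x - \lfloor x \rfloor)/r!}, the scaled
#' Bernoulli polynomial extended periodically with period 1.  These are the
#' building blocks of the periodic spline kernels; orders 1, 2, 4 and 6 (the
#' ones needed for spline orders \eqn{m \le 3}) have closed forms.
#'
#' @param r Polynomial order; one of 1, 2, 4, 6.
#' @param x Numeric vector; reduced to \eqn{[0, 1)} by its fractional part.
#' @return Numeric vector of kernel values.
#' @examples
#' scaled_bernoulli(2, 0)      # 1/12
#' scaled_bernoulli(4, 0)      # -1/720
#' @export
scaled_bernoulli <- function(r, x) {
  f <- .bernoulli_scaled[[as.character(r)]]
  if (is.null(f))
    stop("unsupported Bernoulli order r = ", r,
         " (supported: 1, 2, 4, 6)", call. = FALSE)
  f(x - floor(x))
}

#' Continuous-margin interaction kernel
#'
#' The reproducing kernel \eqn{(-1)^{m-1} k_{2m}(z - x)} of the penalized
#' subspace of the m-th order homogeneous Sobolev space on \eqn{[0, 1]}.
#' Symmetric in its arguments and periodic with period 1.
#'
#' @param x,z Numeric vectors in \eqn{[0, 1]} (recycled).
#' @param m Spline order (1, 2 or 3); `m = 2` is the cubic-spline analogue.
#' @return Numeric vector of kernel values.
#' @examples
#' k1_continuous(0.3, 0.3, m = 2)   # 1/720
#' @export
k1_continuous <- function(x, z, m = 2) {
  (-1)^(m - 1) * scaled_bernoulli(2 * m, z - x)
}

#' Binary-margin kernels
#'
#' Reproducing kernels of the averaging decomposition of the binary margin:
#' the constant component (`component = 0`) is 1/2 for all label pairs, the
#' contrast component (`component = 1`) is \eqn{1(x = z) - 1/2}, i.e. +1/2
#' for equal and -1/2 for unequal labels.
#'
#' @param x2,z2 Group labels in \{0, 1\} (recycled).
#' @param component Which ANOVA component, 0 or 1.
#' @return Numeric vector of kernel values.
#' @export
group_kernel <- function(x2, z2, component) {
  if (length(component) != 1L || !component %in% c(0, 1))
    stop("'component' must be 0 or 1", call. = FALSE)
  if (component == 0) rep_len(0.5, max(length(x2), length(z2)))
  else (x2 == z2) - 0.5
}

#' Kernel and smoothing configuration
#'
#' @param m Spline order of the continuous margin (1, 2 or 3; default 2).
#' @param lambda Smoothing parameter; `NULL` means "choose by the adaptive
#'   testing rule" where applicable ([select_lambda()]).
#' @param theta10,theta11 Positive scale parameters of the two penalized
#'   blocks.  `NULL` (default) means "set by trace equalization"
#'   ([rescale_thetas()]) when Gram matrices are assembled.
#' @param theta00,theta01 Scales of the two unpenalized one-dimensional
#'   blocks; fixed at 1.
#' @return An object of class `"kernel_config"`.
#' @export
kernel_config <- function(m = 2, lambda = NULL, theta10 = NULL, theta11 = NULL,
                          theta00 = 1, theta01 = 1) {
  if (!m %in% 1:3) stop("'m' must be 1, 2 or 3", call. = FALSE)
  for (nm in c("lambda", "theta10", "theta11")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      stop("'", nm, "' must be a positive scalar", call. = FALSE)
  }
  structure(list(m = m, lambda = lambda, theta10 = theta10, theta11 = theta11,
                 theta00 = theta00, theta01 = theta01),
            class = "kernel_config")
}

#' Trace-equalizing scale parameters
#'
#' Sets the scales of the two penalized blocks so that both contribute
#' equally to the penalty: \eqn{\theta_{10} tr(K_{10}) = \theta_{11}
#' tr(K_{11}) = 1}.
#'
#' @param K10,K11 Symmetric positive semi-definite component Gram matrices.
#' @return Named numeric vector `c(theta10, theta11)`.
#' @export
rescale_thetas <- function(K10, K11) {
  t10 <- sum(diag(K10)); t11 <- sum(diag(K11))
  if (t10 <= 0 || t11 <= 0)
    stop("degenerate kernel block: nonpositive trace", call. = FALSE)
  c(theta10 = 1 / t10, theta11 = 1 / t11)
}

# raw component Gram matrices at the observed points (no 1/ns scaling)
.component_grams <- function(position, group, m) {
  Gam <- outer(position, position, k1_continuous, m = m)
  sgn <- ifelse(group == 1, -1, 1)
  list(Gam = Gam, sgn = sgn,
       G00 = matrix(0.5, length(position), length(position)),
       G01 = outer(sgn, sgn) / 2,
       G10 = Gam / 2,
       G11 = Gam * outer(sgn, sgn) / 2)
}

#' Assemble the Gram and design matrices of the model
#'
#' Builds every matrix the penalized least-squares problem and the Wald test
#' need at a given smoothing parameter: the composite kernel matrix `K` and
#' penalty matrix `Q` (both carrying the \eqn{1/(ns)} entry scaling of the
#' fitting objective), the raw component Gram matrices `K10` and `K11`, the
#' design `S` of the unpenalized subspace (intercept and centered group
#' contrast), and the regularized matrix `M` used by the closed-form
#' interaction estimator.
#'
#' With raw component Grams \eqn{G_{\ell\ell'}} and scales \eqn{\theta},
#' `Q = (theta10 G10 + theta11 G11)/ns`, `K = (G00 + G01 + ns Q)/ns` and
#' `M = ns Q + (lambda + jitter) I`, where the jitter
#' \eqn{10^{-10} tr(M)/ns} guards the factorization.
#'
#' @param points A [design_points()] object.
#' @param config A [kernel_config()]; `lambda` must be set.  Unset
#'   `theta10`/`theta11` are filled in by [rescale_thetas()].
#' @return An object of class `"gram_set"`: list with elements `K`, `Q`,
#'   `K10`, `K11`, `S`, `M`, `lambda`, `theta`, `m`, `ns` and the inputs.
#' @examples
#' d <- design_points(runif(20), rep(0:1, each = 10), rnorm(20))
#' g <- assemble_grams(d, kernel_config(lambda = 1e-3))
#' max(abs(g$K - t(g$K)))   # symmetric
#' @export
assemble_grams <- function(points, config = kernel_config(lambda = 1e-3)) {
  points <- as.design_points(points)
  if (is.null(config$lambda))
    stop("'config$lambda' must be set to assemble Gram matrices", call. = FALSE)
  ns <- nrow(points)
  cg <- .component_grams(points$position, points$group, config$m)
  theta <- c(theta10 = config$theta10, theta11 = config$theta11)
  if (is.null(config$theta10) || is.null(config$theta11))
    theta <- rescale_thetas(cg$G10, cg$G11)
  Xi <- theta[["theta10"]] * cg$G10 + theta[["theta11"]] * cg$G11
  K <- (config$theta00 * cg$G00 + config$theta01 * cg$G01 + Xi) / ns
  Q <- Xi / ns
  S <- cbind(intercept = 1, contrast = (points$group == 1) - 0.5)
  if (qr(S)$rank < 2L)
    stop("invalid design: unpenalized design matrix S is rank deficient",
         call. = FALSE)
  M0 <- Xi + config$lambda * diag(ns)
  jitter <- 1e-10 * sum(diag(M0)) / ns
  M <- M0 + jitter * diag(ns)
  structure(list(K = K, Q = Q, K10 = cg$G10, K11 = cg$G11, S = S, M = M,
                 lambda = config$lambda, jitter = jitter, theta = theta,
                 m = config$m, ns = ns, points = points),
            class = "gram_set")
}
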