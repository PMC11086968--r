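# Permutation benchmark for the parallelism test.

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Permutation parallelism test
#'
#' Benchmark test that replaces the Gaussian null calibration with a
#' permutation distribution of the same statistic.  The null (parallel)
#' model containing only the grand mean, the curve main effect and the group
#' shift is fitted by penalized least squares; group labels of its residuals
#' are then permuted within position pairs and the Wald statistic is
#' recomputed on each permuted data set at the same \eqn{\lambda^*}.  The
#' permutation p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{T_b \ge T_{obs}\})/(B + 1)}.
#'
#' With two subjects, observations are paired across groups (by shared
#' position when the two groups share a design, otherwise by within-group
#' position rank) and each pair is swapped independently with probability
#' 1/2.  `scheme = "subject"` instead permutes whole-subject group labels,
#' the natural scheme when there are several curves per group.
#' `permute = "raw"` swaps the raw observations instead of null-model
#' residuals.
#'
#' @param points A [design_points()] object.
#' @param B Number of permutations (default 500).
#' @param seed Integer seed making the permutation draw reproducible; the
#'   caller's RNG state is restored afterwards.
#' @param alpha Nominal level.
#' @param m Spline order.
#' @param lambda Optional fixed smoothing parameter (default: adaptive rule).
#' @param scheme `"within_position"` (default) or `"subject"`.
#' @param permute `"residual"` (default) or `"raw"`.
#' @return List of class `"permutation_test"`: `p_value`, `reject`,
#'   `statistic`, `B`, `lambda_star`, `perm_statistics`.
#' @export
permutation_test <- function(points, B = 500, seed = NULL, alpha = 0.05,
                             m = 2, lambda = NULL,
                             scheme = c("within_position", "subject"),
                             permute = c("residual", "raw")) {
  scheme <- match.arg(scheme)
  permute <- match.arg(permute)
  if (!is.numeric(B) || B < 1) stop("'B' must be >= 1", call. = FALSE)
  B <- as.integer(B)
  points <- as.design_points(points)
  eng <- .pt_engine(points, m)
  y <- points$value
  ns <- eng$ns

  s2 <- .eng_fit(eng, y, .pilot_lambda(eng))$sigma2
  if (is.null(lambda)) {
    grid <- lambda_grid()
    sig <- .eng_sigma_nl(eng, grid, s2)
    ok <- grid < sig
    if (!any(ok) || all(ok))
      stop("adaptive rule failed to bracket a crossing; supply 'lambda'",
           call. = FALSE)
    lambda <- max(grid[ok])
  }
  Tobs <- test_statistic(.eng_fit(eng, y, lambda)$f11)

  if (permute == "residual") {
    base <- .null_model_fit(eng, y, lambda)
    resid <- y - base
  } else {
    base <- rep(0, ns)
    resid <- y
  }

  if (scheme == "within_position") {
    idx0 <- which(points$group == 0L)[order(points$position[points$group == 0L])]
    idx1 <- which(points$group == 1L)[order(points$position[points$group == 1L])]
    if (!isTRUE(all.equal(points$position[idx0[seq_len(min(length(idx0), length(idx1)))]],
                          points$position[idx1[seq_len(min(length(idx0), length(idx1)))]])))
      warning("groups do not share positions; within-position swaps pair by ",
              "rank and the permutation null is only approximate",
              call. = FALSE)
    npair <- min(length(idx0), length(idx1))
    idx0 <- idx0[seq_len(npair)]; idx1 <- idx1[seq_len(npair)]
    draw <- function() {
      swap <- stats::runif(npair) < 0.5
      r <- resid
      r[idx0[swap]] <- resid[idx1[swap]]
      r[idx1[swap]] <- resid[idx0[swap]]
      r
    }
  } else {
    subj <- points$subject
    subj_ids <- unique(subj)
    draw <- function() {
      new_ids <- sample(subj_ids)
      # move each subject's residual curve onto a permuted subject slot
      r <- resid
      for (k in seq_along(subj_ids))
        r[subj == subj_ids[k]] <- resid[subj == new_ids[k]]
      r
    }
  }

  Tb <- .with_seed(seed, vapply(seq_len(B), function(b)
    test_statistic(.eng_fit(eng, base + draw(), lambda)$f11), numeric(1)))
  p <- (1 + sum(Tb >= Tobs)) / (B + 1)
  structure(list(p_value = p, reject = p <= alpha, statistic = Tobs,
                 B = B, alpha = alpha, lambda_star = lambda,
                 perm_statistics = Tb, scheme = scheme, permute = permute),
            class = "permutation_test")
}

# fit of the parallel (null) model f00 + f10 + f01: the 11-block is dropped
# from the penalty Gram, which is then no longer block-diagonal, so a dense
# factorization of M0 = theta10 G10 + lambda I is used.
.null_model_fit <- function(eng, y, lambda) {
  ns <- eng$ns
  ys <- y[eng$ord]
  Xi0 <- eng$theta * eng$Gam / 2             # theta10 * G10, theta10 = 1/tr(G10)
  gam <- .eng_gamma(eng, lambda)
  M0 <- Xi0 + gam * diag(ns)
  R <- chol(M0)
  Minv <- function(v) backsolve(R, forwardsolve(t(R), v))
  W <- Minv(eng$S)
  dcoef <- solve(crossprod(eng$S, W), crossprod(W, ys))
  cc <- Minv(ys) - W %*% dcoef
  fitted <- as.vector(eng$S %*% dcoef) + as.vector(Xi0 %*% cc)
  fitted[order(eng$ord)]
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Permutation parallelism test\n")
  cat(sprintf("  B = %d, scheme = %s (%s), lambda* = %.3g\n",
              x$B, x$scheme, x$permute, x$lambda_star))
  cat(sprintf("  T = %.4g, p = %.4g  ->  %s parallelism at alpha = %g\n",
              x$statistic, x$p_value,
              if (x$reject) "REJECT" else "do not reject", x$alpha))
  invisible(x)
}
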