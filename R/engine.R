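# Internal computational engine.
#
# The trace-equalized penalty Gram Xi = theta10 G10 + theta11 G11 vanishes
# between groups (the two block scales are always equal under trace
# equalization, so within-group entries are theta * Gam and cross-group
# entries cancel).  Xi and M = Xi + lambda I are therefore block-diagonal by
# group, and one symmetric eigendecomposition per group block makes every
# lambda on the selection grid, every fit and every permutation replicate an
# O(ns^2) operation.  All quantities are cross-checked against the dense
# gram_set path in the test suite.
#
# Trace identities used for the null moments, with D_g = diag(+/-1) constant
# within a group block, G11 = D Gam D / 2 and M block-diagonal:
#   tr(Delta)   = tr(M^-1 G11^2 M^-1)     = tr(Gam^2 M^-2) / 4
#   tr(Delta^2) = tr((M^-1 G11^2 M^-1)^2) = tr(Gam^2 M^-2 Gam^2 M^-2) / 16
# which, after rotating Gam^2 into the block eigenbases, reduce to weighted
# sums over the rotated blocks C00 = diag(d0)^2 + B B', C01 = diag(d0) B +
# B diag(d1), C11 = diag(d1)^2 + B' B with B = V0' Gam01 V1.

.pt_engine <- function(points, m = 2) {
  points <- as.design_points(points)
  ord <- order(points$group)
  x <- points$position[ord]
  g <- points$group[ord]
  ns <- length(x)
  i0 <- which(g == 0L); i1 <- which(g == 1L)
  Gam <- outer(x, x, k1_continuous, m = m)
  theta <- 2 / sum(diag(Gam))               # = 1/tr(G10) = 1/tr(G11)
  e0 <- eigen(Gam[i0, i0], symmetric = TRUE)
  e1 <- eigen(Gam[i1, i1], symmetric = TRUE)
  d0 <- pmax(e0$values, 0); d1 <- pmax(e1$values, 0)
  B <- crossprod(e0$vectors, Gam[i0, i1] %*% e1$vectors)
  C00 <- tcrossprod(B); diag(C00) <- diag(C00) + d0^2
  C11 <- crossprod(B);  diag(C11) <- diag(C11) + d1^2
  C01 <- d0 * B + B * rep(d1, each = nrow(B))
  list(points = points, ord = ord, x = x, g = g, ns = ns, i0 = i0, i1 = i1,
       n = ns / attr(points, "s"), s = attr(points, "s"), m = m,
       Gam = Gam, theta = theta,
       V0 = e0$vectors, V1 = e1$vectors, d0 = d0, d1 = d1,
       diagC00 = diag(C00), diagC11 = diag(C11),
       H00 = C00^2, H01 = C01^2, H11 = C11^2,
       S = cbind(1, (g == 1L) - 0.5),
       sgn = ifelse(g == 1L, -1, 1))
}

.eng_gamma <- function(eng, lambda) {
  # effective ridge: lambda plus the same diagonal jitter as the dense path
  lambda + 1e-10 * (2 + eng$ns * lambda) / eng$ns
}

# tr(Delta) and tr(Delta^2) with Delta = M^-1 K11^2 M^-1
.eng_traces <- function(eng, lambda) {
  gam <- .eng_gamma(eng, lambda)
  a0 <- 1 / (eng$theta * eng$d0 + gam)^2
  a1 <- 1 / (eng$theta * eng$d1 + gam)^2
  trD  <- 0.25 * (sum(eng$diagC00 * a0) + sum(eng$diagC11 * a1))
  trD2 <- (sum(a0 * (eng$H00 %*% a0)) + 2 * sum(a0 * (eng$H01 %*% a1)) +
           sum(a1 * (eng$H11 %*% a1))) / 16
  c(trace_delta = trD, trace_delta2 = trD2)
}

# block-diagonal solve M^-1 v
.eng_Minv <- function(eng, v, gam) {
  out <- numeric(eng$ns)
  out[eng$i0] <- eng$V0 %*% (crossprod(eng$V0, v[eng$i0]) /
                               (eng$theta * eng$d0 + gam))
  out[eng$i1] <- eng$V1 %*% (crossprod(eng$V1, v[eng$i1]) /
                               (eng$theta * eng$d1 + gam))
  out
}

.eng_Xi_mul <- function(eng, v) {
  out <- if (is.matrix(v)) v else matrix(v)
  out[eng$i0, ] <- eng$theta * (eng$Gam[eng$i0, eng$i0] %*% out[eng$i0, , drop = FALSE])
  out[eng$i1, ] <- eng$theta * (eng$Gam[eng$i1, eng$i1] %*% out[eng$i1, , drop = FALSE])
  out
}

# penalized least-squares fit at a given lambda; y in original point order
.eng_fit <- function(eng, y, lambda) {
  y <- y[eng$ord]
  ns <- eng$ns
  gam <- .eng_gamma(eng, lambda)
  w <- .eng_Minv(eng, y, gam)
  W <- cbind(.eng_Minv(eng, eng$S[, 1], gam), .eng_Minv(eng, eng$S[, 2], gam))
  StW <- crossprod(eng$S, W)
  dcoef <- solve(StW, crossprod(W, y))
  cc <- w - W %*% dcoef
  f11 <- 0.5 * eng$sgn * as.vector(eng$Gam %*% (eng$sgn * cc))
  fitted <- as.vector(eng$S %*% dcoef) + as.vector(.eng_Xi_mul(eng, cc))
  td0 <- eng$theta * eng$d0; td1 <- eng$theta * eng$d1
  XiW <- .eng_Xi_mul(eng, W)
  edf <- 2 + sum(td0 / (td0 + gam)) + sum(td1 / (td1 + gam)) -
    sum(diag(solve(StW, crossprod(W, XiW))))
  resid <- y - fitted
  if (ns - edf <= 0)
    stop("oversmoothing/undersmoothing error: tr(I - A(lambda)) <= 0",
         call. = FALSE)
  # results mapped back to the original observation order
  back <- order(eng$ord)
  list(f11 = f11[back], fitted = fitted[back], resid = resid[back],
       coef_c = cc[back], coef_d = as.vector(dcoef), edf = edf,
       sigma2 = sum(resid^2) / (ns - edf), lambda = lambda)
}

# sigma_{n,lambda} on a lambda grid, given sigma^2
.eng_sigma_nl <- function(eng, lambda, sigma2) {
  vapply(lambda, function(l)
    sqrt(2 * .eng_traces(eng, l)[["trace_delta2"]]) * sigma2 / eng$ns,
    numeric(1))
}
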