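# small random designs used across the suite
random_design <- function(n_per_group = 10, seed = 1, sd = 1) {
  set.seed(seed)
  design_points(position = runif(2 * n_per_group),
                group = rep(0:1, each = n_per_group),
                value = rnorm(2 * n_per_group, sd = sd))
}

even_design <- function(n_per_group = 10, value = NULL, seed = 1) {
  set.seed(seed)
  x <- (seq_len(n_per_group) - 0.5) / n_per_group
  if (is.null(value)) value <- rnorm(2 * n_per_group)
  design_points(position = rep(x, 2), group = rep(0:1, each = n_per_group),
                value = value)
}

# penalized least-squares functional in the representer parametrization;
# the independent oracle for the closed-form interaction estimator
plsq_objective <- function(par, y, S, Xi, lambda) {
  d <- par[1:2]; cc <- par[-(1:2)]
  sum((y - S %*% d - Xi %*% cc)^2) + lambda * sum(cc * (Xi %*% cc))
}
plsq_gradient <- function(par, y, S, Xi, lambda) {
  d <- par[1:2]; cc <- par[-(1:2)]
  r <- as.vector(y - S %*% d - Xi %*% cc)
  c(-2 * crossprod(S, r), as.vector(-2 * Xi %*% r + 2 * lambda * Xi %*% cc))
}

# minimize the functional numerically and return the implied f11 = K11 c.
# The raw (d, c) problem is too ill-conditioned for a generic optimizer, so
# the exact substitution c = V D^(-1/2) u (with Xi = V D V') is applied
# first: the objective becomes the well-conditioned ridge
# ||y - S d - Z u||^2 + lambda ||u||^2 with Z = V D^(1/2), on which BFGS
# converges to machine precision.
oracle_f11 <- function(y, grams) {
  Xi <- grams$ns * grams$Q
  e <- eigen(Xi, symmetric = TRUE)
  keep <- e$values > 1e-12 * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  sq <- sqrt(e$values[keep])
  Z <- V * rep(sq, each = nrow(V))
  X <- cbind(grams$S, Z)
  q <- ncol(grams$S)
  obj <- function(p) sum((y - X %*% p)^2) +
    grams$lambda * sum(p[-(1:q)]^2)
  grd <- function(p) {
    g <- as.vector(-2 * crossprod(X, y - X %*% p))
    g[-(1:q)] <- g[-(1:q)] + 2 * grams$lambda * p[-(1:q)]
    g
  }
  par <- rep(0, ncol(X)); val <- Inf
  for (k in 1:20) {
    o <- optim(par, obj, grd, method = "BFGS",
               control = list(maxit = 20000, reltol = 1e-16))
    par <- o$par
    if (val - o$value < 1e-15 * (1 + abs(o$value))) break
    val <- o$value
  }
  cc <- V %*% (par[-(1:q)] / sq)
  as.vector(grams$K11 %*% cc)
}
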