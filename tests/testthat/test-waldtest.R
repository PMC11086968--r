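test_that("test statistic is the scaled squared norm", {
  expect_equal(test_statistic(rep(0, 8)), 0)
  expect_equal(test_statistic(c(1, 1, 1, 1)), 1)
  f <- rnorm(10)
  expect_equal(test_statistic(3 * f), 9 * test_statistic(f))
})

test_that("null moments are valid across random designs", {
  for (seed in 1:30) {
    d <- random_design(7, seed = seed)
    g <- assemble_grams(d, kernel_config(lambda = 10^runif(1, -5, -1)))
    nm <- null_moments(g, sigma2 = runif(1, 0.5, 2))
    expect_gte(nm$mu, 0)
    expect_gt(nm$sigma, 0)
    expect_gte(nm$trace_delta, 0)
    expect_gte(nm$trace_delta2, 0)
  }
})

test_that("null moments match direct simulation of the quadratic form", {
  # oracle: draw pure-noise vectors and evaluate eps' Delta eps / ns with
  # Delta built explicitly from the dense matrices
  d <- random_design(50, seed = 31)   # n = 100 per group
  lam <- 1e-3
  g <- assemble_grams(d, kernel_config(lambda = lam))
  Minv <- solve(g$M)
  Delta <- Minv %*% g$K11 %*% g$K11 %*% Minv
  nm <- null_moments(g, sigma2 = 1)
  set.seed(32)
  T1 <- replicate(2000, {
    e <- rnorm(g$ns)
    sum(e * (Delta %*% e)) / g$ns
  })
  mc_se <- sd(T1) / sqrt(length(T1))
  expect_lt(abs(mean(T1) - nm$mu), 3 * mc_se)
  expect_lt(abs(var(T1) - nm$sigma^2) / nm$sigma^2, 0.2)
})

test_that("decision rule standardizes and rejects correctly", {
  nm <- structure(list(mu = 0.2, sigma = 0.05), class = "null_moments")
  d0 <- decide(0.2, nm, alpha = 0.05)
  expect_equal(d0$z, 0)
  expect_equal(d0$p_value, 1)
  expect_false(d0$reject)
  zb <- qnorm(0.975)
  db <- decide(0.2 + zb * 0.05, nm, alpha = 0.05)
  expect_equal(db$p_value, 0.05, tolerance = 1e-10)
  set.seed(33)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.2)
    dd <- decide(rnorm(1, 0.2, 0.1), nm, alpha = a)
    expect_identical(dd$reject, dd$p_value <= a)
  }
  # one-sided option
  d1 <- decide(0.2 + zb * 0.05, nm, alpha = 0.05, alternative = "greater")
  expect_equal(d1$p_value, db$p_value / 2, tolerance = 1e-12)
})

test_that("sigma_{n,lambda} decreases in lambda and the rule finds the crossing", {
  grid <- lambda_grid(30)
  for (seed in c(34, 35, 36)) {
    d <- random_design(40, seed = seed)
    eng <- npparallel:::.pt_engine(d, 2)
    sig <- npparallel:::.eng_sigma_nl(eng, grid, 1)
    expect_true(all(diff(sig) <= 1e-12))
    lam <- select_lambda(d, sigma2 = 1, grid = grid)
    tab <- attr(lam, "table")
    # selected point qualifies, the next grid point does not
    expect_true(tab$qualifies[match(as.numeric(lam), tab$lambda)])
    expect_false(any(tab$qualifies[tab$lambda > as.numeric(lam)]))
  }
  # degenerate grid with a single qualifying value returns it
  d <- random_design(40, seed = 37)
  sig1 <- npparallel:::.eng_sigma_nl(npparallel:::.pt_engine(d, 2), 1e-6, 1)
  expect_true(1e-6 < sig1)
  lam1 <- select_lambda(d, sigma2 = 1, grid = c(1e-6, 0.5, 1))
  expect_equal(as.numeric(lam1), 1e-6)
  # no qualifying lambda -> instructive error
  expect_error(select_lambda(d, sigma2 = 1, grid = c(0.5, 0.7, 1)),
               "expand the grid")
})

test_that("effective dimension counts eigenvalues above the threshold", {
  expect_equal(effective_dimension(c(1, 0.5, 0.1), 0.3), 2)
  expect_equal(effective_dimension(c(1, 0.5, 0.1), 2), 0)
  expect_error(effective_dimension(c(0.1, 0.5), 0.2), "decreasing")
})

test_that("effective dimension grows at the lambda^(-1/(2m)) rate", {
  mu <- k1_spectrum((seq_len(500) - 0.5) / 500, m = 2)
  lams <- 10^seq(-7.5, -4.5, length.out = 12)
  taus <- vapply(lams, effective_dimension, eigenvalues = mu,
                 FUN.VALUE = numeric(1))
  slope <- coef(lm(log(taus) ~ log(lams)))[2]
  expect_lt(abs(slope + 0.25), 0.1)
})

test_that("the full test is deterministic and honours overrides", {
  st <- sim_setting(1, n = 80, delta1 = 0.8, seed = 38)
  d <- simulate_setting(st)
  t1 <- parallelism_test(d)
  t2 <- parallelism_test(d)
  expect_identical(t1$statistic, t2$statistic)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$lambda_star, t2$lambda_star)
  t3 <- parallelism_test(d, lambda = 1e-3)
  expect_equal(t3$lambda_star, 1e-3)
  expect_true(t1$reject == (t1$p_value <= t1$alpha))
  expect_gte(t1$statistic, 0)
})

test_that("null moments are free of the parallel nuisance components (Wilks)", {
  d <- even_design(50, seed = 39)
  # same design, three different parallel mean structures, same sigma^2
  y0 <- d$value
  means <- list(rep(0, 100), 3 * sin(2 * pi * d$position) + 2,
                d$position * 5 + 4 * (d$group == 1))
  moms <- lapply(means, function(mn) {
    dd <- design_points(d$position, d$group, y0 + mn, subject = d$subject)
    parallelism_test(dd, sigma2 = 1)$moments
  })
  for (k in 2:3) {
    expect_identical(moms[[1]]$mu, moms[[k]]$mu)
    expect_identical(moms[[1]]$sigma, moms[[k]]$sigma)
  }
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.001, 0.04)), c(0.002, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.3, 0.9)
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
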