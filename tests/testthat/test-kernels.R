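test_that("scaled Bernoulli polynomials match closed-form values", {
  expect_equal(scaled_bernoulli(1, 0.5), 0)
  expect_equal(scaled_bernoulli(2, 0), 1 / 12)
  expect_equal(scaled_bernoulli(4, 0), -1 / 720)
  # reflection symmetry of the even orders about 1/2
  expect_equal(scaled_bernoulli(2, 0.3), scaled_bernoulli(2, 0.7))
  expect_equal(scaled_bernoulli(4, 0.2), scaled_bernoulli(4, 0.8))
  # periodic extension
  expect_equal(scaled_bernoulli(4, 1.3), scaled_bernoulli(4, 0.3))
  expect_equal(scaled_bernoulli(2, -0.25), scaled_bernoulli(2, 0.75))
  expect_error(scaled_bernoulli(3, 0.1), "unsupported")
  expect_error(scaled_bernoulli(8, 0.1), "unsupported")
})

test_that("continuous-margin kernel values and symmetry", {
  expect_equal(k1_continuous(0.4, 0.4, m = 2), 1 / 720)
  expect_equal(k1_continuous(0.2, 0.7, m = 2), -7 / 5760)
  set.seed(42)
  for (m in 1:3) {
    a <- runif(25); b <- runif(25)
    expect_equal(k1_continuous(a, b, m), k1_continuous(b, a, m),
                 tolerance = 1e-13)
  }
})

test_that("binary-margin kernels implement the averaging decomposition", {
  expect_equal(group_kernel(0, 0, 1), 0.5)
  expect_equal(group_kernel(0, 1, 1), -0.5)
  expect_equal(group_kernel(1, 1, 1), 0.5)
  expect_equal(group_kernel(1, 0, 0), 0.5)
  expect_equal(group_kernel(c(0, 1), c(1, 1), 1), c(-0.5, 0.5))
  expect_error(group_kernel(0, 1, 2), "component")
})

test_that("assembled Gram matrices match independent entrywise evaluation", {
  x <- c(0.05, 0.22, 0.41, 0.63, 0.97)
  d <- design_points(rep(x, 2), rep(0:1, each = 5), value = rnorm(10))
  cfg <- kernel_config(m = 2, lambda = 1e-3)
  g <- assemble_grams(d, cfg)
  ns <- 10
  # scalar-kernel oracle for every entry of K11, K10, Q and K
  K11o <- matrix(NA_real_, ns, ns); K10o <- K11o; Ko <- K11o
  for (i in 1:ns) for (j in 1:ns) {
    kc <- k1_continuous(d$position[i], d$position[j], 2)
    K10o[i, j] <- kc * group_kernel(d$group[i], d$group[j], 0)
    K11o[i, j] <- kc * group_kernel(d$group[i], d$group[j], 1)
    Ko[i, j] <- group_kernel(d$group[i], d$group[j], 0) +
      group_kernel(d$group[i], d$group[j], 1) +
      g$theta[["theta10"]] * K10o[i, j] + g$theta[["theta11"]] * K11o[i, j]
  }
  expect_equal(g$K10, K10o)
  expect_equal(g$K11, K11o)
  expect_equal(g$K, Ko / ns)
  expect_equal(g$Q, (g$theta[["theta10"]] * K10o +
                       g$theta[["theta11"]] * K11o) / ns)
  expect_equal(max(abs(g$K - t(g$K))), 0)
  expect_equal(max(abs(g$Q - t(g$Q))), 0)
  expect_equal(qr(g$S)$rank, 2L)
})

test_that("K and Q are positive semi-definite across random designs (Mercer)", {
  worst_K <- worst_Q <- Inf
  for (seed in 1:100) {
    d <- random_design(6, seed = seed)
    g <- assemble_grams(d, kernel_config(lambda = 1e-4))
    worst_K <- min(worst_K, min(eigen(g$K, symmetric = TRUE,
                                      only.values = TRUE)$values))
    worst_Q <- min(worst_Q, min(eigen(g$Q, symmetric = TRUE,
                                      only.values = TRUE)$values))
  }
  expect_gt(worst_K, -1e-10)
  expect_gt(worst_Q, -1e-10)
})

test_that("assembly rejects single-group designs", {
  expect_error(design_points(runif(10), rep(1, 10), rnorm(10)),
               "both groups")
})

test_that("homogeneous kernel integrates to zero: grid row sums vanish", {
  n <- 200
  x <- (seq_len(n) - 0.5) / n
  G <- outer(x, x, k1_continuous, m = 2)
  expect_lt(max(abs(rowSums(G))), 1 / n)
  expect_lt(max(abs(colSums(G))), 1 / n)
})

test_that("empirical kernel eigenvalues decay at the i^(-2m) rate", {
  mu <- k1_spectrum((seq_len(500) - 0.5) / 500, m = 2)
  i <- 2:40                       # bulk of the spectrum, away from tail noise
  slope <- coef(lm(log(mu[i]) ~ log(i)))[2]
  expect_lt(abs(slope + 4), 0.3)
})
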