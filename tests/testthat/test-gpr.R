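test_that("single-point fits match hand-evaluated posterior formulas", {
  # K + s2 = 1 * 1 + 0.01 for one training point at x = 1
  fit <- gpr(matrix(1), 1, linear_kernel(), noise_var = 0.01)
  expect_equal(drop(fit$L)^2, 1.01)
  # linear kernel, one point, zero noise: interpolating line through origin
  fit0 <- gpr(matrix(1), 1, linear_kernel(), noise_var = 0)
  xs <- c(-2, 0.5, 3)
  expect_equal(predict(fit0, xs), xs)
  # with noise s2 the slope shrinks to 1/(1 + s2)
  s2 <- 0.3
  fits <- gpr(matrix(1), 1, linear_kernel(), noise_var = s2)
  expect_equal(predict(fits, xs), xs / (1 + s2))
})

test_that("posterior mean and variance behave as conditioning requires", {
  set.seed(21)
  d <- make_dataset1(n = 150, seed = 21)
  # rbf mean reverts to the zero prior far from all training inputs
  fit <- gpr(d$X, d$y, rbf_kernel(1), noise_var = 0.0025)
  expect_lt(abs(predict(fit, 50)), 1e-10)
  expect_equal(predict_var(fit, 50), 1 + 0.0025, tolerance = 1e-8)
  # linear-kernel variance at the origin is exactly the test noise
  fl <- gpr(d$X, d$y, linear_kernel(), noise_var = 0.0025)
  expect_equal(predict_var(fl, 0), 0.0025, tolerance = 1e-15)
  # at a training input, with dense data and small noise, the variance
  # approaches the test-noise floor
  x0 <- d$X[1, 1]
  expect_lt(predict_var(fit, x0), 0.0025 * 1.2)
  expect_gte(predict_var(fit, x0), 0.0025 - 1e-9)
})

test_that("the predictive variance does not involve the training outputs", {
  set.seed(5)
  X <- matrix(runif(40, -2, 2))
  xs <- seq(-3, 3, length.out = 25)
  for (nm in names(fit_test_kernels())) {
    k <- fit_test_kernels()[[nm]]
    v0 <- predict_var(gpr(X, rnorm(40), k, 0.0025), xs)
    for (rep in 1:3) {
      v <- predict_var(gpr(X, rnorm(40, sd = rep), k, 0.0025), xs)
      expect_lt(max(abs(v - v0)), 1e-12)
    }
  }
})

test_that("predictions and variances match an independent GPR implementation", {
  skip_if_not_installed("kernlab")
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    l <- runif(1, 0.5, 2)
    s2 <- runif(1, 0.01, 0.5)
    X <- matrix(rnorm(n, sd = 1.5))
    y <- sin(X[, 1]) + rnorm(n, sd = 0.3)
    xs <- matrix(seq(-3, 3, length.out = 15))
    fit <- gpr(X, y, rbf_kernel(l), noise_var = s2)
    p <- predict(fit, xs, var = TRUE)
    ref <- kernlab::gausspr(X, y, kernel = "rbfdot",
                            kpar = list(sigma = 1 / (2 * l^2)),
                            var = s2, scaled = FALSE, variance.model = TRUE)
    expect_equal(p$mean, drop(kernlab::predict(ref, xs)), tolerance = 1e-6)
    # kernlab reports the noise-free predictive sd; add the test noise back
    ref_var <- drop(kernlab::predict(ref, xs, type = "sdeviation"))^2 + s2
    expect_equal(p$var, ref_var, tolerance = 1e-6)
  }
})

test_that("adding a training point never increases the predictive variance", {
  set.seed(9)
  X <- matrix(runif(30, -2, 2))
  y <- rnorm(30)
  probes <- seq(-3, 3, length.out = 100)
  for (nm in names(fit_test_kernels())) {
    k <- fit_test_kernels()[[nm]]
    v_before <- predict_var(gpr(X, y, k, 0.01), probes)
    X2 <- rbind(X, 0.37)
    v_after <- predict_var(gpr(X2, c(y, 0.2), k, 0.01), probes)
    expect_true(all(v_after <= v_before + 1e-10), label = nm)
  }
})

test_that("fits are invariant to training-row order", {
  set.seed(14)
  X <- matrix(runif(25, -2, 2)); y <- rnorm(25)
  perm <- sample(25)
  xs <- seq(-2, 2, length.out = 9)
  f1 <- gpr(X, y, rbf_kernel(1), 0.04)
  f2 <- gpr(X[perm, , drop = FALSE], y[perm], rbf_kernel(1), 0.04)
  expect_equal(predict(f1, xs), predict(f2, xs), tolerance = 1e-9)
  expect_equal(predict_var(f1, xs), predict_var(f2, xs), tolerance = 1e-9)
})

test_that("jitter escalation handles rank-deficient covariances", {
  X <- matrix(c(0.5, 0.5, 1), 3, 1)  # duplicated input, zero noise
  fit <- gpr(X, c(1, 1, 2), rbf_kernel(1), noise_var = 0)
  expect_gt(fit$jitter, 0)
  expect_true(all(is.finite(predict(fit, c(0, 1)))))
  expect_true(all(predict_var(fit, c(0, 1)) >= 0))
})

test_that("log marginal likelihood matches univariate Gaussian closed forms", {
  # n = 1, white kernel, unit variance, y = 0: standard normal log-density
  expect_equal(log_marginal_likelihood(matrix(1), 0, white_kernel(1)),
               -0.5 * log(2 * pi))
  # general univariate case
  a <- 0.7; v <- 0.4
  expect_equal(log_marginal_likelihood(matrix(2), a, white_kernel(v)),
               -0.5 * log(2 * pi * v) - a^2 / (2 * v))
  # the maximizer over v of that likelihood is v = a^2
  f <- function(v) log_marginal_likelihood(matrix(2), a, white_kernel(v))
  vhat <- optimize(f, c(1e-4, 10), maximum = TRUE)$maximum
  expect_equal(vhat, a^2, tolerance = 1e-4)
  # logLik method agrees with the direct evaluation
  set.seed(2)
  X <- matrix(rnorm(12)); y <- rnorm(12)
  fit <- gpr(X, y, rbf_kernel(1), 0.1)
  expect_equal(as.numeric(logLik(fit)),
               log_marginal_likelihood(X, y, rbf_kernel(1), 0.1))
})

test_that("hyperparameter optimization recovers the pure-noise MLE", {
  set.seed(77)
  n <- 50
  X <- matrix(runif(n, -2, 2))
  y <- rnorm(n)
  # linear + white template: the white component must absorb the zero-mean
  # Gaussian variance MLE and the linear weight must collapse
  r <- gpr_optimize(X, y, restarts = 6, seed = 4, fixed = list(w_rbf = 0, l = 1))
  vmle <- mean(y^2)
  expect_equal(r$par[["noise_var"]], vmle, tolerance = 0.05)
  expect_lt(r$par[["w_linear"]], 0.05)
  expect_identical(r$par[["w_rbf"]], 0)
  # reproducible given the seed, and audited
  r2 <- gpr_optimize(X, y, restarts = 6, seed = 4, fixed = list(w_rbf = 0, l = 1))
  expect_identical(r$par, r2$par)
  expect_equal(nrow(r$restarts), 6)
  # full hybrid template on a small sample may spend some variance on the
  # RBF component, but the total explained variance is conserved
  rh <- gpr_optimize(X, y, restarts = 6, seed = 4)
  expect_equal(rh$par[["noise_var"]] + rh$par[["w_rbf"]], vmle,
               tolerance = 0.35)
  # perfect linear data leaves no residual: noise driven to its lower bound
  yl <- 1.7 * X[, 1]
  rl <- gpr_optimize(X, yl, restarts = 6, seed = 4, fixed = list(w_rbf = 0, l = 1))
  expect_equal(rl$par[["noise_var"]], 1e-4, tolerance = 1e-6)
})

test_that("model methods expose coefficients, residuals and simulations", {
  set.seed(6)
  d <- make_dataset1(n = 80, seed = 6)
  fit <- gpr(d$X, d$y, hybrid_kernel(0.5, 1, 1, 0.04), noise_var = 0)
  co <- coef(fit)
  expect_true(all(c("noise_var", "linear.weight", "rbf.weight", "rbf.l",
                    "white.noise_variance") %in% names(co)))
  expect_equal(residuals(fit), d$y - fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 1, xstar = c(-1, 0, 1))
  expect_equal(dim(sims), c(3L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1, xstar = c(-1, 0, 1)))
  s <- summary(fit)
  expect_s3_class(s, "summary.gpr")
  expect_true(is.finite(s$logLik))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_predictions(fit, c(-1, 0, 1), tmp)
  re <- read.table(tmp, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(re$mean, tab$mean, tolerance = 1e-10)
})
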