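test_that("SVD form reduces by hand for a single linear training point", {
  # one point at x = 1, noise s2: only singular value 1/s, variance
  # x*^2 s2/(1 + s2) + s2_test
  s2 <- 0.25
  form <- svd_variance_form(matrix(1), identity, s2, 0.1)
  expect_equal(form$singular_values, 1 / sqrt(s2))
  xs <- c(-2, 0, 0.5, 3)
  expect_equal(eval_variance_form(form, xs),
               xs^2 * s2 / (1 + s2) + 0.1, tolerance = 1e-12)
  # the minimum of the linear-kernel variance sits at the origin at s2_test
  set.seed(1)
  form2 <- svd_variance_form(matrix(rnorm(20)), identity, 0.04, 0.04)
  expect_equal(eval_variance_form(form2, 0), 0.04, tolerance = 1e-15)
})

test_that("SVD quadratic form equals the conditioning formula", {
  set.seed(42)
  X <- matrix(runif(60, -pi, pi))
  y <- rnorm(60)
  s2 <- 0.09
  xs <- seq(-pi, pi, length.out = 41)
  # exact feature map (linear kernel)
  v_direct <- predict_var(gpr(X, y, linear_kernel(), s2), xs)
  v_svd <- eval_variance_form(svd_variance_form(X, identity, s2, s2), xs)
  expect_lt(max(abs(v_direct - v_svd)), 1e-10)
  # truncated RBF map at J = 40
  v_rbf <- predict_var(gpr(X, y, rbf_kernel(1), s2), xs)
  fm <- function(x) rbf_feature_map_1d(x, l = 1, J = 40)
  v_rbf_svd <- eval_variance_form(svd_variance_form(X, fm, s2, s2), xs)
  expect_lt(max(abs(v_rbf - v_rbf_svd)), 1e-6)
  # V has orthonormal columns; quadratic term is never negative
  form <- svd_variance_form(X, fm, s2, 0)
  V <- form$V
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-10)
  expect_true(all(eval_variance_form(form, seq(-6, 6, by = 0.1)) >= 0))
  expect_true(all(form$shrink > 0 & form$shrink <= 1))
})

test_that("linear closed form matches the conditioning formula everywhere", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(1:30, 1)
    X <- matrix(rnorm(n, sd = 2))
    s2_train <- runif(1, 0.01, 1)
    s2_test <- runif(1, 0, 1)
    xstar <- rnorm(1, sd = 3)
    v_closed <- linear_variance_closed_form(X, s2_train, s2_test, xstar)
    fit <- gpr(X, rnorm(n), linear_kernel(), s2_train)
    v_direct <- predict_var(fit, xstar) - s2_train + s2_test
    expect_equal(v_closed, v_direct, tolerance = 1e-10)
    # symmetric in x*, minimum value s2_test at the origin
    expect_equal(v_closed,
                 linear_variance_closed_form(X, s2_train, s2_test, -xstar))
    expect_equal(linear_variance_closed_form(X, s2_train, s2_test, 0), s2_test)
  }
  # an uninformative-at-origin singular value of 0: X = 0 gives x*^2 + s2_test
  expect_equal(linear_variance_closed_form(matrix(0), 0.1, 0.02, 3),
               9 + 0.02)
})

test_that("sliding-window estimator recovers local residual variance", {
  # constant residuals have zero variance everywhere
  x <- seq(-1, 1, length.out = 200)
  a <- estimate_aleatoric_sliding_window(x, rep(0.7, 200), c(-0.5, 0, 0.5),
                                         window = 0.5, min_points = 10)
  expect_equal(a$var, rep(0, 3))
  expect_false(any(a$unreliable))
  # homoskedastic uniform residuals: estimates near pi^2/3 across the range
  d3 <- make_dataset3(n = 1000, seed = 2)
  r3 <- d3$y - d3$reference_fn(d3$X[, 1])
  a3 <- estimate_aleatoric_sliding_window(d3$X[, 1], r3,
                                          seq(-2.5, 2.5, length.out = 11),
                                          window = 1)
  expect_false(any(a3$unreliable))
  expect_equal(mean(a3$var), pi^2 / 3, tolerance = 0.1)
  expect_true(all(abs(a3$var - pi^2 / 3) / (pi^2 / 3) < 0.45))
  # windows poorer than min_points are flagged, not extrapolated
  sparse <- estimate_aleatoric_sliding_window(x, rep(0, 200), c(0, 5),
                                              window = 0.5, min_points = 10)
  expect_identical(sparse$unreliable, c(FALSE, TRUE))
  expect_true(is.na(sparse$var[2]))
  # the window is half-open: a residual exactly at the right edge is excluded
  xe <- c(0, 1, 2)
  ae <- estimate_aleatoric_sliding_window(xe, c(0, 10, 0), 1.5,
                                          window = 1, min_points = 2)
  expect_equal(ae$n_window, 1L)   # only x = 1 lies in [1, 2)
})

test_that("uncertainty decomposition adds epistemic and aleatoric parts", {
  d <- make_dataset1(n = 120, seed = 3)
  fit <- gpr(d$X, d$y, rbf_kernel(1), noise_var = 0.0025)
  xs <- seq(-1.5, 1.5, length.out = 30)
  # zero aleatoric: total collapses to the GPR predictive variance
  res0 <- decompose_uncertainty(fit, xs)
  expect_equal(res0$total_var, predict_var(fit, xs), tolerance = 1e-14)
  expect_equal(res0$total_var, res0$epistemic_var + res0$aleatoric_var)
  # constant aleatoric shifts the total by that constant
  res1 <- decompose_uncertainty(fit, xs, aleatoric = 2)
  expect_equal(res1$total_var, res0$total_var + 2)
  expect_error(decompose_uncertainty(fit, xs, aleatoric = -1), "negative")
  # z-scores: zero residual scores zero; both flavours finite
  ys <- predict(fit, xs)
  res2 <- decompose_uncertainty(fit, xs, aleatoric = 1, y = ys)
  expect_equal(res2$z_gpr_only, rep(0, 30))
  expect_equal(res2$z_corrected, rep(0, 30))
  expect_identical(z_scores(res2, "gpr_variance_only"), res2$z_gpr_only)
  expect_identical(z_scores(res2, "decomposed_total"), res2$z_corrected)
  # unreliable aleatoric locations propagate as NA without failing
  al <- res2$aleatoric_var; al[5] <- NA
  res3 <- decompose_uncertainty(fit, xs, aleatoric = al, y = ys)
  expect_true(res3$unreliable[5])
  expect_true(is.na(res3$total_var[5]) && is.na(res3$z_corrected[5]))
})

test_that("aleatoric parts reflect the generating heteroskedastic envelope", {
  # windowed brute force on a large sample: variance ratio between x = pi/2
  # and x = -pi/2 approaches (1.5/0.5)^2 = 9
  big3 <- make_dataset3(n = 4e4, seed = 8)
  big4 <- make_dataset4(big3)
  a <- estimate_aleatoric_sliding_window(big4$X[, 1], big4$y, c(pi / 2, -pi / 2),
                                         window = 0.4)
  expect_equal(a$var[1] / a$var[2], 9, tolerance = 0.15)
  # homoskedastic counterpart is flat at pi^2/3
  a3 <- estimate_aleatoric_sliding_window(big3$X[, 1], big3$y, c(pi / 2, -pi / 2),
                                          window = 0.4)
  expect_equal(a3$var, rep(pi^2 / 3, 2), tolerance = 0.05)
})

test_that("normative results export to delimited text", {
  d <- make_dataset1(n = 60, seed = 4)
  fit <- gpr(d$X, d$y, rbf_kernel(1), 0.0025)
  x <- d$X[, 1]
  al <- estimate_aleatoric_sliding_window(x, residuals(fit), x,
                                          window = 1, min_points = 5)
  res <- decompose_uncertainty(fit, x, aleatoric = al, y = d$y)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_normative(res, tmp)
  re <- read.table(tmp, header = TRUE, sep = "\t")
  expect_named(re, c("x", "y", "y_reference", "epistemic_var", "aleatoric_var",
                     "total_var", "z_gpr_only", "z_corrected",
                     "unreliable_flag"))
  expect_equal(re$total_var, res$total_var, tolerance = 1e-6)
})
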