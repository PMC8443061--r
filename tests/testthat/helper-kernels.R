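# Shared fixtures: one representative kernel of every kind, built in code.
all_test_kernels <- function() {
  list(
    linear = linear_kernel(),
    rbf = rbf_kernel(l = 1),
    matern05 = matern_kernel(l = 1, nu = 0.5),
    matern15 = matern_kernel(l = 1, nu = 1.5),
    matern25 = matern_kernel(l = 0.7, nu = 2.5),
    matern_bessel = matern_kernel(l = 1, nu = 3.7),
    rq = rq_kernel(l = 1, alpha = 1),
    white = white_kernel(0.3),
    hybrid = hybrid_kernel(0.5, 1.2, 0.8, 0.05)
  )
}

# kernels usable as the sole covariance of a GPR fit on distinct points
fit_test_kernels <- function() {
  k <- all_test_kernels()
  k[c("linear", "rbf", "matern15", "rq")]
}
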