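#' SVD quadratic form for the GPR predictive variance
#'
#' Writing the kernel as an inner product of feature coordinates,
#' \eqn{k(x_1,x_2) = z(x_1) z(x_2)^T}, the predictive variance becomes a
#' quadratic form in \eqn{z(x_*)}. With the singular value decomposition
#' \eqn{\Sigma_{train}^{-1} Z(X) = U \Sigma V^T} it reduces to
#' \deqn{\Sigma^2_*(x_*) = z(x_*)\, V\,[I - \Sigma^T(\Sigma\Sigma^T + I)^{-1}
#'   \Sigma]\, V^T z(x_*)^T + \sigma^2_{test},}
#' a non-negative quadratic term plus a constant. \eqn{V} and the singular
#' values depend only on the training inputs, the training noise and the
#' feature map -- the training outputs `y` appear nowhere, which makes the
#' epistemic-only nature of the GPR variance explicit. The bracketed matrix
#' has eigenvalues \eqn{1/(\sigma_i^2 + 1) \le 1} (and 1 on the complement of
#' the row space), so it is positive semi-definite and the quadratic term is
#' never negative.
#'
#' @param X n x 1 matrix (or numeric vector) of training inputs.
#' @param feature_map a function mapping a numeric vector of inputs to an
#'   n x p matrix of feature coordinates. `identity` (the default) is the
#'   linear-kernel map; use a closure over [rbf_feature_map_1d()] for the
#'   truncated RBF map.
#' @param noise_var_train positive training-noise variance
#'   \eqn{\sigma^2_{train}}.
#' @param noise_var_test non-negative test-noise variance added as the
#'   constant term.
#' @return an object of class `"svd_variance_form"` with fields `V`
#'   (orthonormal columns), `singular_values`, `feature_dimension`,
#'   `noise_var_test`, and the precomputed middle eigenvalues `shrink`
#'   \eqn{= 1/(\sigma_i^2+1)}. Evaluate it with [eval_variance_form()].
#' @export
svd_variance_form <- function(X, feature_map = identity,
                              noise_var_train, noise_var_test = noise_var_train) {
  X <- as_input_matrix(X)
  stopifnot(ncol(X) == 1L, noise_var_train > 0, noise_var_test >= 0)
  Z <- feature_map(X[, 1])
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = 1L)
  if (any(!is.finite(Z))) stop("feature map produced non-finite values")
  if (nrow(Z) != nrow(X)) stop("feature map must return one row per input")
  A <- Z / sqrt(noise_var_train)          # Sigma_train^{-1} Z(X), iid noise
  p <- ncol(Z)
  sv <- svd(A, nu = 0, nv = p)
  # eigenvalues of I - Sigma^T (Sigma Sigma^T + I)^{-1} Sigma in the V basis:
  # 1/(sigma_i^2 + 1) on the first min(n, p) directions, 1 beyond
  shrink <- rep(1, p)
  r <- min(nrow(Z), p)
  shrink[seq_len(r)] <- 1 / (sv$d[seq_len(r)]^2 + 1)
  structure(list(V = sv$v, singular_values = sv$d,
                 feature_dimension = p, noise_var_test = noise_var_test,
                 shrink = shrink, feature_map = feature_map),
            class = "svd_variance_form")
}

#' @rdname svd_variance_form
#' @param form an `"svd_variance_form"`.
#' @param xstar numeric vector of test inputs.
#' @return `eval_variance_form()` returns the predictive variance at each
#'   `xstar`: quadratic term plus `noise_var_test`, always
#'   `>= noise_var_test`.
#' @export
eval_variance_form <- function(form, xstar) {
  stopifnot(inherits(form, "svd_variance_form"))
  Zs <- form$feature_map(as.numeric(xstar))
  if (is.null(dim(Zs))) Zs <- matrix(Zs, ncol = 1L)
  B <- Zs %*% form$V                      # coordinates in the V basis
  drop(B^2 %*% form$shrink) + form$noise_var_test
}

#' @export
print.svd_variance_form <- function(x, ...) {
  cat(sprintf("SVD variance form: feature dimension %d, %d singular value(s)\n",
              x$feature_dimension, length(x$singular_values)))
  cat(sprintf("  leading singular value: %g, noise_var_test = %g\n",
              max(x$singular_values), x$noise_var_test))
  invisible(x)
}

#' Closed-form linear-kernel predictive variance in one dimension
#'
#' For the linear kernel on 1-D inputs the feature map is the identity, the
#' SVD has a single non-zero singular value
#' \eqn{\sigma = \|X\| / \sigma_{train}}, and the variance collapses to
#' \deqn{\Sigma^2_*(x_*) = \frac{x_*^2}{\sigma^2 + 1} + \sigma^2_{test},}
#' a quadratic in \eqn{x_*} whose global minimum sits at \eqn{x_* = 0} with
#' value \eqn{\sigma^2_{test}} -- regardless of the outputs and of where the
#' training inputs lie.
#'
#' @param X training inputs (n x 1 matrix or numeric vector).
#' @param noise_var_train positive training-noise variance.
#' @param noise_var_test non-negative test-noise variance.
#' @param xstar numeric vector of test inputs.
#' @return predictive variance at each `xstar`.
#' @export
linear_variance_closed_form <- function(X, noise_var_train, noise_var_test,
                                        xstar) {
  X <- as_input_matrix(X)
  stopifnot(ncol(X) == 1L, noise_var_train > 0, noise_var_test >= 0)
  s2 <- sum(X[, 1]^2) / noise_var_train   # squared singular value
  as.numeric(xstar)^2 / (s2 + 1) + noise_var_test
}

#' Sliding-window aleatoric variance estimator
#'
#' Estimates the conditional outcome variance \eqn{\sigma^2_{aleatoric}(x_*)}
#' as the sample variance of reference-model residuals whose inputs fall in
#' the half-open window \eqn{[x_* - w/2,\ x_* + w/2)}. Windows holding fewer
#' than `min_points` residuals are flagged `unreliable` and their estimate is
#' set to `NA`: where data are sparse the local variance cannot be estimated
#' honestly, and the flag is propagated rather than papered over by
#' extrapolation.
#'
#' @param x numeric vector of training inputs (1-D).
#' @param residuals numeric vector of residuals `y - y_reference` at `x`.
#' @param xstar numeric vector of evaluation locations.
#' @param window window width; defaults to one tenth of the input range.
#' @param min_points minimum residual count for a trustworthy estimate.
#' @return an object of class `"aleatoric_estimate"`: a data frame with
#'   columns `x`, `var` (NA where unreliable), `n_window`, `unreliable`, and
#'   attributes `window`/`min_points`.
#' @export
estimate_aleatoric_sliding_window <- function(x, residuals, xstar,
                                              window = diff(range(x)) / 10,
                                              min_points = 20) {
  stopifnot(length(x) == length(residuals), window > 0, min_points >= 2)
  ord <- order(x)
  xs <- x[ord]; rs <- residuals[ord]
  lo <- findInterval(xstar - window / 2, xs, left.open = TRUE) + 1L
  hi <- findInterval(xstar + window / 2, xs, left.open = TRUE)
  n_win <- pmax(hi - lo + 1L, 0L)
  v <- vapply(seq_along(xstar), function(i) {
    if (n_win[i] < min_points) return(NA_real_)
    stats::var(rs[lo[i]:hi[i]])
  }, numeric(1))
  out <- data.frame(x = as.numeric(xstar), var = v, n_window = n_win,
                    unreliable = n_win < min_points)
  attr(out, "window") <- window
  attr(out, "min_points") <- min_points
  class(out) <- c("aleatoric_estimate", "data.frame")
  out
}

#' Decompose predictive uncertainty into epistemic and aleatoric parts
#'
#' Extends the GPR predictive variance into a usable normative-model variance
#' by adding an aleatoric term:
#' \deqn{Var(y_*|x_*) = \underbrace{\Sigma^2_*(x_*)}_{epistemic}
#'   + \underbrace{\sigma^2_{aleatoric}(x_*)}_{aleatoric}.}
#' The epistemic part is the GPR predictive variance at `xstar`; the
#' aleatoric part comes from an external estimator such as
#' [estimate_aleatoric_sliding_window()]. When the observations `y` at
#' `xstar` are supplied, residuals against the posterior mean and both
#' flavours of z-score are included: `z_gpr_only` divides by the GPR standard
#' deviation alone (the naive score, valid only when the GPR variance happens
#' to track \eqn{Var(y|x)}), and `z_corrected` divides by the square root of
#' the decomposed total.
#'
#' @param model a `"gpr"` fit.
#' @param xstar evaluation inputs (1-D).
#' @param aleatoric an `"aleatoric_estimate"` aligned with `xstar`, a numeric
#'   vector (length 1 or `length(xstar)`), or `NULL` for zero aleatoric
#'   variance. Negative values are an error. `NA` entries mark unreliable
#'   locations and propagate into `total_var` and `z_corrected`.
#' @param y optional observations at `xstar` for residuals and z-scores.
#' @param include_noise logical, passed to [predict_var()]: whether the
#'   epistemic term keeps the test-noise diagonal. Keep `TRUE` when the noise
#'   level is a genuine known observation noise; set `FALSE` when a fitted
#'   noise hyperparameter has absorbed the residual variance, otherwise the
#'   aleatoric contribution would be counted twice.
#' @return an object of class `"normative_result"`: a data frame with columns
#'   `x`, `y`, `y_reference`, `epistemic_var`, `aleatoric_var`, `total_var`,
#'   `z_gpr_only`, `z_corrected`, `unreliable`.
#' @export
decompose_uncertainty <- function(model, xstar, aleatoric = NULL, y = NULL,
                                  include_noise = TRUE) {
  stopifnot(inherits(model, "gpr"))
  xs <- as.numeric(as_input_matrix(xstar))
  m <- length(xs)
  epistemic <- predict_var(model, xs, include_noise = include_noise)
  # the naive score always divides by the full GPR predictive variance,
  # noise diagonal included -- that is the practice under examination
  naive_var <- if (include_noise) epistemic else
    predict_var(model, xs, include_noise = TRUE)
  if (is.null(aleatoric)) {
    alea <- rep(0, m); unrel <- rep(FALSE, m)
  } else if (inherits(aleatoric, "aleatoric_estimate")) {
    if (nrow(aleatoric) != m)
      stop("aleatoric estimate is not aligned with xstar")
    alea <- aleatoric$var
    unrel <- aleatoric$unreliable
  } else {
    alea <- rep_len(as.numeric(aleatoric), m)
    unrel <- is.na(alea)
  }
  if (any(alea < 0, na.rm = TRUE))
    stop("negative aleatoric variance estimate")
  total <- epistemic + alea
  mu <- predict(model, xs)
  res <- data.frame(x = xs,
                    y = if (is.null(y)) NA_real_ else as.numeric(y),
                    y_reference = mu,
                    epistemic_var = epistemic,
                    aleatoric_var = alea,
                    total_var = total,
                    z_gpr_only = NA_real_,
                    z_corrected = NA_real_,
                    unreliable = unrel)
  if (!is.null(y)) {
    r <- res$y - mu
    res$z_gpr_only <- z_from(r, naive_var)
    res$z_corrected <- z_from(r, total)
  }
  class(res) <- c("normative_result", "data.frame")
  res
}

z_from <- function(residual, variance) {
  z <- rep(NA_real_, length(residual))
  ok <- !is.na(variance)
  if (any(variance[ok] <= 0))
    stop("z-score undefined where the chosen variance is zero")
  z[ok] <- residual[ok] / sqrt(variance[ok])
  z
}

#' Extract z-scores from a normative result
#'
#' @param result a `"normative_result"`.
#' @param use `"gpr_variance_only"` reproduces the naive score that divides
#'   residuals by the GPR predictive standard deviation -- a normalized
#'   deviation only when the GPR variance happens to match `Var(y|x)`;
#'   `"decomposed_total"` uses the epistemic + aleatoric total.
#' @return numeric vector of z-scores (NA at unreliable locations).
#' @export
z_scores <- function(result, use = c("decomposed_total", "gpr_variance_only")) {
  stopifnot(inherits(result, "normative_result"))
  use <- match.arg(use)
  if (use == "gpr_variance_only") result$z_gpr_only else result$z_corrected
}

#' @export
print.normative_result <- function(x, ...) {
  cat(sprintf("normative_result: %d locations, %d unreliable\n",
              nrow(x), sum(x$unreliable)))
  cat(sprintf("  mean epistemic var %.4g, mean aleatoric var %.4g\n",
              mean(x$epistemic_var), mean(x$aleatoric_var, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Write a normative result table
#'
#' Tab-separated export with columns `x, y, y_reference, epistemic_var,
#' aleatoric_var, total_var, z_gpr_only, z_corrected, unreliable_flag`.
#'
#' @param result a `"normative_result"`.
#' @param path output file.
#' @export
write_normative <- function(result, path) {
  stopifnot(inherits(result, "normative_result"))
  out <- as.data.frame(result)
  names(out)[names(out) == "unreliable"] <- "unreliable_flag"
  out$unreliable_flag <- as.integer(out$unreliable_flag)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
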