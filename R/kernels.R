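#' Covariance (kernel) functions
#'
#' Constructors for the covariance functions used throughout the package.
#' A kernel is a list of class `"gpr_kernel"` holding its kind and
#' hyperparameters; [kernel_eval()] evaluates it on a pair of points and
#' [kernel_gram()] builds Gram matrices.
#'
#' The available kinds are:
#' \describe{
#'   \item{linear}{\eqn{k(x_1, x_2) = x_1 \cdot x_2} (non-stationary; the
#'     feature map is the identity).}
#'   \item{rbf}{\eqn{k(x_1, x_2) = \exp(-\|x_1 - x_2\|^2 / (2 l^2))} with
#'     length-scale \eqn{l > 0}.}
#'   \item{matern}{Matern covariance with smoothness \eqn{\nu > 0} and
#'     length-scale \eqn{l}; closed forms are used for
#'     \eqn{\nu \in \{0.5, 1.5, 2.5\}} and the gamma/Bessel form otherwise.
#'     As \eqn{\nu \to \infty} it approaches the RBF kernel.}
#'   \item{rational_quadratic}{\eqn{(1 + \|x_1-x_2\|^2/(2\alpha l^2))^{-\alpha}},
#'     a scale mixture of RBF kernels; \eqn{\alpha \to \infty} recovers RBF.}
#'   \item{white}{iid observation noise: contributes `noise_variance` to the
#'     self-covariance of a point and 0 between distinct points. Identity is
#'     declared structurally (see [kernel_gram()]'s `same` flag), never by
#'     floating-point coordinate comparison.}
#'   \item{weighted_sum}{a non-negatively weighted sum of kernels; any such
#'     sum of valid kernels is itself a valid kernel.}
#' }
#'
#' @param l positive length-scale.
#' @param nu positive Matern smoothness.
#' @param alpha positive rational-quadratic mixture parameter.
#' @param noise_variance non-negative white-noise variance.
#' @param ... for [sum_kernel()], kernels to combine.
#' @param weights non-negative weights, one per component.
#' @return an object of class `"gpr_kernel"`.
#' @examples
#' k <- rbf_kernel(l = 1)
#' kernel_eval(k, 0, 2)            # exp(-2)
#' kernel_gram(k, matrix(0:2), same = TRUE)
#' @name kernels
NULL

new_kernel <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "gpr_kernel")
}

#' @rdname kernels
#' @export
linear_kernel <- function() new_kernel("linear")

#' @rdname kernels
#' @export
rbf_kernel <- function(l = 1) {
  stopifnot(is.numeric(l), length(l) == 1L, l > 0)
  new_kernel("rbf", l = l)
}

#' @rdname kernels
#' @export
matern_kernel <- function(l = 1, nu = 1.5) {
  stopifnot(is.numeric(l), length(l) == 1L, l > 0,
            is.numeric(nu), length(nu) == 1L, nu > 0)
  new_kernel("matern", l = l, nu = nu)
}

#' @rdname kernels
#' @export
rq_kernel <- function(l = 1, alpha = 1) {
  stopifnot(is.numeric(l), length(l) == 1L, l > 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  new_kernel("rational_quadratic", l = l, alpha = alpha)
}

#' @rdname kernels
#' @export
white_kernel <- function(noise_variance) {
  stopifnot(is.numeric(noise_variance), length(noise_variance) == 1L,
            noise_variance >= 0)
  new_kernel("white", noise_variance = noise_variance)
}

#' @rdname kernels
#' @export
sum_kernel <- function(..., weights = NULL) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1]]) &&
      !inherits(comps[[1]], "gpr_kernel")) {
    comps <- comps[[1]]
  }
  stopifnot(length(comps) >= 1L,
            all(vapply(comps, inherits, logical(1), "gpr_kernel")))
  if (is.null(weights)) weights <- rep(1, length(comps))
  stopifnot(length(weights) == length(comps), all(weights >= 0))
  new_kernel("weighted_sum", components = comps, weights = as.numeric(weights))
}

#' Hybrid linear + RBF + white kernel
#'
#' The kernel used in the unknown-noise scenario:
#' \deqn{k(x_1,x_2) = w_{lin}\, x_1 x_2^T + w_{rbf}\, e^{-\|x_1-x_2\|^2/(2l^2)}
#'   + k_{white}(x_1,x_2),}
#' where the white component carries the iid observation-noise variance and
#' appears only on the training/test self-covariance blocks (never between
#' training and test points).
#'
#' @param w_linear,w_rbf non-negative component weights.
#' @param l positive RBF length-scale.
#' @param noise_variance non-negative observation-noise variance.
#' @return a `"gpr_kernel"` of kind `weighted_sum`.
#' @export
hybrid_kernel <- function(w_linear, w_rbf, l, noise_variance) {
  sum_kernel(linear_kernel(), rbf_kernel(l), white_kernel(noise_variance),
             weights = c(w_linear, w_rbf, 1))
}

#' @export
print.gpr_kernel <- function(x, ...) {
  cat(format_kernel(x), sep = "\n")
  invisible(x)
}

format_kernel <- function(k, indent = "") {
  pars <- switch(k$kind,
    linear = "",
    rbf = sprintf("(l = %g)", k$l),
    matern = sprintf("(l = %g, nu = %g)", k$l, k$nu),
    rational_quadratic = sprintf("(l = %g, alpha = %g)", k$l, k$alpha),
    white = sprintf("(noise_variance = %g)", k$noise_variance),
    weighted_sum = "")
  head <- paste0(indent, k$kind, " kernel ", pars)
  if (k$kind == "weighted_sum") {
    sub <- unlist(mapply(function(w, comp) {
      c(paste0(indent, "  weight ", format(w, digits = 4), " *"),
        format_kernel(comp, paste0(indent, "    ")))
    }, k$weights, k$components, SIMPLIFY = FALSE))
    c(head, sub)
  } else head
}

#' Evaluate a kernel on a pair of points
#'
#' @param kernel a `"gpr_kernel"`.
#' @param x1,x2 numeric vectors of equal length (a single point each).
#' @param same logical; `TRUE` declares that `x1` and `x2` are the *same*
#'   observation, which is the only case in which a white component
#'   contributes. Point identity is a property of the data layout, not of
#'   coordinates, so it is declared, not inferred.
#' @return the scalar covariance \eqn{k(x_1, x_2)}.
#' @export
kernel_eval <- function(kernel, x1, x2, same = FALSE) {
  stopifnot(inherits(kernel, "gpr_kernel"))
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  if (length(x1) != length(x2))
    stop("x1 and x2 must have the same dimension")
  switch(kernel$kind,
    linear = sum(x1 * x2),
    rbf = exp(-sum((x1 - x2)^2) / (2 * kernel$l^2)),
    matern = matern_cov(sqrt(sum((x1 - x2)^2)), kernel$l, kernel$nu),
    rational_quadratic =
      (1 + sum((x1 - x2)^2) / (2 * kernel$alpha * kernel$l^2))^(-kernel$alpha),
    white = if (same) kernel$noise_variance else 0,
    weighted_sum = sum(kernel$weights *
      vapply(kernel$components, kernel_eval, numeric(1),
             x1 = x1, x2 = x2, same = same)),
    stop("unknown kernel kind: ", kernel$kind))
}

# Matern covariance as a function of distance r >= 0. Closed forms for the
# half-integer orders used in practice; gamma/Bessel otherwise. r = 0 returns
# the limit value 1 exactly (the general formula is 0 * Inf there).
matern_cov <- function(r, l, nu) {
  out <- numeric(length(r))
  zero <- r <= 0
  out[zero] <- 1
  r <- r[!zero]
  if (length(r)) {
    val <- if (nu == 0.5) {
      exp(-r / l)
    } else if (nu == 1.5) {
      s <- sqrt(3) * r / l
      (1 + s) * exp(-s)
    } else if (nu == 2.5) {
      s <- sqrt(5) * r / l
      (1 + s + s^2 / 3) * exp(-s)
    } else {
      s <- sqrt(2 * nu) * r / l
      2^(1 - nu) / gamma(nu) * s^nu * besselK(s, nu)
    }
    # besselK underflows to 0 for large arguments; the kernel limit is 0 too,
    # so NaN from 0 * Inf patterns is mapped to 0.
    val[!is.finite(val)] <- 0
    out[!zero] <- val
  }
  out
}

#' Gram matrix of a kernel
#'
#' Pairwise covariance matrix between the rows of `X1` and `X2`. Stationary
#' kernels are evaluated vectorised on the distance matrix.
#'
#' @param kernel a `"gpr_kernel"`.
#' @param X1 numeric matrix (n x d), one point per row.
#' @param X2 numeric matrix (m x d); defaults to `X1`.
#' @param same logical; `TRUE` declares that `X1` and `X2` are the same set of
#'   observations in the same order, so a white component contributes its
#'   variance on the diagonal. The cross-covariance between training and test
#'   blocks is built with `same = FALSE`, where white contributes zero.
#' @return an n x m covariance matrix.
#' @export
kernel_gram <- function(kernel, X1, X2 = X1, same = missing(X2)) {
  stopifnot(inherits(kernel, "gpr_kernel"))
  X1 <- as_input_matrix(X1); X2 <- as_input_matrix(X2)
  if (ncol(X1) != ncol(X2))
    stop("X1 and X2 must have the same number of columns")
  if (same && nrow(X1) != nrow(X2))
    stop("'same = TRUE' requires X1 and X2 to be the same set of points")
  n <- nrow(X1); m <- nrow(X2)
  # cancellation in the squared-distance expansion can leave O(eps) residue
  # on the diagonal of a self-Gram; identical observations are exactly at
  # distance zero, so force it
  dist2 <- function() {
    D <- sqdist(X1, X2)
    if (same) diag(D) <- 0
    D
  }
  switch(kernel$kind,
    linear = X1 %*% t(X2),
    rbf = exp(-dist2() / (2 * kernel$l^2)),
    matern = matrix(matern_cov(sqrt(dist2()), kernel$l, kernel$nu), n, m),
    rational_quadratic =
      (1 + dist2() / (2 * kernel$alpha * kernel$l^2))^(-kernel$alpha),
    white = if (same) diag(kernel$noise_variance, n) else matrix(0, n, m),
    weighted_sum = {
      K <- matrix(0, n, m)
      for (i in seq_along(kernel$components)) {
        w <- kernel$weights[i]
        if (w > 0)
          K <- K + w * kernel_gram(kernel$components[[i]], X1, X2, same = same)
      }
      K
    },
    stop("unknown kernel kind: ", kernel$kind))
}

# squared Euclidean distances between rows; clipped at 0 against cancellation
sqdist <- function(X1, X2) {
  D <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
  pmax(D, 0)
}

as_input_matrix <- function(X) {
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("inputs must be finite")
  X
}

#' Truncated explicit feature map of the 1-D RBF kernel
#'
#' The RBF kernel is an inner product in an infinite-dimensional feature
#' space. In one dimension the coordinates factorise as
#' \deqn{z_j(x) = e^{-x^2/(2l^2)} \frac{x^j}{l^j \sqrt{j!}}, \quad j = 0, 1, \dots}
#' so that \eqn{\sum_j z_j(x_1) z_j(x_2) = e^{-(x_1-x_2)^2/(2l^2)}}. Truncating
#' at order `J` gives a finite map whose inner products converge to the kernel
#' as `J` grows; with `J = 40` the truncation error is below 1e-10 for
#' \eqn{|x| \le \pi}, `l = 1`. Used as a verification oracle for the SVD
#' variance form; only the 1-D specialisation is implemented.
#'
#' @param x numeric vector of scalar inputs.
#' @param l positive length-scale.
#' @param J truncation order (highest power retained); non-negative integer.
#' @return a `length(x)` x `(J + 1)` matrix of feature coordinates. Terms are
#'   accumulated in log space to avoid overflow of `x^j / sqrt(j!)`.
#' @export
rbf_feature_map_1d <- function(x, l = 1, J = 40) {
  stopifnot(is.numeric(x), l > 0, J >= 0, J == round(J))
  x <- as.numeric(x)
  j <- 0:J
  # log |x|^j / (l^j sqrt(j!)); sign handled separately so x < 0 works
  logmag <- outer(log(abs(x)), j) - outer(rep(log(l), length(x)), j) -
    rep(0.5 * lgamma(j + 1), each = length(x))
  Z <- exp(-x^2 / (2 * l^2)) * sign(x)^rep(j, each = length(x)) * exp(logmag)
  Z[x == 0, ] <- 0
  Z[x == 0, 1] <- 1
  Z[, 1] <- exp(-x^2 / (2 * l^2))  # j = 0 term: 0^0 = 1
  Z
}

#' Read and write kernel configurations
#'
#' Kernels serialise to a small YAML document (kind plus hyperparameters,
#' nested components for weighted sums) so that an analysis configuration can
#' live next to its outputs. `kernel_to_yaml()` / `kernel_from_yaml()`
#' round-trip exactly.
#'
#' @param kernel a `"gpr_kernel"`.
#' @param path file to write to / read from; `kernel_to_yaml()` returns the
#'   YAML string invisibly and writes only when `path` is given.
#' @return `kernel_from_yaml()` returns a `"gpr_kernel"`.
#' @export
kernel_to_yaml <- function(kernel, path = NULL) {
  stopifnot(inherits(kernel, "gpr_kernel"))
  txt <- yaml::as.yaml(kernel_to_list(kernel))
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

kernel_to_list <- function(k) {
  out <- unclass(k)
  if (k$kind == "weighted_sum") {
    out$components <- lapply(k$components, kernel_to_list)
    out$weights <- as.list(out$weights)  # keep length-1 lists stable in YAML
  }
  out
}

#' @rdname kernel_to_yaml
#' @param text YAML string, as an alternative to `path`.
#' @export
kernel_from_yaml <- function(path = NULL, text = NULL) {
  spec <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  kernel_from_list(spec)
}

kernel_from_list <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  switch(spec$kind,
    linear = linear_kernel(),
    rbf = rbf_kernel(l = spec$l),
    matern = matern_kernel(l = spec$l, nu = spec$nu),
    rational_quadratic = rq_kernel(l = spec$l, alpha = spec$alpha),
    white = white_kernel(noise_variance = spec$noise_variance),
    weighted_sum = sum_kernel(lapply(spec$components, kernel_from_list),
                              weights = unlist(spec$weights)),
    stop("unknown kernel kind: ", spec$kind))
}
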