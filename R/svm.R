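#' Specification of the maximum-margin classifier
#'
#' A soft-margin SVM with polynomial kernel `K(x, y) = (x'y + c)^d`,
#' degrees 1 to 5 (degree 1 is the linear kernel; 5 is the cap, guarding
#' against overfitting), trained by sequential minimal optimisation with a
#' large iteration budget (default 1e7) to allow convergence. Kernel
#' offset `c = 1` and margin penalty `C = 1` are the defaults of the
#' reference implementation the method was built on, and training columns
#' are standardized to zero mean / unit variance by default (applied to
#' test points with the training transform).
#'
#' @param degree polynomial degree, integer in 1..5.
#' @param coef0 kernel offset c (default 1).
#' @param cost margin penalty C (> 0, default 1).
#' @param tol KKT violation tolerance of the solver.
#' @param max_iter iteration budget of the SMO solver.
#' @param standardize standardize columns per training set?
#' @return An `svm_spec` list.
#' @export
svm_spec <- function(degree = 1, coef0 = 1, cost = 1, tol = 1e-3,
                     max_iter = 1e7, standardize = TRUE) {
  if (!degree %in% 1:5) stop("`degree` must be an integer in 1..5")
  if (cost <= 0) stop("`cost` must be > 0")
  structure(list(degree = as.integer(degree), coef0 = coef0, cost = cost,
                 tol = tol, max_iter = max_iter,
                 standardize = isTRUE(standardize)),
            class = "svm_spec")
}

#' Polynomial kernel matrix
#'
#' @param X,Y numeric matrices with matching column count.
#' @param degree polynomial degree.
#' @param coef0 kernel offset.
#' @return `nrow(X)` x `nrow(Y)` kernel matrix `(X Y' + coef0)^degree`.
#' @export
poly_kernel <- function(X, Y, degree, coef0 = 1) {
  (tcrossprod(as.matrix(X), as.matrix(Y)) + coef0)^degree
}

#' Train a polynomial-kernel SVM
#'
#' Fits the soft-margin dual by SMO. Non-convergence within the iteration
#' budget is reported via a warning and the `converged` flag, never
#' silently ignored.
#'
#' @param X numeric training matrix (rows = patients).
#' @param y labels in \{+1, -1\}.
#' @param spec an [svm_spec()].
#' @return A `cis_svm` model (support coefficients, intercept,
#'   standardization transform, training data reference).
#' @export
svm_train <- function(X, y, spec = svm_spec()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  if (spec$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale <= 0] <- 1   # zero-variance guard
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  K <- poly_kernel(Z, Z, spec$degree, spec$coef0)
  fit <- smo_solve_cpp(K, y, spec$cost, spec$tol, spec$max_iter)
  if (!fit$converged)
    warning("SMO did not converge within ", format(spec$max_iter),
            " iterations", call. = FALSE)
  structure(list(alpha = fit$alpha, b = fit$b, y = y, Z = Z,
                 center = center, scale = scale, spec = spec,
                 converged = fit$converged, iterations = fit$iterations),
            class = "cis_svm")
}

#' Predict from a trained SVM
#'
#' The decision value is `f(x) = sum_i alpha_i y_i K(x_i, x) + b`;
#' `f(x) > 0` predicts converter (+1). A decision value of exactly 0 is
#' classified as non-converter (-1) — the deterministic, conservative
#' tie rule (no second attack predicted).
#'
#' @param object a `cis_svm`.
#' @param newdata numeric matrix of test rows.
#' @param type `"class"` for +1/-1 labels, `"decision"` for raw values.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.cis_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(newdata), ncol = length(object$center))
  Zt <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  K <- poly_kernel(Zt, object$Z, object$spec$degree, object$spec$coef0)
  f <- as.vector(K %*% (object$alpha * object$y)) + object$b
  if (type == "decision") f else ifelse(f > 0, 1, -1)
}

#' @export
print.cis_svm <- function(x, ...) {
  cat(sprintf("<cis_svm> degree %d, C = %g, %d support vectors, %s\n",
              x$spec$degree, x$spec$cost, sum(x$alpha > 1e-8),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
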