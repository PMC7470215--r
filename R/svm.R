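#' Linear support vector machine (squared hinge loss)
#'
#' Trains an L2-regularized squared-hinge linear SVM
#' `min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (w'x_i + b))^2`
#' by dual coordinate descent (compiled). The bias enters through an
#' augmented constant feature and is therefore regularized along with `w`
#' (the standard choice for dual solvers). The squared hinge keeps the
#' primal smooth, so fits can be verified against direct numerical
#' minimization, while the weight vector behaves like the classic hinge
#' SVM's for feature-ranking purposes.
#'
#' @param x numeric matrix (rows = observations). Standardize beforehand;
#'   no scaling is done here.
#' @param y two-valued vector; the first of `sort(unique(y))` maps to -1,
#'   the second to +1 (or pass `positive` explicitly).
#' @param C cost parameter (default 1).
#' @param positive value of `y` mapped to +1; default the larger of the
#'   two sorted unique values.
#' @param tol convergence tolerance on the projected gradient (default 1e-4).
#' @param max_iter maximum epochs (default 200).
#' @param seed integer seed for the coordinate permutation (default 1;
#'   fits are bit-reproducible and do not touch R's RNG).
#' @return object of class `"linear_svm"`: `w`, `b`, `levels`
#'   (`c(negative, positive)`), `C`, `converged`.
#' @export
linear_svm <- function(x, y, C = 1, positive = NULL,
                       tol = 1e-4, max_iter = 200, seed = 1L) {
  x <- as.matrix(x)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("y must take exactly two values")
  if (is.null(positive)) positive <- lev[2]
  neg <- setdiff(lev, positive)
  yy <- ifelse(y == positive, 1, -1)
  fit <- svm_dcd_fit(x, as.numeric(yy), C, tol, as.integer(max_iter),
                     1.0, as.integer(seed))
  structure(list(w = setNames(as.numeric(fit$w), colnames(x)),
                 b = fit$b, levels = c(neg, positive), C = C,
                 converged = fit$converged),
            class = "linear_svm")
}

#' Decision values of a linear SVM
#'
#' @param object a `"linear_svm"`.
#' @param x feature matrix on the same scale as training.
#' @return numeric vector `x %*% w + b`; positive means the positive class.
#' @export
decision_values <- function(object, x) {
  as.numeric(as.matrix(x) %*% object$w + object$b)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  d <- decision_values(object, newdata)
  ifelse(d > 0, object$levels[2], object$levels[1])
}
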