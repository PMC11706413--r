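#' Variance-scaled RBF bandwidth
#'
#' The automatic gamma rule `gamma = 1 / (n_features * Var(X))`, where
#' `Var(X)` is the population variance of all entries of `X` pooled. Scaling
#' the data by `s` scales gamma by `1/s^2`, so the kernel adapts to the
#' input scale.
#'
#' @param X Sample x feature numeric matrix, not constant.
#' @return A positive scalar gamma.
#' @export
auto_gamma <- function(X) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  v <- mean((X - mean(X))^2)
  if (v <= 0) stop("pooled variance is zero; gamma is undefined", call. = FALSE)
  1 / (ncol(X) * v)
}

#' RBF kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`, in `(0, 1]` with `K(x, x) = 1`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive bandwidth parameter.
#' @return Kernel value.
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  exp(-gamma * sum((x - y)^2))
}

# Cross kernel matrix K[i, j] = rbf_kernel(A[i, ], B[j, ], gamma), vectorized.
rbf_kernel_matrix <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Platt sigmoid calibration with smoothed targets: fits P(y = 1 | d) =
# plogis(a + b * d) by minimizing cross-entropy against targets
# (N+ + 1)/(N+ + 2) and 1/(N- + 2), which keeps the fit finite even on
# separable data.
platt_fit <- function(d, y) {
  np <- sum(y == 1); nn <- sum(y == 0)
  t <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  obj <- function(par) {
    p <- stats::plogis(par[1] + par[2] * d)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- stats::optim(c(0, 1), obj, method = "BFGS")
  c(a = fit$par[1], b = fit$par[2])
}

# Decision values oriented so that larger values favour class "1".
# e1071 names the decision column "<first>/<second>" with positive values
# favouring the first class.
svm_decision_oriented <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (startsWith(colnames(dv)[1], "1/")) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

#' Train a soft-margin RBF support vector classifier
#'
#' Fits the SVM on the LSTM's penultimate features (or any sample x feature
#' matrix) with the RBF kernel at `gamma = auto_gamma(features)` unless a
#' gamma is supplied. Class probabilities come from a Platt sigmoid fit on
#' decision values from a seeded internal cross-validation (in-sample when a
#' class has fewer members than folds). Prediction re-evaluates the kernel
#' expansion `sum_i alpha_i y_i K(s_i, x) + b` directly from the stored
#' support vectors, so the fitted model is a plain, serializable list.
#'
#' @param features Sample x feature numeric matrix.
#' @param y 0/1 labels; both classes must be present.
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF bandwidth; default `auto_gamma(features)`.
#' @param calib_folds Folds for the calibration cross-validation (default 3).
#' @param seed Seed for the calibration fold assignment (default 1).
#' @return An object of class `rbf_svm`: support vectors `SV`, signed dual
#'   coefficients `coefs`, intercept `rho`, `gamma`, orientation `pos_sign`
#'   (+1 if positive raw decision values favour class 1), and Platt
#'   parameters `platt`.
#' @export
train_rbf_svm <- function(features, y, cost = 1, gamma = NULL,
                          calib_folds = 3, seed = 1L) {
  stopifnot(is.matrix(features))
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  y <- as.integer(y)
  if (is.null(gamma)) gamma <- auto_gamma(features)
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(features, yf, scale = FALSE, kernel = "radial",
                    gamma = gamma, cost = cost)
  dv_first <- attr(stats::predict(fit, features[1, , drop = FALSE],
                                  decision.values = TRUE), "decision.values")
  pos_sign <- if (startsWith(colnames(dv_first)[1], "1/")) 1 else -1

  # calibration decision values: held-out where class sizes allow
  if (min(table(y)) >= calib_folds && calib_folds >= 2) {
    set.seed(seed)
    fold <- stats::ave(seq_along(y), y, FUN = function(ix) {
      sample(rep_len(seq_len(calib_folds), length(ix)))
    })
    d_cal <- numeric(length(y))
    for (f in seq_len(calib_folds)) {
      te <- fold == f
      sub <- e1071::svm(features[!te, , drop = FALSE], yf[!te], scale = FALSE,
                        kernel = "radial", gamma = gamma, cost = cost)
      d_cal[te] <- svm_decision_oriented(sub, features[te, , drop = FALSE])
    }
  } else {
    d_cal <- svm_decision_oriented(fit, features)
  }
  platt <- platt_fit(d_cal, y)

  structure(list(SV = fit$SV, coefs = as.numeric(fit$coefs), rho = fit$rho,
                 gamma = gamma, pos_sign = pos_sign, platt = platt,
                 cost = cost, n_features = ncol(features)),
            class = "rbf_svm")
}

#' Predict with a trained RBF SVM
#'
#' @param model An [train_rbf_svm()] fit.
#' @param X Sample x feature matrix with the training dimensionality.
#' @return List with `decision` (oriented decision values, larger = more
#'   case-like), `prob` (calibrated positive-class probabilities, clamped to
#'   the open interval (0, 1)), and `label` (0/1 at the 0.5 probability
#'   threshold).
#' @export
predict_rbf_svm <- function(model, X) {
  stopifnot(inherits(model, "rbf_svm"), is.matrix(X))
  if (ncol(X) != model$n_features) {
    stop(sprintf("X has %d features but the SVM expects %d", ncol(X), model$n_features),
         call. = FALSE)
  }
  K <- rbf_kernel_matrix(X, model$SV, model$gamma)
  raw <- as.numeric(K %*% model$coefs) - model$rho
  d <- model$pos_sign * raw
  p <- stats::plogis(model$platt["a"] + model$platt["b"] * d)
  p <- pmin(pmax(as.numeric(p), 1e-7), 1 - 1e-7)
  list(decision = d, prob = p, label = as.integer(p >= 0.5))
}
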