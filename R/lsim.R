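#' Fit the LSIM hybrid classifier
#'
#' Trains the LSTM with a softmax head on the min-max-normalized selected
#' taxa, extracts each training sample's penultimate (final hidden) vector,
#' and fits the RBF SVM on those vectors with the variance-scaled gamma.
#' The two components give two probability readings per sample that the
#' pipeline later fuses by soft voting.
#'
#' @param train A [labeled_dataset()] whose `X` is already normalized to
#'   `[0, 1]`.
#' @param epochs,lr,batch,hidden Passed to [train_lstm_classifier()].
#' @param cost SVM soft-margin cost (default 1).
#' @param seed Mandatory seed covering initialization, shuffling and the
#'   SVM calibration.
#' @return An object of class `lsim_model`: `lstm` (trained
#'   [lstm_parameters()]), `svm` ([train_rbf_svm()] fit), `feature_names`.
#' @export
lsim_fit <- function(train, epochs = 300, lr = 0.001, batch = 6, hidden = 32,
                     cost = 1, seed) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  lstm <- train_lstm_classifier(train$X, train$y, epochs = epochs, lr = lr,
                                batch = batch, hidden = hidden, seed = seed)
  pen <- extract_penultimate_features(lstm, train$X)
  svm <- train_rbf_svm(pen, train$y, cost = cost, seed = seed)
  structure(list(lstm = lstm, svm = svm, feature_names = train$feature_names),
            class = "lsim_model")
}

#' @export
print.lsim_model <- function(x, ...) {
  cat(sprintf("<lsim_model> D = %d taxa, H = %d, SVM: %d support vectors, gamma = %.4g\n",
              x$lstm$D, x$lstm$H, nrow(x$svm$SV), x$svm$gamma))
  invisible(x)
}

#' Predict case probabilities with an LSIM model
#'
#' Returns both voters' positive-class probabilities per sample: the LSTM
#' softmax output and the calibrated SVM output on the penultimate features.
#' Inputs must carry exactly the feature names, in the order, the model was
#' fitted on.
#'
#' @param model An [lsim_fit()] result.
#' @param X Sample x feature matrix, normalized with the training fold's
#'   min-max ranges.
#' @return List with numeric vectors `p_lstm` and `p_svm` (length
#'   `nrow(X)`, entries in `[0, 1]`).
#' @export
lsim_predict_proba <- function(model, X) {
  stopifnot(inherits(model, "lsim_model"), is.matrix(X))
  if (is.null(colnames(X)) || !identical(colnames(X), model$feature_names)) {
    stop("feature names/order of X differ from the model's feature_names", call. = FALSE)
  }
  p_lstm <- lstm_predict_proba(model$lstm, X)
  pen <- extract_penultimate_features(model$lstm, X)
  p_svm <- predict_rbf_svm(model$svm, pen)$prob
  list(p_lstm = p_lstm, p_svm = p_svm)
}

LSIM_SCHEMA_VERSION <- 1L

#' Serialize an LSIM model to JSON
#'
#' Writes every component needed for prediction — LSTM weights, softmax
#' head, SVM support vectors and dual coefficients, gamma, Platt
#' calibration, feature names and optional min-max ranges — under a
#' versioned schema.
#'
#' @param model An `lsim_model`.
#' @param path Output path.
#' @param ranges Optional 2 x feature min-max matrix from
#'   [minmax_normalize()] to store alongside the model.
#' @return `path`, invisibly.
#' @export
write_lsim <- function(model, path, ranges = NULL) {
  stopifnot(inherits(model, "lsim_model"))
  lstm <- model$lstm
  obj <- list(
    schema_version = LSIM_SCHEMA_VERSION,
    feature_names = model$feature_names,
    lstm = list(
      D = lstm$D, H = lstm$H,
      W_f = lstm$W_f, W_i = lstm$W_i, W_o = lstm$W_o, W_c = lstm$W_c,
      b_f = lstm$b_f, b_i = lstm$b_i, b_o = lstm$b_o, b_c = lstm$b_c,
      W_y = lstm$W_y, b_y = lstm$b_y
    ),
    svm = list(
      SV = model$svm$SV, coefs = model$svm$coefs, rho = model$svm$rho,
      gamma = model$svm$gamma, pos_sign = model$svm$pos_sign,
      platt = as.list(model$svm$platt), cost = model$svm$cost,
      n_features = model$svm$n_features
    ),
    ranges = if (!is.null(ranges)) {
      list(min = ranges["min", ], max = ranges["max", ])
    }
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized LSIM model
#'
#' @param path Path written by [write_lsim()].
#' @return List with `model` (the `lsim_model`) and `ranges` (2 x feature
#'   min-max matrix, or NULL).
#' @export
read_lsim <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != LSIM_SCHEMA_VERSION) {
    stop("unsupported model schema version", call. = FALSE)
  }
  lstm <- structure(c(
    lapply(obj$lstm[c("W_f", "W_i", "W_o", "W_c", "W_y")], as.matrix),
    obj$lstm[c("b_f", "b_i", "b_o", "b_c", "b_y")],
    list(D = obj$lstm$D, H = obj$lstm$H)
  ), class = "lstm_parameters")
  svm <- structure(list(
    SV = as.matrix(obj$svm$SV), coefs = obj$svm$coefs, rho = obj$svm$rho,
    gamma = obj$svm$gamma, pos_sign = obj$svm$pos_sign,
    platt = unlist(obj$svm$platt), cost = obj$svm$cost,
    n_features = obj$svm$n_features
  ), class = "rbf_svm")
  ranges <- NULL
  if (!is.null(obj$ranges)) {
    ranges <- rbind(min = obj$ranges$min, max = obj$ranges$max)
    colnames(ranges) <- obj$feature_names
  }
  model <- structure(list(lstm = lstm, svm = svm,
                          feature_names = obj$feature_names),
                     class = "lsim_model")
  list(model = model, ranges = ranges)
}
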