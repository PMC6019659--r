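## SVM combination of the three probability scores into a
## positive/negative disulfide call. Training goes through e1071 (libsvm);
## prediction re-evaluates the RBF decision function from the stored
## support vectors so that serialized models reproduce predictions
## exactly.

#' Cross-validated accuracy of an RBF-SVM at fixed hyperparameters
#'
#' @param features n x 3 numeric matrix (p_geom, p_rmsd, p_delta_s),
#'   already on a common scale.
#' @param labels Factor or character vector with two classes.
#' @param cost,gamma SVM hyperparameters.
#' @param k Number of folds.
#' @param seed RNG seed controlling fold assignment.
#' @return Mean held-out accuracy across folds.
#' @export
cv_accuracy <- function(features, labels, cost = 1, gamma = 0.1,
                        k = 5, seed = 42) {
  features <- as.matrix(features)
  labels <- factor(labels)
  n <- nrow(features)
  if (n < k) stop_ssf("fewer examples than folds", "ssf_contract_error")
  set.seed(seed)
  ## stratified folds: per-class round-robin assignment after shuffling,
  ## so fold class balance matches the data and held-out accuracy under
  ## a permutation null is centred on chance
  fold <- integer(n)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) { acc[f] <- NA; next }
    fit <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    pred <- stats::predict(fit, features[!tr, , drop = FALSE])
    acc[f] <- mean(pred == labels[!tr])
  }
  mean(acc, na.rm = TRUE)
}

#' Train the score-combining SVM
#'
#' Fits an RBF-kernel support vector machine on (p_geom, p_rmsd,
#' p_delta_s) triples after per-feature min-max scaling (scaling
#' constants are stored in the model). Hyperparameters are chosen by
#' k-fold cross-validated grid search with a fixed fold seed, then the
#' model is refitted on the full set.
#'
#' @param features n x 3 numeric matrix or data.frame of score triples.
#' @param labels Vector of labels, coerced to a factor with levels
#'   `positive`, `negative`.
#' @param cost_grid,gamma_grid Hyperparameter grids.
#' @param k Folds for cross-validation (default 5).
#' @param seed Fold-assignment seed.
#' @return Object of class `ssf_classifier`: serializable list with the
#'   support vectors, dual coefficients, rho, kernel parameters, scaling
#'   constants and training metadata (`n`, `class_balance`,
#'   `cv_accuracy`).
#' @export
train_classifier <- function(features, labels,
                             cost_grid = c(0.1, 1, 10, 100),
                             gamma_grid = c(0.01, 0.1, 1, 10),
                             k = 5, seed = 42) {
  features <- as.matrix(features)
  if (ncol(features) != 3L) {
    stop_ssf("features must have 3 columns (p_geom, p_rmsd, p_delta_s)",
             "ssf_contract_error")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    stop_ssf("labels must be 'positive'/'negative'", "ssf_contract_error")
  }
  labels <- factor(labels, levels = c("positive", "negative"))
  tab <- table(labels)
  if (any(tab == 0)) stop_ssf("both classes must be present", "ssf_contract_error")
  if (any(tab < 5)) stop_ssf("need at least 5 examples per class",
                             "ssf_contract_error")
  if (nrow(features) < k) stop_ssf("fewer examples than folds",
                                   "ssf_contract_error")
  ## min-max scaling frozen into the model
  mins <- apply(features, 2, min)
  rngs <- apply(features, 2, max) - mins
  rngs[rngs == 0] <- 1
  X <- sweep(sweep(features, 2, mins), 2, rngs, "/")
  best <- list(acc = -1, cost = cost_grid[1], gamma = gamma_grid[1])
  for (g in gamma_grid) for (cst in cost_grid) {
    a <- cv_accuracy(X, labels, cost = cst, gamma = g, k = k, seed = seed)
    if (a > best$acc + 1e-12) best <- list(acc = a, cost = cst, gamma = g)
  }
  fit <- e1071::svm(X, labels, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  model <- structure(list(
    schema_version = 1L, kernel = "rbf",
    cost = best$cost, gamma = best$gamma,
    sv = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho),
    sign_flip = 1,
    scale_min = as.numeric(mins), scale_range = as.numeric(rngs),
    levels = c("positive", "negative"),
    n = nrow(features),
    class_balance = as.numeric(tab) / nrow(features),
    cv_accuracy = best$acc, seed = seed), class = "ssf_classifier")
  ## pin the decision-value sign convention to libsvm's own predictions
  dec <- rbf_decision(model, X)
  libsvm_lab <- as.character(stats::predict(fit, X))
  agree <- mean((dec > 0) == (libsvm_lab == "positive"))
  if (agree < 0.5) model$sign_flip <- -1
  model
}

## raw RBF decision values for pre-scaled feature rows
rbf_decision <- function(model, X) {
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- rowSums(sweep(model$sv, 2, X[i, ])^2)
    sum(model$coefs * exp(-model$gamma * d2)) - model$rho
  }, numeric(1))
}

#' @export
print.ssf_classifier <- function(x, ...) {
  cat(sprintf(
    "ssf_classifier: RBF SVM, C = %g, gamma = %g, %d SVs, CV accuracy %.3f (n = %d)\n",
    x$cost, x$gamma, nrow(x$sv), x$cv_accuracy, x$n))
  invisible(x)
}

#' Predict with a trained score classifier
#'
#' @param model An `ssf_classifier`.
#' @param triples Numeric 3-vector or n x 3 matrix of score triples on
#'   the original `[0, 1]` scale. Out-of-range values are clipped with a
#'   warning.
#' @return List with `label` (character vector) and `margin` (signed
#'   decision value; positive margin means label `positive`).
#' @export
predict_classifier <- function(model, triples) {
  if (is.null(dim(triples))) triples <- matrix(triples, nrow = 1)
  triples <- as.matrix(triples)
  if (any(!is.finite(triples))) {
    stop_ssf("non-finite features", "ssf_contract_error")
  }
  if (any(triples < 0 | triples > 1)) {
    warning("features outside [0, 1] clipped")
    triples <- pmin(pmax(triples, 0), 1)
  }
  X <- sweep(sweep(triples, 2, model$scale_min), 2, model$scale_range, "/")
  margin <- model$sign_flip * rbf_decision(model, X)
  list(label = ifelse(margin > 0, model$levels[1], model$levels[2]),
       margin = margin)
}

#' Save a classifier to JSON
#' @param model An `ssf_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  ## prediction-critical doubles are serialized as %.17g strings: decimal
  ## JSON numbers lose ulps, and loaded models must predict bit-identically
  exact <- function(x) {
    y <- sprintf("%.17g", x)
    if (is.matrix(x)) dim(y) <- dim(x)
    y
  }
  obj$sv <- exact(unname(as.matrix(obj$sv)))
  for (nm in c("coefs", "rho", "gamma", "scale_min", "scale_range")) {
    obj[[nm]] <- exact(obj[[nm]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a classifier from JSON
#' @param path Path written by [save_model()].
#' @return An `ssf_classifier` whose predictions match the saved model
#'   exactly.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_ssf(paste0("model parse error: ", conditionMessage(e)),
                             "ssf_parse_error"))
  if (is.null(obj$schema_version)) {
    stop_ssf("model parse error: no schema_version", "ssf_parse_error")
  }
  if (obj$schema_version > 1) {
    stop_ssf(sprintf("model schema version %s is newer than supported (1)",
                     obj$schema_version), "ssf_version_error")
  }
  sv <- do.call(rbind, lapply(obj$sv, function(r) as.numeric(unlist(r))))
  structure(list(
    schema_version = as.integer(obj$schema_version), kernel = obj$kernel,
    cost = as.numeric(obj$cost), gamma = as.numeric(obj$gamma),
    sv = sv, coefs = as.numeric(unlist(obj$coefs)),
    rho = as.numeric(obj$rho), sign_flip = as.numeric(obj$sign_flip),
    scale_min = as.numeric(unlist(obj$scale_min)),
    scale_range = as.numeric(unlist(obj$scale_range)),
    levels = as.character(unlist(obj$levels)),
    n = as.integer(obj$n),
    class_balance = as.numeric(unlist(obj$class_balance)),
    cv_accuracy = as.numeric(obj$cv_accuracy),
    seed = as.numeric(obj$seed)), class = "ssf_classifier")
}
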