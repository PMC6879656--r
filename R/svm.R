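#' Classifier specification
#'
#' Encodes the SVM configuration used throughout the pipeline. The defaults
#' reproduce the classic libsvm/e1071 `svm()` defaults for C-classification:
#' RBF kernel, cost 1, gamma = 1/n_features, and z-score feature scaling.
#' Other SVM implementations ship different defaults; results are only
#' comparable under the same spec.
#'
#' @param cost positive soft-margin cost C.
#' @param gamma RBF width; `NULL` (default) means 1/n_features at fit time.
#' @param scale logical; scale each feature to zero mean / unit variance,
#'   with scaling parameters fitted on training data only (per LOOCV fold).
#' @param kernel only `"rbf"` is supported.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(cost = 1, gamma = NULL, scale = TRUE,
                            kernel = "rbf") {
  kernel <- match.arg(kernel, "rbf")
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0)
    stop("`cost` must be a single positive number")
  if (!is.null(gamma) &&
      (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0))
    stop("`gamma` must be NULL or a single positive number")
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 scale = isTRUE(scale)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("classifier_spec: %s kernel, cost = %g, gamma = %s, scale = %s\n",
              x$kernel, x$cost,
              if (is.null(x$gamma)) "1/n_features" else format(x$gamma),
              x$scale))
  invisible(x)
}

# Samples-x-features design matrix and +1/-1 label vector for a gene subset,
# samples sorted by id so results are invariant to input column order.
.design <- function(m, genes) {
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (is.null(m$labels)) stop("labels are required")
  ord <- order(sample_ids(m), method = "radix")
  X <- t(m$values[genes, ord, drop = FALSE])
  y <- ifelse(m$labels[rownames(X)] == "POSITIVE", 1L, -1L)
  list(X = X, y = y)
}

.fit_scaling <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

.apply_scaling <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# Train an RBF C-SVC; internal (the public surface is LOOCV / train-and-test).
.svm_fit <- function(X, y, spec) {
  gamma <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
  sc <- if (spec$scale) .fit_scaling(X) else NULL
  Xs <- if (spec$scale) .apply_scaling(X, sc) else X
  fit <- .svm_train_cpp(Xs, y, spec$cost, gamma)
  list(X = Xs, y = y, alpha = drop(fit$alpha), b = fit$b,
       gamma = gamma, scaling = sc)
}

.svm_decision <- function(model, Xnew) {
  if (!is.null(model$scaling)) Xnew <- .apply_scaling(Xnew, model$scaling)
  drop(.svm_decision_cpp(model$X, model$y, model$alpha, model$b,
                         Xnew, model$gamma))
}

# decision value -> predicted label (ties at exactly 0 go to POSITIVE)
.decide <- function(dec) ifelse(dec >= 0, "POSITIVE", "NEGATIVE")
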