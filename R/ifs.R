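#' Confusion matrix for binary classification
#'
#' Counts of predicted vs actual classes with the disease convention: the
#' positive class (COPD in the motivating study) drives TP/FN, the negative
#' class (ILD) drives TN/FP.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion-matrix counts must be non-negative integers")
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

.cm_from_labels <- function(predicted, actual) {
  confusion_matrix(tp = sum(predicted == "POSITIVE" & actual == "POSITIVE"),
                   fn = sum(predicted == "NEGATIVE" & actual == "POSITIVE"),
                   fp = sum(predicted == "POSITIVE" & actual == "NEGATIVE"),
                   tn = sum(predicted == "NEGATIVE" & actual == "NEGATIVE"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("Predicted POS", "Predicted NEG"),
                              c("Actual POS", "Actual NEG")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN); Sn = TP/(TP+FN); Sp = TN/(TN+FP). Values are
#' returned at full precision; round to 3 decimals for reporting.
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector `c(acc, sn, sp)`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0)
    stop("no actual-positive samples: sensitivity undefined")
  if (cm$tn + cm$fp == 0)
    stop("no actual-negative samples: specificity undefined")
  c(acc = (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn),
    sn = cm$tp / (cm$tp + cm$fn),
    sp = cm$tn / (cm$tn + cm$fp))
}

#' Leave-one-out cross-validated SVM accuracy
#'
#' Runs exactly N train/predict rounds on the N samples of `m` restricted to
#' `genes`: in each round one sample is held out and the classifier is trained
#' on the other N-1. Feature-scaling parameters are refitted within every fold
#' on the training samples only, so no information leaks from the held-out
#' sample. Samples are processed in sorted sample-id order, making the result
#' identical across input column orderings; there is no randomness anywhere.
#'
#' @param m an `expression_matrix` with labels; both classes need >= 2 samples.
#' @param genes ordered character vector of genes to use as features.
#' @param spec a `classifier_spec`.
#' @return list with `accuracy` (= (TP+TN)/N), `cm` (pooled
#'   `confusion_matrix`), and `predictions` (named character vector).
#' @export
loocv_accuracy <- function(m, genes, spec = classifier_spec()) {
  d <- .design(m, genes)
  if (min(table(d$y)) < 2L)
    stop("each class needs >= 2 samples for LOOCV ",
         "(some folds would be single-class)")
  gamma <- if (is.null(spec$gamma)) 0 else spec$gamma
  dec <- .svm_loocv_cpp(d$X, d$y, spec$cost, gamma, spec$scale,
                        is.null(spec$gamma))
  pred <- .decide(drop(dec))
  actual <- ifelse(d$y == 1L, "POSITIVE", "NEGATIVE")
  cm <- .cm_from_labels(pred, actual)
  list(accuracy = (cm$tp + cm$tn) / nrow(d$X), cm = cm,
       predictions = stats::setNames(pred, rownames(d$X)))
}

#' Incremental feature selection curve
#'
#' For each k = 1..k_max, evaluates the LOOCV accuracy of an SVM trained on
#' the top-k genes of the mRMR ranking. The resulting curve (accuracy vs
#' number of genes) is the basis for choosing the signature size.
#'
#' @param m an `expression_matrix` with labels (the training set).
#' @param ranked a `ranked_gene_list` (or character vector of gene ids in
#'   rank order).
#' @param k_max largest gene-set size to evaluate; at most the length of the
#'   ranking.
#' @param spec a `classifier_spec`.
#' @return an object of class `ifs_curve`: data.frame with columns `k` and
#'   `accuracy`, attribute `k_max`.
#' @export
run_ifs <- function(m, ranked, k_max, spec = classifier_spec()) {
  genes <- if (is.character(ranked)) ranked else ranked$gene_id
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > length(genes))
    stop("`k_max` must be between 1 and the length of the ranking")
  acc <- vapply(seq_len(k_max), function(k)
    loocv_accuracy(m, genes[seq_len(k)], spec)$accuracy, numeric(1))
  structure(data.frame(k = seq_len(k_max), accuracy = acc),
            k_max = k_max, class = c("ifs_curve", "data.frame"))
}

#' Choose the signature size from an IFS curve
#'
#' Formalizes the plateau judgment: among gene-set sizes whose accuracy is
#' within `delta` of the curve maximum (strictly above `max - delta`) and at
#' least `acc_floor`, the smallest k wins — fewer genes at essentially the
#' same performance. The global argmax is reported alongside. If no size
#' reaches `acc_floor`, the argmax is returned with `warning = TRUE`.
#'
#' @param curve an `ifs_curve`.
#' @param delta non-negative accuracy slack relative to the curve maximum.
#' @param acc_floor minimum acceptable accuracy in \[0, 1\].
#' @return list with `chosen_k`, `argmax_k`, `accuracy` (at `chosen_k`), and
#'   `warning` (TRUE when the floor was unattainable).
#' @export
select_signature_size <- function(curve, delta = 0.01, acc_floor = 0.90) {
  stopifnot(nrow(curve) > 0, delta >= 0, acc_floor >= 0, acc_floor <= 1)
  acc <- curve$accuracy
  best <- max(acc)
  qual <- acc > best - delta
  if (!any(qual)) qual <- acc == best       # delta = 0 degenerates to argmax
  ok <- qual & acc >= acc_floor
  argmax_k <- curve$k[which.max(acc)]
  if (!any(ok))
    return(list(chosen_k = argmax_k, argmax_k = argmax_k,
                accuracy = best, warning = TRUE))
  chosen <- curve$k[which(ok)[1L]]
  list(chosen_k = chosen, argmax_k = argmax_k,
       accuracy = acc[curve$k == chosen], warning = FALSE)
}

#' Train the final classifier and evaluate on the independent test set
#'
#' Fits the SVM once on all training samples of `pair` (scaling fitted on the
#' training set only, then applied to the test set) and returns the confusion
#' matrix of its predictions on the test samples.
#'
#' @param pair a `dataset_pair` with labels on both matrices.
#' @param genes character vector of signature genes, present in both matrices.
#' @param spec a `classifier_spec`.
#' @return list with `cm` (test `confusion_matrix`), `metrics` (acc/sn/sp on
#'   the test set) and `predictions`.
#' @export
train_final_and_test <- function(pair, genes, spec = classifier_spec()) {
  tr <- .design(pair$train, genes)
  te <- .design(pair$test, genes)
  model <- .svm_fit(tr$X, tr$y, spec)
  pred <- .decide(.svm_decision(model, te$X))
  actual <- ifelse(te$y == 1L, "POSITIVE", "NEGATIVE")
  cm <- .cm_from_labels(pred, actual)
  list(cm = cm, metrics = metrics(cm),
       predictions = stats::setNames(pred, rownames(te$X)))
}
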