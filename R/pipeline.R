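#' Run the full biomarker-discovery pipeline on a dataset pair
#'
#' End-to-end convenience wrapper: optionally quantile-normalize both
#' datasets, discretize the training set, rank genes by mRMR, trace the IFS
#' curve by LOOCV SVM, choose the signature size from the plateau, train the
#' final classifier on all training samples, and evaluate it on the
#' independent test set.
#'
#' @param pair a `dataset_pair` with labels on both matrices.
#' @param top_n number of genes to rank (capped at the gene count).
#' @param k_max largest signature size to evaluate (capped at `top_n`).
#' @param k_sd discretization threshold, see [discretize()].
#' @param criterion mRMR criterion, `"MID"` or `"MIQ"`.
#' @param delta,acc_floor plateau parameters, see [select_signature_size()].
#' @param spec a `classifier_spec`.
#' @param normalize quantile-normalize train and test (separately) first.
#' @return list with `ranked`, `curve`, `selection`, `signature` (gene ids),
#'   `train_loocv` (accuracy + confusion matrix at the chosen size) and
#'   `test` (result of [train_final_and_test()]).
#' @export
run_pipeline <- function(pair, top_n = 500L, k_max = 50L, k_sd = 1.0,
                         criterion = "MID", delta = 0.01, acc_floor = 0.90,
                         spec = classifier_spec(), normalize = TRUE) {
  if (normalize)
    pair <- dataset_pair(quantile_normalize(pair$train),
                         quantile_normalize(pair$test))
  top_n <- min(as.integer(top_n), n_genes(pair$train))
  k_max <- min(as.integer(k_max), top_n)
  ranked <- mrmr_rank(discretize(pair$train, k_sd), top_n, criterion)
  curve <- run_ifs(pair$train, ranked, k_max, spec)
  selection <- select_signature_size(curve, delta, acc_floor)
  signature <- ranked$gene_id[seq_len(selection$chosen_k)]
  train_loocv <- loocv_accuracy(pair$train, signature, spec)
  test <- train_final_and_test(pair, signature, spec)
  list(ranked = ranked, curve = curve, selection = selection,
       signature = signature, train_loocv = train_loocv, test = test)
}
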