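#' Hierarchical clustering of train+test samples on the signature genes
#'
#' Combines the training and test samples, restricts to the signature genes,
#' z-scores each gene across the combined samples for display, and clusters
#' both samples and genes agglomeratively. Cutting the sample dendrogram into
#' two clusters yields a purity score: the best label-to-cluster assignment's
#' fraction of correctly grouped samples. A clustering whose purity does not
#' beat the majority-class fraction by more than 0.05 is flagged as
#' uninformative. The stored matrices are never modified — the z-scoring is a
#' display transform only.
#'
#' @param pair a `dataset_pair` with labels on both matrices.
#' @param genes signature genes, present in both matrices (>= 2).
#' @param distance `"correlation"` (1 - Pearson, the default for expression
#'   heatmaps) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"`, or `"ward"` (ward.D2).
#' @param file optional path for a heatmap image (png/pdf via pheatmap, which
#'   must be installed); `NULL` draws nothing.
#' @return an object of class `clustering_result`: list with `sample_order`,
#'   `gene_order`, `distance`, `linkage`, `purity`, `majority_fraction`, and
#'   `uninformative` flag.
#' @export
cluster_heatmap <- function(pair, genes,
                            distance = c("correlation", "euclidean"),
                            linkage = c("average", "complete", "ward"),
                            file = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (length(genes) < 2L) stop("need >= 2 signature genes to cluster")
  tr <- subset_genes(pair$train, genes)
  te <- subset_genes(pair$test, genes)
  combined <- cbind(tr$values, te$values)
  if (ncol(combined) < 2L) stop("need >= 2 samples to cluster")
  labels <- c(tr$labels, te$labels)
  # display z-score per gene; constant genes stay at 0
  sdv <- apply(combined, 1, stats::sd)
  z <- (combined - rowMeans(combined)) / ifelse(sdv > 0, sdv, 1)

  hc_method <- c(average = "average", complete = "complete",
                 ward = "ward.D2")[[linkage]]
  dist_fun <- function(x) {        # rows of x are the objects to cluster
    if (distance == "euclidean") return(stats::dist(x))
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[!is.finite(cc)] <- 0
    stats::as.dist(1 - cc)
  }
  hc_samples <- stats::hclust(dist_fun(t(z)), method = hc_method)
  hc_genes <- stats::hclust(dist_fun(z), method = hc_method)

  cut2 <- stats::cutree(hc_samples, k = 2)
  tab <- table(cut2, labels[colnames(combined)])
  purity <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / sum(tab)
  majority <- max(table(labels)) / length(labels)

  if (!is.null(file)) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      stop("package 'pheatmap' is required to draw the heatmap image")
    ann <- data.frame(class = labels[colnames(combined)])
    rownames(ann) <- colnames(combined)
    grDevices::png(file, width = 1200, height = 900)
    pheatmap::pheatmap(z, cluster_rows = hc_genes, cluster_cols = hc_samples,
                       annotation_col = ann, show_colnames = FALSE,
                       main = sprintf("%d-gene signature", length(genes)))
    grDevices::dev.off()
  }
  structure(list(sample_order = colnames(combined)[hc_samples$order],
                 gene_order = rownames(combined)[hc_genes$order],
                 distance = distance, linkage = linkage,
                 purity = unname(purity),
                 majority_fraction = unname(majority),
                 uninformative = unname(purity < majority + 0.05)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(paste0("clustering_result: %d samples, %d genes ",
                     "(%s distance, %s linkage)\n  2-cut purity %.3f%s\n"),
              length(x$sample_order), length(x$gene_order),
              x$distance, x$linkage, x$purity,
              if (x$uninformative) " [uninformative clustering]" else ""))
  invisible(x)
}

#' Assemble and write the machine-readable run report
#'
#' Gathers the outputs of the pipeline stages into one JSON document plus a
#' short human-readable summary. Metric values are rounded to 3 decimals in
#' the report, matching the reporting convention of the field.
#'
#' @param config named list echoing the run configuration (free-form).
#' @param n_common_genes intersection size after gene harmonization.
#' @param selection result of [select_signature_size()].
#' @param train_cm training-set LOOCV `confusion_matrix`.
#' @param test_cm independent-test `confusion_matrix`.
#' @param clustering a `clustering_result`, or `NULL` to omit.
#' @param path output path for the JSON report; `NULL` returns the list only.
#' @return the report list, invisibly when written to `path`.
#' @export
write_report <- function(config, n_common_genes, selection,
                         train_cm, test_cm, clustering = NULL, path = NULL) {
  stages <- list(config = config, n_common_genes = n_common_genes,
                 selection = selection, train_cm = train_cm,
                 test_cm = test_cm)
  missing <- names(stages)[vapply(stages, is.null, logical(1))]
  if (length(missing))
    stop("missing stage output(s): ", paste(missing, collapse = ", "))
  tr_m <- round(metrics(train_cm), 3)
  te_m <- round(metrics(test_cm), 3)
  report <- list(
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    n_common_genes = n_common_genes,
    chosen_k = selection$chosen_k,
    argmax_k = selection$argmax_k,
    train = list(confusion = unclass(train_cm), metrics = as.list(tr_m)),
    test = list(confusion = unclass(test_cm), metrics = as.list(te_m)))
  if (!is.null(clustering)) {
    report$clustering <- list(
      distance = clustering$distance, linkage = clustering$linkage,
      purity = round(clustering$purity, 3),
      uninformative = clustering$uninformative)
  }
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}

#' One-page text summary of a report list
#'
#' @param report a list as produced by [write_report()].
#' @return character vector of summary lines, invisibly; printed as a side
#'   effect.
#' @export
summarize_report <- function(report) {
  lines <- c(
    sprintf("common genes: %d", report$n_common_genes),
    sprintf("signature size: %d (argmax %d)",
            report$chosen_k, report$argmax_k),
    sprintf("train LOOCV  acc %.3f  sn %.3f  sp %.3f",
            report$train$metrics$acc, report$train$metrics$sn,
            report$train$metrics$sp),
    sprintf("test         acc %.3f  sn %.3f  sp %.3f",
            report$test$metrics$acc, report$test$metrics$sn,
            report$test$metrics$sp))
  if (!is.null(report$clustering))
    lines <- c(lines, sprintf("cluster purity: %.3f%s",
                              report$clustering$purity,
                              if (isTRUE(report$clustering$uninformative))
                                " [uninformative]" else ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
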