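#' Construct an expression matrix
#'
#' The core container of the package: a genes x samples real-valued matrix with
#' unique gene and sample identifiers and, optionally, a binary class label per
#' sample. Labels use the canonical values `"POSITIVE"` and `"NEGATIVE"`; in the
#' motivating application the positive class is COPD and the negative class ILD.
#'
#' @param values numeric matrix, genes in rows, samples in columns; `rownames`
#'   are gene identifiers and `colnames` sample identifiers.
#' @param labels optional character (or factor) vector of `"POSITIVE"` /
#'   `"NEGATIVE"`, either named by sample id or in column order of `values`.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `labels` (named character vector or `NULL`).
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
#'   labels = c(s1 = "POSITIVE", s2 = "NEGATIVE"))
#' n_genes(m)
#' @export
expression_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (anyNA(values))
    stop("`values` contains missing entries; apply the missing policy on read")
  if (!is.null(labels)) {
    labels <- validate_labels(labels, colnames(values))
  }
  structure(list(values = values, labels = labels),
            class = "expression_matrix")
}

validate_labels <- function(labels, sample_ids) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels))) {
    if (length(labels) != length(sample_ids))
      stop("unnamed `labels` must have one entry per sample")
    names(labels) <- sample_ids
  }
  unknown <- setdiff(names(labels), sample_ids)
  if (length(unknown))
    stop("labels refer to unknown sample(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("samples without a label: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(labels), c("POSITIVE", "NEGATIVE"))
  if (length(bad))
    stop("labels must be POSITIVE/NEGATIVE, got: ", paste(bad, collapse = ", "))
  labels[sample_ids]
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
n_samples <- function(x) ncol(x$values)

#' Per-class sample counts
#'
#' @param x an `expression_matrix` with labels.
#' @return named integer vector with elements `POSITIVE` and `NEGATIVE`.
#' @export
label_counts <- function(x) {
  if (is.null(x$labels)) stop("expression matrix has no labels")
  c(POSITIVE = sum(x$labels == "POSITIVE"),
    NEGATIVE = sum(x$labels == "NEGATIVE"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              n_genes(x), n_samples(x)))
  if (!is.null(x$labels)) {
    n <- label_counts(x)
    cat(sprintf("  labels: %d POSITIVE, %d NEGATIVE\n",
                n[["POSITIVE"]], n[["NEGATIVE"]]))
  }
  invisible(x)
}

#' Restrict an expression matrix to a gene subset
#'
#' @param x an `expression_matrix`.
#' @param genes character vector of gene ids, all present in `x`.
#' @return an `expression_matrix` with rows `genes`, in the given order.
#' @export
subset_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  expression_matrix(x$values[genes, , drop = FALSE], x$labels)
}

#' Pair a training and a test expression matrix
#'
#' Both matrices must carry the same genes in the same order and have disjoint
#' sample ids (the two-platform design: samples profiled on one platform train
#' the model, samples from the other platform test it).
#'
#' @param train,test `expression_matrix` objects.
#' @return an object of class `dataset_pair`: list with `train` and `test`.
#' @export
dataset_pair <- function(train, test) {
  if (!identical(gene_ids(train), gene_ids(test)))
    stop("train and test must share the same genes in the same order")
  common <- intersect(sample_ids(train), sample_ids(test))
  if (length(common))
    stop("train and test sample ids overlap: ", paste(common, collapse = ", "))
  structure(list(train = train, test = test), class = "dataset_pair")
}

#' @export
print.dataset_pair <- function(x, ...) {
  cat("dataset_pair\n  train: ")
  print(x$train)
  cat("  test:  ")
  print(x$test)
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' The file layout is genes in rows: the first column holds gene identifiers,
#' the header row holds sample identifiers, values are tab-separated with "."
#' as the decimal mark. Gene rows containing any missing or non-numeric value
#' are dropped with a message (downstream discretization assumes complete rows).
#'
#' @param path path to the matrix TSV.
#' @param label_path optional path to a two-column TSV `sample_id<TAB>label`
#'   (no header). Labels are mapped to POSITIVE/NEGATIVE via `label_map`.
#' @param label_map named character vector mapping raw labels to
#'   `"POSITIVE"`/`"NEGATIVE"`; default treats COPD as positive, ILD negative.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, label_path = NULL,
                                   label_map = c(COPD = "POSITIVE",
                                                 ILD = "NEGATIVE")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2)
    stop("matrix file must have a gene-id column and at least one sample")
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  samp <- colnames(raw)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s))
    stop("duplicate sample ids in ", path, ": ", paste(dup_s, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, samp))
  bad <- apply(vals, 1, anyNA)
  if (any(bad)) {
    message(sum(bad), " gene row(s) dropped (missing or non-numeric values)")
    vals <- vals[!bad, , drop = FALSE]
  }
  labels <- NULL
  if (!is.null(label_path)) {
    lab <- utils::read.delim(label_path, header = FALSE, sep = "\t",
                             colClasses = "character")
    if (ncol(lab) < 2) stop("label file must have two columns")
    unknown <- setdiff(lab[[1]], samp)
    if (length(unknown))
      stop("label file refers to unknown sample(s): ",
           paste(unknown, collapse = ", "))
    unmapped <- setdiff(unique(lab[[2]]), names(label_map))
    if (length(unmapped))
      stop("label(s) not covered by label_map: ",
           paste(unmapped, collapse = ", "))
    labels <- stats::setNames(unname(label_map[lab[[2]]]), lab[[1]])
  }
  expression_matrix(vals, labels)
}

#' Write an expression matrix (and optionally its labels) as TSV
#'
#' @param x an `expression_matrix`.
#' @param path output path for the matrix TSV.
#' @param label_path optional output path for the two-column label TSV; raw
#'   label names are produced by inverting `label_map`.
#' @inheritParams read_expression_matrix
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, label_path = NULL,
                                    label_map = c(COPD = "POSITIVE",
                                                  ILD = "NEGATIVE")) {
  df <- data.frame(gene_id = gene_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_path)) {
    if (is.null(x$labels)) stop("matrix has no labels to write")
    inv <- stats::setNames(names(label_map), unname(label_map))
    utils::write.table(
      data.frame(sample_ids(x), unname(inv[x$labels])),
      label_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Restrict two expression matrices to their common genes
#'
#' Emulates cross-platform harmonization: both matrices are cut down to the
#' genes present on both platforms, rows sorted into one shared lexicographic
#' order so that downstream runs are reproducible regardless of input ordering.
#'
#' @param a,b `expression_matrix` objects (conventionally train and test).
#' @return a `dataset_pair` with `train = a` and `test = b` restricted to the
#'   common genes.
#' @export
intersect_genes <- function(a, b) {
  common <- sort(intersect(gene_ids(a), gene_ids(b)), method = "radix")
  if (!length(common))
    stop("no genes in common between the two matrices")
  message(length(common), " common gene(s) retained")
  dataset_pair(subset_genes(a, common), subset_genes(b, common))
}

#' Quantile normalization
#'
#' Forces every sample (column) to share one empirical value distribution: the
#' value at within-column rank r is replaced by the mean, across samples, of
#' the rank-r order statistics. Tied values within a column receive the mean of
#' the rank-means their tie block spans ("ties = average"), which makes the
#' transform deterministic and symmetric in the tied entries. Idempotent.
#'
#' @param m an `expression_matrix` with no missing values.
#' @return an `expression_matrix` with identical per-column sorted vectors;
#'   gene/sample ids and labels are preserved.
#' @export
quantile_normalize <- function(m) {
  x <- m$values
  if (nrow(x) == 1L || ncol(x) == 1L) return(m)
  mu <- rowMeans(apply(x, 2, sort))
  cs <- c(0, cumsum(mu))
  out <- apply(x, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, m$labels)
}
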