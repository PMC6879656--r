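#' Three-state discretization of expression values
#'
#' Per gene, expression is z-scored across samples and binned into three states
#' relative to a threshold of `k_sd` standard deviations: -1 (z <= -k_sd),
#' 0 (inside the open band), +1 (z >= +k_sd). This is the classic preprocessing for
#' mutual-information feature scoring on continuous microarray data; k_sd = 1
#' is the historical default of the original C mRMR implementation. A gene with
#' zero variance maps to the all-0 state.
#'
#' @param m an `expression_matrix` with at least 2 samples.
#' @param k_sd positive threshold, in standard-deviation units.
#' @return an object of class `discretized_matrix`: list with `states`
#'   (integer matrix in \{-1, 0, +1\}, same dimnames as `m$values`) and
#'   `labels` (carried over from `m`).
#' @export
discretize <- function(m, k_sd = 1.0) {
  if (n_samples(m) < 2L)
    stop("discretization needs >= 2 samples (no variance estimate)")
  if (!is.numeric(k_sd) || length(k_sd) != 1L || k_sd <= 0)
    stop("`k_sd` must be a single positive number")
  x <- m$values
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  s <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  s[z <= -k_sd] <- -1L
  s[z >= k_sd] <- 1L
  s[sd == 0, ] <- 0L
  structure(list(states = s, labels = m$labels),
            class = "discretized_matrix")
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat(sprintf("discretized_matrix: %d genes x %d samples, states {-1,0,+1}\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Mutual information of two discrete vectors
#'
#' Plug-in (empirical) mutual information
#' \deqn{I(X;Y) = \sum_{a,b} p(a,b) \log \frac{p(a,b)}{p(a)\,p(b)}}
#' over the observed state pairs, with 0 log 0 terms contributing 0.
#'
#' @param x,y atomic vectors of equal length; treated as categorical.
#' @param base logarithm base; 2 (bits, the default) or `exp(1)` (nats). The
#'   base rescales scores and never changes an mRMR ranking.
#' @return non-negative scalar (up to floating-point error).
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length")
  p <- table(x, y) / length(x)
  px <- rowSums(p)
  py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx])) / log(base)
}

# MI from a contingency-count matrix (internal fast path; bits).
.mi_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log2(p[idx] / outer(px, py)[idx]))
}

# MI between two state rows coded in 0..(k-1) (internal fast path; bits).
.mi_coded <- function(a, b, ka, kb) {
  .mi_counts(matrix(tabulate(a * kb + b + 1L, ka * kb), ka, kb, byrow = TRUE))
}

#' mRMR ranking of genes against the disease label
#'
#' Greedy forward selection under the minimal-redundancy-maximal-relevance
#' objective. Step 1 picks the gene with maximal relevance \eqn{I(g, t)} to the
#' binary label t. With m genes already selected, redundancy is
#' \eqn{R(g) = \frac{1}{m} \sum_{g_i \in \Omega_s} I(g, g_i)} and each later
#' step maximizes \eqn{I(g,t) - R(g)} (criterion `"MID"`, the default) or
#' \eqn{I(g,t) / R(g)} (`"MIQ"`) over the not-yet-selected genes. Ties are
#' broken toward the lexicographically smallest gene id so the ranking does not
#' depend on input row order.
#'
#' @param d a `discretized_matrix` with labels on every sample.
#' @param top_n number of genes to rank (default 500, the conventional depth
#'   for downstream incremental feature selection).
#' @param criterion `"MID"` (difference) or `"MIQ"` (quotient).
#' @return an object of class `ranked_gene_list`: data.frame with columns
#'   `rank`, `gene_id`, `score` (the maximized objective at selection, in
#'   bits), plus attributes `criterion` and `relevance` (named vector of
#'   \eqn{I(g,t)} for all input genes).
#' @export
mrmr_rank <- function(d, top_n = 500L, criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  if (is.null(d$labels)) stop("labels are required for mRMR ranking")
  s <- d$states
  n_g <- nrow(s)
  top_n <- as.integer(top_n)
  if (top_n < 1L || top_n > n_g)
    stop("`top_n` must be between 1 and the number of genes (", n_g, ")")
  y <- as.integer(d$labels[colnames(s)] == "POSITIVE")      # 0/1
  coded <- s + 1L                                           # rows in 0..2
  genes <- rownames(s)

  rel <- vapply(seq_len(n_g), function(i)
    .mi_coded(coded[i, ], y, 3L, 2L), numeric(1))
  names(rel) <- genes

  selected <- integer(top_n)
  scores <- numeric(top_n)
  remaining <- rep(TRUE, n_g)
  red_sum <- numeric(n_g)                                   # sum of MI vs selected
  eps <- .Machine$double.eps

  for (step in seq_len(top_n)) {
    if (step == 1L) {
      obj <- rel
    } else {
      red <- red_sum / (step - 1L)
      obj <- if (criterion == "MID") rel - red
             else rel / pmax(red, eps)
    }
    obj[!remaining] <- -Inf
    best <- max(obj)
    cand <- which(obj >= best - 1e-12 & remaining)
    pick <- cand[order(genes[cand], method = "radix")][1L]
    selected[step] <- pick
    scores[step] <- obj[pick]
    remaining[pick] <- FALSE
    if (step < top_n) {
      idx <- which(remaining)
      new_row <- coded[pick, ]
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(i)
        .mi_coded(coded[i, ], new_row, 3L, 3L), numeric(1))
    }
  }
  structure(
    data.frame(rank = seq_len(top_n), gene_id = genes[selected],
               score = scores, stringsAsFactors = FALSE),
    criterion = criterion, relevance = rel,
    class = c("ranked_gene_list", "data.frame"))
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat(sprintf("ranked_gene_list (%s criterion): %d genes\n",
              attr(x, "criterion"), nrow(x)))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
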