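# Independent oracles and fixture builders shared across the test files.
# Everything here deliberately avoids the package's own code paths: mutual
# information goes through entropies of pasted symbols, the mRMR oracle
# re-evaluates the greedy objective from scratch at every step.

make_em <- function(values, labels = NULL, genes = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-class matrix with a given per-class mean shift on the first few genes
make_labeled_em <- function(n_genes, n_pos, n_neg, shift = 0, n_shifted = 0,
                            seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  x <- matrix(rnorm(n_genes * n), n_genes, n)
  if (n_shifted > 0)
    x[seq_len(n_shifted), seq_len(n_pos)] <-
      x[seq_len(n_shifted), seq_len(n_pos)] + shift
  rownames(x) <- sprintf("g%02d", seq_len(n_genes))
  colnames(x) <- sprintf("s%02d", seq_len(n))
  labels <- setNames(c(rep("POSITIVE", n_pos), rep("NEGATIVE", n_neg)),
                     colnames(x))
  expression_matrix(x, labels)
}

# plug-in entropy in bits of a discrete vector
entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# mutual information in bits via I(X;Y) = H(X) + H(Y) - H(X,Y)
mi_oracle <- function(x, y) {
  entropy_oracle(x) + entropy_oracle(y) -
    entropy_oracle(paste(x, y, sep = "\r"))
}

# Brute-force greedy mRMR on a state matrix (rows = genes, named) against a
# label vector: recompute relevance and mean redundancy over all remaining
# candidates at every step, tie-break toward the smallest gene id.
mrmr_oracle <- function(states, y, top_n = nrow(states),
                        criterion = "MID", base = 2) {
  genes <- rownames(states)
  rel <- vapply(genes, function(g)
    mi_oracle(states[g, ], y) * log(2) / log(base), numeric(1))
  selected <- character(0)
  for (step in seq_len(top_n)) {
    remaining <- setdiff(genes, selected)
    obj <- vapply(remaining, function(g) {
      if (!length(selected)) return(rel[[g]])
      red <- mean(vapply(selected, function(s)
        mi_oracle(states[g, ], states[s, ]) * log(2) / log(base), numeric(1)))
      if (criterion == "MID") rel[[g]] - red
      else rel[[g]] / max(red, .Machine$double.eps)
    }, numeric(1))
    best <- max(obj)
    cand <- sort(remaining[obj >= best - 1e-12], method = "radix")
    selected <- c(selected, cand[1])
  }
  selected
}

# random discretized fixture for oracle-equivalence checks
random_discretized <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  rownames(x) <- sprintf("g%02d", seq_len(n_genes))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  labels <- setNames(sample(c("POSITIVE", "NEGATIVE"), n_samples,
                            replace = TRUE, prob = c(0.5, 0.5)),
                     colnames(x))
  # guarantee both classes
  labels[1] <- "POSITIVE"; labels[2] <- "NEGATIVE"
  discretize(expression_matrix(x, labels), k_sd = 0.7)
}
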