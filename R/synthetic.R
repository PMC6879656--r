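#' Specification of the two-class synthetic expression generator
#'
#' Describes a stylized two-class (disease A vs disease B) expression dataset
#' with the structure mRMR exploits: informative genes whose class means are
#' shifted by `effect_size` standard deviations, co-expressed redundant copies
#' of each informative gene, and label-independent noise genes. Defaults
#' encode the strong-signal regime used throughout the test-suite simulations:
#' 60 + 60 samples, 5 informative genes with 2 redundant copies each, 200
#' noise genes, effect size 3 SD, within-block correlation 0.7.
#'
#' @param n_pos,n_neg samples per class (>= 2 each).
#' @param n_informative number of label-relevant genes.
#' @param n_redundant_per_informative redundant copies per informative gene.
#' @param n_noise number of label-independent genes.
#' @param effect_size between-class mean shift of informative genes, in
#'   within-class standard-deviation units.
#' @param within_block_correlation within-class correlation rho in \[0, 1)
#'   between an informative gene and each of its redundant copies.
#' @param noise_sd standard deviation of noise genes (> 0).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param platform_scale_sd optional per-gene multiplicative scale jitter
#'   (log-normal sd) applied to the test matrix only, mimicking a second
#'   measurement platform; 0 (default) disables it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 60L, n_neg = 60L,
                           n_informative = 5L,
                           n_redundant_per_informative = 2L,
                           n_noise = 200L,
                           effect_size = 3,
                           within_block_correlation = 0.7,
                           noise_sd = 1,
                           seed = 1L,
                           platform_scale_sd = 0) {
  spec <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
               n_informative = as.integer(n_informative),
               n_redundant_per_informative =
                 as.integer(n_redundant_per_informative),
               n_noise = as.integer(n_noise),
               effect_size = effect_size,
               within_block_correlation = within_block_correlation,
               noise_sd = noise_sd, seed = as.integer(seed),
               platform_scale_sd = platform_scale_sd)
  problems <- character()
  if (spec$n_pos < 2L || spec$n_neg < 2L)
    problems <- c(problems, "n_pos and n_neg must be >= 2")
  if (spec$n_informative < 0L || spec$n_redundant_per_informative < 0L ||
      spec$n_noise < 0L)
    problems <- c(problems, "gene counts must be >= 0")
  if (spec$n_informative + spec$n_noise < 1L)
    problems <- c(problems, "at least one gene is required")
  if (!is.finite(spec$effect_size) || spec$effect_size < 0)
    problems <- c(problems, "effect_size must be a finite number >= 0")
  if (spec$within_block_correlation < 0 || spec$within_block_correlation >= 1)
    problems <- c(problems, "within_block_correlation must be in [0, 1)")
  if (!is.finite(spec$noise_sd) || spec$noise_sd <= 0)
    problems <- c(problems, "noise_sd must be > 0")
  if (spec$platform_scale_sd < 0)
    problems <- c(problems, "platform_scale_sd must be >= 0")
  if (length(problems))
    stop("invalid synthetic_spec:\n  - ", paste(problems, collapse = "\n  - "))
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_spec: %d+%d samples; %d informative x(1+%d) + %d noise genes;\n",
    "  effect %g SD, rho %g, noise sd %g, seed %d\n"),
    x$n_pos, x$n_neg, x$n_informative, x$n_redundant_per_informative,
    x$n_noise, x$effect_size, x$within_block_correlation, x$noise_sd, x$seed))
  invisible(x)
}

# one matrix draw under the spec; samples are n_pos positives then n_neg negatives
.draw_matrix <- function(spec, sample_prefix) {
  n <- spec$n_pos + spec$n_neg
  shift <- c(rep(spec$effect_size / 2, spec$n_pos),
             rep(-spec$effect_size / 2, spec$n_neg))
  rho <- spec$within_block_correlation
  rows <- list()
  roles <- character()
  for (i in seq_len(spec$n_informative)) {
    parent_id <- sprintf("sig%03d", i)
    # alternate up-/down-regulation across blocks: real signatures mix both,
    # and an all-one-direction signal would be invisible to correlation
    # distance after per-sample centering
    direction <- if (i %% 2L == 1L) 1 else -1
    parent <- stats::rnorm(n, mean = direction * shift, sd = 1)
    rows[[parent_id]] <- parent
    roles[parent_id] <- "informative"
    for (r in seq_len(spec$n_redundant_per_informative)) {
      id <- sprintf("%s_r%02d", parent_id, r)
      rows[[id]] <- rho * parent + sqrt(1 - rho^2) * stats::rnorm(n)
      roles[id] <- "redundant"
    }
  }
  for (i in seq_len(spec$n_noise)) {
    id <- sprintf("noise%04d", i)
    rows[[id]] <- stats::rnorm(n, 0, spec$noise_sd)
    roles[id] <- "noise"
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- sprintf("%s%03d", sample_prefix, seq_len(n))
  labels <- stats::setNames(
    c(rep("POSITIVE", spec$n_pos), rep("NEGATIVE", spec$n_neg)),
    colnames(vals))
  list(m = expression_matrix(vals, labels), roles = roles)
}

#' Generate a synthetic train/test dataset pair
#'
#' Draws two independent datasets (train and test) from the generative law of
#' `spec` — the same-population, different-platform design: both draws share
#' gene identifiers and class structure but none of their samples. Informative
#' gene i is N(+effect/2, 1) in positives and N(-effect/2, 1) in negatives
#' (direction alternating between blocks, emulating mixed up-/down-regulated
#' signature genes);
#' each redundant copy is `rho * parent + sqrt(1 - rho^2) * eps` with
#' independent standard-normal `eps`, so its within-class correlation with the
#' parent is exactly rho and its within-class variance 1; noise genes are
#' N(0, noise_sd) regardless of label. With `platform_scale_sd > 0` every test
#' gene is additionally multiplied by a log-normal scale factor.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `pair` (a `dataset_pair`) and `truth` (data.frame with
#'   columns `gene_id`, `role` in \{informative, redundant, noise\}).
#' @export
generate_dataset_pair <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  train <- .draw_matrix(spec, "TR")
  test <- .draw_matrix(spec, "TE")
  if (spec$platform_scale_sd > 0) {
    fac <- exp(stats::rnorm(n_genes(test$m), 0, spec$platform_scale_sd))
    test$m$values <- test$m$values * fac
  }
  list(pair = dataset_pair(train$m, test$m),
       truth = data.frame(gene_id = names(train$roles),
                          role = unname(train$roles),
                          stringsAsFactors = FALSE))
}
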