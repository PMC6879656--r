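test_that("expression_matrix enforces its invariants", {
  v <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- expression_matrix(v * 1.0)
  expect_s3_class(m, "expression_matrix")
  expect_equal(n_genes(m), 3)

  vd <- v; rownames(vd) <- c("a", "a", "c")
  expect_error(expression_matrix(vd * 1.0), "duplicate gene ids: a")
  vs <- v; colnames(vs) <- c("s1", "s1")
  expect_error(expression_matrix(vs * 1.0), "duplicate sample ids: s1")
  vn <- v * 1.0; vn[2, 1] <- NA
  expect_error(expression_matrix(vn), "missing")

  expect_error(expression_matrix(v * 1.0, c(s1 = "POSITIVE")), "without a label")
  expect_error(expression_matrix(v * 1.0, c(s1 = "POSITIVE", s2 = "ild")),
               "POSITIVE/NEGATIVE")
  expect_error(expression_matrix(v * 1.0,
                                 c(s1 = "POSITIVE", s2 = "NEGATIVE",
                                   sX = "POSITIVE")),
               "unknown sample")
  m2 <- expression_matrix(v * 1.0, c(s2 = "NEGATIVE", s1 = "POSITIVE"))
  expect_equal(unname(label_counts(m2)), c(1L, 1L))
})

test_that("read_expression_matrix parses, drops incomplete rows, maps labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "g1\t1.5\t2\t3",
               "g2\t4\tNA\t6",
               "g3\t7\t8\t9",
               "g4\t1\t2\tx"), path)
  writeLines(c("s1\tCOPD", "s2\tILD", "s3\tILD"), lab)

  expect_message(m <- read_expression_matrix(path, lab), "2 gene row")
  expect_equal(dim(m$values), c(2L, 3L))        # g2 and g4 dropped
  expect_equal(gene_ids(m), c("g1", "g3"))
  expect_equal(unname(m$labels),
               c("POSITIVE", "NEGATIVE", "NEGATIVE"))

  # well-formed 3x2 parses to shape (3, 2)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ta\tb", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"), p2)
  expect_equal(dim(read_expression_matrix(p2)$values), c(3L, 2L))

  # duplicated gene row id is a hard error naming the id
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ta\tb", "g1\t1\t2", "g1\t3\t4"), p3)
  expect_error(read_expression_matrix(p3), "g1")

  # label file referencing an unknown sample is a hard error
  lab2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tCOPD", "nope\tILD"), lab2)
  expect_error(read_expression_matrix(p2, lab2), "nope")
})

test_that("write_expression_matrix round-trips through read", {
  m <- make_labeled_em(5, 3, 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path, lab)
  m2 <- read_expression_matrix(path, lab)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_equal(m2$labels, m$labels)
})

test_that("intersect_genes restricts to sorted common genes", {
  a <- make_em(matrix(1:6, 3, 2) * 1.0, genes = c("C", "A", "B"),
               samples = c("x1", "x2"))
  b <- make_em(matrix(1:8, 4, 2) * 1.0, genes = c("B", "C", "D", "E"),
               samples = c("y1", "y2"))
  suppressMessages(pair <- intersect_genes(a, b))
  expect_equal(gene_ids(pair$train), c("B", "C"))
  expect_equal(gene_ids(pair$test), c("B", "C"))
  expect_equal(pair$train$values["B", ], a$values["B", ])

  # symmetric in the produced gene set
  suppressMessages(rev <- intersect_genes(b, a))
  expect_equal(gene_ids(rev$train), gene_ids(pair$train))

  # identity up to row order
  a2 <- make_em(matrix(rnorm(8), 4, 2), samples = c("z1", "z2"))
  v3 <- a2$values[c(3, 1, 4, 2), ]
  colnames(v3) <- c("w1", "w2")
  suppressMessages(p2 <- intersect_genes(a2, expression_matrix(v3)))
  expect_setequal(gene_ids(p2$train), gene_ids(a2))

  # larger fixture: 6 of 10 genes shared
  g1 <- sprintf("g%02d", 1:10); g2 <- sprintf("g%02d", 5:14)
  aa <- make_em(matrix(rnorm(20), 10, 2), genes = g1, samples = c("u1", "u2"))
  bb <- make_em(matrix(rnorm(20), 10, 2), genes = g2, samples = c("v1", "v2"))
  suppressMessages(pp <- intersect_genes(aa, bb))
  expect_equal(n_genes(pp$train), 6L)

  # empty intersection errors; overlapping samples error
  cc <- make_em(matrix(rnorm(4), 2, 2), genes = c("zz1", "zz2"),
                samples = c("q1", "q2"))
  expect_error(suppressMessages(intersect_genes(aa, cc)), "no genes in common")
  expect_error(dataset_pair(aa, make_em(aa$values)), "overlap")
})

test_that("quantile_normalize matches the hand-computed 3x2 reference", {
  # columns (5,2,3) and (4,1,4); rank means 1.5, 3.5, 4.5; the tie in column 2
  # spans ranks 2..3 and receives (3.5 + 4.5)/2 = 4
  m <- make_em(cbind(c(5, 2, 3), c(4, 1, 4)))
  q <- quantile_normalize(m)
  expect_equal(unname(q$values), cbind(c(4.5, 1.5, 3.5), c(4, 1.5, 4)))
  # under ties = average the tied column is NOT a permutation of the untied
  # one (4 replaces both 3.5 and 4.5); multiset equality holds tie-free only
})

test_that("quantile_normalize edge cases and properties hold", {
  # one sample: unchanged
  m1 <- make_em(matrix(c(3, 1, 2), 3, 1))
  expect_equal(quantile_normalize(m1)$values, m1$values)
  # one gene: unchanged
  mg <- make_em(matrix(c(3, 1, 2), 1, 3))
  expect_equal(quantile_normalize(mg)$values, mg$values)
  # columns already sharing a sorted vector are a fixed point up to order
  mfp <- make_em(cbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(quantile_normalize(mfp)$values, mfp$values)

  for (seed in 1:5) {
    set.seed(seed)
    m <- make_em(matrix(rnorm(20 * 6), 20, 6),
                 labels = rep(c("POSITIVE", "NEGATIVE"), 3))
    q <- quantile_normalize(m)
    ref <- unname(sort(q$values[, 1]))
    for (j in 2:6)
      expect_equal(unname(sort(q$values[, j])), ref, tolerance = 1e-9)
    # idempotent
    expect_equal(quantile_normalize(q)$values, q$values, tolerance = 1e-9)
    # labels and ids preserved
    expect_equal(q$labels, m$labels)
    expect_equal(dimnames(q$values), dimnames(m$values))
  }
})

test_that("quantile_normalize agrees with the limma oracle", {
  skip_if_not_installed("limma")
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(50 * 4), 50, 4)        # continuous: no ties
    q <- quantile_normalize(make_em(x))
    expect_equal(unname(q$values),
                 unname(limma::normalizeQuantiles(x, ties = TRUE)),
                 tolerance = 1e-12)
  }
  # and on the tied fixture, the ties = average dialect agrees too
  x <- cbind(c(5, 2, 3), c(4, 1, 4))
  expect_equal(unname(quantile_normalize(make_em(x))$values),
               unname(limma::normalizeQuantiles(x, ties = TRUE)),
               tolerance = 1e-12)
})
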