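test_that("AAindex1 flat-file parsing maps records to canonical columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(aaindex_fixture(), f)
  tab <- read_aaindex(f)
  expect_s3_class(tab, "property_table")
  expect_equal(nrow(tab$values), 2L)
  expect_false(any(tab$missing_mask))
  expect_equal(tab$index_ids, c("TEST000101", "TEST000102"))
  # first record counts 0.1..2.0 in file order = canonical order
  expect_equal(unname(tab$values[1, ]), (1:20) / 10)
  expect_equal(colnames(tab$values), AA_ORDER)
})

test_that("NA tokens are flagged missing and malformed records are rejected", {
  v2 <- sprintf("%6.2f", 20:1 / 10)
  v2[3] <- "NA"
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(aaindex_fixture(values2 = v2), f)
  tab <- read_aaindex(f)
  expect_true(tab$missing_mask[2, 3])
  expect_true(is.na(tab$values[2, 3]))
  expect_equal(sum(tab$missing_mask), 1L)

  bad <- strsplit(aaindex_fixture(), "\n")[[1]]
  bad <- bad[-4]  # drop a value row -> 10 tokens
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(bad, f2)
  expect_error(read_aaindex(f2), "TEST000101")

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("", f3)
  expect_error(read_aaindex(f3), "empty")
})

test_that("missing values are imputed with the row mean of observed values", {
  vals <- matrix(rnorm(60), 3, 20)
  vals[1, 5] <- NA
  tab <- property_table(vals, c("a", "b", "c"))
  imp <- impute_missing(tab)
  expect_equal(imp$values[1, 5], mean(vals[1, -5]))
  expect_true(imp$missing_mask[1, 5])  # provenance kept
  expect_identical(impute_missing(property_table(matrix(rnorm(40), 2, 20),
                                                 c("x", "y")))$missing_mask,
                   matrix(FALSE, 2, 20, dimnames = list(c("x", "y"), AA_ORDER)))
  # toy contract: mean of {1, 3} is 2
  row <- c(1, 3, NA, rnorm(17))
  tab2 <- impute_missing(property_table(rbind(row, rnorm(20)), c("p", "q")))
  expect_equal(tab2$values["p", 3], mean(row[-3], na.rm = TRUE))
})

test_that("property correlation is Pearson across amino-acid values", {
  base <- rnorm(20)
  tab <- property_table(rbind(base, base, -base), c("a", "b", "neg"))
  corr <- property_correlation(tab)
  expect_equal(corr["a", "b"], 1)
  expect_equal(corr["a", "neg"], -1)
  expect_equal(diag(corr), setNames(rep(1, 3), c("a", "b", "neg")))

  set.seed(11)
  v <- matrix(rnorm(100), 5, 20)
  got <- property_correlation(property_table(v, paste0("i", 1:5)))
  # direct covariance / sigma oracle
  for (p in 1:5) for (q in 1:5) {
    expect_equal(got[p, q],
                 cov(v[p, ], v[q, ]) / (sd(v[p, ]) * sd(v[q, ])),
                 tolerance = 1e-12)
  }

  const <- property_table(rbind(rep(2, 20), rnorm(20)), c("flat", "ok"))
  expect_error(property_correlation(const), "flat")
})

test_that("complete-linkage clustering cuts at the cophenetic threshold", {
  base <- rnorm(20)
  tab <- property_table(rbind(base, base, base, -base),
                        c("a", "b", "c", "neg"))
  corr <- property_correlation(tab)
  expect_equal(length(unique(cluster_properties(corr, 0.2))), 2L)
  lab <- cluster_properties(corr, 0.2)
  expect_equal(lab[["a"]], lab[["b"]])
  expect_false(lab[["a"]] == lab[["neg"]])

  # all identical rows: max distance 0, threshold 0, single cluster
  same <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(unique(cluster_properties(same, 0.2))), 1L)

  expect_error(cluster_properties(corr[1, 1, drop = FALSE]), "at least 2")
})

test_that("cluster count is non-increasing in the threshold fraction", {
  set.seed(3)
  tab <- synthetic_property_table(15, 3, within_group_correlation = 0.6,
                                  seed = 5)
  corr <- property_correlation(impute_missing(tab))
  counts <- vapply(c(0.05, 0.1, 0.2, 0.5, 1),
                   function(f) length(unique(cluster_properties(corr, f))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering is invariant to row permutation up to relabeling", {
  set.seed(7)
  tab <- synthetic_property_table(10, 3, seed = 9)
  corr <- property_correlation(tab)
  lab <- cluster_properties(corr, 0.3)
  perm <- sample(10)
  lab_p <- cluster_properties(corr[perm, perm], 0.3)
  expect_equal(canonical_partition(lab_p[order(perm)]),
               canonical_partition(lab))
})

test_that("flat clusters match a brute-force farthest-pair agglomeration", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- sample(4:8, 1)
    tab <- synthetic_property_table(P, 2, within_group_correlation = 0.5,
                                    seed = seed + 100)
    corr <- property_correlation(tab)
    D <- as.matrix(dist(corr))
    h <- 0.3 * max(D)
    expect_equal(canonical_partition(cluster_properties(corr, 0.3)),
                 canonical_partition(bf_complete_cut(D, h)))
  }
})

test_that("class means average members then studentize per row", {
  set.seed(21)
  v <- matrix(rnorm(120), 6, 20)
  tab <- property_table(v, paste0("i", 1:6))
  labels <- c(1, 1, 1, 2, 2, 2)
  cm <- class_means(tab, labels)
  expect_equal(cm$n_classes, 2L)
  for (c_i in 1:2) {
    raw <- colMeans(v[labels == c_i, ])
    expect_equal(unname(cm$raw_means[c_i, ]), raw, tolerance = 1e-12)
    expect_equal(unname(cm$means[c_i, ]), (raw - mean(raw)) / sd(raw),
                 tolerance = 1e-12)
  }
  # studentized rows: mean 0, unit sample sd
  expect_true(all(abs(rowMeans(cm$means)) < 1e-9))
  expect_true(all(abs(apply(cm$means, 1, sd) - 1) < 1e-9))
  # singleton class mean equals its member row pre-studentization
  cm2 <- class_means(tab, c(1, 2, 2, 2, 2, 2))
  expect_equal(unname(cm2$raw_means[1, ]), v[1, ])
  expect_equal(cm2$member_map$C1, "i1")
})

test_that("a constant class mean row studentizes to zeros with a warning", {
  v <- rbind(0:19, 19:0)
  tab <- property_table(v, c("up", "down"))
  expect_warning(cm <- class_means(tab, c(1, 1)), "constant")
  expect_equal(unname(cm$raw_means[1, ]), rep(9.5, 20))
  expect_equal(unname(cm$means[1, ]), rep(0, 20))
})

test_that("quadruple partition uses equal-width left-closed bins", {
  m <- matrix(c(0, 0.3, 0.6, 1.0), 1, dimnames = list("c1", c("A", "B", "C", "D")))
  quad <- quadruple_partition(m)
  g <- quad$groups$c1
  expect_equal(lengths(g), setNames(c(1L, 1L, 1L, 1L), as.character(1:4)))
  expect_equal(g[[2]], "B")  # 0.3 falls in [0.25, 0.5)
  expect_equal(g[[4]], "D")  # max is in the closed last bin
  expect_equal(quad$bin_edges$c1, c(0, 0.25, 0.5, 0.75, 1))

  # constant row: everything in group 1
  mc <- matrix(1, 1, 20, dimnames = list("flat", NULL))
  qc <- quadruple_partition(mc)
  expect_equal(lengths(qc$groups$flat), setNames(c(20L, 0L, 0L, 0L),
                                                 as.character(1:4)))
})

test_that("quadruple groups partition the alphabet for every class", {
  set.seed(31)
  classes <- random_classes(12, seed = 31)
  quad <- quadruple_partition(classes)
  for (cl in names(quad$groups)) {
    members <- unname(unlist(quad$groups[[cl]]))
    expect_equal(sort(members), sort(AA_ORDER))
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("property classes survive a write/read round-trip", {
  tab <- synthetic_property_table(12, 3, n_missing = 2, seed = 17)
  res <- build_property_classes(tab, 0.25)
  dir <- withr::local_tempdir()
  write_property_classes(res, dir)
  back <- read_property_classes(dir)
  expect_equal(back$classes$means, res$classes$means, tolerance = 1e-12)
  expect_equal(back$quad$groups, res$quad$groups)
  expect_equal(back$threshold_fraction, 0.25)
  # the reloaded tables drive the encoder identically
  w <- random_window(10)
  p <- blocking_params(10, 2)
  expect_equal(encode_block(w, back$classes, back$quad, p),
               encode_block(w, res$classes, res$quad, p), tolerance = 1e-12)
})
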