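test_that("read_view parses well-formed matrices and flags blank rows", {
  p <- write_temp_view(matrix(c(1.5, 2, 3, 4, 5, 6), 3, 2),
                       ids = c("s1", "s2", "s3"), feats = c("g1", "g2"))
  v <- read_view(p, name = "mrna")
  expect_s3_class(v, "omics_view")
  expect_equal(dim(v), c(3L, 2L))
  expect_equal(v$sample_ids, c("s1", "s2", "s3"))
  expect_true(all(v$observed))
  expect_equal(v$values[2, 1], 2)

  # blank row -> observed = FALSE for that sample only
  writeLines(c("sample_id\tg1\tg2", "s1\t1\t2", "s2\t\t", "s3\t5\t6"),
             p2 <- tempfile(fileext = ".tsv"))
  v2 <- read_view(p2)
  expect_equal(v2$observed, c(TRUE, FALSE, TRUE))

  # csv dialect
  pc <- write_temp_view(matrix(1:4, 2, 2), c("a", "b"), c("f1", "f2"),
                        sep = ",", ext = ".csv")
  expect_equal(dim(read_view(pc)), c(2L, 2L))
})

test_that("read_view rejects malformed input with informative errors", {
  writeLines(c("sample_id\tg1", "s1\t1", "s1\t2"),
             p <- tempfile(fileext = ".tsv"))
  expect_error(read_view(p), "duplicate sample ID")

  writeLines(c("sample_id\tg1\tg2", "s1\t1\tabc"),
             p2 <- tempfile(fileext = ".tsv"))
  expect_error(read_view(p2), "non-numeric cell.*g2")

  expect_error(read_view(tempfile()), "not found")
})

test_that("write_view round-trips through read_view", {
  x <- matrix(rnorm(12), 4, 3)
  v <- omics_view(x, "v", paste0("s", 1:4), paste0("f", 1:3))
  p <- tempfile(fileext = ".tsv")
  write_view(v, p)
  v2 <- read_view(p)
  expect_equal(v2$values, v$values, tolerance = 1e-12)
  expect_equal(v2$feature_ids, v$feature_ids)
})

test_that("log_transform computes log2(1 + x) and rejects negatives", {
  v <- omics_view(matrix(c(0, 1, 7, 3), 2, 2), "v")
  out <- log_transform(v)
  expect_equal(out$values[1, 1], 0)   # log2(1) = 0
  expect_equal(out$values[2, 1], 1)   # log2(2) = 1
  expect_equal(out$values[1, 2], 3)   # log2(8) = 3
  vneg <- omics_view(matrix(c(-1, 2), 1, 2), "v")
  expect_error(log_transform(vneg), "non-negative")
})

test_that("drop_zero_variance removes exactly the constant features", {
  x <- matrix(rnorm(20), 4, 5)
  x[, 2] <- 7; x[, 5] <- 0
  v <- omics_view(x, "v", feature_ids = paste0("f", 1:5))
  out <- drop_zero_variance(v)
  # brute-force per-column variance oracle
  keep <- apply(x, 2, function(col) var(col) > 0)
  expect_equal(out$feature_ids, paste0("f", 1:5)[keep])
  expect_equal(out$values, x[, keep, drop = FALSE],
               ignore_attr = TRUE)
  # identity when nothing is constant
  v2 <- omics_view(matrix(rnorm(12), 4, 3), "v")
  expect_identical(drop_zero_variance(v2)$values, v2$values)
  # all-constant -> error
  v3 <- omics_view(matrix(1, 3, 2), "v")
  expect_error(drop_zero_variance(v3), "zero variance")
})

test_that("select_top_variance matches exhaustive variance ranking", {
  set.seed(7)
  x <- matrix(rnorm(15), 3, 5) %*% diag(c(0.1, 5, 1, 3, 0.5))
  v <- omics_view(x, "v", feature_ids = paste0("f", 1:5))
  out <- select_top_variance(v, 2)
  pvar <- apply(x, 2, function(c) mean(c^2) - mean(c)^2)
  want <- sort(order(-pvar)[1:2])
  expect_equal(out$feature_ids, paste0("f", 1:5)[want])
  # min(n, D) rule
  expect_equal(ncol(select_top_variance(v, 10)$values), 5L)
  # idempotence at the same n
  expect_identical(select_top_variance(out, 2), out)
  # ties broken by original feature order
  xt <- cbind(c(1, 2, 3), c(3, 2, 1), c(1, 1, 1))
  vt <- omics_view(xt, "v", feature_ids = c("a", "b", "c"))
  expect_equal(select_top_variance(vt, 1)$feature_ids, "a")
})

test_that("zscore standardizes with population sd and is idempotent", {
  v <- omics_view(cbind(c(1, 2, 3)), "v")
  out <- zscore(v)
  expect_equal(unname(out$values[, 1]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  out2 <- zscore(out)
  expect_equal(out2$values, out$values, tolerance = 1e-8)
  expect_error(zscore(omics_view(cbind(c(1, 1, 1)), "v")),
               "zero-variance")
  # property: random matrices come out with mean ~0, sd ~1 per feature
  set.seed(11)
  for (rep in 1:5) {
    z <- zscore(omics_view(matrix(rnorm(60, sd = rep), 12, 5), "v"))$values
    expect_lt(max(abs(colMeans(z))), 1e-8)
    expect_lt(max(abs(sqrt(colMeans(z^2) - colMeans(z)^2) - 1)), 1e-6)
  }
})

test_that("preprocessing statistics ignore unobserved rows", {
  x <- rbind(c(1, 10), c(2, 20), c(999, 999))
  v <- omics_view(x, "v", observed = c(TRUE, TRUE, FALSE))
  z <- zscore(v)
  expect_equal(unname(z$values[1:2, 1]), c(-1, 1))
  expect_true(all(z$values[3, ] == 0))
})

test_that("align_samples builds the union ordering and per-view masks", {
  va <- omics_view(matrix(1:6, 3, 2), "a", c("s1", "s2", "s3"))
  vb <- omics_view(matrix(1:4, 2, 2), "b", c("s1", "s2"))
  ds <- align_samples(list(va, vb))
  expect_equal(ds$sample_ids, c("s1", "s2", "s3"))
  expect_true(all(ds$views$a$observed))
  expect_equal(ds$views$b$observed, c(TRUE, TRUE, FALSE))
  # identical IDs -> all masks true
  ds2 <- align_samples(list(va, omics_view(matrix(1:6, 3, 2), "b2",
                                           c("s1", "s2", "s3"))))
  expect_true(all(vapply(ds2$views, function(v) all(v$observed),
                         logical(1))))
  # clinical extras are dropped with a message
  cl <- clinical_table(data.frame(sample_id = c("s1", "s2", "s3", "zz"),
                                  time = 1:4, event = c(1, 0, 1, 1)))
  expect_message(ds3 <- align_samples(list(va), cl), "ignored")
  expect_equal(nrow(ds3$clinical), 3L)
})

test_that("the full preprocessing pipeline is deterministic", {
  set.seed(5)
  x <- matrix(rexp(200), 10, 20)
  v <- omics_view(x, "v")
  a <- preprocess_view(v, count_like = TRUE, n_top = 8)
  b <- preprocess_view(v, count_like = TRUE, n_top = 8)
  expect_identical(a, b)
  expect_equal(ncol(a$values), 8L)
})
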