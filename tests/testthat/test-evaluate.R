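test_that("kmeans_assign splits separated clouds and is seed-stable", {
  set.seed(30)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  lab <- kmeans_assign(x, 2, seed = 3)
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_equal(length(unique(lab[21:40])), 1L)
  expect_false(lab[1] == lab[21])
  expect_identical(lab, kmeans_assign(x, 2, seed = 3))
  expect_equal(kmeans_assign(x, 1, seed = 1), rep(1L, 40))
  expect_error(kmeans_assign(x[1:3, ], 5, seed = 1), "exceeds")
})

test_that("log-rank test matches a hand-tabulated O-E oracle", {
  # 2-group toy: times 1..4, all events, groups A A B B
  cl <- clinical_table(data.frame(sample_id = paste0("s", 1:4),
                                  time = 1:4, event = 1))
  lr <- logrank_test(c("A", "A", "B", "B"), cl)
  want <- oracle_logrank2(1:4, rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, want, tolerance = 1e-9)
  expect_equal(lr$df, 1L)
  expect_equal(lr$neg_log10_p, -log10(lr$p))
  # identical survival in both groups -> statistic ~ 0, p ~ 1
  cl2 <- clinical_table(data.frame(sample_id = paste0("s", 1:6),
                                   time = rep(c(1, 2, 3), 2),
                                   event = 1))
  lr2 <- logrank_test(rep(c("A", "B"), each = 3), cl2)
  expect_lt(lr2$statistic, 1e-10)
  expect_equal(lr2$p, 1, tolerance = 1e-8)
  expect_equal(lr2$neg_log10_p, 0, tolerance = 1e-8)
  expect_error(logrank_test(rep("A", 4), cl), ">= 2 groups")
})

test_that("log-rank agrees with the O-E oracle across random datasets", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    time <- rexp(n, 0.1)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2) group[1:2] <- c("A", "B")
    cl <- clinical_table(data.frame(sample_id = paste0("s", 1:n),
                                    time = time, event = event))
    expect_equal(logrank_test(group, cl)$statistic,
                 oracle_logrank2(time, event, group), tolerance = 1e-6)
  }
})

test_that("clinical enrichment counts significant labels at p < 0.05", {
  # perfectly aligned discrete label (10/0 vs 0/10) -> significant
  lab <- rep(1:2, each = 10)
  cl <- clinical_table(data.frame(
    sample_id = paste0("s", 1:20),
    grade = rep(c("lo", "hi"), each = 10),
    noise = rep(c("x", "y"), 10)))
  enr <- clinical_enrichment(lab, cl)
  expect_equal(enr$n_enriched, 1L)
  expect_lt(enr$tests$p[enr$tests$label == "grade"], 0.05)
  # chi-square value matches stats::chisq.test without correction
  expect_equal(enr$tests$p[1],
               suppressWarnings(
                 chisq.test(table(lab, cl$grade), correct = FALSE)$p.value))
  # continuous label via Kruskal-Wallis
  cl2 <- clinical_table(data.frame(sample_id = paste0("s", 1:20),
                                   age = c(rnorm(10, 40), rnorm(10, 80))))
  expect_equal(clinical_enrichment(lab, cl2)$n_enriched, 1L)
  # single-category label skipped with warning
  cl3 <- clinical_table(data.frame(sample_id = paste0("s", 1:20),
                                   sex = rep("F", 20)))
  expect_warning(out <- clinical_enrichment(lab, cl3), "single category")
  expect_equal(out$n_enriched, 0L)
})

test_that("independent labels are rarely enriched", {
  set.seed(32)
  hits <- 0L
  for (rep in 1:20) {
    lab <- sample(1:4, 200, replace = TRUE)
    cl <- clinical_table(data.frame(sample_id = paste0("s", 1:200),
                                    g = sample(c("a", "b"), 200, TRUE)))
    hits <- hits + clinical_enrichment(lab, cl)$n_enriched
  }
  expect_lte(hits, 4L)   # ~5% false positive rate over 20 reps
})

test_that("external metrics are exact on canonical cases", {
  truth <- rep(1:3, each = 5)
  # permuted labels: all metrics 1
  perm <- c(3, 1, 2)[truth]
  m <- external_metrics(perm, truth)
  expect_equal(unlist(m), c(acc = 1, nmi = 1, ari = 1, purity = 1))
  # single cluster over 2 balanced classes
  m2 <- external_metrics(rep(1, 20), rep(1:2, each = 10))
  expect_equal(m2$purity, 0.5)
  expect_equal(m2$acc, 0.5)
  expect_equal(m2$ari, 0)
  expect_equal(m2$nmi, 0)
})

test_that("external metrics match brute-force references on random labelings", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    m <- external_metrics(a, b)
    expect_equal(m$ari, oracle_ari(a, b), tolerance = 1e-8)
    expect_equal(m$acc, oracle_acc(a, b), tolerance = 1e-8)
    tab <- table(a, b)
    expect_equal(m$purity, sum(apply(tab, 1, max)) / n, tolerance = 1e-12)
    # label-permutation invariance on both sides
    m2 <- external_metrics(c(3, 1, 2)[a], c(2, 3, 4, 1)[b])
    expect_equal(unlist(m2), unlist(m), tolerance = 1e-10)
  }
  # ARI cross-check against an independent implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    set.seed(34)
    for (rep in 1:10) {
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(external_metrics(a, b)$ari,
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-10)
    }
  }
})

test_that("silhouette agrees with the a/b definition and handles singletons", {
  set.seed(35)
  x <- matrix(rnorm(60), 30, 2)
  lab <- sample(1:3, 30, replace = TRUE)
  expect_equal(silhouette_width(x, lab), oracle_silhouette(x, lab),
               tolerance = 1e-8)
  # two tight, far-apart clusters -> silhouette near 1
  y <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
             matrix(rnorm(20, 100, 0.01), 10, 2))
  expect_gt(silhouette_width(y, rep(1:2, each = 10)), 0.99)
  # singleton cluster contributes 0
  z <- rbind(c(0, 0), c(0.1, 0), c(50, 50))
  expect_equal(silhouette_width(z, c(1, 1, 2)),
               oracle_silhouette(z, c(1, 1, 2)), tolerance = 1e-8)
  expect_error(silhouette_width(x, rep(1, 30)), ">= 2 clusters")
})

test_that("PAC is 0 for perfectly stable clusterings and tracks separation", {
  set.seed(36)
  far <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 50), 30, 2))
  expect_equal(pac_score(far, 2, reps = 30, seed = 2), 0)
  # PAC does not increase as separation grows
  pacs <- vapply(c(0, 2, 8), function(sep) {
    spec <- synthetic_spec(n_samples = 80, n_clusters = 2, view_dims = 6,
                           separation = sep, seed = 37)
    x <- generate_multiview(spec)$dataset$views$view1$values
    pac_score(x, 2, reps = 40, seed = 3)
  }, numeric(1))
  expect_lte(pacs[3], pacs[1])
  expect_lte(pacs[3], pacs[2])
})

test_that("select_k prefers survival separation and falls back to silhouette", {
  # majority vote over replicate cohorts with 4 true hazard groups
  picks <- vapply(1:7, function(r) {
    spec <- synthetic_spec(n_samples = 200, n_clusters = 4,
                           view_dims = 10, separation = 8,
                           hazard_per_cluster = c(1, 3, 9, 27) / 1000,
                           seed = 38 + r)
    sim <- generate_multiview(spec)
    x <- sim$dataset$views$view1$values
    rownames(x) <- sim$dataset$sample_ids
    cl <- generate_survival(sim$truth, spec)
    select_k(x, cl, candidates = 3:5, seed = 4)$k
  }, integer(1))
  expect_gte(sum(picks == 4L), 4L)
  spec <- synthetic_spec(n_samples = 200, n_clusters = 4,
                         view_dims = 10, separation = 8,
                         hazard_per_cluster = c(1, 3, 9, 27) / 1000,
                         seed = 39)
  sim <- generate_multiview(spec)
  x <- sim$dataset$views$view1$values
  rownames(x) <- sim$dataset$sample_ids
  cl <- generate_survival(sim$truth, spec)
  sel <- select_k(x, cl, candidates = 3:5, seed = 4)
  expect_equal(sel$criterion, "logrank")
  # degenerate survival (no events) -> silhouette fallback
  cl0 <- cl; cl0$event <- 0
  sel0 <- select_k(x, cl0, candidates = 3:5, seed = 4)
  expect_equal(sel0$criterion, "silhouette")
  expect_true(sel0$k %in% 3:5)
  # no clinical at all -> silhouette
  expect_equal(select_k(x, NULL, candidates = 3:5, seed = 4)$criterion,
               "silhouette")
})
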