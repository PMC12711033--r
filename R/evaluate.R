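# Subtype assignment and the evaluation battery: K-means with
# cluster-number selection, log-rank survival separation, clinical label
# enrichment, external clustering metrics (ACC/NMI/ARI/purity), silhouette
# width, and the proportion of ambiguous clustering (PAC).

#' K-means subtype assignment
#'
#' Lloyd's K-means with 10 random restarts; the restart with the lowest
#' within-cluster sum of squares is kept. Deterministic under `seed`.
#'
#' @param features numeric matrix, samples in rows.
#' @param k number of clusters (`k <= N`).
#' @param seed integer seed.
#' @param nstart number of restarts.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
kmeans_assign <- function(features, k, seed = 1L, nstart = 10L) {
  features <- as.matrix(features)
  if (k > nrow(features)) stop("k (", k, ") exceeds sample count (",
                               nrow(features), ")")
  if (k == 1L) return(rep(1L, nrow(features)))
  with_seed(seed, {
    km <- stats::kmeans(features, centers = k, nstart = nstart,
                        iter.max = 100L)
  })
  as.integer(km$cluster)
}

#' Select the number of clusters
#'
#' Each candidate `k` is clustered by K-means and scored by the log-rank
#' test's -log10 P across the resulting groups; the candidate with the
#' strongest survival separation wins (ties -> smaller k). Without
#' survival data the candidate with the highest silhouette width wins.
#'
#' @param features numeric matrix, samples in rows (aligned to
#'   `clinical$sample_id` by rowname when available).
#' @param clinical optional [clinical_table()] with `time` and `event`.
#' @param candidates candidate cluster numbers (default 3, 4, 5).
#' @param seed integer seed for the K-means runs.
#' @return List with the chosen `k`, per-candidate `scores`, and the
#'   `criterion` used (`"logrank"` or `"silhouette"`).
#' @export
select_k <- function(features, clinical = NULL, candidates = 3:5,
                     seed = 1L) {
  features <- as.matrix(features)
  candidates <- candidates[candidates <= nrow(features)]
  if (length(candidates) == 0L) stop("no feasible candidate k")
  surv_ok <- !is.null(clinical) && all(c("time", "event") %in% names(clinical)) &&
    sum(clinical$event, na.rm = TRUE) >= 1 &&
    stats::var(clinical$time, na.rm = TRUE) > 0
  scores <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    lab <- kmeans_assign(features, candidates[i],
                         seed = derive_seed(seed, paste0("selk", candidates[i])))
    scores[i] <- if (surv_ok) {
      cl <- match_clinical(clinical, rownames(features))
      tryCatch(logrank_test(lab, cl)$neg_log10_p, error = function(e) -Inf)
    } else {
      silhouette_width(features, lab)
    }
  }
  best <- candidates[which.max(scores)]   # which.max: first max -> smaller k
  list(k = best, candidates = candidates, scores = scores,
       criterion = if (surv_ok) "logrank" else "silhouette")
}

# Reorder a clinical table to match a sample-ID vector (NULL ids = as-is).
match_clinical <- function(clinical, ids) {
  if (is.null(ids)) return(clinical)
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx))
    stop(sum(is.na(idx)), " samples have no clinical row")
  clinical[idx, , drop = FALSE]
}

#' K-group log-rank test
#'
#' Chi-square log-rank statistic with `k - 1` degrees of freedom across
#' the clusters, via [survival::survdiff()].
#'
#' @param labels cluster labels (length N).
#' @param clinical [clinical_table()] with `time` and `event`, ordered as
#'   `labels`.
#' @return List with `statistic`, `df`, `p`, `neg_log10_p`.
#' @export
logrank_test <- function(labels, clinical) {
  stopifnot(length(labels) == nrow(clinical))
  groups <- factor(labels)
  if (nlevels(groups) < 2L) stop("log-rank test needs >= 2 groups")
  if (sum(clinical$event, na.rm = TRUE) < 1) stop("no events observed")
  sd <- survival::survdiff(
    survival::Surv(clinical$time, clinical$event) ~ groups)
  df <- nlevels(groups) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), df = df, p = p,
       neg_log10_p = -log10(p))
}

#' Clinical label enrichment
#'
#' Tests each clinical label for association with cluster membership:
#' chi-square (without continuity correction) on the cluster-by-category
#' contingency table for discrete labels, Kruskal-Wallis across clusters
#' for continuous labels. Missing values are dropped per label; labels
#' with a single observed category are skipped with a warning.
#'
#' @param labels cluster labels (length N).
#' @param clinical [clinical_table()] ordered as `labels`; every column
#'   other than `sample_id`, `time`, `event` is treated as a label
#'   (character/factor = discrete, numeric = continuous).
#' @param alpha significance cut (default 0.05).
#' @return List with `n_enriched`, and a data.frame `tests` of per-label
#'   p-values.
#' @export
clinical_enrichment <- function(labels, clinical, alpha = 0.05) {
  stopifnot(length(labels) == nrow(clinical))
  label_cols <- setdiff(names(clinical), c("sample_id", "time", "event"))
  if (length(label_cols) == 0L) stop("clinical table has no label columns")
  rows <- lapply(label_cols, function(col) {
    x <- clinical[[col]]
    keep <- !is.na(x)
    cl <- factor(labels[keep])
    x <- x[keep]
    discrete <- is.character(x) || is.factor(x) || is.logical(x)
    if (discrete) {
      x <- factor(x)
      if (nlevels(x) < 2L || nlevels(cl) < 2L) {
        warning("label '", col, "' has a single category; skipped")
        return(data.frame(label = col, type = "discrete", p = NA_real_))
      }
      tab <- table(cl, x)
      if (any(suppressWarnings(stats::chisq.test(tab)$expected) < 5))
        message("label '", col, "': expected counts < 5 in some cells")
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      data.frame(label = col, type = "discrete", p = p)
    } else {
      if (nlevels(cl) < 2L || stats::var(x) == 0) {
        warning("label '", col, "' is constant; skipped")
        return(data.frame(label = col, type = "continuous", p = NA_real_))
      }
      p <- stats::kruskal.test(x, cl)$p.value
      data.frame(label = col, type = "continuous", p = p)
    }
  })
  tests <- do.call(rbind, rows)
  list(n_enriched = sum(tests$p < alpha, na.rm = TRUE), tests = tests)
}

# Exhaustive optimal one-to-one cluster/class matching for ACC. Pads the
# confusion matrix to square and enumerates permutations of the smaller
# side; exact for up to 8 clusters (all supported uses have k <= 5).
.best_match_count <- function(tab) {
  k <- max(dim(tab))
  if (k > 8L) stop("exhaustive cluster matching supports at most 8 clusters")
  M <- matrix(0, k, k)
  M[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, sum(M[cbind(seq_len(k), p)]))
  best
}

#' External clustering metrics
#'
#' Clustering accuracy (optimal one-to-one cluster-to-class matching),
#' normalized mutual information (arithmetic-mean normalization),
#' adjusted Rand index, and purity.
#'
#' @param labels predicted cluster labels.
#' @param truth ground-truth class labels (same length).
#' @return Named list `acc`, `nmi`, `ari`, `purity`.
#' @export
external_metrics <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  n <- length(labels)
  tab <- table(labels, truth)
  acc <- .best_match_count(tab) / n
  purity <- sum(apply(tab, 1L, max)) / n

  # NMI with arithmetic-mean normalization
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  pjk <- tab / n
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / (pj[row(tab)[nz]] * pk[col(tab)[nz]])))
  hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hk <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  nmi <- if (hj + hk == 0) 1 else 2 * mi / (hj + hk)

  # ARI from the pair-counting contingency formula
  a <- rowSums(tab); b <- colSums(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  exp_idx <- sum_comb(a) * sum_comb(b) / choose(n, 2)
  max_idx <- (sum_comb(a) + sum_comb(b)) / 2
  ari <- if (max_idx == exp_idx) 0 else (idx - exp_idx) / (max_idx - exp_idx)

  list(acc = acc, nmi = max(0, min(1, nmi)), ari = ari, purity = purity)
}

#' Mean silhouette width
#'
#' Euclidean-distance silhouette averaged over samples; members of
#' singleton clusters contribute 0.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels cluster labels with >= 2 distinct values.
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_width <- function(features, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette needs >= 2 clusters")
  sil <- cluster::silhouette(labels, stats::dist(features))
  mean(sil[, "sil_width"])
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Consensus clustering by repeated subsampled K-means: in each rep a
#' random `subsample` fraction of the samples is clustered and
#' co-clustering is recorded for all co-subsampled pairs. PAC is the
#' fraction of pairs whose consensus index lies strictly inside
#' `(u1, u2)`; lower is more stable.
#'
#' @param features numeric matrix, samples in rows.
#' @param k number of clusters per rep.
#' @param reps number of subsampling repetitions (default 100).
#' @param subsample fraction of samples per rep (default 0.8).
#' @param seed integer seed.
#' @param u1,u2 ambiguity band (default 0.1, 0.9).
#' @return Scalar in `[0, 1]`.
#' @export
pac_score <- function(features, k, reps = 100L, subsample = 0.8,
                      seed = 1L, u1 = 0.1, u2 = 0.9) {
  stopifnot(reps >= 2L, subsample > 0, subsample <= 1, u1 < u2)
  features <- as.matrix(features)
  n <- nrow(features)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, max(k, round(subsample * n))))
      km <- stats::kmeans(features[idx, , drop = FALSE], centers = k,
                          nstart = 3L, iter.max = 100L)
      same <- outer(km$cluster, km$cluster, "==")
      co_cluster[idx, idx] <- co_cluster[idx, idx] + same
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
    }
  })
  ut <- upper.tri(co_sample)
  seen <- ut & co_sample > 0
  consensus <- co_cluster[seen] / co_sample[seen]
  mean(consensus > u1 & consensus < u2)
}
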