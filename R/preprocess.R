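# Preprocessing for omics matrices: log transform (sequencing-derived
# count-like views), zero-variance feature removal, top-variance feature
# selection, and per-feature z-scoring. All feature statistics are computed
# over observed samples only; unobserved rows are carried through as zeros
# and excluded from every statistic.

# Population (divide-by-N) per-feature variance over observed rows.
# Ranking by variance is invariant to the N vs N-1 convention; the
# population form is used throughout for consistency with z-scoring.
.feature_var <- function(view) {
  x <- view$values[view$observed, , drop = FALSE]
  n <- nrow(x)
  if (n == 0L) stop("view '", view$name, "' has no observed samples")
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}

#' Log-transform a count-like view
#'
#' Applies `log2(1 + x)` elementwise. Intended for sequencing-derived
#' expression views (mRNA, miRNA); methylation beta values are typically
#' left untransformed.
#'
#' @param view an [omics_view()]; all observed values must be non-negative.
#' @return The transformed view.
#' @export
log_transform <- function(view) {
  obs <- view$values[view$observed, , drop = FALSE]
  if (any(obs < 0))
    stop("log_transform requires non-negative values (view '", view$name, "')")
  view$values[view$observed, ] <- log2(1 + obs)
  view
}

#' Drop features with zero variance
#'
#' Removes features whose sample variance over observed rows is exactly
#' zero, preserving the order of the survivors.
#'
#' @param view an [omics_view()].
#' @return The filtered view.
#' @export
drop_zero_variance <- function(view) {
  v <- .feature_var(view)
  keep <- v > 0
  if (!any(keep))
    stop("all features in view '", view$name, "' have zero variance")
  if (all(keep)) return(view)
  omics_view(view$values[, keep, drop = FALSE], name = view$name,
             sample_ids = view$sample_ids,
             feature_ids = view$feature_ids[keep], observed = view$observed)
}

#' Keep the most variable features
#'
#' Retains the `min(n, D)` features with the largest variance. Ties are
#' broken by original feature order so the selection is reproducible.
#'
#' @param view an [omics_view()].
#' @param n number of features to keep (default 2000).
#' @return The reduced view.
#' @export
select_top_variance <- function(view, n = 2000L) {
  stopifnot(n >= 1L)
  v <- .feature_var(view)
  n <- min(n, length(v))
  ord <- order(-v, seq_along(v))          # stable: ties keep original order
  keep <- sort(ord[seq_len(n)])           # survivors keep original order
  omics_view(view$values[, keep, drop = FALSE], name = view$name,
             sample_ids = view$sample_ids,
             feature_ids = view$feature_ids[keep], observed = view$observed)
}

#' Z-score features to zero mean and unit standard deviation
#'
#' Per-feature standardisation using the population (divide-by-N) standard
#' deviation over observed rows. Zero-variance features are an error; drop
#' them first with [drop_zero_variance()].
#'
#' @param view an [omics_view()].
#' @return The standardised view.
#' @export
zscore <- function(view) {
  v <- .feature_var(view)
  if (any(v <= 0))
    stop("zero-variance feature(s) in view '", view$name,
         "': ", paste(utils::head(view$feature_ids[v <= 0], 5L), collapse = ", "),
         " - drop them before z-scoring")
  x <- view$values[view$observed, , drop = FALSE]
  mu <- colMeans(x)
  view$values[view$observed, ] <- sweep(sweep(x, 2L, mu), 2L, sqrt(v), "/")
  view$values[!view$observed, ] <- 0
  view
}

#' Run the standard preprocessing pipeline on one view
#'
#' Order: optional `log2(1+x)` (count-like views only), zero-variance
#' removal, top-`n` variance selection, z-scoring. The pipeline is fully
#' deterministic.
#'
#' @param view an [omics_view()].
#' @param count_like apply the log transform first? Use `TRUE` for
#'   mRNA/miRNA expression, `FALSE` for methylation beta values.
#' @param n_top number of top-variance features to keep.
#' @return The preprocessed view.
#' @export
preprocess_view <- function(view, count_like = TRUE, n_top = 2000L) {
  if (count_like) view <- log_transform(view)
  view <- drop_zero_variance(view)
  view <- select_top_variance(view, n_top)
  zscore(view)
}

#' Preprocess every view of a multi-view dataset
#'
#' @param ds a `multi_omics` dataset from [align_samples()].
#' @param count_like logical vector (recycled) saying per view whether the
#'   log transform applies.
#' @param n_top number of top-variance features to keep per view.
#' @return The dataset with preprocessed views.
#' @export
preprocess_dataset <- function(ds, count_like = TRUE, n_top = 2000L) {
  count_like <- rep_len(count_like, length(ds$views))
  ds$views <- Map(function(v, cl) preprocess_view(v, cl, n_top),
                  ds$views, count_like)
  ds
}
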