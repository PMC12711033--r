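# Synthetic multi-view generator. Emulates the structure the subtyping
# pipeline consumes: V views sharing one latent cluster partition,
# view-specific Gaussian noise, optional missing views, cluster-linked
# exponential survival, and range-scaled Gaussian augmentation. It does not
# attempt to mimic real omics marginals (counts, beta values).

#' Specification of a synthetic multi-view dataset
#'
#' @param n_samples number of samples.
#' @param n_clusters number of latent clusters shared by all views.
#' @param view_dims integer vector of per-view feature counts.
#' @param separation minimum pairwise distance between cluster centroids,
#'   in units of `noise_sd`.
#' @param noise_sd within-cluster Gaussian noise standard deviation
#'   (isotropic, per view).
#' @param missing_rate fraction of samples in `[0, 1)` that lose at least
#'   one view.
#' @param hazard_per_cluster per-cluster exponential event rates
#'   (events/day). Default spans a 3-fold hazard ratio around a
#'   1/1000-days baseline.
#' @param censor_time administrative right-censoring time (days).
#' @param seed integer seed; every generator below is a pure function of
#'   (spec, seed).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 400L, n_clusters = 4L,
                           view_dims = c(100L, 80L, 60L),
                           separation = 8, noise_sd = 1,
                           missing_rate = 0,
                           hazard_per_cluster = NULL,
                           censor_time = 3000, seed = 1L) {
  if (is.null(hazard_per_cluster)) {
    expo <- if (n_clusters > 1L) (seq_len(n_clusters) - 1L) / (n_clusters - 1L) else 0
    hazard_per_cluster <- (1 / 1000) * 3^expo
  }
  spec <- list(n_samples = as.integer(n_samples),
               n_clusters = as.integer(n_clusters),
               view_dims = as.integer(view_dims),
               separation = separation, noise_sd = noise_sd,
               missing_rate = missing_rate,
               hazard_per_cluster = hazard_per_cluster,
               censor_time = censor_time, seed = as.integer(seed))
  stopifnot(spec$n_samples >= spec$n_clusters, spec$n_clusters >= 1L,
            all(spec$view_dims >= 1L), spec$separation >= 0,
            spec$noise_sd > 0, spec$missing_rate >= 0, spec$missing_rate < 1,
            length(spec$hazard_per_cluster) == spec$n_clusters,
            all(spec$hazard_per_cluster > 0), spec$censor_time >= 0)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a multi-view dataset with known cluster structure
#'
#' Labels are balanced up to rounding and shuffled. Per view, cluster
#' centroids are drawn from an isotropic Gaussian and rescaled so the
#' minimum pairwise centroid distance equals `separation * noise_sd`;
#' sample `i` is then `centroid[label_i] + N(0, noise_sd^2 I)`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `dataset` (a `multi_omics` object) and `truth`
#'   (list of `labels` in `1..n_clusters` and per-view `centroids`).
#' @export
generate_multiview <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_clusters; n <- spec$n_samples
  with_seed(derive_seed(spec$seed, "multiview"), {
    labels <- sample(rep_len(seq_len(k), n))
    centroids <- vector("list", length(spec$view_dims))
    views <- vector("list", length(spec$view_dims))
    for (v in seq_along(spec$view_dims)) {
      d <- spec$view_dims[v]
      cen <- matrix(stats::rnorm(k * d), k, d)
      if (k > 1L) {
        min_dist <- min(stats::dist(cen))
        cen <- cen * (spec$separation * spec$noise_sd / min_dist)
      }
      x <- cen[labels, , drop = FALSE] +
        matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
      ids <- sprintf("S%04d", seq_len(n))
      views[[v]] <- omics_view(
        x, name = paste0("view", v), sample_ids = ids,
        feature_ids = sprintf("V%d_F%04d", v, seq_len(d)))
      centroids[[v]] <- cen
    }
    ds <- align_samples(views)
    if (spec$missing_rate > 0)
      ds <- apply_missing(ds, spec$missing_rate,
                          derive_seed(spec$seed, "missing"))
    list(dataset = ds,
         truth = list(labels = labels, centroids = centroids))
  })
}

#' Generate cluster-linked survival and clinical labels
#'
#' Survival times are exponential with cluster-specific rates, right
#' censored administratively at `censor_time`. Two clinical labels are
#' attached for enrichment testing: `grade`, a discrete noisy copy of the
#' cluster label (flipped to a random other cluster with probability
#' `label_flip_rate`), and `age`, a continuous covariate whose mean shifts
#' with the cluster.
#'
#' @param truth ground truth from [generate_multiview()].
#' @param spec the matching [synthetic_spec()].
#' @param label_flip_rate probability a sample's discrete label disagrees
#'   with its cluster (1 - 1/k of flips land on another category).
#' @param age_shift per-cluster shift (years) of the mean of `age`.
#' @return A [clinical_table()] with columns `sample_id, time, event,
#'   grade, age`.
#' @export
generate_survival <- function(truth, spec, label_flip_rate = 0.3,
                              age_shift = 4) {
  labels <- truth$labels
  n <- length(labels)
  k <- spec$n_clusters
  with_seed(derive_seed(spec$seed, "survival"), {
    rate <- spec$hazard_per_cluster[labels]
    t_event <- stats::rexp(n, rate = rate)
    event <- as.integer(t_event <= spec$censor_time)
    time <- pmin(t_event, spec$censor_time)
    flip <- stats::runif(n) < label_flip_rate
    grade <- labels
    if (k > 1L && any(flip))
      grade[flip] <- vapply(labels[flip], function(l)
        sample(setdiff(seq_len(k), l), 1L), integer(1))
    age <- stats::rnorm(n, mean = 60 + age_shift * (labels - (k + 1) / 2),
                        sd = 10)
    clinical_table(data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      time = time, event = event,
      grade = paste0("G", grade), age = age,
      stringsAsFactors = FALSE))
  })
}

#' Mask views at random to emulate incomplete multi-omics data
#'
#' Exactly `round(rate * N)` samples (chosen uniformly at random) lose at
#' least one view; the number and identity of masked views per affected
#' sample are uniform, subject to every sample keeping at least one
#' observed view.
#'
#' @param ds a `multi_omics` dataset whose views are currently observed.
#' @param rate fraction of samples in `[0, 1)` to affect.
#' @param seed integer seed.
#' @return The dataset with updated `observed` masks (masked rows zeroed).
#' @export
apply_missing <- function(ds, rate, seed = 1L) {
  stopifnot(inherits(ds, "multi_omics"), rate >= 0)
  if (rate >= 1) stop("missing rate must be < 1")
  V <- length(ds$views)
  if (rate == 0 || V < 2L) return(ds)
  n <- length(ds$sample_ids)
  n_affect <- round(rate * n)
  with_seed(seed, {
    hit <- sample.int(n, n_affect)
    for (i in hit) {
      avail <- which(vapply(ds$views, function(v) v$observed[i], logical(1)))
      if (length(avail) < 2L) next   # already down to its last view
      n_mask <- sample.int(length(avail) - 1L, 1L)
      drop <- sample(avail, n_mask)
      for (v in drop) {
        ds$views[[v]]$observed[i] <- FALSE
        ds$views[[v]]$values[i, ] <- 0
      }
    }
  })
  ds
}

#' Gaussian augmentation with range-scaled, dimension-varying noise
#'
#' Adds elementwise Gaussian noise whose standard deviation for feature
#' `d` is `0.05 * range_d * u_d` with `u_d ~ Uniform(0.5, 1.5)` drawn once
#' per feature: a base level of 5% of the feature's range, perturbed so the
#' noise is non-uniform across dimensions. Constant features (zero range)
#' are left untouched. Used to manufacture a second view when only a single
#' modality is available.
#'
#' @param view an [omics_view()].
#' @param seed integer seed.
#' @param base_sd_frac base noise level as a fraction of the feature range.
#' @return The augmented view (same name with suffix `_aug`).
#' @export
gaussian_augment <- function(view, seed = 1L, base_sd_frac = 0.05) {
  x <- view$values[view$observed, , drop = FALSE]
  rng <- apply(x, 2L, function(col) diff(range(col)))
  with_seed(seed, {
    u <- stats::runif(ncol(x), 0.5, 1.5)
    sds <- base_sd_frac * rng * u
    noise <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
    noise <- sweep(noise, 2L, sds, "*")
  })
  view$values[view$observed, ] <- x + noise
  view$name <- paste0(view$name, "_aug")
  view
}

#' Write a synthetic dataset (views + clinical) to a directory
#'
#' @param sim output of [generate_multiview()].
#' @param clinical optional [clinical_table()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, clinical = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in sim$dataset$views)
    write_view(v, file.path(dir, paste0(v$name, ".tsv")))
  utils::write.table(
    data.frame(sample_id = sim$dataset$sample_ids,
               label = sim$truth$labels),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(clinical))
    utils::write.table(clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
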