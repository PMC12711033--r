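# One-call subtyping pipeline: preprocess -> fit -> extract features ->
# select k -> K-means -> evaluation battery, with optional artifact
# output (labels, features, JSON report, config copy, loss history).

#' Build (or load) a pipeline configuration
#'
#' Either pass a YAML file path or named arguments. Recognized fields:
#' `views` (named list/vector of file paths) or `dataset` (an in-memory
#' `multi_omics` object), `clinical` (path or `clinical_table`),
#' `truth` (optional ground-truth labels for external metrics),
#' `count_like` (per-view logical, recycled), `n_top` (top-variance
#' feature count), `k_candidates`, `pac_reps`, `out_dir`, `seed`, and
#' `train` (a list of [train_config()] arguments).
#'
#' @param path optional YAML file.
#' @param ... fields overriding/completing the file's contents.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_top <- as.integer(cfg$n_top %||% 2000L)
  cfg$count_like <- cfg$count_like %||% TRUE
  cfg$k_candidates <- as.integer(cfg$k_candidates %||% 3:5)
  cfg$pac_reps <- as.integer(cfg$pac_reps %||% 100L)
  cfg$preprocess <- cfg$preprocess %||% TRUE
  train_args <- cfg$train %||% list()
  train_args$seed <- train_args$seed %||% derive_seed(cfg$seed, "train")
  train_args$k_candidates <- train_args$k_candidates %||% cfg$k_candidates
  cfg$train <- do.call(train_config, train_args)
  if (is.null(cfg$dataset) && is.null(cfg$views))
    stop("config needs either 'views' (file paths) or 'dataset'")
  if (!is.null(cfg$views)) {
    missing <- !vapply(unlist(cfg$views), file.exists, logical(1))
    if (any(missing))
      stop("view file(s) not found: ",
           paste(unlist(cfg$views)[missing], collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# Load + align the inputs a config describes.
.load_inputs <- function(cfg) {
  if (!is.null(cfg$dataset)) {
    ds <- cfg$dataset
    if (!is.null(cfg$clinical) && is.null(ds$clinical)) {
      cl <- if (is.character(cfg$clinical)) read_clinical(cfg$clinical)
            else clinical_table(cfg$clinical)
      ds <- align_samples(ds$views, cl)
    }
    return(ds)
  }
  paths <- unlist(cfg$views)
  nms <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
  views <- Map(read_view, paths, nms)
  cl <- NULL
  if (!is.null(cfg$clinical))
    cl <- if (is.character(cfg$clinical)) read_clinical(cfg$clinical)
          else clinical_table(cfg$clinical)
  align_samples(views, cl)
}

#' Run the full subtyping pipeline
#'
#' @param cfg a [pipeline_config()].
#' @return A `subtype_result`: cluster `labels` (named by sample ID),
#'   `n_clusters`, survival separation (`neg_log10_p`), clinical
#'   enrichment count, internal validity (`silhouette`, `pac`), external
#'   metrics when ground truth is supplied, the `k_selection` trace, the
#'   extracted `features`, and the trained `model`.
#' @export
run_subtyping <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  ds <- .load_inputs(cfg)
  if (isTRUE(cfg$preprocess))
    ds <- preprocess_dataset(ds, count_like = cfg$count_like,
                             n_top = cfg$n_top)
  model <- dcmc_fit(ds, cfg$train)
  features <- extract_features(model, ds)

  clinical <- ds$clinical
  if (!is.null(clinical))
    clinical <- match_clinical(clinical, rownames(features))
  sel <- select_k(features, clinical, candidates = cfg$k_candidates,
                  seed = derive_seed(cfg$seed, "selectk"))
  labels <- kmeans_assign(features, sel$k,
                          seed = derive_seed(cfg$seed, "kmeans"))
  names(labels) <- rownames(features)

  res <- list(labels = labels, n_clusters = sel$k, k_selection = sel,
              neg_log10_p = NA_real_, enriched_label_count = NA_integer_,
              internal = list(
                silhouette = silhouette_width(features, labels),
                pac = pac_score(features, sel$k, reps = cfg$pac_reps,
                                seed = derive_seed(cfg$seed, "pac"))),
              external = NULL, features = features, model = model,
              history = model$history)
  if (!is.null(clinical)) {
    if (all(c("time", "event") %in% names(clinical)) &&
        sum(clinical$event, na.rm = TRUE) >= 1) {
      lr <- logrank_test(labels, clinical)
      res$neg_log10_p <- lr$neg_log10_p
      res$logrank <- lr
    }
    lab_cols <- setdiff(names(clinical), c("sample_id", "time", "event"))
    if (length(lab_cols) > 0L) {
      enr <- clinical_enrichment(labels, clinical)
      res$enriched_label_count <- enr$n_enriched
      res$enrichment <- enr$tests
    }
  }
  truth <- cfg$truth
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(labels))
    res$external <- external_metrics(labels, truth)
  }
  class(res) <- "subtype_result"
  if (!is.null(cfg$out_dir)) .write_artifacts(res, cfg)
  res
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("<subtype_result> %d samples in %d clusters\n",
              length(x$labels), x$n_clusters))
  if (is.finite(x$neg_log10_p))
    cat(sprintf("  log-rank -log10 P: %.2f\n", x$neg_log10_p))
  if (!is.na(x$enriched_label_count))
    cat(sprintf("  enriched clinical labels: %d\n", x$enriched_label_count))
  cat(sprintf("  silhouette: %.3f  PAC: %.3f\n",
              x$internal$silhouette, x$internal$pac))
  if (!is.null(x$external))
    cat(sprintf("  ACC %.3f  NMI %.3f  ARI %.3f  purity %.3f\n",
                x$external$acc, x$external$nmi, x$external$ari,
                x$external$purity))
  invisible(x)
}

.write_artifacts <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(sample_id = names(res$labels), label = unname(res$labels)),
    file.path(cfg$out_dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(res$features), res$features,
               check.names = FALSE),
    file.path(cfg$out_dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    n_clusters = res$n_clusters,
    neg_log10_p = res$neg_log10_p,
    enriched_label_count = res$enriched_label_count,
    internal = res$internal, external = res$external,
    k_selection = res$k_selection[c("k", "candidates", "scores",
                                    "criterion")],
    seed = cfg$seed)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  ser <- cfg
  ser$dataset <- NULL; ser$truth <- NULL
  ser$train <- unclass(ser$train)
  yaml::write_yaml(unclass(ser), file.path(cfg$out_dir, "config.yaml"))
  if (nrow(res$history %||% data.frame()) > 0L)
    utils::write.table(res$history,
                       file.path(cfg$out_dir, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cfg$out_dir)
}

#' Run a component-ablation variant of the pipeline
#'
#' Variants mirror the component ablations: `full` is the complete
#' model; `no_decoder` applies the inter-view loss directly to the
#' online/target embeddings; `no_rectification` removes the
#' pseudo-target weighting entirely; `fne` hard-eliminates flagged false
#' negatives (weight 0); `shared_encoder` replaces the target encoder by
#' the online encoder.
#'
#' @param cfg a [pipeline_config()].
#' @param variant one of `"full"`, `"no_decoder"`, `"no_rectification"`,
#'   `"fne"`, `"shared_encoder"`.
#' @return A `subtype_result` (see [run_subtyping()]).
#' @export
run_ablation <- function(cfg, variant = c("full", "no_decoder",
                                          "no_rectification", "fne",
                                          "shared_encoder")) {
  variant <- match.arg(variant)
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  tr <- unclass(cfg$train)
  switch(variant,
         full = NULL,
         no_decoder = { tr$use_decoder <- FALSE },
         no_rectification = { tr$fn_mode <- "none" },
         fne = { tr$fn_mode <- "eliminate" },
         shared_encoder = { tr$shared_encoder <- TRUE })
  cfg$train <- do.call(train_config, tr)
  if (!is.null(cfg$out_dir))
    cfg$out_dir <- file.path(cfg$out_dir, variant)
  run_subtyping(cfg)
}
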