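#' Construct a single-omics view
#'
#' An `omics_view` holds one data modality (e.g. mRNA expression, miRNA
#' expression, DNA methylation) measured on a common set of samples: a
#' numeric sample-by-feature matrix together with an `observed` mask marking
#' the samples for which this modality was actually measured. Rows flagged
#' unobserved take no part in preprocessing statistics or model training;
#' their representation is recovered from an observed view at run time.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param name single string naming the view.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `values`).
#' @param feature_ids character vector of unique feature identifiers
#'   (default: colnames of `values`).
#' @param observed logical vector, one entry per sample; `FALSE` marks a
#'   sample for which this view is missing. Defaults to all `TRUE` except
#'   rows containing any non-finite value.
#' @return An object of class `omics_view`.
#' @export
omics_view <- function(values, name, sample_ids = rownames(values),
                       feature_ids = colnames(values), observed = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length (", length(sample_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length (", length(feature_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (is.null(observed)) {
    observed <- apply(values, 1L, function(r) all(is.finite(r)))
    if (nrow(values) == 0L) observed <- logical(0)
  }
  observed <- as.logical(observed)
  if (length(observed) != nrow(values))
    stop("observed mask length does not match sample count")
  rownames(values) <- sample_ids
  colnames(values) <- feature_ids
  structure(
    list(name = as.character(name)[1L], values = values,
         sample_ids = sample_ids, feature_ids = feature_ids,
         observed = observed),
    class = "omics_view"
  )
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("<omics_view> '%s': %d samples x %d features (%d observed)\n",
              x$name, nrow(x$values), ncol(x$values), sum(x$observed)))
  invisible(x)
}

#' @export
dim.omics_view <- function(x) dim(x$values)

#' Read a view matrix from delimited text
#'
#' Expects samples in rows and features in columns: the first column holds
#' sample IDs and the header row holds feature IDs. The delimiter is sniffed
#' from the extension (`.csv` -> comma, otherwise tab). A row whose cells are
#' all empty/NA is kept but flagged `observed = FALSE` (view missing for that
#' sample); an isolated non-numeric cell is an error naming its position.
#'
#' @param path file path to a TSV/CSV matrix.
#' @param name view name; defaults to the file stem.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return An [omics_view()].
#' @export
read_view <- function(path, name = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("malformed header in ", path,
                           ": need sample-ID column plus >=1 feature")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample ID in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feat <- colnames(raw)[-1L]
  if (anyDuplicated(feat))
    stop("duplicate feature ID in ", path, ": ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  blank <- cells == "" | is.na(cells) | toupper(cells) == "NA"
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!blank & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s': '%s'",
                 path, ids[bad[1L, 1L]], feat[bad[1L, 2L]],
                 cells[bad[1L, 1L], bad[1L, 2L]]))
  observed <- rowSums(blank) == 0L
  num[blank] <- NA_real_
  omics_view(num, name = name, sample_ids = ids, feature_ids = feat,
             observed = observed)
}

#' Write a view matrix as delimited text
#'
#' Inverse of [read_view()]: sample IDs in the first column, feature IDs in
#' the header. Unobserved rows are written as empty cells.
#'
#' @param view an [omics_view()].
#' @param path output path; `.csv` extension selects comma delimiting.
#' @return `path`, invisibly.
#' @export
write_view <- function(view, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  vals <- view$values
  vals[!view$observed, ] <- NA_real_
  df <- data.frame(sample_id = view$sample_ids, vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a clinical table
#'
#' Columns: `sample_id`, `time` (survival time, days), `event` (1 = death
#' observed, 0 = censored), plus any number of clinical label columns.
#' Non-numeric label columns are treated as discrete, numeric ones as
#' continuous.
#'
#' @param path TSV/CSV file.
#' @param sep delimiter; `NULL` to infer from the extension.
#' @return A `data.frame` of class `clinical_table`.
#' @export
read_clinical <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  clinical_table(df)
}

#' Validate a clinical data.frame
#'
#' @param df data.frame with at least a `sample_id` column; `time`/`event`
#'   are optional but required for survival-based evaluation.
#' @return `df` with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  if (!"sample_id" %in% names(df)) stop("clinical table needs a 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if ("time" %in% names(df)) {
    if (any(df$time < 0, na.rm = TRUE)) stop("negative survival time")
  }
  if ("event" %in% names(df)) {
    if (!all(df$event %in% c(0, 1, NA))) stop("event must be 0/1")
  }
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Align views (and clinical data) onto a shared sample ordering
#'
#' Builds a multi-view dataset over the union of all sample IDs, sorted
#' lexicographically for determinism. A view's `observed` mask is `FALSE` for
#' samples it never measured (filled with zero rows) and inherits any
#' pre-existing `FALSE` flags. Clinical rows are matched by ID; clinical IDs
#' absent from every view are dropped with a message.
#'
#' @param views list of [omics_view()] objects.
#' @param clinical optional [clinical_table()].
#' @return A `multi_omics` object: named list of aligned views plus shared
#'   `sample_ids` and (optionally) the matched clinical table.
#' @export
align_samples <- function(views, clinical = NULL) {
  if (length(views) < 1L) stop("need at least one view")
  if (inherits(views, "omics_view")) views <- list(views)
  all_ids <- sort(unique(unlist(lapply(views, `[[`, "sample_ids"))))
  aligned <- lapply(views, function(v) {
    idx <- match(all_ids, v$sample_ids)
    vals <- matrix(0, length(all_ids), ncol(v$values),
                   dimnames = list(all_ids, v$feature_ids))
    obs <- !is.na(idx)
    vals[obs, ] <- v$values[idx[obs], , drop = FALSE]
    obs[obs] <- v$observed[idx[obs]]
    vals[!obs, ] <- 0
    omics_view(vals, name = v$name, sample_ids = all_ids,
               feature_ids = v$feature_ids, observed = obs)
  })
  names(aligned) <- vapply(aligned, `[[`, "", "name")
  out <- structure(list(views = aligned, sample_ids = all_ids,
                        clinical = NULL),
                   class = "multi_omics")
  if (!is.null(clinical)) {
    clinical <- clinical_table(as.data.frame(clinical))
    hit <- clinical$sample_id %in% all_ids
    if (!any(hit))
      warning("clinical table shares no sample IDs with the views")
    if (any(!hit))
      message(sum(!hit), " clinical rows without matching omics samples ignored")
    out$clinical <- clinical[hit, , drop = FALSE]
  }
  out
}

#' @export
print.multi_omics <- function(x, ...) {
  cat(sprintf("<multi_omics> %d samples, %d views\n",
              length(x$sample_ids), length(x$views)))
  for (v in x$views)
    cat(sprintf("  %s: %d features, %d/%d observed\n", v$name,
                ncol(v$values), sum(v$observed), length(v$observed)))
  invisible(x)
}
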