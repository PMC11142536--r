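# Plain-text interchange: feature matrices as CSV with a JSON sidecar,
# per-pipeline score files, and serialized comparison reports.

#' Write a feature matrix as CSV with a JSON metadata sidecar
#'
#' Rows are spot ids (first column `spot_id`); the sidecar
#' (`<path>.json`) records the column names plus any extra metadata.
#'
#' @param x Numeric matrix with rownames.
#' @param path CSV output path.
#' @param meta Named list of extra metadata for the sidecar.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(x, path, meta = list()) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(spot_id = rownames(x), unclass(x), check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  meta$columns <- colnames(x)
  meta$n_rows <- nrow(x)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return Numeric matrix with `spot_id` rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$spot_id
  m
}

#' Write a score set as CSV (spot_id, label, score)
#' @param s A `score_set`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_scores_csv <- function(s, path) {
  stopifnot(inherits(s, "score_set"))
  utils::write.csv(data.frame(spot_id = s$spot_ids, label = s$labels,
                              score = s$scores),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a score CSV written by [write_scores_csv()]
#' @param path CSV path.
#' @return A `score_set`.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path)
  score_set(df$score, df$label, spot_ids = df$spot_id)
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `pipeline_report`.
#' @param path JSON output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- list(
    metrics = report$metrics,
    delong = lapply(report$delong, function(d)
      list(auc_a = d$auc_a, auc_b = d$auc_b, var_diff = d$var_diff,
           z = d$z, p_value = d$p_value)),
    heldout_patients = report$plan$heldout_patients,
    seed = report$plan$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
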