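## Plain-text readers/writers for the clone-assay tables, homology matrices
## and run manifests.  Percents are printed at one decimal in report files;
## manifests carry parameters at full precision.

#' Read a clone-counts table
#'
#' Expected TSV columns: `strain`, `condition` (`induced`/`uninduced`),
#' `n_scored`, `n_hygS`, `class_I`, `class_II`, `class_III`, `class_other`.
#'
#' @param path Path to the TSV.
#' @return Named list (by strain) of lists with `$induced` and `$uninduced`
#'   [clone_assay_counts()].
#' @export
read_clone_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "condition", "n_scored", "n_hygS", "class_I",
           "class_II", "class_III", "class_other")
  if (!all(req %in% names(df))) {
    stop(path, ": missing column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    cc <- tryCatch(
      clone_assay_counts(df$condition[i], df$n_scored[i], df$n_hygS[i],
                         df$class_I[i], df$class_II[i], df$class_III[i],
                         df$class_other[i]),
      error = function(e) stop(path, " line ", i + 1L, ": ",
                               conditionMessage(e), call. = FALSE))
    out[[df$strain[i]]][[df$condition[i]]] <- cc
  }
  out
}

#' Read a plug-survey table
#'
#' Expected TSV columns: `strain`, `class`, `type`, `count`.
#'
#' @param path Path to the TSV.
#' @return Named list (by strain) of [plug_survey()] objects.
#' @export
read_plug_surveys <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "class", "type", "count")
  if (!all(req %in% names(df))) {
    stop(path, ": missing column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  sapply(unique(df$strain), function(s) {
    plug_survey(df[df$strain == s, c("class", "type", "count")])
  }, simplify = FALSE)
}

#' Read an outcome-frequency table written by [write_outcome_table()]
#'
#' Also reads packaged reference tables (e.g. the published strain rows under
#' `inst/extdata`); a `strain` column, when present, is used to select rows.
#'
#' @param path Path to the TSV.
#' @param strain Optional strain to select when the file is multi-strain.
#' @return An `outcome_table`.
#' @export
read_outcome_table <- function(path, strain = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(strain)) {
    if (!"strain" %in% names(df)) stop(path, " has no strain column")
    df <- df[df$strain == strain, , drop = FALSE]
    if (!nrow(df)) stop("no rows for strain ", strain, " in ", path)
  }
  as_outcome_table(df)
}

#' Write an outcome table as TSV (one-decimal percents)
#'
#' @param table An `outcome_table`.
#' @param path Output path.
#' @param strain Optional strain label added as a column.
#' @return Invisibly, the table.
#' @export
write_outcome_table <- function(table, path, strain = NULL) {
  stopifnot(inherits(table, "outcome_table"))
  out <- data.frame(
    type = table$type,
    frequency = sprintf("%.1f", table$frequency),
    sem = ifelse(is.na(table$sem), "NA", sprintf("%.1f", table$sem)),
    bound = table$bound,
    bound_value = ifelse(is.na(table$bound_value), "NA",
                         sprintf("%.1f", table$bound_value)))
  if (!is.null(strain)) out <- cbind(strain = strain, out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Write a homology matrix (long TSV and/or square CSV)
#'
#' @param hm A `homology_matrix`.
#' @param long_path Optional path for the long-form TSV
#'   (`id_a, id_b, metric, value, strand_used`).
#' @param square_path Optional path for the square CSV (ids as row/column
#'   names, `NA` diagonal).
#' @return Invisibly, `hm`.
#' @export
write_homology_matrix <- function(hm, long_path = NULL, square_path = NULL) {
  stopifnot(inherits(hm, "homology_matrix"))
  if (!is.null(long_path)) {
    write.table(homology_long(hm), long_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(square_path)) {
    write.csv(hm$values, square_path)
  }
  invisible(hm)
}

#' Read a square homology-matrix CSV back into a `homology_matrix`
#'
#' @param path CSV written by [write_homology_matrix()].
#' @param metric Metric name to attach.
#' @return A `homology_matrix` (without strand/params information).
#' @export
read_homology_matrix <- function(path, metric) {
  m <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
  structure(list(metric = metric, ids = rownames(m), values = m,
                 strand = NULL, params = NULL, strand_mode = NULL),
            class = "homology_matrix")
}

#' Write a JSON run manifest
#'
#' Every pipeline output directory gets a manifest recording inputs,
#' parameters, seed and package version, so a run can be reproduced exactly.
#'
#' @param path Output path.
#' @param ... Named manifest entries.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, ...) {
  manifest <- c(list(package = "tynahr",
                     version = as.character(utils::packageVersion("tynahr")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                list(...))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
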