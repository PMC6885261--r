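## Feature-table persistence: CSV (lossless %.17g) and ARFF (via foreign).

#' Write a feature table to disk
#'
#' CSV output has a header row with the label column last and numeric values
#' formatted with 17 significant digits so a read-back reproduces every double
#' bit-exactly. ARFF output declares each feature as numeric and the class
#' attribute as nominal over the table's class levels.
#'
#' @param table A `feature_table` (or data.frame with a trailing `label`
#'   column).
#' @param path Output file path.
#' @param format `"csv"` or `"arff"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, format = c("csv", "arff")) {
  format <- match.arg(format)
  fn <- ft_feature_names(table)
  labels <- ft_labels(table)
  if (format == "csv") {
    chr <- lapply(table[, fn, drop = FALSE],
                  function(col) sprintf("%.17g", col))
    out <- as.data.frame(chr, check.names = FALSE)
    out$label <- as.character(labels)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- table[, fn, drop = FALSE]
    out <- as.data.frame(out, check.names = FALSE)
    out$label <- labels
    foreign::write.arff(out, path, relation = "emg_wpd_features")
  }
  invisible(path)
}

#' Read a feature table from disk
#'
#' @param path File written by [write_feature_table()].
#' @param format `"csv"` or `"arff"`; inferred from the file extension by
#'   default.
#' @return A `feature_table` data.frame.
#' @export
read_feature_table <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "arff")) ext else
      stop("cannot infer format from extension '", ext,
           "'; pass format = \"csv\" or \"arff\"", call. = FALSE)
  }
  format <- match.arg(format, c("csv", "arff"))
  tab <- if (format == "csv") {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    foreign::read.arff(path)
  }
  if (!"label" %in% colnames(tab)) {
    stop("feature table at '", path, "' has no label column", call. = FALSE)
  }
  fn <- setdiff(colnames(tab), "label")
  if (!all(vapply(tab[fn], is.numeric, logical(1)))) {
    stop("non-numeric feature column in '", path, "'", call. = FALSE)
  }
  tab$label <- as_class_factor(as.character(tab$label))
  attr(tab, "feature_names") <- fn
  class(tab) <- c("feature_table", "data.frame")
  tab
}
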