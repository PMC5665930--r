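#' Write a data frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#' @param path Input path.
#' @return data.frame with columns as in the file.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a feature abundance table with a group-label header row
#'
#' First column `feature_id`; first data row is the per-sample metabotype
#' label (feature_id `#group`), remaining rows are abundances.
#'
#' @param table Features x samples matrix.
#' @param labels Named per-sample labels matching the table's columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(table, labels, path) {
  stopifnot(setequal(names(labels), colnames(table)))
  labels <- labels[colnames(table)]
  df <- data.frame(feature_id = c("#group", rownames(table)),
                   rbind(unname(labels), apply(table, 2, as.character)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(table))
  write_tsv(df, path)
}

#' Read a feature abundance table written by [write_feature_tsv()]
#' @param path Input path.
#' @return List with `table` (numeric matrix) and `labels` (named vector).
#' @export
read_feature_tsv <- function(path) {
  df <- read_tsv(path)
  if (df$feature_id[1] != "#group")
    stop("feature table is missing the '#group' label row")
  labels <- setNames(as.character(df[1, -1]), colnames(df)[-1])
  mat <- as.matrix(df[-1, -1, drop = FALSE])
  mat <- matrix(as.numeric(mat), nrow = nrow(mat),
                dimnames = list(df$feature_id[-1], colnames(df)[-1]))
  list(table = mat, labels = labels)
}
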