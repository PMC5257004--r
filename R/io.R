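#' Read and write snapshot tables
#'
#' Snapshot tables are stored as UTF-8 CSV with a header row and one row per
#' cell (`cell_id`, `condition_id`, `strain`, `promoter`, `A`, `B`).
#' `read_snapshot_table()` validates on read: malformed rows (negative or
#' non-finite fluorescence, missing fields) are rejected with their file
#' line numbers. Write followed by read is lossless up to numeric printing
#' precision (15 significant digits).
#'
#' @param x a `snapshot_table` (see [generate_sweep()]).
#' @param path file path.
#' @return `read_snapshot_table()` returns a `snapshot_table`;
#'   `write_snapshot_table()` returns `path` invisibly.
#' @export
write_snapshot_table <- function(x, path) {
  validate_snapshot_table(x)
  df <- as.data.frame(x)
  df$A <- sprintf("%.15g", df$A)
  df$B <- sprintf("%.15g", df$B)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_snapshot_table
#' @export
read_snapshot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character",
                                       condition_id = "character",
                                       strain = "character",
                                       promoter = "character",
                                       A = "numeric", B = "numeric"),
                        fileEncoding = "UTF-8")
  line_of <- function(rows) paste(rows + 1L, collapse = ", ")  # header = line 1
  bad <- which((!is.na(df$A) & (!is.finite(df$A) | df$A < 0)) |
                 (!is.na(df$B) & (!is.finite(df$B) | df$B < 0)))
  if (length(bad))
    stop(sprintf("%s: negative or non-finite fluorescence at line(s) %s",
                 basename(path), line_of(utils::head(bad, 10))),
         call. = FALSE)
  incomplete <- which(is.na(df$cell_id) | is.na(df$condition_id) |
                        is.na(df$strain) | is.na(df$promoter) | is.na(df$B))
  if (length(incomplete))
    stop(sprintf("%s: missing fields at line(s) %s", basename(path),
                 line_of(utils::head(incomplete, 10))), call. = FALSE)
  as_snapshot_table(df)
}
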