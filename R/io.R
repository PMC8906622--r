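# Tab-separated readers/writers for the package's tabular interchange
# formats. Conventions: tab delimiter, header row, '.' decimal point,
# case-sensitive ids, no locale formatting. A missing concentration must
# be written as 0, never as an empty cell.

#' Read a feature table from TSV
#'
#' Expects samples in rows: first column holds sample ids, remaining
#' header fields are feature ids. Metadata is read from a companion TSV
#' with columns `sample_id`, `strain`, `day`, `arm`.
#'
#' @param path path to the feature TSV.
#' @param layer omics layer tag (see [feature_table()]).
#' @param metadata_path path to the sample metadata TSV, or a data.frame
#'   already in memory.
#' @return A validated [feature_table()] with row/column order as on file.
#' @export
read_feature_table <- function(path, layer, metadata_path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) ov_stop("empty feature table file", "format")
  sids <- df[[1]]
  fids <- names(df)[-1]
  if (anyDuplicated(fids)) {
    ov_stop(sprintf("duplicated feature column(s): %s",
                    paste(unique(fids[duplicated(fids)]), collapse = ", ")), "format")
  }
  if (anyDuplicated(sids)) {
    ov_stop(sprintf("duplicated sample row(s): %s",
                    paste(unique(sids[duplicated(sids)]), collapse = ", ")), "format")
  }
  vals <- matrix(0, nrow = length(sids), ncol = length(fids),
                 dimnames = list(sids, fids))
  for (j in seq_along(fids)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !is.finite(num) | num < 0)
    if (length(bad) > 0L) {
      ov_stop(sprintf("non-numeric or negative value at sample '%s', feature '%s'",
                      sids[bad[1]], fids[j]), "value")
    }
    vals[, j] <- num
  }
  meta <- if (is.data.frame(metadata_path)) metadata_path else read_metadata(metadata_path)
  feature_table(vals, layer, meta)
}

#' @rdname read_feature_table
#' @param t a [feature_table()] to serialize.
#' @export
write_feature_table <- function(t, path) {
  stopifnot(inherits(t, "feature_table"))
  con <- tryCatch(file(path, "w"), error = function(e) ov_stop(conditionMessage(e), "io"))
  on.exit(close(con))
  fids <- colnames(t$values)
  writeLines(paste(c("sample_id", fids), collapse = "\t"), con)
  for (i in seq_len(nrow(t$values))) {
    writeLines(paste(c(rownames(t$values)[i], fmt_num(t$values[i, ])), collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Read / write sample metadata TSV (sample_id, strain, day, arm)
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("sample_id", "strain", "day", "arm")
  if (!all(need %in% names(meta))) {
    ov_stop("metadata TSV needs columns sample_id, strain, day, arm", "metadata")
  }
  meta$day <- as.integer(meta$day)
  meta
}

#' @rdname read_metadata
#' @param metadata data.frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read / write a taxonomy map TSV (feature_id, phylum, genus, ...)
#' @param path file path.
#' @return a [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  taxonomy_map(utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                                 colClasses = "character"))
}

#' @rdname read_taxonomy
#' @param tax a [taxonomy_map()].
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read / write an annotation table TSV (feature_id, label)
#' @param path file path.
#' @param layer omics layer tag.
#' @return an [annotation_table()].
#' @export
read_annotation <- function(path, layer = "transcript") {
  annotation_table(utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                                     colClasses = "character"), layer = layer)
}

#' @rdname read_annotation
#' @param ann an [annotation_table()].
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read / write clinical records TSV
#' @param path file path.
#' @return a [clinical_records()].
#' @export
read_clinical <- function(path) {
  clinical_records(utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' @rdname read_clinical
#' @param records a [clinical_records()].
#' @export
write_clinical <- function(records, path) {
  df <- as.data.frame(records)
  df$weight_change <- fmt_num(df$weight_change)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
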