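#' Condition keys: one strain x day x arm cell of the study design
#'
#' Every vector statistic in the package is computed at the level of a
#' *condition*: a (strain, day, arm) triple such as C57BL/6, day 15,
#' treated. A condition key is serialized as a single string
#' `"strain|day|arm"` so it can index lists and table columns; these
#' helpers build and take apart that encoding.
#'
#' @param strain character strain label (e.g. `"C57BL/6"`, `"BALB/c"`).
#' @param day non-negative integer day since treatment start.
#' @param arm `"control"` or `"treated"`.
#' @return `condition_id()` returns the key string; `parse_condition()`
#'   returns a list with elements `strain`, `day`, `arm`.
#' @examples
#' condition_id("C57BL/6", 15, "treated")
#' parse_condition("BALB/c|7|control")
#' @export
condition_id <- function(strain, day, arm) {
  if (any(!is.finite(day)) || any(day < 0) || any(day != floor(day))) {
    ov_stop("'day' must be a non-negative integer", "value")
  }
  arm <- as.character(arm)
  if (!all(arm %in% c("control", "treated"))) {
    ov_stop("'arm' must be 'control' or 'treated'", "value")
  }
  if (any(grepl("|", c(strain, arm), fixed = TRUE))) {
    ov_stop("'|' is reserved as the condition-key separator", "value")
  }
  paste(strain, as.integer(day), arm, sep = "|")
}

#' @rdname condition_id
#' @param id a condition key string produced by [condition_id()].
#' @export
parse_condition <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L) ov_stop(sprintf("malformed condition key '%s'", id), "key")
  list(strain = parts[1], day = as.integer(parts[2]), arm = parts[3])
}

# condition key for every sample of a metadata data.frame, in row order
metadata_condition_ids <- function(metadata) {
  condition_id(metadata$strain, metadata$day, metadata$arm)
}
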