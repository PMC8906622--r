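# internal helpers: classed errors, seed derivation, formatting

ov_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("omivec_error_", class), "omivec_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ov_warn <- function(msg) warning(msg, call. = FALSE)

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Splitting one global seed into independent per-layer / per-condition
#' streams means regenerating one layer never perturbs another. The
#' derivation is a small deterministic string hash folded into the master
#' seed, kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param tag character label of the stream (e.g. `"otu"`, a condition id).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# deterministic numeric formatting used by all writers (15 significant
# digits survives a write/read round trip for doubles at printed precision)
fmt_num <- function(x) {
  formatC(x, digits = 15, format = "g")
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
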