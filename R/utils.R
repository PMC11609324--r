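#' Canonical network and feature keys
#'
#' The four emotion-regulation networks are keyed `ERN1`..`ERN4`; the ten
#' connectivity features are the four within-network means followed by the
#' six unordered between-network pairs (`ERN12`, `ERN13`, `ERN14`, `ERN23`,
#' `ERN24`, `ERN34`). All downstream tables use these keys in this order.
#'
#' @return `network_keys()`: character vector of length 4. `feature_keys()`:
#'   character vector of length 10, within features first.
#' @export
network_keys <- function() paste0("ERN", 1:4)

#' @rdname network_keys
#' @export
feature_keys <- function() {
  nets <- network_keys()
  pairs <- utils::combn(1:4, 2)
  c(nets, paste0("ERN", pairs[1, ], pairs[2, ]))
}

#' @rdname network_keys
#' @param key a feature key.
#' @return `feature_kind()`: `"within"` or `"between"` for a feature key.
#' @export
feature_kind <- function(key) {
  key <- match.arg(key, feature_keys())
  if (key %in% network_keys()) "within" else "between"
}

# networks entering a between key, e.g. "ERN24" -> c("ERN2", "ERN4")
between_pair <- function(key) {
  digits <- strsplit(sub("^ERN", "", key), "")[[1]]
  paste0("ERN", digits)
}

# z-score a numeric vector; constant input is an error because standardized
# coefficients are undefined for it
zscore <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("cannot standardize %s: zero or non-finite variance", what))
  }
  (x - mean(x)) / s
}

# sex contrast code: factor/character/0-1 -> -0.5 / +0.5
sex_code <- function(sex) {
  if (is.numeric(sex)) {
    u <- sort(unique(sex))
    if (length(u) > 2) stop("sex must be binary")
    return(ifelse(sex == u[1], -0.5, 0.5))
  }
  f <- as.factor(sex)
  if (nlevels(f) > 2) stop("sex must be binary")
  ifelse(as.integer(f) == 1L, -0.5, 0.5)
}

# deterministic per-task seed stream, kept under 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * (as.integer(k) %% 1000L) +
     as.integer(k)) %% .Machine$integer.max
}

#' Read and write tab-separated tables
#'
#' Thin wrappers fixing the conventions used by every pipeline stage:
#' tab-separated, header row, no quoting, no row names.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
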