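`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg, call. = FALSE) {
  if (!isTRUE(ok)) stop(msg, call. = call.)
}

#' Normalize a term to canonical form
#'
#' Uppercases, trims leading/trailing whitespace and collapses internal
#' whitespace runs to a single space. Used for both drug names and
#' reaction preferred terms so that membership tests are case- and
#' spacing-insensitive.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @keywords internal
.canon <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# flatten a list column and remember which row each element came from
.flat <- function(lst) {
  list(values = unlist(lst, use.names = FALSE),
       row = rep.int(seq_along(lst), lengths(lst)))
}
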