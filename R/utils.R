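#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# C-locale, byte-wise ordering so signature tie-breaks and exported tables do
# not depend on the session locale.
lex_order <- function(...) order(..., method = "radix")

lex_sort <- function(x) sort(x, method = "radix")

#' Normalize gene symbols
#'
#' Upper-cases symbols and strips surrounding whitespace, the canonicalisation
#' applied to every gene identifier entering the package (panel rows, query
#' lists, reference sets), so that case or whitespace variants of the same
#' symbol always collide.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of the same length.
#' @examples
#' normalize_symbols(c(" cd19", "Ms4a1 "))
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
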