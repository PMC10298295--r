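#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix (any case) and surrounding whitespace so that
#' "chr5", "Chr5" and "5" compare equal. Labels are compared as strings; no
#' numeric ordering is implied.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chr <- function(x) {
  x <- trimws(as.character(x))
  sub("^[Cc][Hh][Rr]", "", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mlm <- function(...) stop(..., call. = FALSE)
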