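#' The 21-symbol amino-acid alphabet
#'
#' The 20 canonical amino acids in fixed alphabetical order, followed by the
#' wildcard symbol `"X"`. This ordering is part of the package's on-disk
#' contract: it fixes the 21 columns of the one-hot composition vectors and the
#' row-major (first-symbol-major) ordering of the 441 = 21^2 Sequence Graph
#' Transform features.
#'
#' @return Character vector of length 21.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
  )
}

.aa_canonical <- "ACDEFGHIKLMNPQRSTVWY"

#' Sanitize raw amino-acid sequences
#'
#' Uppercases and maps every symbol outside the 20 canonical amino acids
#' (ambiguity codes B/Z/J, the rare U/O, stop `*`, gap characters, anything
#' else) to the wildcard `"X"`, yielding strings over [aa_alphabet()].
#' Whitespace is stripped first. The function is idempotent.
#'
#' @param raw Character vector of raw sequences.
#' @return Character vector of sanitized sequences, same length as `raw`.
#' @examples
#' sanitize_sequence("acdef")
#' sanitize_sequence("ACUZ")
#' @export
sanitize_sequence <- function(raw) {
  if (!is.character(raw)) {
    stop_invalid("`raw` must be a character vector.", "drembed_invalid_sequence")
  }
  x <- gsub("[[:space:]]", "", raw)
  if (any(!nzchar(x))) {
    stop_invalid(
      "Invalid sequence: empty after stripping whitespace.",
      "drembed_invalid_sequence"
    )
  }
  if (any(grepl("[0-9]", x))) {
    stop_invalid(
      "Invalid sequence: contains digits.",
      "drembed_invalid_sequence"
    )
  }
  x <- toupper(x)
  gsub(sprintf("[^%s]", .aa_canonical), "X", x)
}
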