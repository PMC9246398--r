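#' Built-in alphabets
#'
#' The two standard alphabets: the four DNA nucleotides and the twenty
#' proteinogenic amino acids.  Any other character vector of single-letter
#' symbols can be used as a custom alphabet.
#'
#' @format A named list of character vectors.
#' @export
sw_alphabets <- list(
  dna = c("A", "C", "G", "T"),
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

resolve_alphabet <- function(alphabet) {
  if (is.character(alphabet) && length(alphabet) == 1L &&
      alphabet %in% names(sw_alphabets)) {
    list(name = alphabet, symbols = sw_alphabets[[alphabet]])
  } else if (is.character(alphabet) && length(alphabet) >= 2L) {
    if (anyDuplicated(alphabet))
      sw_value_error("custom alphabet contains duplicated symbols")
    list(name = "custom", symbols = alphabet)
  } else {
    sw_value_error(
      "alphabet must be \"dna\", \"protein\", or a character vector of symbols")
  }
}

#' Construct a validated sequence
#'
#' A sequence is an ordered vector of symbols over a declared alphabet: the
#' query `q` (length N) or the database sequence `s` (length M) of a local
#' alignment.  Input is upper-cased for the built-in alphabets and every
#' symbol is checked for membership; ambiguity codes (e.g. `N` under the DNA
#' alphabet) are rejected.
#'
#' @param x A single string (split into characters), a character vector of
#'   symbols, or an existing `sw_sequence` (returned unchanged).
#' @param alphabet `"dna"`, `"protein"`, or a character vector defining a
#'   custom alphabet.
#' @param name Free-text identifier (e.g. a FASTA header).
#' @return An object of class `sw_sequence` with fields `symbols`,
#'   `alphabet` (the symbol set), `alphabet_name` and `name`.
#' @examples
#' q <- sw_sequence("ACGT")
#' length(q)
#' @export
sw_sequence <- function(x, alphabet = "dna", name = "") {
  if (inherits(x, "sw_sequence")) return(x)
  if (!is.character(x) || length(x) < 1L || anyNA(x))
    sw_input_error("sequence input must be a non-empty character vector")
  symbols <- if (length(x) == 1L) strsplit(x, "", fixed = TRUE)[[1L]] else x
  alpha <- resolve_alphabet(alphabet)
  if (alpha$name %in% c("dna", "protein")) symbols <- toupper(symbols)
  if (length(symbols) < 1L)
    sw_input_error("sequence must contain at least one symbol")
  bad <- which(!symbols %in% alpha$symbols)
  if (length(bad)) {
    sw_alphabet_error(sprintf(
      "symbol '%s' at position %d is not in the %s alphabet",
      symbols[bad[1L]], bad[1L], alpha$name))
  }
  structure(
    list(symbols = symbols, alphabet = alpha$symbols,
         alphabet_name = alpha$name, name = as.character(name)[1L]),
    class = "sw_sequence")
}

#' @export
length.sw_sequence <- function(x) length(x$symbols)

#' @export
as.character.sw_sequence <- function(x, ...) paste0(x$symbols, collapse = "")

#' @export
print.sw_sequence <- function(x, ...) {
  txt <- as.character(x)
  if (nchar(txt) > 60L) txt <- paste0(substr(txt, 1L, 57L), "...")
  cat(sprintf("<sw_sequence %s> %s alphabet, %d symbols\n  %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              x$alphabet_name, length(x), txt))
  invisible(x)
}

# Both sequences of an alignment must live over one symbol set.
check_same_alphabet <- function(q, s) {
  if (!identical(q$alphabet, s$alphabet))
    sw_alphabet_error("query and database sequences use different alphabets")
  invisible(TRUE)
}
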