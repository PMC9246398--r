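#' Scoring scheme for local alignment
#'
#' Holds the match reward \eqn{\alpha}, mismatch penalty \eqn{\beta} and
#' linear gap penalty \eqn{\gamma}, or alternatively a full substitution
#' matrix \eqn{P}.  Without a matrix, \eqn{P(a,b)} is \eqn{\alpha} when
#' \eqn{a = b} and \eqn{\beta} otherwise.  The gap penalty is stored as a
#' non-negative magnitude and is subtracted in the recurrence; a gap opens
#' and extends at the same cost (the linear special case of the affine
#' model).
#'
#' @param match Integer match reward \eqn{\alpha} (default 5).
#' @param mismatch Integer mismatch penalty \eqn{\beta} (default -5).
#' @param gap Non-negative integer gap penalty \eqn{\gamma} (default 1),
#'   subtracted per gap symbol.
#' @param matrix Optional square integer matrix with identical row and
#'   column names giving \eqn{P(a,b)}; rows index the database symbol,
#'   columns the query symbol.  No symmetry is assumed.
#' @return An object of class `sw_scoring`.
#' @examples
#' scoring_scheme(match = 5, mismatch = -5, gap = 1)
#' @export
scoring_scheme <- function(match = 5L, mismatch = -5L, gap = 1L, matrix = NULL) {
  as_int1 <- function(v, what) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v))
      sw_value_error(sprintf("%s must be a single integer", what))
    as.integer(v)
  }
  match <- as_int1(match, "match")
  mismatch <- as_int1(mismatch, "mismatch")
  gap <- as_int1(gap, "gap")
  if (gap < 0L)
    sw_value_error("gap penalty must be non-negative (it is subtracted)")
  if (!is.null(matrix)) {
    if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix) ||
        is.null(rownames(matrix)) || is.null(colnames(matrix)) ||
        !identical(rownames(matrix), colnames(matrix)))
      sw_value_error(
        "substitution matrix must be square with identical row/column names")
    if (any(matrix != round(matrix)))
      sw_value_error("substitution matrix must be integer-valued")
    storage.mode(matrix) <- "integer"
  }
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 matrix = matrix),
            class = "sw_scoring")
}

#' @export
print.sw_scoring <- function(x, ...) {
  cat(sprintf("<sw_scoring> match %d, mismatch %d, gap %d%s\n",
              x$match, x$mismatch, x$gap,
              if (is.null(x$matrix)) ""
              else sprintf(", %dx%d substitution matrix",
                           nrow(x$matrix), ncol(x$matrix))))
  invisible(x)
}

#' Substitution score of a symbol pair
#'
#' Returns \eqn{P(a,b)}: the configured matrix entry when a full matrix is
#' present, otherwise the match reward when `a == b` and the mismatch
#' penalty otherwise.
#'
#' @param a,b Single symbols; by convention `a` is the database symbol and
#'   `b` the query symbol (rows/columns of the matrix).
#' @param scheme An [scoring_scheme()].
#' @return An integer score.
#' @examples
#' substitution_score("A", "A", scoring_scheme(5, -5, 1))
#' @export
substitution_score <- function(a, b, scheme) {
  stopifnot(inherits(scheme, "sw_scoring"))
  if (!is.null(scheme$matrix)) {
    syms <- rownames(scheme$matrix)
    if (!a %in% syms)
      sw_alphabet_error(sprintf(
        "symbol '%s' (first argument) is not in the scheme's alphabet", a))
    if (!b %in% syms)
      sw_alphabet_error(sprintf(
        "symbol '%s' (second argument) is not in the scheme's alphabet", b))
    return(scheme$matrix[a, b])
  }
  if (identical(a, b)) scheme$match else scheme$mismatch
}

# Dense K x K integer matrix over `alphabet`, rows = database symbol,
# columns = query symbol.  Used by the C++ fill and the simulator.
expand_substitution_matrix <- function(scheme, alphabet) {
  k <- length(alphabet)
  if (is.null(scheme$matrix)) {
    m <- matrix(scheme$mismatch, k, k, dimnames = list(alphabet, alphabet))
    diag(m) <- scheme$match
    storage.mode(m) <- "integer"
    return(m)
  }
  missing <- setdiff(alphabet, rownames(scheme$matrix))
  if (length(missing))
    sw_alphabet_error(sprintf(
      "substitution matrix lacks alphabet symbol(s): %s",
      paste(missing, collapse = ", ")))
  scheme$matrix[alphabet, alphabet, drop = FALSE]
}
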