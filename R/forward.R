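#' Forward stage: fill the score and direction matrices
#'
#' Computes the full \eqn{(M+1) \times (N+1)} local-alignment score matrix
#' `H` (row and column 0 are the zero border) and, alongside it, the
#' direction matrix `D` whose two-bit codes record which recurrence term
#' won each cell (see [cell_update()]).  The running maximum is tracked
#' during the fill with strict-greater replacement, so on ties the first
#' maximum in column-major order (query symbol outer, database symbol
#' inner) is reported.  Storing directions during the forward stage is what
#' lets traceback walk a chain directly instead of re-deriving each step
#' from `H`.
#'
#' Rows of `H`/`D` are indexed by the database sequence `s` (1-based `i`),
#' columns by the query `q` (1-based `j`).  All reported positions are
#' 1-based matrix coordinates.  When the matrix is all zero (no positive
#' candidate ever arises) the maximum is reported at position (1, 1) with
#' value 0 by convention.
#'
#' @param q Query sequence (`sw_sequence` or string; length N).
#' @param s Database sequence (`sw_sequence` or string; length M).
#' @param scheme An [scoring_scheme()].
#' @return An object of class `sw_forward` with fields `H`, `D` (integer
#'   matrices), `max_value`, `max_row`, `max_col`, and `cell_count`
#'   (\eqn{M \times N} interior cells).
#' @examples
#' fw <- forward_fill("AC", "AC", scoring_scheme(5, -5, 1))
#' fw$max_value  # 10
#' @export
forward_fill <- function(q, s, scheme) {
  q <- sw_sequence(q)
  s <- sw_sequence(s)
  stopifnot(inherits(scheme, "sw_scoring"))
  check_same_alphabet(q, s)
  alpha <- q$alphabet
  submat <- expand_substitution_matrix(scheme, alpha)
  res <- forward_fill_cpp(match(q$symbols, alpha), match(s$symbols, alpha),
                          submat, scheme$gap)
  structure(
    list(H = res$H, D = res$D, max_value = res$max_value,
         max_row = res$max_row, max_col = res$max_col,
         cell_count = length(q) * length(s)),
    class = "sw_forward")
}

#' @export
print.sw_forward <- function(x, ...) {
  cat(sprintf(
    "<sw_forward> %d x %d cells, maximum %d at (row %d, col %d)\n",
    nrow(x$H) - 1L, ncol(x$H) - 1L, x$max_value, x$max_row, x$max_col))
  invisible(x)
}

#' Pack direction codes into 2 bits per cell
#'
#' The direction alphabet has exactly four levels (0, 1, 2, 3), so each
#' cell needs only two bits — the storage economy that makes keeping the
#' whole traceback path feasible.  `pack_directions()` packs a direction
#' matrix (or vector) into a raw vector at four cells per byte;
#' `unpack_directions()` restores it.
#'
#' @param d Integer matrix or vector of codes in \{0, 1, 2, 3\}.
#' @return For `pack_directions()`, a raw vector with attributes `n` (cell
#'   count) and `dim_orig`; for `unpack_directions()`, the original integer
#'   matrix or vector.
#' @examples
#' fw <- forward_fill("AC", "AC", scoring_scheme(5, -5, 1))
#' p <- pack_directions(fw$D)
#' identical(unpack_directions(p), fw$D)
#' @export
pack_directions <- function(d) {
  v <- as.integer(d)
  if (anyNA(v) || any(v < 0L | v > 3L))
    sw_value_error("direction codes must lie in {0, 1, 2, 3}")
  n <- length(v)
  v <- c(v, integer((-n) %% 4L))
  m <- matrix(v, nrow = 4L)
  bytes <- as.raw(m[1L, ] + 4L * m[2L, ] + 16L * m[3L, ] + 64L * m[4L, ])
  structure(bytes, n = n, dim_orig = dim(d))
}

#' @rdname pack_directions
#' @param p A raw vector produced by `pack_directions()`.
#' @export
unpack_directions <- function(p) {
  if (!is.raw(p) || is.null(attr(p, "n")))
    sw_value_error("input must come from pack_directions()")
  b <- as.integer(p)
  m <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  v <- as.integer(m)[seq_len(attr(p, "n"))]
  dim(v) <- attr(p, "dim_orig")
  v
}
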