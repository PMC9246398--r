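#' Single-cell score and direction update
#'
#' The update rule applied at every cell of the forward stage.  Given the
#' three already-computed neighbours of cell \eqn{H(i,j)} — diagonal
#' \eqn{x = H(i-1,j-1)}, vertical \eqn{y = H(i-1,j)} and horizontal
#' \eqn{v = H(i,j-1)} — and the substitution score for the symbol pair, the
#' candidates are \eqn{c_d = x + sub}, \eqn{c_y = y - \gamma} and
#' \eqn{c_v = v - \gamma}; the cell score is \eqn{\max(0, c_d, c_y, c_v)}.
#'
#' The direction code records which candidate won, in two bits:
#' \describe{
#'   \item{2}{diagonal step (match/mismatch); wins all ties it is part of}
#'   \item{1}{vertical step (gap rendered in the query row)}
#'   \item{3}{horizontal step (gap rendered in the database row); wins a
#'     vertical/horizontal tie}
#'   \item{0}{the zero floor won — an alignment ends (and traceback stops)
#'     here; emitted if and only if the score is 0}
#' }
#'
#' @param x,y,v Non-negative integers: the diagonal, vertical and
#'   horizontal neighbour scores.
#' @param sub Integer substitution score for this cell's symbol pair.
#' @param gap Non-negative integer linear gap penalty \eqn{\gamma}.
#' @return A list of class `sw_cell` with integer fields `score` and
#'   `direction`.
#' @examples
#' cell_update(0, 0, 0, sub = 5, gap = 1)   # score 5, diagonal
#' cell_update(3, 10, 10, sub = -5, gap = 1) # tie resolved horizontally
#' @export
cell_update <- function(x, y, v, sub, gap) {
  for (nm in c("x", "y", "v", "sub", "gap")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val != round(val))
      sw_value_error(sprintf("%s must be a single integer", nm))
  }
  if (x < 0 || y < 0 || v < 0)
    sw_contract_error("neighbour scores x, y, v must be non-negative")
  if (gap < 0)
    sw_value_error("gap penalty must be non-negative")
  cd <- as.integer(x + sub)
  cy <- as.integer(y - gap)
  cv <- as.integer(v - gap)
  if (cd >= cy && cd >= cv && cd > 0L) {
    score <- cd; direction <- 2L
  } else if (cy > cv && cy > 0L) {
    score <- cy; direction <- 1L
  } else if (cv > 0L) {
    score <- cv; direction <- 3L
  } else {
    score <- 0L; direction <- 0L
  }
  structure(list(score = score, direction = direction), class = "sw_cell")
}

#' @export
print.sw_cell <- function(x, ...) {
  cat(sprintf("<sw_cell> score %d, direction %d\n", x$score, x$direction))
  invisible(x)
}
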