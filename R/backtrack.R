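# Map traceback codes (in left-to-right alignment order) to a CIGAR string.
# Query-relative SAM semantics: 2 -> M (match or mismatch), 3 -> I (query
# symbol against a gap), 1 -> D (gap against a database symbol).
cigar_from_codes <- function(codes_alignment_order) {
  if (!length(codes_alignment_order)) return("")
  ops <- c("D", "M", "I")[codes_alignment_order]  # codes 1, 2, 3
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

new_alignment <- function(codes_traceback_order, q_aln, s_aln, score,
                          start_row, start_col, end_row, end_col) {
  structure(
    list(path_codes = codes_traceback_order,
         pairs = data.frame(q = rev(q_aln), s = rev(s_aln),
                            stringsAsFactors = FALSE),
         cigar = cigar_from_codes(rev(codes_traceback_order)),
         score = as.integer(score),
         start_row = as.integer(start_row), start_col = as.integer(start_col),
         end_row = as.integer(end_row), end_col = as.integer(end_col)),
    class = "sw_alignment")
}

#' Backtracking stage: walk the stored direction chain
#'
#' Starting at the maximum-score cell recorded by [forward_fill()], reads
#' the direction matrix repeatedly: code 2 consumes one symbol from each
#' sequence and moves diagonally; code 3 consumes a query symbol (dash in
#' the database row) and moves left; code 1 consumes a database symbol
#' (dash in the query row) and moves up.  The walk stops on reading a 0.
#' Because directions were stored during the forward stage, no score
#' arithmetic is needed here.
#'
#' @param fw An `sw_forward` result produced from `q` and `s`.
#' @param q,s The same sequences given to [forward_fill()].
#' @return An object of class `sw_alignment` with fields `path_codes` (the
#'   codes in the order visited during traceback, excluding the terminal
#'   0), `pairs` (aligned symbol pairs with dashes, in left-to-right
#'   order), `cigar`, `score`, and the 1-based matrix coordinates
#'   `start_row`, `start_col`, `end_row`, `end_col` of the aligned region.
#'   A zero maximum yields an empty alignment (no pairs, empty CIGAR,
#'   score 0).
#' @examples
#' sc <- scoring_scheme(5, -5, 1)
#' backtrack(forward_fill("ACT", "AT", sc), "ACT", "AT")$cigar  # "1M1I1M"
#' @export
backtrack <- function(fw, q, s) {
  stopifnot(inherits(fw, "sw_forward"))
  q <- sw_sequence(q)
  s <- sw_sequence(s)
  M <- length(s)
  N <- length(q)
  if (nrow(fw$H) != M + 1L || ncol(fw$H) != N + 1L)
    sw_contract_error("forward result does not match the given sequences")
  if (fw$max_row < 1L || fw$max_row > M || fw$max_col < 1L || fw$max_col > N)
    sw_contract_error("maximum-score position lies outside the matrix")
  i <- fw$max_row
  j <- fw$max_col
  codes <- integer(0)
  qa <- character(0)
  sa <- character(0)
  aux <- fw$D[i + 1L, j + 1L]
  while (aux > 0L) {
    if (!aux %in% 1:3)  # unreachable given D's invariant
      sw_contract_error("direction matrix contains a code outside {0,1,2,3}")
    codes <- c(codes, aux)
    if (aux == 2L) {
      qa <- c(qa, q$symbols[j]); sa <- c(sa, s$symbols[i])
      i <- i - 1L; j <- j - 1L
    } else if (aux == 3L) {
      qa <- c(qa, q$symbols[j]); sa <- c(sa, "-")
      j <- j - 1L
    } else {
      qa <- c(qa, "-"); sa <- c(sa, s$symbols[i])
      i <- i - 1L
    }
    aux <- fw$D[i + 1L, j + 1L]
  }
  if (length(codes)) {
    start_row <- i + 1L; start_col <- j + 1L
  } else {
    start_row <- fw$max_row; start_col <- fw$max_col
  }
  new_alignment(codes, qa, sa, fw$max_value,
                start_row, start_col, fw$max_row, fw$max_col)
}

#' Raw traceback path including the terminal zero
#'
#' The stored path list seeded with the starting cell's code and including
#' the final 0 read that terminates the walk (the sentinel is dropped from
#' `path_codes` itself).
#'
#' @param aln An `sw_alignment`.
#' @return Integer vector of codes ending in 0.
#' @export
path_trace <- function(aln) {
  stopifnot(inherits(aln, "sw_alignment"))
  c(aln$path_codes, 0L)
}

#' Align two sequences (forward fill + backtrack)
#'
#' @param q,s Sequences (`sw_sequence` or string).
#' @param scheme An [scoring_scheme()].
#' @return A list of class `sw_align_result` with fields `forward`
#'   (`sw_forward`) and `alignment` (`sw_alignment`).
#' @examples
#' res <- align("AC", "AC", scoring_scheme(5, -5, 1))
#' res$alignment$score  # 10
#' @export
align <- function(q, s, scheme) {
  q <- sw_sequence(q)
  s <- sw_sequence(s)
  fw <- forward_fill(q, s, scheme)
  structure(list(forward = fw, alignment = backtrack(fw, q, s)),
            class = "sw_align_result")
}

# Three-row rendering of the aligned region: query row, match bar, database
# row.  A bar marks identical symbols; gaps and mismatches get a space.
render_alignment <- function(aln) {
  if (!nrow(aln$pairs)) return(c("", "", ""))
  qr <- paste0(aln$pairs$q, collapse = "")
  sr <- paste0(aln$pairs$s, collapse = "")
  bar <- paste0(ifelse(aln$pairs$q == aln$pairs$s & aln$pairs$q != "-",
                       "|", " "), collapse = "")
  c(qr, bar, sr)
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %d, CIGAR %s\n",
              x$score, if (nzchar(x$cigar)) x$cigar else "(empty)"))
  if (nrow(x$pairs)) {
    rows <- render_alignment(x)
    cat(sprintf("  q  %s\n     %s\n  s  %s\n", rows[1], rows[2], rows[3]))
    cat(sprintf("  region: rows %d..%d, cols %d..%d\n",
                x$start_row, x$end_row, x$start_col, x$end_col))
  }
  invisible(x)
}

#' @export
print.sw_align_result <- function(x, ...) {
  print(x$forward)
  print(x$alignment)
  invisible(x)
}
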