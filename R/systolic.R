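# Cycle-stepped simulation of the processing-element (PE) array.  One PE
# per query symbol; PE j (0-based) owns matrix column j+1 and a direction
# memory of M words (one per database symbol).  Cells are computed along
# anti-diagonal wavefronts: at step t, PE j computes row i = t - j + 1.
# Each PE keeps two registers: its previous output Sc (= H(i-1, j+1)) and a
# one-step-delayed copy of the upstream PE's output (= H(i-1, j), the
# diagonal dependency).  The maximum-score record chains down the PEs with
# one register of delay per hop, so the last PE holds the global maximum by
# the final cycle.

# Vectorised comparison of (value, row, col) records; on equal value the
# lexicographically smaller (col, row) wins, which reproduces the
# sequential column-major first-maximum rule.
pick_max_record <- function(av, ar, ac, bv, br, bc) {
  a_wins <- av > bv | (av == bv & (ac < bc | (ac == bc & ar < br)))
  list(val = ifelse(a_wins, av, bv),
       row = ifelse(a_wins, ar, br),
       col = ifelse(a_wins, ac, bc))
}

#' Simulate the forward stage on the systolic PE array
#'
#' Steps the array cycle by cycle under an idealised one-cell-per-PE-per-
#' cycle wavefront model: the fill of an \eqn{M \times N} matrix takes
#' exactly \eqn{M + N - 1} cycles.  Each computed direction code is written
#' once to the owning PE's direction memory (address = database row - 1);
#' scores are never stored in the array — only the two per-PE registers and
#' the chained maximum record carry them forward.  The simulator records
#' the scores it computes on the side so the result can be verified
#' cell-for-cell against [forward_fill()].
#'
#' @param q Query sequence; the array holds one PE per query symbol.
#' @param s Database sequence; its length must be at least the query's
#'   (each direction memory holds one word per database symbol).
#' @param scheme An [scoring_scheme()].
#' @param pe_count Number of PEs; must equal `length(q)` (the default).
#' @param trace If `TRUE`, attach a per-cycle event log (`step`, `pe`,
#'   `row`, `col`, `score`, `direction`) as a data frame.
#' @return An object of class `sw_pe_array`: `pe_states` (a list per PE
#'   with `index`, `held_q_symbol`, `direction_memory`, the two registers,
#'   `local_max` and `row_counter`), the global `max_value`/`max_row`/
#'   `max_col`, `forward_cycles`, `pe_count`, the score record, and the
#'   optional `trace`.
#' @examples
#' pa <- simulate_forward("AC", "AC", scoring_scheme(5, -5, 1))
#' pa$forward_cycles  # 3
#' @export
simulate_forward <- function(q, s, scheme, pe_count = NULL, trace = FALSE) {
  q <- sw_sequence(q)
  s <- sw_sequence(s)
  stopifnot(inherits(scheme, "sw_scoring"))
  check_same_alphabet(q, s)
  N <- length(q)
  M <- length(s)
  if (is.null(pe_count)) pe_count <- N
  if (pe_count != N)
    sw_config_error(sprintf(
      "pe_count (%d) must equal the query length (%d): one PE per query symbol",
      pe_count, N))
  if (M < N)
    sw_constraint_error(paste0(
      "database sequence is shorter than the query (M = ", M, " < N = ", N,
      "); swap the inputs or call simulate_systolic(..., swap = TRUE)"))
  alpha <- q$alphabet
  submat <- expand_substitution_matrix(scheme, alpha)
  qi <- match(q$symbols, alpha)
  si <- match(s$symbols, alpha)
  gap <- scheme$gap

  sc <- integer(N)   # previous output of each PE: H(i-1, j+1)
  dg <- integer(N)   # delayed upstream output: H(i-1, j)
  Hc <- matrix(0L, M, N)
  Dc <- matrix(0L, M, N)
  chain_val <- integer(N)
  chain_row <- rep(1L, N)   # all-zero convention: value 0 at (1, 1)
  chain_col <- rep(1L, N)
  steps <- M + N - 1L
  trace_rows <- if (trace) vector("list", steps) else NULL

  for (t in 0:(steps - 1L)) {
    j <- max(0L, t - M + 1L):min(N - 1L, t)  # active PEs (0-based)
    i <- t - j + 1L                          # database rows (1-based)
    left_in <- c(0L, sc)[j + 1L]             # upstream output = H(i, j)
    cd <- dg[j + 1L] + submat[cbind(si[i], qi[j + 1L])]
    cy <- sc[j + 1L] - gap
    cv <- left_in - gap
    dir2 <- cd >= cy & cd >= cv & cd > 0L
    dir1 <- !dir2 & cy > cv & cy > 0L
    dir3 <- !dir2 & !dir1 & cv > 0L
    score <- integer(length(j))
    score[dir2] <- cd[dir2]
    score[dir1] <- cy[dir1]
    score[dir3] <- cv[dir3]
    dirn <- integer(length(j))
    dirn[dir2] <- 2L; dirn[dir1] <- 1L; dirn[dir3] <- 3L
    Hc[cbind(i, j + 1L)] <- score
    Dc[cbind(i, j + 1L)] <- dirn   # single write per memory address
    if (trace)
      trace_rows[[t + 1L]] <- data.frame(step = t, pe = j, row = i,
                                         col = j + 1L, score = score,
                                         direction = dirn)
    # register updates: delayed diagonal, own output
    dg[j + 1L] <- left_in
    sc[j + 1L] <- score
    # chained maximum: each PE combines the upstream register (previous
    # cycle), its own register, and — if active — its new cell
    up <- pick_max_record(c(-1L, chain_val[-N]), c(1L, chain_row[-N]),
                          c(1L, chain_col[-N]),
                          chain_val, chain_row, chain_col)
    cand_val <- rep(-1L, N); cand_row <- rep(1L, N); cand_col <- rep(1L, N)
    cand_val[j + 1L] <- score
    cand_row[j + 1L] <- i
    cand_col[j + 1L] <- j + 1L
    comb <- pick_max_record(up$val, up$row, up$col,
                            cand_val, cand_row, cand_col)
    chain_val <- as.integer(comb$val)
    chain_row <- as.integer(comb$row)
    chain_col <- as.integer(comb$col)
  }

  pe_states <- lapply(seq_len(N), function(k) {
    list(index = k - 1L,
         held_q_symbol = q$symbols[k],
         direction_memory = Dc[, k],
         prev_score_register = sc[k],
         diag_register = dg[k],
         local_max = list(value = chain_val[k], row = chain_row[k],
                          col = chain_col[k]),
         row_counter = M)
  })
  structure(
    list(pe_states = pe_states,
         max_value = chain_val[N], max_row = chain_row[N],
         max_col = chain_col[N],
         forward_cycles = steps, pe_count = N,
         score_record = Hc,
         trace = if (trace) do.call(rbind, trace_rows) else NULL),
    class = "sw_pe_array")
}

#' @export
print.sw_pe_array <- function(x, ...) {
  cat(sprintf(
    "<sw_pe_array> %d PEs, %d-word direction memories, %d forward cycles\n",
    x$pe_count, length(x$pe_states[[1L]]$direction_memory),
    x$forward_cycles))
  cat(sprintf("  maximum %d at (row %d, col %d)\n",
              x$max_value, x$max_row, x$max_col))
  invisible(x)
}

#' Simulate the backtracking chain walk
#'
#' After the forward stage raises the traceback flag, the maximum-score
#' address propagates from the last PE down the chain to the PE holding the
#' maximum column (one cycle per hop), and the walk begins: a code 2 read
#' decrements both the memory address and the active PE; code 3 keeps the
#' address and moves one PE back; code 1 decrements the address within the
#' same PE.  The walk stops on reading 0 or on stepping past PE 0 /
#' address 0.  `backtrack_cycles` charges one cycle per PE hop plus one per
#' memory read (including the terminating 0 read when one occurs).
#'
#' @param pe_array An `sw_pe_array` from [simulate_forward()].
#' @param q,s The sequences given to [simulate_forward()].
#' @return A list with `alignment` (an `sw_alignment`, identical to the
#'   sequential [backtrack()] result) and `backtrack_cycles`.
#' @export
simulate_backtrack <- function(pe_array, q, s) {
  stopifnot(inherits(pe_array, "sw_pe_array"))
  q <- sw_sequence(q)
  s <- sw_sequence(s)
  N <- pe_array$pe_count
  M <- length(pe_array$pe_states[[1L]]$direction_memory)
  if (length(q) != N || length(s) != M)
    sw_contract_error("sequences do not match the simulated PE array")
  if (pe_array$max_row < 1L || pe_array$max_row > M ||
      pe_array$max_col < 1L || pe_array$max_col > N)
    sw_contract_error("maximum-score record lies outside the array")
  if (pe_array$max_value > 0L &&
      pe_array$pe_states[[pe_array$max_col]]$direction_memory[
        pe_array$max_row] == 0L)
    sw_contract_error("maximum-score record inconsistent with PE memories")

  pe <- pe_array$max_col - 1L   # 0-based PE of the maximum
  addr <- pe_array$max_row - 1L # 0-based memory address
  hops <- (N - 1L) - pe
  reads <- 0L
  codes <- integer(0)
  qa <- character(0)
  sa <- character(0)
  while (pe >= 0L && addr >= 0L) {
    code <- pe_array$pe_states[[pe + 1L]]$direction_memory[addr + 1L]
    reads <- reads + 1L
    if (code == 0L) break
    codes <- c(codes, code)
    if (code == 2L) {
      qa <- c(qa, q$symbols[pe + 1L]); sa <- c(sa, s$symbols[addr + 1L])
      addr <- addr - 1L; pe <- pe - 1L
    } else if (code == 3L) {
      qa <- c(qa, q$symbols[pe + 1L]); sa <- c(sa, "-")
      pe <- pe - 1L
    } else {
      qa <- c(qa, "-"); sa <- c(sa, s$symbols[addr + 1L])
      addr <- addr - 1L
    }
  }
  if (length(codes)) {
    start_row <- addr + 2L
    start_col <- pe + 2L
  } else {
    start_row <- pe_array$max_row
    start_col <- pe_array$max_col
  }
  aln <- new_alignment(codes, qa, sa, pe_array$max_value,
                       start_row, start_col,
                       pe_array$max_row, pe_array$max_col)
  list(alignment = aln, backtrack_cycles = hops + reads)
}

#' Full systolic simulation (forward + backtracking)
#'
#' Composes [simulate_forward()] and [simulate_backtrack()] and reassembles
#' a forward result from the PE direction memories, the simulator's score
#' record, and the chained maximum.  Both components are, by contract,
#' identical to the sequential [forward_fill()]/[backtrack()] outputs on
#' the same inputs.
#'
#' @param q,s Sequences (`sw_sequence` or string).
#' @param scheme An [scoring_scheme()].
#' @param pe_count Number of PEs; must equal the query length (default).
#' @param swap If `TRUE` and the database sequence is shorter than the
#'   query, the two are swapped before simulation (the array requires
#'   \eqn{M \ge N}); the result notes `swapped = TRUE` and all coordinates
#'   refer to the swapped orientation.  Without the flag the constraint
#'   violation is an error, so a caller cannot swap roles by accident.
#' @param trace Passed to [simulate_forward()].
#' @return An object of class `sw_sim` with fields `forward`
#'   (`sw_forward`), `alignment` (`sw_alignment`), `forward_cycles`
#'   (\eqn{M + N - 1}), `backtrack_cycles`, `pe_count`, `swapped`, and
#'   `trace`.
#' @examples
#' sim <- simulate_systolic("AC", "AC", scoring_scheme(5, -5, 1))
#' sim$forward_cycles  # 3
#' @export
simulate_systolic <- function(q, s, scheme, pe_count = NULL, swap = FALSE,
                              trace = FALSE) {
  q <- sw_sequence(q)
  s <- sw_sequence(s)
  swapped <- FALSE
  if (length(s) < length(q) && isTRUE(swap)) {
    tmp <- q; q <- s; s <- tmp
    swapped <- TRUE
  }
  pa <- simulate_forward(q, s, scheme, pe_count = pe_count, trace = trace)
  bt <- simulate_backtrack(pa, q, s)
  M <- length(s)
  N <- length(q)
  H <- matrix(0L, M + 1L, N + 1L)
  D <- matrix(0L, M + 1L, N + 1L)
  H[-1L, -1L] <- pa$score_record
  D[-1L, -1L] <- vapply(pa$pe_states, `[[`, integer(M), "direction_memory")
  fw <- structure(
    list(H = H, D = D, max_value = pa$max_value,
         max_row = pa$max_row, max_col = pa$max_col,
         cell_count = M * N),
    class = "sw_forward")
  structure(
    list(forward = fw, alignment = bt$alignment,
         forward_cycles = pa$forward_cycles,
         backtrack_cycles = bt$backtrack_cycles,
         pe_count = pa$pe_count, swapped = swapped, trace = pa$trace),
    class = "sw_sim")
}

#' @export
print.sw_sim <- function(x, ...) {
  cat(sprintf(
    "<sw_sim> %d PEs, %d forward + %d backtrack cycles%s\n",
    x$pe_count, x$forward_cycles, x$backtrack_cycles,
    if (x$swapped) " (inputs swapped)" else ""))
  print(x$alignment)
  invisible(x)
}
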