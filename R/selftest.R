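# Plainly written reference scorer, kept deliberately separate from the
# C++ fill: a row-major textbook recurrence that computes only the maximum
# local-alignment score.  Used by sw_selftest() to cross-check the
# implementation at run time.
reference_local_score <- function(q, s, scheme) {
  q <- sw_sequence(q)
  s <- sw_sequence(s)
  n <- length(q)
  m <- length(s)
  H <- matrix(0L, m + 1L, n + 1L)
  best <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- substitution_score(s$symbols[i], q$symbols[j], scheme)
      h <- max(0L, H[i, j] + sub, H[i, j + 1L] - scheme$gap,
               H[i + 1L, j] - scheme$gap)
      H[i + 1L, j + 1L] <- h
      if (h > best) best <- h
    }
  }
  best
}

#' Run the built-in cross-check suite
#'
#' Aligns `n_cases` random sequence pairs with randomly drawn scoring
#' parameters and verifies, for each, that (a) the forward-stage maximum
#' equals an independently coded reference scorer, (b) the systolic
#' simulation reproduces the sequential forward and backtracking results
#' exactly, and (c) the score recomputed from the rendered alignment pairs
#' equals the reported maximum.
#'
#' @param n_cases Number of random cases (default 50).
#' @param seed Integer seed.
#' @param max_len Maximum sequence length drawn (default 24).
#' @return `TRUE` invisibly if every check passes; otherwise an error
#'   describing the first failing case.
#' @export
sw_selftest <- function(n_cases = 50, seed = 1, max_len = 24) {
  set.seed(seed)
  for (k in seq_len(n_cases)) {
    n <- sample.int(max_len, 1L)
    # keep M >= N so the array applies directly
    m <- n + sample.int(max_len - n + 1L, 1L) - 1L
    p <- list(q = sw_sequence(sample(sw_alphabets$dna, n, TRUE)),
              s = sw_sequence(sample(sw_alphabets$dna, m, TRUE)))
    scheme <- scoring_scheme(match = sample(1:9, 1L),
                             mismatch = -sample(0:9, 1L),
                             gap = sample(0:4, 1L))
    res <- align(p$q, p$s, scheme)
    ref <- reference_local_score(p$q, p$s, scheme)
    if (res$forward$max_value != ref)
      stop(sprintf("selftest case %d: forward maximum %d != reference %d",
                   k, res$forward$max_value, ref))
    sim <- simulate_systolic(p$q, p$s, scheme)
    if (!identical(sim$forward$H, res$forward$H) ||
        !identical(sim$forward$D, res$forward$D) ||
        !identical(sim$alignment, res$alignment))
      stop(sprintf("selftest case %d: simulator diverged from aligner", k))
    if (recompute_alignment_score(res$alignment, scheme) !=
        res$alignment$score)
      stop(sprintf("selftest case %d: pair-recomputed score mismatch", k))
  }
  invisible(TRUE)
}

#' Recompute an alignment score from its rendered pairs
#'
#' Sums the per-column contributions of the gapped pairs: the substitution
#' score for each dash-free pair, minus the gap penalty for each dash.
#' For a valid traceback this equals the reported maximum score.
#'
#' @param aln An `sw_alignment`.
#' @param scheme The [scoring_scheme()] used to produce it.
#' @return Integer score.
#' @export
recompute_alignment_score <- function(aln, scheme) {
  stopifnot(inherits(aln, "sw_alignment"))
  if (!nrow(aln$pairs)) return(0L)
  total <- 0L
  for (k in seq_len(nrow(aln$pairs))) {
    qs <- aln$pairs$q[k]
    ss <- aln$pairs$s[k]
    total <- total + if (qs == "-" || ss == "-") -scheme$gap
                     else substitution_score(ss, qs, scheme)
  }
  as.integer(total)
}
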