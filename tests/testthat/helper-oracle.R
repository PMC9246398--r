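# Independent oracles, written against the textbook recurrence and kept
# deliberately separate from the package implementation.

# uniform integer in [lo, hi] without the length-one sample() trap
ri <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_dna <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_case <- function(min_len = 1L, max_len = 32L, m_ge_n = FALSE) {
  n <- ri(min_len, max_len)
  m <- if (m_ge_n) ri(n, max_len) else ri(min_len, max_len)
  list(q = random_dna(n), s = random_dna(m),
       scheme = scoring_scheme(match = ri(1L, 9L), mismatch = -ri(0L, 9L),
                               gap = ri(0L, 4L)))
}

# Brute-force textbook local-alignment DP: row-major, scores only.
oracle_sw_score <- function(q, s, scheme) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc)
  m <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- if (sc[i] == qc[j]) scheme$match else scheme$mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + sub,
                             H[i, j + 1] - scheme$gap,
                             H[i + 1, j] - scheme$gap)
    }
  }
  max(H)
}

# Exhaustive enumeration: best score over every gapped global alignment of
# q[qi..n] vs s[si..m], by recursing over the three column types (no
# memoisation — every alignment path is visited).
enum_global_best <- function(qc, sc, qi, si, scheme) {
  n <- length(qc)
  m <- length(sc)
  if (qi > n && si > m) return(0)
  best <- -Inf
  if (qi <= n && si <= m) {
    sub <- if (qc[qi] == sc[si]) scheme$match else scheme$mismatch
    best <- max(best, sub + enum_global_best(qc, sc, qi + 1, si + 1, scheme))
  }
  if (qi <= n)
    best <- max(best, -scheme$gap + enum_global_best(qc, sc, qi + 1, si, scheme))
  if (si <= m)
    best <- max(best, -scheme$gap + enum_global_best(qc, sc, qi, si + 1, scheme))
  best
}

# Best local score = max over all substring pairs (empty pair scores 0).
enum_local_best <- function(q, s, scheme) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  best <- 0
  for (a in seq_along(qc)) for (b in a:length(qc)) {
    for (cc in seq_along(sc)) for (d in cc:length(sc)) {
      best <- max(best, enum_global_best(qc[a:b], sc[cc:d], 1, 1, scheme))
    }
  }
  best
}

# Third route: Biostrings' Smith-Waterman with linear gaps.
biostrings_local_score <- function(q, s, scheme) {
  letters4 <- c("A", "C", "G", "T")
  sm <- matrix(scheme$mismatch, 4, 4, dimnames = list(letters4, letters4))
  diag(sm) <- scheme$match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = scheme$gap,
    type = "local")
  as.numeric(Biostrings::score(pa))
}

# Sum the per-column contributions of a rendered alignment.
pairwise_recount <- function(aln, scheme) {
  if (!nrow(aln$pairs)) return(0)
  total <- 0
  for (k in seq_len(nrow(aln$pairs))) {
    a <- aln$pairs$q[k]
    b <- aln$pairs$s[k]
    total <- total + if (a == "-" || b == "-") -scheme$gap
                     else if (a == b) scheme$match else scheme$mismatch
  }
  total
}

# Build a PE-array object from a sequential forward result by transcribing
# the direction-matrix columns into per-PE memories.
pe_array_from_forward <- function(fw, q) {
  M <- nrow(fw$H) - 1L
  N <- ncol(fw$H) - 1L
  qc <- strsplit(q, "")[[1]]
  states <- lapply(seq_len(N), function(k) {
    list(index = k - 1L, held_q_symbol = qc[k],
         direction_memory = fw$D[-1L, k + 1L],
         prev_score_register = fw$H[M + 1L, k + 1L],
         diag_register = fw$H[M, k + 1L],
         local_max = list(value = fw$max_value, row = fw$max_row,
                          col = fw$max_col),
         row_counter = M)
  })
  structure(
    list(pe_states = states, max_value = fw$max_value, max_row = fw$max_row,
         max_col = fw$max_col, forward_cycles = M + N - 1L, pe_count = N,
         score_record = fw$H[-1L, -1L, drop = FALSE], trace = NULL),
    class = "sw_pe_array")
}
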