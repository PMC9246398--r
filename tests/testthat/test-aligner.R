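sc551 <- scoring_scheme(match = 5, mismatch = -5, gap = 1)

test_that("forward fill matches the hand-worked AC/AC case", {
  fw <- forward_fill("AC", "AC", sc551)
  expect_identical(fw$max_value, 10L)
  expect_identical(fw$max_row, 2L)
  expect_identical(fw$max_col, 2L)
  expect_identical(fw$D[2:3, 2:3], matrix(c(2L, 1L, 3L, 2L), 2, 2))
  expect_identical(fw$H[1, ], c(0L, 0L, 0L))  # zero border (row 0)
  expect_identical(fw$H[, 1], c(0L, 0L, 0L))
  expect_identical(fw$cell_count, 4L)
})

test_that("an alignment with no positive cell reports (1,1)/0 by convention", {
  fw <- forward_fill("A", "T", sc551)
  expect_identical(max(fw$H), 0L)
  expect_identical(fw$max_value, 0L)
  expect_identical(fw$max_row, 1L)
  expect_identical(fw$max_col, 1L)
  aln <- backtrack(fw, "A", "T")
  expect_identical(nrow(aln$pairs), 0L)
  expect_identical(aln$cigar, "")
  expect_identical(aln$score, 0L)
})

test_that("backtracking renders pairs, CIGAR and coordinates", {
  aln <- backtrack(forward_fill("AC", "AC", sc551), "AC", "AC")
  expect_identical(aln$pairs$q, c("A", "C"))
  expect_identical(aln$pairs$s, c("A", "C"))
  expect_identical(aln$cigar, "2M")
  expect_identical(aln$score, 10L)
  expect_identical(c(aln$start_row, aln$start_col), c(1L, 1L))
  expect_identical(c(aln$end_row, aln$end_col), c(2L, 2L))
  expect_identical(path_trace(aln), c(2L, 2L, 0L))  # raw path keeps the 0

  # the C aligns against a dash via a horizontal (code 3) step
  res <- align("ACT", "AT", sc551)
  expect_identical(res$alignment$score, 9L)
  expect_identical(res$alignment$cigar, "1M1I1M")
  expect_identical(res$alignment$pairs$q, c("A", "C", "T"))
  expect_identical(res$alignment$pairs$s, c("A", "-", "T"))
  expect_identical(res$alignment$path_codes, c(2L, 3L, 2L))
})

test_that("input contracts are enforced", {
  expect_error(forward_fill("AC", "MK", sc551), class = "sw_alphabet_error")
  expect_error(
    forward_fill(sw_sequence("AC"), sw_sequence("MK", alphabet = "protein"),
                 sc551),
    class = "sw_alphabet_error")
  fw <- forward_fill("AC", "AC", sc551)
  expect_error(backtrack(fw, "ACGT", "AC"), class = "sw_contract_error")
  bad <- fw
  bad$max_col <- 7L
  expect_error(backtrack(bad, "AC", "AC"), class = "sw_contract_error")
})

test_that("max score matches brute-force DP and Biostrings on random cases", {
  set.seed(101)
  for (k in 1:80) {
    cs <- random_case(1L, 32L)
    fw <- forward_fill(cs$q, cs$s, cs$scheme)
    expect_identical(as.numeric(fw$max_value),
                     oracle_sw_score(cs$q, cs$s, cs$scheme))
    expect_true(min(fw$H) == 0L)
    expect_true(all(fw$D %in% 0:3))
  }
  # third, library-independent route on a smaller batch
  for (k in 1:25) {
    cs <- random_case(2L, 24L)
    fw <- forward_fill(cs$q, cs$s, cs$scheme)
    expect_identical(as.numeric(fw$max_value),
                     biostrings_local_score(cs$q, cs$s, cs$scheme))
  }
})

test_that("max position obeys the first-in-column-major tie rule", {
  # two equal maxima in one column: the smaller row wins
  fw <- forward_fill("A", "AA", sc551)
  expect_identical(fw$max_value, 5L)
  expect_identical(c(fw$max_row, fw$max_col), c(1L, 1L))
  # two equal maxima in one row: the smaller column wins
  fw <- forward_fill("AA", "A", sc551)
  expect_identical(c(fw$max_row, fw$max_col), c(1L, 1L))
})

test_that("recomputing the score from the rendered pairs gives the maximum", {
  set.seed(77)
  for (k in 1:60) {
    cs <- random_case(1L, 24L)
    res <- align(cs$q, cs$s, cs$scheme)
    expect_identical(pairwise_recount(res$alignment, cs$scheme),
                     as.numeric(res$alignment$score))
    # dash-stripped rows are contiguous substrings of the inputs
    qsub <- paste0(res$alignment$pairs$q[res$alignment$pairs$q != "-"],
                   collapse = "")
    ssub <- paste0(res$alignment$pairs$s[res$alignment$pairs$s != "-"],
                   collapse = "")
    expect_true(grepl(qsub, cs$q, fixed = TRUE))
    expect_true(grepl(ssub, cs$s, fixed = TRUE))
  }
})

test_that("the maximum score is monotone in the match reward", {
  set.seed(5)
  for (k in 1:10) {
    q <- random_dna(ri(4L, 16L))
    s <- random_dna(ri(4L, 16L))
    prev <- -1L
    for (a in 1:8) {
      fw <- forward_fill(q, s, scoring_scheme(match = a, mismatch = -4,
                                              gap = 2))
      expect_gte(fw$max_value, prev)
      prev <- fw$max_value
    }
  }
})

test_that("swapping the inputs preserves the score; CIGAR swaps I and D", {
  set.seed(13)
  for (k in 1:50) {
    q <- random_dna(ri(1L, 20L))
    s <- random_dna(ri(1L, 20L))
    scheme <- scoring_scheme(match = ri(1L, 8L), mismatch = -ri(1L, 8L),
                             gap = ri(0L, 3L))
    expect_identical(forward_fill(q, s, scheme)$max_value,
                     forward_fill(s, q, scheme)$max_value)
  }
  # deterministic example with a unique optimal path
  a1 <- align("ACT", "AT", sc551)$alignment
  a2 <- align("AT", "ACT", sc551)$alignment
  expect_identical(a1$cigar, "1M1I1M")
  expect_identical(a2$cigar, "1M1D1M")
})
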