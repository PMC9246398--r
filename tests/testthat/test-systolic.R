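sc551 <- scoring_scheme(match = 5, mismatch = -5, gap = 1)

test_that("PE direction memories transcribe the direction-matrix columns", {
  pa <- simulate_forward("AC", "AC", sc551)
  expect_identical(pa$pe_states[[1]]$direction_memory, c(2L, 1L))
  expect_identical(pa$pe_states[[2]]$direction_memory, c(3L, 2L))
  expect_identical(pa$max_value, 10L)
  expect_identical(c(pa$max_row, pa$max_col), c(2L, 2L))
  expect_identical(pa$forward_cycles, 3L)  # M + N - 1
  expect_identical(pa$pe_states[[2]]$row_counter, 2L)
})

test_that("a single matching symbol uses one PE and one cycle", {
  pa <- simulate_forward("A", "A", sc551)
  expect_identical(pa$pe_count, 1L)
  expect_identical(pa$pe_states[[1]]$direction_memory, 2L)
  expect_identical(pa$max_value, 5L)
  expect_identical(c(pa$max_row, pa$max_col), c(1L, 1L))
  expect_identical(pa$forward_cycles, 1L)
})

test_that("array configuration contracts are enforced", {
  expect_error(simulate_forward("ACGT", "AC", sc551),
               class = "sw_constraint_error")
  expect_error(simulate_forward("AC", "ACGT", sc551, pe_count = 3),
               class = "sw_config_error")
  # the swap flag makes the long sequence the database
  sim <- simulate_systolic("ACGT", "AC", sc551, swap = TRUE)
  expect_true(sim$swapped)
  expect_identical(sim$pe_count, 2L)
  expect_identical(sim$forward$max_value,
                   forward_fill("AC", "ACGT", sc551)$max_value)
})

test_that("simulation equals the sequential aligner on random cases", {
  set.seed(202)
  for (k in 1:60) {
    cs <- random_case(1L, 32L, m_ge_n = TRUE)
    seq_res <- align(cs$q, cs$s, cs$scheme)
    sim <- simulate_systolic(cs$q, cs$s, cs$scheme)
    expect_identical(sim$forward$H, seq_res$forward$H)
    expect_identical(sim$forward$D, seq_res$forward$D)
    expect_identical(sim$forward$max_value, seq_res$forward$max_value)
    expect_identical(c(sim$forward$max_row, sim$forward$max_col),
                     c(seq_res$forward$max_row, seq_res$forward$max_col))
    expect_identical(sim$alignment, seq_res$alignment)
    expect_identical(sim$forward_cycles,
                     nchar(cs$q) + nchar(cs$s) - 1L)  # M + N - 1
  }
})

test_that("the chained maximum lands on the sequential tie cell", {
  # constructed ties within a column and across columns
  for (case in list(c("A", "AA"), c("AA", "AT"), c("AA", "AAA"),
                    c("ACAC", "ACACACAC"))) {
    fw <- forward_fill(case[1], case[2], sc551)
    pa <- simulate_forward(case[1], case[2], sc551)
    expect_identical(c(pa$max_value, pa$max_row, pa$max_col),
                     c(fw$max_value, fw$max_row, fw$max_col))
  }
})

test_that("the wavefront never reads a value before it is produced", {
  pa <- simulate_forward("ACGT", "TGCACGT", sc551, trace = TRUE)
  tr <- pa$trace
  # each cell (row i, col j) is computed at step i + j - 2: its
  # neighbours (earlier row/column) were all computed at earlier steps
  expect_identical(tr$step, tr$row + tr$col - 2L)
  # memory discipline: every direction-memory address is written once
  expect_identical(nrow(unique(tr[, c("pe", "row")])), nrow(tr))
  expect_identical(nrow(tr), 4L * 7L)  # every cell computed exactly once
  # and the log's scores agree with the assembled record
  expect_identical(pa$score_record[cbind(tr$row, tr$col)], tr$score)
})

test_that("the backtracking walk steps PEs and addresses per the code read", {
  fw <- forward_fill("ACT", "AT", sc551)
  pa <- pe_array_from_forward(fw, "ACT")
  bt <- simulate_backtrack(pa, "ACT", "AT")
  expect_identical(bt$alignment$cigar, "1M1I1M")
  expect_identical(bt$alignment$path_codes, c(2L, 3L, 2L))
  expect_identical(bt$alignment, backtrack(fw, "ACT", "AT"))
  # start at PE 2 (max col 3): no hops; 3 reads, border exit without a 0 read
  expect_identical(bt$backtrack_cycles, 3L)

  # all-zero array, one PE: a single terminating read
  fw0 <- forward_fill("A", "T", sc551)
  bt0 <- simulate_backtrack(pe_array_from_forward(fw0, "A"), "A", "T")
  expect_identical(nrow(bt0$alignment$pairs), 0L)
  expect_identical(bt0$backtrack_cycles, 1L)

  # hop accounting: maximum in PE 0 of a 3-PE array costs 2 hops + reads
  fw1 <- forward_fill("AGG", "ATT", sc551)  # single match at (1,1)
  expect_identical(c(fw1$max_row, fw1$max_col), c(1L, 1L))
  bt1 <- simulate_backtrack(pe_array_from_forward(fw1, "AGG"), "AGG", "ATT")
  expect_identical(bt1$backtrack_cycles, 2L + 1L)  # 2 hops, 1 read (code 2)

  # inconsistent max record is a contract violation
  bad <- pe_array_from_forward(fw, "ACT")
  bad$max_row <- 9L
  expect_error(simulate_backtrack(bad, "ACT", "AT"),
               class = "sw_contract_error")
})
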