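#' Read sequences from a FASTA file
#'
#' One `sw_sequence` per record, in file order; the header text becomes
#' the name.  Symbols are upper-cased and validated against the alphabet —
#' ambiguity codes (e.g. `N` under DNA) are rejected, naming the record
#' and offset.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"`, `"protein"`, or a custom symbol vector.
#' @return A list of `sw_sequence` objects.
#' @export
read_fasta <- function(path, alphabet = "dna") {
  if (!file.exists(path))
    sw_input_error(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first))
    sw_parse_error(sprintf("'%s' is empty, no FASTA records", path))
  if (!startsWith(trimws(lines[first]), ">"))
    sw_parse_error(sprintf(
      "'%s' line %d: expected a '>' FASTA header", path, first))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) sw_parse_error(sprintf(
      "malformed FASTA in '%s': %s", path, conditionMessage(e))))
  lapply(seq_along(set), function(k) {
    nm <- names(set)[k]
    tryCatch(
      sw_sequence(as.character(set[[k]]), alphabet = alphabet, name = nm),
      sw_alphabet_error = function(e) sw_alphabet_error(sprintf(
        "record '%s': %s", nm, conditionMessage(e))))
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs A single `sw_sequence` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "sw_sequence")) seqs <- list(seqs)
  txt <- vapply(seqs, as.character, character(1))
  nms <- vapply(seqs, function(x) x$name, character(1))
  nms[!nzchar(nms)] <- paste0("seq", which(!nzchar(nms)))
  set <- Biostrings::BStringSet(stats::setNames(txt, nms))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Generate a random query/database sequence pair
#'
#' Symbols are drawn i.i.d. uniformly over the alphabet; the same seed
#' reproduces the same pair.  This emulates the randomly generated
#' validation inputs used to exercise the aligner and the array simulator.
#'
#' @param n Query length (N).
#' @param m Database length (M).
#' @param alphabet `"dna"`, `"protein"`, or a custom symbol vector.
#' @param seed Optional integer seed.
#' @return A list with elements `q` and `s` (`sw_sequence`).
#' @examples
#' p <- generate_sequences(8, 12, seed = 7)
#' length(p$s)  # 12
#' @export
generate_sequences <- function(n, m, alphabet = "dna", seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      !is.numeric(m) || length(m) != 1L || is.na(m) || m < 1)
    sw_value_error("sequence lengths must be positive")
  alpha <- resolve_alphabet(alphabet)
  if (!is.null(seed)) set.seed(seed)
  list(q = sw_sequence(sample(alpha$symbols, n, replace = TRUE),
                       alphabet = alphabet, name = "q"),
       s = sw_sequence(sample(alpha$symbols, m, replace = TRUE),
                       alphabet = alphabet, name = "s"))
}

#' Serialize an alignment result
#'
#' Renders a forward result plus alignment (and optional performance
#' report) as human-readable text, machine-readable JSON, or a one-row
#' TSV.  The text format shows the two gapped alignment rows with a match
#' line and reports the maximum score, the 1-based row/column at which the
#' aligned region starts, and the CIGAR.
#'
#' @param fw An `sw_forward`.
#' @param aln The matching `sw_alignment`.
#' @param perf Optional `sw_perf` from [perf_report()].
#' @param format One of `"text"`, `"json"`, `"tsv"`.
#' @return A single character string.
#' @export
write_result <- function(fw, aln, perf = NULL, format = "text") {
  stopifnot(inherits(fw, "sw_forward"), inherits(aln, "sw_alignment"))
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("text", "json", "tsv"))
    sw_config_error("format must be one of \"text\", \"json\", \"tsv\"")
  rows <- render_alignment(aln)
  if (format == "text") {
    out <- c(
      if (nrow(aln$pairs)) c(paste0("q: ", rows[1]),
                             paste0("   ", rows[2]),
                             paste0("s: ", rows[3]))
      else "(empty alignment)",
      sprintf("Maximum Value: %d", aln$score),
      sprintf("Row: %d", aln$start_row),
      sprintf("Column: %d", aln$start_col),
      sprintf("CIGAR: %s", aln$cigar),
      if (!is.null(perf)) sprintf("GCUPS: %.6g", perf$gcups))
    return(paste(out, collapse = "\n"))
  }
  if (format == "json") {
    obj <- list(
      score = aln$score, max_value = fw$max_value,
      max_row = fw$max_row, max_col = fw$max_col,
      start_row = aln$start_row, start_col = aln$start_col,
      end_row = aln$end_row, end_col = aln$end_col,
      cigar = aln$cigar,
      q_aligned = rows[1], s_aligned = rows[3],
      path_codes = aln$path_codes,
      cell_count = fw$cell_count)
    if (!is.null(perf))
      obj$perf <- list(cell_count = perf$cell_count,
                       elapsed_seconds = perf$elapsed_seconds,
                       clock_hz = perf$clock_hz, pe_count = perf$pe_count,
                       gcups = perf$gcups)
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         null = "null", digits = NA)))
  }
  # tsv: header plus one row per alignment
  header <- paste(c("score", "start_row", "start_col", "end_row", "end_col",
                    "cigar", "q_aligned", "s_aligned"), collapse = "\t")
  row <- paste(c(aln$score, aln$start_row, aln$start_col, aln$end_row,
                 aln$end_col, aln$cigar, rows[1], rows[3]), collapse = "\t")
  paste(header, row, sep = "\n")
}
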