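#' GCUPS from cell count and elapsed time
#'
#' Achieved throughput in giga cell updates per second: the number of
#' matrix cells computed divided by the total processing time, scaled to
#' giga.
#'
#' @param cell_count Number of cells computed (\eqn{M \times N}); at
#'   least 1.
#' @param elapsed_seconds Total processing time in seconds; positive.
#' @return Throughput in GCUPS.
#' @examples
#' gcups_from_time(1e9, 1)  # 1
#' @export
gcups_from_time <- function(cell_count, elapsed_seconds) {
  if (!is.numeric(cell_count) || length(cell_count) != 1L ||
      is.na(cell_count) || cell_count < 1)
    sw_value_error("cell_count must be a positive count")
  if (!is.numeric(elapsed_seconds) || length(elapsed_seconds) != 1L ||
      is.na(elapsed_seconds) || elapsed_seconds <= 0)
    sw_value_error("elapsed_seconds must be positive")
  cell_count / elapsed_seconds / 1e9
}

#' Peak GCUPS from PE count and clock frequency
#'
#' A systolic array updates one cell per processing element per clock
#' cycle, so the number of cells updated per second equals the PE count
#' times the clock frequency; this is the peak-throughput form of the
#' metric, conventionally used to compare array designs without timing a
#' full run.
#'
#' @param pe_count Number of processing elements; at least 1.
#' @param clock_hz Clock frequency in Hz; positive.
#' @return Peak throughput in GCUPS.
#' @examples
#' gcups_from_frequency(128, 100e6)  # 12.8
#' @export
gcups_from_frequency <- function(pe_count, clock_hz) {
  if (!is.numeric(pe_count) || length(pe_count) != 1L ||
      is.na(pe_count) || pe_count < 1)
    sw_value_error("pe_count must be a positive count")
  if (!is.numeric(clock_hz) || length(clock_hz) != 1L ||
      is.na(clock_hz) || clock_hz <= 0)
    sw_value_error("clock_hz must be positive")
  pe_count * clock_hz * 1e-9
}

#' Performance report
#'
#' Bundles a cell count with either an elapsed time (achieved GCUPS, via
#' [gcups_from_time()]) or a nominal clock frequency (peak GCUPS for
#' `pe_count` elements, via [gcups_from_frequency()]).  Exactly one of the
#' two drivers must be supplied.
#'
#' @param cell_count Cells computed (\eqn{M \times N}).
#' @param elapsed_seconds Optional elapsed time in seconds.
#' @param clock_hz Optional clock frequency in Hz.
#' @param pe_count PE count, required with `clock_hz`.
#' @return An object of class `sw_perf` with fields `cell_count`,
#'   `elapsed_seconds`, `clock_hz`, `pe_count` and `gcups`.
#' @export
perf_report <- function(cell_count, elapsed_seconds = NULL, clock_hz = NULL,
                        pe_count = NULL) {
  if (is.null(elapsed_seconds) == is.null(clock_hz))
    sw_value_error(
      "supply exactly one of elapsed_seconds (achieved) or clock_hz (peak)")
  gcups <- if (!is.null(elapsed_seconds)) {
    gcups_from_time(cell_count, elapsed_seconds)
  } else {
    if (is.null(pe_count))
      sw_value_error("pe_count is required with clock_hz")
    gcups_from_frequency(pe_count, clock_hz)
  }
  structure(list(cell_count = cell_count, elapsed_seconds = elapsed_seconds,
                 clock_hz = clock_hz, pe_count = pe_count, gcups = gcups),
            class = "sw_perf")
}

#' @export
print.sw_perf <- function(x, ...) {
  cat(sprintf("<sw_perf> %s cells, %.4f GCUPS (%s)\n",
              format(x$cell_count, big.mark = ","), x$gcups,
              if (!is.null(x$elapsed_seconds)) "achieved" else "peak"))
  invisible(x)
}
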