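BENCH_ALGORITHMS <- c("classic_full", "classic_tworow", "v1", "v2")
SEQUENTIAL_ALGORITHMS <- c("classic_full", "classic_tworow")

# timed region: alphabet construction + P-table construction + score loop;
# file I/O and sanitization are excluded. minimum resolution clamp keeps the
# "all wall times positive" invariant on sub-millisecond runs
time_one <- function(algorithm, A, B, policy) {
  t <- system.time({
    len <- switch(algorithm,
      classic_full = {
        R <- cpp_lcs_table(A, B)
        R[nrow(R), ncol(R)]
      },
      classic_tworow = cpp_lcs_length_classic(A, B),
      v1 = lcs_length_rowwise(A, B, version = "v1", policy = policy),
      v2 = lcs_length_rowwise(A, B, version = "v2", policy = policy)
    )
  })
  list(elapsed = max(unname(t["elapsed"]), 1e-9), length = as.integer(len))
}

#' Run a timing benchmark over algorithms and execution policies
#'
#' Times each `(algorithm, policy)` combination `repeats` times on one
#' sequence pair. The timed region covers alphabet construction, P-table
#' construction and the score loop (the algorithm proper); sequence I/O and
#' validation are excluded. Every record carries the LCS length it computed
#' so that cross-algorithm agreement can be re-checked under benchmark
#' conditions.
#'
#' @param pair List of two [sequence_record()]s (elements `a`-like and
#'   `b`-like, or just a length-2 list).
#' @param algorithms Character vector from `classic_full`, `classic_tworow`,
#'   `v1`, `v2`.
#' @param policies A single [execution_policy()] or a list of them.
#' @param repeats Number of timed repetitions per record (>= 1).
#' @return List of `benchmark_record` objects, one per (algorithm, policy),
#'   each with fields `algorithm`, `policy`, `length_a`, `length_b`,
#'   `repeats`, `wall_times` (seconds), `result_length`.
#' @export
run_benchmark <- function(pair, algorithms = c("classic_tworow", "v2"),
                          policies = list(execution_policy()), repeats = 3L) {
  if (!is.list(pair) || length(pair) != 2L ||
      !all(vapply(pair, inherits, logical(1), "sequence_record")))
    abort_usage("pair must be a list of two sequence_record objects")
  unknown <- setdiff(algorithms, BENCH_ALGORITHMS)
  if (length(unknown) > 0L)
    abort_usage(sprintf("unknown algorithm '%s' (choose from %s)",
                        unknown[1], paste(BENCH_ALGORITHMS, collapse = ", ")))
  if (length(algorithms) == 0L) abort_usage("no algorithms given")
  if (!is_count(repeats, min = 1L))
    abort_usage("repeats must be a positive integer")
  if (inherits(policies, "execution_policy")) policies <- list(policies)
  if (!all(vapply(policies, inherits, logical(1), "execution_policy")))
    abort_usage("policies must be execution_policy objects")
  A <- pair[[1]]$residues; B <- pair[[2]]$residues
  records <- list()
  for (algorithm in algorithms) {
    for (policy in policies) {
      runs <- lapply(seq_len(repeats), function(r) time_one(algorithm, A, B, policy))
      records[[length(records) + 1L]] <- structure(
        list(algorithm = algorithm, policy = policy,
             length_a = pair[[1]]$length, length_b = pair[[2]]$length,
             repeats = as.integer(repeats),
             wall_times = vapply(runs, `[[`, numeric(1), "elapsed"),
             result_length = runs[[1]]$length),
        class = "benchmark_record")
    }
  }
  records
}

#' @export
print.benchmark_record <- function(x, ...) {
  cat(sprintf(
    "<benchmark_record> %s workers=%d %s chunk=%s: min %.4gs over %d repeats, LCS=%d\n",
    x$algorithm, x$policy$workers, x$policy$schedule, as.character(x$policy$chunk),
    min(x$wall_times), x$repeats, x$result_length))
  invisible(x)
}

#' Derive relative and absolute speedups from benchmark records
#'
#' Relative speedup of a record is the minimum wall time of the same
#' algorithm at one worker divided by the record's minimum wall time (how
#' much the extra workers buy). Absolute speedup divides the best
#' sequential algorithm's time (`classic_full` / `classic_tworow`) by the
#' record's time (how the parallel code compares with the best serial
#' baseline). A missing baseline yields `NA` for that record, never an
#' error.
#'
#' @param records List of `benchmark_record`s from [run_benchmark()].
#' @return Data frame with one row per record: `algorithm`, `workers`,
#'   `schedule`, `chunk`, `length_a`, `length_b`, `repeats`,
#'   `result_length`, `time_min`, `time_mean`, `rel_speedup`, `abs_speedup`.
#' @export
compute_speedups <- function(records) {
  if (!all(vapply(records, inherits, logical(1), "benchmark_record")))
    abort_contract("records must be benchmark_record objects")
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(algorithm = r$algorithm, workers = r$policy$workers,
               schedule = r$policy$schedule,
               chunk = as.character(r$policy$chunk),
               length_a = r$length_a, length_b = r$length_b,
               repeats = r$repeats, result_length = r$result_length,
               time_min = min(r$wall_times), time_mean = mean(r$wall_times),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(algorithm = character(0), workers = integer(0),
                     schedule = character(0), chunk = character(0),
                     length_a = integer(0), length_b = integer(0),
                     repeats = integer(0), result_length = integer(0),
                     time_min = numeric(0), time_mean = numeric(0))
  }
  seq_times <- df$time_min[df$algorithm %in% SEQUENTIAL_ALGORITHMS]
  abs_base <- if (length(seq_times)) min(seq_times) else NA_real_
  df$rel_speedup <- vapply(seq_len(nrow(df)), function(i) {
    base <- df$time_min[df$algorithm == df$algorithm[i] & df$workers == 1L]
    if (length(base) == 0L) NA_real_ else min(base) / df$time_min[i]
  }, numeric(1))
  df$abs_speedup <- abs_base / df$time_min
  df
}

REPORT_COLUMNS <- c("algorithm", "workers", "schedule", "chunk", "length_a",
                    "length_b", "repeats", "result_length", "time_min",
                    "time_mean", "rel_speedup", "abs_speedup", "wall_times")

#' Write a benchmark report as CSV
#'
#' One data row per record, stable column order, '.' decimal separator;
#' the individual repeat timings are joined with ';' in the `wall_times`
#' column. [read_report()] parses the file back.
#'
#' @param records List of `benchmark_record`s.
#' @param speedups Data frame from [compute_speedups()] over the same
#'   records (recomputed if `NULL`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, speedups = NULL, path) {
  if (is.null(speedups)) speedups <- compute_speedups(records)
  if (!dir.exists(dirname(path)))
    abort_io(sprintf("directory does not exist: '%s'", dirname(path)))
  speedups$wall_times <- vapply(records, function(r)
    paste(formatC(r$wall_times, format = "g", digits = 17), collapse = ";"),
    character(1))
  out <- speedups[, REPORT_COLUMNS]
  tryCatch(write.csv(out, path, row.names = FALSE, quote = TRUE),
           error = function(e) abort_io(conditionMessage(e)))
  invisible(path)
}

#' Read a benchmark report written by [write_report()]
#'
#' @param path CSV path.
#' @return Data frame with the report columns; `wall_times` is a list column
#'   of numeric vectors.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("report not found: '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(chunk = "character"))
  if (nrow(df) > 0L)
    df$wall_times <- lapply(strsplit(as.character(df$wall_times), ";", fixed = TRUE),
                            as.numeric)
  df
}
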