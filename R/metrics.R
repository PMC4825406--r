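#' Parallel speedup
#'
#' \eqn{S = T_1 / T_N}: the ratio of the reference elapsed time to the
#' elapsed time measured with N times as many cores as the reference.
#'
#' @param t_ref reference elapsed time, seconds (> 0).
#' @param t_n elapsed time at the larger core count, seconds (> 0).
#' @return unitless speedup.
#' @export
speedup <- function(t_ref, t_n) {
  if (any(t_ref <= 0) || any(t_n <= 0)) {
    stop("elapsed times must be positive")
  }
  t_ref / t_n
}

#' Amdahl parallelization ratio
#'
#' \deqn{P = \frac{N}{N-1}\left(1 - \frac{T_N}{T_1}\right) \cdot 100\%}
#' The parallelizable fraction of a program inferred from two timings via
#' Amdahl's law. 0\% means no parallelism, 100\% perfect scaling; values
#' above 100\% indicate superlinear speedup (typically a cache effect).
#'
#' @param t_ref reference elapsed time, seconds.
#' @param t_n elapsed time with \code{n} times as many cores, seconds.
#' @param n core multiple relative to the reference (>= 2; the formula is
#'   singular at N = 1).
#' @return percentage.
#' @export
parallelization_ratio <- function(t_ref, t_n, n) {
  if (any(n < 2)) stop("core multiple n must be >= 2 (singular at N = 1)")
  if (any(t_ref <= 0) || any(t_n <= 0)) {
    stop("elapsed times must be positive")
  }
  100 * (n / (n - 1)) * (1 - t_n / t_ref)
}

#' Karp-Flatt experimentally determined serial fraction
#'
#' \deqn{f = \frac{1/S - 1/N}{1 - 1/N}, \qquad P = 1 - f}
#' The serial fraction inferred from an observed speedup; \eqn{P}
#' (returned as a percentage) coincides with the Amdahl parallelization
#' ratio when \eqn{S} is formed from the same pair of timings.
#'
#' @param s observed speedup (> 0).
#' @param n core multiple (>= 2).
#' @return list with \code{f} (serial fraction, unitless) and \code{p}
#'   (percentage, \eqn{100(1-f)}).
#' @export
karp_flatt <- function(s, n) {
  if (any(s <= 0)) stop("speedup must be positive")
  if (any(n < 2)) stop("core multiple n must be >= 2 (singular at N = 1)")
  f <- (1 / s - 1 / n) / (1 - 1 / n)
  list(f = f, p = 100 * (1 - f))
}

#' Timing table
#'
#' @param n_cpus,n_threads integer vectors; \code{n_cores} must equal
#'   their product.
#' @param n_cores total core counts.
#' @param elapsed_time seconds (> 0).
#' @param reference_row index of the reference measurement (default: the
#'   row with the fewest cores).
#' @return data.frame of class \code{qmmd_timing_table}.
#' @export
timing_table <- function(n_cpus, n_threads, n_cores, elapsed_time,
                         reference_row = which.min(n_cores)) {
  if (any(elapsed_time <= 0)) stop("elapsed times must be positive")
  if (any(n_cores != n_cpus * n_threads)) {
    stop("n_cores must equal n_cpus * n_threads")
  }
  tt <- data.frame(n_cpus = as.integer(n_cpus),
                   n_threads = as.integer(n_threads),
                   n_cores = as.integer(n_cores),
                   elapsed_time = elapsed_time)
  attr(tt, "reference_row") <- as.integer(reference_row)
  class(tt) <- c("qmmd_timing_table", "data.frame")
  tt
}

#' Read a timing table from TSV
#'
#' Columns: \code{n_cpus}, \code{n_threads}, \code{n_cores},
#' \code{elapsed_time}.
#'
#' @param path TSV file path.
#' @param reference_row reference row index (default: fewest cores).
#' @return a \code{\link{timing_table}}.
#' @export
read_timing_table <- function(path, reference_row = NULL) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("n_cpus", "n_threads", "n_cores", "elapsed_time")
  if (!all(need %in% names(d))) {
    stop("timing table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(reference_row)) reference_row <- which.min(d$n_cores)
  timing_table(d$n_cpus, d$n_threads, d$n_cores, d$elapsed_time,
               reference_row)
}

#' Whole-table scaling report
#'
#' Applies the speedup, Amdahl and Karp-Flatt formulas row-wise against the
#' reference row. Rows whose speedup exceeds the core multiple are flagged
#' superlinear. Duplicate core counts are kept with a warning.
#'
#' @param table a \code{\link{timing_table}}.
#' @return data.frame of class \code{qmmd_scaling_report} with columns
#'   \code{n_cores}, \code{elapsed_time}, \code{core_multiple},
#'   \code{speedup}, \code{parallelization_ratio} (\%),
#'   \code{serial_fraction}, \code{superlinear}; the reference row is
#'   excluded.
#' @export
scaling_report <- function(table) {
  ref <- attr(table, "reference_row")
  if (is.null(ref)) stop("timing table has no reference row")
  if (anyDuplicated(table$n_cores)) {
    warning("duplicate core counts in timing table; keeping all rows")
  }
  t1 <- table$elapsed_time[ref]
  c1 <- table$n_cores[ref]
  rows <- setdiff(seq_len(nrow(table)), ref)
  if (!length(rows)) {
    out <- data.frame(n_cores = integer(0), elapsed_time = numeric(0),
                      core_multiple = numeric(0), speedup = numeric(0),
                      parallelization_ratio = numeric(0),
                      serial_fraction = numeric(0),
                      superlinear = logical(0))
    class(out) <- c("qmmd_scaling_report", "data.frame")
    return(out)
  }
  N <- table$n_cores[rows] / c1
  S <- speedup(t1, table$elapsed_time[rows])
  kf <- karp_flatt(S, N)
  out <- data.frame(n_cores = table$n_cores[rows],
                    elapsed_time = table$elapsed_time[rows],
                    core_multiple = N,
                    speedup = S,
                    parallelization_ratio = kf$p,
                    serial_fraction = kf$f,
                    superlinear = S > N)
  class(out) <- c("qmmd_scaling_report", "data.frame")
  out
}
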