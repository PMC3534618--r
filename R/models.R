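# Analytic cost models: predictors of the original streaming-compression
# design, not introspection of this implementation.

#' Reference aligner/compressor speed ratios
#'
#' Benchmark-derived ratios of wrapper speed to aligner speed (s_a/s_o,
#' reads per unit time over reads per unit time) for Bowtie and BWA,
#' single-end and paired-end, shipped as documented defaults for
#' [runtime_ratio()].
#'
#' @format a data frame with columns `aligner`, `layout`, `speed_ratio`.
#' @export
aligner_speed_ratios <- data.frame(
  aligner = c("bowtie", "bowtie", "bwa", "bwa"),
  layout = c("SE", "PE", "SE", "PE"),
  speed_ratio = c(0.079, 0.023, 0.017, 0.015),
  stringsAsFactors = FALSE
)

#' Predicted wrapped/unwrapped runtime ratio
#'
#' The aligner alone costs `n_input / s_a`; the wrapped pipeline costs
#' `n_input / s_o + n_compressed / s_a` (a streaming pass over every read
#' plus alignment of the unique set). Their ratio is
#' `speed_ratio + n_compressed / n_input`, with `speed_ratio = s_a / s_o`.
#' Values below 1 predict a net benefit: with the Bowtie single-end ratio
#' 0.079, anything more than about 10% redundant reads pays off.
#'
#' @param n_input total input reads (or pairs), `N_i`.
#' @param n_compressed unique reads passed to the aligner, `N_c`.
#' @param speed_ratio `s_a / s_o`; see [aligner_speed_ratios].
#' @return the dimensionless predicted runtime ratio.
#' @examples
#' runtime_ratio(1e6, 5e5, 0.079)  # 0.579: predicted 1.7x speedup
#' @export
runtime_ratio <- function(n_input, n_compressed, speed_ratio) {
  if (any(n_input <= 0)) stop("n_input must be positive", call. = FALSE)
  if (any(n_compressed < 0) || any(n_compressed > n_input))
    stop("n_compressed must lie in [0, n_input]", call. = FALSE)
  if (any(speed_ratio < 0)) stop("speed_ratio must be >= 0", call. = FALSE)
  speed_ratio + n_compressed / n_input
}

#' Unique fraction at which wrapping breaks even
#'
#' Solves `runtime_ratio == 1` for the unique fraction: wrapping wins
#' whenever `n_compressed / n_input < 1 - speed_ratio`.
#'
#' @inheritParams runtime_ratio
#' @export
break_even_unique_fraction <- function(speed_ratio) {
  1 - speed_ratio
}

#' Predicted map memory, in bytes
#'
#' Each map entry costs the packed sequence (one byte per 4 bases) plus a
#' 20-byte overhead: two 4-byte count integers, the 4-byte hash, a pointer
#' (up to 8), a 2-byte size field and heap structure overhead. Pair entries
#' store both mates together, so the overhead is charged once per pair —
#' halved per read. Memory scales linearly with the number of unique
#' entries: redundancy translates linearly to memory saved.
#'
#' @param n_unique number of unique reads (or pairs): map entry count.
#' @param read_length bases per entry; for pairs, the summed mate length.
#' @param paired pair entries (one 20-byte overhead per pair)?
#' @return predicted bytes. Divide by `2^30` for binary gigabytes (the
#'   convention used by [memory_report()]).
#' @examples
#' predict_memory_bytes(1e8, 80) / 2^30   # ~3.7 GiB for 10^8 unique 80-mers
#' @export
predict_memory_bytes <- function(n_unique, read_length, paired = FALSE) {
  stopifnot(all(n_unique > 0), all(read_length > 0))
  per_entry <- ceiling(read_length / 4) + 20
  n_unique * per_entry
}

#' Small memory-prediction report
#'
#' @inheritParams predict_memory_bytes
#' @return a one-row data frame with the entry count, per-entry bytes,
#'   total bytes, and both binary (2^30) and decimal (10^9) gigabytes.
#' @export
memory_report <- function(n_unique, read_length, paired = FALSE) {
  bytes <- predict_memory_bytes(n_unique, read_length, paired)
  data.frame(n_unique = n_unique, read_length = read_length,
             paired = paired,
             bytes_per_entry = ceiling(read_length / 4) + 20,
             total_bytes = bytes,
             gib = bytes / 2^30, gb_decimal = bytes / 1e9)
}
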