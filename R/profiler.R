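# Redundancy profiling: unique-read fraction as a function of random
# subset size and 3' trim length.

as_profile_seqs <- function(reads, paired) {
  if (paired) {
    if (is.list(reads) && all(c("mate1", "mate2") %in% names(reads))) {
      m1 <- if (is.data.frame(reads$mate1)) reads$mate1$sequence
            else reads$mate1
      m2 <- if (is.data.frame(reads$mate2)) reads$mate2$sequence
            else reads$mate2
      stopifnot(length(m1) == length(m2))
      return(list(mate1 = m1, mate2 = m2))
    }
    stop("paired profiling needs list(mate1, mate2)", call. = FALSE)
  }
  if (is.data.frame(reads)) return(reads$sequence)
  if (is.character(reads)) return(unname(reads))
  stop("reads must be a character vector or read table", call. = FALSE)
}

trim_to <- function(seqs, trim_length) {
  if (is.null(trim_length) || is.na(trim_length)) return(seqs)
  substr(seqs, 1L, trim_length)
}

check_trim <- function(trim_length, seqs) {
  if (is.null(trim_length) || all(is.na(trim_length))) return(invisible())
  if (any(trim_length < 1L))
    stop("trim length must be at least 1 base", call. = FALSE)
  native <- min(nchar(seqs))
  if (any(trim_length > native))
    stop("trim length ", max(trim_length), " exceeds the native read ",
         "length ", native, call. = FALSE)
  invisible()
}

pct_unique_seqs <- function(seqs, rc_mode, paired) {
  if (paired) {
    percent_unique(list(mate1 = data.frame(name = "x", sequence = seqs$mate1,
                                           quality = NA, stringsAsFactors = FALSE),
                        mate2 = data.frame(name = "x", sequence = seqs$mate2,
                                           quality = NA, stringsAsFactors = FALSE)),
                   compression_options(rc_mode = rc_mode, paired = TRUE))
  } else {
    percent_unique(seqs, compression_options(rc_mode = rc_mode))
  }
}

#' Unique fraction versus sequencing depth
#'
#' For each requested size, draws a seeded uniform random subset without
#' replacement, trims every read to `trim_length` bases from the 3' end,
#' and computes the unique canonical-key fraction. On redundant libraries
#' the fraction falls (in expectation) as the subset grows: each
#' incremental read is ever more likely to duplicate an earlier one.
#'
#' @param reads sequences (character vector or read table; for pairs, a
#'   `list(mate1, mate2)`).
#' @param sizes subset sizes (reads, or pairs when `paired`), each at most
#'   the input size.
#' @param trim_length keep this many 5' bases of every read (`NA` = native
#'   length).
#' @param rc_mode,paired passed to the canonicalization.
#' @param seed RNG seed; results are reproducible and the session RNG is
#'   left untouched.
#' @return a data frame of profile points: `subset_size`, `trim_length`,
#'   `percent_unique`, `rc_mode`, `paired`, `seed`.
#' @export
profile_depth <- function(reads, sizes, trim_length = NA, rc_mode = TRUE,
                          paired = FALSE, seed = 1L) {
  seqs <- as_profile_seqs(reads, paired)
  n <- if (paired) length(seqs$mate1) else length(seqs)
  if (any(sizes > n))
    stop("subset size ", max(sizes), " exceeds the ", n, " available ",
         if (paired) "pairs" else "reads", call. = FALSE)
  if (any(sizes < 1L)) stop("subset sizes must be positive", call. = FALSE)
  check_trim(trim_length, if (paired) c(seqs$mate1, seqs$mate2) else seqs)
  pts <- lapply(sizes, function(k) {
    idx <- with_seed(seed + k, sample.int(n, k))
    sub <- if (paired)
      list(mate1 = trim_to(seqs$mate1[idx], trim_length),
           mate2 = trim_to(seqs$mate2[idx], trim_length))
    else trim_to(seqs[idx], trim_length)
    data.frame(subset_size = k, trim_length = trim_length,
               percent_unique = pct_unique_seqs(sub, rc_mode, paired),
               rc_mode = rc_mode, paired = paired, seed = seed)
  })
  do.call(rbind, pts)
}

#' Unique fraction versus read length
#'
#' Fixes one seeded subset and computes the unique fraction for a series
#' of 3'-trim lengths. Longer reads can only split equivalence classes,
#' never merge them, so the fraction is non-decreasing in trim length on
#' any fixed subset.
#'
#' @inheritParams profile_depth
#' @param trim_lengths trim lengths to evaluate, each between 1 and the
#'   native read length.
#' @param subset_size size of the fixed subset (`NA` = all reads).
#' @return a data frame of profile points (see [profile_depth()]).
#' @export
profile_length <- function(reads, trim_lengths, subset_size = NA,
                           rc_mode = TRUE, paired = FALSE, seed = 1L) {
  seqs <- as_profile_seqs(reads, paired)
  n <- if (paired) length(seqs$mate1) else length(seqs)
  k <- if (is.na(subset_size)) n else subset_size
  if (k > n) stop("subset size exceeds input", call. = FALSE)
  check_trim(trim_lengths, if (paired) c(seqs$mate1, seqs$mate2) else seqs)
  idx <- with_seed(seed, sample.int(n, k))
  sub <- if (paired) list(mate1 = seqs$mate1[idx], mate2 = seqs$mate2[idx])
         else seqs[idx]
  pts <- lapply(trim_lengths, function(tl) {
    trimmed <- if (paired)
      list(mate1 = trim_to(sub$mate1, tl), mate2 = trim_to(sub$mate2, tl))
    else trim_to(sub, tl)
    data.frame(subset_size = k, trim_length = tl,
               percent_unique = pct_unique_seqs(trimmed, rc_mode, paired),
               rc_mode = rc_mode, paired = paired, seed = seed)
  })
  do.call(rbind, pts)
}
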