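#' Options for the compression pass
#'
#' @param rc_mode collapse reverse complements (single-end) or order-swapped
#'   strand duplicates (paired-end) onto one key. Off by default: a read and
#'   its reverse complement are then distinct sequences.
#' @param force_two_bit evaluate every N as an A and always pack at 2
#'   bits/base. The substitution happens before canonicalization, so a read
#'   and its reverse complement are compared after N replacement.
#' @param paired treat input as mate pairs (deduplicated on the
#'   concatenation of the two mates).
#' @param singleton_set use the membership-set optimization in the store.
#' @param preserve_names_quals write a sidecar with every read's original
#'   name and quality so they can be restored during reconstitution.
#' @return a `compression_options` list.
#' @export
compression_options <- function(rc_mode = FALSE, force_two_bit = FALSE,
                                paired = FALSE, singleton_set = FALSE,
                                preserve_names_quals = FALSE) {
  structure(list(rc_mode = isTRUE(rc_mode),
                 force_two_bit = isTRUE(force_two_bit),
                 paired = isTRUE(paired),
                 singleton_set = isTRUE(singleton_set),
                 preserve_names_quals = isTRUE(preserve_names_quals)),
            class = "compression_options")
}

# normalize reads input to a data.frame (SE) or list(mate1, mate2) (PE)
as_read_input <- function(reads, paired) {
  if (paired) {
    if (is.list(reads) && !is.data.frame(reads) &&
        all(c("mate1", "mate2") %in% names(reads)))
      return(reads)
    stop("paired input must be a list with data frames $mate1 and $mate2",
         call. = FALSE)
  }
  if (is.data.frame(reads)) return(reads)
  if (is.character(reads)) {
    nm <- names(reads) %||%
      if (length(reads)) paste0("r", seq_along(reads)) else character()
    return(data.frame(name = nm, sequence = unname(reads),
                      quality = rep(NA_character_, length(reads)),
                      stringsAsFactors = FALSE))
  }
  stop("reads must be a data frame (name, sequence, quality) or a ",
       "character vector", call. = FALSE)
}

orientation_code <- c(forward = "F", reverse = "R",
                      original = "O", swapped = "S")

#' Streaming compression: deduplicate reads and emit unique sequences
#'
#' Canonicalizes every read (or pair), counts observations in `store`, and
#' writes one FASTA record per first occurrence, in first-occurrence order.
#' Emitted records are named by a synthetic stable key identifier
#' (`u0`, `u1`, ...) so SAM qnames stay unique even when input names
#' collide; the first-seen original name is kept in the store. For pairs,
#' two synchronized FASTA files are written (mate-1 keys and mate-2 keys)
#' while the store key is the packed concatenation of the two mates.
#'
#' @param reads a read table from [read_sequences()], a named character
#'   vector of sequences, or (with `options$paired`) a list from
#'   [read_pairs()].
#' @param store an empty [read_store()].
#' @param options a [compression_options()] object.
#' @param fasta_path output FASTA of unique sequences (mate 1 for pairs).
#' @param fasta2_path mate-2 output FASTA, required when paired.
#' @param sidecar_path tab-separated sidecar (one line per input read:
#'   key id, original name, orientation, qualities), written when
#'   `options$preserve_names_quals` is on; sorted by key id.
#' @return invisibly, a list with the output paths, `n_input` and
#'   `n_unique`.
#' @export
compress <- function(reads, store, options = compression_options(),
                     fasta_path = tempfile(fileext = ".fa"),
                     fasta2_path = NULL, sidecar_path = NULL) {
  stopifnot(inherits(store, "read_store"))
  if (store$n_obs > 0) stop("store must be empty", call. = FALSE)
  if (options$singleton_set && !store$singleton) enable_singleton_set(store)
  if (options$preserve_names_quals && is.null(sidecar_path))
    sidecar_path <- tempfile(fileext = ".sidecar.tsv")
  reads <- as_read_input(reads, options$paired)

  if (options$paired) {
    if (is.null(fasta2_path)) fasta2_path <- tempfile(fileext = ".fa")
    m1 <- reads$mate1; m2 <- reads$mate2
    stopifnot(nrow(m1) == nrow(m2))
    n <- nrow(m1)
    s1 <- m1$sequence; s2 <- m2$sequence
    if (options$force_two_bit) {
      s1 <- gsub("N", "A", s1, fixed = TRUE)
      s2 <- gsub("N", "A", s2, fixed = TRUE)
    }
    can <- canonical_pair(s1, s2, options$rc_mode)
    keys <- paste0(can$key1, can$key2)
    packed <- pack_all(keys, options$force_two_bit)
    len1 <- nchar(can$key1)
    names_in <- m1$name
    qual1 <- m1$quality; qual2 <- m2$quality
  } else {
    n <- nrow(reads)
    s <- reads$sequence
    if (options$force_two_bit) s <- gsub("N", "A", s, fixed = TRUE)
    can <- canonical_single(s, options$rc_mode)
    packed <- pack_all(can$key, options$force_two_bit)
    len1 <- rep(NA_integer_, n)
    names_in <- reads$name
    qual1 <- reads$quality
    qual2 <- rep(NA_character_, n)
  }
  if (n == 0L) stop("no input reads", call. = FALSE)

  keep_quals <- options$preserve_names_quals
  new_idx <- integer(0)
  key_ids <- character(n)
  for (i in seq_len(n)) {
    r <- observe_entry(store, packed[[i]], can$orientation[i], names_in[i],
                       quality = if (keep_quals) qual1[i],
                       quality2 = if (keep_quals) qual2[i],
                       len1 = if (options$paired) len1[i])
    key_ids[i] <- r$entry$key_id
    if (r$is_new) new_idx <- c(new_idx, i)
  }

  if (options$paired) {
    write_fasta(key_ids[new_idx], can$key1[new_idx], fasta_path)
    write_fasta(key_ids[new_idx], can$key2[new_idx], fasta2_path)
  } else {
    write_fasta(key_ids[new_idx], can$key[new_idx], fasta_path)
  }

  if (!is.null(sidecar_path)) {
    sc <- data.frame(key_id = key_ids, name = names_in,
                     orientation = unname(orientation_code[can$orientation]),
                     qual1 = ifelse(is.na(qual1), "*", qual1),
                     qual2 = ifelse(is.na(qual2), "*", qual2),
                     stringsAsFactors = FALSE)
    # external sort stand-in: group lines by key id, stable within key
    ord <- order(as.integer(sub("^u", "", sc$key_id)))
    utils::write.table(sc[ord, ], sidecar_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }

  invisible(list(fasta = fasta_path,
                 fasta2 = if (options$paired) fasta2_path,
                 sidecar = sidecar_path, n_input = n,
                 n_unique = length(new_idx)))
}

#' Unique read (or pair) fraction of a stream
#'
#' The compression currency: 100 x distinct canonical keys / total reads.
#'
#' @inheritParams compress
#' @return a percentage in (0, 100].
#' @examples
#' percent_unique(c("AAAA", "TTTT"), compression_options(rc_mode = TRUE))
#' # 50: the two reads share one canonical key
#' @export
percent_unique <- function(reads, options = compression_options()) {
  reads <- as_read_input(reads, options$paired)
  if (options$paired) {
    n <- nrow(reads$mate1)
    if (n == 0L) stop("percent_unique is undefined for empty input",
                      call. = FALSE)
    s1 <- reads$mate1$sequence; s2 <- reads$mate2$sequence
    if (options$force_two_bit) {
      s1 <- gsub("N", "A", s1, fixed = TRUE)
      s2 <- gsub("N", "A", s2, fixed = TRUE)
    }
    can <- canonical_pair(s1, s2, options$rc_mode)
    keys <- paste0(can$key1, can$key2)
  } else {
    n <- nrow(reads)
    if (n == 0L) stop("percent_unique is undefined for empty input",
                      call. = FALSE)
    s <- reads$sequence
    if (options$force_two_bit) s <- gsub("N", "A", s, fixed = TRUE)
    keys <- canonical_single(s, options$rc_mode)$key
  }
  100 * length(unique(keys)) / n
}
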