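#' Options for reconstitution
#'
#' @param restore_names_quals re-attach original read names and qualities
#'   from the compressor's sidecar.
#' @param emit_unmapped also expand unmapped records; on by default so the
#'   pipeline is lossless at the sequence level.
#' @return a `reconstitution_options` list.
#' @export
reconstitution_options <- function(restore_names_quals = FALSE,
                                   emit_unmapped = TRUE) {
  structure(list(restore_names_quals = isTRUE(restore_names_quals),
                 emit_unmapped = isTRUE(emit_unmapped)),
            class = "reconstitution_options")
}

reverse_cigar <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(cg)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (nchar(paste(ops, collapse = "")) != nchar(cg))
      stop("malformed CIGAR: ", cg, call. = FALSE)
    paste(rev(ops), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Flip the strand of SAM records
#'
#' Represents the reverse complement of the stored read at the same locus:
#' the strand bit (0x10) is toggled, the sequence is reverse complemented,
#' the quality string is reversed, and the CIGAR is reversed element-wise
#' (positions are left unchanged; for ungapped equal-length alignments the
#' locus is identical, and gapped flips reverse the CIGAR only — an
#' approximation, documented). Unmapped records (0x4) only have their
#' sequence and quality transformed. Vectorized over rows; an involution.
#'
#' @param records a SAM record data frame (see [read_sam()]).
#' @return the flipped records.
#' @examples
#' r <- data.frame(qname = "u0", flag = 0L, rname = "chr-001", pos = 10L,
#'                 mapq = 255L, cigar = "4M", rnext = "*", pnext = 0L,
#'                 tlen = 0L, seq = "AAAA", qual = "*", tags = "")
#' flip_orientation(r)$seq   # "TTTT"
#' flip_orientation(r)$flag  # 16
#' @export
flip_orientation <- function(records) {
  if (nrow(records) == 0L) return(records)
  unmapped <- bitwAnd(records$flag, 4L) != 0L
  has_seq <- records$seq != "*"
  records$seq[has_seq] <- .revcomp_cpp(records$seq[has_seq])
  has_qual <- records$qual != "*"
  records$qual[has_qual] <- str_reverse(records$qual[has_qual])
  records$flag[!unmapped] <- bitwXor(records$flag[!unmapped], 16L)
  records$cigar[!unmapped] <- reverse_cigar(records$cigar[!unmapped])
  records
}

swap_mate_flags <- function(flag) {
  m1 <- bitwAnd(flag, 64L) != 0L
  m2 <- bitwAnd(flag, 128L) != 0L
  flag <- bitwAnd(flag, bitwNot(192L))
  flag + ifelse(m1, 128L, 0L) + ifelse(m2, 64L, 0L)
}

#' Expand deduplicated SAM back to the full read multiset
#'
#' Every alignment line the aligner reported for key `K` with counts
#' `(f, r)` is emitted `f` times as-is and `r` times orientation-flipped;
#' multi-line (multi-mapping) reports are expanded per line. For pair keys
#' observed in swapped order, flipped copies additionally exchange the mate
#' flags 0x40/0x80 so the record that carried mate 1's canonical sequence
#' is reported as mate 2 of the original pair. Output is grouped by key in
#' aligner-output order (the original input order is sacrificed); copies of
#' a key are contiguous, forward copies first. Without restoration every
#' copy carries the key's first-seen original name.
#'
#' @param sam a list with `header` and `records` (from [read_sam()] or an
#'   aligner call), or just the record data frame.
#' @param store the [read_store()] populated by [compress()].
#' @param options a [reconstitution_options()] object.
#' @param sidecar path to (or data frame of) the compressor sidecar,
#'   required when `options$restore_names_quals` is on.
#' @return a SAM record data frame of the expanded alignment.
#' @export
reconstitute <- function(sam, store, options = reconstitution_options(),
                         sidecar = NULL) {
  records <- if (is.data.frame(sam)) sam else sam$records
  if (options$restore_names_quals && is.null(sidecar))
    stop("name/quality restoration requires the compressor sidecar",
         call. = FALSE)
  if (nrow(records) == 0L) {
    out <- records
    out$.flipped <- logical(0)
    return(strip_internal(out, options, sidecar, store))
  }
  groups <- split(seq_len(nrow(records)),
                  factor(records$qname, levels = unique(records$qname)))
  pieces <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    key_id <- names(groups)[g]
    e <- get_entry_by_id(store, key_id)
    if (is.null(e))
      stop("consistency error: SAM qname '", key_id,
           "' is not a key emitted by the compressor", call. = FALSE)
    block <- records[groups[[g]], , drop = FALSE]
    paired <- !is.null(e$len1) && !is.na(e$len1 %||% NA)
    fwd <- block
    fwd$.flipped <- FALSE
    rev <- flip_orientation(block)
    if (paired) rev$flag <- swap_mate_flags(rev$flag)
    rev$.flipped <- TRUE
    copies <- c(rep(list(fwd), e$fwd), rep(list(rev), e$rev))
    expanded <- do.call(rbind, copies)
    expanded$.copy <- rep(seq_len(e$fwd + e$rev), each = nrow(block))
    expanded$qname <- e$first_name
    expanded$.key_id <- key_id
    pieces[[g]] <- expanded
  }
  out <- do.call(rbind, pieces)
  if (!options$emit_unmapped)
    out <- out[bitwAnd(out$flag, 4L) == 0L, , drop = FALSE]
  strip_internal(out, options, sidecar, store)
}

strip_internal <- function(out, options, sidecar, store) {
  if (options$restore_names_quals && nrow(out) > 0L)
    out <- restore_names_quals(out, sidecar)
  out$.flipped <- NULL
  out$.copy <- NULL
  out$.key_id <- NULL
  rownames(out) <- NULL
  out
}

read_sidecar <- function(sidecar) {
  if (is.data.frame(sidecar)) return(sidecar)
  utils::read.table(sidecar, sep = "\t", header = FALSE,
                    col.names = c("key_id", "name", "orientation",
                                  "qual1", "qual2"),
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
}

#' Restore original read names and qualities
#'
#' Consumes the sorted sidecar written by [compress()]: within each key,
#' forward copies take the forward sidecar lines in input order, then
#' reverse copies take the reverse lines. Restored qualities are reversed
#' for orientation-flipped copies; for swapped pair copies each record
#' takes the quality of the mate it now represents. Normally called through
#' [reconstitute()] with `restore_names_quals = TRUE`.
#'
#' @param expanded an expanded record data frame still carrying the
#'   internal `.key_id`/`.copy`/`.flipped` columns.
#' @param sidecar sidecar path or data frame.
#' @return the records with `qname` and `qual` restored.
#' @export
restore_names_quals <- function(expanded, sidecar) {
  sc <- read_sidecar(sidecar)
  for (key in unique(expanded$.key_id)) {
    rows <- which(expanded$.key_id == key)
    sub <- sc[sc$key_id == key, , drop = FALSE]
    # forward lines first, then reverse/swapped, stable in input order
    sub <- sub[order(sub$orientation %in% c("R", "S")), , drop = FALSE]
    copies <- unique(expanded$.copy[rows])
    if (length(copies) != nrow(sub))
      stop("consistency error: key '", key, "' has ", length(copies),
           " copies but ", nrow(sub), " sidecar lines", call. = FALSE)
    for (j in seq_along(copies)) {
      crow <- rows[expanded$.copy[rows] == copies[j]]
      expanded$qname[crow] <- sub$name[j]
      flipped <- expanded$.flipped[crow]
      paired_rec <- bitwAnd(expanded$flag[crow], 1L) != 0L
      mate2 <- bitwAnd(expanded$flag[crow], 128L) != 0L
      qual <- ifelse(paired_rec & mate2, sub$qual2[j], sub$qual1[j])
      qual[flipped & qual != "*"] <- str_reverse(qual[flipped & qual != "*"])
      expanded$qual[crow] <- qual
    }
  }
  expanded
}
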