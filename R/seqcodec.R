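#' Pack a DNA sequence into 2 or 3 bits per base
#'
#' Sequences over A, C, G, T pack at 2 bits per base (A=00, C=01, G=10,
#' T=11); the presence of an N switches the whole sequence to a 3-bit code
#' (A=000 ... N=100). Bases fill each byte left to right, first base in the
#' most significant bits, and the final byte is zero-padded on the right.
#' The packed object keeps the encoding bit, the payload byte count and the
#' base count; the explicit base count is what keeps packing injective when
#' trailing A bases would otherwise be indistinguishable from padding.
#'
#' @param sequence a single DNA string over A, C, G, T, N (upper case).
#' @param force_two_bit if `TRUE`, every N is evaluated as an A and the
#'   2-bit code is used regardless of N content.
#' @return an object of class `packed_seq` with fields `encoding` (0 = 2
#'   bits/base, 1 = 3 bits/base), `byte_size`, `base_length` and `payload`
#'   (a raw vector of `byte_size` bytes).
#' @examples
#' p <- pack("ACGTAA")
#' p$byte_size        # 2
#' unpack(p)          # "ACGTAA"
#' @export
pack <- function(sequence, force_two_bit = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  structure(.pack_cpp(sequence, force_two_bit), class = "packed_seq")
}

# vectorized internal: list of packed_seq
pack_all <- function(sequences, force_two_bit = FALSE) {
  lapply(.pack_many_cpp(sequences, force_two_bit),
         structure, class = "packed_seq")
}

#' Unpack a packed sequence back to text
#'
#' Inverse of [pack()]. Pad bits beyond the encoded bases must be zero;
#' anything else is reported as corruption.
#'
#' @param p a `packed_seq` object.
#' @return the DNA string (with N replaced by A if the object was packed in
#'   forced 2-bit mode).
#' @export
unpack <- function(p) {
  stopifnot(inherits(p, "packed_seq"))
  .unpack_cpp(p$encoding, p$payload, p$base_length)
}

#' @export
print.packed_seq <- function(x, ...) {
  cat(sprintf("<packed_seq: %d bases, %d bits/base, %d payload byte%s>\n",
              x$base_length, if (x$encoding == 0) 2L else 3L, x$byte_size,
              if (x$byte_size == 1) "" else "s"))
  invisible(x)
}

#' Compare two packed sequences for equality
#'
#' Short-circuits on the header fields (encoding, then base count) before
#' touching payload bytes, so differently sized or differently encoded
#' sequences are told apart in constant time; payloads are then compared
#' blockwise as raw bytes.
#'
#' @param a,b `packed_seq` objects.
#' @return `TRUE` iff encoding, base length and payload all match.
#' @export
packed_equal <- function(a, b) {
  if (a$encoding != b$encoding) return(FALSE)
  if (a$base_length != b$base_length) return(FALSE)
  identical(a$payload, b$payload)
}

#' Reverse complement
#'
#' Vectorized A<->T, C<->G complement with N fixed, order reversed. An
#' involution: applying it twice returns the input.
#'
#' @param sequence character vector of DNA strings over A, C, G, T, N.
#' @return character vector of the same length.
#' @examples
#' reverse_complement(c("AAAA", "CAGT"))  # "TTTT" "ACTG"
#' @export
reverse_complement <- function(sequence) {
  .revcomp_cpp(sequence)
}

#' Canonicalize single-end reads for strand-insensitive deduplication
#'
#' With `rc_mode` off each sequence is its own key. With `rc_mode` on, a
#' sequence and its reverse complement share one key: the bytewise
#' lexicographically smaller of the two. The returned orientation records
#' which form the input was; palindromes count as forward.
#'
#' @param sequence character vector of reads.
#' @param rc_mode collapse reverse complements?
#' @return a list with `key` (character) and `orientation` ("forward" or
#'   "reverse"), both parallel to the input.
#' @examples
#' canonical_single("TTTT", rc_mode = TRUE)   # key "AAAA", reverse
#' canonical_single("TTTT", rc_mode = FALSE)  # key "TTTT", forward
#' @export
canonical_single <- function(sequence, rc_mode = FALSE) {
  if (!rc_mode) {
    return(list(key = sequence,
                orientation = rep("forward", length(sequence))))
  }
  rc <- .revcomp_cpp(sequence)
  fwd <- .bytewise_leq_cpp(sequence, rc)   # ties (palindromes) -> forward
  list(key = ifelse(fwd, sequence, rc),
       orientation = ifelse(fwd, "forward", "reverse"))
}

#' Canonicalize mate pairs for order-insensitive deduplication
#'
#' A forward-reverse oriented pair sequenced from the opposite strand of
#' the same fragment shows up with mates swapped and reverse complemented:
#' pair (s1, s2) duplicates pair (rc(s2), rc(s1)). With `rc_mode` on, the
#' candidate whose concatenation is bytewise smaller becomes the key; the
#' orientation records whether the input had to be swapped to reach it.
#'
#' @param seq1,seq2 character vectors of mate-1 and mate-2 sequences.
#' @param rc_mode collapse order-swapped strand duplicates?
#' @return a list with `key1`, `key2` and `orientation` ("original" or
#'   "swapped").
#' @export
canonical_pair <- function(seq1, seq2, rc_mode = FALSE) {
  stopifnot(length(seq1) == length(seq2))
  if (!rc_mode) {
    return(list(key1 = seq1, key2 = seq2,
                orientation = rep("original", length(seq1))))
  }
  alt1 <- .revcomp_cpp(seq2)
  alt2 <- .revcomp_cpp(seq1)
  orig <- .bytewise_leq_cpp(paste0(seq1, seq2), paste0(alt1, alt2))
  list(key1 = ifelse(orig, seq1, alt1),
       key2 = ifelse(orig, seq2, alt2),
       orientation = ifelse(orig, "original", "swapped"))
}
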