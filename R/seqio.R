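# FASTA/FASTQ/SAM text I/O.
#
# These are deliberately small line-based parsers: the contracts here (fail
# fast with a record index, strict ACGTN alphabet with an opt-in IUPAC->N
# mapping, byte-faithful SAM pass-through) drive the error handling, and the
# scale is whole-file at once. Gzip input is detected by magic bytes, never
# by file extension.

is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

read_text_lines <- function(path) {
  if (is_gzip(path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  } else {
    readLines(path, warn = FALSE)
  }
}

first_token <- function(x) sub("[ \t].*$", "", x)

#' Read a FASTA or FASTQ file into a read table
#'
#' @param path path to a FASTA or FASTQ file, plain or gzip-compressed
#'   (compression is detected from the leading magic bytes).
#' @param format `"auto"` detects from the first character (`>` FASTA,
#'   `@` FASTQ); or force `"fasta"` / `"fastq"`.
#' @param permissive map non-ACGTN IUPAC ambiguity codes to N instead of
#'   failing.
#' @return a data frame with columns `name` (first whitespace token of the
#'   header), `sequence` (upper-cased) and `quality` (`NA` for FASTA).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           permissive = FALSE) {
  format <- match.arg(format)
  lines <- read_text_lines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) {
    return(data.frame(name = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (format == "auto") {
    format <- if (startsWith(lines[1], ">")) "fasta"
              else if (startsWith(lines[1], "@")) "fastq"
              else stop("cannot auto-detect format: first character is ",
                        "neither '>' nor '@'", call. = FALSE)
  }
  if (format == "fasta") parse_fasta(lines, permissive)
  else parse_fastq(lines, permissive)
}

parse_fasta <- function(lines, permissive) {
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("malformed FASTA: record 1 does not start with '>'",
                    call. = FALSE)
  rec <- cumsum(hdr)
  name <- first_token(sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 paste, character(1), collapse = "")
  # headers with no sequence lines
  full <- as.character(seq_len(sum(hdr)))
  seq_out <- stats::setNames(rep("", length(full)), full)
  seq_out[names(seqs)] <- seqs
  if (any(seq_out == ""))
    stop(sprintf("malformed FASTA: record %d has an empty sequence",
                 which(seq_out == "")[1]), call. = FALSE)
  data.frame(name = name,
             sequence = normalize_sequence(unname(seq_out), permissive,
                                           "FASTA record"),
             quality = NA_character_, stringsAsFactors = FALSE)
}

parse_fastq <- function(lines, permissive) {
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf(paste0("truncated FASTQ: %d lines is not a multiple of 4 ",
                        "(record %d is incomplete)"), n, n %/% 4L + 1L),
         call. = FALSE)
  idx <- seq(1L, n, by = 4L)
  head_ok <- startsWith(lines[idx], "@")
  if (!all(head_ok))
    stop(sprintf("malformed FASTQ: record %d header does not start with '@'",
                 which(!head_ok)[1]), call. = FALSE)
  plus_ok <- startsWith(lines[idx + 2L], "+")
  if (!all(plus_ok))
    stop(sprintf("malformed FASTQ: record %d is missing its '+' line",
                 which(!plus_ok)[1]), call. = FALSE)
  seqs <- normalize_sequence(lines[idx + 1L], permissive, "FASTQ record")
  quals <- lines[idx + 3L]
  len_ok <- nchar(quals) == nchar(seqs)
  if (!all(len_ok))
    stop(sprintf("malformed FASTQ: record %d quality length differs from %s",
                 which(!len_ok)[1], "sequence length"), call. = FALSE)
  data.frame(name = first_token(sub("^@", "", lines[idx])),
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

#' Read two mate files as a pair table
#'
#' Mate suffixes `/1` and `/2` are stripped from the names so the pair
#' shares one name, following the SAM qname convention.
#'
#' @param path1,path2 mate-1 and mate-2 FASTA/FASTQ files.
#' @inheritParams read_sequences
#' @return a list with data frames `mate1` and `mate2` of equal row count.
#' @export
read_pairs <- function(path1, path2, format = c("auto", "fasta", "fastq"),
                       permissive = FALSE) {
  format <- match.arg(format)
  m1 <- read_sequences(path1, format, permissive)
  m2 <- read_sequences(path2, format, permissive)
  if (nrow(m1) != nrow(m2))
    stop(sprintf("pairing error: mate files have %d and %d records",
                 nrow(m1), nrow(m2)), call. = FALSE)
  m1$name <- sub("/1$", "", m1$name)
  m2$name <- sub("/2$", "", m2$name)
  list(mate1 = m1, mate2 = m2)
}

#' Write sequences as FASTA
#'
#' @param names,sequences parallel character vectors.
#' @param path output file.
#' @param line_width wrap sequences at this many columns; 0 (the default)
#'   writes each sequence on a single line.
#' @export
write_fasta <- function(names, sequences, path, line_width = 0L) {
  stopifnot(length(names) == length(sequences))
  if (length(names) == 0L) {  # paste0 would recycle zero-length to ""
    writeLines(character(), path)
    return(invisible(path))
  }
  if (line_width > 0L) {
    sequences <- vapply(sequences, function(s) {
      starts <- seq(1L, max(nchar(s), 1L), by = line_width)
      paste(substring(s, starts, starts + line_width - 1L), collapse = "\n")
    }, character(1), USE.NAMES = FALSE)
  }
  writeLines(paste0(">", names, "\n", sequences), path, sep = "\n")
  invisible(path)
}

sam_columns <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "rnext", "pnext", "tlen", "seq", "qual")

empty_sam_records <- function() {
  df <- data.frame(qname = character(), flag = integer(),
                   rname = character(), pos = integer(), mapq = integer(),
                   cigar = character(), rnext = character(),
                   pnext = integer(), tlen = integer(), seq = character(),
                   qual = character(), tags = character(),
                   stringsAsFactors = FALSE)
  df
}

parse_sam_lines <- function(lines) {
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  body_no <- which(!is_hdr)
  if (length(body) == 0L)
    return(list(header = header, records = empty_sam_records()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("malformed SAM: line %d has %d fields (11 required)",
                 body_no[which(nf < 11L)[1]], nf[nf < 11L][1]), call. = FALSE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  tags <- vapply(fields, function(f)
    if (length(f) > 11L) paste(f[12:length(f)], collapse = "\t") else "",
    character(1))
  data.frame(qname = get(1), flag = as.integer(get(2)), rname = get(3),
             pos = as.integer(get(4)), mapq = as.integer(get(5)),
             cigar = get(6), rnext = get(7), pnext = as.integer(get(8)),
             tlen = as.integer(get(9)), seq = get(10), qual = get(11),
             tags = tags, stringsAsFactors = FALSE) -> records
  list(header = header, records = records)
}

#' Read / write SAM text
#'
#' `read_sam()` splits a SAM file into header lines and a record table of
#' the 11 mandatory fields plus a `tags` column holding any optional fields
#' verbatim (tab-joined). `write_sam()` is the byte-faithful inverse for
#' unmodified records.
#'
#' @param path SAM file (read) or output path (write).
#' @return for `read_sam()`: a list with `header` (character vector) and
#'   `records` (data frame).
#' @export
read_sam <- function(path) {
  parse_sam_lines(read_text_lines(path))
}

format_sam_records <- function(records) {
  if (nrow(records) == 0L) return(character())
  base <- do.call(paste, c(unname(records[sam_columns]), sep = "\t"))
  ifelse(records$tags == "", base, paste(base, records$tags, sep = "\t"))
}

#' @param header character vector of `@`-prefixed header lines.
#' @param records a record data frame as produced by `read_sam()`.
#' @rdname read_sam
#' @export
write_sam <- function(header, records, path) {
  writeLines(c(header, format_sam_records(records)), path, sep = "\n")
  invisible(path)
}
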