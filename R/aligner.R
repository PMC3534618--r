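# Aligner bridge: a shell-template contract for wrapping any external
# SAM-producing aligner, plus a deterministic built-in toy aligner so the
# whole pipeline is testable without Bowtie or BWA.

#' Describe an external aligner invocation
#'
#' @param template shell command with placeholders `{reads}` (input FASTA),
#'   optionally `{reads2}` (mate-2 FASTA) and `{out}` (output SAM path).
#'   Without `{out}`, the aligner's standard output is taken as SAM.
#' @param workdir working directory for the subprocess.
#' @param expects_paired whether the template consumes mate pairs; paired
#'   templates must contain `{reads2}`.
#' @return an `aligner_command` object.
#' @export
aligner_command <- function(template, workdir = tempdir(),
                            expects_paired = FALSE) {
  if (!grepl("{reads}", template, fixed = TRUE))
    stop("aligner template must contain the {reads} placeholder",
         call. = FALSE)
  if (expects_paired && !grepl("{reads2}", template, fixed = TRUE))
    stop("paired aligner template must contain the {reads2} placeholder",
         call. = FALSE)
  structure(list(template = template, workdir = workdir,
                 expects_paired = isTRUE(expects_paired)),
            class = "aligner_command")
}

#' Run an external aligner on unique-sequence FASTA
#'
#' Substitutes the placeholders, runs the command through `/bin/sh`, and
#' parses the resulting SAM. A nonzero exit raises an error carrying the
#' aligner's diagnostic output.
#'
#' @param cmd an [aligner_command()].
#' @param fasta input FASTA path (mate 1 for pairs).
#' @param fasta2 mate-2 FASTA path for paired templates.
#' @return a list with `header` and `records` (see [read_sam()]).
#' @export
run_external <- function(cmd, fasta, fasta2 = NULL) {
  stopifnot(inherits(cmd, "aligner_command"))
  if (!is.null(fasta2) && !grepl("{reads2}", cmd$template, fixed = TRUE))
    stop("configuration error: mate-2 input given but the template has ",
         "no {reads2} placeholder", call. = FALSE)
  if (cmd$expects_paired && is.null(fasta2))
    stop("configuration error: paired template needs a mate-2 FASTA",
         call. = FALSE)
  if (!file.exists(fasta)) stop("input FASTA not found: ", fasta,
                                call. = FALSE)
  use_out <- grepl("{out}", cmd$template, fixed = TRUE)
  out_path <- tempfile(fileext = ".sam")
  line <- gsub("{reads}", shQuote(fasta), cmd$template, fixed = TRUE)
  if (!is.null(fasta2))
    line <- gsub("{reads2}", shQuote(fasta2), line, fixed = TRUE)
  if (use_out) line <- gsub("{out}", shQuote(out_path), line, fixed = TRUE)
  err_file <- tempfile(fileext = ".err")
  old_wd <- setwd(cmd$workdir)
  on.exit(setwd(old_wd))
  stdout <- tryCatch(
    suppressWarnings(
      system2("/bin/sh", c("-c", shQuote(line)),
              stdout = if (use_out) FALSE else TRUE, stderr = err_file)),
    error = function(e) structure(character(), status = 127L))
  status <- if (use_out) stdout else attr(stdout, "status") %||% 0L
  if (!identical(as.integer(status), 0L)) {
    diag <- tryCatch(readLines(err_file, warn = FALSE),
                     error = function(e) character())
    stop("aligner exited with status ", status, ":\n",
         paste(diag, collapse = "\n"), call. = FALSE)
  }
  sam <- if (use_out) read_sam(out_path)
         else parse_sam_lines(as.character(stdout))
  n_in <- sum(startsWith(readLines(fasta, warn = FALSE), ">"))
  if (n_in > 0L && nrow(sam$records) == 0L)
    stop("aligner produced no SAM records for ", n_in, " input sequences",
         call. = FALSE)
  sam
}

toy_header <- function(ref_name, ref_len) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
}

toy_records <- function(qname, seqs, scan, ref_name, flag_extra = 0L) {
  L <- nchar(seqs)
  mapped <- !is.na(scan$pos)
  flag <- ifelse(mapped, ifelse(scan$strand == 1L, 16L, 0L), 4L) +
    flag_extra
  data.frame(qname = qname, flag = as.integer(flag),
             rname = ifelse(mapped, ref_name, "*"),
             pos = ifelse(mapped, scan$pos + 1L, 0L),
             mapq = ifelse(mapped, 255L, 0L),
             cigar = ifelse(mapped, paste0(L, "M"), "*"),
             rnext = "*", pnext = 0L, tlen = 0L,
             seq = seqs, qual = "*", tags = "", stringsAsFactors = FALSE)
}

as_toy_reference <- function(reference) {
  if (is.list(reference))
    return(list(name = reference$name, sequence = reference$sequence))
  if (is.character(reference) && length(reference) == 1L)
    return(list(name = names(reference) %||% "ref", sequence = unname(reference)))
  stop("reference must be a single named DNA string or a list with ",
       "$name and $sequence", call. = FALSE)
}

#' Deterministic built-in toy aligner
#'
#' Ungapped exhaustive scan of every reference offset on both strands,
#' scored by mismatch count. Two modes:
#'
#' * `symmetric`: score is the plain Hamming distance; a read and its
#'   reverse complement always receive mirror-image hits, so wrapping the
#'   pipeline around this mode is exactly lossless.
#' * `left_seed`: the first `seed_len` bases *of the read* must match
#'   exactly, and mismatches are counted only outside the seed. Because the
#'   read's left end sits at opposite ends of the forward projection on the
#'   two strands, a read and its reverse complement can legitimately win
#'   different loci — the seed-handedness effect real left-seeded aligners
#'   (Bowtie, BWA) exhibit.
#'
#' Ties are broken by fewest mismatches, then leftmost position, then
#' forward strand; identical inputs give byte-identical SAM. Emitted
#' records are minimal valid SAM: the sequence field carries the read
#' verbatim, mapq 255, qual `*`; unaligned reads get flag 0x4.
#'
#' @param reads named character vector of read sequences (names become
#'   qnames) or a data frame with `name` and `sequence`.
#' @param reference a single named DNA string (or `list(name=, sequence=)`).
#' @param mode `"symmetric"` or `"left_seed"`.
#' @param seed_len exact-match prefix length for `left_seed` mode; must be
#'   shorter than every read.
#' @param max_mismatch maximum mismatches for a reportable hit.
#' @return a list with `header` and `records`.
#' @export
toy_align <- function(reads, reference, mode = c("symmetric", "left_seed"),
                      seed_len = 2L, max_mismatch = 2L) {
  mode <- match.arg(mode)
  ref <- as_toy_reference(reference)
  if (nchar(ref$sequence) == 0L) stop("empty reference", call. = FALSE)
  if (is.data.frame(reads)) {
    qname <- reads$name
    seqs <- reads$sequence
  } else {
    qname <- names(reads) %||% paste0("r", seq_along(reads))
    seqs <- unname(reads)
  }
  scan <- .toy_scan_cpp(seqs, ref$sequence,
                        if (mode == "symmetric") 0L else 1L,
                        as.integer(seed_len), as.integer(max_mismatch))
  list(header = toy_header(ref$name, nchar(ref$sequence)),
       records = toy_records(qname, seqs, scan, ref$name))
}

#' @param reads1,reads2 mate sequence vectors or data frames, parallel.
#' @rdname toy_align
#' @export
toy_align_pairs <- function(reads1, reads2, reference,
                            mode = c("symmetric", "left_seed"),
                            seed_len = 2L, max_mismatch = 2L) {
  mode <- match.arg(mode)
  ref <- as_toy_reference(reference)
  get <- function(r) {
    if (is.data.frame(r)) list(name = r$name, seq = r$sequence)
    else list(name = names(r) %||% paste0("r", seq_along(r)),
              seq = unname(r))
  }
  r1 <- get(reads1); r2 <- get(reads2)
  stopifnot(length(r1$seq) == length(r2$seq))
  m <- if (mode == "symmetric") 0L else 1L
  s1 <- .toy_scan_cpp(r1$seq, ref$sequence, m, as.integer(seed_len),
                      as.integer(max_mismatch))
  s2 <- .toy_scan_cpp(r2$seq, ref$sequence, m, as.integer(seed_len),
                      as.integer(max_mismatch))
  rec1 <- toy_records(r1$name, r1$seq, s1, ref$name, flag_extra = 1L + 64L)
  rec2 <- toy_records(r2$name, r2$seq, s2, ref$name, flag_extra = 1L + 128L)
  # interleave mate lines per pair
  ord <- as.vector(rbind(seq_len(nrow(rec1)),
                         nrow(rec1) + seq_len(nrow(rec2))))
  list(header = toy_header(ref$name, nchar(ref$sequence)),
       records = rbind(rec1, rec2)[ord, , drop = FALSE])
}

#' Package the toy aligner as a pipeline-ready function
#'
#' Returns a function with the calling convention [wrap_align()] expects of
#' an aligner backend: it takes FASTA path(s), reads them, and returns SAM.
#'
#' @inheritParams toy_align
#' @return a function `(fasta, fasta2 = NULL) -> list(header, records)`.
#' @export
toy_aligner <- function(reference, mode = c("symmetric", "left_seed"),
                        seed_len = 2L, max_mismatch = 2L) {
  mode <- match.arg(mode)
  force(reference); force(seed_len); force(max_mismatch)
  function(fasta, fasta2 = NULL) {
    f1 <- read_sequences(fasta, "fasta")
    if (is.null(fasta2)) {
      toy_align(f1, reference, mode, seed_len, max_mismatch)
    } else {
      f2 <- read_sequences(fasta2, "fasta")
      toy_align_pairs(f1, f2, reference, mode, seed_len, max_mismatch)
    }
  }
}
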