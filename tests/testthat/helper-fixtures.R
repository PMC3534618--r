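# shared fixture builders and independent oracles

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

write_fastq_tmp <- function(names, seqs, quals = NULL) {
  quals <- quals %||% vapply(seqs, function(s) strrep("I", nchar(s)),
                             character(1))
  write_tmp(as.vector(rbind(paste0("@", names), seqs, "+", quals)), ".fq")
}

write_fasta_tmp <- function(names, seqs) {
  write_tmp(as.vector(rbind(paste0(">", names), seqs)), ".fa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent reverse complement: complement via lookup then reverse
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(s, NULL), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
}

# independent bit-level packer: build the bit string then chop into bytes
oracle_pack_bytes <- function(seq, bits) {
  code2 <- c(A = "00", C = "01", G = "10", T = "11")
  code3 <- c(A = "000", C = "001", G = "010", T = "011", N = "100")
  code <- if (bits == 2) code2 else code3
  bitstr <- paste(code[strsplit(seq, NULL)[[1]]], collapse = "")
  pad <- (8 - nchar(bitstr) %% 8) %% 8
  bitstr <- paste0(bitstr, strrep("0", pad))
  starts <- seq(1, nchar(bitstr), by = 8)
  vapply(starts, function(i)
    strtoi(substr(bitstr, i, i + 7), base = 2L), numeric(1))
}

# brute-force strand/offset scan: all hits with <= max_mm mismatches
oracle_scan <- function(read, ref, max_mm) {
  L <- nchar(read)
  n <- nchar(ref)
  hits <- list()
  for (strand in 0:1) {
    p <- if (strand == 0) read else oracle_revcomp(read)
    pc <- strsplit(p, NULL)[[1]]
    if (L > n) next
    for (o in 0:(n - L)) {
      rc <- strsplit(substr(ref, o + 1, o + L), NULL)[[1]]
      mm <- sum(pc != rc)
      if (mm <= max_mm)
        hits[[length(hits) + 1]] <- c(pos = o, strand = strand, score = mm)
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

oracle_best_hit <- function(read, ref, max_mm) {
  h <- oracle_scan(read, ref, max_mm)
  if (is.null(h)) return(NULL)
  h <- h[order(h[, "score"], h[, "pos"], h[, "strand"]), , drop = FALSE]
  h[1, ]
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# alignment identity used for pipeline concordance: location, sequence and
# mapped-status (plus mate index), strand bit deliberately excluded -- see
# the methods vignette on same-position cross-strand ties
concordance_keys <- function(records) {
  mate <- ifelse(bitwAnd(records$flag, 128L) != 0L, 2L,
                 ifelse(bitwAnd(records$flag, 64L) != 0L, 1L, 0L))
  unmapped <- bitwAnd(records$flag, 4L) != 0L
  sort(paste(records$rname, records$pos, records$cigar, records$seq,
             mate, unmapped, sep = "|"))
}

# direct (unwrapped) alignment of every raw read, the pipeline's oracle
direct_align <- function(reads, ref, paired) {
  if (paired)
    toy_align_pairs(reads$mate1, reads$mate2, ref)
  else
    toy_align(reads, ref)
}
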