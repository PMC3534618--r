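`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse each string in a character vector
str_reverse <- function(x) {
  vapply(strsplit(x, NULL, fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Run code with a temporary RNG state; the caller's .Random.seed is restored
# on exit so profiling/simulation never perturbs the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# uppercase + alphabet check shared by the parsers and the codec front door.
# Non-ACGTN IUPAC ambiguity codes are rejected unless permissive, in which
# case they collapse to N (the packed alphabet has no wider codes).
normalize_sequence <- function(seq, permissive = FALSE, context = "sequence") {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    if (permissive) {
      iupac_ok <- !grepl("[^ACGTNRYSWKMBDHVU]", seq)
      if (!all(iupac_ok))
        stop(sprintf("%s %s contains characters outside the IUPAC alphabet",
                     context, which(!iupac_ok)[1]), call. = FALSE)
      seq[bad] <- gsub("[RYSWKMBDHVU]", "N", seq[bad])
    } else {
      stop(sprintf(paste0("%s %d contains non-ACGTN characters; ",
                          "use permissive = TRUE to map IUPAC codes to N"),
                   context, which(bad)[1]), call. = FALSE)
    }
  }
  seq
}
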