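#' Compress, align, reconstitute: the full wrap pipeline
#'
#' Runs the whole loop in one call: deduplicate the input through a fresh
#' [read_store()], hand the unique-sequence FASTA to the aligner backend,
#' and expand the resulting SAM back to one record per input read (or pair)
#' with strand/mate-order correction. One `@PG` line recording the wrapper
#' is appended to the aligner's header.
#'
#' @param reads input reads, as accepted by [compress()].
#' @param aligner either an [aligner_command()] for an external aligner or
#'   a function `(fasta, fasta2 = NULL) -> list(header, records)` such as
#'   [toy_aligner()] returns.
#' @param options a [compression_options()].
#' @param recon_options a [reconstitution_options()].
#' @return a list with `header`, `records` (the expanded SAM), `store`,
#'   `n_input` and `n_unique`.
#' @examples
#' lib <- generate_library(library_spec(5, 20, 30, rc_fraction = 0.5,
#'                                      seed = 7))
#' ref <- generate_reference(lib$templates, 400, seed = 8)
#' res <- wrap_align(lib$reads, toy_aligner(ref),
#'                   compression_options(rc_mode = TRUE))
#' nrow(res$records)  # 30: one record per input read
#' @export
wrap_align <- function(reads, aligner,
                       options = compression_options(),
                       recon_options = reconstitution_options()) {
  store <- read_store(options$singleton_set)
  fasta <- tempfile(fileext = ".fa")
  fasta2 <- if (options$paired) tempfile(fileext = ".fa")
  sidecar <- if (options$preserve_names_quals ||
                 recon_options$restore_names_quals)
    tempfile(fileext = ".sidecar.tsv")
  if (!is.null(sidecar)) options$preserve_names_quals <- TRUE
  comp <- compress(reads, store, options, fasta, fasta2, sidecar)
  sam <- if (inherits(aligner, "aligner_command"))
    run_external(aligner, comp$fasta, comp$fasta2)
  else if (is.function(aligner))
    aligner(comp$fasta, comp$fasta2)
  else stop("aligner must be an aligner_command or a function",
            call. = FALSE)
  header <- c(sam$header,
              paste0("@PG\tID:readsqueeze\tPN:readsqueeze\tVN:",
                     as.character(utils::packageVersion("readsqueeze")),
                     "\tCL:wrap_align"))
  records <- reconstitute(sam, store, recon_options, sidecar = comp$sidecar)
  list(header = header, records = records, store = store,
       n_input = comp$n_input, n_unique = comp$n_unique)
}
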