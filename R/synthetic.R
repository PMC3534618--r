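# Synthetic library generator: controlled redundancy, orientation mixture
# and pairing, plus toy references, so every pipeline stage is testable
# with no external dataset.

random_dna <- function(n, len, n_rate = 0) {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  if (n_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      hit <- stats::runif(nchar(s)) < n_rate
      if (any(hit)) {
        ch <- strsplit(s, NULL)[[1]]
        ch[hit] <- "N"
        s <- paste(ch, collapse = "")
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  seqs
}

#' Specify a synthetic read library
#'
#' Emulates expression-driven redundancy: a fixed set of template
#' sequences, power-law (Zipf-like) copy numbers so a few templates
#' dominate (as highly expressed genes do in RNA-Seq), a strand mixture,
#' and optional N noise and pairing.
#'
#' @param n_templates distinct source sequences.
#' @param read_length bases per read (per mate when paired).
#' @param total_reads total reads (or pairs) emitted; at least
#'   `n_templates` so every template appears.
#' @param abundance_skew exponent of the power-law copy-number
#'   distribution; 0 gives uniform copies (genome/exome-like low
#'   redundancy), 1 a typical expression-like skew.
#' @param rc_fraction probability that a copy is emitted reverse
#'   complemented (for pairs: order-swapped from the opposite strand).
#' @param n_rate per-base probability of an N in a template.
#' @param paired emit forward-reverse mate pairs.
#' @param inner_distance unsequenced bases between the mates of a fragment.
#' @param seed RNG seed; generation is fully reproducible.
#' @return a `library_spec` list.
#' @export
library_spec <- function(n_templates, read_length, total_reads,
                         abundance_skew = 1, rc_fraction = 0, n_rate = 0,
                         paired = FALSE, inner_distance = 0L, seed = 1L) {
  if (total_reads < n_templates)
    stop("infeasible spec: total_reads must be >= n_templates",
         call. = FALSE)
  stopifnot(rc_fraction >= 0, rc_fraction <= 1, n_rate >= 0, n_rate <= 1)
  structure(list(n_templates = n_templates, read_length = read_length,
                 total_reads = total_reads, abundance_skew = abundance_skew,
                 rc_fraction = rc_fraction, n_rate = n_rate,
                 paired = isTRUE(paired),
                 inner_distance = as.integer(inner_distance),
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Generate a synthetic library from a spec
#'
#' Templates are uniform random DNA; copy numbers give every template one
#' copy and distribute the remainder with probability proportional to
#' `rank^-abundance_skew`. Each copy is reverse complemented (or, for
#' pairs, emitted order-swapped from the opposite strand) with probability
#' `rc_fraction`. Qualities are a fixed high-quality band: quality realism
#' is irrelevant to the dedup/align/expand mechanism under test.
#'
#' @param spec a [library_spec()].
#' @return a list with `reads` (a read table, or `list(mate1, mate2)` when
#'   paired), `truth` (per-read template id and orientation), `templates`
#'   (the template sequences; for pairs these are full fragments of length
#'   `2 * read_length + inner_distance`).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  with_seed(spec$seed, {
    tlen <- if (spec$paired)
      2L * spec$read_length + spec$inner_distance else spec$read_length
    templates <- random_dna(spec$n_templates, tlen, spec$n_rate)
    extra <- spec$total_reads - spec$n_templates
    copies <- rep(1L, spec$n_templates)
    if (extra > 0) {
      w <- seq_len(spec$n_templates)^(-spec$abundance_skew)
      more <- sample.int(spec$n_templates, extra, replace = TRUE,
                         prob = w / sum(w))
      tab <- tabulate(more, nbins = spec$n_templates)
      copies <- copies + tab
    }
    template_id <- rep(seq_len(spec$n_templates), copies)
    rc <- stats::runif(spec$total_reads) < spec$rc_fraction
    name <- paste0("r", seq_len(spec$total_reads))
    qual <- strrep("I", spec$read_length)
    truth <- data.frame(name = name, template = template_id,
                        orientation = ifelse(rc, "R", "F"),
                        stringsAsFactors = FALSE)
    if (spec$paired) {
      frag <- templates[template_id]
      m1 <- substr(frag, 1L, spec$read_length)
      m2 <- .revcomp_cpp(substr(frag, tlen - spec$read_length + 1L, tlen))
      # opposite-strand copies: mates swap and complement
      swapped1 <- .revcomp_cpp(m2)
      swapped2 <- .revcomp_cpp(m1)
      reads <- list(
        mate1 = data.frame(name = name,
                           sequence = ifelse(rc, swapped1, m1),
                           quality = qual, stringsAsFactors = FALSE),
        mate2 = data.frame(name = name,
                           sequence = ifelse(rc, swapped2, m2),
                           quality = qual, stringsAsFactors = FALSE))
    } else {
      seqs <- templates[template_id]
      seqs[rc] <- .revcomp_cpp(seqs[rc])
      reads <- data.frame(name = name, sequence = seqs, quality = qual,
                          stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = truth, templates = templates)
  })
}

#' Embed templates in a random decoy reference
#'
#' Places the templates non-overlapping, in order, separated by random
#' decoy gaps, inside a decoy background of total length `decoy_length`.
#'
#' @param templates template sequences to embed (may be empty).
#' @param decoy_length total reference length; must fit all templates.
#' @param seed RNG seed.
#' @param name reference sequence name.
#' @return a list with `name`, `sequence`, and `placements` (a data frame
#'   with 1-based `start`/`end` per template).
#' @export
generate_reference <- function(templates, decoy_length, seed = 1L,
                               name = "chr-001") {
  tlen <- sum(nchar(templates))
  if (tlen > decoy_length)
    stop("insufficient decoy length: templates need ", tlen, " bases but ",
         decoy_length, " were given", call. = FALSE)
  with_seed(seed, {
    k <- length(templates)
    slack <- decoy_length - tlen
    gaps <- if (k == 0L) slack else
      as.vector(stats::rmultinom(1, slack, rep(1, k + 1L)))
    pieces <- character(0)
    starts <- integer(k)
    at <- 1L
    for (i in seq_len(k)) {
      g <- gaps[i]
      if (g > 0) pieces <- c(pieces, random_dna(1L, g))
      at <- at + g
      starts[i] <- at
      pieces <- c(pieces, templates[i])
      at <- at + nchar(templates[i])
    }
    if (k == 0L) pieces <- random_dna(1L, decoy_length)
    else if (gaps[k + 1L] > 0) pieces <- c(pieces, random_dna(1L, gaps[k + 1L]))
    list(name = name, sequence = paste(pieces, collapse = ""),
         placements = data.frame(template = seq_len(k), start = starts,
                                 end = starts + nchar(templates) - 1L))
  })
}
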