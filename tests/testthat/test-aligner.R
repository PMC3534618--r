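test_that("run_external passes a SAM fixture through cat", {
  fixture <- write_tmp(c("@HD\tVN:1.6",
                         "u0\t0\tchr-001\t10\t40\t4M\t*\t0\t0\tAAAA\t*"),
                       ".sam")
  # the 'aligner' copies its input verbatim: harness self-test
  cmd <- aligner_command("cat {reads}")
  # {reads} here is the SAM fixture itself, standing in for FASTA
  sam <- run_external(cmd, fixture)
  expect_equal(length(sam$header), 1)
  expect_equal(sam$records$qname, "u0")
  expect_equal(sam$records$pos, 10L)
})

test_that("run_external honors the {out} placeholder", {
  fixture <- write_tmp(c("@HD\tVN:1.6",
                         "u0\t0\tchr-001\t10\t40\t4M\t*\t0\t0\tAAAA\t*"),
                       ".sam")
  sam <- run_external(aligner_command("cp {reads} {out}"), fixture)
  expect_equal(sam$records$seq, "AAAA")
})

test_that("nonzero exits surface the aligner's diagnostics", {
  fixture <- write_tmp(">u0\nACGT", ".fa")
  cmd <- aligner_command("sh -c 'echo boom-diagnostic >&2; exit 3' x {reads}")
  expect_error(run_external(cmd, fixture), "boom-diagnostic")
  missing_exe <- aligner_command("definitely-not-a-real-binary {reads}")
  expect_error(run_external(missing_exe, fixture), "status")
})

test_that("template validation happens before execution", {
  expect_error(aligner_command("tool"), "\\{reads\\}")
  expect_error(aligner_command("tool {reads}", expects_paired = TRUE),
               "\\{reads2\\}")
  fixture <- write_tmp(">u0\nACGT", ".fa")
  expect_error(run_external(aligner_command("cat {reads}"), fixture,
                            fasta2 = fixture),
               "configuration error")
})

test_that("symmetric mode matches the brute-force Hamming-scan oracle", {
  set.seed(41)
  for (rep in 1:6) {
    ref <- random_seq(sample(100:400, 1))
    reads <- vapply(1:15, function(i) random_seq(sample(8:30, 1)),
                    character(1))
    mm <- sample(0:3, 1)
    sam <- toy_align(setNames(reads, paste0("r", 1:15)), c(ref = ref),
                     mode = "symmetric", max_mismatch = mm)
    for (i in seq_along(reads)) {
      best <- oracle_best_hit(reads[i], ref, mm)
      rec <- sam$records[i, ]
      if (is.null(best)) {
        expect_equal(bitwAnd(rec$flag, 4L), 4L)
      } else {
        expect_equal(rec$pos, unname(best["pos"]) + 1L)
        expect_equal(bitwAnd(rec$flag, 16L) != 0L,
                     unname(best["strand"]) == 1)
      }
    }
  }
})

test_that("symmetric hits strand-mirror under reverse complementation", {
  set.seed(43)
  ref <- random_seq(500)
  reads <- vapply(1:25, function(i) random_seq(15), character(1))
  fwd <- toy_align(reads, c(ref = ref), max_mismatch = 3)$records
  rev <- toy_align(reverse_complement(reads), c(ref = ref),
                   max_mismatch = 3)$records
  expect_equal(fwd$pos, rev$pos)
  expect_equal(fwd$rname, rev$rname)
  mapped <- bitwAnd(fwd$flag, 4L) == 0L
  same_pos_tie <- mapped &
    vapply(seq_along(reads), function(i) {
      h <- oracle_scan(reads[i], ref, 3)
      if (is.null(h)) return(FALSE)
      best <- min(h[, "score"])
      b <- h[h[, "score"] == best, , drop = FALSE]
      any(duplicated(b[, "pos"]))
    }, logical(1))
  # outside same-position cross-strand ties, strands mirror exactly
  idx <- mapped & !same_pos_tie
  expect_equal(bitwAnd(fwd$flag[idx], 16L), 16L - bitwAnd(rev$flag[idx], 16L))
})

test_that("toy output is deterministic", {
  set.seed(47)
  ref <- c(ref = random_seq(300))
  reads <- setNames(vapply(1:10, function(i) random_seq(12), character(1)),
                    paste0("r", 1:10))
  a <- toy_align(reads, ref)
  b <- toy_align(reads, ref)
  expect_identical(a, b)
})

test_that("left_seed mode reproduces seed-handedness asymmetry", {
  # two candidate loci one mismatch from the read: CATT and CCGT
  ref <- c(genome = "CATTCCGT")
  fwd <- toy_align(c(q = "CAGT"), ref, mode = "left_seed",
                   seed_len = 2, max_mismatch = 1)$records
  expect_equal(fwd$pos, 1L)   # seed CA matches only the CATT locus
  rev <- toy_align(c(q = reverse_complement("CAGT")), ref,
                   mode = "left_seed", seed_len = 2,
                   max_mismatch = 1)$records
  expect_equal(rev$pos, 5L)   # opposite-direction seed picks the CCGT locus
  expect_false(fwd$pos == rev$pos)
  expect_error(toy_align(c(q = "CAGT"), ref, mode = "left_seed",
                         seed_len = 4), "seed_len")
})

test_that("paired toy alignment emits mate-flagged interleaved records", {
  lib <- generate_library(library_spec(4, 15, 8, paired = TRUE,
                                       inner_distance = 5, seed = 3))
  ref <- generate_reference(lib$templates, 400, seed = 4)
  sam <- toy_align_pairs(lib$reads$mate1, lib$reads$mate2, ref)
  expect_equal(nrow(sam$records), 16)
  expect_equal(bitwAnd(sam$records$flag, 1L), rep(1L, 16))
  expect_equal(bitwAnd(sam$records$flag, 64L) != 0L,
               rep(c(TRUE, FALSE), 8))
})
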