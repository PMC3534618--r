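test_that("N-free sequences pack at 2 bits/base with MSB-first bytes", {
  p <- pack("ACGTAA")
  expect_s3_class(p, "packed_seq")
  expect_equal(p$encoding, 0)
  expect_equal(p$byte_size, 2)
  expect_equal(p$base_length, 6)
  expect_equal(as.integer(p$payload), c(0x1B, 0x00))
})

test_that("an N switches the whole sequence to the 3-bit code", {
  p <- pack("ACGTNA")
  expect_equal(p$encoding, 1)
  expect_equal(p$byte_size, 3)
  # frozen from the independent bit-concatenation oracle
  expect_equal(as.integer(p$payload), c(0x05, 0x38, 0x00))
  expect_equal(as.integer(p$payload), oracle_pack_bytes("ACGTNA", 3))
})

test_that("forced 2-bit mode evaluates N as A", {
  expect_identical(pack("ACGTNA", force_two_bit = TRUE)$payload,
                   pack("ACGTAA")$payload)
  expect_equal(pack("ACGTNA", force_two_bit = TRUE)$encoding, 0)
  expect_equal(unpack(pack("ACGTNA", force_two_bit = TRUE)), "ACGTAA")
})

test_that("pack rejects empty and non-ACGTN input", {
  expect_error(pack(""), "empty")
  expect_error(pack("ACGR"), "invalid base")
})

test_that("unpack is the exact inverse of pack (random ACGTN strings)", {
  set.seed(42)
  for (i in 1:60) {
    len <- sample(1:300, 1)
    s <- random_seq(len, c("A", "C", "G", "T", if (i %% 2) "N"))
    p <- pack(s)
    expect_identical(unpack(p), s)
    expect_equal(p$byte_size,
                 ceiling(len * (if (grepl("N", s)) 3 else 2) / 8))
    # payload agrees with the independent bit-string oracle
    expect_equal(as.integer(p$payload),
                 oracle_pack_bytes(s, if (grepl("N", s)) 3 else 2))
  }
})

test_that("nonzero pad bits are reported as corruption", {
  p <- pack("ACGTAA")
  p$payload[2] <- as.raw(0x01)  # pad bit set
  expect_error(unpack(p), "pad bits")
  expect_identical(unpack(pack("A")), "A")
})

test_that("packing density is 2 bits/base: quarter the ASCII bytes", {
  set.seed(7)
  for (len in c(4, 8, 36, 100)) {
    s <- random_seq(len)
    p <- pack(s)
    expect_identical(p$byte_size, as.integer(len / 4))
  }
  # 3-bit worst case stays under ceil(3L/8)
  s <- random_seq(200, c("A", "C", "G", "T", "N"))
  expect_lte(pack(paste0(s, "N"))$byte_size, ceiling(3 * 201 / 8))
})

test_that("pack distinguishes lengths that share payload bytes", {
  a <- pack("AAAA")
  b <- pack("AAAAA")
  expect_identical(as.integer(a$payload), 0L)
  expect_identical(as.integer(b$payload), c(0L, 0L))
  expect_false(packed_equal(a, b))
})

test_that("packed_equal compares header fields before payload", {
  expect_true(packed_equal(pack("ACGTAA"), pack("ACGTAA")))
  # different encodings: unequal without looking at payload
  expect_false(packed_equal(pack("ACGTAA"), pack("ACGTNA")))
  expect_false(packed_equal(pack("ACGT"), pack("ACGA")))
})

test_that("pack is injective over random sequence pairs", {
  set.seed(11)
  for (i in 1:40) {
    s <- random_seq(sample(1:50, 1), c("A", "C", "G", "T", "N"))
    t <- random_seq(sample(1:50, 1), c("A", "C", "G", "T", "N"))
    if (s == t) next
    expect_false(packed_equal(pack(s), pack(t)))
  }
})

test_that("reverse_complement matches the by-hand oracle and involutes", {
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_identical(reverse_complement("CAGT"), "ACTG")
  set.seed(3)
  s <- vapply(1:30, function(i)
    random_seq(sample(1:80, 1), c("A", "C", "G", "T", "N")), character(1))
  expect_identical(reverse_complement(s), oracle_revcomp(s))
  expect_identical(reverse_complement(reverse_complement(s)), s)
})

test_that("canonical_single collapses strands only in rc mode", {
  on_ <- canonical_single("TTTT", rc_mode = TRUE)
  expect_identical(on_$key, "AAAA")
  expect_identical(on_$orientation, "reverse")
  off <- canonical_single("TTTT", rc_mode = FALSE)
  expect_identical(off$key, "TTTT")
  expect_identical(off$orientation, "forward")
  pal <- canonical_single("ACGT", rc_mode = TRUE)
  expect_identical(pal$orientation, "forward")
})

test_that("a read and its reverse complement share one canonical key", {
  set.seed(5)
  s <- vapply(1:25, function(i) random_seq(sample(4:60, 1)), character(1))
  k1 <- canonical_single(s, rc_mode = TRUE)$key
  k2 <- canonical_single(reverse_complement(s), rc_mode = TRUE)$key
  expect_identical(k1, k2)
})

test_that("canonical_pair collapses order-swapped strand duplicates", {
  sw <- canonical_pair("GGGG", "TTTT", rc_mode = TRUE)
  expect_identical(sw$key1, "AAAA")
  expect_identical(sw$key2, "CCCC")
  expect_identical(sw$orientation, "swapped")
  keep <- canonical_pair("AAAA", "CCCC", rc_mode = TRUE)
  expect_identical(keep$orientation, "original")
  off <- canonical_pair("AAAA", "CCCC", rc_mode = FALSE)
  expect_identical(c(off$key1, off$key2, off$orientation),
                   c("AAAA", "CCCC", "original"))
  # the swapped form of a pair always reaches the same key
  set.seed(9)
  for (i in 1:20) {
    a <- random_seq(12); b <- random_seq(12)
    k <- canonical_pair(a, b, TRUE)
    ks <- canonical_pair(oracle_revcomp(b), oracle_revcomp(a), TRUE)
    expect_identical(c(k$key1, k$key2), c(ks$key1, ks$key2))
  }
})
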