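# The RNF data model: segment/tuple encoding, decoding, sorting,
# naming policy and validation.

test_that("encode_segment renders the parenthesized template and rejects invalid intervals", {
  expect_equal(encode_segment(rnf_segment(1, 2, "F", 100, 199)), "(1,2,F,100,199)")
  expect_equal(encode_segment(rnf_segment(1, 0, "N", 0, 0)), "(1,0,N,0,0)")
  expect_error(rnf_segment(1, 2, "F", 200, 100), "left > right")
  expect_error(rnf_segment(1, 2, "X", 100, 199), "invalid direction")
  expect_error(rnf_segment(-1, 2, "F", 100, 199), "genome_id")
})

test_that("decode_segment inverts encode_segment", {
  set.seed(11)
  for (i in 1:50) {
    s <- random_segment()
    expect_true(seg_text_eq <- identical(encode_segment(decode_segment(encode_segment(s))),
                                         encode_segment(s)))
  }
  expect_error(decode_segment("(1,2,F,100)"), "malformed segment")
})

test_that("sort_segments orders by genome, chromosome, left, right, direction", {
  a <- rnf_segment(1, 2, "F", 300, 349)
  b <- rnf_segment(1, 1, "F", 100, 149)
  expect_true(segs_identical(sort_segments(list(a, b)), list(b, a)))
  expect_identical(sort_segments(list()), list())
  # direction order F < N < R by character code
  d1 <- rnf_segment(1, 1, "R", 0, 0)
  d2 <- rnf_segment(1, 1, "N", 0, 0)
  d3 <- rnf_segment(1, 1, "F", 0, 0)
  expect_equal(vapply(sort_segments(list(d1, d2, d3)), `[[`, character(1),
                      "direction"), c("F", "N", "R"))
})

test_that("sort_segments is permutation-invariant and idempotent (exhaustive, n = 5)", {
  set.seed(7)
  segs <- replicate(5, random_segment(unknown_prob = 0), simplify = FALSE)
  ref <- sort_segments(segs)
  expect_true(segs_identical(ref, oracle_sort_segments(segs)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(1:5))
    expect_true(segs_identical(sort_segments(segs[p]), ref))
  expect_true(segs_identical(sort_segments(ref), ref))
})

test_that("encode_lrn builds the four-part name", {
  t1 <- rnf_tuple(0x00A, "sim", list(list(rnf_segment(1, 2, "F", 100, 199))))
  expect_equal(encode_lrn(t1, rnf_policy(3)), "sim__00a__(1,2,F,100,199)__")
  t2 <- rnf_tuple(1, "sim", list(list(rnf_segment(1, 1, "F", 100, 149)),
                                 list(rnf_segment(1, 1, "R", 300, 349))))
  expect_equal(encode_lrn(t2, rnf_policy(1)),
               "sim__1__(1,1,F,100,149),(1,1,R,300,349)__")
  # segments of all reads are sorted jointly, regardless of read order
  t3 <- rnf_tuple(1, "sim", list(list(rnf_segment(1, 1, "R", 300, 349)),
                                 list(rnf_segment(1, 1, "F", 100, 149))))
  expect_equal(encode_lrn(t3, rnf_policy(1)), encode_lrn(t2, rnf_policy(1)))
  expect_error(rnf_tuple(1, "a__b", list(list(rnf_segment()))), "__")
})

test_that("decode_lrn inverts encode_lrn and reports malformed names", {
  d <- decode_lrn("sim__00a__(1,2,F,100,199)__")
  expect_equal(d$tuple_id, 10L)
  expect_equal(d$prefix, "sim")
  expect_true(segs_identical(tuple_segments(d), list(rnf_segment(1, 2, "F", 100, 199))))
  # contaminant tuple with all-unknown placement
  d2 <- decode_lrn("sim__1__(1,0,N,0,0)__")
  expect_true(segs_identical(tuple_segments(d2), list(rnf_segment(1, 0, "N", 0, 0))))
  expect_error(decode_lrn("sim__1__(1,2,F,100,199)"), "expected 4 parts, found 3")
  expect_error(decode_lrn("sim__zz__(1,2,F,100,199)__"), "non-hexadecimal")
  expect_error(decode_lrn("sim__1__(1,2,F,100,199),(1,2)__"), "segment 2")
})

test_that("encode_srn matches an independent base-16 conversion", {
  t255 <- rnf_tuple(255, "x", list(list(rnf_segment())))
  expect_equal(encode_srn(t255, rnf_policy(4)), "#00ff")
  expect_equal(encode_srn(rnf_tuple(1, "x", list(list(rnf_segment()))),
                          rnf_policy(1)), "#1")
  expect_error(rnf_tuple(0, "x", list(list(rnf_segment()))), "tuple_id must be >= 1")
  set.seed(3)
  for (id in sample.int(10^6, 25L)) {
    tt <- rnf_tuple(id, "x", list(list(rnf_segment())))
    expect_equal(encode_srn(tt, rnf_policy(8)),
                 paste0("#", format(as.hexmode(id), width = 8)))
    expect_equal(decode_srn(encode_srn(tt, rnf_policy(8))), id)
  }
})

test_that("choose_name switches from LRN to SRN exactly between 255 and 256", {
  seg <- rnf_segment(1, 2, "F", 100, 199)
  base_len <- nchar(encode_lrn(rnf_tuple(1, "", list(list(seg))), rnf_policy(1)))
  k255 <- 255L - base_len
  t255 <- rnf_tuple(1, strrep("a", k255), list(list(seg)))
  t256 <- rnf_tuple(1, strrep("a", k255 + 1L), list(list(seg)))
  c255 <- choose_name(t255)
  c256 <- choose_name(t256)
  expect_equal(nchar(c255$name), 255L)
  expect_false(c255$used_srn)
  expect_true(c256$used_srn)
  expect_equal(c256$name, "#1")
  expect_equal(nchar(c256$lrn), 256L)
  # short tuples always keep the LRN
  expect_false(choose_name(rnf_tuple(1, "a", list(list(seg))))$used_srn)
  # fallback can be disabled
  expect_error(choose_name(t256, rnf_policy(srn_fallback = FALSE)), "disabled")
})

test_that("validate_name lints LRNs and SRNs", {
  expect_identical(validate_name("sim__1__(1,2,F,100,199)__"), character(0))
  expect_identical(validate_name("#00ff"), character(0))
  expect_equal(validate_name("sim__1__(1,2,X,100,199)__"), "invalid direction 'X'")
  expect_match(validate_name("sim__1__(1,2,F,100,199)"), "found 3")
  expect_match(validate_name("#xyz"), "malformed SRN")
  expect_match(validate_name("sim__1__(1,2,F,300,100)__"), "left > right")
  expect_match(validate_name("sim__zz__(1,2,F,100,199)__"), "not hexadecimal")
})

test_that("round-trip preserves id, prefix, extensions and sorted segments", {
  set.seed(101)
  for (i in 1:500) {
    t <- random_tuple(sample.int(100000L, 1L))
    d <- decode_lrn(encode_lrn(t, rnf_policy(sample.int(6L, 1L))))
    expect_true(tuples_equivalent(t, d))
  }
})

test_that("extensions encode as [tag:value] units in the suffix", {
  t <- rnf_tuple(1, "p", list(list(rnf_segment(1, 1, "F", 1, 50))),
                 list(c("pair", "1"), c("cg", "50M")))
  nm <- encode_lrn(t)
  expect_equal(nm, "p__1__(1,1,F,1,50)__[pair:1][cg:50M]")
  expect_identical(decode_lrn(nm)$extensions, list(c("pair", "1"), c("cg", "50M")))
  expect_error(rnf_tuple(1, "p", list(list(rnf_segment())),
                         list(c("bad tag", "v"))), "tag")
  expect_error(rnf_tuple(1, "p", list(list(rnf_segment())),
                         list(c("t", "a_b"))), "forbidden")
})

test_that("chimeric reads require at least two segments", {
  s <- rnf_segment(1, 1, "F", 1, 50)
  expect_error(rnf_read(list(s), chimeric = TRUE), "at least two segments")
  r <- rnf_read(list(s, rnf_segment(1, 2, "F", 900, 949)))
  expect_true(attr(r, "chimeric"))
  expect_false(attr(rnf_read(list(s)), "chimeric"))
})

test_that("name_batch enforces ID uniqueness and batch-level hex width", {
  seg <- list(list(rnf_segment(1, 1, "F", 1, 50)))
  tuples <- lapply(c(1L, 10L, 255L), rnf_tuple, prefix = "b", reads = seg)
  nb <- name_batch(tuples)
  expect_equal(nb$names, c("b__01__(1,1,F,1,50)__", "b__0a__(1,1,F,1,50)__",
                           "b__ff__(1,1,F,1,50)__"))
  expect_error(name_batch(list(rnf_tuple(1, "b", seg), rnf_tuple(1, "b", seg))),
               "duplicate tuple IDs")
})

test_that("write_rnf_fastq writes decodable names and the correspondence file", {
  tmp <- withr::local_tempdir()
  fq <- file.path(tmp, "x.fq")
  seg_many <- lapply(1:40, function(i)
    list(rnf_segment(1, 1, "F", i * 10L, i * 10L + 49L)))
  tuples <- list(
    rnf_tuple(1, "ok", list(list(rnf_segment(1, 1, "F", 1, 50)))),
    rnf_tuple(2, "long", seg_many))   # LRN far beyond 255 -> SRN fallback
  res <- write_rnf_fastq(fq, tuples, c("ACGT", "GGCC"), c("IIII", "IIII"))
  expect_true(res$used_srn[2] && !res$used_srn[1])
  corr <- read_correspondence_file(correspondence_path(fq))
  expect_equal(names(corr), "#2")
  back <- read_rnf_fastq(fq)
  expect_equal(back$tuples[[2]]$tuple_id, 2L)
  expect_equal(length(tuple_segments(back$tuples[[2]])), 40L)
  # all emitted names valid, all SRNs distinct
  expect_true(all(vapply(res$names, function(n) length(validate_name(n)) == 0L,
                         logical(1))))
  expect_false(anyDuplicated(res$names) > 0L)
})
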