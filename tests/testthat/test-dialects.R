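# Dialect converters: name grammars, coordinate semantics, FASTQ and
# SAM-truth conversion.

dwgsim_name <- function(chrom, pos1, pos2, s1, s2, counter, end = NULL) {
  nm <- sprintf("%s_%d_%d_%d_%d_0_0_0:0:0_0:0:0_%x", chrom, pos1, pos2, s1, s2,
                counter)
  if (!is.null(end)) nm <- paste0(nm, "/", end)
  nm
}
wgsim_name <- function(chrom, pos1, pos2, counter, end = NULL) {
  nm <- sprintf("%s_%d_%d_0:0:0_0:0:0_%x", chrom, pos1, pos2, counter)
  if (!is.null(end)) nm <- paste0(nm, "/", end)
  nm
}

test_that("dialect grammars load from the shipped pattern files", {
  for (d in c("wgsim", "dwgsim", "curesim")) {
    g <- builtin_dialect(d)
    expect_s3_class(g, "rnf_dialect")
    expect_equal(g$dialect_name, d)
  }
  expect_equal(builtin_dialect("wgsim")$semantics, "FIRST_NUCLEOTIDE_EACH_END")
  expect_equal(builtin_dialect("dwgsim")$semantics, "LEFTMOST_EACH_END")
})

test_that("leftmost semantics: dwgsim position is the left coordinate on both strands", {
  g <- builtin_dialect("dwgsim")
  ends <- parse_dialect_name(dwgsim_name("chr1", 1001L, 1501L, 0L, 1L, 1L), g, 100L)
  expect_equal(ends[[1]][c("chrom", "direction", "left", "right")],
               list(chrom = "chr1", direction = "F", left = 1001L, right = 1100L))
  expect_equal(ends[[2]][c("direction", "left", "right")],
               list(direction = "R", left = 1501L, right = 1600L))
})

test_that("first-nucleotide semantics: a reverse end's position is its rightmost base", {
  g <- builtin_dialect("wgsim")
  ends <- parse_dialect_name(wgsim_name("chr2", 1001L, 2100L, 7L), g, 100L)
  expect_equal(ends[[1]][c("direction", "left", "right")],
               list(direction = "F", left = 1001L, right = 1100L))
  expect_equal(ends[[2]][c("direction", "left", "right")],
               list(direction = "R", left = 2001L, right = 2100L))
})

test_that("unknown strand yields direction N and right 0; mismatches are errors", {
  g <- builtin_dialect("curesim")
  ends <- parse_dialect_name("chrZ_500_3", g, 100L)
  expect_equal(ends[[1]][c("direction", "left", "right")],
               list(direction = "N", left = 500L, right = 0L))
  expect_error(parse_dialect_name("not_a_simulated_read", builtin_dialect("dwgsim"),
                                  100L), "does not match")
})

test_that("scripted-simulator oracle: converted segments equal explicit truth under both semantics", {
  # A toy 'simulator' plants reads at known intervals and emits both the
  # dialect name and the explicit truth; conversion must recover the truth.
  set.seed(21)
  tmp <- withr::local_tempdir()
  rl <- 60L
  n <- 30L
  truth <- data.frame(left = sample.int(5000L, n), dir = sample(c("F", "R"), n,
                                                                replace = TRUE))
  truth$right <- truth$left + rl - 1L
  seqs <- strrep("A", rl)
  for (dialect in c("dwgsim", "wgsim")) {
    names <- vapply(seq_len(n), function(i) {
      if (dialect == "dwgsim")
        # leftmost of each end; strand bit 1 = reverse
        dwgsim_name("chr1", truth$left[i], truth$left[i],
                    as.integer(truth$dir[i] == "R"),
                    as.integer(truth$dir[i] == "R"), i)
      else
        # first nucleotide of each end (use the read as end 1 or end 2
        # according to its strand, matching the FR pair convention)
        wgsim_name("chr1", truth$left[i], truth$right[i], i,
                   end = if (truth$dir[i] == "R") 2L else 1L)
    }, character(1))
    fq <- file.path(tmp, paste0(dialect, ".fq"))
    write_fastq(fq, names, rep(seqs, n), rep(strrep("I", rl), n))
    out <- file.path(tmp, paste0(dialect, ".rnf.fq"))
    convert_fastq(fq, builtin_dialect(dialect), 1L, c(chr1 = 1L), out)
    dec <- read_rnf_fastq(out)
    for (i in seq_len(n)) {
      seg <- tuple_segments(dec$tuples[[i]])[[1]]
      expect_equal(seg$left, truth$left[i])
      expect_equal(seg$right, truth$right[i])
      expect_equal(seg$direction, truth$dir[i])
    }
  }
})

test_that("convert_fastq conserves record counts, assigns sequential IDs, preserves pairing", {
  tmp <- withr::local_tempdir()
  g <- builtin_dialect("dwgsim")
  # 10-record single-end file
  nms <- vapply(1:10, function(i) dwgsim_name("chr1", 100L * i, 100L * i, 0L, 1L, i),
                character(1))
  fq <- file.path(tmp, "se.fq")
  write_fastq(fq, nms, rep(strrep("C", 50L), 10), rep(strrep("I", 50L), 10))
  out <- file.path(tmp, "se.rnf.fq")
  res <- convert_fastq(fq, g, 1L, c(chr1 = 1L), out)
  dec <- read_rnf_fastq(out)
  expect_equal(length(dec$tuples), 10L)
  expect_equal(vapply(dec$tuples, `[[`, integer(1), "tuple_id"), 1:10)
  expect_true(all(vapply(dec$records$names,
                         function(n) length(validate_name(n)) == 0L, logical(1))))
  # empty input -> empty output + empty correspondence
  empty <- file.path(tmp, "empty.fq"); file.create(empty)
  out_e <- file.path(tmp, "empty.rnf.fq")
  convert_fastq(empty, g, 1L, c(chr1 = 1L), out_e)
  expect_equal(length(read_fastq(out_e)$names), 0L)
  expect_equal(length(read_correspondence_file(correspondence_path(out_e))), 0L)
  # paired 5+5 -> 5 tuples with 2 segments, ends matched to files
  nms_p <- vapply(1:5, function(i) dwgsim_name("chr1", 10L * i, 10L * i + 200L,
                                               0L, 1L, i), character(1))
  fq1 <- file.path(tmp, "p1.fq"); fq2 <- file.path(tmp, "p2.fq")
  write_fastq(fq1, paste0(nms_p, "/1"), rep(strrep("G", 50L), 5), rep(strrep("I", 50L), 5))
  write_fastq(fq2, paste0(nms_p, "/2"), rep(strrep("G", 50L), 5), rep(strrep("I", 50L), 5))
  o1 <- file.path(tmp, "p1.rnf.fq"); o2 <- file.path(tmp, "p2.rnf.fq")
  convert_fastq(c(fq1, fq2), g, 1L, c(chr1 = 1L), c(o1, o2))
  d1 <- read_rnf_fastq(o1); d2 <- read_rnf_fastq(o2)
  expect_equal(d1$records$names, d2$records$names)  # mates share the tuple name
  for (i in 1:5) {
    segs <- tuple_segments(d1$tuples[[i]])
    expect_equal(length(segs), 2L)
    expect_setequal(vapply(segs, `[[`, character(1), "direction"), c("F", "R"))
  }
  # unknown chromosome is an error naming the offender
  bad <- file.path(tmp, "bad.fq")
  write_fastq(bad, dwgsim_name("chrX", 5L, 5L, 0L, 0L, 1L), "ACGTA", "IIIII")
  expect_error(convert_fastq(bad, g, 1L, c(chr1 = 1L), file.path(tmp, "bad.out.fq")),
               "chrX")
})

test_that("cigar_ref_length agrees with the GenomicAlignments oracle", {
  cases <- c("50M", "30M5I20M", "30M5D20M", "10S40M", "20M100N30M", "5H10M3I2D8M")
  expect_equal(cigar_ref_length(cases),
               GenomicAlignments::cigarWidthAlongReferenceSpace(cases))
  expect_equal(cigar_ref_length("30M5I20M"), 50L)
  expect_equal(cigar_ref_length("30M5D20M"), 55L)
  expect_error(cigar_ref_length("xyz"), "malformed CIGAR")
  expect_error(cigar_ref_length("*"), "CIGAR unavailable")
})

test_that("convert_from_sam recovers truth segments via CIGAR arithmetic", {
  tmp <- withr::local_tempdir()
  sam <- file.path(tmp, "truth.sam")
  sq <- c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:chr1\tLN:10000", "@SQ\tSN:chr2\tLN:10000")
  mk <- function(qname, flag, chrom, pos, cigar, seq)
    paste(qname, flag, chrom, pos, 60L, cigar, "*", 0L, 0L, seq,
          strrep("I", nchar(seq)), sep = "\t")
  writeLines(c(sq,
    mk("t1", 0L, "chr2", 100L, "50M", strrep("A", 50L)),
    mk("t2", 0L, "chr1", 100L, "30M5I20M", strrep("C", 55L)),
    mk("t3", 16L, "chr1", 200L, "30M5D20M", strrep("G", 50L)),
    # chimeric truth: supplementary record becomes a second segment
    mk("t4", 0L, "chr1", 500L, "25M", strrep("T", 25L)),
    paste("t4", 2048L, "chr2", 900L, 60L, "25M", "*", 0L, 0L, strrep("T", 25L),
          strrep("I", 25L), sep = "\t")), sam)
  out <- file.path(tmp, "truth.rnf.fq")
  convert_from_sam(sam, 3L, out)
  dec <- read_rnf_fastq(out)
  expect_equal(length(dec$tuples), 4L)
  seg <- function(i) tuple_segments(dec$tuples[[i]])
  expect_equal(encode_segment(seg(1)[[1]]), "(3,2,F,100,149)")
  expect_equal(encode_segment(seg(2)[[1]]), "(3,1,F,100,149)")
  expect_equal(encode_segment(seg(3)[[1]]), "(3,1,R,200,254)")
  expect_equal(length(seg(4)), 2L)
  expect_setequal(vapply(seg(4), encode_segment, character(1)),
                  c("(3,1,F,500,524)", "(3,2,F,900,924)"))
  # reverse-flagged record is emitted re-oriented to the original strand
  expect_equal(dec$records$seq[3],
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(strrep("G", 50L)))))
  # missing @SQ headers are an error
  nosq <- file.path(tmp, "nosq.sam")
  writeLines(c("@HD\tVN:1.6", mk("x", 0L, "chr1", 1L, "10M", strrep("A", 10L))), nosq)
  expect_error(convert_from_sam(nosq, 1L, file.path(tmp, "x.fq")), "@SQ")
})
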