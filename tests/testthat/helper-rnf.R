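# Shared generators and independent oracles for the test suite.

# Random valid segment; with probability unknown_prob an all-unknown
# contaminant-style segment.
random_segment <- function(unknown_prob = 0.1, genome_ids = 1:3) {
  if (runif(1) < unknown_prob)
    return(rnf_segment(sample(c(0L, genome_ids), 1L), 0L, "N", 0L, 0L))
  left <- sample.int(100000L, 1L)
  rnf_segment(sample(genome_ids, 1L), sample.int(30L, 1L),
              sample(c("F", "R"), 1L), left, left + sample.int(500L, 1L) - 1L)
}

# Random valid tuple with 1-3 reads of 1-2 segments and 0-2 extensions.
random_tuple <- function(id, unknown_prob = 0.1) {
  n_reads <- sample.int(3L, 1L)
  reads <- replicate(n_reads, {
    replicate(sample.int(2L, 1L), random_segment(unknown_prob),
              simplify = FALSE)
  }, simplify = FALSE)
  n_ext <- sample(0:2, 1L)
  exts <- if (n_ext) replicate(n_ext, c(
    paste(sample(letters, 3L, replace = TRUE), collapse = ""),
    paste(sample(c(letters, 0:9), 4L, replace = TRUE), collapse = "")),
    simplify = FALSE) else list()
  prefix <- sample(c("", "sim", "a-b", "X9"), 1L)
  rnf_tuple(id, prefix, reads, exts)
}

# Independent sort oracle: fixed-width string keys + base::sort.
oracle_sort_segments <- function(segments) {
  if (!length(segments)) return(segments)
  keys <- vapply(segments, function(s)
    sprintf("%010d|%010d|%010d|%010d|%s", s$genome_id, s$chromosome_id,
            s$left, s$right, s$direction), character(1))
  segments[order(keys, method = "radix")]
}

segs_identical <- function(a, b) {
  identical(vapply(a, encode_segment, character(1)),
            vapply(b, encode_segment, character(1)))
}

tuples_equivalent <- function(t1, t2) {
  t1$tuple_id == t2$tuple_id && t1$prefix == t2$prefix &&
    identical(t1$extensions, t2$extensions) &&
    segs_identical(sort_segments(tuple_segments(t1)),
                   sort_segments(tuple_segments(t2)))
}

write_tiny_fasta <- function(path, seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  path
}

# Fixture world shared by the heavier tests, built once per run.
fixture_world <- local({
  fx <- NULL
  function() {
    if (is.null(fx))
      fx <<- make_fixtures(file.path(tempdir(), "rnfr-fixture-world"),
                           seed = 42L, n_host = 1000L, n_contaminant = 1000L)
    fx
  }
})
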