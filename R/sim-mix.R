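# Minimal built-in read simulator emitting RNF-named reads straight from
# a FASTA, and the sample mixer that merges several RNF read sets into a
# contamination / metagenome-style sample with provenance preserved.
#
# The error model is deliberately simple (uniform substitutions only, no
# indels, no quality model): realistic error profiles are the job of
# dedicated simulators; this one exists so the whole toolchain is
# testable stand-alone, with the central property that at error rate 0
# every emitted sequence equals the reference substring its own name
# addresses.

#' Specification of a simulation run
#'
#' @param n_reads Number of read tuples to emit (>= 0).
#' @param read_length Read length in bases (>= 1; must not exceed the
#'   longest chromosome).
#' @param substitution_error_rate Per-base probability in `[0, 1]` of a
#'   substitution to a uniformly chosen different base.
#' @param paired Emit paired-end tuples (FR orientation) instead of
#'   single-end.
#' @param fragment_mean,fragment_sd Fragment length distribution for
#'   paired mode (normal, rounded, clamped to at least `read_length` and
#'   at most the chromosome length).
#' @param rng_seed Integer seed; identical seed and spec give
#'   byte-identical output.
#' @param genome_id Integer >= 1 stamped on every segment.
#' @param prefix RNF name prefix.
#' @return An object of class `rnf_simspec`.
#' @export
sim_spec <- function(n_reads, read_length, substitution_error_rate = 0,
                     paired = FALSE, fragment_mean = 3 * read_length,
                     fragment_sd = 0.1 * fragment_mean, rng_seed = 1L,
                     genome_id = 1L, prefix = "sim") {
  stopifnot(n_reads >= 0, read_length >= 1,
            substitution_error_rate >= 0, substitution_error_rate <= 1,
            genome_id >= 1)
  if (paired) stopifnot(fragment_mean > 0, fragment_sd >= 0)
  check_prefix(prefix)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_error_rate = substitution_error_rate,
                 paired = isTRUE(paired),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 rng_seed = as.integer(rng_seed),
                 genome_id = as.integer(genome_id), prefix = prefix),
            class = "rnf_simspec")
}

.bases <- c("A", "C", "G", "T")

# Substitute each base independently with probability rate, to a
# uniformly chosen different base ('N' turns into any of ACGT).
apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    for (i in which(hit)) {
      alt <- setdiff(.bases, ch[i])
      ch[i] <- alt[sample.int(length(alt), 1L)]
    }
  }
  paste(ch, collapse = "")
}

#' Simulate RNF-named reads from a reference FASTA
#'
#' Chromosomes are chosen with probability proportional to their length
#' (among chromosomes at least one read long), the start position
#' uniformly over valid positions, and the strand uniformly. Each tuple's
#' name records the true sampled interval (1-based, closed) and strand;
#' reverse-strand reads are emitted reverse-complemented, as a sequencer
#' would deliver them. Qualities are constant `'I'` (Q40).
#'
#' @param fasta Reference FASTA path.
#' @param spec An [rnf_simspec].
#' @param out Output FASTQ path (single-end), or a vector of two paths
#'   (paired mode).
#' @param policy An [rnf_policy].
#' @return Invisible list with `outputs`, `correspondence`, `tuples`
#'   (the truth as a list of [rnf_tuple] objects).
#' @export
simulate_reads <- function(fasta, spec, out, policy = rnf_policy()) {
  stopifnot(inherits(spec, "rnf_simspec"))
  ref <- Biostrings::readDNAStringSet(fasta)
  if (!length(ref)) stop(sprintf("empty FASTA: '%s'", fasta), call. = FALSE)
  names(ref) <- sub("\\s.*$", "", names(ref))
  widths <- Biostrings::width(ref)
  usable <- which(widths >= spec$read_length)
  if (!length(usable))
    stop(sprintf("read_length %d exceeds every chromosome length (max %d)",
                 spec$read_length, max(widths)), call. = FALSE)
  if (spec$paired && length(out) != 2L)
    stop("paired mode requires two output paths", call. = FALSE)
  if (!spec$paired && length(out) != 1L)
    stop("single-end mode requires one output path", call. = FALSE)

  n <- spec$n_reads; rl <- spec$read_length
  withr::with_seed(spec$rng_seed, {
    chrom_idx <- if (n) usable[sample.int(length(usable), n, replace = TRUE,
                                          prob = widths[usable])] else integer(0)
    tuples <- vector("list", n)
    seq1 <- character(n); seq2 <- character(n)
    for (i in seq_len(n)) {
      ci <- chrom_idx[i]
      L <- widths[ci]
      if (!spec$paired) {
        start <- sample.int(L - rl + 1L, 1L)
        fwd <- stats::runif(1) < 0.5
        seg <- rnf_segment(spec$genome_id, ci, if (fwd) "F" else "R",
                           start, start + rl - 1L)
        s <- as.character(Biostrings::subseq(ref[[ci]], start, start + rl - 1L))
        if (!fwd) s <- revcomp(s)
        seq1[i] <- apply_substitutions(s, spec$substitution_error_rate)
        tuples[[i]] <- rnf_tuple(i, spec$prefix, list(list(seg)))
      } else {
        frag <- round(stats::rnorm(1, spec$fragment_mean, spec$fragment_sd))
        frag <- max(rl, min(L, frag))
        start <- sample.int(L - frag + 1L, 1L)
        left1 <- start; right1 <- start + rl - 1L
        right2 <- start + frag - 1L; left2 <- right2 - rl + 1L
        seg1 <- rnf_segment(spec$genome_id, ci, "F", left1, right1)
        seg2 <- rnf_segment(spec$genome_id, ci, "R", left2, right2)
        s1 <- as.character(Biostrings::subseq(ref[[ci]], left1, right1))
        s2 <- revcomp(as.character(Biostrings::subseq(ref[[ci]], left2, right2)))
        seq1[i] <- apply_substitutions(s1, spec$substitution_error_rate)
        seq2[i] <- apply_substitutions(s2, spec$substitution_error_rate)
        tuples[[i]] <- rnf_tuple(i, spec$prefix, list(list(seg1), list(seg2)))
      }
    }
  })
  qual <- strrep("I", rl)
  nb <- name_batch(tuples, policy)
  write_fastq(out[[1L]], nb$names, seq1, rep(qual, n))
  if (spec$paired) write_fastq(out[[2L]], nb$names, seq2, rep(qual, n))
  cp <- correspondence_path(out[[1L]])
  write_correspondence_file(cp, nb$correspondence)
  invisible(list(outputs = out, correspondence = cp, tuples = tuples))
}

#' Mix RNF read sets into one sample
#'
#' Merges several RNF FASTQ files -- e.g. reads simulated from different
#' genomes -- into one file simulating a contaminated or metagenomic
#' sample. Every segment's genome ID is rewritten to its sample's
#' assigned ID (so provenance survives the merge), tuple IDs are
#' re-assigned to be unique across the output, and records are
#' interleaved round-robin across samples (deterministic) or shuffled
#' with a seed.
#'
#' @param inputs Character vector of RNF FASTQ paths, one per sample.
#' @param genome_ids Integer vector, same length: the genome ID assigned
#'   to each sample. Duplicates are an error (provenance would be
#'   ambiguous).
#' @param out Output FASTQ path.
#' @param shuffle_seed Optional integer; when given, output order is a
#'   seeded shuffle instead of round-robin.
#' @param policy An [rnf_policy].
#' @return Invisible list with `out`, `correspondence`, `n_records`.
#' @export
mix_samples <- function(inputs, genome_ids, out, shuffle_seed = NULL,
                        policy = rnf_policy()) {
  stopifnot(length(inputs) >= 1L, length(genome_ids) == length(inputs))
  genome_ids <- as.integer(genome_ids)
  if (anyDuplicated(genome_ids))
    stop("duplicate genome_id across samples: provenance would be ambiguous",
         call. = FALSE)
  sets <- lapply(inputs, read_rnf_fastq)
  counts <- vapply(sets, function(s) length(s$tuples), integer(1))
  # Round-robin interleave: record j of every sample before record j+1.
  ord <- do.call(rbind, lapply(seq_along(sets), function(s)
    if (counts[s]) cbind(s, seq_len(counts[s])) else NULL))
  if (!is.null(ord)) ord <- ord[order(ord[, 2L], ord[, 1L]), , drop = FALSE]
  n <- sum(counts)
  if (!is.null(shuffle_seed) && n > 1L)
    ord <- withr::with_seed(as.integer(shuffle_seed),
                            ord[sample.int(n), , drop = FALSE])
  tuples <- vector("list", n); seqs <- character(n); quals <- character(n)
  for (k in seq_len(n)) {
    s <- ord[k, 1L]; j <- ord[k, 2L]
    old <- sets[[s]]$tuples[[j]]
    reads <- lapply(old$reads, function(r) lapply(r, function(seg) {
      seg$genome_id <- genome_ids[s]
      seg
    }))
    tuples[[k]] <- rnf_tuple(k, old$prefix, reads, old$extensions)
    seqs[k] <- sets[[s]]$records$seq[[j]]
    quals[k] <- sets[[s]]$records$qual[[j]]
  }
  nb <- name_batch(tuples, policy)
  write_fastq(out, nb$names, seqs, quals)
  cp <- correspondence_path(out)
  write_correspondence_file(cp, nb$correspondence)
  invisible(list(out = out, correspondence = cp, n_records = n))
}
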