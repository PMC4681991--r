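# Deterministic fixture world: two small random genomes, simulated RNF
# read sets, a contaminated mixture, scripted pseudo-mapper SAM outputs
# (perfect / contaminant-blind / contaminant-aware) and a toy chain
# file. Everything downstream tests consume is generated here from one
# seed; the same seed produces a byte-identical directory.

#' Write a random genome FASTA
#'
#' @param path Output FASTA.
#' @param chrom_lengths Named integer vector: chromosome name to length.
#' @param seed Integer seed.
#' @return Invisible `path`.
#' @export
random_genome_fasta <- function(path, chrom_lengths, seed) {
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(chrom_lengths, function(L)
      paste(sample(.bases, L, replace = TRUE), collapse = ""), character(1))
  })
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(chrom_lengths)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a SAM file from a record table
#'
#' Minimal single-end SAM writer for the scripted pseudo-mappers: takes
#' a data.frame with columns `qname`, `mapped`, `chrom`, `pos`,
#' `reverse`, `mapq`, `cigar` and writes valid SAM (SEQ/QUAL `*`).
#'
#' @param path Output SAM.
#' @param records The record data.frame.
#' @param sq Named integer vector: reference name to length (the `@SQ`
#'   header lines).
#' @return Invisible `path`.
#' @export
write_sam <- function(path, records, sq) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (!r$mapped)
      return(paste(r$qname, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, "*", "*",
                   sep = "\t"))
    flag <- if (isTRUE(r$reverse)) 16L else 0L
    paste(r$qname, flag, r$chrom, r$pos, r$mapq, r$cigar, "*", 0L, 0L, "*", "*",
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Fabricate a perfect mapper's SAM from RNF truth
#'
#' Every read from the reference genome is "mapped" exactly at its true
#' coordinates with MAPQ 60; reads from any other genome (contaminants)
#' are left unmapped. Evaluating this file must give sensitivity 1 and
#' FDR 0 at every threshold -- the end-to-end self-consistency check of
#' the whole toolchain.
#'
#' @param fastq RNF FASTQ (single-end).
#' @param out_sam Output SAM path.
#' @param chrom_names Character vector mapping chromosome ID (index) to
#'   the mapper's reference name.
#' @param sq Named integer vector of reference lengths for the header.
#' @param reference_genome_id Genome the pseudo-mapper "aligned to".
#' @return Invisible `out_sam`.
#' @export
perfect_mapper_sam <- function(fastq, out_sam, chrom_names, sq,
                               reference_genome_id = 1L) {
  x <- read_rnf_fastq(fastq)
  n <- length(x$tuples)
  rec <- data.frame(qname = x$records$names, mapped = FALSE,
                    chrom = "*", pos = 0L, reverse = FALSE, mapq = 0L,
                    cigar = "*", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    segs <- tuple_segments(x$tuples[[i]])
    hit <- Filter(function(s) s$genome_id == reference_genome_id &&
                    s$left > 0L, segs)
    if (!length(hit)) next
    s <- hit[[1L]]
    rec$mapped[i] <- TRUE
    rec$chrom[i] <- chrom_names[[s$chromosome_id]]
    rec$pos[i] <- s$left
    rec$reverse[i] <- s$direction == "R"
    rec$mapq[i] <- 60L
    rec$cigar[i] <- sprintf("%dM", s$right - s$left + 1L)
  }
  write_sam(out_sam, rec, sq)
  invisible(out_sam)
}

#' Generate the deterministic fixture world
#'
#' Builds, under one seed: a 10-kb "host" genome and a 10-kb
#' "contaminant" genome; `n_host` + `n_contaminant` single-end reads at
#' error rate 0 (genome IDs 1 and 2) mixed into one sample; three
#' scripted pseudo-mapper SAM files over the host reference --
#' `perfect.sam` (truth positions, contaminants unmapped), `blind.sam`
#' (maps every read: each host read's position is corrupted with
#' probability `corrupt_fraction`, and every contaminant is placed at a
#' random host position; MAPQ correlates with correctness), and
#' `aware.sam` (identical host records, contaminants unmapped) -- plus a
#' toy liftover chain with a 1-kb gap in the middle of the host
#' chromosome. A `params.txt` records the generating parameters.
#'
#' MAPQ rule: correctly placed host reads draw from 40..60, corrupted
#' ones from 0..20, blind-mapped contaminants from 20..60 (so the two
#' mappers share thresholds across the whole range).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_host,n_contaminant Reads per genome (defaults 1000 + 1000,
#'   the contamination experiment design at toy scale).
#' @param read_length Read length (default 100).
#' @param corrupt_fraction Per-read probability that the blind/aware
#'   mappers corrupt a host read's position (default 0.2).
#' @return Invisible list of the paths and planted truth counts.
#' @export
make_fixtures <- function(dir, seed = 1L, n_host = 1000L, n_contaminant = 1000L,
                          read_length = 100L, corrupt_fraction = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  glen <- 10000L
  seed <- as.integer(seed)
  random_genome_fasta(p("host.fa"), c(host_chr1 = glen), seed)
  random_genome_fasta(p("contaminant.fa"), c(cont_chr1 = glen), seed + 1L)
  simulate_reads(p("host.fa"),
                 sim_spec(n_host, read_length, 0, rng_seed = seed + 2L,
                          genome_id = 1L, prefix = "host"),
                 p("host.fq"))
  simulate_reads(p("contaminant.fa"),
                 sim_spec(n_contaminant, read_length, 0, rng_seed = seed + 3L,
                          genome_id = 2L, prefix = "cont"),
                 p("contaminant.fq"))
  mix_samples(c(p("host.fq"), p("contaminant.fq")), c(1L, 2L), p("mixed.fq"))

  sq <- c(host_chr1 = glen)
  chrom_names <- "host_chr1"
  perfect_mapper_sam(p("mixed.fq"), p("perfect.sam"), chrom_names, sq, 1L)

  # Scripted noisy mappers: one shared draw for the host reads, so the
  # blind and aware mappers differ only in contaminant handling.
  x <- read_rnf_fastq(p("mixed.fq"))
  n <- length(x$tuples)
  base <- data.frame(qname = x$records$names, mapped = FALSE, chrom = "*",
                     pos = 0L, reverse = FALSE, mapq = 0L, cigar = "*",
                     stringsAsFactors = FALSE)
  blind <- base; aware <- base
  n_corrupted <- 0L
  withr::with_seed(seed + 4L, {
    for (i in seq_len(n)) {
      s <- tuple_segments(x$tuples[[i]])[[1L]]
      rl <- s$right - s$left + 1L
      if (s$genome_id == 1L) {
        corrupt <- stats::runif(1) < corrupt_fraction
        if (corrupt) {
          n_corrupted <- n_corrupted + 1L
          repeat {
            pos <- sample.int(glen - read_length + 1L, 1L)
            if (abs(pos - s$left) > 50L) break
          }
          mq <- sample(0:20, 1L)
        } else {
          pos <- s$left
          mq <- sample(40:60, 1L)
        }
        row <- list(mapped = TRUE, chrom = "host_chr1", pos = pos,
                    reverse = s$direction == "R", mapq = mq,
                    cigar = sprintf("%dM", read_length))
        for (f in names(row)) {
          blind[[f]][i] <- row[[f]]
          aware[[f]][i] <- row[[f]]
        }
      } else {
        # Contaminant: the blind mapper places it somewhere on the host
        # with a respectable MAPQ; the aware mapper refuses to map it.
        blind$mapped[i] <- TRUE
        blind$chrom[i] <- "host_chr1"
        blind$pos[i] <- sample.int(glen - read_length + 1L, 1L)
        blind$reverse[i] <- stats::runif(1) < 0.5
        blind$mapq[i] <- sample(20:60, 1L)
        blind$cigar[i] <- sprintf("%dM", read_length)
      }
    }
  })
  write_sam(p("blind.sam"), blind, sq)
  write_sam(p("aware.sam"), aware, sq)

  # Toy chain: host_chr1 lifts to lifted_chr1 except for a 1-kb gap in
  # the middle; the second half shifts left by the gap width.
  writeLines(c("chain 1000 host_chr1 10000 + 0 10000 lifted_chr1 9000 + 0 9000",
               "4000\t1000\t0",
               "5000",
               ""), p("toy.chain"))

  writeLines(c(sprintf("seed=%d", seed),
               sprintf("n_host=%d", n_host),
               sprintf("n_contaminant=%d", n_contaminant),
               sprintf("read_length=%d", read_length),
               sprintf("corrupt_fraction=%g", corrupt_fraction),
               sprintf("genome_length=%d", glen)), p("params.txt"))

  invisible(list(dir = dir,
                 host_fa = p("host.fa"), contaminant_fa = p("contaminant.fa"),
                 host_fq = p("host.fq"), contaminant_fq = p("contaminant.fq"),
                 mixed_fq = p("mixed.fq"),
                 perfect_sam = p("perfect.sam"), blind_sam = p("blind.sam"),
                 aware_sam = p("aware.sam"), chain = p("toy.chain"),
                 sq = sq, chrom_names = chrom_names,
                 n_host = n_host, n_contaminant = n_contaminant,
                 n_corrupted = n_corrupted))
}
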