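# Truth-aware evaluation of mapper output: decode the RNF truth from
# each alignment's read name, classify every read at a mapping-quality
# threshold, and sweep the threshold to obtain
# sensitivity/precision/FDR curves parametrized by MAPQ.
#
# The unit of evaluation is the individual read via its primary SAM
# record; paired ends are scored independently (each segment of a tuple
# corresponds to one SAM line, so the ANY-segment match rule scores each
# end against its own true segment).

#' Evaluation configuration
#'
#' @param reference_genome_id The RNF genome ID of the genome the reads
#'   were mapped against; reads whose truth has no segment from this
#'   genome are contaminants.
#' @param tolerance Maximum allowed distance, in bases, between the
#'   reported and the true leftmost coordinate (default 5). Correctness
#'   definitions legitimately vary between studies; this one is the knob.
#' @param require_strand Require strand agreement (default `TRUE`); a
#'   truth direction of `'N'` matches either strand.
#' @param chrom_map Named integer vector mapping SAM chromosome names to
#'   RNF chromosome IDs.
#' @param contaminants_in_fdr Count contaminant reads that were mapped
#'   (and pass the threshold) as false discoveries (default `TRUE`; a
#'   contamination-detection comparison requires it).
#' @return An object of class `rnf_evalconfig`.
#' @export
eval_config <- function(reference_genome_id, chrom_map, tolerance = 5L,
                        require_strand = TRUE, contaminants_in_fdr = TRUE) {
  stopifnot(tolerance >= 0)
  structure(list(reference_genome_id = as.integer(reference_genome_id),
                 tolerance = as.integer(tolerance),
                 require_strand = isTRUE(require_strand),
                 chrom_map = chrom_map,
                 contaminants_in_fdr = isTRUE(contaminants_in_fdr)),
            class = "rnf_evalconfig")
}

.categories <- c("CORRECT", "WRONG_POSITION", "CONTAMINANT_MAPPED",
                 "SHOULD_MAP_UNMAPPED", "CONTAMINANT_UNMAPPED",
                 "UNDER_THRESHOLD")

# Does any truth segment match this observation under the config?
obs_matches_truth <- function(obs, truth, config) {
  if (!obs$mapped) return(FALSE)
  obs_chrom <- resolve_chrom(obs$chrom, config$chrom_map, "alignment file")
  for (seg in tuple_segments(truth)) {
    if (seg$genome_id != config$reference_genome_id) next
    if (seg$chromosome_id != obs_chrom) next
    if (seg$left == 0L) next
    if (abs(obs$pos - seg$left) > config$tolerance) next
    if (config$require_strand && seg$direction != "N") {
      if ((seg$direction == "R") != isTRUE(obs$reverse)) next
    }
    return(TRUE)
  }
  FALSE
}

is_contaminant_truth <- function(truth, config) {
  !any(vapply(tuple_segments(truth), `[[`, integer(1), "genome_id") ==
         config$reference_genome_id)
}

#' Classify one read at one MAPQ threshold
#'
#' A read is "reported" when it is mapped with `mapq >= q`. The six
#' categories are exhaustive and mutually exclusive: a reported read is
#' `CONTAMINANT_MAPPED` (truth has no segment from the reference
#' genome), `CORRECT` (some truth segment matches within the position
#' tolerance) or `WRONG_POSITION`; an unreported contaminant is
#' `CONTAMINANT_UNMAPPED`; an unreported genuine read is
#' `UNDER_THRESHOLD` if it was mapped (the threshold demoted it) and
#' `SHOULD_MAP_UNMAPPED` if the mapper left it unmapped.
#'
#' @param obs A list (one row of [read_alignments()] output) with fields
#'   `mapped`, `chrom`, `pos`, `reverse`, `mapq`.
#' @param truth The decoded [rnf_tuple] for the read's name.
#' @param config An [eval_config()].
#' @param q Integer MAPQ threshold.
#' @return One of the six category strings.
#' @export
classify_read <- function(obs, truth, config, q = 0L) {
  contaminant <- is_contaminant_truth(truth, config)
  reported <- isTRUE(obs$mapped) && obs$mapq >= q
  if (reported) {
    if (contaminant) return("CONTAMINANT_MAPPED")
    if (obs_matches_truth(obs, truth, config)) return("CORRECT")
    return("WRONG_POSITION")
  }
  if (contaminant) return("CONTAMINANT_UNMAPPED")
  if (isTRUE(obs$mapped)) return("UNDER_THRESHOLD")
  "SHOULD_MAP_UNMAPPED"
}

#' Read primary alignment observations from a SAM/BAM file
#'
#' Keeps one primary record per read (secondary and supplementary
#' records are dropped; multi-mapping policy is mapper-specific, so only
#' the primary is scored) and decodes each QNAME's RNF truth, resolving
#' short names through a correspondence table when supplied.
#'
#' @param path SAM or BAM file of a mapper under test.
#' @param correspondence Optional named character vector (SRN to LRN) or
#'   a path to a correspondence TSV.
#' @return A list: `obs` -- data.frame of primary observations (`qname`,
#'   `end`, `mapped`, `chrom`, `pos`, `reverse`, `mapq`) -- and `truths`,
#'   a list of decoded [rnf_tuple] objects parallel to the rows.
#' @export
read_alignments <- function(path, correspondence = NULL) {
  df <- load_sam(path)
  df <- df[!df$secondary & !df$supplementary, , drop = FALSE]
  key <- paste(df$qname, ifelse(df$paired & !df$first, 2L, 1L))
  if (anyDuplicated(key))
    warning(sprintf("%d duplicate primary records in '%s'; keeping the first of each",
                    sum(duplicated(key)), path))
  df <- df[!duplicated(key), , drop = FALSE]
  if (is.character(correspondence) && length(correspondence) == 1L &&
      file.exists(correspondence) && is.null(names(correspondence)))
    correspondence <- read_correspondence_file(correspondence)
  lrn_cache <- new.env(parent = emptyenv())
  truths <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    nm <- df$qname[[i]]
    if (startsWith(nm, "#")) {
      if (is.null(correspondence) || !nm %in% names(correspondence))
        stop(sprintf("QNAME '%s' is an SRN but no correspondence entry was supplied",
                     nm), call. = FALSE)
      nm <- correspondence[[nm]]
    }
    t <- get0(nm, envir = lrn_cache)
    if (is.null(t)) {
      t <- tryCatch(decode_lrn(nm), error = function(e)
        stop(sprintf("QNAME '%s' is not a valid RNF name: %s", df$qname[[i]],
                     conditionMessage(e)), call. = FALSE))
      assign(nm, t, envir = lrn_cache)
    }
    truths[[i]] <- t
  }
  obs <- data.frame(qname = df$qname,
                    end = ifelse(df$paired & !df$first, 2L, 1L),
                    mapped = df$mapped, chrom = df$chrom, pos = df$pos,
                    reverse = df$reverse, mapq = df$mapq,
                    stringsAsFactors = FALSE)
  obs$mapq[!obs$mapped] <- 0L
  obs$mapq[is.na(obs$mapq)] <- 0L
  list(obs = obs, truths = truths)
}

#' Build the MAPQ-parametrized evaluation curve
#'
#' Classifies every read at every threshold in the sweep and derives the
#' rates. The default sweep is the sorted set of distinct observed MAPQ
#' values plus a sentinel 0 -- the curve is identical to a dense 0..255
#' sweep, with fewer points. At threshold `q`:
#' `sensitivity = CORRECT / (number of non-contaminant reads)`;
#' `precision = CORRECT / (CORRECT + WRONG_POSITION + CONTAMINANT_MAPPED)`
#' (1 when the denominator is 0: no discoveries means no false
#' discoveries); `fdr = 1 - precision`. With
#' `contaminants_in_fdr = FALSE` mapped contaminants are excluded from
#' the precision denominator.
#'
#' @param alignments The list returned by [read_alignments()] (or built
#'   by hand: `obs` data.frame plus parallel `truths` list).
#' @param config An [eval_config()].
#' @param thresholds Optional integer vector overriding the sweep.
#' @return A data.frame of curve points, ordered by increasing `q`, with
#'   the six category counts, `sensitivity`, `precision`, `fdr`.
#' @export
build_curve <- function(alignments, config, thresholds = NULL) {
  obs <- alignments$obs
  truths <- alignments$truths
  n <- nrow(obs)
  stopifnot(length(truths) == n)
  contaminant <- vapply(truths, is_contaminant_truth, logical(1), config = config)
  match0 <- logical(n)
  for (i in seq_len(n))
    match0[i] <- obs_matches_truth(as.list(obs[i, , drop = FALSE]), truths[[i]],
                                   config)
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0L, obs$mapq[obs$mapped])))
  } else {
    thresholds <- sort(unique(as.integer(thresholds)))
  }
  rows <- lapply(thresholds, function(q) {
    reported <- obs$mapped & obs$mapq >= q
    correct <- sum(reported & !contaminant & match0)
    wrong <- sum(reported & !contaminant & !match0)
    cont_map <- sum(reported & contaminant)
    cont_unmap <- sum(!reported & contaminant)
    under <- sum(!reported & !contaminant & obs$mapped)
    should <- sum(!contaminant & !obs$mapped)
    n_genuine <- sum(!contaminant)
    sens <- if (n_genuine) correct / n_genuine else 1
    denom <- correct + wrong + if (config$contaminants_in_fdr) cont_map else 0L
    prec <- if (denom) correct / denom else 1
    data.frame(q = q, CORRECT = correct, WRONG_POSITION = wrong,
               CONTAMINANT_MAPPED = cont_map,
               SHOULD_MAP_UNMAPPED = should,
               CONTAMINANT_UNMAPPED = cont_unmap,
               UNDER_THRESHOLD = under,
               sensitivity = sens, precision = prec, fdr = 1 - prec)
  })
  do.call(rbind, rows)
}

#' Evaluate one mapper's SAM/BAM against its RNF truth
#'
#' Convenience wrapper: reads the alignments, builds the curve, and
#' writes the per-threshold curve TSV plus a per-read audit TSV (name,
#' end, category at q = 0, MAPQ).
#'
#' @param path SAM/BAM of the mapper under test.
#' @param config An [eval_config()].
#' @param out_prefix Path prefix; writes `<prefix>.curve.tsv` and
#'   `<prefix>.reads.tsv`.
#' @param correspondence Passed to [read_alignments()].
#' @param thresholds Passed to [build_curve()].
#' @return Invisible list with `curve` (data.frame), `curve_tsv`,
#'   `reads_tsv`.
#' @export
evaluate_mapper <- function(path, config, out_prefix,
                            correspondence = NULL, thresholds = NULL) {
  al <- read_alignments(path, correspondence)
  curve <- build_curve(al, config, thresholds)
  curve_tsv <- paste0(out_prefix, ".curve.tsv")
  utils::write.table(curve, curve_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat0 <- vapply(seq_len(nrow(al$obs)), function(i)
    classify_read(as.list(al$obs[i, , drop = FALSE]), al$truths[[i]], config, 0L),
    character(1))
  reads_tsv <- paste0(out_prefix, ".reads.tsv")
  utils::write.table(
    data.frame(name = al$obs$qname, end = al$obs$end, category = cat0,
               mapq = al$obs$mapq),
    reads_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(curve = curve, curve_tsv = curve_tsv, reads_tsv = reads_tsv))
}
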