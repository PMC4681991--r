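# Converters from upstream simulators' read-naming dialects (wgsim,
# dwgsim, CuReSim name grammars; SAM truth files) into RNF-named FASTQ.
#
# Two coordinate semantics occur in the wild: wgsim names carry the
# FIRST nucleotide of each end (so a reverse end's encoded position is
# its rightmost base), while dwgsim and CuReSim carry the LEFTMOST
# nucleotide of each end regardless of strand.

#' Construct a dialect grammar
#'
#' A grammar describes one simulator's read-name convention: a Perl
#' regular expression with named capture groups (`chrom`, `pos1` and
#' optionally `pos2`, `strand1`, `strand2`, `counter`, `end`), the
#' coordinate semantics, and how end membership is determined.
#'
#' @param dialect_name Identifier (e.g. `"dwgsim"`).
#' @param pattern Perl regex with named groups.
#' @param semantics `"FIRST_NUCLEOTIDE_EACH_END"` or `"LEFTMOST_EACH_END"`.
#' @param pairing `"suffix"` (trailing `/1` `/2` in the name) or `"file"`
#'   (end membership from the file of origin).
#' @param strands_default Directions assumed for ends 1 and 2 when the
#'   name does not encode strand, e.g. `c("F", "R")` for wgsim's
#'   forward/reverse pair convention; use `c("N", "N")` to refuse to guess.
#' @return An object of class `rnf_dialect`.
#' @export
dialect_grammar <- function(dialect_name, pattern, semantics, pairing = "suffix",
                            strands_default = c("N", "N")) {
  semantics <- match.arg(semantics,
                         c("FIRST_NUCLEOTIDE_EACH_END", "LEFTMOST_EACH_END"))
  pairing <- match.arg(pairing, c("suffix", "file"))
  structure(list(dialect_name = dialect_name, pattern = pattern,
                 semantics = semantics, pairing = pairing,
                 strands_default = strands_default),
            class = "rnf_dialect")
}

#' Load a dialect grammar from a key=value pattern file
#'
#' Pattern files are plain text with one `key=value` per line (keys
#' `name`, `pattern`, `semantics`, `pairing`, `strands_default`); lines
#' starting with `#` are comments. The built-in dialects live in
#' `system.file("extdata", "dialects", package = "rnfr")` and can be used
#' as templates for overriding drifting upstream formats.
#'
#' @param path Pattern file.
#' @return An `rnf_dialect`.
#' @export
load_dialect_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[[match(k, keys)]] else default
  }
  for (req in c("name", "pattern", "semantics"))
    if (is.null(get(req)))
      stop(sprintf("dialect file '%s' is missing key '%s'", path, req), call. = FALSE)
  dialect_grammar(get("name"), get("pattern"), get("semantics"),
                  get("pairing", "suffix"),
                  strsplit(get("strands_default", "N,N"), ",", fixed = TRUE)[[1L]])
}

#' Built-in dialect grammars
#'
#' @param name One of `"wgsim"`, `"dwgsim"`, `"curesim"`.
#' @return An `rnf_dialect` loaded from the shipped pattern file.
#' @export
builtin_dialect <- function(name = c("wgsim", "dwgsim", "curesim")) {
  name <- match.arg(name)
  path <- system.file("extdata", "dialects", paste0(name, ".dialect"),
                      package = "rnfr", mustWork = TRUE)
  load_dialect_file(path)
}

# Match a perl regex with named groups against one string; NULL on mismatch.
match_named <- function(pattern, x) {
  m <- regexpr(pattern, x, perl = TRUE)
  if (m == -1L) return(NULL)
  st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
  nm <- attr(m, "capture.names")
  out <- list()
  for (i in seq_along(nm)) {
    if (!nzchar(nm[i])) next
    out[[nm[i]]] <- if (st[i] > 0L) substr(x, st[i], st[i] + len[i] - 1L) else NA_character_
  }
  out
}

#' Parse one dialect-named read into per-end origin records
#'
#' Under `LEFTMOST_EACH_END` the captured position is the left coordinate
#' and `right = left + read_length - 1` when the strand is known (right
#' is 0 and direction `"N"` when it is not). Under
#' `FIRST_NUCLEOTIDE_EACH_END` a forward end's first nucleotide is its
#' leftmost base while a reverse end's first nucleotide is its rightmost
#' base, so `left = pos - read_length + 1` for a reverse end.
#'
#' @param name The read name (may include a trailing `/1` or `/2`).
#' @param grammar An `rnf_dialect`.
#' @param read_length Read length in bases, used to reconstruct the
#'   missing interval endpoint.
#' @return List of per-end records, each a list with `end`, `chrom`,
#'   `direction`, `left`, `right`; plus attribute `end_hint` (integer or
#'   NA) from the name's `/1` `/2` suffix.
#' @export
parse_dialect_name <- function(name, grammar, read_length) {
  stopifnot(inherits(grammar, "rnf_dialect"))
  cap <- match_named(grammar$pattern, name)
  if (is.null(cap))
    stop(sprintf("read name '%s' does not match the %s dialect pattern",
                 name, grammar$dialect_name), call. = FALSE)
  rl <- as.integer(read_length)
  ends <- list()
  for (e in 1:2) {
    pos_key <- paste0("pos", e)
    if (is.null(cap[[pos_key]]) || is.na(cap[[pos_key]])) next
    pos <- as.integer(cap[[pos_key]])
    strand_key <- paste0("strand", e)
    dir <- if (!is.null(cap[[strand_key]]) && !is.na(cap[[strand_key]])) {
      if (cap[[strand_key]] %in% c("1", "-", "R")) "R" else "F"
    } else grammar$strands_default[e]
    if (grammar$semantics == "LEFTMOST_EACH_END") {
      left <- pos
      right <- if (dir == "N") 0L else pos + rl - 1L
    } else {  # FIRST_NUCLEOTIDE_EACH_END
      if (dir == "R") { right <- pos; left <- pos - rl + 1L }
      else if (dir == "F") { left <- pos; right <- pos + rl - 1L }
      else { left <- pos; right <- 0L }
    }
    ends[[length(ends) + 1L]] <- list(end = e, chrom = cap$chrom, direction = dir,
                                      left = left, right = right)
  }
  if (!length(ends))
    stop(sprintf("read name '%s' encodes no position", name), call. = FALSE)
  end_hint <- if (!is.null(cap$end) && !is.na(cap$end)) as.integer(cap$end)
              else NA_integer_
  structure(ends, end_hint = end_hint)
}

precursor_segment <- function(p, genome_id, chrom_map, context) {
  rnf_segment(genome_id, resolve_chrom(p$chrom, chrom_map, context),
              p$direction, p$left, p$right)
}

#' Convert dialect-named FASTQ file(s) into RNF-named FASTQ
#'
#' Reads one (single-end) or two (paired) FASTQ files whose names follow
#' an upstream simulator's convention, decodes each name, and writes
#' RNF-named FASTQ with tuple IDs assigned sequentially in input order
#' starting at 1. Mates of a pair share one tuple name; end membership is
#' carried by the file of origin. The record count of every file is
#' preserved, and an SRN-LRN correspondence file is always written
#' (empty when no name fell back).
#'
#' @param inputs Character vector of 1 or 2 FASTQ paths.
#' @param grammar An `rnf_dialect` (see [builtin_dialect()]).
#' @param genome_id Integer >= 1 assigned to every segment.
#' @param chrom_map Named integer vector mapping chromosome names
#'   occurring in read names to RNF chromosome IDs.
#' @param outputs Character vector of output FASTQ paths, same length as
#'   `inputs`.
#' @param prefix RNF name prefix; defaults to the dialect name.
#' @param policy An [rnf_policy].
#' @return Invisible list with `outputs`, `correspondence`, `n_tuples`.
#' @export
convert_fastq <- function(inputs, grammar, genome_id, chrom_map, outputs,
                          prefix = grammar$dialect_name, policy = rnf_policy()) {
  stopifnot(length(inputs) %in% 1:2, length(outputs) == length(inputs))
  paired <- length(inputs) == 2L
  files <- lapply(inputs, read_fastq)
  n <- length(files[[1L]]$names)
  if (paired && length(files[[2L]]$names) != n)
    stop(sprintf("paired inputs have different record counts (%d vs %d)",
                 n, length(files[[2L]]$names)), call. = FALSE)
  tuples <- vector("list", n)
  for (i in seq_len(n)) {
    reads <- vector("list", length(files))
    for (f in seq_along(files)) {
      nm <- files[[f]]$names[[i]]
      rl <- nchar(files[[f]]$seq[[i]])
      ends <- tryCatch(parse_dialect_name(nm, grammar, rl), error = function(e)
        stop(sprintf("record %d (file %d): %s", i, f, conditionMessage(e)),
             call. = FALSE))
      want <- if (grammar$pairing == "file" || !paired) {
        hint <- attr(ends, "end_hint")
        if (paired) f else if (!is.na(hint)) hint else 1L
      } else {
        hint <- attr(ends, "end_hint")
        if (!is.na(hint)) hint else f
      }
      idx <- match(want, vapply(ends, `[[`, integer(1), "end"))
      if (is.na(idx)) idx <- 1L
      reads[[f]] <- list(precursor_segment(ends[[idx]], genome_id, chrom_map,
                                           sprintf("record %d", i)))
    }
    tuples[[i]] <- rnf_tuple(i, prefix, reads)
  }
  nb <- name_batch(tuples, policy)
  for (f in seq_along(files))
    write_fastq(outputs[[f]], nb$names, files[[f]]$seq, files[[f]]$qual)
  cp <- correspondence_path(outputs[[1L]])
  write_correspondence_file(cp, nb$correspondence)
  invisible(list(outputs = outputs, correspondence = cp, n_tuples = n))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Convert a SAM/BAM truth file into RNF-named FASTQ
#'
#' Simulators in the Art/Mason family emit the truth as alignment
#' records. Records are grouped by QNAME; each mapped record contributes
#' one segment with `left = POS` and
#' `right = POS + reference-consumed CIGAR length - 1`, direction from
#' the reverse-strand flag. Primary records define the reads (and supply
#' sequence/quality, re-oriented to the original strand); secondary and
#' supplementary records become additional segments of the same read,
#' supporting chimeric truth.
#'
#' @param sam_path SAM (with `@SQ` headers) or BAM truth file.
#' @param genome_id Integer >= 1 assigned to every segment.
#' @param outputs Character vector of 1 (single-end) or 2 (paired)
#'   output FASTQ paths.
#' @param chrom_map Named integer vector; defaults to `@SQ` header order.
#' @param prefix RNF name prefix.
#' @param policy An [rnf_policy].
#' @return Invisible list with `outputs`, `correspondence`, `n_tuples`.
#' @export
convert_from_sam <- function(sam_path, genome_id, outputs, chrom_map = NULL,
                             prefix = "sam", policy = rnf_policy()) {
  df <- load_sam(sam_path, include_seq = TRUE)
  if (is.null(chrom_map)) chrom_map <- default_chrom_map(attr(df, "sq"))
  qnames <- unique(df$qname)
  paired <- any(df$paired)
  if (paired && length(outputs) != 2L)
    stop("paired truth records require two output paths", call. = FALSE)
  if (!paired && length(outputs) != 1L)
    stop("single-end truth records require one output path", call. = FALSE)

  rec_segment <- function(row) {
    if (!row$mapped) return(rnf_segment(genome_id, 0L, "N", 0L, 0L))
    right <- row$pos + cigar_ref_length(row$cigar) - 1L
    rnf_segment(genome_id, resolve_chrom(row$chrom, chrom_map, sam_path),
                if (row$reverse) "R" else "F", row$pos, right)
  }

  tuples <- vector("list", length(qnames))
  seqs <- list(character(length(qnames)), character(length(qnames)))
  quals <- list(character(length(qnames)), character(length(qnames)))
  for (i in seq_along(qnames)) {
    g <- df[df$qname == qnames[[i]], , drop = FALSE]
    ends <- if (paired) 1:2 else 1L
    reads <- vector("list", length(ends))
    for (e in ends) {
      sel <- if (paired) (g$first == (e == 1L)) else rep(TRUE, nrow(g))
      ge <- g[sel, , drop = FALSE]
      prim <- ge[!ge$secondary & !ge$supplementary, , drop = FALSE]
      if (nrow(prim) != 1L)
        stop(sprintf("template '%s' end %d has %d primary records (expected 1)",
                     qnames[[i]], e, nrow(prim)), call. = FALSE)
      segs <- list(rec_segment(prim[1L, ]))
      extra <- ge[ge$secondary | ge$supplementary, , drop = FALSE]
      if (nrow(extra))
        for (j in seq_len(nrow(extra)))
          if (extra$mapped[j]) segs <- c(segs, list(rec_segment(extra[j, ])))
      reads[[e]] <- segs
      sq <- prim$seq[1L]; ql <- prim$qual[1L]
      if (isTRUE(prim$reverse[1L]) && prim$mapped[1L]) {
        sq <- revcomp(sq)
        ql <- paste(rev(strsplit(ql, "")[[1L]]), collapse = "")
      }
      seqs[[e]][i] <- sq
      quals[[e]][i] <- ql
    }
    tuples[[i]] <- rnf_tuple(i, prefix, reads)
  }
  nb <- name_batch(tuples, policy)
  for (e in seq_along(outputs))
    write_fastq(outputs[[e]], nb$names, seqs[[e]][seq_along(qnames)],
                quals[[e]][seq_along(qnames)])
  cp <- correspondence_path(outputs[[1L]])
  write_correspondence_file(cp, nb$correspondence)
  invisible(list(outputs = outputs, correspondence = cp, n_tuples = length(qnames)))
}
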