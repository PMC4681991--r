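# Shared SAM/BAM plumbing: loading records via Rsamtools and CIGAR
# reference-length arithmetic.

#' Reference-consumed length of a CIGAR string
#'
#' Sums the lengths of operations that consume reference bases
#' (`M`, `D`, `N`, `=`, `X`); insertions and clips consume none. This is
#' the span a mapped record covers on the reference, so a record at POS
#' `p` ends at `p + cigar_ref_length(cigar) - 1`.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference-consumed lengths.
#' @export
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*")
      stop("CIGAR unavailable on a mapped record", call. = FALSE)
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg, perl = TRUE)[[1L]]
    if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(cg))
      stop(sprintf("malformed CIGAR '%s'", cg), call. = FALSE)
    ops <- regmatches(cg, gregexpr("(\\d+)([MIDNSHP=X])", cg, perl = TRUE))[[1L]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# SAM flag bit helpers.
flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Load a SAM or BAM file into a flat record table
#'
#' SAM input is converted to BAM in a temporary location via
#' `Rsamtools::asBam` (so `@SQ` headers are required), then scanned.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param include_seq Also extract sequence and quality strings.
#' @return A data.frame with one row per record: `qname`, `flag`,
#'   `chrom`, `pos`, `mapq`, `cigar`, logicals `mapped`, `reverse`,
#'   `paired`, `first`, `secondary`, `supplementary`, and (optionally)
#'   `seq`, `qual`; plus attribute `sq` with the header sequence names.
#' @export
load_sam <- function(path, include_seq = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    hdr <- readLines(path, n = 200L)
    if (!any(startsWith(hdr, "@SQ")))
      stop(sprintf("'%s' has no @SQ header lines", path), call. = FALSE)
    bam <- Rsamtools::asBam(path, tempfile(fileext = ""), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar")
  if (include_seq) what <- c(what, "seq", "qual")
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  sq <- names(Rsamtools::scanBamHeader(bam)[[1L]]$targets)
  flag <- b$flag
  df <- data.frame(
    qname = b$qname,
    flag = flag,
    chrom = as.character(b$rname),
    pos = b$pos,
    mapq = b$mapq,
    cigar = b$cigar,
    mapped = !flag_bit(flag, 4L),
    reverse = flag_bit(flag, 16L),
    paired = flag_bit(flag, 1L),
    first = !flag_bit(flag, 128L),
    secondary = flag_bit(flag, 256L),
    supplementary = flag_bit(flag, 2048L),
    stringsAsFactors = FALSE)
  if (include_seq) {
    df$seq <- as.character(b$seq)
    df$qual <- as.character(b$qual)
  }
  attr(df, "sq") <- sq
  df
}

#' Default chromosome name-to-ID map
#'
#' RNF addresses chromosomes by integer ID; converters default to the
#' 1-based order of appearance in the FASTA / `@SQ` headers.
#'
#' @param chrom_names Character vector of chromosome names in file order.
#' @return Named integer vector mapping name to ID.
#' @export
default_chrom_map <- function(chrom_names) {
  stats::setNames(seq_along(chrom_names), chrom_names)
}

resolve_chrom <- function(name, chrom_map, context = "input") {
  if (!name %in% names(chrom_map))
    stop(sprintf("unknown chromosome '%s' in %s (not in the chromosome map)",
                 name, context), call. = FALSE)
  as.integer(chrom_map[[name]])
}
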