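# FASTQ reading/writing (via Biostrings) and the batch name writer that
# enforces ID uniqueness, fixed hex width and the SRN correspondence file.

#' Read a FASTQ file
#'
#' @param path FASTQ file (Sanger qualities).
#' @return A list with character vectors `names`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  if (file.size(path) == 0L)
    return(list(names = character(0), seq = character(0), qual = character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(names = names(x),
       seq = as.character(x, use.names = FALSE),
       qual = as.character(S4Vectors::mcols(x)$qualities, use.names = FALSE))
}

#' Write a FASTQ file
#'
#' @param path Output file.
#' @param names,seq,qual Parallel character vectors.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(path, names, seq, qual) {
  stopifnot(length(names) == length(seq), length(seq) == length(qual))
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- names
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Correspondence-file path for an RNF FASTQ
#' @param fastq_path Path of the RNF FASTQ file.
#' @return The sibling path with suffix `.sl.tsv`.
#' @export
correspondence_path <- function(fastq_path) paste0(fastq_path, ".sl.tsv")

#' Assign final read names to a batch of tuples
#'
#' Applies the naming policy to every tuple of one output file: checks ID
#' uniqueness, fixes the hexadecimal width at the number of digits of the
#' largest ID, emits the long name unless it exceeds the length limit,
#' and collects (SRN, LRN) correspondence rows for tuples that fell back
#' to the short name.
#'
#' @param tuples List of [rnf_tuple] objects.
#' @param policy An [rnf_policy]; its `id_hex_width` is overridden by the
#'   batch width unless `fixed_width = TRUE`.
#' @param fixed_width Keep `policy$id_hex_width` instead of deriving it.
#' @return List with `names` (character, one per tuple), `used_srn`
#'   (logical vector) and `correspondence` (data.frame with columns
#'   `srn`, `lrn`, zero rows when no fallback occurred).
#' @export
name_batch <- function(tuples, policy = rnf_policy(), fixed_width = FALSE) {
  if (!length(tuples))
    return(list(names = character(0), used_srn = logical(0),
                correspondence = data.frame(srn = character(0), lrn = character(0),
                                            stringsAsFactors = FALSE)))
  ids <- vapply(tuples, `[[`, integer(1), "tuple_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate tuple IDs in batch: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  if (!fixed_width)
    policy <- rnf_policy(hex_width_for(max(ids)), policy$max_lrn_length,
                         policy$srn_fallback)
  names <- character(length(tuples))
  used <- logical(length(tuples))
  srn <- character(0); lrn <- character(0)
  for (i in seq_along(tuples)) {
    ch <- choose_name(tuples[[i]], policy)
    names[i] <- ch$name
    used[i] <- ch$used_srn
    if (ch$used_srn) { srn <- c(srn, ch$srn); lrn <- c(lrn, ch$lrn) }
  }
  list(names = names, used_srn = used,
       correspondence = data.frame(srn = srn, lrn = lrn, stringsAsFactors = FALSE))
}

#' Write an RNF FASTQ plus its correspondence file
#'
#' @param path Output FASTQ path.
#' @param tuples List of [rnf_tuple] objects, one per record.
#' @param seq,qual Parallel character vectors of sequences and qualities.
#' @param policy An [rnf_policy].
#' @param write_correspondence Write the (possibly empty) `.sl.tsv`
#'   correspondence file alongside the FASTQ.
#' @return List with `fastq`, `correspondence` paths and the `names` used.
#' @export
write_rnf_fastq <- function(path, tuples, seq, qual, policy = rnf_policy(),
                            write_correspondence = TRUE) {
  nb <- name_batch(tuples, policy)
  write_fastq(path, nb$names, seq, qual)
  cp <- correspondence_path(path)
  if (write_correspondence)
    write_correspondence_file(cp, nb$correspondence)
  invisible(list(fastq = path, correspondence = if (write_correspondence) cp else NULL,
                 names = nb$names, used_srn = nb$used_srn))
}

#' Write an SRN-LRN correspondence table
#' @param path Output TSV path (two columns, no header).
#' @param correspondence Data frame with columns `srn`, `lrn`.
#' @return `path`, invisibly.
#' @export
write_correspondence_file <- function(path, correspondence) {
  utils::write.table(correspondence[, c("srn", "lrn"), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SRN-LRN correspondence table
#' @param path TSV path written by [write_correspondence_file()].
#' @return Named character vector mapping SRN to LRN.
#' @export
read_correspondence_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = "character", comment.char = "")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Decode all names of an RNF FASTQ
#'
#' @param path RNF FASTQ file.
#' @param correspondence Optional named character vector (SRN to LRN) for
#'   resolving short names; defaults to the sibling `.sl.tsv` if present.
#' @return List with `records` (the [read_fastq()] result) and `tuples`
#'   (list of decoded [rnf_tuple] objects).
#' @export
read_rnf_fastq <- function(path, correspondence = NULL) {
  rec <- read_fastq(path)
  if (is.null(correspondence)) {
    cp <- correspondence_path(path)
    correspondence <- if (file.exists(cp)) read_correspondence_file(cp)
                      else stats::setNames(character(0), character(0))
  }
  tuples <- vector("list", length(rec$names))
  for (i in seq_along(rec$names)) {
    nm <- rec$names[[i]]
    if (startsWith(nm, "#")) {
      if (!nm %in% names(correspondence))
        stop(sprintf("record %d: SRN '%s' not found in correspondence file", i, nm),
             call. = FALSE)
      nm <- correspondence[[nm]]
    }
    tuples[[i]] <- tryCatch(decode_lrn(nm), error = function(e)
      stop(sprintf("record %d: %s", i, conditionMessage(e)), call. = FALSE))
  }
  list(records = rec, tuples = tuples)
}
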