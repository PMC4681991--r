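# LiftOver of RNF coordinates through a UCSC chain file.
#
# The chain format is parsed into its native 0-based half-open
# convention; conversion to RNF's 1-based closed coordinates happens at
# exactly one boundary (map_position), so off-by-ones cannot multiply.
# Truth coordinates must never be approximate: a segment lifts only if
# BOTH endpoints map through the same chain to the same target
# chromosome; anything else comes back with coordinates zeroed and
# direction 'N'.

#' Load a UCSC chain file into a queryable index
#'
#' Each chain starts with a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd [id]`
#' followed by `size [dt dq]` block lines; block arithmetic is checked
#' against the header extents and inconsistencies are reported with
#' their line number. The source assembly is the `t` side.
#'
#' @param path Chain file.
#' @return An object of class `rnf_chain_index`.
#' @export
load_chain <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (f[1L] != "chain" || length(f) < 12L)
      stop(sprintf("chain parse error at line %d: expected a chain header", i),
           call. = FALSE)
    hdr <- list(score = as.numeric(f[2L]),
                t_name = f[3L], t_size = as.integer(f[4L]), t_strand = f[5L],
                t_start = as.integer(f[6L]), t_end = as.integer(f[7L]),
                q_name = f[8L], q_size = as.integer(f[9L]), q_strand = f[10L],
                q_start = as.integer(f[11L]), q_end = as.integer(f[12L]))
    if (hdr$t_strand != "+")
      stop(sprintf("chain parse error at line %d: tStrand must be '+'", i),
           call. = FALSE)
    header_line <- i
    i <- i + 1L
    sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
    repeat {
      if (i > n) stop(sprintf("chain parse error: truncated file after line %d", n),
                      call. = FALSE)
      b <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(b) == 1L && nzchar(b)) {
        sizes <- c(sizes, as.integer(b)); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        i <- i + 1L
        break
      } else if (length(b) == 3L) {
        sizes <- c(sizes, as.integer(b[1L]))
        dts <- c(dts, as.integer(b[2L])); dqs <- c(dqs, as.integer(b[3L]))
        i <- i + 1L
      } else {
        stop(sprintf("chain parse error at line %d: expected 'size dt dq' or final 'size'",
                     i), call. = FALSE)
      }
    }
    if (sum(sizes) + sum(dts) != hdr$t_end - hdr$t_start ||
        sum(sizes) + sum(dqs) != hdr$q_end - hdr$q_start)
      stop(sprintf("chain parse error: block sizes of chain at line %d do not sum to the header extents",
                   header_line), call. = FALSE)
    t0 <- hdr$t_start + c(0L, cumsum(sizes + dts))[seq_along(sizes)]
    q0 <- hdr$q_start + c(0L, cumsum(sizes + dqs))[seq_along(sizes)]
    hdr$blocks <- data.frame(t_start = t0, t_end = t0 + sizes, q_start = q0,
                             size = sizes)
    chains[[length(chains) + 1L]] <- hdr
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  # Highest score wins when chains overlap; ties broken by file order.
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"), seq_along(chains))
  structure(list(chains = chains[ord]), class = "rnf_chain_index")
}

# Map one 1-based source position. Returns NULL when unmappable, else
# list(chrom, pos [1-based target forward strand], strand, chain_idx).
map_position <- function(index, chrom, pos) {
  p0 <- pos - 1L
  for (ci in seq_along(index$chains)) {
    ch <- index$chains[[ci]]
    if (ch$t_name != chrom) next
    b <- ch$blocks
    hit <- which(b$t_start <= p0 & p0 < b$t_end)
    if (!length(hit)) next
    off <- p0 - b$t_start[hit[1L]]
    q0 <- b$q_start[hit[1L]] + off
    if (ch$q_strand == "-") q0 <- ch$q_size - 1L - q0
    return(list(chrom = ch$q_name, pos = q0 + 1L, strand = ch$q_strand,
                chain_idx = ci))
  }
  NULL
}

flip_direction <- function(d) switch(d, F = "R", R = "F", "N")

#' Lift one RNF segment through a chain index
#'
#' Both endpoints are mapped independently; the segment lifts only when
#' both map through the same chain (hence the same target chromosome and
#' strand) and the lifted interval has the same length as the source
#' interval, so endpoints straddling an indel gap never produce an
#' approximated interval. On a reverse-strand chain the interval endpoints swap and
#' the direction flips. Any failure -- an endpoint in a chain gap, the
#' endpoints straddling two chains, an unresolvable chromosome -- yields
#' the segment with coordinates zeroed and direction `'N'`, never a
#' fabricated interval. Already-unknown segments pass through unchanged.
#'
#' @param segment An [rnf_segment].
#' @param index An `rnf_chain_index` from [load_chain()].
#' @param src_names Character vector mapping chromosome ID (position in
#'   the vector) to source chromosome name.
#' @param tgt_map Named integer vector mapping target chromosome name to
#'   chromosome ID.
#' @return A list: `segment` (the lifted or zeroed [rnf_segment]) and
#'   `lifted` (logical).
#' @export
lift_segment <- function(segment, index, src_names, tgt_map) {
  unknown <- function() {
    list(segment = rnf_segment(segment$genome_id, segment$chromosome_id, "N",
                               0L, 0L),
         lifted = FALSE)
  }
  if (segment$left == 0L || segment$right == 0L || segment$direction == "N" ||
      segment$chromosome_id == 0L)
    return(list(segment = segment, lifted = FALSE))
  if (segment$chromosome_id > length(src_names))
    return(unknown())
  chrom <- src_names[[segment$chromosome_id]]
  a <- map_position(index, chrom, segment$left)
  b <- map_position(index, chrom, segment$right)
  if (is.null(a) || is.null(b) || a$chain_idx != b$chain_idx)
    return(unknown())
  # Endpoints straddling an indel gap inside the chain would change the
  # segment's length; truth coordinates must never be approximate.
  if (abs(a$pos - b$pos) != segment$right - segment$left)
    return(unknown())
  if (!a$chrom %in% names(tgt_map)) return(unknown())
  new_chrom <- as.integer(tgt_map[[a$chrom]])
  left <- min(a$pos, b$pos); right <- max(a$pos, b$pos)
  dir <- if (a$strand == "-") flip_direction(segment$direction) else segment$direction
  list(segment = rnf_segment(segment$genome_id, new_chrom, dir, left, right),
       lifted = TRUE)
}

#' Lift every RNF name in a FASTQ file
#'
#' Decodes each record's name, lifts all its segments, re-sorts them and
#' re-encodes the name; the record count, tuple IDs, prefixes and
#' extensions are preserved. A summary TSV of lifted / unmapped /
#' unchanged segment counts is written alongside the output.
#'
#' @param input,output RNF FASTQ paths.
#' @param index An `rnf_chain_index`.
#' @param src_names,tgt_map As in [lift_segment()].
#' @param policy An [rnf_policy].
#' @return Invisible list with `output`, `summary` (path), and the
#'   counts `lifted`, `unmapped`, `passthrough`.
#' @export
lift_fastq <- function(input, output, index, src_names, tgt_map,
                       policy = rnf_policy()) {
  x <- read_rnf_fastq(input)
  n_lift <- 0L; n_unmap <- 0L; n_pass <- 0L
  tuples <- vector("list", length(x$tuples))
  for (i in seq_along(x$tuples)) {
    old <- x$tuples[[i]]
    reads <- lapply(old$reads, function(r) lapply(r, function(seg) {
      was_known <- seg$left > 0L && seg$right > 0L && seg$direction != "N" &&
        seg$chromosome_id > 0L
      res <- lift_segment(seg, index, src_names, tgt_map)
      if (res$lifted) n_lift <<- n_lift + 1L
      else if (was_known) n_unmap <<- n_unmap + 1L
      else n_pass <<- n_pass + 1L
      res$segment
    }))
    tuples[[i]] <- rnf_tuple(old$tuple_id, old$prefix, reads, old$extensions)
  }
  nb <- name_batch(tuples, policy)
  write_fastq(output, nb$names, x$records$seq, x$records$qual)
  write_correspondence_file(correspondence_path(output), nb$correspondence)
  sm <- paste0(output, ".liftover.tsv")
  utils::write.table(
    data.frame(lifted = n_lift, unmapped = n_unmap, passthrough = n_pass),
    sm, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(output = output, summary = sm, lifted = n_lift,
                 unmapped = n_unmap, passthrough = n_pass))
}
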