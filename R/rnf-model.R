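# Core RNF data model: segments, read tuples, naming policy, and the
# canonical long/short read-name encoder, decoder and validator.

#' Create an RNF segment
#'
#' A segment is one spatially distinct origin interval of a read:
#' the source genome, the chromosome, the strand, and the leftmost and
#' rightmost 1-based inclusive coordinates. Zero encodes "unknown" for
#' the numeric fields and `"N"` for the direction (the convention used
#' for, e.g., random contaminating reads whose placement is unspecified).
#'
#' @param genome_id Integer >= 0; 0 means the source genome is unknown.
#' @param chromosome_id Integer >= 0; 0 means the chromosome is unknown.
#' @param direction One of `"F"`, `"R"`, `"N"`.
#' @param left,right Integers >= 0; 1-based inclusive interval endpoints,
#'   0 meaning unknown. When both are positive, `left <= right` is required.
#' @return An object of class `rnf_segment`.
#' @examples
#' rnf_segment(1, 2, "F", 100, 199)
#' rnf_segment(1, 0, "N", 0, 0)   # contaminant-style unknown placement
#' @export
rnf_segment <- function(genome_id = 0L, chromosome_id = 0L, direction = "N",
                        left = 0L, right = 0L) {
  seg <- structure(
    list(genome_id = as.integer(genome_id),
         chromosome_id = as.integer(chromosome_id),
         direction = as.character(direction),
         left = as.integer(left),
         right = as.integer(right)),
    class = "rnf_segment")
  err <- segment_violations(seg)
  if (length(err)) stop("invalid segment: ", paste(err, collapse = "; "),
                        call. = FALSE)
  seg
}

# Violations of the segment invariants; character(0) when valid.
segment_violations <- function(seg) {
  v <- character(0)
  num <- c("genome_id", "chromosome_id", "left", "right")
  for (f in num) {
    x <- seg[[f]]
    if (length(x) != 1L || is.na(x) || x < 0L)
      v <- c(v, sprintf("field '%s' must be a single integer >= 0", f))
  }
  if (!is.character(seg$direction) || length(seg$direction) != 1L ||
      !seg$direction %in% c("F", "R", "N"))
    v <- c(v, sprintf("invalid direction '%s'", paste(seg$direction, collapse = ",")))
  if (!length(v) && seg$left > 0L && seg$right > 0L && seg$left > seg$right)
    v <- c(v, sprintf("left > right (%d > %d)", seg$left, seg$right))
  v
}

#' @export
print.rnf_segment <- function(x, ...) {
  cat("<rnf_segment> ", encode_segment(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rnf_segment <- function(x, ...) encode_segment(x)

seg_equal <- function(a, b) {
  a$genome_id == b$genome_id && a$chromosome_id == b$chromosome_id &&
    a$direction == b$direction && a$left == b$left && a$right == b$right
}

#' Create an RNF read tuple
#'
#' A read tuple is everything sequenced from one fragment of DNA: a
#' single-end read is a tuple with one read, a paired-end read is a tuple
#' with two reads, and a chimeric read is a single read with two or more
#' segments. Each read is an ordered chain of at least one segment.
#'
#' @param tuple_id Integer >= 1; unique within any emitted file (uniqueness
#'   is enforced by the batch FASTQ writer, not here).
#' @param prefix String over `[A-Za-z0-9-]`; must not contain `"__"`.
#'   May be empty.
#' @param reads List of reads; each read is a list of [rnf_segment] objects
#'   (or a single segment, promoted to a one-segment read).
#' @param extensions List of `c(tag, value)` pairs (or 2-element lists)
#'   carried in the name suffix as `[tag:value]` units. Tags are
#'   alphanumeric; values may not contain `[`, `]` or `_`.
#' @return An object of class `rnf_tuple`.
#' @seealso [rnf_read()] for declaring a chimeric read explicitly.
#' @examples
#' rnf_tuple(1, "sim", list(rnf_segment(1, 2, "F", 100, 199)))
#' @export
rnf_tuple <- function(tuple_id, prefix = "", reads, extensions = list()) {
  if (inherits(reads, "rnf_segment")) reads <- list(list(reads))
  reads <- lapply(reads, function(r) {
    if (inherits(r, "rnf_segment")) r <- list(r)
    if (!length(r)) stop("every read must have at least one segment", call. = FALSE)
    for (s in r)
      if (!inherits(s, "rnf_segment")) stop("reads must contain rnf_segment objects",
                                            call. = FALSE)
    r
  })
  if (!length(reads)) stop("a read tuple must contain at least one read", call. = FALSE)
  tuple_id <- as.integer(tuple_id)
  if (is.na(tuple_id) || tuple_id < 1L)
    stop("tuple_id must be >= 1", call. = FALSE)
  check_prefix(prefix)
  extensions <- lapply(extensions, function(e) {
    e <- as.character(unlist(e, use.names = FALSE))
    if (length(e) != 2L) stop("each extension must be a (tag, value) pair", call. = FALSE)
    if (!grepl("^[A-Za-z0-9]+$", e[1L]))
      stop(sprintf("invalid extension tag '%s'", e[1L]), call. = FALSE)
    if (grepl("[][_]", e[2L]))
      stop(sprintf("extension value '%s' contains a forbidden character", e[2L]),
           call. = FALSE)
    e
  })
  structure(list(tuple_id = tuple_id, prefix = prefix, reads = reads,
                 extensions = extensions),
            class = "rnf_tuple")
}

check_prefix <- function(prefix) {
  if (!is.character(prefix) || length(prefix) != 1L || is.na(prefix))
    stop("prefix must be a single string", call. = FALSE)
  if (grepl("__", prefix, fixed = TRUE))
    stop("prefix must not contain '__'", call. = FALSE)
  if (nchar(prefix) && !grepl("^[A-Za-z0-9-]+$", prefix))
    stop(sprintf("prefix '%s' contains characters outside [A-Za-z0-9-]", prefix),
         call. = FALSE)
  invisible(prefix)
}

#' Declare a read (an ordered chain of segments)
#'
#' Chimeric reads -- reads spanning a genomic fusion, long deletion or
#' translocation -- must carry at least two segments; declaring a read
#' chimeric with fewer is refused.
#'
#' @param segments List of [rnf_segment] objects (a single segment is
#'   promoted to a one-element list).
#' @param chimeric Logical; defaults to `TRUE` exactly when the read has
#'   two or more segments. Passing `chimeric = TRUE` with fewer than two
#'   segments is an error.
#' @return The read: a list of segments with logical attribute `chimeric`.
#' @export
rnf_read <- function(segments, chimeric = length(segments) >= 2L) {
  if (inherits(segments, "rnf_segment")) segments <- list(segments)
  if (!length(segments)) stop("a read must have at least one segment", call. = FALSE)
  if (isTRUE(chimeric) && length(segments) < 2L)
    stop("a chimeric read must have at least two segments", call. = FALSE)
  structure(segments, chimeric = isTRUE(chimeric))
}

#' Flat list of all segments of a tuple
#' @param tuple An [rnf_tuple].
#' @return List of [rnf_segment] objects, in read order (unsorted).
#' @export
tuple_segments <- function(tuple) {
  stopifnot(inherits(tuple, "rnf_tuple"))
  unlist(tuple$reads, recursive = FALSE)
}

#' @export
print.rnf_tuple <- function(x, ...) {
  cat(sprintf("<rnf_tuple> id=%d prefix='%s' reads=%d segments=%d extensions=%d\n",
              x$tuple_id, x$prefix, length(x$reads),
              length(tuple_segments(x)), length(x$extensions)))
  invisible(x)
}

#' Naming policy for RNF encoders
#'
#' @param id_hex_width Zero-padding width of the hexadecimal tuple ID
#'   (lowercase hex; fixed width makes lexicographic order equal numeric
#'   order within a batch).
#' @param max_lrn_length Maximum length of a long read name before the
#'   short-name fallback triggers. The default is 255, the maximum read
#'   name length permitted in SAM; a name of exactly 255 characters is
#'   kept, 256 triggers the fallback.
#' @param srn_fallback Logical; whether [choose_name()] may fall back to
#'   the short read name at all. When `FALSE` an over-long name is an error.
#' @return An object of class `rnf_policy`.
#' @export
rnf_policy <- function(id_hex_width = 1L, max_lrn_length = 255L,
                       srn_fallback = TRUE) {
  id_hex_width <- as.integer(id_hex_width)
  if (is.na(id_hex_width) || id_hex_width < 1L)
    stop("id_hex_width must be >= 1", call. = FALSE)
  structure(list(id_hex_width = id_hex_width,
                 max_lrn_length = as.integer(max_lrn_length),
                 srn_fallback = isTRUE(srn_fallback)),
            class = "rnf_policy")
}

#' Sort segments by the canonical RNF keys
#'
#' Segments inside a long read name are sorted by source genome,
#' chromosome, left coordinate, right coordinate, and direction. The
#' direction order is by character code (`F < N < R`); the sort is
#' stable and a total order, so the output is independent of input order.
#'
#' @param segments List of [rnf_segment] objects.
#' @return The same segments in canonical order.
#' @export
sort_segments <- function(segments) {
  if (!length(segments)) return(segments)
  g <- vapply(segments, `[[`, integer(1), "genome_id")
  c <- vapply(segments, `[[`, integer(1), "chromosome_id")
  l <- vapply(segments, `[[`, integer(1), "left")
  r <- vapply(segments, `[[`, integer(1), "right")
  d <- vapply(segments, `[[`, character(1), "direction")
  segments[order(g, c, l, r, d, method = "radix")]
}

#' Encode one segment as its parenthesized RNF string
#'
#' Renders `(genome_id,chromosome_id,direction,left,right)` with decimal
#' integers and no whitespace; unknown values render as `0` (`N` for the
#' direction).
#'
#' @param segment An [rnf_segment].
#' @return A single string.
#' @export
encode_segment <- function(segment) {
  err <- segment_violations(segment)
  if (length(err)) stop("invalid segment: ", paste(err, collapse = "; "),
                        call. = FALSE)
  sprintf("(%d,%d,%s,%d,%d)", segment$genome_id, segment$chromosome_id,
          segment$direction, segment$left, segment$right)
}

.seg_re <- "\\((\\d+),(\\d+),([A-Za-z]),(\\d+),(\\d+)\\)"

#' Decode one parenthesized segment string
#' @param text A string like `"(1,2,F,100,199)"`.
#' @return An [rnf_segment].
#' @export
decode_segment <- function(text) {
  m <- regexpr(paste0("^", .seg_re, "$"), text, perl = TRUE)
  if (m == -1L)
    stop(sprintf("malformed segment '%s'", text), call. = FALSE)
  p <- sub(paste0("^", .seg_re, "$"), "\\1\034\\2\034\\3\034\\4\034\\5", text,
           perl = TRUE)
  p <- strsplit(p, "\034", fixed = TRUE)[[1L]]
  rnf_segment(as.integer(p[1L]), as.integer(p[2L]), p[3L],
              as.integer(p[4L]), as.integer(p[5L]))
}

format_hex_id <- function(id, width) {
  sprintf("%0*x", as.integer(width), as.integer(id))
}

encode_extensions <- function(extensions) {
  if (!length(extensions)) return("")
  paste(vapply(extensions, function(e) sprintf("[%s:%s]", e[1L], e[2L]),
               character(1)), collapse = "")
}

decode_extensions <- function(suffix) {
  if (!nchar(suffix)) return(list())
  re <- "\\[([A-Za-z0-9]+):([^][_]*)\\]"
  m <- gregexpr(re, suffix, perl = TRUE)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(suffix))
    stop(sprintf("malformed extension suffix '%s'", suffix), call. = FALSE)
  units <- regmatches(suffix, gregexpr(re, suffix, perl = TRUE))[[1L]]
  lapply(units, function(u) {
    c(sub(re, "\\1", u, perl = TRUE), sub(re, "\\2", u, perl = TRUE))
  })
}

# Split on "__" keeping trailing empty fields (strsplit drops them).
split_name_parts <- function(name) {
  parts <- strsplit(paste0(name, "\034"), "__", fixed = TRUE)[[1L]]
  parts[length(parts)] <- sub("\034$", "", parts[length(parts)])
  parts
}

#' Encode the long read name (LRN) of a tuple
#'
#' An LRN has four parts joined by double underscore: the prefix, the
#' zero-padded lowercase hexadecimal tuple ID, the comma-separated block
#' of all segments of all reads in canonical sorted order, and the
#' extension suffix (empty when there are no extensions). Because all
#' segments are sorted jointly, read membership is not recoverable from
#' the name; it is carried by FASTQ file pairing instead.
#'
#' @param tuple An [rnf_tuple].
#' @param policy An [rnf_policy]; controls the hex ID width.
#' @return A single string that splits on `"__"` into exactly 4 fields.
#' @export
encode_lrn <- function(tuple, policy = rnf_policy()) {
  stopifnot(inherits(tuple, "rnf_tuple"), inherits(policy, "rnf_policy"))
  check_prefix(tuple$prefix)
  segs <- sort_segments(tuple_segments(tuple))
  block <- paste(vapply(segs, encode_segment, character(1)), collapse = ",")
  paste(tuple$prefix, format_hex_id(tuple$tuple_id, policy$id_hex_width),
        block, encode_extensions(tuple$extensions), sep = "__")
}

#' Encode the short read name (SRN) of a tuple
#'
#' The SRN is `"#"` followed by the zero-padded lowercase hexadecimal
#' tuple ID; it is used when the long name would exceed the policy's
#' length limit, together with an SRN-LRN correspondence file.
#'
#' @inheritParams encode_lrn
#' @return A single string.
#' @export
encode_srn <- function(tuple, policy = rnf_policy()) {
  stopifnot(inherits(tuple, "rnf_tuple"))
  if (tuple$tuple_id < 1L) stop("tuple_id must be >= 1", call. = FALSE)
  paste0("#", format_hex_id(tuple$tuple_id, policy$id_hex_width))
}

#' Decode a long read name
#'
#' Inverse of [encode_lrn()] on its image: recovers the tuple ID, prefix,
#' extensions and the sorted segment list. Read-boundary grouping is not
#' encoded in the name, so all segments come back as a single chain.
#'
#' @param name An LRN string.
#' @return An [rnf_tuple] whose single read holds the sorted segments.
#' @export
decode_lrn <- function(name) {
  parts <- split_name_parts(name)
  if (length(parts) != 4L)
    stop(sprintf("malformed LRN '%s': expected 4 parts, found %d",
                 name, length(parts)), call. = FALSE)
  prefix <- parts[1L]
  if (!grepl("^[0-9a-fA-F]+$", parts[2L]))
    stop(sprintf("malformed LRN '%s': non-hexadecimal ID '%s'", name, parts[2L]),
         call. = FALSE)
  id <- strtoi(parts[2L], 16L)
  seg_texts <- strsplit(parts[3L], ",(?=\\()", perl = TRUE)[[1L]]
  if (!length(seg_texts) || !nchar(parts[3L]))
    stop(sprintf("malformed LRN '%s': empty segment block", name), call. = FALSE)
  segs <- vector("list", length(seg_texts))
  for (i in seq_along(seg_texts)) {
    segs[[i]] <- tryCatch(decode_segment(seg_texts[[i]]), error = function(e)
      stop(sprintf("malformed LRN '%s': segment %d: %s", name, i,
                   conditionMessage(e)), call. = FALSE))
  }
  rnf_tuple(id, prefix, list(segs), decode_extensions(parts[4L]))
}

#' Decode a short read name
#' @param name An SRN string (`"#"` + hex ID).
#' @return The integer tuple ID.
#' @export
decode_srn <- function(name) {
  if (!grepl("^#[0-9a-fA-F]+$", name))
    stop(sprintf("malformed SRN '%s'", name), call. = FALSE)
  strtoi(sub("^#", "", name), 16L)
}

#' Choose between the long and the short read name
#'
#' Returns the LRN when its length is within the policy limit (a name of
#' exactly `max_lrn_length` characters is kept); otherwise returns the
#' SRN and flags that an SRN-LRN correspondence record must be written.
#'
#' @inheritParams encode_lrn
#' @return A list with elements `name`, `used_srn` (logical), `lrn`, `srn`.
#' @export
choose_name <- function(tuple, policy = rnf_policy()) {
  lrn <- encode_lrn(tuple, policy)
  if (nchar(lrn) <= policy$max_lrn_length)
    return(list(name = lrn, used_srn = FALSE, lrn = lrn, srn = NULL))
  if (!policy$srn_fallback)
    stop(sprintf("LRN of tuple %d has %d characters (limit %d) and SRN fallback is disabled",
                 tuple$tuple_id, nchar(lrn), policy$max_lrn_length), call. = FALSE)
  srn <- encode_srn(tuple, policy)
  list(name = srn, used_srn = TRUE, lrn = lrn, srn = srn)
}

#' Check whether a name looks like RNF at all
#' @param name A candidate read name.
#' @return `TRUE` for SRN-shaped names (`#` prefix) and 4-part LRN-shaped
#'   names, without validating the parts.
#' @export
is_rnf_name <- function(name) {
  startsWith(name, "#") || length(split_name_parts(name)) == 4L
}

#' Validate a read name against the RNF grammar
#'
#' Lints a candidate name and reports every defect found; an empty
#' character vector means the name is a well-formed LRN or SRN and all
#' segment invariants hold.
#'
#' @param name A candidate read name.
#' @return Character vector of violation messages (possibly empty).
#' @export
validate_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    return("name must be a single string")
  if (startsWith(name, "#")) {
    if (!grepl("^#[0-9a-fA-F]+$", name))
      return(sprintf("malformed SRN '%s': expected '#' followed by hexadecimal digits", name))
    if (strtoi(sub("^#", "", name), 16L) < 1L)
      return("tuple ID must be >= 1")
    return(character(0))
  }
  v <- character(0)
  parts <- split_name_parts(name)
  if (length(parts) != 4L)
    return(sprintf("expected 4 '__'-delimited parts, found %d", length(parts)))
  if (nchar(parts[1L]) && !grepl("^[A-Za-z0-9-]+$", parts[1L]))
    v <- c(v, sprintf("prefix '%s' contains characters outside [A-Za-z0-9-]", parts[1L]))
  if (!grepl("^[0-9a-fA-F]+$", parts[2L]))
    v <- c(v, sprintf("ID '%s' is not hexadecimal", parts[2L]))
  else if (strtoi(parts[2L], 16L) < 1L)
    v <- c(v, "tuple ID must be >= 1")
  if (!nchar(parts[3L])) {
    v <- c(v, "empty segment block")
  } else {
    seg_texts <- strsplit(parts[3L], ",(?=\\()", perl = TRUE)[[1L]]
    for (i in seq_along(seg_texts)) {
      st <- seg_texts[[i]]
      m <- regexpr(paste0("^", .seg_re, "$"), st, perl = TRUE)
      if (m == -1L) {
        v <- c(v, sprintf("segment %d ('%s') is malformed", i, st))
        next
      }
      fields <- strsplit(gsub("[()]", "", st), ",", fixed = TRUE)[[1L]]
      if (!fields[3L] %in% c("F", "R", "N"))
        v <- c(v, sprintf("invalid direction '%s'", fields[3L]))
      l <- as.integer(fields[4L]); r <- as.integer(fields[5L])
      if (l > 0L && r > 0L && l > r)
        v <- c(v, sprintf("segment %d: left > right (%d > %d)", i, l, r))
    }
  }
  if (nchar(parts[4L])) {
    ok <- tryCatch({ decode_extensions(parts[4L]); TRUE }, error = function(e) FALSE)
    if (!ok) v <- c(v, sprintf("malformed extension suffix '%s'", parts[4L]))
  }
  v
}

#' Hexadecimal width needed for a batch of tuple IDs
#'
#' The batch-level ID width is the number of hex digits of the largest ID
#' in the batch, so all names in one file share a fixed width and sort
#' lexicographically in numeric order.
#'
#' @param max_id Largest tuple ID in the batch.
#' @return Integer width >= 1.
#' @export
hex_width_for <- function(max_id) {
  max_id <- max(1L, as.integer(max_id))
  nchar(sprintf("%x", max_id))
}
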