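# MAF (UCSC Multiple Alignment Format) reading and block-aligned chunking.
#
# A MAF file is a series of alignment blocks. Each block starts with an "a"
# line (optionally carrying key=value pairs such as score=), followed by one
# "s" line per aligned sequence:
#
#   s src start size strand srcSize text
#
# start is strand-relative and 0-based, size is the ungapped length, text is
# the gapped alignment row. "i", "e" and "q" lines may appear and carry no
# alignment text needed here; they are skipped. Blocks are separated by blank
# lines; "#" lines are comments.

#' Construct one aligned sequence (an "s" line of a MAF block)
#'
#' @param src source identifier, conventionally `"genome.chromosome"`.
#' @param start 0-based strand-relative start of the aligned slice.
#' @param size ungapped length of the aligned slice.
#' @param strand `"+"` or `"-"`.
#' @param src_size full length of the source sequence.
#' @param text gapped alignment text (`"-"` is the gap character).
#' @return an object of class `aligned_sequence`.
#' @export
aligned_sequence <- function(src, start, size, strand, src_size, text) {
  stopifnot(is.character(src), length(src) == 1L,
            is.character(text), length(text) == 1L)
  start <- as.integer(start); size <- as.integer(size); src_size <- as.integer(src_size)
  if (is.na(start) || start < 0L) stop("aligned_sequence: start must be >= 0")
  if (is.na(size) || size < 0L) stop("aligned_sequence: size must be >= 0")
  if (!strand %in% c("+", "-")) stop("aligned_sequence: strand must be '+' or '-'")
  if (is.na(src_size) || src_size <= 0L) stop("aligned_sequence: src_size must be > 0")
  ungapped_n <- nchar(gsub("-", "", text, fixed = TRUE))
  if (ungapped_n != size) {
    stop(sprintf("aligned_sequence: size %d does not match %d non-gap characters in text",
                 size, ungapped_n))
  }
  if (start + size > src_size) {
    stop(sprintf("aligned_sequence: start + size (%d) exceeds src_size (%d)",
                 start + size, src_size))
  }
  structure(list(src = src, start = start, size = size, strand = strand,
                 src_size = src_size, text = text),
            class = "aligned_sequence")
}

#' Construct an alignment block
#'
#' @param sequences list of [aligned_sequence()] objects; the first is the
#'   block's reference sequence. All gapped texts must have equal length.
#' @param score optional numeric block score (from the `a score=` line).
#' @param file_offset byte offset of the block's "a" line in its file, when known.
#' @return an object of class `alignment_block`.
#' @export
alignment_block <- function(sequences, score = NA_real_, file_offset = NA_integer_) {
  if (length(sequences) < 1L) stop("alignment_block: needs at least one sequence")
  widths <- vapply(sequences, function(s) nchar(s$text), integer(1))
  if (length(unique(widths)) != 1L) {
    stop("alignment_block: sequences have unequal gapped text lengths")
  }
  structure(list(score = as.numeric(score), sequences = sequences,
                 file_offset = file_offset),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block: %d sequences, width %d, score %s>\n",
              length(x$sequences), nchar(x$sequences[[1]]$text),
              ifelse(is.na(x$score), "NA", format(x$score))))
  invisible(x)
}

maf_input_lines <- function(input) {
  if (inherits(input, "connection")) {
    lines <- readLines(input, warn = FALSE)
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("\n", input, fixed = TRUE) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else if (is.character(input)) {
    # split embedded newlines but keep empty elements (strsplit("", ...) would
    # drop them, shifting byte offsets)
    lines <- unlist(lapply(input, function(x) {
      if (grepl("\n", x, fixed = TRUE)) strsplit(x, "\n", fixed = TRUE)[[1]] else x
    }), use.names = FALSE)
  } else {
    stop("parse_maf: input must be a file path, connection, or character vector")
  }
  lines
}

parse_s_line <- function(line, lineno) {
  fields <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(fields) != 7L) {
    stop(sprintf("MAF parse error at line %d: 's' line has %d fields, expected 7",
                 lineno, length(fields)), call. = FALSE)
  }
  start <- suppressWarnings(as.integer(fields[3]))
  size <- suppressWarnings(as.integer(fields[4]))
  src_size <- suppressWarnings(as.integer(fields[6]))
  if (anyNA(c(start, size, src_size))) {
    stop(sprintf("MAF parse error at line %d: non-integer start/size/srcSize field", lineno),
         call. = FALSE)
  }
  if (!fields[5] %in% c("+", "-")) {
    stop(sprintf("MAF parse error at line %d: strand must be '+' or '-'", lineno),
         call. = FALSE)
  }
  text <- fields[7]
  ungapped_n <- nchar(gsub("-", "", text, fixed = TRUE))
  if (ungapped_n != size) {
    stop(sprintf("MAF parse error at line %d: declared size %d but text has %d non-gap characters",
                 lineno, size, ungapped_n), call. = FALSE)
  }
  if (start + size > src_size) {
    stop(sprintf("MAF parse error at line %d: start + size exceeds srcSize", lineno),
         call. = FALSE)
  }
  aligned_sequence(fields[2], start, size, fields[5], src_size, text)
}

#' Parse a MAF stream into alignment blocks
#'
#' Comments (`#`) are allowed anywhere; any number of blank lines may separate
#' blocks; `i`, `e` and `q` lines are skipped. Sequence case is preserved.
#' An empty input yields an empty list. Malformed `s` lines raise an error
#' naming the offending line number.
#'
#' @param input file path, connection, or character vector of MAF text.
#' @param offset0 byte offset of the first line (used when parsing a chunk of
#'   a larger file, so block `file_offset`s stay file-absolute).
#' @return list of [alignment_block()] in file order.
#' @export
parse_maf <- function(input, offset0 = 0L) {
  lines <- maf_input_lines(input)
  # byte offset of the start of each line, assuming "\n" terminators
  offsets <- offset0 + c(0, cumsum(nchar(lines, type = "bytes") + 1L))[seq_along(lines)]

  blocks <- list()
  cur_score <- NA_real_
  cur_offset <- NA_integer_
  cur_seqs <- list()
  in_block <- FALSE
  block_line <- NA_integer_

  flush_block <- function() {
    if (!in_block) return(invisible())
    if (length(cur_seqs) == 0L) {
      log_debug("dropping block with no 's' lines at line ", block_line)
    } else {
      widths <- vapply(cur_seqs, function(s) nchar(s$text), integer(1))
      if (length(unique(widths)) != 1L) {
        stop(sprintf("MAF parse error: block starting at line %d has unequal gapped text lengths",
                     block_line), call. = FALSE)
      }
      blocks[[length(blocks) + 1L]] <<- alignment_block(cur_seqs, cur_score, cur_offset)
    }
    in_block <<- FALSE
    cur_seqs <<- list()
    cur_score <<- NA_real_
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^\\s*$", line)) { flush_block(); next }
    first <- substr(line, 1L, 1L)
    if (first == "#") next
    if (first == "a" && grepl("^a(\\s|$)", line)) {
      flush_block()
      in_block <- TRUE
      block_line <- i
      cur_offset <- offsets[i]
      m <- regmatches(line, regexec("score=([-+0-9.eE]+)", line))[[1]]
      cur_score <- if (length(m) == 2L) as.numeric(m[2]) else NA_real_
      next
    }
    if (first == "s" && grepl("^s\\s", line)) {
      if (!in_block) {
        stop(sprintf("MAF parse error at line %d: 's' line outside an alignment block", i),
             call. = FALSE)
      }
      cur_seqs[[length(cur_seqs) + 1L]] <- parse_s_line(line, i)
      next
    }
    if (first %in% c("i", "e", "q") && grepl("^[ieq]\\s", line)) {
      log_debug("skipping '", first, "' line at line ", i)
      next
    }
    stop(sprintf("MAF parse error at line %d: unrecognised line type", i), call. = FALSE)
  }
  flush_block()
  blocks
}

#' Plan block-aligned byte ranges for parallel parsing
#'
#' Splits a MAF file into at most `n_chunks` contiguous byte ranges whose
#' boundaries coincide with the start of an "a" line (or end of file), so each
#' chunk parses to a whole number of blocks and per-chunk parses concatenate to
#' the single-pass parse.
#'
#' @param path MAF file path.
#' @param n_chunks upper bound on the number of ranges (>= 1).
#' @return object of class `chunk_plan`: a data frame with columns
#'   `byte_start`, `byte_end` (half-open), `n_blocks`, `first_block`
#'   (0-based index of the first block of the chunk in file order).
#' @export
chunk_maf <- function(path, n_chunks = 1L) {
  if (!file.exists(path)) stop("chunk_maf: cannot read '", path, "'")
  if (!is_count(n_chunks)) stop("chunk_maf: n_chunks must be a positive integer")
  n_chunks <- as.integer(n_chunks)

  lines <- readLines(path, warn = FALSE)
  offsets <- c(0, cumsum(nchar(lines, type = "bytes") + 1L))[seq_along(lines)]
  file_size <- file.size(path)
  a_offsets <- offsets[grepl("^a(\\s|$)", lines)]

  if (length(a_offsets) == 0L) {
    plan <- data.frame(byte_start = 0, byte_end = file_size,
                       n_blocks = 0L, first_block = 0L)
    class(plan) <- c("chunk_plan", class(plan))
    return(plan)
  }

  naive <- floor(file_size * seq_len(n_chunks - 1L) / n_chunks)
  snap <- vapply(naive, function(cut) {
    nxt <- a_offsets[a_offsets >= cut]
    if (length(nxt)) nxt[1] else as.numeric(file_size)
  }, numeric(1))
  bounds <- sort(unique(c(0, snap, file_size)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  n_blocks <- vapply(seq_along(starts), function(i) {
    sum(a_offsets >= starts[i] & a_offsets < ends[i])
  }, integer(1))
  keep <- ends > starts & (n_blocks > 0L | seq_along(starts) == 1L)
  starts <- starts[keep]; ends <- ends[keep]; n_blocks <- n_blocks[keep]
  # ranges must tile the file: extend each kept range to the next kept start
  if (length(starts)) {
    ends[-length(ends)] <- starts[-1]
    ends[length(ends)] <- file_size
    starts[1] <- 0
  }
  plan <- data.frame(byte_start = starts, byte_end = ends, n_blocks = n_blocks,
                     first_block = cumsum(c(0L, n_blocks[-length(n_blocks)])))
  class(plan) <- c("chunk_plan", class(plan))
  plan
}

#' Parse one byte range of a MAF file
#'
#' @param path MAF file path.
#' @param byte_start,byte_end half-open byte range, as planned by [chunk_maf()].
#' @return list of [alignment_block()] with file-absolute `file_offset`s.
#' @export
parse_maf_range <- function(path, byte_start, byte_end) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = byte_start)
  n <- byte_end - byte_start
  if (n <= 0) return(list())
  txt <- rawToChar(readBin(con, what = "raw", n = n))
  parse_maf(strsplit(txt, "\n", fixed = TRUE)[[1]], offset0 = as.integer(byte_start))
}

#' Serialize alignment blocks back to MAF text
#'
#' Round-trip helper used by the synthetic generator and the tests.
#'
#' @param blocks list of [alignment_block()].
#' @return character scalar of MAF text (with trailing newline).
#' @export
format_maf <- function(blocks) {
  out <- c("##maf version=1")
  for (b in blocks) {
    a <- if (is.na(b$score)) "a" else sprintf("a score=%s", format(b$score))
    s <- vapply(b$sequences, function(sq) {
      sprintf("s %s %d %d %s %d %s", sq$src, sq$start, sq$size, sq$strand,
              sq$src_size, sq$text)
    }, character(1))
    out <- c(out, a, s, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
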