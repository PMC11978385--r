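# Shared fixtures and independent oracles used across the test files.
# Everything is built in code; no binary fixtures.

SIM_DASH <- "–"  # reference-gap symbol in similarity vectors

# write MAF text to a temp file, returning the path
write_maf_tmp <- function(text) {
  path <- tempfile(fileext = ".maf")
  # format_maf already carries a trailing newline; writeLines adds one more
  writeLines(sub("\n$", "", text), path)
  path
}

# a tiny two-sequence block: searched "AC-GT" vs compared "ACAGT"
tiny_maf_lines <- function() {
  c("##maf version=1",
    "# synthetic two-sequence block",
    "a score=5.0",
    "s hg.chr1 10 4 + 100 AC-GT",
    "s mm.chr1 3 5 + 50 ACAGT",
    "")
}

# a deterministic 4-block MAF used by the chunking tests
four_block_maf <- function() {
  seqs <- c("ACGTACGTAC", "TTTTGGGGCC", "GATTACAGAT", "CCCCAAAATT")
  blocks <- lapply(seq_along(seqs), function(i) {
    alignment_block(list(
      aligned_sequence("g1.chr1", (i - 1L) * 10L, 10L, "+", 1000L, seqs[i]),
      aligned_sequence("g2.chr1", (i - 1L) * 10L, 10L, "+", 1000L,
                       chartr("ACGT", "CAGT", seqs[i]))
    ), score = i)
  })
  blocks
}

# strongly-informative consensus PWM for a given consensus sequence
consensus_pwm <- function(consensus, name = "toy", n = 100, background = NULL,
                          pseudocount = 0.1) {
  chars <- strsplit(toupper(consensus), NULL)[[1]]
  counts <- matrix(0, 4, length(chars), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(chars)) counts[chars[j], j] <- n
  pwm(name, counts, background = background, pseudocount = pseudocount)
}

# a fixed mixed-count 8-column PWM with a near-continuous score distribution
# (used by the calibration tests; counts chosen once, not tuned)
mixed_pwm8 <- function(background = NULL) {
  counts <- rbind(
    A = c(12,  3,  0,  7,  1,  9,  4,  2),
    C = c( 2, 10,  1,  5,  8,  0,  6,  3),
    G = c( 5,  1, 14,  2,  6,  4,  1,  8),
    T = c( 1,  6,  5,  6,  5,  7,  9,  7)
  )
  pwm("mixed8", counts, background = background)
}

# --- independent oracles ------------------------------------------------------

# naive O(n*m) multi-pattern scan: all overlapping occurrences, 0-based
oracle_kmer_hits <- function(patterns, ids, seq) {
  up <- toupper(seq)
  out <- list()
  for (i in seq_along(patterns)) {
    p <- toupper(patterns[i]); L <- nchar(p); n <- nchar(up)
    if (L > n) next
    for (s in 0:(n - L)) {
      if (substr(up, s + 1, s + L) == p) {
        out[[length(out) + 1L]] <- data.frame(
          motif_id = ids[i], u_start = s, u_end = s + L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif_id = character(0), u_start = integer(0),
                      u_end = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$u_start, df$motif_id), , drop = FALSE]
}

# direct per-window PWM scoring (no vectorised lookup)
oracle_pwm_hits <- function(p, seq) {
  up <- toupper(seq)
  L <- ncol(p$log_odds)
  n <- nchar(up)
  out <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      win <- strsplit(substr(up, s + 1, s + L), NULL)[[1]]
      idx <- match(win, c("A", "C", "G", "T"))
      if (anyNA(idx)) next
      sc <- 0
      for (j in seq_len(L)) sc <- sc + p$log_odds[idx[j], j]
      if (sc >= p$threshold) {
        out[[length(out) + 1L]] <- data.frame(u_start = s, u_end = s + L,
                                              score = sc)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(u_start = integer(0), u_end = integer(0), score = numeric(0)))
  }
  do.call(rbind, out)
}

# scan-and-resume regex matching via repeated regexpr (independent of gregexpr)
oracle_regex_hits <- function(pattern, seq) {
  out <- list()
  pos <- 1L
  n <- nchar(seq)
  while (pos <= n) {
    rest <- substr(seq, pos, n)
    m <- regexpr(pattern, rest, perl = TRUE, ignore.case = TRUE)
    if (m < 0) break
    len <- attr(m, "match.length")
    if (len > 0) {
      s <- pos + as.integer(m) - 2L   # 0-based start
      out[[length(out) + 1L]] <- data.frame(u_start = s, u_end = s + len)
      pos <- s + len + 1L
    } else {
      pos <- pos + as.integer(m)      # skip past a zero-length match
    }
  }
  if (!length(out)) {
    return(data.frame(u_start = integer(0), u_end = integer(0)))
  }
  do.call(rbind, out)
}

# exact enumeration of the null score distribution of a PWM for L <= 8:
# returns data.frame(score, prob) over all 4^L windows
oracle_enumerate_null <- function(p) {
  L <- ncol(p$log_odds)
  stopifnot(L <= 8)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(L)) {
    scores <- scores + p$log_odds[cbind(grid[, j], j)]
    probs <- probs * p$background[grid[, j]]
  }
  data.frame(score = scores, prob = probs)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
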