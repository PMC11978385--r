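# Search engine: gapped/ungapped coordinate mapping, an Aho-Corasick automaton
# for multi-k-mer search, PWM window scanning, regex scanning, and the
# per-block driver that turns raw matches into fully annotated motif hits.

#' Index the gap structure of a gapped alignment row
#'
#' @param text gapped string (`"-"` is the gap character).
#' @return object of class `gap_index`: `ungapped` (text with gaps removed) and
#'   `u2g`, a strictly increasing integer vector mapping each 0-based ungapped
#'   position to its 0-based gapped column.
#' @export
build_gap_index <- function(text) {
  chars <- strsplit(text, NULL)[[1]]
  keep <- chars != "-"
  structure(list(ungapped = paste(chars[keep], collapse = ""),
                 u2g = which(keep) - 1L,
                 gapped_length = length(chars)),
            class = "gap_index")
}

#' Map an ungapped span to gapped block columns
#'
#' @param index a [build_gap_index()] result.
#' @param u_start,u_end 0-based half-open span on the ungapped sequence.
#' @return integer vector `c(g_start, g_end)`, 0-based half-open gapped columns.
#' @export
map_to_gapped <- function(index, u_start, u_end) {
  n <- length(index$u2g)
  if (u_start < 0L || u_end <= u_start || u_end > n) {
    stop(sprintf("map_to_gapped: span [%d, %d) out of range for ungapped length %d",
                 u_start, u_end, n))
  }
  c(index$u2g[u_start + 1L], index$u2g[u_end] + 1L)
}

# ---- Aho-Corasick automaton --------------------------------------------------

# Build the automaton for a set of (uppercase) patterns: a trie with BFS
# failure links and merged output sets. Node 1 is the root; children are named
# integer vectors keyed by character.
ac_build <- function(patterns) {
  children <- list(integer(0))
  fail <- 1L
  out <- list(integer(0))
  for (p in seq_along(patterns)) {
    chs <- strsplit(patterns[p], NULL)[[1]]
    node <- 1L
    for (ch in chs) {
      nxt <- unname(children[[node]][ch])
      if (is.na(nxt)) {
        children[[length(children) + 1L]] <- integer(0)
        out[[length(out) + 1L]] <- integer(0)
        fail[length(children)] <- 1L
        nxt <- length(children)
        children[[node]][ch] <- nxt
      }
      node <- nxt
    }
    out[[node]] <- c(out[[node]], p)
  }
  queue <- unname(children[[1]])
  fail[queue] <- 1L
  qi <- 1L
  while (qi <= length(queue)) {
    u <- queue[qi]; qi <- qi + 1L
    for (ch in names(children[[u]])) {
      v <- unname(children[[u]][ch])
      queue <- c(queue, v)
      f <- fail[u]
      repeat {
        nxt <- unname(children[[f]][ch])
        if (!is.na(nxt) && nxt != v) { fail[v] <- nxt; break }
        if (f == 1L) { fail[v] <- 1L; break }
        f <- fail[f]
      }
      out[[v]] <- c(out[[v]], out[[fail[v]]])
    }
  }
  list(children = children, fail = fail, out = out,
       lengths = nchar(patterns))
}

# Scan text (character vector of single chars) with a built automaton.
# Returns a list(pattern = int vector, end = int vector of 1-based inclusive
# match end positions).
ac_scan <- function(ac, chars) {
  state <- 1L
  pat <- integer(0)
  end <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    repeat {
      nxt <- unname(ac$children[[state]][ch])
      if (!is.na(nxt)) { state <- nxt; break }
      if (state == 1L) break
      state <- ac$fail[state]
    }
    hits <- ac$out[[state]]
    if (length(hits)) {
      pat <- c(pat, hits)
      end <- c(end, rep.int(i, length(hits)))
    }
  }
  list(pattern = pat, end = end)
}

empty_raw_hits <- function() {
  data.frame(motif_id = character(0), motif_kind = character(0),
             u_start = integer(0), u_end = integer(0),
             strand_of_match = character(0), matched_sequence = character(0),
             score = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

sort_raw_hits <- function(hits) {
  hits[order(hits$u_start, hits$motif_id, hits$strand_of_match), , drop = FALSE]
}

#' Find all k-mer occurrences in an ungapped sequence
#'
#' Aho-Corasick search over the full motif set in one pass; matching is
#' case-insensitive and overlapping occurrences (including self-overlaps) are
#' all reported. `matched_sequence` preserves the original sequence case.
#'
#' @param kmers a [kmer_set()].
#' @param seq gap-free subject sequence.
#' @param strand strand label attached to the hits (default `"+"`).
#' @return data frame of raw hits sorted by (`u_start`, `motif_id`) with
#'   0-based half-open `u_start`/`u_end`.
#' @export
find_kmer_hits <- function(kmers, seq, strand = "+") {
  stopifnot(inherits(kmers, "kmer_set"))
  if (nchar(seq) == 0L) return(empty_raw_hits())
  upper <- toupper(seq)
  uniq <- unique(kmers$sequences)
  ac <- ac_build(uniq)
  res <- ac_scan(ac, strsplit(upper, NULL)[[1]])
  if (!length(res$pattern)) return(empty_raw_hits())
  lens <- ac$lengths[res$pattern]
  starts <- res$end - lens          # 0-based
  # one row per (occurrence, id carrying that sequence)
  rows <- lapply(seq_along(res$pattern), function(i) {
    ids <- kmers$ids[kmers$sequences == uniq[res$pattern[i]]]
    data.frame(motif_id = ids, motif_kind = "kmer",
               u_start = starts[i], u_end = res$end[i],
               strand_of_match = strand,
               matched_sequence = substr(seq, starts[i] + 1L, res$end[i]),
               score = NA_real_, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  sort_raw_hits(do.call(rbind, rows))
}

# score every window of length L; NA where the window holds a non-ACGT base
pwm_window_scores <- function(log_odds, seq_upper) {
  idx <- match(strsplit(seq_upper, NULL)[[1]], DNA_BASES)
  L <- ncol(log_odds)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (j in seq_len(L)) {
    scores <- scores + log_odds[cbind(idx[j:(j + n - 1L)], j)]
  }
  scores
}

#' Find PWM hits above the calibrated threshold
#'
#' Every length-L window scoring at or above the calibrated threshold becomes
#' a hit with its log-odds score and add-one empirical p-value. Windows
#' containing characters outside A/C/G/T are skipped; overlapping hits are
#' allowed. A subject shorter than the motif yields no hits.
#'
#' @param x a calibrated [pwm()] (see [calibrate_threshold()]).
#' @param seq gap-free subject sequence (matching is case-insensitive).
#' @param strand strand label attached to the hits (default `"+"`).
#' @param motif_id identifier reported for the hits (defaults to the PWM name).
#' @return data frame of raw hits sorted by `u_start`.
#' @export
find_pwm_hits <- function(x, seq, strand = "+", motif_id = NULL) {
  stopifnot(inherits(x, "pwm"))
  if (is.null(x$threshold)) {
    stop("find_pwm_hits: PWM is not calibrated; run calibrate_threshold() first")
  }
  motif_id <- motif_id %||% x$name
  scores <- pwm_window_scores(x$log_odds, toupper(seq))
  keep <- which(!is.na(scores) & scores >= x$threshold)
  if (!length(keep)) return(empty_raw_hits())
  L <- ncol(x$log_odds)
  hits <- data.frame(motif_id = motif_id, motif_kind = "pwm",
                     u_start = keep - 1L, u_end = keep - 1L + L,
                     strand_of_match = strand,
                     matched_sequence = substring(seq, keep, keep + L - 1L),
                     score = scores[keep],
                     p_value = empirical_p_value(scores[keep], x$null_scores),
                     stringsAsFactors = FALSE)
  sort_raw_hits(hits)
}

#' Find regex matches in an ungapped sequence
#'
#' Each pattern is scanned independently with PCRE, case-insensitively, with
#' the engine's leftmost non-overlapping (scan-and-resume) semantics; matches
#' from different patterns may overlap. Zero-length matches are discarded.
#'
#' @param patterns a [regex_set()].
#' @param seq gap-free subject sequence.
#' @param strand strand label attached to the hits (default `"+"`).
#' @return data frame of raw hits sorted by (`u_start`, `motif_id`).
#' @export
find_regex_hits <- function(patterns, seq, strand = "+") {
  stopifnot(inherits(patterns, "regex_set"))
  if (nchar(seq) == 0L) return(empty_raw_hits())
  rows <- lapply(seq_along(patterns$patterns), function(i) {
    m <- gregexpr(patterns$patterns[i], seq, perl = TRUE, ignore.case = TRUE)[[1]]
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    keep <- starts > 0L & lens > 0L
    starts <- starts[keep]; lens <- lens[keep]
    if (!length(starts)) return(NULL)
    data.frame(motif_id = patterns$ids[i], motif_kind = "regex",
               u_start = starts - 1L, u_end = starts - 1L + lens,
               strand_of_match = strand,
               matched_sequence = substring(seq, starts, starts + lens - 1L),
               score = NA_real_, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_raw_hits())
  sort_raw_hits(do.call(rbind, rows))
}

#' Convert an ungapped span to forward-strand genomic coordinates
#'
#' MAF starts are strand-relative: on `"+"` the forward start is
#' `start + u_start`; on `"-"` it is `src_size - (start + u_end)`.
#'
#' @param aseq an [aligned_sequence()].
#' @param u_start,u_end 0-based half-open span on the sequence's ungapped text
#'   (`u_end <= aseq$size`).
#' @return list with `genome`, `chrom`, `fwd_start`, `fwd_end` (0-based
#'   half-open, forward strand).
#' @export
to_genomic <- function(aseq, u_start, u_end) {
  if (u_start < 0L || u_end <= u_start || u_end > aseq$size) {
    stop(sprintf("to_genomic: span [%d, %d) out of range for size %d",
                 u_start, u_end, aseq$size))
  }
  parts <- split_src(aseq$src)
  if (aseq$strand == "+") {
    fwd_start <- aseq$start + u_start
  } else {
    fwd_start <- aseq$src_size - (aseq$start + u_end)
  }
  list(genome = parts$genome, chrom = parts$chrom,
       fwd_start = fwd_start, fwd_end = fwd_start + (u_end - u_start))
}

# pick the searched sequence of a block: the reference (first "s" line) or the
# first sequence whose src or genome prefix equals search_src. NULL if absent.
pick_search_seq <- function(block, search_src) {
  if (identical(search_src, "reference")) return(1L)
  for (i in seq_along(block$sequences)) {
    src <- block$sequences[[i]]$src
    if (src == search_src || split_src(src)$genome == search_src) return(i)
  }
  NULL
}

# raw hits of the prepared motif set on the searched ungapped sequence,
# including reverse-complement passes when requested
raw_hits_for <- function(prepared, useq, rc) {
  kind <- prepared$kind
  if (kind == "kmer") {
    hits <- find_kmer_hits(prepared$kmers, useq, strand = "+")
    if (rc) {
      rc_set <- kmer_set(revcomp(prepared$kmers$sequences), prepared$kmers$ids)
      hits <- rbind(hits, find_kmer_hits(rc_set, useq, strand = "-"))
    }
  } else if (kind == "pwm") {
    parts <- lapply(prepared$pwms, function(entry) {
      find_pwm_hits(entry$pwm, useq, strand = entry$strand,
                    motif_id = entry$motif_id)
    })
    hits <- do.call(rbind, c(list(empty_raw_hits()), parts))
  } else if (kind == "regex") {
    hits <- find_regex_hits(prepared$regexes, useq, strand = "+")
    if (rc) {
      n <- nchar(useq)
      rev_hits <- find_regex_hits(prepared$regexes, revcomp(useq), strand = "-")
      if (nrow(rev_hits)) {
        u_start <- n - rev_hits$u_end
        u_end <- n - rev_hits$u_start
        rev_hits$u_start <- u_start
        rev_hits$u_end <- u_end
        # report the forward-strand text at the hit position
        rev_hits$matched_sequence <- substring(useq, u_start + 1L, u_end)
        hits <- rbind(hits, rev_hits)
      }
    }
  } else {
    stop("unknown motif kind: ", kind)
  }
  sort_raw_hits(hits)
}

#' Search one alignment block for motif instances
#'
#' Runs the motif finder on the ungapped text of the searched sequence, maps
#' each raw match to gapped block columns and forward-strand genomic
#' coordinates, and scores its conservation against every other aligned
#' sequence of the block (optionally restricted to `genome_ids`, matched
#' against the src prefix before the first `"."`).
#'
#' @param block an [alignment_block()].
#' @param motifs a [prepare_motifs()] result (a raw `kmer_set` or `regex_set`
#'   is accepted and wrapped on the fly).
#' @param search_src `"reference"` (the block's first sequence) or a source ID;
#'   blocks lacking the ID yield `NULL` (logged at debug level).
#' @param rc also search the reverse complement (k-mers: reverse-complemented
#'   patterns; PWMs: the pre-calibrated reverse-complement matrices; regexes:
#'   the reverse-complemented subject, mapped back), reporting strand `"-"`.
#' @param genome_ids optional character vector restricting the conservation
#'   comparisons.
#' @param block_index 0-based index of the block in file order (carried into
#'   the hits).
#' @return list of `motif_hit` objects sorted by (`g_start`, `motif_id`,
#'   strand), or `NULL` when the block lacks the searched source.
#' @export
search_block <- function(block, motifs, search_src = "reference", rc = FALSE,
                         genome_ids = NULL, block_index = 0L) {
  prepared <- as_prepared_motifs(motifs)
  si <- pick_search_seq(block, search_src)
  if (is.null(si)) {
    log_debug("block ", block_index, ": searched source '", search_src,
              "' absent; skipping")
    return(NULL)
  }
  aseq <- block$sequences[[si]]
  gi <- build_gap_index(aseq$text)
  raw <- raw_hits_for(prepared, gi$ungapped, rc)
  if (!nrow(raw)) return(list())

  others <- block$sequences[-si]
  if (!is.null(genome_ids)) {
    others <- Filter(function(s) split_src(s$src)$genome %in% genome_ids, others)
  }

  hits <- lapply(seq_len(nrow(raw)), function(i) {
    g <- map_to_gapped(gi, raw$u_start[i], raw$u_end[i])
    gen <- to_genomic(aseq, raw$u_start[i], raw$u_end[i])
    ref_slice <- substr(aseq$text, g[1] + 1L, g[2])
    records <- lapply(others, function(s) {
      cmp_slice <- substr(s$text, g[1] + 1L, g[2])
      conservation_record(s$src, ref_slice, cmp_slice)
    })
    motif_hit(
      genome = gen$genome, chromosome = gen$chrom,
      fwd_start = gen$fwd_start, fwd_end = gen$fwd_end,
      strand_of_match = raw$strand_of_match[i],
      motif_kind = raw$motif_kind[i], motif_id = raw$motif_id[i],
      matched_sequence = raw$matched_sequence[i],
      g_start = g[1], g_end = g[2],
      u_start = raw$u_start[i], u_end = raw$u_end[i],
      block_index = block_index,
      score = raw$score[i], p_value = raw$p_value[i],
      records = records
    )
  })
  ord <- order(vapply(hits, function(h) h$g_start, numeric(1)),
               vapply(hits, function(h) h$motif_id, character(1)),
               vapply(hits, function(h) h$strand_of_match, character(1)))
  hits[ord]
}
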