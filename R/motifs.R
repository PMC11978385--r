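# Motif models: literal k-mer sets, JASPAR position weight matrices with
# log-odds scoring and p-value-calibrated hit thresholds, and regex pattern
# sets. PWM thresholds follow the sampling recipe: draw windows from the
# background nucleotide frequencies, score them, and take the empirical
# (1 - p) quantile of the null scores as the threshold.

#' Construct a k-mer motif set
#'
#' @param sequences character vector of gap-free motif sequences (DNA or
#'   protein); stored uppercased.
#' @param ids optional unique identifiers, defaults to `kmer_<i>`.
#' @return object of class `kmer_set`.
#' @export
kmer_set <- function(sequences, ids = NULL) {
  if (length(sequences) < 1L) stop("kmer_set: needs at least one sequence")
  if (any(!nzchar(sequences))) stop("kmer_set: empty motif sequence")
  if (any(grepl("[-\\s]", sequences, perl = TRUE))) {
    stop("kmer_set: motif sequences must be gap-free and contain no whitespace")
  }
  if (is.null(ids)) ids <- paste0("kmer_", seq_along(sequences))
  if (anyDuplicated(ids)) stop("kmer_set: ids must be unique")
  structure(list(ids = as.character(ids), sequences = toupper(sequences)),
            class = "kmer_set")
}

#' Read a k-mer list file
#'
#' One motif per line, either the bare sequence or `id<TAB>sequence`.
#' Blank lines and `#` comments are skipped; sequences are uppercased.
#' Lines whose sequence contains gaps or internal whitespace are an error.
#'
#' @param path file path (or character vector of lines).
#' @return a [kmer_set()].
#' @export
parse_kmer_file <- function(path) {
  lines <- maf_input_lines(path)
  ids <- character(0); seqs <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^\\s*$", line) || grepl("^\\s*#", line)) next
    parts <- strsplit(sub("\\s+$", "", line), "\t", fixed = FALSE)[[1]]
    if (length(parts) == 1L) {
      id <- paste0("kmer_", i); sq <- parts[1]
    } else if (length(parts) == 2L) {
      id <- parts[1]; sq <- parts[2]
    } else {
      stop(sprintf("k-mer file line %d: expected 'sequence' or 'id<TAB>sequence'", i))
    }
    if (grepl("[-\\s]", sq, perl = TRUE) || !nzchar(sq)) {
      stop(sprintf("k-mer file line %d: sequence contains a gap or whitespace", i))
    }
    ids <- c(ids, id); seqs <- c(seqs, sq)
  }
  if (!length(seqs)) stop("k-mer file contains no motifs")
  kmer_set(seqs, ids)
}

#' Construct a regex motif set
#'
#' Patterns are validated against the PCRE engine at construction time, so a
#' bad pattern fails at startup rather than mid-scan.
#'
#' @param patterns character vector of regular expressions.
#' @param ids optional unique identifiers, defaults to `regex_<i>`.
#' @return object of class `regex_set`.
#' @export
regex_set <- function(patterns, ids = NULL) {
  if (length(patterns) < 1L) stop("regex_set: needs at least one pattern")
  for (p in patterns) {
    ok <- tryCatch({ grepl(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("regex_set: pattern does not compile: ", p)
  }
  if (is.null(ids)) ids <- paste0("regex_", seq_along(patterns))
  if (anyDuplicated(ids)) stop("regex_set: ids must be unique")
  structure(list(ids = as.character(ids), patterns = as.character(patterns)),
            class = "regex_set")
}

#' Validate background nucleotide frequencies
#'
#' @param freqs `NULL` (uniform assumed) or four non-negative numbers for
#'   A, C, G, T that must sum to 1 within 1e-6.
#' @return numeric vector of length 4.
#' @export
validate_background <- function(freqs = NULL) {
  if (is.null(freqs)) return(rep(0.25, 4))
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || anyNA(freqs)) {
    stop("background must be four numbers (A, C, G, T)")
  }
  if (any(freqs < 0)) stop("background frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-6) {
    stop(sprintf("background frequencies must sum to 1 (got %.8g)", sum(freqs)))
  }
  freqs
}

#' Log-odds matrix of a count matrix against a background
#'
#' Entry `[b, j]` is
#' `log2(((counts[b,j] + pseudocount) / (colsum_j + 4 * pseudocount)) / background[b])`.
#'
#' @param counts 4 x L numeric matrix (rows A, C, G, T), counts >= 0.
#' @param background four frequencies summing to 1 (see [validate_background()]).
#' @param pseudocount positive value added to every count cell.
#' @return 4 x L log-odds matrix (base 2).
#' @export
build_log_odds <- function(counts, background = NULL, pseudocount = 0.1) {
  background <- validate_background(background)
  if (any(background <= 0)) stop("build_log_odds: background frequencies must be > 0")
  if (!is.matrix(counts) || nrow(counts) != 4L) stop("counts must be a 4-row matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  lo <- log2(probs / background)
  rownames(lo) <- DNA_BASES
  lo
}

#' Construct a position weight matrix model
#'
#' @param name motif identifier.
#' @param counts 4 x L count matrix, rows in A, C, G, T order.
#' @param background four frequencies for A, C, G, T summing to 1;
#'   `NULL` for uniform.
#' @param pseudocount added to every cell before normalisation (default 0.1).
#' @return object of class `pwm` with the derived `log_odds` matrix;
#'   `threshold`/`null_scores` are unset until [calibrate_threshold()].
#' @export
pwm <- function(name, counts, background = NULL, pseudocount = 0.1) {
  background <- validate_background(background)
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("pwm: counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("pwm: counts must have at least one column")
  rownames(counts) <- DNA_BASES
  structure(list(name = as.character(name), counts = counts,
                 background = background, pseudocount = pseudocount,
                 log_odds = build_log_odds(counts, background, pseudocount),
                 threshold = NULL, null_scores = NULL, p_value_target = NULL,
                 calibration = NULL),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s: %d columns, %s>\n", x$name, ncol(x$counts),
              if (is.null(x$threshold)) "uncalibrated"
              else sprintf("threshold %.4f at p = %g", x$threshold, x$p_value_target)))
  invisible(x)
}

#' Parse JASPAR-format PWM records
#'
#' JASPAR 2016+ plain text: a `>ID name` header, then four bracketed count
#' rows (`A [ 4 0 ... ]` etc.) in any row order. Multiple records per file
#' are supported. Unequal row lengths, missing base rows or negative counts
#' raise an error naming the record.
#'
#' @param path file path (or character vector of lines).
#' @param background,pseudocount passed to [pwm()].
#' @return list of uncalibrated [pwm()] objects in file order.
#' @export
parse_jaspar <- function(path, background = NULL, pseudocount = 0.1) {
  lines <- maf_input_lines(path)
  pwms <- list()
  cur_id <- NULL
  rows <- list()

  flush_record <- function() {
    if (is.null(cur_id)) return(invisible())
    missing <- setdiff(DNA_BASES, names(rows))
    if (length(missing)) {
      stop(sprintf("JASPAR record '%s': missing row(s) %s",
                   cur_id, paste(missing, collapse = ", ")))
    }
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop(sprintf("JASPAR record '%s': rows have unequal lengths", cur_id))
    }
    counts <- rbind(A = rows[["A"]], C = rows[["C"]], G = rows[["G"]], T = rows[["T"]])
    if (any(counts < 0)) stop(sprintf("JASPAR record '%s': negative counts", cur_id))
    pwms[[length(pwms) + 1L]] <<- pwm(cur_id, counts, background, pseudocount)
    cur_id <<- NULL
    rows <<- list()
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_record()
      cur_id <- strsplit(sub("^>\\s*", "", line), "\\s+")[[1]][1]
      if (is.na(cur_id) || !nzchar(cur_id)) cur_id <- sprintf("jaspar_line_%d", i)
      next
    }
    m <- regmatches(line, regexec("^([ACGTacgt])\\s*\\[?\\s*([-0-9.eE+ \t]*?)\\s*\\]?$", line))[[1]]
    if (length(m) == 3L && !is.null(cur_id)) {
      base <- toupper(m[2])
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (!length(vals) || anyNA(vals)) {
        stop(sprintf("JASPAR record '%s': cannot parse counts on line %d", cur_id, i))
      }
      if (!is.null(rows[[base]])) {
        stop(sprintf("JASPAR record '%s': duplicate '%s' row", cur_id, base))
      }
      rows[[base]] <- vals
      next
    }
    stop(sprintf("JASPAR parse error at line %d: unrecognised line", i))
  }
  flush_record()
  if (!length(pwms)) stop("JASPAR file contains no records")
  pwms
}

# Score n i.i.d. background windows of length L under a log-odds matrix.
sample_null_scores <- function(log_odds, background, n, chunk = 1e6L) {
  L <- ncol(log_odds)
  out <- numeric(n)
  done <- 0L
  while (done < n) {
    k <- min(as.integer(chunk), n - done)
    idx <- matrix(sample.int(4L, k * L, replace = TRUE, prob = background), k, L)
    s <- numeric(k)
    for (j in seq_len(L)) s <- s + log_odds[cbind(idx[, j], j)]
    out[(done + 1L):(done + k)] <- s
    done <- done + k
  }
  out
}

#' Calibrate a PWM hit threshold to a target p-value
#'
#' Draws `n_samples` i.i.d. windows of the motif's length with per-position
#' base probabilities equal to the background, scores them with the log-odds
#' matrix, and sets the threshold to the smallest sampled score `s` whose
#' empirical exceedance fraction (share of null scores `>= s`) is at most
#' `p_value` — i.e. the conservative empirical `(1 - p)` quantile. The sorted
#' null sample is retained for per-hit empirical p-values. Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param x a [pwm()].
#' @param p_value target p-value in (0, 1].
#' @param n_samples number of null windows (>= 1000; default 1e5).
#' @param seed RNG seed.
#' @return the input `pwm` with `threshold`, `null_scores` (sorted ascending),
#'   `p_value_target` and `calibration` metadata filled in.
#' @export
calibrate_threshold <- function(x, p_value = 1e-4, n_samples = 1e5, seed = 1L) {
  stopifnot(inherits(x, "pwm"))
  if (!is.numeric(p_value) || length(p_value) != 1L || p_value <= 0 || p_value > 1) {
    stop("calibrate_threshold: p_value must be in (0, 1]")
  }
  if (!is_count(n_samples, min = 1000L)) {
    stop("calibrate_threshold: n_samples must be an integer >= 1000")
  }
  n_samples <- as.integer(n_samples)
  ns <- with_seed(seed, sample_null_scores(x$log_odds, x$background, n_samples))
  ns <- sort(ns)
  m_allow <- floor(n_samples * p_value)
  if (m_allow < 1L) {
    threshold <- ns[n_samples] + 1e-9
  } else {
    r <- rle(ns)
    first_idx <- cumsum(r$lengths) - r$lengths + 1L
    ok <- which(first_idx >= n_samples - m_allow + 1L)
    threshold <- if (length(ok)) r$values[ok[1]] else ns[n_samples] + 1e-9
  }
  x$threshold <- threshold
  x$null_scores <- ns
  x$p_value_target <- p_value
  x$calibration <- list(n_samples = n_samples, seed = seed)
  x
}

#' Empirical p-value of a score against a null sample
#'
#' Add-one empirical tail: `(1 + #\{null >= score\}) / (1 + n)`; monotone
#' non-increasing in `score`.
#'
#' @param score numeric vector of scores.
#' @param null_scores sorted (ascending) nonempty numeric null sample.
#' @return numeric vector of p-values in (0, 1].
#' @export
empirical_p_value <- function(score, null_scores) {
  n <- length(null_scores)
  if (n < 1L) stop("empirical_p_value: null_scores is empty")
  # count(null < s) via findInterval on the sorted sample
  below <- findInterval(score, null_scores, left.open = TRUE)
  (1 + (n - below)) / (1 + n)
}

#' Reverse complement of a nucleotide PWM
#'
#' Columns are reversed and base rows swapped A<->T, C<->G; the log-odds
#' matrix is rebuilt against the same background. Any calibration is
#' invalidated (set to `NULL`) because the null distribution belongs to the
#' forward orientation.
#'
#' @param x a nucleotide [pwm()].
#' @return a new uncalibrated `pwm` named `<name>_rc`.
#' @export
reverse_complement_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (!identical(rownames(x$counts), DNA_BASES)) {
    stop("reverse_complement_pwm: only nucleotide PWMs (rows A, C, G, T) are supported")
  }
  rc_counts <- x$counts[4:1, rev(seq_len(ncol(x$counts))), drop = FALSE]
  rownames(rc_counts) <- DNA_BASES
  pwm(paste0(x$name, "_rc"), rc_counts, x$background, x$pseudocount)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment: on sorted p-values,
#' `q(i) = min_{j >= i} (m * p(j) / j)`, mapped back to input order and capped
#' at 1. Always `q >= p`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return numeric vector of q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}
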