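# Output writers: BED6 (default), JSON (metadata header + one entry per hit)
# and CSV (long form: one row per hit x compared sequence), plus per-motif
# summary statistics. All writers are deterministic: identical hits and
# parameters produce byte-identical files regardless of process count.

hit_sort_order <- function(hits) {
  order(vapply(hits, function(h) h$block_index, integer(1)),
        vapply(hits, function(h) h$fwd_start, integer(1)),
        vapply(hits, function(h) h$motif_id, character(1)),
        vapply(hits, function(h) h$strand_of_match, character(1)))
}

write_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

fmt_num <- function(x, digits = 10) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.numeric(v) && v == round(v) && abs(v) < 1e15) {
      return(format(v, scientific = FALSE))
    }
    trimws(formatC(v, digits = digits, format = "g"))
  }, character(1))
}

#' Write hits as BED6
#'
#' Columns: chrom, forward-strand start/end (0-based half-open), name
#' `motif_id|motif_kind|block_index`, score = rounded block conservation
#' clamped to \[0, 1000\] (0 when undefined), strand of the match. Rows are
#' sorted by (block_index, fwd_start, motif_id).
#'
#' @param hits list of [motif_hit()] objects.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  hits <- hits[hit_sort_order(hits)]
  lines <- vapply(hits, function(h) {
    sc <- if (is.na(h$block_conservation)) 0 else round(h$block_conservation)
    sc <- max(0, min(1000, sc))
    sprintf("%s\t%d\t%d\t%s|%s|%d\t%d\t%s",
            h$chromosome, h$fwd_start, h$fwd_end,
            h$motif_id, h$motif_kind, h$block_index, sc, h$strand_of_match)
  }, character(1))
  write_utf8(lines, path)
}

hit_json_key <- function(h) {
  sprintf("hit_%d_%d_%s_%s", h$block_index, h$g_start, h$motif_id,
          h$strand_of_match)
}

hit_to_json_value <- function(h) {
  v <- list(
    genome = h$genome, chromosome = h$chromosome,
    fwd_start = h$fwd_start, fwd_end = h$fwd_end,
    strand = h$strand_of_match,
    motif_kind = h$motif_kind, motif_id = h$motif_id,
    motif_length = h$motif_length, matched_sequence = h$matched_sequence,
    g_start = h$g_start, g_end = h$g_end,
    u_start = h$u_start, u_end = h$u_end,
    block_index = h$block_index
  )
  if (identical(h$motif_kind, "pwm")) {
    v$score <- h$score
    v$p_value <- h$p_value
    v$fdr <- h$fdr
  }
  v$block_conservation <- h$block_conservation
  v$conservation <- setNames(
    lapply(h$records, function(r) list(vector = r$vector, percent = r$percent)),
    vapply(h$records, function(r) r$compared_src, character(1))
  )
  v
}

#' Write hits as JSON
#'
#' Top-level object with a `metadata` header (run parameters, seed,
#' background, target p-value) and a `hits` map keyed
#' `hit_<block_index>_<g_start>_<motif_id>_<strand>`. Each hit entry carries
#' every field plus, per compared sequence, the similarity vector and the
#' conservation percentage. PWM hits additionally carry score, p-value and
#' FDR.
#'
#' @param hits list of [motif_hit()] objects.
#' @param path output file path.
#' @param metadata named list stored under `metadata`.
#' @return the path, invisibly.
#' @export
write_hits_json <- function(hits, path, metadata = list()) {
  hits <- hits[hit_sort_order(hits)]
  obj <- list(
    metadata = metadata,
    hits = setNames(lapply(hits, hit_to_json_value),
                    vapply(hits, hit_json_key, character(1)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

csv_quote <- function(x) {
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

CSV_HEADER <- c("genome", "chromosome", "fwd_start", "fwd_end", "strand",
                "motif_kind", "motif_id", "motif_length", "matched_sequence",
                "g_start", "g_end", "u_start", "u_end", "block_index",
                "score", "p_value", "fdr", "block_conservation",
                "compared_src", "similarity_vector", "conservation_percent")

#' Write hits as CSV (long form)
#'
#' One row per (hit, compared sequence); a hit with no compared sequences
#' still yields one row with empty comparison columns. The header is fixed
#' (see `mafscan:::CSV_HEADER`); RFC 4180 quoting; UTF-8 (similarity vectors
#' contain the EN DASH reference-gap symbol).
#'
#' @param hits list of [motif_hit()] objects.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_hits_csv <- function(hits, path) {
  hits <- hits[hit_sort_order(hits)]
  rows <- unlist(lapply(hits, function(h) {
    base <- c(h$genome, h$chromosome, fmt_num(h$fwd_start), fmt_num(h$fwd_end),
              h$strand_of_match, h$motif_kind, h$motif_id,
              fmt_num(h$motif_length), h$matched_sequence,
              fmt_num(h$g_start), fmt_num(h$g_end),
              fmt_num(h$u_start), fmt_num(h$u_end), fmt_num(h$block_index),
              fmt_num(h$score), fmt_num(h$p_value), fmt_num(h$fdr),
              fmt_num(h$block_conservation))
    recs <- if (length(h$records)) h$records else list(NULL)
    vapply(recs, function(r) {
      cmp <- if (is.null(r)) c("", "", "")
             else c(r$compared_src, r$vector, fmt_num(r$percent))
      paste(csv_quote(c(base, cmp)), collapse = ",")
    }, character(1))
  }), use.names = FALSE)
  write_utf8(c(paste(CSV_HEADER, collapse = ","), rows), path)
}

#' Per-motif summary statistics
#'
#' @param hits list of [motif_hit()] objects.
#' @return data frame with one row per motif id (sorted), giving the hit
#'   count and the mean/min/max block conservation over hits with a defined
#'   value.
#' @export
summary_stats <- function(hits) {
  if (!length(hits)) {
    return(data.frame(motif_id = character(0), n_hits = integer(0),
                      mean_block_conservation = numeric(0),
                      min = numeric(0), max = numeric(0)))
  }
  ids <- vapply(hits, function(h) h$motif_id, character(1))
  cons <- vapply(hits, function(h) h$block_conservation, numeric(1))
  out <- do.call(rbind, lapply(sort(unique(ids)), function(id) {
    ci <- cons[ids == id]
    def <- ci[!is.na(ci)]
    data.frame(motif_id = id, n_hits = sum(ids == id),
               mean_block_conservation = if (length(def)) mean(def) else NA_real_,
               min = if (length(def)) min(def) else NA_real_,
               max = if (length(def)) max(def) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
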