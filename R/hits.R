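# The motif hit container: one motif instance in one block, with coordinates
# in three systems (ungapped offsets on the searched sequence, gapped block
# columns, forward-strand genomic), optional PWM statistics and the
# conservation records against the other sequences of the block.

#' Construct a motif hit
#'
#' @param genome,chromosome genome ID and chromosome (split from the searched
#'   sequence's src at the first `"."`).
#' @param fwd_start,fwd_end 0-based half-open forward-strand genomic span.
#' @param strand_of_match `"+"` or `"-"` (orientation of the matched motif).
#' @param motif_kind one of `"kmer"`, `"pwm"`, `"regex"`.
#' @param motif_id motif identifier.
#' @param matched_sequence matched text (forward strand of the searched
#'   sequence, original case).
#' @param g_start,g_end 0-based half-open gapped block columns.
#' @param u_start,u_end 0-based half-open ungapped offsets.
#' @param block_index 0-based index of the block in file order.
#' @param score,p_value,fdr PWM statistics (`NA` for k-mer/regex hits).
#' @param records list of [conservation_record()] objects.
#' @return object of class `motif_hit`; `block_conservation` is derived from
#'   `records`.
#' @export
motif_hit <- function(genome, chromosome, fwd_start, fwd_end, strand_of_match,
                      motif_kind, motif_id, matched_sequence,
                      g_start, g_end, u_start, u_end, block_index,
                      score = NA_real_, p_value = NA_real_, fdr = NA_real_,
                      records = list()) {
  motif_length <- u_end - u_start
  stopifnot(motif_length >= 1L, fwd_end - fwd_start == motif_length,
            nchar(matched_sequence) == motif_length,
            strand_of_match %in% c("+", "-"),
            motif_kind %in% c("kmer", "pwm", "regex"))
  structure(list(
    genome = genome, chromosome = chromosome,
    fwd_start = as.integer(fwd_start), fwd_end = as.integer(fwd_end),
    strand_of_match = strand_of_match,
    motif_kind = motif_kind, motif_id = motif_id,
    motif_length = as.integer(motif_length),
    matched_sequence = matched_sequence,
    g_start = as.integer(g_start), g_end = as.integer(g_end),
    u_start = as.integer(u_start), u_end = as.integer(u_end),
    block_index = as.integer(block_index),
    score = score, p_value = p_value, fdr = fdr,
    records = records,
    block_conservation = block_conservation(records)
  ), class = "motif_hit")
}

#' @export
print.motif_hit <- function(x, ...) {
  cat(sprintf("<motif_hit %s (%s) %s:%d-%d %s block %d, conservation %s>\n",
              x$motif_id, x$motif_kind, x$chromosome, x$fwd_start, x$fwd_end,
              x$strand_of_match, x$block_index,
              if (is.na(x$block_conservation)) "NA"
              else sprintf("%.1f%%", x$block_conservation)))
  invisible(x)
}

#' Flatten motif hits to a data frame (one row per hit)
#'
#' Conservation records are summarised into `n_compared` and
#' `block_conservation`; use [write_hits_csv()] for the per-comparison long
#' form.
#'
#' @param hits list of [motif_hit()] objects.
#' @return data frame with one row per hit.
#' @export
hits_to_df <- function(hits) {
  cols <- c("genome", "chromosome", "fwd_start", "fwd_end", "strand_of_match",
            "motif_kind", "motif_id", "motif_length", "matched_sequence",
            "g_start", "g_end", "u_start", "u_end", "block_index",
            "score", "p_value", "fdr", "block_conservation")
  if (!length(hits)) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    df$n_compared <- integer(0)
    return(df)
  }
  df <- do.call(rbind, lapply(hits, function(h) {
    as.data.frame(h[cols], stringsAsFactors = FALSE)
  }))
  df$n_compared <- vapply(hits, function(h) length(h$records), integer(1))
  rownames(df) <- NULL
  df
}
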