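# Conservation scoring of a motif instance against the other sequences of its
# block. The comparison walks the gapped alignment columns of the motif span
# and emits one symbol per column:
#
#   both gaps                  -> column ignored
#   searched gap vs character  -> "–" (EN DASH)
#   characters equal           -> "1"
#   otherwise (incl. cmp gap)  -> "0"
#
# The conservation percentage is 100 * #"1" / vector length, so "0" and "–"
# both count in the denominator.

#' Similarity vector between two gapped slices
#'
#' @param ref_slice gapped slice of the searched sequence over the motif's
#'   block columns.
#' @param cmp_slice gapped slice of the compared sequence over the same
#'   columns (equal length required).
#' @return character scalar over the alphabet `{"1", "0", "–"}`; zero-length
#'   when every column is gap/gap. Character equality is case-insensitive.
#' @export
similarity_vector <- function(ref_slice, cmp_slice) {
  r <- strsplit(ref_slice, NULL)[[1]]
  cc <- strsplit(cmp_slice, NULL)[[1]]
  if (length(r) != length(cc)) {
    stop(sprintf("similarity_vector: slice lengths differ (%d vs %d)",
                 length(r), length(cc)))
  }
  rgap <- r == "-"
  cgap <- cc == "-"
  keep <- !(rgap & cgap)
  r <- r[keep]; cc <- cc[keep]; rgap <- rgap[keep]; cgap <- cgap[keep]
  if (!length(r)) return("")
  sym <- ifelse(rgap, SIM_REFGAP,
                ifelse(!cgap & toupper(r) == toupper(cc), "1", "0"))
  paste(sym, collapse = "")
}

#' Conservation percentage of a similarity vector
#'
#' `100 * #"1" / nchar(vector)`; both `"0"` and `"–"` count in the
#' denominator. An empty vector (motif span entirely gap/gap) has no defined
#' conservation: `NA` is returned with a warning and the record is excluded
#' from block averages.
#'
#' @param vector similarity vector string from [similarity_vector()].
#' @return percentage in \[0, 100\], or `NA_real_` for an empty vector.
#' @export
conservation_percent <- function(vector) {
  n <- nchar(vector)
  if (is.na(n) || n == 0L) {
    warning("conservation_percent: empty similarity vector; conservation undefined")
    return(NA_real_)
  }
  ones <- n - nchar(gsub("1", "", vector, fixed = TRUE))
  100 * ones / n
}

#' Conservation record of one motif instance vs one compared sequence
#'
#' @param compared_src src of the compared sequence.
#' @param ref_slice,cmp_slice gapped slices over the motif's block columns.
#' @return object of class `conservation_record` with fields `compared_src`,
#'   `vector` and `percent` (NA for an all-gap/gap span).
#' @export
conservation_record <- function(compared_src, ref_slice, cmp_slice) {
  vec <- similarity_vector(ref_slice, cmp_slice)
  pct <- if (nchar(vec) == 0L) {
    warning(sprintf("motif span vs '%s' is entirely gap/gap; conservation undefined",
                    compared_src))
    NA_real_
  } else {
    conservation_percent(vec)
  }
  structure(list(compared_src = compared_src, vector = vec, percent = pct),
            class = "conservation_record")
}

#' Block-level conservation of a motif instance
#'
#' Unweighted arithmetic mean of the defined conservation percentages over
#' all compared sequences; `NA` when no record has a defined percentage.
#'
#' @param records list of [conservation_record()] objects (a bare numeric
#'   vector of percentages is also accepted).
#' @return mean percentage in \[0, 100\] or `NA_real_`.
#' @export
block_conservation <- function(records) {
  pcts <- if (is.numeric(records)) records
          else vapply(records, function(r) r$percent, numeric(1))
  pcts <- pcts[!is.na(pcts)]
  if (!length(pcts)) return(NA_real_)
  mean(pcts)
}
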