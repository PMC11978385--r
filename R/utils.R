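# Shared helpers: alphabet constants, reverse complement, scoped RNG, logging.

DNA_BASES <- c("A", "C", "G", "T")

# symbol recorded when the searched (reference) sequence has a gap opposite a
# character in the compared sequence: U+2013 EN DASH (escaped: source stays ASCII)
SIM_REFGAP <- "\u2013"

IUPAC_FWD <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
IUPAC_REV <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

#' Reverse complement of nucleotide strings
#'
#' IUPAC ambiguity codes are complemented; case is preserved.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  bad <- grepl(sprintf("[^%s-]", IUPAC_FWD), x)
  if (any(bad)) {
    stop("revcomp: non-nucleotide characters in sequence: ",
         x[bad][1], call. = FALSE)
  }
  comp <- chartr(IUPAC_FWD, IUPAC_REV, x)
  vapply(strsplit(comp, NULL),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

log_debug <- function(...) {
  if (isTRUE(getOption("mafscan.verbose", FALSE))) {
    message("[mafscan debug] ", ...)
  }
}

log_info <- function(...) {
  if (!isTRUE(getOption("mafscan.quiet", TRUE))) {
    message("[mafscan] ", ...)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

# genome id = part of src before the first "."; chromosome = the rest.
split_src <- function(src) {
  dot <- regexpr(".", src, fixed = TRUE)
  if (dot < 0L) {
    log_debug("source '", src, "' has no '.'; using it as both genome and chromosome")
    list(genome = src, chrom = src)
  } else {
    list(genome = substr(src, 1L, dot - 1L), chrom = substr(src, dot + 1L, nchar(src)))
  }
}
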