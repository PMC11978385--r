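# Run orchestration: motif preparation (including PWM threshold calibration),
# block-aligned chunking, optional multi-process workers, deterministic
# merging in file order, FDR assignment across all PWM hits of the run, and
# output writing. All randomness (threshold calibration) happens in the
# parent before any worker starts, so the process count can never change the
# results.

#' Prepare a motif set for searching
#'
#' Wraps a motif source into the internal prepared form. PWMs are calibrated
#' here (forward and, when `rc`, reverse complement, each with a seed derived
#' deterministically from `seed`), so that searching is RNG-free.
#'
#' @param motifs a [kmer_set()], [regex_set()], single [pwm()] or list of
#'   `pwm` objects.
#' @param rc prepare reverse-complement PWMs as well.
#' @param background,p_value,n_samples,seed calibration parameters (PWMs only).
#' @return object of class `prepared_motifs`.
#' @export
prepare_motifs <- function(motifs, rc = FALSE, background = NULL,
                           p_value = 1e-4, n_samples = 1e5, seed = 1L) {
  if (inherits(motifs, "prepared_motifs")) return(motifs)
  if (inherits(motifs, "kmer_set")) {
    return(structure(list(kind = "kmer", kmers = motifs, rc = rc),
                     class = "prepared_motifs"))
  }
  if (inherits(motifs, "regex_set")) {
    return(structure(list(kind = "regex", regexes = motifs, rc = rc),
                     class = "prepared_motifs"))
  }
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  if (is.list(motifs) && length(motifs) && all(vapply(motifs, inherits, logical(1), "pwm"))) {
    background <- validate_background(background)
    entries <- list()
    for (i in seq_along(motifs)) {
      p <- motifs[[i]]
      if (!identical(p$background, background)) {
        p <- pwm(p$name, p$counts, background, p$pseudocount)
      }
      p <- calibrate_threshold(p, p_value, n_samples, seed = seed + 2L * i)
      entries[[length(entries) + 1L]] <-
        list(pwm = p, strand = "+", motif_id = p$name)
      if (rc) {
        prc <- reverse_complement_pwm(p)
        prc <- calibrate_threshold(prc, p_value, n_samples, seed = seed + 2L * i + 1L)
        entries[[length(entries) + 1L]] <-
          list(pwm = prc, strand = "-", motif_id = p$name)
      }
    }
    return(structure(list(kind = "pwm", pwms = entries, rc = rc),
                     class = "prepared_motifs"))
  }
  stop("prepare_motifs: unsupported motif source")
}

as_prepared_motifs <- function(motifs) {
  if (inherits(motifs, "prepared_motifs")) motifs else prepare_motifs(motifs)
}

#' Run a full MAF motif scan
#'
#' Validates the configuration, loads and prepares the motifs, plans
#' block-aligned chunks, searches every block (optionally with forked
#' workers), merges hits in file order, assigns Benjamini-Hochberg FDR across
#' all PWM hits of the run, and writes the requested outputs.
#'
#' Exactly one of `kmers`, `jaspar`, `regexes` must be given.
#'
#' @param maf_path MAF file to scan.
#' @param kmers k-mer list file path or a [kmer_set()].
#' @param jaspar JASPAR matrix file path, a [pwm()] or list of `pwm`s.
#' @param regexes comma-separated pattern string or a [regex_set()].
#' @param search_src `"reference"` or a source/genome ID to search.
#' @param genome_ids optional path to a genome-ID list file (one per line) or
#'   character vector; restricts conservation comparisons.
#' @param rc also search the reverse complement.
#' @param processes number of worker processes (forked; >1 requires unix).
#' @param background A/C/G/T frequencies summing to 1; `NULL` = uniform.
#' @param p_value PWM threshold p-value target (default 1e-4).
#' @param n_samples null sample size for calibration (default 1e5).
#' @param seed run seed; all stochastic steps derive from it.
#' @param bed BED output path (default `<maf_path>.motifs.bed`); `NA` to skip.
#' @param json,csv optional JSON/CSV output paths.
#' @return (invisibly) list with `hits`, `summary`, `n_blocks`, `plan`,
#'   `config`.
#' @export
run_scan <- function(maf_path,
                     kmers = NULL, jaspar = NULL, regexes = NULL,
                     search_src = "reference", genome_ids = NULL, rc = FALSE,
                     processes = 1L, background = NULL,
                     p_value = 1e-4, n_samples = 1e5, seed = 1L,
                     bed = NULL, json = NULL, csv = NULL) {
  if (!file.exists(maf_path)) stop("run_scan: MAF file not found: ", maf_path)
  modes <- c(kmers = !is.null(kmers), jaspar = !is.null(jaspar),
             regexes = !is.null(regexes))
  if (sum(modes) != 1L) {
    stop("run_scan: exactly one of kmers/jaspar/regexes must be given")
  }
  if (!is_count(processes)) stop("run_scan: processes must be a positive integer")
  processes <- as.integer(processes)
  background <- validate_background(background)

  motifs <- if (!is.null(kmers)) {
    if (inherits(kmers, "kmer_set")) kmers else parse_kmer_file(kmers)
  } else if (!is.null(jaspar)) {
    if (inherits(jaspar, "pwm") || is.list(jaspar) && !is.character(jaspar)) jaspar
    else parse_jaspar(jaspar, background = background)
  } else {
    if (inherits(regexes, "regex_set")) regexes
    else regex_set(trimws(strsplit(regexes, ",", fixed = TRUE)[[1]]))
  }
  prepared <- prepare_motifs(motifs, rc = rc, background = background,
                             p_value = p_value, n_samples = n_samples,
                             seed = seed)

  if (!is.null(genome_ids) && length(genome_ids) == 1L && file.exists(genome_ids)) {
    genome_ids <- readLines(genome_ids, warn = FALSE)
    genome_ids <- trimws(genome_ids[nzchar(trimws(genome_ids))])
  }

  plan <- chunk_maf(maf_path, processes)
  worker <- function(i) {
    blocks <- parse_maf_range(maf_path, plan$byte_start[i], plan$byte_end[i])
    res <- lapply(seq_along(blocks), function(j) {
      search_block(blocks[[j]], prepared, search_src = search_src, rc = rc,
                   genome_ids = genome_ids,
                   block_index = plan$first_block[i] + j - 1L)
    })
    log_info("chunk ", i, "/", nrow(plan), ": ", length(blocks), " blocks")
    res
  }
  chunk_results <- if (processes > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(plan)), worker, mc.cores = processes)
  } else {
    lapply(seq_len(nrow(plan)), worker)
  }
  for (cr in chunk_results) {
    if (inherits(cr, "try-error")) stop("run_scan: worker failed: ", cr)
  }
  per_block <- unlist(chunk_results, recursive = FALSE)
  n_blocks <- length(per_block)
  hits <- unlist(Filter(Negate(is.null), per_block), recursive = FALSE)
  hits <- hits %||% list()

  # FDR across all PWM hits of the run
  is_pwm <- vapply(hits, function(h) identical(h$motif_kind, "pwm"), logical(1))
  if (any(is_pwm)) {
    q <- benjamini_hochberg(vapply(hits[is_pwm], function(h) h$p_value, numeric(1)))
    k <- 1L
    for (i in which(is_pwm)) { hits[[i]]$fdr <- q[k]; k <- k + 1L }
  }

  metadata <- list(
    maf = basename(maf_path),
    motif_kind = prepared$kind,
    search_src = search_src,
    reverse_complement = rc,
    # the process count is deliberately NOT recorded: outputs are contracted
    # to be byte-identical regardless of parallelism
    background = background,
    p_value_target = p_value,
    n_samples = n_samples,
    seed = seed
  )
  if (is.null(bed)) bed <- paste0(maf_path, ".motifs.bed")
  if (!is.na(bed)) write_hits_bed(hits, bed)
  if (!is.null(json)) write_hits_json(hits, json, metadata = metadata)
  if (!is.null(csv)) write_hits_csv(hits, csv)

  stats <- summary_stats(hits)
  log_info("scanned ", n_blocks, " blocks; ", length(hits), " hits")
  invisible(list(hits = hits, summary = stats, n_blocks = n_blocks,
                 plan = plan, config = metadata))
}

#' Command-line entry point
#'
#' Flags: positional MAF path; `--kmers FILE` | `--jaspar FILE` |
#' `--regexes "p1,p2"`; `--search-genome ID`; `--genome-ids FILE`;
#' `--reverse-complement`; `--processes N`; `--background "A,C,G,T"`;
#' `--pvalue X`; `--seed N`; `--bed PATH`; `--json PATH`; `--csv PATH`.
#'
#' @param args character vector of command-line arguments (default: the real
#'   command line).
#' @return integer exit status (0 on success), invisibly.
#' @export
mafscan_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "mafscan [options] <alignment.maf>",
    option_list = list(
      optparse::make_option("--kmers", type = "character", default = NULL,
                            help = "k-mer list file (one motif per line, optional id<TAB>seq)"),
      optparse::make_option("--jaspar", type = "character", default = NULL,
                            help = "JASPAR-format PWM file"),
      optparse::make_option("--regexes", type = "character", default = NULL,
                            help = "comma-separated regular expressions"),
      optparse::make_option("--search-genome", type = "character",
                            default = "reference", dest = "search_genome",
                            help = "source/genome ID to search [default: the block reference]"),
      optparse::make_option("--genome-ids", type = "character", default = NULL,
                            dest = "genome_ids",
                            help = "file of genome IDs to compare against (one per line)"),
      optparse::make_option("--reverse-complement", action = "store_true",
                            default = FALSE, dest = "reverse_complement",
                            help = "also search the reverse complement"),
      optparse::make_option("--processes", type = "integer", default = 1L,
                            help = "number of worker processes [default 1]"),
      optparse::make_option("--background", type = "character", default = NULL,
                            help = "A,C,G,T background frequencies summing to 1 [default uniform]"),
      optparse::make_option("--pvalue", type = "double", default = 1e-4,
                            help = "PWM threshold p-value [default 1e-4]"),
      optparse::make_option("--nsamples", type = "integer", default = 100000L,
                            help = "null sample size for PWM calibration [default 100000]"),
      optparse::make_option("--seed", type = "integer", default = 1L,
                            help = "run seed [default 1]"),
      optparse::make_option("--bed", type = "character", default = NULL,
                            help = "BED output path [default <maf>.motifs.bed]"),
      optparse::make_option("--json", type = "character", default = NULL,
                            help = "JSON output path (optional)"),
      optparse::make_option("--csv", type = "character", default = NULL,
                            help = "CSV output path (optional)"),
      optparse::make_option("--verbose", action = "store_true", default = FALSE,
                            help = "log progress")
    )
  )
  status <- tryCatch({
    parsed <- optparse::parse_args(parser, args = args, positional_arguments = 1)
    opt <- parsed$options
    bg <- if (is.null(opt$background)) NULL
          else as.numeric(strsplit(opt$background, "[, ]+")[[1]])
    if (opt$verbose) options(mafscan.quiet = FALSE)
    res <- run_scan(parsed$args[1],
                    kmers = opt$kmers, jaspar = opt$jaspar, regexes = opt$regexes,
                    search_src = opt$search_genome, genome_ids = opt$genome_ids,
                    rc = opt$reverse_complement, processes = opt$processes,
                    background = bg, p_value = opt$pvalue,
                    n_samples = opt$nsamples, seed = opt$seed,
                    bed = opt$bed, json = opt$json, csv = opt$csv)
    if (nrow(res$summary)) {
      utils::write.table(format(res$summary, digits = 4), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    0L
  }, error = function(e) {
    message("mafscan error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
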