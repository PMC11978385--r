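# Synthetic MAF generator: random background blocks with motifs planted at
# known positions in the searched (reference) genome, and compared sequences
# derived from the reference by a prescribed per-genome edit plan
# (substitutions, compared-sequence gaps, reference-gap column insertions).
# The generator emits the exact expected hit table (coordinates, similarity
# vectors, conservation percentages), so every pipeline stage can be checked
# against ground truth without any external data.
#
# Ground truth stays exact because blocks are rejection-sampled: a block whose
# reference sequence contains an occurrence of any planted motif outside the
# planted positions is redrawn.

#' Specify one planted motif instance
#'
#' @param motif literal motif sequence (A/C/G/T).
#' @param block_index 0-based index of the target block.
#' @param u_position 0-based ungapped start of the plant in the reference
#'   sequence of the block.
#' @param edits named list (one entry per compared genome, name = genome id
#'   such as `"g2"`) of lists with fields `subs` (number of substituted
#'   positions), `cmp_gaps` (number of positions where the compared sequence
#'   gets a gap) and `ref_gaps` (number of reference-gap columns inserted
#'   inside the motif span, opposite a character in that genome). Genomes not
#'   listed get zero edits.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(motif, block_index, u_position, edits = list()) {
  stopifnot(nchar(motif) >= 2L, !grepl("[^ACGTacgt]", motif),
            block_index >= 0L, u_position >= 0L)
  for (e in edits) {
    stopifnot(is.list(e))
    subs <- e$subs %||% 0L; cg <- e$cmp_gaps %||% 0L; rg <- e$ref_gaps %||% 0L
    if (subs + cg > nchar(motif)) {
      stop("plant_spec: more substitutions + compared gaps than motif positions")
    }
    if (rg > nchar(motif) - 1L) {
      stop("plant_spec: reference-gap insertions must fit between motif characters")
    }
  }
  structure(list(motif = toupper(motif), block_index = as.integer(block_index),
                 u_position = as.integer(u_position), edits = edits),
            class = "plant_spec")
}

draw_seq <- function(n, background) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = background), collapse = "")
}

# all 0-based occurrence starts of `motif` in `seq` (overlapping included)
naive_occurrences <- function(motif, seq) {
  n <- nchar(seq); L <- nchar(motif)
  if (L > n) return(integer(0))
  starts <- seq_len(n - L + 1L)
  starts[substring(toupper(seq), starts, starts + L - 1L) == toupper(motif)] - 1L
}

#' Generate a synthetic MAF file with planted motifs and exact ground truth
#'
#' Block reference sequences are drawn from the background frequencies with
#' motifs planted verbatim; compared genomes are copies of the reference with
#' the plant edit plan applied inside motif spans and light random divergence
#' outside them. Deterministic given `seed`.
#'
#' @param n_blocks number of alignment blocks.
#' @param n_genomes number of genomes per block (>= 2; the first, `g1`, is the
#'   reference/searched genome).
#' @param block_width ungapped reference length of each block.
#' @param plants list of [plant_spec()] objects; plants within one block must
#'   not overlap.
#' @param seed RNG seed.
#' @param background A/C/G/T frequencies of the random sequence.
#' @param divergence substitution rate applied to compared genomes outside
#'   motif spans (does not affect ground truth).
#' @param max_tries rejection-sampling cap per block.
#' @return list with `maf` (MAF text), `blocks` (parsed block list), `truth`
#'   (data frame: one row per plant x compared genome with expected
#'   coordinates, vector and percent), `kmers` (a [kmer_set()] of the unique
#'   planted motifs with ids matching `truth$motif_id`).
#' @export
generate_maf <- function(n_blocks, n_genomes, block_width, plants, seed = 1L,
                         background = rep(0.25, 4), divergence = 0.02,
                         max_tries = 1000L) {
  stopifnot(n_blocks >= 1L, n_genomes >= 2L, block_width >= 4L)
  background <- validate_background(background)
  genomes <- paste0("g", seq_len(n_genomes))
  motifs_uniq <- unique(vapply(plants, function(p) p$motif, character(1)))
  motif_ids <- setNames(paste0("m", seq_along(motifs_uniq)), motifs_uniq)

  for (p in plants) {
    if (p$block_index >= n_blocks) stop("generate_maf: plant block_index out of range")
    if (p$u_position + nchar(p$motif) > block_width) {
      stop("generate_maf: plant does not fit inside its block")
    }
    for (g in names(p$edits)) {
      if (!g %in% genomes[-1]) stop("generate_maf: unknown compared genome ", g)
    }
  }
  # overlapping plants in one block are a generation error
  by_block <- split(plants, vapply(plants, function(p) p$block_index, integer(1)))
  for (bp in by_block) {
    if (length(bp) < 2L) next
    spans <- do.call(rbind, lapply(bp, function(p) {
      c(p$u_position, p$u_position + nchar(p$motif))
    }))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (any(spans[-1, 1] < spans[-nrow(spans), 2])) {
      stop("generate_maf: overlapping plants in one block")
    }
  }
  # cross-containment makes exact ground truth impossible (motif A inside
  # planted motif B occurs deterministically): refuse up front
  if (length(motifs_uniq) > 1L) {
    for (a in motifs_uniq) for (b in motifs_uniq) {
      if (a != b && grepl(a, b, fixed = TRUE)) {
        stop("generate_maf: motif ", a, " is a substring of motif ", b)
      }
    }
  }

  with_seed(seed, {
    blocks <- list()
    truth <- list()
    starts <- setNames(rep(0L, n_genomes), genomes)  # per-genome running start
    src_size <- as.integer(n_blocks * block_width + 1000L)

    for (b in seq_len(n_blocks) - 1L) {
      bp <- by_block[[as.character(b)]] %||% list()
      planted_starts <- lapply(motifs_uniq, function(m) {
        unlist(lapply(bp, function(p) if (p$motif == m) p$u_position else NULL)) %||% integer(0)
      })
      names(planted_starts) <- motifs_uniq

      ref <- NULL
      for (try in seq_len(max_tries)) {
        cand <- draw_seq(block_width, background)
        for (p in bp) {
          substr(cand, p$u_position + 1L, p$u_position + nchar(p$motif)) <- p$motif
        }
        ok <- all(vapply(motifs_uniq, function(m) {
          identical(naive_occurrences(m, cand), sort(planted_starts[[m]]))
        }, logical(1)))
        if (ok) { ref <- cand; break }
      }
      if (is.null(ref)) {
        stop("generate_maf: could not draw a block free of spurious motif occurrences")
      }

      in_span <- rep(FALSE, block_width)
      for (p in bp) {
        in_span[(p$u_position + 1L):(p$u_position + nchar(p$motif))] <- TRUE
      }

      # per-genome character rows (columns = ungapped reference positions)
      ref_chars <- strsplit(ref, NULL)[[1]]
      mat <- matrix(rep(ref_chars, n_genomes), nrow = n_genomes, byrow = TRUE,
                    dimnames = list(genomes, NULL))
      # divergence outside motif spans for compared genomes
      for (gi in seq_len(n_genomes)[-1]) {
        flip <- which(!in_span & stats::runif(block_width) < divergence)
        if (length(flip)) {
          mat[gi, flip] <- vapply(mat[gi, flip], function(ch) {
            sample(setdiff(DNA_BASES, ch), 1L)
          }, character(1))
        }
      }

      # apply edit plans; record per-plant per-genome expected symbols
      inserts <- list()  # each: list(after_upos, genome, char)
      plant_info <- list()
      for (p in bp) {
        L <- nchar(p$motif)
        span <- (p$u_position + 1L):(p$u_position + L)  # 1-based columns
        per_genome <- list()
        for (g in genomes[-1]) {
          e <- p$edits[[g]] %||% list()
          subs <- e$subs %||% 0L; cgaps <- e$cmp_gaps %||% 0L; rgaps <- e$ref_gaps %||% 0L
          pos_pool <- sample(seq_len(L))      # positions within the motif
          sub_pos <- sort(pos_pool[seq_len(subs)])
          gap_pos <- sort(pos_pool[subs + seq_len(cgaps)])
          for (k in sub_pos) {
            mat[g, span[k]] <- sample(setdiff(DNA_BASES, mat[g, span[k]]), 1L)
          }
          for (k in gap_pos) mat[g, span[k]] <- "-"
          rg_offsets <- if (rgaps > 0L) sort(sample(seq_len(L - 1L), rgaps)) else integer(0)
          for (o in rg_offsets) {
            inserts[[length(inserts) + 1L]] <-
              list(after_upos = p$u_position + o, genome = g,
                   char = sample(DNA_BASES, 1L, prob = background))
          }
          symbols <- rep("1", L)
          symbols[sub_pos] <- "0"
          symbols[gap_pos] <- "0"
          per_genome[[g]] <- list(symbols = symbols, rg_offsets = rg_offsets)
        }
        plant_info[[length(plant_info) + 1L]] <- list(plant = p, per_genome = per_genome)
      }

      # assemble gapped columns: before reference position u, emit any
      # insertion columns registered at that point (ordered by genome)
      ins_at <- split(inserts, vapply(inserts, function(x) x$after_upos, integer(1)))
      cols <- vector("list", 0L)
      colmap <- integer(block_width)  # ungapped ref pos (1-based) -> column (1-based)
      for (u in seq_len(block_width)) {
        key <- as.character(u - 1L)
        for (ins in (ins_at[[key]] %||% list())) {
          col <- rep("-", n_genomes)
          col[match(ins$genome, genomes)] <- ins$char
          cols[[length(cols) + 1L]] <- col
        }
        colmap[u] <- length(cols) + 1L
        cols[[length(cols) + 1L]] <- mat[, u]
      }
      gapped <- do.call(cbind, cols)
      texts <- apply(gapped, 1, paste, collapse = "")

      seqs <- lapply(seq_len(n_genomes), function(gi) {
        txt <- texts[gi]
        size <- nchar(gsub("-", "", txt, fixed = TRUE))
        aligned_sequence(paste0(genomes[gi], ".chr1"), starts[gi], size, "+",
                         src_size, txt)
      })
      for (gi in seq_len(n_genomes)) starts[gi] <- starts[gi] + seqs[[gi]]$size
      blocks[[length(blocks) + 1L]] <- alignment_block(seqs)

      # ground-truth rows
      for (pi in plant_info) {
        p <- pi$plant; L <- nchar(p$motif)
        g_start <- colmap[p$u_position + 1L] - 1L
        g_end <- colmap[p$u_position + L]    # 0-based half-open
        pcts <- numeric(0)
        rows <- list()
        for (g in genomes[-1]) {
          info <- pi$per_genome[[g]]
          # interleave "–" symbols at this genome's insertion offsets;
          # other genomes' insertion columns are gap/gap for g and ignored
          vec_syms <- character(0)
          for (k in seq_len(L)) {
            offs <- info$rg_offsets
            if (k > 1L && (k - 1L) %in% offs) vec_syms <- c(vec_syms, SIM_REFGAP)
            vec_syms <- c(vec_syms, info$symbols[k])
          }
          vec <- paste(vec_syms, collapse = "")
          pct <- 100 * sum(vec_syms == "1") / length(vec_syms)
          pcts <- c(pcts, pct)
          rows[[length(rows) + 1L]] <- data.frame(
            motif_id = unname(motif_ids[p$motif]), motif = p$motif,
            block_index = b,
            u_start = p$u_position, u_end = p$u_position + L,
            g_start = g_start, g_end = g_end,
            fwd_start = seqs[[1]]$start + p$u_position,
            fwd_end = seqs[[1]]$start + p$u_position + L,
            chromosome = "chr1",
            compared_src = paste0(g, ".chr1"),
            vector = vec, percent = pct,
            stringsAsFactors = FALSE)
        }
        bc <- mean(pcts)
        for (r in rows) {
          r$block_conservation <- bc
          truth[[length(truth) + 1L]] <- r
        }
      }
    }

    truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
    km <- if (length(motifs_uniq)) {
      kmer_set(motifs_uniq, unname(motif_ids[motifs_uniq]))
    }
    list(maf = format_maf(blocks), blocks = blocks, truth = truth_df,
         kmers = km)
  })
}
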