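# Search engine: gap indexing, coordinate mapping, the three finders (each
# against an independent oracle), genomic coordinate conversion and the
# per-block driver.

test_that("build_gap_index maps ungapped positions to gapped columns", {
  gi <- build_gap_index("AC-G-T")
  expect_equal(gi$ungapped, "ACGT")
  expect_equal(gi$u2g, c(0L, 1L, 3L, 5L))

  gi2 <- build_gap_index("ACGT")        # gap-free: identity
  expect_equal(gi2$u2g, 0:3)

  gi3 <- build_gap_index("----")        # all gaps
  expect_equal(gi3$ungapped, "")
  expect_length(gi3$u2g, 0)
})

test_that("map_to_gapped maps spans and round-trips the matched text", {
  gi <- build_gap_index("AC-G-T")
  expect_equal(map_to_gapped(gi, 1, 3), c(1L, 4L))   # "CG" -> "C-G"
  expect_equal(map_to_gapped(gi, 0, 4), c(0L, 6L))   # full span
  gi2 <- build_gap_index("ACGT")
  expect_equal(map_to_gapped(gi2, 1, 3), c(1L, 3L))  # identity on gap-free
  expect_error(map_to_gapped(gi, 3, 5), "out of range")
  expect_error(map_to_gapped(gi, 2, 2), "out of range")

  # property: ungapping the gapped slice reproduces the ungapped slice
  set.seed(31)
  for (rep in 1:50) {
    txt <- paste(sample(c("A", "C", "G", "T", "-", "-"), 30, replace = TRUE),
                 collapse = "")
    gi <- build_gap_index(txt)
    n <- nchar(gi$ungapped)
    if (n < 2) next
    s <- sample(0:(n - 2), 1); e <- sample((s + 1):n, 1)
    g <- map_to_gapped(gi, s, e)
    slice <- substr(txt, g[1] + 1, g[2])
    expect_equal(gsub("-", "", slice, fixed = TRUE),
                 substr(gi$ungapped, s + 1, e))
    # boundary columns of the span are never gaps
    expect_false(substr(slice, 1, 1) == "-")
    expect_false(substr(slice, nchar(slice), nchar(slice)) == "-")
  }
})

test_that("find_kmer_hits reports all overlapping occurrences (spec examples)", {
  km <- kmer_set("ACA", "k1")
  h <- find_kmer_hits(km, "ACACA")
  expect_equal(h$u_start, c(0L, 2L))
  expect_equal(h$u_end, c(3L, 5L))

  expect_equal(nrow(find_kmer_hits(kmer_set("AAA"), "CCCC")), 0)

  km2 <- kmer_set(c("AC", "ACA"), c("a", "b"))
  h2 <- find_kmer_hits(km2, "ACA")
  expect_equal(h2$motif_id, c("a", "b"))
  expect_equal(h2$u_start, c(0L, 0L))
  expect_equal(h2$u_end, c(2L, 3L))

  # case-insensitive matching, original case reported
  h3 <- find_kmer_hits(kmer_set("acgt", "m"), "ttAcGtt")
  expect_equal(h3$matched_sequence, "AcGt")
  expect_equal(h3$u_start, 2L)
})

test_that("find_kmer_hits equals the naive scan oracle on random instances", {
  set.seed(17)
  for (rep in 1:120) {
    n_pat <- sample(1:5, 1)
    pats <- vapply(seq_len(n_pat),
                   function(i) random_dna(sample(2:6, 1)), character(1))
    ids <- paste0("p", seq_len(n_pat))
    seq <- random_dna(sample(10:80, 1), prob = c(0.4, 0.1, 0.1, 0.4))
    got <- find_kmer_hits(kmer_set(pats, ids), seq)
    want <- oracle_kmer_hits(pats, ids, seq)
    expect_equal(got[c("motif_id", "u_start", "u_end")],
                 want[c("motif_id", "u_start", "u_end")],
                 ignore_attr = TRUE)
  }
})

test_that("find_pwm_hits matches all-window scoring and skips non-ACGT windows", {
  p <- calibrate_threshold(consensus_pwm("AC"), p_value = 0.1,
                           n_samples = 5000, seed = 2)
  h <- find_pwm_hits(p, "TTACTT")
  expect_equal(h$u_start, 2L)
  expect_equal(h$u_end, 4L)
  expect_equal(h$matched_sequence, "AC")
  expect_true(h$p_value <= 0.1)

  expect_equal(nrow(find_pwm_hits(p, "NNNN")), 0)   # no valid window
  expect_equal(nrow(find_pwm_hits(p, "A")), 0)      # shorter than the motif

  # p = 1: every ACGT-only window is a hit
  p1 <- calibrate_threshold(consensus_pwm("AC"), p_value = 1.0,
                            n_samples = 1000, seed = 2)
  expect_equal(nrow(find_pwm_hits(p1, "ACGTN")), 3)  # windows AC, CG, GT

  expect_error(find_pwm_hits(consensus_pwm("AC"), "ACGT"), "calibrat")
})

test_that("find_pwm_hits equals the per-window oracle on random instances", {
  set.seed(23)
  p <- calibrate_threshold(mixed_pwm8(), p_value = 0.01,
                           n_samples = 20000, seed = 5)
  for (rep in 1:60) {
    seq <- random_dna(sample(20:120, 1))
    if (rep %% 7 == 0) substr(seq, 5, 5) <- "N"
    got <- find_pwm_hits(p, seq)
    want <- oracle_pwm_hits(p, seq)
    expect_equal(got$u_start, want$u_start)
    expect_equal(got$score, want$score)
  }
})

test_that("find_regex_hits uses leftmost non-overlapping semantics (spec examples)", {
  rs <- regex_set("GA+T", "r1")
  h <- find_regex_hits(rs, "GAATXGAT")
  expect_equal(h$u_start, c(0L, 5L))
  expect_equal(h$u_end, c(4L, 8L))
  expect_equal(h$matched_sequence, c("GAAT", "GAT"))

  expect_equal(nrow(find_regex_hits(regex_set("^$"), "ACGT")), 0)
  expect_equal(nrow(find_regex_hits(regex_set("X*"), "ACGT")), 0)  # zero-length dropped
  expect_error(regex_set("("), "compile")
})

test_that("find_regex_hits equals the scan-and-resume oracle on random instances", {
  set.seed(29)
  pieces <- c("GA+T", "AC.T", "(CG){2,}", "T{3}", "A[CG]A")
  for (rep in 1:100) {
    pat <- sample(pieces, 1)
    seq <- random_dna(sample(15:100, 1), prob = c(0.3, 0.2, 0.2, 0.3))
    got <- find_regex_hits(regex_set(pat, "r"), seq)
    want <- oracle_regex_hits(pat, seq)
    expect_equal(got$u_start, want$u_start)
    expect_equal(got$u_end, want$u_end)
  }
})

test_that("to_genomic converts both strands (hand-computed cases)", {
  plus <- aligned_sequence("hg.chr1", 10L, 20L, "+", 100L,
                           paste(rep("A", 20), collapse = ""))
  g <- to_genomic(plus, 5, 9)
  expect_equal(c(g$fwd_start, g$fwd_end), c(15, 19))
  expect_equal(g$chrom, "chr1")
  expect_equal(g$genome, "hg")

  minus <- aligned_sequence("hg.chr1", 10L, 20L, "-", 100L,
                            paste(rep("A", 20), collapse = ""))
  g2 <- to_genomic(minus, 5, 9)
  expect_equal(c(g2$fwd_start, g2$fwd_end), c(81, 85))

  # full span on "+" is [start, start + size)
  g3 <- to_genomic(plus, 0, 20)
  expect_equal(c(g3$fwd_start, g3$fwd_end), c(10, 30))

  # src without "." -> chrom = src
  nodot <- aligned_sequence("plasmid", 0L, 4L, "+", 10L, "ACGT")
  expect_equal(to_genomic(nodot, 0, 4)$chrom, "plasmid")
  expect_error(to_genomic(plus, 10, 25), "out of range")
})

test_that("search_block maps hits through gaps and scores conservation (spec example)", {
  block <- parse_maf(c("a",
                       "s hg.chr1 0 4 + 100 AC-GT",
                       "s mm.chr1 0 5 + 100 ACAGT"))[[1]]
  hits <- search_block(block, kmer_set("ACGT", "m1"))
  expect_length(hits, 1)
  h <- hits[[1]]
  expect_equal(c(h$u_start, h$u_end), c(0L, 4L))
  expect_equal(c(h$g_start, h$g_end), c(0L, 5L))
  expect_equal(h$records[[1]]$vector, paste0("11", SIM_DASH, "11"))
  expect_equal(h$records[[1]]$percent, 80)
  expect_equal(h$block_conservation, 80)

  # motif absent -> empty list
  expect_length(search_block(block, kmer_set("GGGG")), 0)
})

test_that("search_block honours search_src, genome_ids and reverse complement", {
  block <- parse_maf(c("a",
                       "s hg.chr1 0 6 + 100 ATGCAT",
                       "s mm.chr1 0 6 + 100 ATGCAT",
                       "s rn.chr2 0 6 + 100 ATGAAT"))[[1]]
  # search a named source instead of the reference
  h <- search_block(block, kmer_set("ATGCAT", "m"), search_src = "mm")
  expect_length(h, 1)
  expect_equal(h[[1]]$genome, "mm")
  expect_length(h[[1]]$records, 2)

  # genome_ids restricts the comparison set
  h2 <- search_block(block, kmer_set("ATGCAT", "m"), genome_ids = "rn")
  expect_length(h2[[1]]$records, 1)
  expect_equal(h2[[1]]$records[[1]]$compared_src, "rn.chr2")

  # block lacking the searched source is skipped
  expect_null(search_block(block, kmer_set("AT"), search_src = "dr"))

  # rc: k-mer "CAT" is revcomp "ATG"; hit reported on "-" where forward is ATG
  h3 <- search_block(block, kmer_set("CAT", "m"), rc = TRUE)
  strands <- vapply(h3, function(x) x$strand_of_match, character(1))
  starts <- vapply(h3, function(x) x$u_start, integer(1))
  expect_true(any(strands == "-" & starts == 0L))  # ATG at 0 on "-"
  expect_true(any(strands == "+" & starts == 3L))  # CAT at 3 on "+"
  minus_hit <- h3[[which(strands == "-" & starts == 0L)]]
  expect_equal(minus_hit$matched_sequence, "ATG")  # forward-strand text
})

test_that("regex reverse-complement hits map back to forward coordinates", {
  block <- parse_maf(c("a",
                       "s hg.chr1 0 8 + 100 TTATCTTT",
                       "s mm.chr1 0 8 + 100 TTATCTTT"))[[1]]
  # pattern GA+T matches the revcomp AAAGATAA at [4,7) ("GAT");
  # forward span is [1,4) = "TAT" whose revcomp is ATA... use exact arithmetic:
  # revcomp(TTATCTTT) = AAAGATAA; GA+T matches at 0-based [3,6) -> fwd [2,5)
  h <- search_block(block, regex_set("GA+T", "r"), rc = TRUE)
  strands <- vapply(h, function(x) x$strand_of_match, character(1))
  expect_true("-" %in% strands)
  mh <- h[[which(strands == "-")[1]]]
  expect_equal(c(mh$u_start, mh$u_end), c(2L, 5L))
  expect_equal(mh$matched_sequence, "ATC")   # forward text; revcomp = GAT
})

test_that("block independence: permuting blocks permutes output groups only", {
  set.seed(37)
  blocks <- four_block_maf()
  km <- kmer_set(c("ACGT", "GATTACA"), c("m1", "m2"))
  fwd <- lapply(seq_along(blocks), function(i) {
    search_block(blocks[[i]], km, block_index = i - 1L)
  })
  perm <- c(3, 1, 4, 2)
  back <- lapply(perm, function(i) {
    search_block(blocks[[i]], km, block_index = i - 1L)
  })
  for (k in seq_along(perm)) {
    expect_equal(back[[k]], fwd[[perm[k]]])
  }
})
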