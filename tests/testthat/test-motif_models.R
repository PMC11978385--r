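# Motif models: k-mer/JASPAR/regex parsing, log-odds, threshold calibration,
# empirical p-values, reverse complement, Benjamini-Hochberg.

test_that("parse_kmer_file handles bare, id-tagged and malformed lines", {
  km <- parse_kmer_file(c("GATTACA"))
  expect_equal(km$ids, "kmer_1")
  expect_equal(km$sequences, "GATTACA")

  km2 <- parse_kmer_file(c("m1\tacgt"))
  expect_equal(km2$ids, "m1")
  expect_equal(km2$sequences, "ACGT")   # case folding

  expect_error(parse_kmer_file(c("AC-GT")), "gap")
  expect_error(parse_kmer_file(c("AC GT")), "gap|whitespace")
  expect_error(kmer_set(c("AA", "CC"), c("x", "x")), "unique")
})

test_that("parse_jaspar reads records in any row order, rejects malformed ones", {
  rec <- c(">M1 first", "A [ 4 0 ]", "C [ 0 4 ]", "G [0 0]", "T  [ 0 0 ]")
  p <- parse_jaspar(rec)
  expect_length(p, 1)
  expect_equal(ncol(p[[1]]$counts), 2)
  expect_equal(unname(p[[1]]$counts["A", 1]), 4)
  expect_equal(unname(p[[1]]$counts["C", 2]), 4)

  two <- parse_jaspar(c(rec, ">M2", "T [ 1 ]", "G [ 2 ]", "C [ 3 ]", "A [ 4 ]"))
  expect_length(two, 2)
  expect_equal(two[[2]]$name, "M2")
  expect_equal(unname(two[[2]]$counts[, 1]), c(4, 3, 2, 1))

  expect_error(parse_jaspar(c(">B1", "A [ 1 2 3 ]", "C [ 1 2 ]",
                              "G [ 1 2 3 ]", "T [ 1 2 3 ]")),
               "B1.*unequal")
  expect_error(parse_jaspar(c(">B2", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]")),
               "B2.*missing")
})

test_that("build_log_odds follows the stated formula", {
  # uniform counts, uniform background: odds ratio 1 everywhere
  lo <- build_log_odds(matrix(1, 4, 3), NULL, pseudocount = 0.1)
  expect_equal(unname(lo), matrix(0, 4, 3))

  # hand arithmetic: column [4,0,0,0], pc 0.1 -> A entry log2((4.1/4.4)/0.25)
  lo2 <- build_log_odds(matrix(c(4, 0, 0, 0), 4, 1), NULL, pseudocount = 0.1)
  expect_equal(unname(lo2["A", 1]), log2((4.1 / 4.4) / 0.25), tolerance = 1e-12)
  expect_equal(unname(lo2["C", 1]), log2((0.1 / 4.4) / 0.25), tolerance = 1e-12)

  # scale invariance in the pseudocount -> 0 limit
  a <- build_log_odds(matrix(c(3, 1, 5, 1), 4, 1), NULL, pseudocount = 1e-9)
  b <- build_log_odds(2 * matrix(c(3, 1, 5, 1), 4, 1), NULL, pseudocount = 1e-9)
  expect_equal(a, b, tolerance = 1e-6)

  expect_error(build_log_odds(matrix(1, 4, 2), c(0.5, 0.5, 0.5, 0.5)), "sum")
})

test_that("calibrate_threshold is deterministic and degenerates correctly at p = 1", {
  p <- consensus_pwm("ACGT")
  c1 <- calibrate_threshold(p, p_value = 1.0, n_samples = 1000, seed = 3)
  expect_equal(c1$threshold, min(c1$null_scores))  # every window is a hit

  c2 <- calibrate_threshold(p, p_value = 0.05, n_samples = 5000, seed = 9)
  c3 <- calibrate_threshold(p, p_value = 0.05, n_samples = 5000, seed = 9)
  expect_identical(c2$threshold, c3$threshold)
  expect_identical(c2$null_scores, c3$null_scores)
  c4 <- calibrate_threshold(p, p_value = 0.05, n_samples = 5000, seed = 10)
  expect_false(identical(c2$null_scores, c4$null_scores))

  expect_error(calibrate_threshold(p, p_value = 0), "p_value")
  expect_error(calibrate_threshold(p, n_samples = 10), "n_samples")
})

test_that("calibrated threshold matches the exact enumerated quantile for small L", {
  # L = 4 mixed-count PWM: enumerate all 4^4 windows as the exact null
  counts <- rbind(A = c(5, 1, 0, 2), C = c(1, 6, 2, 1),
                  G = c(2, 0, 7, 1), T = c(1, 2, 0, 5))
  p <- pwm("toy4", counts)
  p_val <- 0.05
  cal <- calibrate_threshold(p, p_value = p_val, n_samples = 50000, seed = 21)

  null <- oracle_enumerate_null(p)
  exact_tail <- function(thr) sum(null$prob[null$score >= thr])
  # enumerated tail at the calibrated threshold is within sampling error of p
  se <- sqrt(p_val * (1 - p_val) / 50000)
  expect_lt(abs(exact_tail(cal$threshold) - p_val), 5 * se + 1e-12)
  # conservative convention: empirical exceedance on the null sample <= p
  expect_lte(mean(cal$null_scores >= cal$threshold), p_val)
})

test_that("log-odds columns have non-positive expected score under the background", {
  set.seed(5)
  for (rep in 1:20) {
    counts <- matrix(rexp(4 * 5), 4, 5)
    bg <- rexp(4); bg <- bg / sum(bg)
    lo <- build_log_odds(counts, bg, pseudocount = 0.1)
    for (j in 1:5) expect_lte(sum(bg * lo[, j]), 1e-12)
  }
})

test_that("empirical_p_value is an add-one tail, monotone, enumeration-consistent", {
  ns <- sort(c(1, 2, 3, 4, 5))
  expect_equal(empirical_p_value(10, ns), 1 / 6)       # above max
  expect_equal(empirical_p_value(0, ns), 1)            # below min
  expect_equal(empirical_p_value(1, ns), 1)            # ties at min count as >=
  expect_equal(empirical_p_value(3, ns), (1 + 3) / 6)
  # agrees with the direct definition on random data, vectorised
  set.seed(8)
  null <- sort(rnorm(500))
  scores <- rnorm(50)
  direct <- vapply(scores, function(s) (1 + sum(null >= s)) / 501, numeric(1))
  expect_equal(empirical_p_value(scores, null), direct)
  expect_true(all(diff(empirical_p_value(sort(scores), null)) <= 0))
})

test_that("reverse_complement_pwm swaps and reverses; involution; palindrome fixed point", {
  p <- consensus_pwm("AC")
  rc <- reverse_complement_pwm(p)
  expect_equal(unname(rc$counts["G", 1]), 100)  # consensus AC -> GT
  expect_equal(unname(rc$counts["T", 2]), 100)
  back <- reverse_complement_pwm(rc)
  expect_equal(unname(back$counts), unname(p$counts))
  expect_equal(unname(back$log_odds), unname(p$log_odds))

  pal <- pwm("pal", rbind(A = c(2, 1), C = c(3, 4), G = c(4, 3), T = c(1, 2)))
  expect_equal(unname(reverse_complement_pwm(pal)$counts), unname(pal$counts))

  cal <- calibrate_threshold(p, 0.1, 1000, 1)
  expect_null(reverse_complement_pwm(cal)$threshold)
})

test_that("benjamini_hochberg matches the hand step-up and stats::p.adjust", {
  expect_equal(benjamini_hochberg(c(0.001, 0.02, 0.04)), c(0.003, 0.03, 0.04))
  expect_equal(benjamini_hochberg(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  set.seed(13)
  for (rep in 1:10) {
    pv <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(pv)
    expect_equal(q, stats::p.adjust(pv, method = "BH"))
    expect_true(all(q >= pv - 1e-15))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("validate_background defaults to uniform and rejects bad sums", {
  expect_equal(validate_background(NULL), rep(0.25, 4))
  expect_equal(validate_background(c(0.3, 0.2, 0.2, 0.3)), c(0.3, 0.2, 0.2, 0.3))
  expect_error(validate_background(c(0.5, 0.5, 0.5, 0.5)), "2")
  expect_error(validate_background(c(0.5, 0.5)), "four")
})
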