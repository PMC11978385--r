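---
title: "Motif detection and conservation scoring in MAF alignments: methods"
author: "mafscan developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif detection and conservation scoring in MAF alignments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafscan)
```

## The problem

Whole-genome (and whole-proteome) alignments are commonly distributed as UCSC
Multiple Alignment Format (MAF) files: a sequence of independent alignment
blocks, each holding one gapped row per genome, with the first row acting as
the block's reference. Biologists routinely need to know where short
functional motifs — transcription factor binding sites, CRISPR repeats,
protein signatures — occur in such alignments, and how well each occurrence
is conserved across the aligned genomes. General-purpose motif scanners work
on single sequences and ignore the alignment structure; `mafscan` searches
the blocks directly and scores conservation column-by-column against every
other genome in the block.

Searches never span block boundaries: blocks are independent alignment units,
which is also what makes parallel processing trivially safe.

## Motif models

Three motif classes are supported, mirroring how motifs are stored in
practice:

* **k-mers** — literal subsequences, matched exactly and case-insensitively.
  All patterns are compiled into a single Aho-Corasick automaton, so one pass
  over each sequence finds every (overlapping) occurrence of every pattern in
  time linear in the sequence length.
* **PWMs** — JASPAR-format count matrices. Column $j$ of the count matrix is
  turned into log-odds scores
  $w_{bj} = \log_2 \frac{(c_{bj} + s)/(\sum_b c_{bj} + 4s)}{\pi_b}$,
  with pseudocount $s$ (default 0.1) and background frequencies $\pi$
  (default uniform). A window of the motif's length is a hit when its summed
  score reaches the calibrated threshold (below).
* **regexes** — comma-separated patterns handed to the PCRE engine,
  case-insensitively, with standard leftmost non-overlapping
  (scan-and-resume) semantics per pattern. Zero-length matches are discarded:
  a motif has positive length.

### PWM threshold calibration

The hit threshold is tied to a target p-value (default $10^{-4}$) by
sampling: draw $n$ windows (default $10^5$) i.i.d. from the background
frequencies, score them, and take as threshold the smallest sampled score
whose empirical exceedance fraction is at most $p$ — the conservative
empirical $(1-p)$ quantile, which guarantees a hit rate $\le p$ on the null
sample itself. The sorted null sample is kept, and every reported hit gets
the add-one empirical p-value $(1 + \#\{\text{null} \ge \text{score}\})/(1 + n)$.
False discovery rates are Benjamini–Hochberg q-values computed across all
PWM hits of one run.

Two consequences of the conservative convention are worth knowing:

* For a very short or degenerate PWM the exact null can be so coarse that no
  score has tail probability $\le p$; the threshold is then placed above the
  maximum null score and the PWM yields no hits. This is deliberate — the
  alternative (anti-conservative rounding) would report hits at a false
  positive rate above the requested $p$.
* At $p = 10^{-4}$ and $n = 10^5$ the threshold is set by the 10 largest null
  scores, so the *true* tail probability at the threshold fluctuates around
  $p$ with standard deviation $\approx \sqrt{p/n} \approx 3\times 10^{-5}$.
  A validation experiment that rescores a large fresh null sample therefore
  sees the combined noise of both stages; the calibration test uses the
  combined binomial standard error
  $\sqrt{p(1-p)(1/n_{\mathrm{cal}} + 1/n_{\mathrm{val}})}$ as its yardstick.
  Using the validation-sample error alone would reject any correct
  implementation once $n_{\mathrm{val}} \gg n_{\mathrm{cal}}$.

$n = 10^5$ is the default because the $(1-p)$ quantile needs on the order of
$10/p$ samples for stability at the default $p = 10^{-4}$, while staying
fast on a laptop.

### Reverse-complement searches

With `rc = TRUE`, k-mer searches also run each pattern's reverse complement
(hits reported on strand `-` at the forward-strand position); PWM searches
additionally scan with the reverse-complemented matrix, calibrated
separately with a seed derived from the run seed; regex searches scan the
reverse complement of the subject and map coordinates back. A motif found in
both orientations at the same span is reported twice with opposite strands —
two distinct biological events. The reported `matched_sequence` is always
the forward-strand text of the searched sequence, in its original case.

## Conservation scoring

For each hit, the gapped columns of the motif span are compared between the
searched sequence and every other row of the block (optionally restricted to
a genome-ID list, matched against the src prefix before the first `.`). Per
column:

| searched | compared | symbol |
|----------|----------|--------|
| gap      | gap      | *(ignored)* |
| gap      | char     | `–` |
| char     | equal char (case-insensitive) | `1` |
| char     | unequal char or gap | `0` |

The conservation percentage is $100 \cdot \#1 / L$ where $L$ counts every
emitted symbol — `0` **and** `–` both sit in the denominator. The block-level
conservation of a hit is the unweighted mean over the compared genomes with a
defined percentage; a comparison whose span is entirely gap/gap has no
defined percentage, is flagged with a warning, and is excluded from the mean.

Note that `–` symbols make the vector *longer* than the ungapped motif: a
reference gap inside the motif span adds a column. The four per-column rules
and the ratio definition above are taken as authoritative; "N vs N" counts
as a match (literal equality — no special ambiguity handling).

## Coordinates

Every hit carries three coordinate systems, all 0-based half-open:

* `u_start`/`u_end` — offsets on the ungapped searched sequence of the block;
* `g_start`/`g_end` — gapped block columns (`g_start` maps the first motif
  character, `g_end` is one past the column of the last; interior columns may
  be gaps);
* `fwd_start`/`fwd_end` — forward-strand genomic coordinates. MAF starts are
  strand-relative, so on `+` rows `fwd_start = start + u_start` and on `-`
  rows `fwd_start = srcSize - (start + u_end)`.

`strand_of_match` is the orientation of the motif relative to the aligned
text of the searched row. For minus-strand rows the genomic orientation of
the motif is the product of the two strands; the BED writer reports
`strand_of_match` directly, which is exact whenever the searched rows are on
`+` (the usual case for a reference genome).

## Parallelism and determinism

The file is split into at most `processes` byte ranges whose boundaries are
snapped forward to the next `a` line, so each chunk parses to whole blocks
and the concatenation of per-chunk parses equals the single-pass parse.
Workers are forked (`parallel::mclapply`); results are merged in chunk
order, i.e. file order, regardless of completion order. All randomness
(threshold calibration) runs in the parent before workers start, and run
metadata deliberately omits the process count, so BED/JSON/CSV outputs are
byte-identical for any `processes` value. On non-unix platforms the workers
fall back to sequential evaluation with identical results.

## The synthetic-data generator

`generate_maf()` builds test worlds with exact ground truth: reference
sequences drawn i.i.d. from the background frequencies (uniform by default),
motifs planted verbatim at prescribed positions, and compared genomes derived
from the reference by a per-genome edit plan — `subs` substituted positions
(expected symbol `0`), `cmp_gaps` compared-side gaps (`0`), and `ref_gaps`
inserted reference-gap columns (`–`, lengthening the vector). Inserted
columns hold a gap in every other genome, so they are invisible (gap/gap) to
the other comparisons. Outside motif spans, compared genomes receive light
random divergence (default 2% substitutions) for realism; it cannot affect
the truth table, which only concerns motif spans of the searched genome.

Blocks are rejection-sampled so that no planted motif occurs anywhere in a
reference sequence except where planted (cross-containment between motifs is
refused up front, since no amount of redrawing can fix it). Ground truth is
therefore exact, and the end-to-end tests demand *exact* recovery — same
coordinates, same vectors, same percentages.

What the generator does **not** emulate: realistic indel/substitution
processes, phylogenetic correlation between genomes, soft-masked case
structure, or minus-strand rows. A green end-to-end test establishes that
the pipeline's bookkeeping (parsing, searching, mapping, scoring, writing)
is exact on alignments of this idealized form — not that the tool has been
validated on real whole-genome alignments.

## Numerical and design choices

* Log-odds use base 2; any base is monotone-equivalent, base 2 is stated for
  reproducibility.
* Pseudocount 0.1 on every count cell avoids infinite log-odds for zero
  counts.
* Background frequencies must sum to 1 within $10^{-6}$; absent, uniform is
  assumed.
* Block `score=` values are parsed and carried but unused downstream.
* MAF `i`/`e`/`q` lines are skipped (they carry no alignment text needed
  here); comments and blank lines are tolerated liberally; sequence text
  validation is permissive so protein MAFs parse.
* One motif mode per run; when a source ID is given, the searched row of a
  block is the first `s` line whose src or genome prefix equals the ID, and
  blocks lacking it are skipped with a debug log entry.
* The JSON key scheme `hit_<block>_<g_start>_<motif_id>_<strand>` is a
  documented convention of this package.

## Known limitations

* PWMs are nucleotide-only (4-row matrices); k-mers and regexes also work on
  protein alignments.
* No cross-block motif stitching; a motif truncated by a block boundary is
  not found.
* The p-value attached to PWM hits is the per-window probability under the
  background model, estimated from the calibration sample; no exact
  dynamic-programming tail computation is attempted.
* Wall-clock scaling with process count depends on hardware and is not
  asserted by the test suite; only the determinism contract is.
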