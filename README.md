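# mafscan

Motif detection and conservation scoring directly in Multiple Alignment
Format (MAF) files.

## What it is for

Whole-genome and whole-proteome alignments are distributed as MAF files: a
series of independent alignment blocks, each with one gapped row per genome,
the first row being the block's reference. Comparative genomicists who need
to locate short functional motifs — transcription factor binding sites,
CRISPR repeats, protein signatures — in such alignments usually have to
extract sequences, scan them, and then map everything back by hand.
`mafscan` scans the blocks directly and reports, for every motif instance,
its coordinates in three systems (ungapped, gapped block columns,
forward-strand genomic) plus a per-genome conservation score derived from
the alignment columns themselves.

Motifs can be given as:

* **k-mers** — literal sequences, matched with an Aho-Corasick automaton
  (all patterns in one linear pass, overlapping occurrences included);
* **PWMs** — JASPAR-format count matrices, scored as base-2 log-odds against
  a background; the hit threshold is calibrated to a target p-value
  (default 1e-4) by sampling windows from the background model, and each hit
  carries an empirical p-value and a Benjamini–Hochberg FDR;
* **regular expressions** — comma-separated PCRE patterns, leftmost
  non-overlapping matches per pattern.

For each hit, the motif span of the searched row is compared column-by-column
with every other row of the block. Per column: both gaps → ignored; searched
gap vs character → `–`; equal characters (case-insensitive) → `1`; anything
else (mismatch or compared gap) → `0`. The conservation percentage is
`100 · #1 / length(vector)` (both `0` and `–` count in the denominator), and
a hit's block conservation is the unweighted mean over the compared genomes.

Searches never cross block boundaries. Large files are split at block
boundaries across forked worker processes; outputs are byte-identical
regardless of the process count.

## Worked example

The package ships a synthetic-MAF generator that plants motifs with known
edits, so the example is fully self-contained:

```r
library(mafscan)

g <- generate_maf(3, 4, 80, list(
  plant_spec("GATTACA", 0, 12, edits = list(g2 = list(subs = 1),
                                            g3 = list(ref_gaps = 1))),
  plant_spec("TTAGGCAT", 2, 40, edits = list(g4 = list(cmp_gaps = 1)))
), seed = 99)
writeLines(sub("\n$", "", g$maf), "example.maf")
writeLines(paste(g$kmers$ids, g$kmers$sequences, sep = "\t"), "motifs.txt")

res <- run_scan("example.maf", kmers = "motifs.txt",
                bed = "hits.bed", csv = "hits.csv", seed = 1)
res$summary
#>   motif_id n_hits mean_block_conservation      min      max
#> 1       m1      1                91.07143 91.07143 91.07143
#> 2       m2      1                95.83333 95.83333 95.83333
```

`hits.bed` (BED6: chrom, forward-strand 0-based half-open span, name =
`motif|kind|block`, score = rounded block conservation, strand):

```
chr1	12	19	m1|kmer|0	91	+
chr1	200	208	m2|kmer|2	96	+
```

The first hit is `GATTACA` planted at position 12 of block 0. Its block
conservation 91.1% is the mean over the three compared genomes: `g2` has one
substitution (vector `1111101`, 85.7%), `g3` has one reference-gap column
inserted in the motif span (vector `11–11111`, 8 symbols, 87.5%), and `g4`
is identical (`1111111`, 100%). The CSV holds one row per comparison:

```
genome,chromosome,fwd_start,fwd_end,strand,motif_kind,motif_id,motif_length,matched_sequence,g_start,g_end,u_start,u_end,block_index,score,p_value,fdr,block_conservation,compared_src,similarity_vector,conservation_percent
g1,chr1,12,19,+,kmer,m1,7,GATTACA,12,20,12,19,0,,,,91.07142857,g2.chr1,1111101,85.71428571
g1,chr1,12,19,+,kmer,m1,7,GATTACA,12,20,12,19,0,,,,91.07142857,g3.chr1,11–11111,87.5
g1,chr1,12,19,+,kmer,m1,7,GATTACA,12,20,12,19,0,,,,91.07142857,g4.chr1,1111111,100
```

Note `g_end = 20` while `u_end = 19`: the inserted reference-gap column
widens the gapped span by one.

## Command line

The same pipeline is exposed as a CLI (installed under
`<library>/mafscan/exec/mafscan`, or call `mafscan_main()` directly):

```sh
mafscan example.maf --kmers motifs.txt --bed hits.bed --csv hits.csv
mafscan aln.maf --jaspar motifs.jaspar --pvalue 1e-4 \
        --background 0.3,0.2,0.2,0.3 --reverse-complement \
        --processes 8 --json hits.json
mafscan aln.maf --regexes "GTTTCAGA[ACGT]{28,36}GTTTCAGA" --search-genome g7
```

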