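# ribothrough

Detection and quantification of programmed stop-codon readthrough from
ribosome profiling data, in R.

Some mRNAs carry a second stop codon downstream of and in frame with the
canonical one. When ribosomes occasionally read through the canonical stop,
they translate the intervening segment — the **inter-stop codon region
(ISR)** — into a C-terminal protein extension, terminating at the downstream
stop. `ribothrough` provides the computational evidence chain for calling
such readthrough on a transcript:

- **ISR annotation** — scan for the first downstream in-frame stop, define
  the ISR, translate the extension, and partition the transcript into
  counting regions (5′UTR, CDS, ISR, distal 3′UTR) with 12-nt exclusion
  zones after the start codon and both stop codons.
- **Footprint mapping** — place ribosome footprint reads (≥ 24 nt) on
  transcripts by exact matching (100% identity, no mismatches or gaps), or
  ingest transcript-space SAM/BAM alignments; assign each read a P-site at
  its central nucleotide.
- **Four-criterion readthrough calling** — a dataset is positive for
  readthrough of a transcript iff
  1. ≥ 45 reads in the coding sequence,
  2. ≥ 1 read in the second half of the ISR,
  3. ≥ 10% of the ISR covered by footprints,
  4. footprint density (reads/nt) in the ISR ≥ 3× that of the rest of the
     3′UTR.
- **3-nt periodicity** — metagene profile around the start codon
  (offsets −24…62), selection of periodic fragment lengths (default
  27–29 nt), per-region reading-frame proportions `(f0, f1, f2)` and their
  coefficient of variation, CV = sd/mean. Translated regions show strong
  frame bias (high CV); untranslated regions are near-uniform (CV ≈ 0).
- **Proteogenomics** — build the 20-variant readthrough protein database
  (each standard amino acid substituted at the stop position), digest
  in silico with trypsin (configurable missed cleavages, default 5), and
  flag extension-specific peptides absent from a background proteome.
- **Reporter quantification** — percent readthrough from dual-luciferase
  readouts, `100 × mean(FLuc/RLuc)_stop / mean(FLuc/RLuc)_no-stop`, with a
  delta-method standard error; plus tethering-assay percent change and
  identifier-set overlap statistics.
- **Synthetic data** — a seeded generator for transcripts with a designed
  ISR, region- and frame-structured footprints, and noisy reporter
  readouts, so the whole pipeline is testable without any download.

## Worked example

Simulate an AGO1-like transcript (2,574-nt CDS, 99-nt ISR, 20-fold
ISR vs distal-3′UTR density excess), map the reads back and call
readthrough:

```r
library(ribothrough)

spec <- sim_spec(seed = 7)            # AGO1-like defaults
tx   <- make_transcript(spec)
tx$annotation
#> Transcript synth_seed7 ( 4426 nt )
#>   CDS:   251 - 2824
#>   ISR:   2825 - 2923  ( 33 codons )
#>   stop2: 2924 - 2926

nchar(translate_extension(tx$annotation))
#> [1] 34                                # readthrough residue + 33 ISR codons

sim <- simulate_footprints(tx, spec)
fp  <- map_reads(sim$reads, setNames(tx$sequence, "synth_seed7"))
st  <- region_stats(fp, tx$annotation)
call_readthrough(st)
#> Readthrough call: POSITIVE
#>   ISR/3'UTR density ratio: 19.9
#>    c1_cds_reads : TRUE
#>    c2_second_half : TRUE
#>    c3_coverage : TRUE
#>    c4_density_ratio : TRUE
```

The 19.9 is the exclusion-adjusted reads-per-nt density of the ISR divided
by that of the distal 3′UTR — here recovering the simulated 20-fold excess.
Frame analysis of the same footprints separates translated from
untranslated regions:

```r
frame_table(fp, tx$annotation, lengths = 27:29)
#>      region     n        f0        f1        f2        cv
#> 1       cds 19653 0.6062688 0.1999186 0.1938126 0.7091662
#> 2       isr    71 0.6197183 0.1971831 0.1830986 0.7443499
#> 3 utr3_rest    59 0.3728814 0.3050847 0.3220339 0.1058474
```

The CDS and ISR share the same frame-0 bias (readthrough continues in the
CDS frame), while the distal 3′UTR is near-uniform — the periodicity
signature of genuine ISR translation. A simulated dual-luciferase assay
with a true readthrough fraction of 0.2 recovers it:

```r
rs <- simulate_reporter(0.2, noise_cv = 0.1, n_replicates = 6, seed = 8)
percent_readthrough(rs$test, rs$control)
#> $percent
#> [1] 19.17774
#> $se
#> [1] 1.02762
```

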