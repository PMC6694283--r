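---
title: "Calling stop-codon readthrough from ribosome footprints: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling stop-codon readthrough from ribosome footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribothrough)
```

## The problem and the model

Translational readthrough produces a C-terminally extended protein isoform
when ribosomes decode the canonical stop codon as a sense codon and
continue to the next in-frame stop. Direct evidence comes from ribosome
profiling: footprints — the ~24–36-nt mRNA fragments protected by a
translating ribosome — found between the two stops (the inter-stop codon
region, ISR) indicate ribosomes translating past termination. Because the
3′UTR also collects background signal (scanning ribosomes, ligation
artifacts, residual mRNA contamination), a single ISR read is not
evidence; the package instead applies a conjunction of four deterministic
filters to the P-site-resolved footprint distribution of one transcript in
one dataset:

1. **Depth**: at least 45 P-sites in the coding sequence, so that the
   library actually sampled the transcript;
2. **Reach**: at least one read in the second half of the ISR, so that the
   signal is not just a termination-peak shoulder;
3. **Breadth**: at least 10% of the ISR covered by footprint spans, so
   that a single stacked position cannot qualify;
4. **Contrast**: ISR footprint density (reads/nt) at least 3× the density
   of the remaining 3′UTR, the region-level signal-to-background test.

Criteria are compared inclusively ("at least" means ≥). The verdict is the
conjunction; there is no significance test, because the criteria are
designed as conservative filters rather than estimators.

A complementary line of evidence is 3-nucleotide periodicity: P-sites of
elongating ribosomes fall preferentially into one residue class modulo 3.
The package quantifies this as the frame proportions `(f0, f1, f2)` of
P-sites in a region — frames defined relative to the annotated CDS start,
so the ISR inherits the CDS frame grid — summarized by their coefficient
of variation. Under frame uniformity the proportions are ≈ 1/3 each and
the CV is near 0; complete confinement to one frame gives the maximum
CV of √3 (n−1 convention, below).

## Region conventions

Coordinates are 1-based and closed throughout the package, the IRanges
convention; BED export converts to 0-based half-open. The transcript is
tiled by four counting regions:

| region      | interval                                | note |
|-------------|-----------------------------------------|------|
| `utr5`      | `[1, cds_start − 1]`                    | may be empty |
| `cds`       | `[cds_start, cds_end]`                  | includes the canonical stop codon |
| `isr`       | `[cds_end + 1, stop2_end]`              | includes the downstream stop codon |
| `utr3_rest` | `[stop2_end + 1, L]`                    | the background region |

A P-site on the canonical stop belongs to the CDS; one on the downstream
stop belongs to the ISR — readthrough ribosomes terminate there, so it is
part of the readthrough signal. Three 12-nt exclusion zones, starting
immediately after the start codon, the canonical stop and the downstream
stop, remove the initiation and termination peaks from counting. Excluded
positions are also removed from the density denominators ("effective
lengths"), so counts and lengths always refer to the same position set;
`use_effective_lengths = FALSE` switches to nominal denominators, and
`readthrough_report()` emits both ratios, since the convention affects the
ratio only through the two denominators (90 vs 102 for a 99-nt ISR). On
transcripts whose ISR is shorter than the zone width the zones overlap;
effective lengths are computed over distinct excluded positions.

Two criteria deliberately do **not** use the exclusion-adjusted machinery:

- the *second half* of the ISR is defined on the nominal ISR (between the
  stops, excluding both); for an ISR of `n` nt it begins `ceil(n/2)` nt in
  and extends through the downstream stop. Exclusions are not applied —
  the criterion asks whether such a read exists at all.
- *coverage* is the union of full footprint spans intersected with the
  nominal ISR, divided by the nominal ISR length. The criterion concerns
  physical coverage by footprints, for which the span, not the P-site, is
  the relevant object. A zero-length ISR (adjacent stops) has no defined
  coverage and auto-fails this criterion.

## P-sites and mapping

The P-site is estimated as the central nucleotide of the footprint. For
even lengths "central" is ambiguous; the package fixes the left-central
position (offset `len/2 − 1` from the 5′ end), a single documented
convention that keeps results deterministic. No per-length offset
calibration is attempted.

Mapping is by exact occurrence: a read is placed wherever it matches the
transcript verbatim (forward strand, no mismatches or gaps) and reads
shorter than 24 nt are discarded, as are reads containing `N` (which can
never match at 100% identity). Reads matching more than one location are
ambiguous and discarded by default (`multi = "keep-all"` keeps every hit;
discarding avoids double-counting density). Matching is full-read only;
local (partial-read) matching is a possible extension, not implemented.
Pre-aligned transcript-space SAM/BAM is ingested with the same filters
(forward strand, all-`M` CIGAR, `NM == 0` when `require_perfect`).
Quality and adapter trimming are upstream concerns and not reimplemented.

The density-ratio conventions avoid silent `NaN`s: the ratio is `+Inf`
when the 3′UTR density is 0 and the ISR density positive (criterion 4
holds), and 0 when the ISR density is 0 (criterion 4 fails), regardless of
the denominator.

## Periodicity parameters

The metagene profile pools P-site offsets relative to the A of the start
codon (offset 0) over the window −24…62 (87 columns), per fragment
length, storing `log(count + 1)` for display and the raw counts as an
attribute. Fragment-length selection defaults to the fixed set 27–29 nt,
the lengths that typically show clean periodicity; `auto = TRUE` instead
keeps lengths whose in-CDS (offset ≥ 0) frame-0 share exceeds 0.4, a
heuristic cutoff well above the uniform expectation of 1/3.

The CV uses the sample (n−1) standard deviation of the three proportions
divided by their mean. Since proportions sum to 1, the mean is exactly
1/3 and CV = 3·sd; the population-sd convention differs by the constant
√(2/3) and is available via `population = TRUE`. Closed forms used as
test anchors: CV(1/3, 1/3, 1/3) = 0, CV(1, 0, 0) = √3,
CV(0.5, 0.3, 0.2) ≈ 0.458.

## Proteogenomic database and digestion

Because the residue decoded at the stop codon is unknown, the search
database holds all 20 possibilities: `base + X + extension` for X over the
standard amino acids. Digestion follows the classical trypsin rule —
cleave after K or R, not before P; `rule = "trypsin/p"` drops the proline
exception (search engines differ on this). The missed-cleavage maximum
defaults to 5, appropriate for K/R-rich extensions. Reported peptides are
bounded to 7–40 residues by default (a typical search range; unbounded on
request). A peptide is *extension-specific* when it overlaps the
readthrough position or the extension and occurs verbatim neither in the
background proteome nor in the canonical protein; `il_equivalent = TRUE`
collapses I/L, which are isobaric. One subtlety of the proline rule: the
variant with P at the readthrough position suppresses the cleavage at the
base protein's C-terminal K/R, so its base-internal peptide set differs
from the other 19 variants'; under `trypsin/p` all 20 agree. Spectrum
matching, scoring and FDR control are out of scope — the module prepares
and interprets databases.

## Reporter arithmetic

Percent readthrough is the RLuc-normalized FLuc activity of the
stop-containing construct relative to a matched no-stop (sense-codon)
control: `100 × mean(FLuc/RLuc)_test / mean(FLuc/RLuc)_control`. The
ratio-of-means is the headline estimator (stable for the usual 3–6
replicates); the mean of per-replicate ratios is available as a mode. The
standard error propagates the two means' SEs by the delta method. The
statistic is invariant to rescaling all FLuc or all RLuc readouts, so
instrument units never matter. Readouts must be positive.

## What the generator emulates — and what it does not

`sim_spec()` defaults describe an AGO1-like transcript and a
readthrough-positive library: 250-nt 5′UTR, 2,574-nt CDS, 99-nt ISR
(33 codons), 1,500-nt distal 3′UTR; relative densities
`utr5:cds:isr:utr3_rest = 0.05 : 1 : 0.1 : 0.005` (a 20-fold ISR/3′UTR
excess, the magnitude seen in strongly positive cell-line data); P-site
frame probabilities `(0.6, 0.2, 0.2)` in CDS and ISR (a clear but not
extreme frame bias, between the CV levels observed for coding regions and
ISRs in real libraries) with frame-uniform UTRs; fragment lengths uniform
on 27–29 nt. Reads are allocated to regions with probability proportional
to density × length, placed so the central-nucleotide P-site falls on the
drawn position, and emitted verbatim from the transcript. CDS and ISR
codons are drawn from sense codons only, so no unintended in-frame stop
can arise, and every 24-mer is required to be unique (rejection-resampled)
so exact mapping is unambiguous. Reporter noise is multiplicative
log-normal, parameterized by a coefficient of variation, with the mean
correction `−σ²/2` so the expected ratio equals the design value.

The generator does **not** model sequencing errors, adapters, rRNA
contamination, repeat-induced multi-mapping, length-dependent P-site
offsets, biological positional heterogeneity (pause sites, codon-level
dwell times) or isoform mixtures. Passing tests therefore demonstrate
that the pipeline's logic is correct under its stated assumptions — not
that real libraries satisfy those assumptions; on real data the exclusion
zones and the four filters are the robustness mechanisms.

All randomness flows from a single integer seed; the read stream uses
`seed + 1` by default so sequence and footprints are reproducible
separately.

## Problem sizes and numerical checks

The test suite runs at sizes chosen to make sampling error negligible
relative to the asserted tolerances on a single CPU: the exact matcher is
checked against a brute-force sliding-window oracle on 1,000 random
transcript/read cases; digestion against a substring-enumeration oracle
on random 50-residue proteins; frame-bias recovery at 10,000 reads
(binomial 3σ bands); density-ratio recovery for true ratios
{1, 3, 5, 20} at 20,000 reads within 15%; and call calibration over 200
seeded replicates per arm at 5,000 reads (≥ 95% positive at a 5-fold
signal, ≤ 5% at the null). Degenerate inputs are pinned by tests:
zero-length ISRs, empty footprint sets, exclusion zones clipped at the
transcript end, even-length P-sites, all-zero density ratios.

## Known limitations

- Transcript space only: no genome coordinates, splicing or
  negative-strand handling.
- One ISR per transcript: only the first downstream in-frame stop is
  annotated; deeper stops are ignored.
- The exact matcher requires full-read identity; genuinely polymorphic or
  edited positions in a real transcript will drop reads rather than
  mismatch-tolerantly place them.
- Reporter statistics stop at point estimate + SE; no hypothesis tests.
- Uniqueness checks for peptides are exact string containment against the
  provided proteome, not a full translated-genome search.
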