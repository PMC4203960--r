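---
title: "Scanning promoter regions for tandem repeats, CpG islands and G-quadruplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning promoter regions for tandem repeats, CpG islands and G-quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`promoscan` characterises the sequence architecture of promoter regions —
by convention the 2 kb immediately upstream of a transcription start site
(TSS), written 5′→3′ on the gene's strand with the TSS-adjacent base last.
Four motif classes known to shape chromatin accessibility and transcription
are scanned, their abundance and positional distribution relative to the TSS
are summarised, their spatial arrangement with respect to CpG islands is
classified, and a comparative/enrichment statistical layer relates motif
content across species and to gene function. Avian promoters (chicken, duck,
zebra finch) are the motivating system — their GC-rich, repeat-poor genomes
make promoter motif composition quite different from mammals — but nothing
in the package is species-specific.

```{r, eval = FALSE}
library(promoscan)
cfg <- promoscan_config(
  simulate = list(n_promoters = 2000), seed = 1,
  compare = list(ref_tables = list(
    chicken = system.file("extdata", "chicken_promoter_strs.tsv",
                          package = "promoscan"))))
bundle <- run_all(cfg)
report_bundle(bundle)
```

## Coordinates

Intervals are 1-based and closed inside R (the `IRanges` convention);
exported BED6 files and all TSS-relative positions are 0-based half-open
with the TSS at 0, so the TSS-adjacent base occupies `[-1, 0)` and a
canonical TATA zone spanning bases 31–23 upstream of the TSS is reported as
`(-31, -22)`. `to_tss_coords()` / `from_tss_coords()` convert exactly in
both directions. Scanners treat `N` as a universal mismatch: no motif may
span an `N`, and `N` counts toward window lengths but toward no base count.

## Short tandem repeats

`scan_strs()` reports every maximal *perfect* tandem run of a primitive
2–6 bp unit with at least six complete repeat units (defaults chosen to
match the classic perfect-repeat survey conditions for promoter scans).
Decisions that fix the semantics where perfect-repeat tools differ:

* **Complete units only.** A run of length `L` at period `p` carries
  `floor(L / p)` units; trailing partial units are excluded from the
  reported interval.
* **Primitive period.** `(AG)₁₂` is one period-2 call, never additionally a
  period-4 `(AGAG)₆` call; mononucleotide runs (primitive period 1) are
  never reported, which also suppresses `GG`-type calls inside poly-G.
* **Left-greedy adjacency.** Where two runs of different motifs could share
  a base, the left run keeps its full extent and the right run restarts
  after it, surviving only if it still has six complete units (its unit
  becomes a rotation; the canonical motif is unchanged).

Motif families are labelled by `canonicalize_motif()`: the lexicographically
smallest string over all cyclic rotations of the unit and of its reverse
complement, so AC stands for AC/CA/GT/TG and `GGGGT` canonicalises to
`ACCCC`. A brute-force oracle (per-start, per-period substring stepping) is
part of the test suite and the scanner is asserted identical to it on
hundreds of seeded 2-kb sequences; that equivalence, not any one tool's
behaviour, defines the scanner's semantics.

Trinucleotide calls additionally carry a GC class (0/33/67/100%GC by the
count of G or C in the unit), which depends only on the unit's base multiset
and is therefore rotation- and strand-invariant.

## CpG islands

`scan_cgis()` applies the three traditional island criteria — window GC
content above 50%, observed/expected CpG ratio above 0.6 with
`O/E = N(CpG)·L / (N(C)·N(G))`, and a minimum length of 200 bp — with a
100-bp sliding window at step 1. All thresholds are strict: a window at GC
exactly 0.50 or O/E exactly 0.60 fails (the suite contains constructed
fixtures at both boundaries). Qualifying windows merge when their spans
overlap or abut; each candidate is then trimmed until every criterion holds
on the *reported* span. Trimming alternates two deterministic moves: ends
snap inward to CpG dinucleotides (the standard island-caller end
adjustment, without which merged candidates keep up to 99 bp of A/T flank),
and, while the whole span still fails, one bp is removed from whichever end
sits in the locally weaker 10-bp context (fewer C/G; ties trim the 5′ end).
Islands whose right edge reaches the promoter end are emitted as-is with
`truncated_at_tss = TRUE` — the caller never follows an island past the
TSS, so truncated islands can be hundreds of bp shorter than their true
genomic extent, which is worth remembering when interpreting island-length
distributions. Promoters are classed `NCGI` (no island), `LCGI` (total
island length strictly above 800 bp — a chicken-specific top-decile cut,
configurable; `classify_cgi_promoters()` reports the empirical quantile so
a top-decile cut can be re-derived on other data) or `other`.

## Potential G-quadruplexes

`scan_pqs()` enumerates placements of four G-tracts of equal length
`t ≥ 4` (the tetrad count) with loops of length ≥ 0 within a total span of
≤ 30 bp; a longer physical G-run may contribute a tract at any offset.
Candidates whose whole span is undisrupted poly-G are removed — G₃₀
yields no call — which also covers the all-loops-zero case. Overlaps are
resolved by a deterministic rank: larger tetrad, then smaller loop-length
variance, then smaller span, then leftmost; greedy selection keeps disjoint
calls. This rank replaces proprietary G4 scores, which the analysis never
uses — only presence and position matter downstream. Only the given strand
is scanned by default (`both_strands = TRUE` adds the C-rich strand,
reported on forward coordinates). A locus may legitimately be called by
both the STR and the PQS scanner — the 30-nt `(GGGGT)₆` repeat is the
canonical example — and no cross-scanner suppression is applied; only the
gene-group assignment for enrichment resolves such loci (below).

## Consensus motifs and positional structure

`scan_iupac()` matches degenerate IUPAC patterns on both strands (minus
hits on forward coordinates; `N` never matches). The shipped defaults are
the TATA box as `TATAWAW` (the canonical consensus — configurable, since
position preference rather than a fixed pattern is the robust observation)
and the distal consensus `CWGCWSWG` (C[A/T]GC[A/T][C/G][A/T]G).
`scan_polypurine()` reports maximal poly-A/poly-G runs of ≥ 10 bp by
default — long enough to exceed background run lengths at promoter-like
composition; the cutoff is a stated proxy for discovered motif blocks and
is exposed, so sensitivity to it can be reported rather than hidden.

Positional structure uses the distal `[-2000, -500)` / proximal
`[-500, -100)` / core `[-100, 0)` partition (half-open, fixing the
boundary bases that touching printed ranges leave ambiguous), 10-bp or
100-bp bin profiles (`bin_positions()`, count-conserving, midpoint anchor
by default to avoid edge bias for long calls), the per-position average GC
profile (`gc_profile()`), and the motif-vs-island arrangement classes:
*overlapped* (≥ 1 shared base), *intervened* (flanked by islands both
sides without overlap), *upstream* / *downstream* (5′ / 3′ of every
island — defined against all islands, consistent with the intervened
logic), *no_cgi*. These labels are exhaustive and mutually exclusive.

## Statistics

* `compare_frequency_tables()` ranks motifs by the reference table, removes
  the bottom 10% (floor; ties broken alphabetically), aligns the remaining
  motifs across tables with zero-fill, and reports Pearson `r` (Spearman
  available; counts, not percents, are correlated) plus Kendall τ-b.
* `kendall_tau_b()` implements tie-corrected τ-b with a normal-approximation
  two-sided p (tie-corrected variance); for n ≤ 8 without ties the null is
  enumerated exactly over all permutations. The Kendall distance
  `D = (1 − τ)·n(n − 1)/4` is returned as a derived convenience only.
* `mann_whitney_z()` returns U, the z score with tie correction and 0.5
  continuity correction, and a two-sided p — exact by labeling enumeration
  when both samples have ≤ 8 observations.
* `fisher_exact_2x2()` computes one- and two-sided p directly from the
  hypergeometric density (two-sided: sum of tables no more probable than
  observed). `fisher_exact_rxc()` is exact for moderate totals and falls
  back to a seeded Monte-Carlo p (10⁵ margin-preserving permutations,
  standard error reported).
* `go_enrichment()` tests one-sided over-representation of each annotation
  term in each motif-defined gene group against the background, flags raw
  p < 0.01 — deliberately uncorrected, matching the protocol this layer
  reproduces — and emits Benjamini–Hochberg q-values as a clearly marked
  extra column. An `ease = TRUE` flag gives the more conservative
  one-success-removed variant. Group membership (`assign_motif_groups()`)
  is non-exclusive across {PQS, STR, LCGI, NCGI} except for one rule: a
  locus called by both the STR and PQS scanners counts as an STR, so a gene
  joins the PQS group only through a PQS call not overlapping any of its
  STR calls.

All exact tests are asserted against independent enumeration or reference
implementations in the suite, and the r×c p-value is checked for
uniformity under 500 seeded independence simulations.

## The synthetic generator

`generate_promoters()` draws seeded promoter sets with ground truth so that
every stage is testable without genome downloads. The defaults are the
study conditions the package emulates, fixed once:

| parameter | default | rationale |
|---|---|---|
| length | 2000 bp | the promoter-region convention |
| GC gradient | 0.48 → 0.57 linear | rising GC toward the TSS; overall mean ≈ 52.5% |
| background CpG depletion | 70% of chance CpGs | background O/E ≈ 0.24, the vertebrate range |
| TATA | rate 0.10 at −31 | ~10% TATA promoters, preferred site −31/−30 |
| STR rate | 0.114 per promoter | the avian per-sequence density |
| STR motifs | bundled chicken table | rank-correlates with the reference by construction |
| unit counts | di 6–8, tri 6–7, tetra+ 6–12 | avian pattern: tetra+ units exceed di units; tri smallest |
| CGI | rate 0.5, length 250–1000, GC ≈ 0.7, O/E ≈ 1.5 | ~half of genes island-bearing; the >800-bp tail populates LCGI |
| PQS | rate 0.08, four G₄ tracts, loops 1–3 | sparse G4 content |
| GO | 50 terms, 10% prevalence, odds ratio 5 | one enriched term per motif kind |

Planting replaces background bases at uniform non-overlapping positions
(TATA at its fixed site), so coordinates stay comparable across promoters;
a single seed drives one random stream. Island sequence is emitted
token-wise (CpG dinucleotide with probability 0.2, otherwise one base at
GC 0.6) with incidental tandem arrays of six or more units explicitly
broken — islands are CpG-dense, not perfect repeat arrays, and unbroken
runs would contaminate the planted-STR ground truth with spurious CG-family
calls. Background CpG depletion is
applied by iterative composition-preserving `CG → GC` swaps — without it,
i.i.d. background has O/E ≈ 1 and the island criteria fire across every
GC-rich stretch, which is unlike real (CpG-depleted) DNA and collapses the
NCGI class. `background_rates()` measures the spurious call rate of each
scanner on plant-free background; recovery analyses subtract it rather
than suppress it.

What the generator does *not* emulate: dinucleotide/isochore background
structure, repeat-length polymorphism, methylation, real GO-term
correlation structure, and island truncation statistics at the TSS. Tests
passing on synthetic data therefore certify the scanners' calling
semantics and the statistics' calibration, not biological conclusions
about any real promoter set.

Recovery conventions: planted islands and G4s count as recovered when a
call overlaps ≥ 90% of the planted span (background G adjacent to a
planted tract can legitimately shift the preferred G4 frame by a base or
two under the equal-loop preference); planted STRs require the canonical
motif and coverage of the planted run (runs may extend into background);
the STR-density control run keeps all other plants and zeroes only
`str_rate`, because planted islands themselves spawn occasional CG-type
repeats that an all-plants-off control would miss.

## Problem sizes, determinism and limitations

The shipped suite runs the scanner–oracle equivalence on 500 seeded 2-kb
sequences, parameter recovery on 5,000 simulated promoters, the
enrichment power/size simulation over 50 replicates (group 200 of 2,000,
planted odds ratio 5), and uniformity of the exact r×c p over 500
simulations — sizes chosen so each property is measured with comfortable
statistical margin on a single CPU. `run_all()` is deterministic given
config and seed: two runs produce byte-identical tables and manifest, and
the JSON manifest (version, parameters, seed, input checksum, output
checksums) suffices to re-run a result bit-identically.

Known limitations: island calls truncated at the TSS bias O/E and length
distributions low (stratify on `truncated_at_tss`); the Pearson `r`
between a small simulated frequency table and a large reference is noisy
at low call counts (τ-b is the more stable comparison); Monte-Carlo r×c
p-values carry the reported simulation error; and the scanners analyse
sequences shorter than 2 kb as-is after a warning, so positional profiles
of truncated extracts should be interpreted in promoter-relative rather
than TSS-relative terms.
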