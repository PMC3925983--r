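---
title: "Profiling, comparing and quantifying DYZ1 satellite arrays"
author: "dyz1kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling, comparing and quantifying DYZ1 satellite arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyz1kit)
```

## The biological problem

The DYZ1 satellite sits in tandem arrays on the long arm of the human Y
chromosome and makes up roughly a fifth of the chromosome. HaeIII
digestion releases a ~3.4-3.6 kb repeat unit that is itself a
near-tandem array of the pentamer TTCCA, interspersed with pentamers
carrying one to five substitutions ("derivatives") and occasional small
insertions or deletions. Because the male-specific region of the Y does
not recombine, any sequence or copy-number change that arises after a
monozygotic twinning event is faithfully propagated within that twin,
which makes DYZ1 a sensitive recorder of post-twinning divergence
between brothers who started life genetically identical.

dyz1kit implements the computational stages of such a comparison:
pentamer-frame decomposition and derivative profiling of an array unit,
virtual restriction mapping and in-silico digestion, pairwise alignment
with indel-block calling, and absolute qPCR copy-number quantification.
A synthetic-array generator with complete ground truth makes every
stage testable without any sequence download.

## Frame adjustment as minimum-cost tiling

An array unit is decomposed into consecutive segments of 3-7 bp, and
the decomposition chosen is the one minimising the total cost

$$\sum_{\text{segments } s} \Big( d_{\mathrm{Lev}}(s, \mathrm{TTCCA})
  + \lambda\,\big||s| - 5\big| \Big),$$

where $d_{\mathrm{Lev}}$ is Levenshtein edit distance and the length
penalty $\lambda$ defaults to 0 (cost is edit distance alone). This is
computed by dynamic programming over prefix ends (`decompose_array()`).
The idea is the "adjusted TTCCA reading frame": after an insertion or a
deletion the frame re-anchors, and the slipped bases are absorbed by a
single segment of length 4 or 6 rather than corrupting every downstream
unit. Segments of length 5 are classified by Hamming distance to TTCCA
(class 0 = intact TTCCA, class 1 = one of the 15 single-bp derivatives,
... class 5); segments of any other length are reported as *frameshift
units* and never folded into the substitution classes, because the
published derivative classes are substitution-only pentamers.

Three numerical choices matter:

* **Segment length range 3-7.** Wide enough to absorb 1-2 bp slips,
  narrow enough that a single segment cannot swallow a whole indel
  block (which should instead surface in the pairwise comparison).
  Configurable through `decomposition_params()`.
* **Tie-breaking.** Among equal-cost tilings the traceback prefers a
  length-5 segment, then shorter segments; together with left-to-right
  DP order this makes the output fully deterministic.
* **Validation.** Input is uppercased; any non-ACGT character is
  rejected with its position (the deposited array units are
  unambiguous, so ambiguity handling would only mask upstream errors).

### What decomposition can and cannot recover

For arrays whose pentamers stay within one substitution of TTCCA,
minimum-cost tiling provably has nothing to gain from re-framing, and
the profiler recovers the generating unit classes *exactly* (this is a
tested property). A pentamer three or more substitutions away is close
to arbitrary DNA, however, and a cheaper tiling of its neighbourhood
often exists; the decomposition then reports what the sequence actually
supports rather than the generator's bookkeeping. Empirically, with the
default class spectrum (~33% intact, ~41% single-bp, ~20% double-bp,
~6% higher classes) per-class counts still track the generating truth
to within about 2% of the unit count, and the DP tiling never costs
more than the generating segmentation. This is a property of frame
adjustment itself, not an implementation artefact: published derivative
tables produced by any frame-adjustment procedure carry the same
ambiguity for heavily diverged pentamers.

## The synthetic-array generator

`generate_array()` emulates the structure of a sequenced 3564 bp
HaeIII unit:

* **Unit count 710** — the class counts of a real sequenced unit sum
  to 710 pentamers (3550 of 3564 bp); the remainder is boundary
  sequence the generator does not model.
* **Class spectrum 235:290:142:33:9:1** over classes 0-5 — the class
  proportions of that same unit. Within a class, substituted positions
  and replacement bases are uniform (the within-class distribution is
  not published); optionally the 15 single-bp derivatives can be
  weighted.
* **Indel blocks** (tens of bp, as seen between twins) are applied
  after unit concatenation, in descending position order, so stated
  1-based coordinates all refer to the unmodified parent — the same
  convention in which published variant positions are reported.
* **Per-unit 1-bp slips** (`point_indel_rate`, default 0) model the
  frame-shifting micro-indels that motivate frame adjustment.

Every spec carries its own seed and each generator call runs in a
private RNG stream (the caller's stream is saved and restored), so a
spec determines its output byte for byte. The generator returns the
complete ground truth: per-unit classes, every slip and every indel
block with its realised sequence — replaying the edit log on the parent
reproduces the child exactly (a tested invariant).

What the generator does *not* emulate: germline-vs-somatic mutation
biology, array-boundary sequence, GC/composition constraints beyond the
pentamer structure, and cell-to-cell mosaicism. Passing tests on
synthetic arrays therefore validate the *algorithms*, not any claim
about real mutational processes.

## Pairwise comparison

`global_align()` is a Gotoh affine-gap global aligner (match +2,
mismatch -1, gap open -4 including the first gap base, extend -1),
written in C++ with a deterministic traceback (diagonal preferred, then
gap-in-b, then gap-in-a). The published twin comparisons were made with
a general-purpose multiple-alignment tool whose parameters are not
stated; an explicit scored model was chosen instead so that results are
reproducible and tie-breaking is defined. Equal-cost gap placements in
a tandem repeat can differ by a few bp from any other aligner's choice,
but block *lengths* and the net length change cannot: the report
invariant `sum(deletions) - sum(insertions) = len(a) - len(b)` is
checked on every call. `call_variants()` turns gap runs into
deletion/insertion blocks (1-based, inclusive, on the first sequence —
insertions anchor between two reference positions) and mismatch runs
into substitution blocks.

Multiple alignment of more than two sequences is deliberately out of
scope; every published contrast used here is a pairwise one.

## Restriction mapping

`scan_sites()` reports every window matching a degenerate IUPAC motif
(degenerate-pattern matching is delegated to Biostrings). Conventions,
each chosen to make counts well-defined and checkable:

* **Forward strand by default.** All headline motifs checked in tests
  (GAATTC, AATT, TCGA, GATC, ...) are palindromic, so the strand
  convention cannot affect them; `strand_mode = "both"` adds
  reverse-strand hits for non-palindromic motifs and deduplicates
  self-reverse-complementary windows.
* **Overlapping hits are counted** — counts are motif statistics, not
  cut simulations. `digest_fragments()` instead takes a
  leftmost-greedy non-overlapping subset and cuts at site starts; the
  published enzyme panel gives overhang chemistry but no cut offsets,
  so this is documented as an approximation adequate for fragment
  counting (fragment lengths always sum to the input length).
* The shipped panel (66 enzymes) is the union of the two published
  per-sample site tables; panel membership is treated as data, and
  `frequency_table()` / `diff_frequency()` reproduce the
  per-enzyme-count and loss/gain comparisons on any panel.

## Copy-number quantification

The Ct model is $C_t = c_0 - \log(\text{copies}) / \log(1 + E)$ with
efficiency $E \in (0, 1]$; at $E = 1$ a 10-fold dilution step raises Ct
by exactly $\log_2 10 = 3.3219$. `fit_standard_curve()` regresses
replicate-mean Ct on $\log_{10}$(copies) (replicate weighting is not
applied — replicate counts per point are equal in the assay design, and
the published analysis states none), reports $R^2$ with a 0.99 QC
*warning* (not a failure), and derives $E = 10^{-1/\text{slope}} - 1$,
an identity that holds to numerical precision for every fitted curve.
`quantify_sample()` inverts the curve at the replicate-mean Ct; the
replicate spread is the SD of per-replicate back-transformed copies.
Simulated defaults follow the published assay design: 10-fold dilutions
from 2e8 copies, triplicates; the Ct-at-one-copy intercept (38) and
replicate noise (0.15 Ct) are typical values for SYBR assays, chosen
once and documented here.

Absolute per-twin copy numbers are not published as numbers, so they
are treated as non-reproducible; the published copy-number
*differences* are covered by constructed fixtures in which the
pipeline must recover a known planted difference exactly from
noise-free Cts.

## Problem sizes and determinism in the test suite

The suite runs entirely offline and in about half a minute: tiling DP
vs an independent suffix-recursion oracle on 1000 random sequences up
to 40 bp plus exhaustive tiling enumeration up to 15 bp; the aligner
vs exhaustive alignment enumeration up to 6 bp and vs an independent
affine-gap implementation up to array-scale pairs; the motif scanner vs
a naive position-by-position checker over the full 66-enzyme panel on
random 200-mers; and full pipeline reconstructions on ~3.6 kb synthetic
twin pairs. These sizes were chosen so every oracle remains genuinely
independent and exhaustive where claimed. All stochastic fixtures use
fixed seeds; `scripts/acceptance.R` re-derives the headline quantities
from scratch at any seed supplied on the command line.

## Known limitations

* Exact reproduction of published per-accession tables (derivative
  counts, site frequencies, variant coordinates) requires the deposited
  GenBank records; `fetch_accession()` retrieves and caches them when
  network use is explicitly enabled, and reads user-supplied flat files
  offline. The published frame-adjustment procedure itself is not
  specified, so even with the accessions, derivative counts are a soft
  target: the tiling here is an explicit, reproducible formalisation,
  not a re-implementation of an undocumented manual curation.
* `digest_fragments()` does not model cut offsets, partial digestion,
  or methylation sensitivity; no gel migration is simulated.
* Copy numbers are per reaction input; normalisation to per-genome
  copies would need genome-equivalent inputs, which are not modelled.
```{r session}
sessionInfo()
```
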