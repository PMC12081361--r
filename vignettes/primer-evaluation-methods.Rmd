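---
title: "Methods: degenerate primer evaluation and 16S variation profiling"
author: "primerscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degenerate primer evaluation and 16S variation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerscreen)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, and the design choices made
where more than one reasonable option existed.

## The matching model

A degenerate primer is a pool of concrete oligos: each IUPAC symbol
expands to a set of 1–4 bases (`expand_iupac()`), and the pool is the
Cartesian product of the per-position sets. The in silico PCR engine
accepts a template window iff the window could be spelled by *some*
member of the pool — equivalently, iff at every offset the template
symbol's expansion is a **subset** of the primer symbol's expansion.
Nothing outside the designed degeneracy is forgiven: a single
non-degenerate mismatch rejects the site.

Two consequences of the subset rule deserve emphasis:

* A template `N` (or any ambiguity code) never matches a stricter
  primer position. Unknown residues are not counted as amplified. This
  is deliberately conservative; tools differ here and the choice is
  configurable only by pre-cleaning the input.
* Degenerate *templates* match degenerate primers only when the
  template pool is contained in the primer pool, which is the only
  reading under which "no mismatches outside designed degenerate
  positions" is exact for every pool member.

Internally each symbol is a 4-bit mask (A=1, C=2, G=4, T=8) and the
subset test is `bitwAnd(template, bitwNot(primer)) == 0`, so scanning a
template is a handful of vectorised integer operations per primer
position. The engine is verified against an independent brute-force
oracle (expand the pool, compare every window) on randomized cases.

Amplicons pair a forward site with a reverse-complemented reverse-primer
site strictly downstream on the same (sense) strand, as 16S genes are
deposited 5′→3′ in rRNA databases; only that strand is searched.
Coordinates are 1-based inclusive, amplicon length includes both
primers, and a guard of `max_len = 4000` nt (well above real 16S
amplicons, which stay under 1.5 kb) discards pathological pairings.

## Coverage and candidate selection

Coverage of a taxon by a primer pair is the percentage of its
*eligible* sequences with at least one predicted amplicon; a sequence
with several amplicons counts once. Eligible means the requested rank
(phylum / family / genus) is populated; an optional minimum-length
filter (off by default) exists for raw database exports, where length
eligibility is a property of the source release rather than of the
method. Candidate selection is two-stage and inclusive at both
thresholds: ≥ 70 % in each of four named phyla, then ≥ 90 % in at
least 4 of 20 named genera. Percentages are reported to one decimal in
writers; internal math is full precision.

## Entropy profiling

Per alignment column, Shannon entropy over the four bases with
frequencies renormalised over non-gap residues:
\(H = -\sum_i p_i \log_2 p_i\), in bits (log base 2 throughout, which
also fixes the 0–2 bit logo scale). Columns with under 50 % non-gap
residues are masked — excluded from region calls and means — so ragged
alignment edges cannot masquerade as diversity. Ambiguity codes in
alignment rows are normalised to gap before profiling: they carry no
single-residue evidence. Both rules are choices, not forced; the mask
threshold is an argument.

Variable regions are called by thresholding at 0.5 bits (strict
inequality), merging seed runs separated by ≤ `merge_gap` = 5
sub-threshold columns, and dropping merged runs shorter than
`min_len` = 10 columns. The merge/min-length defaults are chosen so a
single noisy column neither creates nor splits a region; both are
exposed in the configuration, and the boundary-recovery contract on
synthetic data is stated as ±`merge_gap` columns.

Processing order per genus is fixed: QC → subsample → align → trim →
entropy → regions. The QC retains a sequence iff the 20-nt conserved
5′ marker `AGAGTTTGATCATGGCTCAG` matches within the first 5 start
positions with ≤ 2 substitutions and no indels — an operationalisation
of "anchored at conserved region 1" that tolerates light noise; the
exactness is configurable. Subsampling (default n = 100 per genus,
seeded, uniform without replacement) passes small genera through
untouched.

## Alignment and the anchored frame

The built-in aligner is center-star: the star is the record minimising
total pairwise distance (Hamming when lengths agree, edit distance
otherwise), every other record is globally aligned to it under
match +1 / mismatch −1 / gap −2 (linear), and rows are **projected onto
the star's residue columns** — after gap propagation, columns where the
star carries a gap (insertions relative to the star) are trimmed. The
projection is the one place the implementation deliberately departs
from textbook center-star: keeping insertion columns makes the column
count grow with the union of pairwise insertions (on 100 substitution-
only 1,542-nt sequences at 50 % variable-column diversity the alignment
inflates to ~2,360 columns), which destroys the stable coordinate frame
that anchored trimming and boundary-exact region recovery require.
Reference-anchored profiling accepts the loss of inserted residues in
exchange for stable coordinates; an external aligner (e.g. MAFFT via
`method = "external"`) is available when insertions matter.

`anchor_trim()` then locates the 5′ marker in the per-column consensus
(≤ 2 mismatches, gap columns count as mismatches, leftmost best window)
and returns exactly `frame_len` = 1,500 columns from there, right-
padding with all-gap columns (flagged) when the alignment is short. All
region and binding-site coordinates live in this frame, whose position
1 is the start of conserved region 1.

One measured caveat: at extreme diversity a global aligner
systematically *under*-estimates column entropy, because it places
residues to maximise matches. The generator-rate calibration tests
therefore profile the raw equal-length matrix, while recovery tests run
the full alignment path at the study conditions (where the bias is far
too small to move any column across the 0.5-bit threshold).

## Binding-site analysis

The consensus takes each column's majority residue over non-gap counts,
encodes ties as the IUPAC symbol of the tied set, and emits gap for
majority-gap columns (skipped during site location, with frame
coordinates preserved). Sites are located by minimising subset-
semantics mismatches over all windows (ties leftmost, default cap 3
mismatches); reverse primers are located as their reverse complement
and their count matrices complemented and reversed so every reported
matrix reads 5′→3′ in primer orientation with the 3′ end last.

Information content is \(R_i = 2 - H_i\) bits, clamped at 0. The
optional small-sample correction (−3/(2 ln 2 · n)) is **off** by
default: the 0-at-uniformity, 2-at-conservation scale is the
uncorrected quantity, and matching that scale keeps logo heights
interpretable against it. The per-position incompatible fraction is
the share of non-gap residues outside the primer symbol's expansion —
the same subset semantics as the PCR engine, for consistency — and the
3′ flag fires when any of the last `three_prime_k` = 4 positions
exceeds `flag_thr` = 0.1. The window of 4 reflects the observation
that even single mismatches in the last 3–4 nucleotides strongly
reduce amplification; both knobs are exposed because the quantitative
cutoff is a modelling choice, not a measured constant.

## The synthetic generator: what it emulates, and what it does not

`gene_layout()` ships the conventional E. coli frame: nine variable
blocks (V1 69–99 … V9 1435–1465) inside 1,542 nt, conserved blocks
filling the gaps. Defaults for the clade substitution rates are
`p_cons` = 0.01 and `p_var` = 0.30 per column — roughly the
within-genus picture of near-identity in conserved regions and strong
diversity in variable ones; recovery and planted-coverage runs use
`p_cons` = 0, `p_var` = 0.5 so that expected variable-column entropy
(≈ 1.8 bits at n = 100) sits far above the 0.5-bit threshold while
conserved columns are exactly invariant. Each sequence mutates each
column independently (uniformly to one of the three alternatives);
columns 1–20 are held fixed so every sequence passes the 5′-marker QC.

`plant_site_mismatches()` realises an **exact count**
`round(q · n)` of site-destroying substitutions — placed at the site's
3′-terminal column, to a base outside the evaluating primer's expansion
— so true coverage is `100 · (1 − round(q·n)/n)` percent in integer
counts, not in expectation, and the coverage table must reproduce it
exactly. Placing the damage at the 3′ end also exercises the binding
analysis's 3′ flag. `make_mock_community()` emulates a defined
multi-copy standard: 19 strains whose copy numbers sum to 110, one
evolved reference per strain plus near-identical copies at 0.002
per-column divergence.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: indels and alignment ambiguity
(substitution-only by default keeps frame coordinates exact),
tree-structured phylogenetic correlation (sequences are independent
given the backbone), chimeras, intragenomic copies beyond simple
near-identity, and base-composition bias. Results on real SILVA/NCBI
exports will additionally reflect database curation artifacts that no
synthetic control covers.

## Problem sizes, determinism, degenerate inputs

The shipped analyses run at the study scale — 100 sequences per genus,
1,500-column frames, a 110-sequence mock community, 10,000 randomized
matching-oracle cases — which keeps a full test-and-acceptance cycle in
the low minutes on one core. Every stochastic step takes an explicit
seed and restores the caller's RNG state (`withr::with_seed`);
regenerated outputs are byte-identical, and the pipeline writers stamp
every file with the tool version, a hash of the scientific
configuration (paths excluded, precisely so identical runs into
different directories compare equal) and the seed. Timestamps appear
only in stderr logs.

Degenerate inputs are handled explicitly: empty FASTA, missing ranks,
all-gap columns (masked, never an error), genera with fewer than two
QC survivors (skipped with a warning; fewer than ten, a low-n warning),
primers longer than templates (no sites, not an error), fully
degenerate 3′ termini (planting refuses: no destroying base exists),
and alignment ties (leftmost/alphabetical, making every caller
deterministic).

## Known limitations

* The center-star projection discards residues inserted relative to
  the star; insertion-rich real data should use the external aligner,
  at the cost of frame-coordinate exactness.
* The matching model is exact-match-within-degeneracy by design; it
  does not model mismatch-tolerant annealing, melting temperature or
  amplification kinetics, so coverage is an upper bound on what a
  permissive PCR would see and a lower bound is not provided.
* Canonical V1–V9 coordinates vary by author; `compare_to_canonical()`
  treats them as configuration, and the shipped defaults are one
  conventional choice, not a measurement.
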