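---
title: "Classifying differential splicing events by RNA-editing proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying differential splicing events by RNA-editing proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedit)
```

## The question and the procedure

A-to-I editing by ADAR enzymes is concentrated in intronic Alu repeats,
which sit close to splice sites by construction of the transcriptome. When
a perturbation of an editing enzyme changes both editing and splicing, the
temptation is to read every splicing change near an editing site as
editing-driven. `splicedit` formalises the opposite, more cautious reading:
it tags an event *editing-dependent* only in the proximity sense — at least
one credible editing site inside fixed windows around the event's splice
junctions — and pairs that tag with null controls that show how often the
same proximity arises for splicing events that did not change.

The pipeline consumes the outputs of the standard engines rather than
re-implementing them: rMATS junction-count (JC) tables for five event
classes (SE, MXE, RI, A5SS, A3SS), DEXSeq-style DEU tables, REDItools-like
editing tables or VCFs, and RADAR/DARNED database BEDs. Stages:

1. **Event filtering** (`filter_rmats`): keep events with ≥ `min_reads`
   (default 20) inclusion + skipping reads in *every* replicate of both
   groups, FDR ≤ 0.05 and |ΔPSI| ≥ 0.1.
2. **Site filtering** (`filter_addressable`, `filter_support`): keep
   addressable A-to-I signatures with total depth ≥ 5 over all samples and
   either ≥ 2 supporting replicates or database membership.
3. **Window construction** (`build_event_windows`): per junction, 50 bp
   into the exon and 200 bp into the intron; 50/50 for retained introns.
4. **Intersection and tagging** (`classify_events`): merged windows vs
   1-bp site intervals, strand ignored; ≥ 1 hit ⇒ editing-dependent.
5. **Context** (`accumulation_curve`, `footprint_site_overlap`,
   `select_null_events`): window-size scans over 50/250/500/1000 bp for the
   significant set and for two null sets (non-significant events; events
   significant by FDR but with |ΔPSI| < 0.1), and the share of database
   sites within growing distances of iCLIP footprints (grid 0–1000 bp).

## Coordinate conventions and the interval engine

Everything internal is 0-based half-open (BED-style). rMATS `_0base`
starts are taken verbatim and rMATS ends are already exclusive; VCF and
REDItools positions are shifted by −1 on read and +1 on write. One
convention removes a whole class of off-by-one errors, and makes the
overlap predicate a single comparison: `q.start < s.end && s.start < q.end`
(touching intervals do not overlap).

The intersection engine is a per-chromosome sort plus linear sweep with
retirement of subjects whose ends fall behind the advancing query start.
Trees are unnecessary at this scale; the test suite holds the engine to an
exhaustive all-pairs oracle on randomized instances under both strand
policies. The default policy ignores strand, matching `bedtools intersect`
without `-s`; `match` treats `.` as a wildcard and is available for
sensitivity analysis.

## Window geometry decisions

*Junction sets.* SE events contribute 4 junctions, MXE 6 (both flanking
introns included), RI 2, A5SS/A3SS 3. The exon/intron side of each junction
is derived purely from the genomic geometry of the event's exons, never
from strand — rMATS coordinates are genomic, and a strand-aware definition
would produce identical windows while inviting sign errors. For A5SS/A3SS
the variable boundary pair depends on where the flanking exon lies: if it
is genomically right of the alternative exons the junctions are
(longExonEnd, shortEE, flankingES), otherwise (longExonStart, shortES,
flankingEE). This geometric rule handles both strand layouts emitted by
rMATS without special-casing.

*No clipping against neighbouring exons.* An intronic window may reach into
an adjacent exon of the same event when the intron is shorter than 200 bp
(visible in the worked SE example, whose merged coverage is a single
interval). The windows emulate a naive fixed-distance `bedtools` strategy;
clipping would silently change the denominator of every fraction.

*DEU windows.* A DEU bin is expanded symmetrically into one body window
`[start − w, end + w)`. For w ≥ 50 this is a superset of the two
boundary-centred windows plus the exon interior, and keeps the feature
count — the curve denominator — fixed across window sizes.

*iCLIP overlap.* Footprints, not sites, are expanded; the fraction is of
database sites. Expansion of either side is distance-equivalent, and
expanding footprints keeps the denominator (total database sites) constant,
so the curve is a CDF-like non-decreasing function bounded by 1.

## Statistical choices

Differential editing per site is a two-sided Fisher's exact test on the
(edited, unedited) × (condition A, condition B) table of summed group
counts, with the standard "sum all margin-fixed tables no more probable
than the observed" two-sided rule. Sites with zero depth in either group
are flagged untestable rather than given a p-value. The default
significance call is raw p < 0.05; Benjamini–Hochberg q-values across
testable sites are reported alongside for users who want FDR control. The
test suite checks the p-values against an exhaustive enumeration oracle
built from log-binomial coefficients, exact to 1e-12.

Interpretation choices a user should know:

- "Observed in at least two replicates" pools all samples of a cell line
  (both conditions), mirroring how the depth clause pools all six samples.
  The depth gate is conjunctive: a database site below depth 5 is dropped.
- Unknown-strand sites are evaluated as A>G only; an unoriented T>C call
  cannot be attributed to editing.
- The read-support clause is per replicate by default
  (`read_rule = "per_replicate"`); a laxer group-mean reading is available
  as a config switch.
- Gene-level summaries uppercase the rMATS gene symbol and count a gene
  dependent if any of its events is. Events appearing in multiple rMATS
  classes are not deduplicated.
- A site found both in the sample calls and in a database counts once in
  each source column but contributes a single hit id, so fractions never
  double-count.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. Defaults
emulate an overexpression-vs-control design: three replicates per group,
junction depth 60 (comfortably above the 20-read gate), half of the events
truly differentially spliced with |ΔPSI| drawn from a truncated normal
(mean 0.25, sd 0.08, floor 0.1), per-sample site depths Poisson(20) over
six samples and editing levels Beta(2, 5) — arbitrary but documented values
chosen to exercise the depth/replicate filters with realistic sparsity.
Junction counts are binomial at the inclusion probability implied by the
replicate's true PSI after length normalisation, ψ = (I/L_I)/(I/L_I +
S/L_S). File-level PValue/FDR are planted from the truth labels, not
recomputed: the pipeline consumes rMATS output, so the file contract — not
the rMATS statistics — is what must be faithful.

Two constructive guarantees make headline checks exact rather than
statistical:

- **Guard distance.** Background sites are a Poisson process over intronic
  space excluding everything within `guard_distance` (default 2000 bp) of
  any event window, so the planted dependent fraction is recovered exactly:
  `round(f · n_significant)` events and no others are tagged dependent.
  Setting the guard to 0 removes the exclusion entirely — background
  becomes uniform over all introns, the null-control regime in which
  significant and null event sets should be statistically indistinguishable.
- **Planted detectability.** Planted sites are forced to carry at least one
  edited read in two samples, so the support filter cannot silently drop
  them. Without this, a rare all-zero sampling of a planted site would make
  exact recovery impossible.

What the generator does *not* emulate: sequence content (coordinates only),
read-level noise (no FASTQ/BAM), overdispersion of junction counts,
correlated replicate structure, overlapping genes, multiple events per
gene, and editing-level dependence on Alu context. Passing tests therefore
demonstrate the correctness of the bookkeeping — filters, windows,
intersections, tags, curves — under the stated statistical shape, not
robustness to the full messiness of real libraries.

## Numerical and degenerate-input behaviour

Floating-point columns written by the generator use 17 significant digits,
so read-back is bit-exact and reruns under the same seed are byte-identical
(the manifest records config, seed and input checksums, and deliberately no
timestamps). Windows are clipped at position 0; zero-length windows after
clipping are dropped. Empty feature lists make `accumulation_curve` error
(the fraction is undefined) while empty site sets simply give zero curves.
Header-only input tables parse to empty, typed tables. Classification
output is sorted by (event class, event id) and hit lists are sorted, so
output files are stable sort-key by sort-key.

## Problem sizes

The test suite and the acceptance script run on simulated instances sized
for a laptop: 50 random interval instances up to 300 × 300 for the engine
oracle, 500 exon-skipping events (400 significant) for planted-fraction
recovery, 75-event runs across ten seeds for the null control, and ~24,000
exhaustively enumerated 2 × 2 tables (plus sampled larger-margin tables)
for the Fisher oracle. These sizes are the package's own choice of
demonstration scale; all of them are parameters, not constants.

## Limitations

The dependence tag is a proximity co-occurrence label, not a causal claim;
a dependent event may be editing-independent biologically and vice versa.
Real analyses should read the tag together with the null-control curves.
The package does not call variants, align reads, quantify proteomics, or
re-run rMATS/DEXSeq; their statistical assumptions travel with their
tables. JCEC-mode rMATS tables are not supported (junction-count mode
only), and hyper-editing detection and editing-index computation are out of
scope.
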