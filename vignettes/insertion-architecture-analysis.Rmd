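---
title: "Detecting and analysing domain insertion architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing domain insertion architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(insertarch)
```

## The problem

A domain insertion is the architecture in which one protein domain (the
*insert*, B) interrupts the sequence of another (the *host*, A), producing
the A1-B-A2 pattern: the host's residue range is split into two segments
with the insert occupying the intervening stretch. "Host" and "insert" are
purely topological labels — the inserted domain may well carry the
catalytic function. Insertion places strong constraints on the insert: it
must fold within the host's gap, and its N- and C-termini must both reach
back to the host's flanks.

`insertarch` takes ECOD-style domain assignments (one row per classified
domain instance, hierarchical family IDs such as `2004.1.1.71`, residue
ranges such as `1-111,177-409` for discontinuous domains) and answers:
where are the insertion events, which families consistently act as hosts
or as inserts, and what size, position, partnership and termini-geometry
regularities do the events show?

## Detection model

Detection works on residue intervals only; no sequences or coordinates are
required.

1. **Gap enumeration.** For every domain with two or more segments, the
   residues strictly between consecutive segments form a gap
   (`end_i + 1` to `start_{i+1} - 1`). Only gaps of at least `min_gap`
   residues (default 30, inclusive) are candidate insertion sites: shorter
   stretches cannot plausibly hold an independently folded domain and are
   treated as boundary noise or linkers.
2. **Containment.** A domain is a candidate insert for a gap when *all*
   of its segments lie inside that single gap. A discontinuous domain
   whose segments straddle two different gaps is not an insert.
3. **Exclusive smallest-gap assignment.** A domain contained in several
   gaps is assigned to the smallest one, so each domain participates in at
   most one insertion event per protein. In the nested A1-B1-C-B2-A2
   architecture this yields exactly two events, B into A and C into B:
   C is contained in both A's gap and B's gap, but B's is smaller.
   Equal-length ties (possible between overlapping gaps of two different
   hosts) are broken by smaller gap start, then by host domain ID —
   the tie cannot arise between nested hosts, whose gaps are strictly
   ordered, and the rule makes the rare overlapping case deterministic.
4. **Nesting depth.** An event has depth 1 when its host is not itself an
   assigned insert, otherwise one more than the host's own event depth.
   Because every insert has exactly one host, the relation is a forest and
   the recursion terminates; depths of 6 and more occur in real proteins
   (cyanobacterial RNA polymerase rpoC2 subunits).

Two conventions are worth stating. Host length is the sum of the host's
segment lengths (A1 + A2), never counting gap residues. The relative
position of an event is the fraction of host residues strictly before the
gap start, bucketed into thirds with half-open intervals `[0, 1/3)`,
`[1/3, 2/3)`, `[2/3, 1]` — a boundary value such as exactly 1/3 falls in
the middle bucket.

Where the input encodes two same-family regions, the package follows the
input's row structure: segments belong to one domain instance if and only
if they share a row (ECOD encodes discontinuity within one record). The
package never merges separate rows of the same family into one
hypothetical split domain; deciding repeat-versus-split is the domain
assigner's job, not the architecture analysis's.

```{r}
mod5 <- domain_table(
  protein_id = "3EPL",
  domain_uid = c("d1", "d2"),
  f_id = c("2004.1.1.71", "3949.1.1.1"),
  range_string = c("1-111,177-409", "112-176")
)
detect_insertions(mod5)
```

## Family roles and partnerships

Every event contributes one host tally and one insert tally to its
families' profiles. Families with at least `min_events` total events
(default 10) are classified **host-consistent** (zero insert events),
**insertion-consistent** (zero host events) or **versatile**; below the
threshold a family is *insufficient* and excluded from role statistics.
The threshold trades coverage for confidence: with fewer than ten events,
"always a host" is too easily a sampling accident.

Partnerships are directional (host family, insert family) pairs; an event
whose families belong to different H-groups (the homology level of the
ECOD hierarchy, the first two fields of the family ID) is a cross-H-group
partnership. The host-diversity spectrum classifies insert families by
the number of distinct host H-groups they appear in: specialists (exactly
one), generalists (`generalist_cutoff` or more, default 11), and
intermediates.

## Statistics

* **Paired sizes.** Host and insert lengths of one event form a natural
  pair; the package reports medians, the fraction of events with a
  strictly smaller insert, the median insert/host ratio, and a Wilcoxon
  signed-rank test on the paired differences. The signed-rank test is
  implemented in-package because the analysis needs an exact null in the
  presence of tied absolute differences: for up to 25 non-zero pairs the
  null distribution of the positive rank sum is computed exactly by
  convolution over sign assignments (valid with average ranks); larger
  samples use the normal approximation with continuity correction and
  tie-corrected variance. Zero differences are dropped before ranking.
* **Enrichment.** Architecture-level role preference uses the 2x2 table
  of host-role versus insert-role instances with and without a given
  secondary-structure architecture label, summarised as a log2 odds ratio
  with a Haldane–Anscombe pseudocount of 0.5 in every cell (no published
  formula accompanies the statistic, so the package states its own:
  `log2(((a+0.5)(d+0.5))/((b+0.5)(c+0.5)))`), classified host- or
  insertion-enriched beyond ±0.5. X-group-level insert
  depletion/enrichment compares each X-group's share of insert-role
  instances with its share of a user-supplied background universe of
  classified domain instances (the package deliberately takes the
  background as an explicit argument rather than fixing a convention),
  with Fisher's exact test and Benjamini–Hochberg FDR across X-groups;
  X-groups need `min_count` background instances (default 10) to be
  tested. Fisher's test, BH adjustment and Spearman correlation delegate
  to R's `stats` routines; the test suite checks them against independent
  enumeration oracles.
* **Termini geometry.** The termini distance of a domain is the Euclidean
  distance between the Cα atoms of its first and last residues (for a
  discontinuous domain, first residue of the first segment and last of
  the last). Insert-versus-background and host-versus-background
  comparisons use the Mann–Whitney U with the rank-biserial effect size
  `r = 1 - 2U/(n_x n_y)`, signed so that a stochastically smaller first
  sample gives positive `r`. Comparisons are run overall and within
  50-residue size bins (50–99 … 450–499, then 500+), because inserts are
  also systematically smaller: the per-bin analysis separates the
  geometric effect from the size confound. Bins with fewer than five
  records on either side are flagged underpowered. The reported 95%
  interval for `r` derives from the null-variance normal approximation
  of U; it is a coverage statement, so one comparison in twenty will
  exclude zero even under the null.

## The synthetic generator

`generate_architectures()` produces domain tables with known ground truth
so that every stage is testable without external data. It emulates:

* a family universe with role propensities — host-only, insert-only,
  versatile, never-insert (defaults 0.20/0.20/0.30/0.30) — spread over
  synthetic X/H/T levels, with about one family in ten carrying a
  T-group-only ID (ending `.0.0`), mirroring the presence of
  topology-only assignments in real classifications;
* log-normal instance lengths, host-role mean 240 residues (sd 90) and
  insert-role mean 133 (sd 45), so inserts are systematically smaller
  within and across families;
* an insertion grammar: proteins are multidomain with probability 0.48
  (the approximate multidomain rate among clustered representatives of
  current structure databases); a multidomain protein carries an
  insertion with probability `p_insertion` (default 0.20, the observed
  prevalence scale); inserts nest with probability `p_nest` (default
  0.12) up to `max_depth` (default 6); a gap holds two side-by-side
  inserts with probability 0.05. Hosts of nested inserts are drawn from
  versatile families only, so obligate roles are never violated by
  construction. Every gap is insert length plus two linkers (default 5
  residues each), hence at least `min_gap` by construction: any
  detector/ground-truth disagreement is a detector bug, not generator
  noise;
* toy Cα traces: planar zig-zag paths with 3.8 Å spacing whose
  first-to-last distance is drawn log-normally — median 14.3 Å for
  insert-role domains, 29.8 Å for hosts and background (host termini are
  deliberately background-like; the closeness requirement is specific to
  the insert role). Geometrically infeasible targets for very short
  domains are clamped and the realised distance recorded.

The family universe defaults to 60 families so that per-family event
counts at desk scale (a few thousand proteins) cross the 10-event role
threshold for a useful number of families.

A separate set of hand-constructed adversarial proteins
(`adversarial_architectures()`) pins the boundary behaviour: gaps of
exactly 29/30/31 residues, an exact tie between two containing gaps of
equal length, side-by-side inserts, a discontinuous insert inside one
gap, and a straddling discontinuous domain that must yield no event.

What the generator does **not** emulate: real linker-length and
domain-order statistics, correlated family co-occurrence, circular
permutations, assignment errors or overlapping/ambiguous boundaries, and
real fold geometry (the traces are not protein-like beyond spacing and
termini distance). Passing tests therefore demonstrate algorithmic
correctness on well-formed assignments, not robustness to noisy domain
parsers — malformed rows are exercised separately through the reader's
reject path.

## Numerical and design choices

* Residue coordinates are 1-based and inclusive on both ends everywhere;
  no half-open conversions in the public data model.
* Family IDs with four or more dot-separated fields are accepted; X/H/T
  prefixes are always the first 1/2/3 fields. T-group-only families
  participate fully in detection and profiles (they can be excluded from
  profiles with `exclude_unassigned`), reflecting their substantial share
  of real insertion events.
* Chain prefixes in range strings are validated for consistency and then
  stripped; multi-chain domains are rejected (single-polypeptide
  analysis).
* Overlapping domains within a protein are input errors: the reader
  rejects the protein's rows and records the reason; `strict = TRUE`
  aborts instead. Rejected rows never silently disappear.
* The event-table TSV schema is frozen (column order documented in
  `write_event_table()`); floats are written with six significant digits,
  and the reader/writer pair round-trips at that precision.
* Prevalence is reported over multidomain proteins only; with no
  multidomain proteins it is reported as 0 with an explicit
  `prevalence_undefined` flag and a warning.
* p-values are never truncated in outputs; display formatting such as
  "< 2.2e-16" is left to reports.

## Problem sizes in the test suite

The suite validates the detector against a brute-force
containment-plus-minimal-gap oracle on over a thousand generated proteins
across mixed configurations plus the adversarial set, runs a
5000-protein end-to-end recovery (exact event-set equality, prevalence
within the 99% binomial interval of the configured 0.20, zero
obligate-role misclassifications), and a 1500-protein termini analysis.
These sizes give the family- and bin-level statistics enough support
while keeping the default run in the minutes range on one core.

## Limitations

* Detection consumes domain assignments; it cannot recover insertions
  missed by the upstream domain parser, and inherits any boundary-
  placement biases.
* A domain overlapping a gap partially ("straddling") is never an event;
  if real assignments produced such cases they would be silently
  non-events, visible only through the candidate/containment diagnostics.
* The X-group enrichment depends on the chosen background universe;
  shares, not absolute rates, are compared.
* Termini distances are measured on whatever coordinates are supplied;
  whether a domain is measured in isolation or in its parent structure
  is the caller's choice and can shift absolute distances.
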