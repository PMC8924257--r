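---
title: "Designing CRMAGE guides and repair oligos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing CRMAGE guides and repair oligos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmage)
```

## The procedure

CRISPR-assisted MAGE (CRMAGE) edits a bacterial genome with a
single-stranded repair oligo while Cas9, programmed with a guide RNA,
cleaves every chromosome that still carries the wild-type locus. Cells
survive only if recombineering wrote the oligo's changes into their
genome, so the oligo must do two things at once: carry the desired point
mutation, and make the edited locus invisible to Cas9.

Given a genome and a desired substitution, `design()` runs the following
steps for each edit:

1. **Window.** An 80-base window — the size of the repair template — is
   placed around the edit. The window is centered on the edited bases;
   centering maximises the homology arms on both sides of the change. A
   window that would leave a linear contig is clipped (with a warning);
   on contigs flagged circular it wraps the origin.
2. **PAM scan.** Every NGG triplet whose three bases lie inside the
   window is a candidate Cas9 site, on either strand. On the forward
   strand an NGG is read directly; on the reverse strand it appears as
   CCN in forward coordinates. The 20-base protospacer immediately 5' of
   the PAM (on the PAM's strand) is extracted as the spacer (N20),
   written 5'→3' on the protospacer strand, the universal gRNA
   convention. The protospacer may extend beyond the window but not
   beyond the contig; candidates containing `N` are dropped.
3. **Off-target scoring.** Each spacer is compared against every 20-base
   window on both strands of every contig. A window is an off-target hit
   when its Hamming distance to the spacer is *strictly less than 2*
   (i.e. 0 or 1 mismatches) — a fuzzy-matching rule with substitutions
   only, no bulges. The on-target window itself is excluded by
   coordinates, so perfect duplicates elsewhere in the genome do count.
   By default no PAM is required next to an off-target window
   (reproducing a plain fuzzy subsequence search); `require_pam = TRUE`
   gives the biologically stricter mode.
4. **Selection.** Candidates are ranked by off-target count (fewest
   first). Ties break by PAM-to-edit distance, then PAM coordinate, then
   `+` strand before `-`; the first `k` (default 6) are kept. The
   ordering is fully deterministic.
5. **Template construction.** The 80-base repair oligo spans the same
   centered interval as the PAM window and carries the alternate allele.
6. **Cas9 escape.** The oligo is recombined in silico and the guide's
   locus re-read. If the edited locus still presents a perfect
   protospacer with an NGG PAM, one further mutation is added inside the
   template at a PAM G (position 3 preferred, G→A), destroying the NGG.
   If the desired edit already falls in the protospacer or PAM, no extra
   mutation is needed. The returned template is guaranteed to produce a
   genome with no cleavable site at the locus.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window` | 80 bases | PAM search neighborhood; equals the template size so every candidate PAM is reachable by the template |
| `template_length` | 80 bases | length of the single-stranded repair oligo |
| `mismatch_threshold` | 2 | off-target boundary: hits deviate by *fewer than* this many bases |
| `k` | 6 | guides kept per edit |
| `require_pam_offtargets` | `FALSE` | require NGG 3' of an off-target window |
| `escape_min_mismatches` | 1 | protospacer mismatches deemed sufficient to escape cleavage; raise for a seed-region safety margin |

The escape criterion deserves a note: Cas9 tolerates some protospacer
mismatches in vivo, PAM-distal ones especially, but there is no single
accepted cutoff. The default treats only a perfect protospacer (plus
NGG) as cleavable — the minimal, defensible rule — and
`escape_min_mismatches` lets cautious users demand more distance. When a
CDS table is supplied (`read_cds_gff()`), the PAM mutation prefers a
substitution that is synonymous under the standard genetic code, falling
back to G→A; with the standard code a third-position G→A is almost
always the silent option when one exists.

## A worked example

```{r example}
fx <- generate_fixture(fixture_spec(
  seed = 11, length = 6000, guides = 1,
  plants = list(plant(1, "+", 1, 0, pam = TRUE, at = 3000),
                plant(1, "-", 2, 1)),
  edit = list(plant = 1)))
reports <- design(fx$genome, fx$edit, k = 3)
reports[[1]]
summary(reports)
```

The planted guide has two planted single-mismatch copies, so it scores 2
off-targets; background candidates in the window typically score 0 and
outrank it.

## What the synthetic genomes emulate — and what they do not

`generate_fixture()` stands in for a real bacterial genome. It produces
i.i.d. background at a requested GC content, embeds protospacer copies
at exact Hamming distances (with NGG PAMs where requested), and then
*rejection-checks* the background: any accidental window within distance
< 2 of a guide is re-rolled, so the ground-truth off-target table is
exact by construction rather than merely probable. A single integer seed
drives every draw in a documented order, making fixtures byte-stable.

This emulates exactly the statistical structure the scanner and scorer
see: sequence composition, planted near-matches, strandedness. It does
not emulate operon structure, GC skew, repeat families, or the sheer
size of a real chromosome — so passing tests demonstrate correctness of
the algorithms, not that any particular biological genome is free of
off-targets. Scans of real genomes remain linear even for circular
chromosomes; windows spanning the origin are ignored by the scorer
(their loss is negligible at chromosome scale), while template windowing
does wrap when a contig is flagged circular.

Test and validation problem sizes are deliberately modest — hundreds of
seeded genomes of 2–8 kb — because the brute-force oracle is quadratic
in spirit and the properties under test (oracle equality, exact
ground-truth recovery, escape guarantees) are size-independent.

## Numerical and design choices

* **Coordinates.** Internal coordinates are 0-based half-open
  everywhere; TSV/VCF input is 1-based; BED output is 0-based. This
  matches each format's convention and removes ambiguity.
* **Window centering.** Only the window's *size* is inherited from the
  template; its placement (centered on the edit) is this package's
  choice, made so both homology arms are maximal.
* **PAM membership.** A PAM qualifies when its triplet lies inside the
  window; the protospacer may extend outside. Cleavage position is
  governed by the PAM, and the window's purpose is to tie candidates to
  the template's reach.
* **Distance-0 duplicates are off-targets.** The scorer searches "the
  rest of the genome": the on-target locus is excluded by coordinates,
  not by distance, so a second perfect copy elsewhere counts.
* **`N` handling.** `N` is preserved at load; candidates with `N` in
  PAM or protospacer are dropped at scan time, and an `N` inside a
  genomic window counts as a mismatch (conservative).
* **Tie-breaking.** Off-target count is the primary key per the
  procedure; the rest of the ladder (edit proximity, coordinate, strand)
  is invented here to make batch output deterministic, with edit
  proximity second because cleavage-to-edit distance drives
  recombineering efficiency.
* **Oligo strand.** Templates are emitted on the forward strand. MAGE's
  lagging-strand preference is real but organism- and locus-specific,
  so it is not automated.
* **Degenerate inputs.** Edits in GG-free deserts yield an empty
  selection with a warning; a candidate whose PAM cannot be mutated
  within the template is dropped and the next-best fills in; one bad
  edit never aborts a batch.

## Screen statistics

Two small utilities quantify the colorimetric readouts used with such
engineering screens. `killing_rate()` is the white-colony proportion
white/(white+red) per biological replicate with the across-replicate
mean and sample standard deviation (n−1; the population/sample choice is
not dictated by convention here, so the sample form is used and
documented). `indigoidine_index()` is A615/A800, which cancels
background turbidity and pipetting volume differences; no blank
subtraction is applied before the ratio. Both are invariant under
common positive scaling of their inputs, which the tests assert.

## Known limitations

* Substitution edits only — no indels.
* NGG PAMs only (no NAG or non-SpCas9 PAMs) and no on-target efficiency
  scoring; candidates are ranked purely by off-target count and the
  deterministic tie-break ladder.
* Hamming (ungapped) off-target model; bulged off-targets are invisible
  to it.
* Off-target scans do not cross the origin of circular contigs.
* The CDS-aware escape assumes phase-0 CDS features and the standard
  genetic code.
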