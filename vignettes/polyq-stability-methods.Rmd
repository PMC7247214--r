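---
title: "Classifying the evolutionary stability of polyglutamine regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the evolutionary stability of polyglutamine regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqevo)
```

## The model

A protein sequence under selection is not static: a glutamine tract can be
held in place, stretched and shrunk by replication slippage, or eroded by
point mutations. This package classifies each polyglutamine (polyQ) region
of an ortholog alignment by which of those regimes dominates, and then asks
whether the features known to accompany polyQ — CAG-biased codon usage,
leucine/proline flanking context, helical context, interaction capacity —
track that classification.

The unit of analysis is the *orthologous polyQ region*: a maximal set of
alignment columns in which at least one sequence carries a polyQ. Detection
uses a glutamine density rule (at least `min_q = 4` glutamines in any
`window = 6` consecutive residues); per-sequence regions are projected to
column space and merged across rows by transitive span overlap. Each column
of the merged span is classified by its glutamine fraction over **all**
rows of the alignment, and the region inherits a five-way category from
strict majorities of column classes (see `?classify_columns` and
`?categorize_region` for the exact rules). Categories 4 (undefined
mechanism) and 5 (uncategorized) are labelled but excluded from the feature
stages by default: only stable, inserted and mutated regions support a
mechanistic reading.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_q` / `window` | 4 / 6 | glutamine density defining a polyQ; 4/6 maximizes the number of detected regions at the cost of diluting features specific to long pure tracts |
| `conserved` | 0.8 | minimum glutamine fraction for a conserved column (inclusive) |
| `uncat` | 0.2 | fraction below which a column is uncategorized (exclusive) |
| `min_rows` | 5 | minimum species per retained ortholog set |
| `links_threshold` | 0.7 | strict lower bound on the STRING combined score |
| `flank` | 10 | context-profile offsets on each side of a repeat |
| `ss_flank` | 20 | residues extracted around a repeat for structure prediction; aggregation then reports only −10..+10 so border effects in the prediction fall outside the plotted range |

All of these surface in `run_config()` and in the command-line wrapper; the
defaults are the canonical values of the method.

## Design choices where the design was open

* **Detection at termini.** The density rule is read as a threshold, not as
  window bookkeeping: a sequence shorter than the window is itself a
  (truncated) window, so a bare `QQQQ` tract qualifies. Covered positions
  of overlapping or adjacent qualifying windows merge, and each merged run
  is trimmed to terminal glutamines.
* **Merging across rows.** Column spans that overlap in at least one column
  merge transitively; spans that merely touch do not. Two orthologous
  regions therefore never share a column, and each is analysed
  independently — one alignment can contribute several regions.
* **Region span.** The span classified is the union of member spans, not
  any single member's tract: stability is a property of the aligned block.
* **Column denominators.** A gapped row counts in the denominator of the
  glutamine fraction — a gap is a row without a glutamine, and gap
  dominance is precisely what the *inserted* sub-value measures.
* **Ties.** All category rules use strict majorities; a conserved/unstable
  tie falls to category 5, a gap/substitution tie to sub-value undefined.
* **Identity.** Average alignment identity is the mean over row pairs of
  identical columns divided by columns where at least one of the pair has
  a residue; double-gap columns are ignored and gap-vs-residue counts as a
  mismatch. This is computed directly from the alignment rather than from
  any external distance tool, and is the one place where the package
  substitutes its own convention for an unstated upstream one.
* **Codon pooling.** A region's %CAG pools glutamine codons across all
  validly paired rows at the region's columns — including glutamines in
  rows that themselves lack the repeat, since those sit in columns where at
  least one ortholog has it. One value per region keeps the downstream
  distributions region-weighted rather than species-weighted; a per-row
  table is available via `region_codon_usage(..., per_row = TRUE)`.
* **CDS validation.** Rows whose CDS fails the codon-count or
  glutamine-codon (CAG/CAA) checks are excluded from codon analyses only,
  with counts reported; they remain in every protein-level analysis.
* **Context offsets.** Profiles are computed in the representative's
  ungapped sequence, relative to its own repeat boundaries, because that is
  how single-sequence context is defined. Positions beyond a terminus are
  skipped rather than padded, so per-position denominators shrink near
  sequence ends; only regions long enough to have a residue at an offset
  contribute there.
* **Interactions.** The score filter is strictly greater than 0.7; files on
  STRING's integer 0–1000 scale are auto-detected (any score above 1) and
  rescaled. Proteins absent from the links table are dropped, not
  zero-filled, since absence from the database is indistinguishable from
  having no interactors. A protein in a multi-region set receives one row
  per region.

## What the synthetic generator emulates

`generate_ortholog_set()` builds one alignment per planted category,
directly in alignment space: a flank of background residues (glutamine-free
by default), a repeat block, and a second flank. The repeat block is
constructed **row-wise** — an anchor row that is glutamine across the whole
span, plus glutamine rows, all-gap rows and all-substitution rows in
proportions drawn from the planted category's composition band. Row-wise
construction was chosen over independent per-column sampling for a specific
reason: it makes every member's realized repeat boundaries coincide with
the planted region boundaries, so a context enrichment planted at offset
−1 is measured at exactly −1 by the profiler regardless of which member is
drawn as representative. Independent columns would let member repeats start
or end mid-region and systematically bias context recovery. Every stated
per-column property still holds: stable plants have ≥ 80% glutamine in
every repeat column, inserted plants sit in the 20–79% band with gaps
strictly outnumbering substitutions, mutated plants the reverse, undefined
plants tie, and uncategorized plants either tie conserved against unstable
columns or keep every column below 20% glutamine.

Three controlled perturbations ride on top:

* **Impurities** (`impurity_prob`, default 0.1): a glutamine row may
  receive one interior non-glutamine residue, applied only when it provably
  preserves both the row's single full-span repeat (one impurity per
  six-residue window keeps every window at ≥ 5 glutamines) and the exact
  class of the affected column.
* **Noise** (`noise`, default 0): per repeat column, with the given
  probability, one non-anchor cell is resampled uniformly among glutamine,
  gap and a background residue. This is the regime for the ≥ 95% noisy
  recovery check; recovery is assessed over all categories pooled, because
  uncategorized tie-plants sit at margin zero by construction — a single
  class-changing cell legitimately flips them — while the four other
  categories are essentially immune to single-column perturbations.
* **Context enrichments**: at each enriched offset the residue appears with
  exactly the planted probability; cells that miss the draw are refilled
  from the background excluding the enriched residue, so recovery tests
  compare against the planted value rather than a background-inflated one.

CDS are derived from the ungapped rows: glutamines draw CAG with the
planted per-category probability (defaults 0.75 stable / 0.85 inserted /
0.70 mutated, i.e. the 3:1 vertebrate background with a slippage-style
elevation in length-variable repeats), other residues draw uniform
synonymous codons. The links generator gives every protein `1 +
rpois(lambda)` distinct high-confidence hub partners (defaults 25 for
stable-region proteins, 15 otherwise) plus two sub-threshold decoy edges
that a correct parser must discard.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: phylogenetic correlation among rows (rows are
exchangeable, real orthologs are tree-structured), realistic indel
placement outside the repeat (flanks are ungapped), compositional
heterogeneity along proteins, actual slippage dynamics (codon usage is
planted, not evolved), and any relationship between interaction counts and
biology beyond the planted shift. Recovery results validate the
bookkeeping of the pipeline, not the biological claims themselves.

## Numerical choices

* Threshold comparisons use a 1e-9 epsilon so that fractions such as 12/15
  compare equal to 0.8 despite binary floating point; with the default
  thresholds this is exactly the integer rule `5·n_Q ≥ 4·n`.
* Mann–Whitney tests run with `exact = FALSE` (normal approximation with
  continuity correction): percentage distributions are heavily tied, and
  the approximation is deterministic and warning-free. In every comparison
  exercised here the p-values sit far from the star-bin boundaries.
* All randomness (representative selection, generation, noise) is seeded;
  child seeds derive from a base seed via a fixed linear map kept inside
  32-bit integer range. Fixed seed means byte-identical outputs, which the
  tests assert file by file.
* Degenerate inputs have defined behaviour: empty columns and empty
  representative sets are fatal; regions with no pooled glutamine codon are
  excluded and counted; all-gap rows yield empty coordinate maps; pairs of
  all-gap rows contribute nothing to average identity.

## Problem sizes used in validation

The shipped tests recover planted categories on 500 unambiguous and 500
noisy sets per category (15 species each), codon usage on 200 regions per
category against 99% binomial intervals, context enrichments on 1,000
regions per category, and detector–oracle equivalence on 10,000 random
sequences of length 10–200 at 5–40% glutamine frequency. The acceptance
script runs reduced versions of the same computations (100 sets per
category, 2,000 oracle sequences) and reports the measured values.

## Known limitations

* Stability is defined relative to the supplied ortholog set; more
  divergent sets shift regions toward the unstable categories, so
  categories are comparable only within a consistent species selection.
* Secondary structure is consumed, never predicted: the package emits
  windows (repeat ± 20 residues) and aggregates externally produced
  H/E/other strings.
* Ortholog inference and alignment are out of scope; inputs are assumed
  pre-aligned, and alignment errors propagate into column classes.
* The generator's uncategorized plants cover the two canonical routes into
  category 5 (ties and low-glutamine spans) but not every alignment that
  real data could produce in that category.

```{r example}
aln <- ortholog_alignment(c(
  human = "MSTLQQQQQQPLA",
  chimp = "MSTLQQQQQQPLA",
  mouse = "MSTLQQQQ--PLA",
  rat   = "MSTLQQQQQ-PLA",
  dog   = "MSTLQQQQQQPLA"), set_id = "demo")
categorize_alignment(aln)$regions
```
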