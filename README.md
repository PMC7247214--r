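# polyqevo

Polyglutamine regions (polyQ) are among the most common homorepeats in
eukaryotic proteins. The same glutamine tract can be a very different
biological object depending on whether it is frozen in evolution or actively
expanding: stable tracts associate with helical context and rich interaction
interfaces, while length-variable tracts carry the signature of CAG
replication slippage. `polyqevo` turns that observation into a reusable
analysis: given aligned sets of orthologous proteins, it detects polyQ
regions, classifies their evolutionary stability from per-column glutamine
conservation, and profiles the features that co-vary with stability —
glutamine codon usage, flanking amino-acid context, secondary-structure
context, and protein–protein interaction capacity. It is aimed at anyone
studying homorepeat evolution who has ortholog alignments (and optionally
CDS, structure predictions, or a STRING-style links table) in hand.

## The classification at the core

A polyQ is any maximal span satisfying the 4-in-6 rule — at least four
glutamines within a window of six residues — merged across overlapping
windows and trimmed to terminal glutamines. Per-row regions are lifted to
alignment columns and merged across rows by transitive span overlap into
*orthologous polyQ regions*.

Each alignment column of a region is classified by its glutamine fraction
over all rows (gaps count in the denominator):

| column value  | rule                       |
|---------------|----------------------------|
| conserved     | ≥ 80% of rows have Q       |
| unstable      | ≥ 20% and < 80% have Q     |
| uncategorized | < 20% have Q               |

Unstable columns carry a sub-value: **inserted** when gaps outnumber
non-glutamine residues, **mutated** when non-glutamine residues outnumber
gaps, **undefined** on a tie. The region's category then follows from
strict majorities over its span (uncategorized columns count for neither
side): **stable** when conserved columns outnumber unstable ones;
**inserted** / **mutated** when unstable columns dominate and the matching
sub-value strictly dominates the other two; **undefined** when unstable
columns dominate without a winning sub-value; **uncategorized** otherwise.
Downstream feature analyses keep categories 1–3 and report the discarded
remainder.

Downstream, %CAG is `100 · CAG / (CAG + CAA)` over the glutamine codons
pooled at a region's columns across all validly paired rows; context
profiles count residue frequencies at offsets −10..−1 and +1..+10 from the
repeat boundaries of one randomly chosen repeat-bearing representative per
region; interactor counts keep STRING partners with combined score
strictly above 0.7. Category distributions are compared with two-sided
Mann–Whitney U tests, star-binned (`****` ≤ 1e-4 … `*` ≤ 0.05).

## Worked example

```r
library(polyqevo)
aln <- ortholog_alignment(c(
  human = "MSTLQQQQQQPLA",
  chimp = "MSTLQQQQQQPLA",
  mouse = "MSTLQQQQ--PLA",
  rat   = "MSTLQQQQQ-PLA",
  dog   = "MSTLQQQQQQPLA"), set_id = "demo")
res <- categorize_alignment(aln)
res$regions[, c("region_id", "col_start", "col_end", "n_members",
                "n_conserved", "n_unstable", "label")]
#>   region_id col_start col_end n_members n_conserved n_unstable  label
#> 1   demo_r1         5      10         5           5          1 stable
res$columns[, c("col", "n_q", "n_gap", "n_other", "value", "subvalue")]
#>   col n_q n_gap n_other     value subvalue
#> 1   5   5     0       0 conserved     none
#> 2   6   5     0       0 conserved     none
#> 3   7   5     0       0 conserved     none
#> 4   8   5     0       0 conserved     none
#> 5   9   4     1       0 conserved     none
#> 6  10   3     2       0  unstable inserted
average_identity(aln)
#> [1] 92.22222
```

One orthologous region spans columns 5–10, carried by all five rows.
Columns 5–9 are conserved (a 4/5 glutamine fraction meets the 80%
threshold); column 10, where two rodents lost the glutamine by deletion, is
unstable-inserted. Five conserved columns against one unstable column make
the region **stable**.

For whole datasets, `run_all(run_config(...))` drives every stage over a
directory of alignment FASTA files and writes TSV tables plus a JSON
summary; `inst/scripts/polyq-evo` exposes the same stages as shell
subcommands (`scan`, `categorize`, `codon-usage`, `context`, `ss-windows`,
`ss-aggregate`, `interactors`, `simulate`, `run-all`). The
`synthetic_spec()` / `generate_dataset()` pair builds ortholog sets with
planted categories, codon usage, context enrichments and interactor counts
for validation; see the methods vignette for what the generator does and
does not emulate.

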