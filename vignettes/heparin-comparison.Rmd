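---
title: "Comparing LMW heparin component tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing LMW heparin component tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heparcomp)
```

## The model

Top-down LC-MS of a low-molecular-weight heparin yields, after charge
deconvolution and hypothesis matching, a table of candidate component
assignments per run: a bracketed *compound key*
`[ΔHexA, HexA, GlcN, Ac, SO3]` naming a composition, a match *score*, and
a *total volume* (summed ion volume, arbitrary units) per row. One
composition typically appears as several rows differing only in ammonium
adduct count (0–14 NH3 in negative-mode ESI), and the composition
hypothesis is dense enough that distinct (composition, adduct) pairs fall
within the 5 ppm match tolerance of one another — the test suite
demonstrates thousands of such near-isobaric pairs in the default
hypothesis. A single run therefore cannot distinguish many false-positive
assignments from true components.

The method implemented here exploits replication instead of scoring:

1. **Noise removal.** Rows with an empty compound key are deconvolution
   noise and are always deleted before pooling (keeping them is not
   supported; it only slows the comparison and changes nothing downstream).
2. **All-presence filter.** Pool the K tables with a provenance label per
   row. A key is retained only if rows carrying it originate from all K
   distinct labels. Row multiplicity does not help: three rows of a key
   confined to two samples are still deleted. This is deliberately
   conservative — a true low-abundance component missed by one replicate
   is lost (that case is manual-curation territory), but the decoys that
   plague single-run matching are removed wholesale.
3. **Adduct merging.** Within each retained (key, sample) group the
   surviving score is the group maximum and the surviving volume the group
   sum. This equals a literal bottom-up walk of the key-sorted table that
   repeatedly folds the lower-scoring of two adjacent same-key, same-label
   rows into the higher-scoring one; on exact score ties that walk retains
   the *earlier*-sorted row, so the production code takes the first
   maximum-score row in pooled order when carrying passthrough columns.
   The equivalence of the two formulations is a tested proof obligation
   (the suite runs a literal row-loop simulator against the max/sum path
   on 1000 fuzzed tables).
4. **Relative quantification.** Per sample, abundances are normalized to
   the sum of the 10 most abundant components' volumes. Normalized values
   are reported for *all* retained components; only the denominator is
   top-n based. Ties straddling rank n are resolved by including every key
   tied with the rank-n volume in the denominator — deterministic, and the
   only unambiguous reading when volumes repeat.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| K (number of tables) | 3 | presence required in all K samples; generalized beyond the conventional three |
| `min_score` | disabled | optional pre-filter before the presence filter; 0.1 is the conventional pre-screen when scores are used at all |
| `top_n` | 10 | components defining the normalization denominator |
| `match_error_ppm` | 5.0 | relative mass tolerance for hypothesis matching |
| MW window | 500–6000 Da | applied to the **unadducted** chain mass (adducts are a mass shift on the molecule, not part of it); an adducted-mass mode is available |
| adducts | 0–14 NH3 | ammonium adduct range |
| dp cap | 18 | maximum A+B+C; kept independent of the MW window since either may bind first |

The hypothesis constraint box (A ∈ {0,1}; B ≤ 9; A+B−1 ≤ C ≤ A+B+1 with
the lower bound clamped at 0; D ≤ 3; B ≤ E ≤ A+B+2C+1−D) is taken as
given, with one chemically forced extension: D is additionally capped at C,
since a chain cannot carry more N-acetyl groups than hexosamines. For
chains with a 1,6-anhydro reducing end the unsaturated uronic residue is
C6H4O4 instead of C6H6O5 — exactly one further water loss, an identity the
tests check to 1e-9 Da. Mass constants are hard-coded from standard atomic
monoisotopic masses (derivation script in `tools/`), and an independent
element-sum oracle in the tests re-derives every composition mass to
below 1e-6 Da.

Two key dialects are supported: the default enoxaparin display order
`[ΔHexA, HexA, GlcN, Ac, SO3]` and the synthesized-standard order
`[HexA, GlcN, PNP, SO3, Ac]` (`profile = "pnp"`), where position 3 flags
the para-nitrophenyl aglycone of chemoenzymatically synthesized standards.
The anhydro flag is table-level metadata (which hypothesis variant a run
was matched against), never inferred from the key, because the bracketed
tuple is identical for both variants.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emits K tab-delimited tables in the reader's dialect
with planted structure: `n_true` components present in every table and
split across 1–3 distinct-adduct rows; `n_decoy` components each planted
in a uniformly chosen *strict* subset of tables (the k−1 case — the
hardest for the filter — occurs with positive probability and is asserted
in tests); and empty-key noise rows at a chosen fraction of each file.
Volumes are log-normal (meanlog `log(1e4)`, sdlog 1 — heavy-tailed like
ion volumes, spanning roughly two orders of magnitude) rounded to integer
cents so merged sums are bit-exact; scores are uniform(0,1) to 4 decimals.
Everything is a deterministic function of the seed (R's Mersenne-Twister,
scoped with `withr::with_seed`), and fixture files are byte-stable.

The generator does *not* emulate retention time, isotope structure,
score–abundance correlation, or the possibility that a *true* component is
missed in one replicate. A green planted-recovery test therefore
establishes that the filter and merge arithmetic are correct, not that the
all-presence principle has any particular sensitivity on real data — on
real tables its false-*negative* behavior is governed by instrument
reproducibility, which is out of scope here.

The bundled tables under `inst/extdata/fdr_synthetic/` are a synthetic
stand-in for a validation data set of four synthesized heparin
oligosaccharides that is only distributed as a binary spreadsheet
supplement: they reproduce its published summary structure (per-replicate
record counts for oligosaccharide A; the number of retained components and
the true/false split per oligosaccharide, hence false-positive rates of
40%, 62.5%, 50% and 40%), while every row-level value is invented. Tests
against them validate the pipeline's arithmetic on realistically shaped
input, not the historical measurement.

## Numerical choices

- Volume sums use compensated (Kahan) addition over the fixed pooled
  order, so outputs are byte-stable under refactoring of the grouping.
- Numeric columns are written with 10 significant digits; the
  read-after-write round trip is exact at that declared precision.
- Score ties in a merge group keep the earliest pooled row's passthrough
  columns (see step 3 above); volumes and scores are unaffected by the
  choice.
- Key ordering everywhere is (dp, then the integer tuple
  lexicographically), so dp-grouped reports fall out naturally.
- `fdr_evaluate` with nothing retained reports an undefined (NA) rate,
  distinct from 0.

## Design choices where the design was open

- **K generalized.** The classical workflow hard-codes three sheets;
  presence is required in all K provided tables, K ≥ 2.
- **MW window on the unadducted mass** (see table above), with the
  adducted mode switchable for pipelines that window the observed mass.
- **Multiple bracketed groups in one cell.** The first, shortest bracketed
  span wins (lazy matching taken literally); behavior on exotic cells is
  documented rather than guessed.
- **Cross-sample merging is a non-goal**: volumes are never summed across
  lots, and partial-presence modes (2-of-3) are deliberately absent.
- **Noise accounting.** `noise_fraction` is the fraction of a file's rows
  that are noise, so a file with P planted rows gains
  `round(P·f/(1−f))` empty-key rows — at f = 0.5 noise doubles the file.
- **Per-sample abundances are emitted, not lot averages**; averaging
  across lots is left to the caller since either convention is defensible.

## Known limitations

- Scores are consumed, never recomputed; the package cannot rescue a run
  whose upstream matching was misparameterized.
- The all-presence filter is exact set intersection: a component present
  in K−1 of K runs is discarded no matter how abundant. Inspect the
  pre-filter pooled table when that matters.
- Average-mass (as opposed to monoisotopic) arithmetic, isotopic fine
  structure, charge-state handling and MS/MS are out of scope.
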