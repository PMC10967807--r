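# dehydrinr

Annotation and characterization of **dehydrins** — group-2 late
embryogenesis abundant (LEA) proteins, Pfam PF00257 — the hydrophilic,
intrinsically disordered proteins that plants accumulate under drought,
cold and salt stress. The package is aimed at plant molecular biologists
and comparative genomicists who have dehydrin candidate sequences (e.g. a
Pfam sweep across woody species) and want the standard characterization
workflow as reproducible code instead of a chain of web tools.

## What it does

Dehydrins are built from a small vocabulary of conserved segments embedded
in disordered Gly/polar-rich linkers:

| Segment | Consensus | Role |
|---|---|---|
| K | `XKXGXX(D/E)KIK(D/E)KXPG` (classic `EKKGIMDKIKEKLPG`) | obligatory; membrane-binding amphipathic helix |
| Y | `D(D/E)(Y/H/F)GNPX` | N-terminal, angiosperm-specific |
| S | `LHR(S/T)G` + serine run (4–8) + acidic tail | phosphorylation / nuclear targeting |
| F | `EXXDRGXFDFX(G/K)` (Phe dyad) | gymnosperm-enriched |

On top of that vocabulary the package provides:

* **Segment scanning** (`scan_segment`, `scan_proteins`) — degenerate
  consensus matching with exact cores and a tunable non-core mismatch
  budget, scored by position-specific probability matrices (log-odds vs a
  uniform background), with greedy overlap resolution.
* **Architecture typing** (`classify_architecture`,
  `architecture_profiles`) — the ordered segment string is classified into
  the seven canonical types `Kn, KnS, SKn, YnKn, YnSKn, FSKn, FnKn` or
  `ATYPICAL`; rare motifs (His-His flanked K segments, the `KKKKKEKK`
  poly-lysine, His-His richness, the metal-binding `HHSGDHH`) are flagged.
* **Biochemical profiles** (`biochem_profiles`) — molecular weight,
  isoelectric point (Henderson–Hasselbalch bisection, Bjellqvist or EMBOSS
  pKa sets), Kyte–Doolittle GRAVY, the fold index
  `2.785·<H> − |<R>| − 1.151`, and Lys/His percentages.
* **Group statistics** (`summarize_groups`, `games_howell`,
  `compare_groups`) — five-number summaries and Games–Howell pairwise
  post-hoc comparisons (Welch SE/df + studentized range) across taxon
  groups such as gymnosperm trees vs angiosperm trees/shrubs vs vines.
* **Promoter cis-element profiling** (`load_catalog`, `scan_promoters`,
  `presence_frequency`) — IUPAC consensus matching on both strands against
  an editable PlantCARE-style catalog (ABRE, G-box, Box 4, LTR, DRE core,
  W box, …), reporting the percentage of promoters containing each element.
* **Synthetic data with ground truth** (`synth_dehydrin`, `synth_cohort`,
  `synth_promoter`) — plants segments/elements at known coordinates so the
  whole pipeline is testable offline.
* **Pipelines** (`run_protein_pipeline`, `run_promoter_pipeline`) — TSV in,
  TSV out, byte-identical on rerun; sequences with no K segment go to a
  rejects file (they are not dehydrins). A thin CLI wrapper lives at
  `inst/cli/dehydrinr.R`.

All coordinates are 0-based, half-open, and every TSV output says so in a
header comment.

## Worked example

Generate a dehydrin with a known `Y2SK3` architecture, scan it, classify
it, and compute its biochemistry:

```r
library(dehydrinr)

out <- synth_dehydrin("Y2SK3", accession = "DHN1", seed = 11)
m <- scan_proteins(out$record)
m[, c("accession", "class", "start", "end", "matched_seq", "score")]
#>   accession class start end     matched_seq score
#> 1      DHN1     K   154 169 NKTGDEDKIKEKGPG 37.35
#> 2      DHN1     K   226 241 EKKGSDEKIKEKCPG 43.67
#> 3      DHN1     K   288 303 KKGGPSDKIKDKDPG 37.35
#> 4      DHN1     Y    43  50         DEYGNPP 24.29
#> 5      DHN1     Y   104 111         DEHGNPN 22.58
#> 6      DHN1     S   123 137  LHRSGSSSSSSDDD 55.84
```

The six matches are the planted segments, at their planted coordinates
(compare `out$truth`), each scored in bits against a uniform background.
The ordered letters `YYSKKK` compress to the formula and canonical type:

```r
architecture_profiles(out$record, m)[, c("formula", "arch_type", "nK", "nY")]
#>   formula arch_type nK nY
#> 1   Y2SK3     YnSKn  3  2

biochem_profiles(out$record)
#>   accession      group length    mw    pi  gravy fold_index lys_pct his_pct
#> 1      DHN1 UNASSIGNED    362 38464 5.491 -1.625    -0.3082   10.22   4.696
```

Negative GRAVY (hydrophilic) and negative fold index (predicted
disordered) are the universal dehydrin signature; the generator's linker
composition guarantees both by construction, as real dehydrins do
empirically.

## Layout

* `R/` — implementation; `inst/extdata/` — constants tables (residue
  masses/hydropathy, pKa sets, phi-background composition) and the
  cis-element catalog, all editable plain text.
* `tests/testthat/` — unit, property and end-to-end tests with independent
  oracles (brute-force window matcher, pH charge-scan, studentized-range
  quadrature).
* `vignettes/dehydrin-annotation-methods.Rmd` — the model, parameter and
  design-choice write-up.
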