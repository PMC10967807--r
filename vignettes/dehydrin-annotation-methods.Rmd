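---
title: "Dehydrin annotation: models, parameters and design choices"
author: "dehydrinr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dehydrin annotation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dehydrinr)
```

## The biological problem

Dehydrins (group-2 LEA proteins, Pfam PF00257) are hydrophilic,
intrinsically disordered plant proteins that accumulate under
dehydration-related stress (drought, cold, salinity). They are built from a
small vocabulary of conserved segments embedded in poorly conserved,
glycine/polar-rich disordered linkers (the "phi" background):

* **K segment** — the obligatory lysine-rich ~15-mer
  (consensus `EKKGIMDKIKEKLPG`, degenerate form `XKXGXX(D/E)KIK(D/E)KXPG`),
  which forms amphipathic helices that bind membranes. A protein without a K
  segment is, by definition, not a dehydrin.
* **Y segment** — an N-terminal ~7-mer (`D(D/E)(Y/H/F)GNPX`), found only in
  angiosperm dehydrins.
* **S segment** — a serine-tract motif: anchor `LHR(S/T)G`, a run of serines,
  then an acidic tail; a phosphorylation site linked to nuclear targeting.
* **F segment** — a 12-mer with a phenylalanine dyad
  (`EXXDRGXFDFX(G/K)`), prevalent in gymnosperm dehydrins.

The ordered combination of segments defines the **architectural type**
(`Kn`, `KnS`, `SKn`, `YnKn`, `YnSKn`, `FSKn`, `FnKn`), which correlates with
taxon and stress behavior. This package annotates segments, classifies
architectures, flags rare His/Lys motifs, computes biochemical properties,
compares taxon groups, and profiles promoter cis-elements — plus a
synthetic-data generator that makes every stage testable against known
ground truth.

## Segment model: degenerate consensus + PSPM score

Each segment class is modelled twice, and both halves are used together:

1. a **degenerate consensus** with per-position allowed residue sets, split
   into *core* positions that must match exactly (K: `G3, K7, I/V8, K9, P13,
   G14`, 0-based — the Lys-Ile-Lys core and the Gly/Pro-Gly anchors; Y:
   `D0, G3, N4, P5`; S: the serine tract; F: the Phe dyad at 7 and 9) and
   non-core positions where up to `max_mismatch` violations are tolerated;
2. a **position-specific probability matrix (PSPM)** seeded with the
   conserved-position frequencies observed across woody-plant dehydrins
   (e.g. Lys at 81–90% through the K segment, Asp 96%/Gly 91%/Asn 92% in the
   Y segment, Phe 98%/81% in the F segment). The remaining probability mass
   is spread uniformly over the residues the pattern allows, and a small
   pseudocount floor (0.002, mixed uniformly) guarantees no residue has zero
   probability. Surviving windows get a log-odds score in bits against a
   uniform 1/20 background.

Defaults: `max_mismatch = 2` at non-core positions and `min_score = 0` bits.
These recover the textbook consensus sequences exactly while rejecting
random windows: on uniform random 200-mers the observed false-positive rate
is below $10^{-3}$ per window for every class (measured by simulation in the
test suite — in practice no hit in >10,000 windows), because a random window
must match all core positions exactly *and* out-score the uniform
background. Both knobs are exposed via `scan_params()`.

The **S segment is variable-width**: published descriptions disagree on the
tract length (4–6 serines in the bracket formula, seven in the observed
consensus, 4–8 in the wider literature), so the scanner anchors `LHR(S/T)G`,
consumes the *maximal* serine run of 4–8 residues, then matches the
3-residue acidic tail, giving widths 12–16, and reports the observed run
length. The PSPM is laid out at the canonical width 15 (run of 7) and the
representative tract column is reused when scoring other run lengths.

Overlaps are resolved greedily by descending score with ties broken by the
smaller start; no two retained matches may overlap, across classes — one
residue belongs to one segment. His–His flanks around K segments are *not*
part of the K window; they are detected separately as rare motifs.

What the scanner deliberately does not do: no EM motif discovery (the
consensus and frequencies are fixed inputs, not re-estimated), no gapped
matching beyond the serine-run length, and no site p-values — windows are
accepted by core-exactness, mismatch budget, and log-odds threshold.

## Architecture grammar

Classification is a pure function of the N→C segment letter string: `K+`,
`SK+`, `K+S`, `Y+K+`, `Y+SK+`, `FSK+`, `F+K+`, tried in that order (they are
mutually exclusive). Everything else is `ATYPICAL`: the seven canonical
names contain no Y after K, no S inside the K block, and no F together with
Y, so interleaved strings such as `YSK2(KS)SK3Y2SK3` route to `ATYPICAL` —
mirroring how the handful of published interleaved dehydrins are handled.
Two design points were genuinely open:

* `FSKn` is read as *exactly one* F and one S (the name subscripts only K);
  an `F2SK3`-like string falls to `ATYPICAL`. No published sequence decides
  the case; the stricter reading keeps `FnKn` and `FSKn` disjoint.
* "K segment flanked by His residues" is read as His-His on **both** sides
  (the censused motif is written `HH-K-seg-HH`); one-sided flanks are
  reported as a diagnostic but do not set the flag. Likewise His-His
  richness counts **non-overlapping** `HH` dimers (`HHH` counts once), and
  the poly-K flag requires the exact printed 8-mer `KKKKKEKK`, with a
  relaxed `K{4,}EK{1,3}` count carried alongside for diagnostics only.

## Biochemical properties

All properties are computed from first principles over non-X residues
(X is retained for scanning but has no physical constants, so it is excluded
from every denominator):

* **Molecular weight**: sum of average residue masses + 18.0153 Da water.
* **Isoelectric point**: bisection on pH ∈ [0, 14] of the
  Henderson–Hasselbalch net charge to |charge| < 1e-4. The pKa set defaults
  to the Bjellqvist (ProtParam) convention and ships as a plain-text table;
  `pka_set("emboss")` swaps in the EMBOSS values.
* **GRAVY**: mean Kyte–Doolittle hydropathy. Negative = hydrophilic.
* **Fold index**: $2.785 \langle H \rangle - |\langle R \rangle| - 1.151$
  with $\langle H \rangle$ the mean scaled hydropathy $(KD + 4.5)/9$ and
  $\langle R \rangle$ the mean net charge (K, R = +1; D, E = −1; His
  neutral, the standard convention — worth noting because dehydrins are
  His-variable). Negative = predicted disordered. The headline value is the
  whole-sequence (global) index, matching how one number per protein is
  plotted; `fold_index_profile()` provides the windowed variant (default
  window 51).

```{r biochem}
gravy("KKKK")                       # uniform-residue identity: KD(K)
fold_index(strrep("A", 20))         # 2.785 * 0.7 - 0 - 1.151
round(isoelectric_point("DDDD"), 2) # acidic homopolymer
```

Group centers are summarized as medians (five-number summaries feed the box
plots); whether reported distribution centers in the source material are
medians or modes is unstated, so the median is the committed choice.

## Games–Howell comparisons

Taxon groups (gymnosperm trees, angiosperm trees/shrubs, angiosperm vines)
differ in spread as well as center, so pairwise comparisons use
Games–Howell: Welch standard errors and degrees of freedom with the
statistic referred to the studentized-range distribution with $k$ groups.
This controls the familywise error under unequal variances without an
additional multiple-testing correction. The procedure is sometimes loosely
called non-parametric; it is implemented as the standard Welch /
studentized-range construction (which drops equal variances, not
normality). The studentized-range CDF is evaluated through R's `ptukey`,
the standard double-integral implementation; the test suite checks it
against an independent Gauss–Legendre/`integrate` quadrature oracle to
1e-4 and verifies the k = 2 reduction to Welch's t and the empirical size
(null rejection rate 0.035–0.065 at α = 0.05 over 5,000 simulations with
variances 1:4:9).

## Promoter cis-element profiling

Promoters (2-kb upstream regions by convention) are scanned against an
editable catalog of named IUPAC consensus strings with categories (light,
hormone, stress, development). Matching is exact degenerate IUPAC set
matching on both strands — no position-weight scores — and an `N` in the
promoter matches nothing. Coordinates are forward-strand, 0-based,
half-open, with a strand flag; for minus-strand hits the reverse complement
of the matched slice satisfies the consensus. The headline quantity is the
**presence frequency**: the percentage of promoters containing each element
at least once; palindromic consensi (e.g. the G-box `CACGTG`) produce paired
+/− hits but count once per promoter. A derived `MeJA-responsive` row
reports the union presence of the `CGTCA-motif` and `TGACG-motif`.

The shipped catalog carries canonical PlantCARE-style consensus strings for
the classic dehydrin-promoter elements (ABRE, G-box, Box 4, LTR, DRE core,
W box, MYB/MYC, as-1, …). The exact matrices behind any given PlantCARE
report are not published alongside element names, so the catalog is **data,
not code**: bar heights for short consensi depend on catalog fidelity, and
users with a better-curated collection should replace the TSV.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth without downloads. It emulates the study design it stands in
for:

* **Cohort sizes** default to 32 gymnosperm (tree), 185 angiosperm
  (tree/shrub) and 36 angiosperm (vine) sequences.
* **Type weights** per group mirror the reported type distribution
  (gymnosperms: FSKn 0.563, FnKn 0.21, no Y-containing types; trees/shrubs:
  FSKn 0.395 leading a full mixture; vines: YnSKn 0.694 with no Kn, YnKn or
  FnKn). Weights must sum to 1 and are validated.
* **Copy numbers**: K segments 1–9 with small counts most likely; Y 1–3;
  F 1–2 for the FnKn type.
* **Segments** are sampled from the class PSPMs restricted to the degenerate
  pattern (core positions stay within their core sets), so a noise-free
  planted segment is always a legal scanner match. One generator-side rule
  keeps truth coordinates well-defined: the acidic tail of an S segment may
  open with a serine only when the tract is already at its 8-residue cap,
  otherwise the tract/tail boundary would be ambiguous under the scanner's
  maximal-run reading.
* **Linkers** of 10–60 residues are drawn from a shipped phi-background
  composition (Gly 0.14, Thr 0.10, elevated E/K/S/D/N/H, suppressed
  aromatics and aliphatics). This composition was chosen once so that
  generated proteins are hydrophilic and predicted disordered by
  construction — mean linker hydropathy ≈ −1.4 — mirroring the universal
  observation that real dehydrins all have negative GRAVY and fold index.
* **Mutations**, when requested, touch only non-core segment positions, so
  planted segments remain recoverable within the scanner's mismatch budget.
* **Promoters** are uniform-ACGT backgrounds with elements inserted verbatim
  (or reverse-complemented) at planned coordinates; degenerate IUPAC letters
  are instantiated by sampling.

Everything is reproducible from `(spec, seed)`; the RNG state of the caller
is saved and restored, so there is no hidden global randomness.

```{r cohort}
coh <- synth_cohort(cohort_spec(n = c(ANGIOSPERM_VINE = 5L), seed = 42))
coh$assignments
```

**What passing tests do and do not show.** The generator produces
unrelated sequences with exactly consensus-shaped segments and i.i.d.
linkers; real dehydrins carry phylogenetic correlation, composition drift,
fragmentary database entries, and segment variants beyond the modelled
degeneracy. Recovery and classification rates on synthetic cohorts
therefore validate the *machinery* (coordinates, grammar, resolution,
statistics), not the field performance of the consensus definitions on
novel taxa. Chance background hits are also real: a 5-base consensus like
the ABRE core appears by chance roughly once per 500 bases of random
sequence per strand, so short elements saturate presence frequencies on
2-kb promoters — synthetic or real — which is why exact-recovery claims in
the tests use long-consensus elements, and why presence percentages for
short motifs should be read as scanner behavior, not planting fidelity.

## Numerical choices and degenerate inputs

* Coordinates everywhere are 0-based, half-open, and every TSV written by
  the package says so in a header comment.
* PSPM columns sum to 1 to 1e-9; quoted frequencies are preserved to within
  the 0.002 pseudocount mixing.
* Bisection for pI stops at |charge| < 1e-4 (≤ 100 halvings); the charge
  curve is strictly decreasing, so the root is unique.
* Ties in overlap resolution break by smaller start, making reruns
  byte-identical.
* Empty FASTA files parse to empty record sets; an empty cis-element catalog
  yields empty profiles with a warning; sequences of only `X` raise an
  "empty effective sequence" error in the biochemical calculators.
* Exact-sequence deduplication is provided (`dedupe_records()`); fragment
  detection is left to the user because no robust, assumption-free rule
  exists for deciding whether a shorter entry is a fragment.
* Group-comparison sizes in the tests (tens per group) and the simulation
  counts (5,000 null replicates; ~1,000-sequence recovery cohorts) were
  chosen as the smallest sizes at which the checked properties are stable.

## Known limitations

* The scanner does not emulate motif *discovery*; if a taxon's segments
  drift from the encoded consensus, sensitivity falls and only the PSPM
  threshold/mismatch budget can compensate.
* The fixed F-segment width (12, from the only complete published bracket
  pattern) means N- or C-terminally extended F variants are scored but not
  specially handled; the conserved Leu-Phe-Asp-Phe-Leu core enters only as
  score weighting.
* Catalog fidelity bounds the promoter module: presence percentages for
  elements whose true PlantCARE matrices differ from the shipped consensus
  strings will differ accordingly.
* No multiple alignment, phylogeny, or stress-response curation is
  attempted; taxon groups enter only as labels.
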