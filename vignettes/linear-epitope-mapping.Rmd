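---
title: "Methods: linear epitope mapping from overlapping peptide arrays"
author: "epitiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear epitope mapping from overlapping peptide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitiler)
```

## The problem

Autoantibodies against C-reactive protein (CRP) are frequent in systemic
lupus erythematosus (SLE) and target neoepitopes that become accessible
when the native pentamer dissociates into its 206-residue monomer. To
localize the linear binding sites, the full monomer sequence is printed on
a peptide microarray as overlapping 15-mers (14-residue overlap) framed by
an antigen control grid, probed with patient serum, and scanned before and
after serum incubation. `epitiler` implements the desk side of that
experiment: tiling-library construction, per-subject positivity calling,
reduction of overlapping positive peptides to minimal consensus epitopes,
cohort harmonization, the accompanying serology normalizations and
nonparametric association battery, and metrics for the neutrophil
functional assays used to follow up an epitope of interest. A synthetic
cohort generator with planted ground truth makes every stage testable
without access to raw scans, which are typically not deposited.

## Tiling geometry

The mature sequence of length $L$ is elongated with a neutral flank on both
sides and a window of `tileLength` residues slides with step
`tileLength - overlap`. Defaults are 15-mers at 14-residue overlap with a
7-residue GS-repeat flank, realized as `GSGSGSG`: the array vendor's
convention specifies length and composition class only, so the concrete
linker is a configuration choice and any alternate can be supplied.
With these defaults a 206-residue monomer yields
$206 + 2\cdot7 - 15 + 1 = 206$ tiles. Coordinates are kept in two systems:
positions on the flanked sequence (internal) and 1-based inclusive spans on
the mature monomer, clipped to $[1, L]$, matching the superscript notation
(e.g. `PDE^168-170`) used for epitopes. Tiles falling wholly inside a flank
are retained — they exist on the physical array — but carry `NA` mature
spans and can never support an epitope. Interior residues are covered by
exactly 15 tiles; terminal residues by at least `flank + 1` tiles.

## Positivity calling

Each array is scanned air-dried before serum incubation; the background
level is summarized as the **median** of that pre-serum scan. A per-array
scalar is robust against isolated bright pre-scan spots; an element-wise
per-spot mode (`perSpot = TRUE`) exists for sensitivity analysis. A tile is
seropositive when its serum-scan fluorescence attains
`factor` $\times$ background (default 2), boundary inclusive: the cutoff is
described as a level to be *reached*, so equality counts. The control grid
is summarized the same way; arrays whose control-spot median falls below
twice the background are flagged, not dropped, because published cohorts do
not report exclusions — exclusion is opt-in (`excludeQcFail`).

## Minimal consensus epitopes

The field's one-sentence rule — the epitope is the minimal stretch shared
by overlapping positive peptides, with at least three residues overlapping
— under-determines an algorithm, so the package fixes one and documents
why:

1. positive tiles are ordered by their mature spans;
2. tiles whose spans share at least `minOverlap` (default 3) residues are
   linked into chains (single linkage);
3. each chain is segmented into runs, every run required to have a
   non-empty common intersection of its tiles' spans;
4. each run emits one call: the intersection span, its motif read from the
   sequence, the supporting tiles and their mean intensity.

Step 3 is a small dynamic programme rather than a left-to-right greedy
sweep. The segmentation minimizes the number of runs, then maximizes the
total intersection length, then the minimum intersection length, and
finally prefers the longer leftmost run. The reason is concrete: when a
subject reacts to two adjacent epitopes — e.g. `DIGN^155-158` and
`PDE^168-170`, whose supporting-tile blocks are contiguous in tile index —
a greedy sweep absorbs the first tiles of the second epitope into the
first run and miscalls both. The balanced segmentation recovers exactly
the planted spans in every case that is decodable at all, and cohort
prevalence makes such co-occurrences unavoidable (the two most prevalent
epitopes together exceed the number of epitope-positive patients).

Two geometric limits are inherent to tiling arrays and documented rather
than hidden:

* **Terminal identifiability.** With a 7-residue flank the last tile
  starts at mature position $L-7$, so no intersection can start later;
  a C-terminal motif such as `QLWP^203-206` is only resolvable as the
  consensus region `199-206` (its end is pinned exactly). The same holds
  mirrored at the N-terminus.
* **Ambiguous pairs.** A few epitope pairs produce merged positive-tile
  patterns that are consistent with more than one planted configuration
  within a single subject; no caller can distinguish them from positives
  alone. The fixture cohort (below) keeps such pairs on different
  subjects.

Calls shorter than `minOverlap` residues can arise from sparse positive
patterns and are flagged with a warning rather than suppressed.

Subject-level calls are harmonized across the cohort by single-linkage
clustering on span overlap (same `minOverlap`); a cluster's canonical span
is the intersection of its member spans, or — if members drifted apart so
far that the intersection is empty — the contiguous region of maximal
member coverage, flagged with a warning. Canonical spans that still
overlap by `minOverlap` after clustering raise an internal-consistency
error. Subjects are positive for a cohort epitope when one of their calls
belongs to its cluster; the boolean matrix and the per-cell mean intensity
form the `EpitopeMatrix`.

Calling is per subject, then harmonized — not on pooled or group-mean
intensities — because cohort reports state per-subject positivity against
named epitopes. A pooled mode can be emulated by passing group-mean
intensities as a single synthetic subject.

## Serology conventions

* Arbitrary units: $100 \times$ sample signal / positive-reference signal.
* Percentile cutoffs (e.g. the 95th percentile of a 100-donor panel) use
  the **nearest-rank** convention, the `ceiling(p \cdot n)`-th order
  statistic, with no interpolation; the same type-1 quantile convention is
  used for all median/IQR summaries in the statistics module.
* Positivity against any cutoff is **strict** (`>`); boundary values are
  negative. Ties at a cutoff are rare and the choice is documented rather
  than consequential.
* netOD = coated-well OD − non-coated-well OD, floored at 0.
* Antiphospholipid positivity: any of aCL IgG/IgM, anti-β2GPI IgG/IgM
  strictly above its kit cutoff (packaged defaults 10/10/8/8 U/ml, a JSON
  config).
* Active disease: activity score (SLEDAI-2K) ≥ 5.

## Statistical battery

Non-paired continuous comparisons use the two-sided Mann-Whitney U test:
exact null when the smaller group has ≤ 12 observations and no ties,
otherwise normal approximation with tie and continuity correction.
Correlations are tie-aware Spearman (average ranks, asymptotic two-sided
p). Binary-by-binary comparisons use Fisher's exact test with the
point-probability method — the standard reading of an "exact chi-square"
on 2×2 tables with small cells — plus the sample odds ratio with a 0.5
cell correction when a zero occurs. Paired comparisons use the Wilcoxon
signed-rank test with zero differences dropped; all-zero or single-pair
inputs return p = 1 with a warning. Multiple paired conditions use the
Friedman test followed by Dunn's z with Bonferroni adjustment over the
tested pairs (the common all-pairs correction; no specific one is
mandated by the source conventions). Fully tied Friedman input (identical
conditions) is reported as chi-square 0, p = 1. The association table
dispatches by variable type (binary×binary → Fisher, binary×continuous →
Mann-Whitney, continuous×continuous → Spearman), flags p < 0.05, and
applies **no multiplicity correction across the table**, mirroring the
descriptive practice of the studies this pipeline supports; a
Benjamini-Hochberg view is one `p.adjust()` call away.

Exact tests are verified in the suite against brute-force enumeration
oracles (all group assignments, all $2^n$ sign vectors, full
hypergeometric support).

## Functional-assay metrics

* Oxidative burst: trapezoid-rule AUC of the kinetic chemiluminescence
  curve on its native 30-second grid over 15 minutes, expressed as percent
  of the negative-control AUC. No baseline subtraction — the ratio already
  removes instrument gain, and the metric is provably invariant to
  multiplying both curves by a constant. The integrated window is the
  stimulated 15-minute read; pre-incubation reads are not included.
* Chemotaxis: per cell, origin-zeroed net displacement along the
  chemoattractant axis (sign configurable, +x by convention) and velocity
  as total path length over total time (path ≥ chord always holds).
  Summaries: mean ± SD for directional movement, median (range) for
  velocity, matching how such panels are usually displayed.
* Extracellular-DNA release: fold of DNA-dye fluorescence over control;
  quantification of DNA-enzyme complex ELISAs against their standard is
  out of scope.

## Synthetic data and the frozen fixture

The generator's reactivity model is **containment**: a tile is reactive
for a subject exactly when its mature span contains one of the subject's
planted epitope spans. This is the unique simple model under which
intersection calling returns exactly the planted span, and it mirrors the
biology of a short linear motif that must be fully present in a peptide to
be bound. Background scans are log-normal (meanlog `log(100)`, sdlog 0.25
by default); non-reactive tiles sit at the background level, reactive
tiles at `gain` (default 5) times it, both with optional multiplicative
log-normal noise; false positives are injected per tile at `fpRate`.
Defaults are 42 patients and 11 donors, the mapped cohort's size. With
`fpRate = 0`, `noiseSd = 0` and `gain` above the positivity factor,
planted recovery is exact by construction — the master property of the
test suite. Clinical covariates are drawn from distributions chosen to
match the published cohort's summary table (log-normal for skewed
laboratory values, normal for age and complement function); they exist to
exercise the association battery and none of the package's guarantees
depends on them.

The frozen fixture (`fixtureAssignment()`, `fixtureCohort()`) is a 0/1
subject-by-epitope matrix constructed once by deterministic greedy search
so that all published marginals hold simultaneously: per-epitope positive
counts in both groups (patients: 13, 12, 10, 10, 8, 7, 5, 3, 2, 2, 1;
donors: 2, 2, 1, 1, 1, 1), 24 of 42 patients and 4 of 11 donors positive
for at least one epitope, patient totals with median 1 and maximum 7,
donor totals with median 0 and maximum 4, and five epitopes exclusive to
patients. Donor counts for three of the shared epitopes are not published
individually; the fixture uses 1 each, the minimum consistent with the
published statement that every shared epitope occurs in at least one
donor. The search keeps the non-decodable pairs described above on
disjoint subjects and every positive subject's planted set is re-verified
for exact recovery at test time; the matrix itself is re-validated against
all marginals every time it is loaded. The C-terminal epitope is planted
as `199-206` for the identifiability reason above.

What the generator does **not** emulate: spot-level image artifacts,
duplicate spots and gridding, dye chemistry, partial-motif reactivity,
discontinuous (conformational) epitopes, and the real joint distribution
of intensities across subjects. Passing the suite therefore demonstrates
the correctness of the pipeline's logic under the stated reactivity model,
not the biological fidelity of any particular scan.

## Numerical and size choices

Tests run the full 206-tile geometry throughout; the stochastic recovery
property uses 200 random planted configurations and a 50-array
false-positive cohort (10 300 tiles), sizes chosen to give the binomial
check useful resolution while keeping the default suite in the
tens-of-seconds range. All simulations are seed-deterministic; RNG state
is restored after each generator call. File exports are tab-separated
UTF-8 with `.` decimal; array round-trips are exact on integer-valued
fluorescence.

## Known limitations

* Terminal epitopes are reported at tile resolution (see above), so their
  labels differ from motif-level annotations at the chain ends.
* The consensus-calling tie-break (leftmost-longer) is a convention;
  genuinely ambiguous merged patterns admit other decompositions.
* The association battery is descriptive (no multiplicity correction by
  default) and implements no regression modelling.
* Printed p-values from the original serum cohort are not reproducible
  targets because raw intensities are not deposited; the package's
  guarantees are anchor identities, geometry, planted recovery, and
  enumeration-exact statistics.
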