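# epitiler

Linear B-cell epitope mapping from overlapping peptide tiling arrays, in R.

## What this is for

Peptide tiling microarrays print the full primary sequence of a protein as
overlapping short peptides (here: 15-mers with 14-residue overlap, framed
by neutral GS flanks) and probe them with patient serum to localize the
linear epitopes of autoantibodies. The motivating application is
autoreactivity against C-reactive protein (CRP) in systemic lupus
erythematosus: IgG anti-CRP antibodies target neoepitopes of the
dissociated 206-residue monomer, and their fine specificities associate
with disease activity, antiphospholipid antibodies and complement
function. `epitiler` implements the complete desk-side analysis for such
experiments, for anyone who has per-spot intensities and wants cohort
epitope tables:

* tiling-library construction and validation against known motif anchors
  (`tileSequence()`, `validateAnchors()`; the 206-residue mature human CRP
  monomer ships as the reference antigen);
* an array-scan container on Bioconductor's `SummarizedExperiment`
  (`PeptideArrayExperiment`, `readArrayTable()`), with control-grid QC;
* the core computation: peptide positivity at a cutoff of
  `factor × background` (default 2× the median pre-serum scan) and
  reduction of overlapping positive peptides to **minimal consensus
  epitopes**, per subject, then harmonized across the cohort into a
  subject-by-epitope matrix (`callPositiveTiles()`,
  `callSubjectEpitopes()`, `harmonizeCohort()`);
* serology normalizations — arbitrary units as percent of a reference
  serum, nearest-rank percentile cutoffs, netOD flooring,
  antiphospholipid positivity (`antiCrpAU()`, `percentileCutoff()`,
  `netOD()`, `aplPositive()`);
* the nonparametric association battery (Mann-Whitney U, Spearman,
  Fisher's exact, Wilcoxon signed rank, Friedman + Dunn) with
  enumeration-verified exact small-sample behaviour
  (`buildAssociationTable()` and friends);
* neutrophil functional-assay metrics: oxidative-burst chemiluminescence
  AUC as percent of control, 3D chemotaxis track metrics (directional
  x displacement, path-based velocity), extracellular-DNA release index
  (`rosAucPercent()`, `trackMetrics()`, `netReleaseIndex()`);
* a synthetic-data module with planted ground truth, including a frozen
  fixture cohort of 42 patients and 11 healthy donors whose epitope
  marginals match the mapped cohort (`simulateCohort()`,
  `fixtureCohort()`).

The epitope rule, in brief: a peptide is positive when its serum-scan
fluorescence reaches twice the array's background level; positive peptides
overlapping by ≥ 3 residues are linked, and each linked run's epitope is
the minimal region shared by its peptides (the intersection of their
spans). The methods vignette
(`vignettes/linear-epitope-mapping.Rmd`) derives the exact segmentation
rule, its tie-breaks, and the geometric identifiability limits near the
chain termini.

## Worked example

The frozen fixture cohort carries a planted subject-by-epitope assignment;
running the full pipeline on it reproduces the cohort-level epitope table:

```r
library(epitiler)
library(SummarizedExperiment)

crp    <- loadMatureSequence("CRP")
tiling <- tileSequence(crp)
tiling
#> PeptideTiling of CRP_mature (206 aa): 206 tiles of 15 aa, 14 aa overlap, flank 'GSGSGSG'

sim   <- fixtureCohort()
calls <- callEpitopes(sim$samples)          # positivity + consensus calls
em    <- harmonizeCohort(calls, tiling, colData(sim$samples)$group)

epitopeCounts(em)[, c("label", "SLE", "HBD")]
#>                   label SLE HBD
#> 1             CLH^36-38   2   0
#> 2           EILIF^62-66   2   0
#> 3            SEIL^80-83  10   1
#> 4            SWE^99-101   7   0
#> 5       VRKSLKK^117-123   1   2
#> 6          ILGQ^134-137   8   1
#> 7  SFGGNFEGSQSL^141-152  10   1
#> 8          DIGN^155-158  12   1
#> 9           PDE^168-170  13   2
#> 10        YEVQG^192-196   5   0
#> 11     FTKPQLWP^199-206   3   0

tot <- subjectTotals(em); grp <- subjectInfo(em)$group
c(sle = sum(tot[grp == "SLE"] > 0), hbd = sum(tot[grp == "HBD"] > 0))
#> sle hbd
#>  24   4
```

Eleven cohort epitopes are recovered; five occur exclusively in patients;
the most prevalent epitope (`PDE^168-170`) is positive in 13 patients; 24
of 42 patients and 4 of 11 donors are positive for at least one epitope.
Each label is `motif^start-end` on the mature monomer. The C-terminal
epitope is reported as `FTKPQLWP^199-206`: with 7-residue flanks the last
printed tile starts at residue 199, so a C-terminal motif (here ending in
`QLWP` at residue 206) is resolvable exactly at its end but only down to
residue 199 at its start — see the vignette.

Per-subject calls carry their support:

```r
calls$SLE01[1:4]
#>   start end motif n_supporting
#> 1    36  38   CLH           13
#> 2    80  83  SEIL           12
#> ...
```

File-level orchestration (`runTile()`, `runSimulate()`, `runCall()`,
`runCohort()`, `runAssays()`) wires the same steps through tab-separated
exports with JSON run manifests.

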