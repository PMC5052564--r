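---
title: "Structure-aware glycosylation-site prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware glycosylation-site prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

N-linked glycosylation attaches a glycan to the side-chain amide of an
asparagine, canonically inside the sequon Asn-X-Ser/Thr with X any residue
except proline; O-linked glycosylation modifies serines and threonines
without a known consensus motif. In both cases the presence of the motif is
necessary at best: whether a candidate residue is actually modified depends
strongly on its three-dimensional context, above all on whether the
glycosyltransferase can reach it. `glycostruct` therefore scores candidate
sites with a classifier that combines local sequence information with
structure-derived accessibility, depth, flexibility and backbone geometry,
each averaged over a spatial neighbourhood of the site.

## Feature model

Each candidate site (Asn for the N-linked model; Ser/Thr for the O-linked
model) is encoded as a fixed-length named vector with two blocks.

**Sequence block (389 values).** A sliding window of `2N + 1 = 15` residues
is centred on the site; positions are named `P1..P15` with the site at
`P8`. The block concatenates, in fixed order:

* the PSSM log-odds column of each window position, flattened to
  `15 x 20 = 300` features `PSSM_P1 .. PSSM_P300` (the column order is the
  ASCII-PSSM order `A R N D C Q E G H I L K M F P S T W Y V`, so for
  example `PSSM_P38` is window position 2, column 18);
* four AAindex scales per window position (60 features): normalized
  average hydrophobicity (AAindex CIDH920105), average flexibility
  (BHAR880101), mean polarity (RADA880108) and beta-turn propensity
  (BEGF750103), taken from the AAindex copy shipped with bio3d;
* a conservation score per window position (15 features), defined from the
  PSSM frequency column as normalized information content
  `1 - H_i / log2(20)`, `H_i = -sum_j p_ij log2 p_ij`: 0 for a uniform
  column, 1 for a one-hot column. The underlying tool's definition of this
  score is not published in a recoverable form, so the package adopts this
  standard bounded formulation and documents it as its own choice;
* the 14 physicochemical properties of the central residue (pK1, pK2, pKR,
  pI, hydropathy, occurrence and burial percentages, volumes, accessible
  surface area, polarity measures, helix/strand preferences), transcribed
  from standard reference tables. These are encoded for the central
  residue only: per-position encoding would multiply 14 properties by 15
  positions for little evident signal, and selected-feature tables in the
  glycosylation literature only ever report central-position
  physicochemical features.

Window positions falling outside the chain are padded neutrally: zero PSSM
columns, per-scale means for AAindex, uniform (zero-conservation) columns,
and an `'X'` residue maps to per-property means.

**Structural block (14 values).** Fourteen per-residue channels are
computed and then averaged over the *structure window* of the site — all
residues with any atom strictly closer than `R = 10` angstrom to any atom
of the site (the site itself included):

1–5. absolute solvent accessibility of all atoms, total side chain, main
chain, non-polar side chain (side-chain C/S) and polar side chain
(side-chain N/O), from Shrake–Rupley sampling with probe radius 3.0
angstrom — the larger-than-water probe reflects the footprint relevant to
glycan transfer — over 960 deterministic golden-spiral points per atom and
NACCESS-style van der Waals radii (C 1.87, N 1.65, O 1.40, S 1.85;
hydrogens stripped);
6–8. `ss_acc`, `phi`, `psi`: solvent accessibility and backbone torsions.
`ss_acc` is proxied by the residue all-atom SASA; when genuine DSSP output
is supplied it overrides all three channels verbatim, which preserves
fidelity to the external tool without re-implementing its hydrogen-bond
machinery;
9. an epitope log-odds score. The package computes a documented internal
approximation — the mean of an embedded 20-value epitope propensity scale
over CA neighbours within 10 angstrom, minus 0.1 per neighbour — and any
externally computed per-residue score table can be injected verbatim
instead;
10–13. depth-index statistics: atom depth is 0 for solvent-accessible
atoms and the distance to the nearest accessible atom otherwise; the
channels are mean/SD over all atoms and over side-chain atoms;
14. the mean atomic B-factor of the residue.

Undefined torsions (termini, missing atoms) are excluded channel-wise from
the window average rather than imputed; an all-missing channel averages to
0 with a flag.

A numerical note on the SASA sampler: the test directions are oriented in
the molecule's principal-axis frame (signs fixed by coordinate skewness),
so rigid motions of the input rotate the sampling sphere with the molecule
and all structural features are rigid-motion invariant to machine
precision rather than only approximately.

## Dataset construction

Candidate sites are all Asn (N-linked) or Ser/Thr (O-linked) residues of a
chain. Experimentally annotated sites become positives; unannotated
candidates *in chains that contain at least one positive* become negatives
— chains without any annotation are left unknown, since absence of
evidence is weakest there. Negatives are under-sampled uniformly to a 1:1
ratio against positives. The benchmark/independent split (default 20%
independent) is performed at the structure level, never the site level, so
that no chain contributes to both partitions; the original procedure does
not state its granularity, and chain-level splitting is the conservative
choice against information leakage. The sequon flag is metadata, not a
filter: annotated positives that violate the sequon are kept with a
warning. Redundancy reduction against homologous chains is exposed as a
hook taking externally computed clusters.

## Two-step feature selection

1. **Linear-SVM ranking.** A soft-margin linear SVM (`C = 1`) is fitted on
   z-scored features; the weight of feature `j` is `|w_j|` with
   `w = sum_i alpha_i y_i x_i` over support vectors. Features are ranked by
   `|w_j|` (ties by column order; zero-variance features get weight 0) and
   the top 300 become the optimal feature candidates (OFCs). The z-scoring
   is needed for the weights to be comparable across scales — raw-unit
   accessibility values would otherwise dominate the PSSM integers.
2. **Incremental feature selection.** For each prefix
   `{f_1}, {f_1, f_2}, ...` of the OFC list, a random forest is evaluated
   by stratified 5-fold cross-validation; held-out scores are pooled into
   one AUC per round, and the procedure is repeated for 20 rounds with
   fresh fold assignments and forest seeds. The optimal feature set (OFS)
   is the prefix with the highest mean AUC, ties resolved to the smallest
   prefix.

The forests inside IFS are compact regression forests on the 0/1 labels:
15 trees, minimum node size 10, 0.632 subsampling without replacement,
fitted in `ranger`'s holdout mode so that held-out predictions come from
all trees without a separate prediction pass. Their predictions are used
only as ranking scores for the AUC; each prefix's value is the mean of
100 cross-validation estimates (5 folds x 20 rounds), so the per-fit
noise of small forests averages out while the full 300-prefix sweep
(30,000 forest fits) stays tractable on a single CPU. The final
classifier is a conventional 500-tree probability forest with `sqrt(p)`
features per split; scores are positive-class probabilities. Fold
assignment is always stratified by label so the AUC is defined in every
fold.

## Evaluation and screening

Six measures are reported: sensitivity, specificity, precision, accuracy,
Matthews correlation coefficient (0 when any marginal is empty) and AUC by
the Mann–Whitney rank statistic with ties averaged — the package verifies
internally that this equals trapezoidal integration of its ROC curve. The
decision rule is `score >= threshold` (closed on the positive side). For
proteome screening the threshold is calibrated on negative scores: the
smallest observed threshold whose achieved specificity reaches the target
(default 99%), so that proteome-wide calls are high-confidence by
construction.

## The synthetic data generator

Because the curated structure-mapped glycosylation data and the outputs of
the licensed external tools cannot be redistributed, the package ships a
generator that emulates every input the pipeline consumes:

* **Structures.** Idealized single chains built by sequential placement
  with standard bond geometry: helices (phi -57, psi -47), extended chains
  (phi -139, psi 135), and collapsed globules — residues packed along a
  serpentine path on a jittered cubic lattice (spacing 3.8 angstrom) with
  randomly oriented local frames, which buries a material fraction
  (>= 20% at the default size) of residues. Each non-glycine residue
  carries one CB-like pseudo-atom: enough to exercise the side-chain
  accessibility and depth channels with verifiable geometry, without
  pretending to rotamer realism. B-factors are gamma-distributed.
* **Profiles.** Dirichlet-sampled PSSM columns concentrated on the true
  residue; log-odds are `round(2 log2(p / 0.05))` clipped to [-10, 10]
  against a uniform background, which removes any hidden dependence on an
  external composition table.
* **Labels.** The planted rule is the biology in miniature: a site is
  positive when it satisfies the sequon (for N-linked) *and* its
  structure-window-averaged all-atom SASA exceeds a threshold (36
  angstrom^2 at the defaults, the median window accessibility of the
  generated candidate pool, i.e. the natural split between
  surface-adjacent and buried sites), after which labels are flipped with
  a small noise rate. With zero noise the label is an exact function of
  the generated features, so any shortfall from AUC 1 in cross-validation
  is attributable to the learner rather than to the data.

A design constraint worth making explicit: with symmetric label flips at
rate `e` on a candidate pool with clean positive prevalence `p`, the
flipped former negatives make up a fraction `e(1-p) / (e(1-p) + (1-e)p)`
of the observed positive class, and no classifier — including the Bayes
posterior itself — can exceed an AUC ceiling determined by that
contamination. At 5% noise, a prevalence near 13% caps the achievable AUC
around 0.86, which would defeat the purpose of a recovery check; the
default composition (background Asn 5%, around 2.5 planted sequons per
chain, threshold at the accessibility median) therefore targets a clean
prevalence near one third, for a ceiling around 0.94 that leaves the
learner measurable headroom.

Default study conditions are 200 proteins of 40–80 residues (generator
seed 7, noise 0.05), giving roughly 1,000 candidate sites and a balanced
set of around 790 after 1:1 under-sampling, of which 80% (structure-level
split) is used for selection and cross-validation. What passing the
planted-rule recovery shows is that the pipeline end to end — encoding,
ranking, IFS, forest — can find a sequon-plus-accessibility signal buried
in 403 features; it does not show that real glycosylation has this simple
structure, that the generator's geometry is physically realistic, or that
performance on curated structures would match.

## Numerical choices and edge cases

* Altloc resolution keeps the highest occupancy, ties to the
  lexicographically first identifier; modified residues with conventional
  parents (MSE and friends) are mapped, others skipped with a warning;
  only MODEL 1 of multi-model files is read.
* The structure-window distance test is strictly `<` so boundary cases are
  deterministic.
* PSSM frequency rows are renormalized to sum to 1; all-zero rows (which
  profile tools do emit) become uniform before the entropy.
* All randomness flows through per-call seeds derived from a master seed
  with a bounded linear-congruential mix, so every result in the package
  is reproducible from a single integer and the global RNG state of the
  session is never disturbed.
* MCC returns 0 on empty marginals; AUC raises an error on single-class
  input rather than returning a silent 0.5.

## Known limitations

* The epitope channel is an approximation unless real predictor output is
  injected; its embedded propensity scale is a package constant, not a
  fit to antibody data.
* `ss_acc` proxies the water-contact count by SASA when no DSSP file is
  given; the two are correlated but not identical.
* Sulfur is counted as non-polar in the accessibility classes; tools
  differ on this convention.
* The published total of 385 sequence features is not internally
  consistent with its stated components; this package's layout is
  300 + 60 + 15 + 14 = 389 and is documented rather than forced to match.
* Chains with unresolved residues are indexed by observed residues only;
  author numbering is preserved for reporting but never used for ordering.
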