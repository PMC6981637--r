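---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thqche)
```

`thqche` re-implements, as one tested pipeline, the analysis chain used in
studies of tetrahydroquinoline (THQ) hybrid cholinesterase inhibitors:
registry mass arithmetic, activity analytics, inhibition kinetics,
consensus binding-mode selection from ensemble docking, and geometric
interaction fingerprints. This vignette records the models behind each
stage, the parameters that matter, and the decisions taken where the
underlying methodology is conventionally left unstated.

## Mass calculus

Formulas are element-count maps over C, H, N, O, F, Cl, Br, Na, K, S,
displayed in Hill order. Two mass tables back all arithmetic: IUPAC 2021
conventional standard atomic weights for average masses and elemental
percentages, and principal-isotope exact masses (carbon fixed at exactly
12) for monoisotopic masses and ESI adduct m/z. The monoisotopic values
reproduce published high-resolution "Anal. Calcd." figures at their
4-decimal display precision. Average masses can differ from older
published values in the third decimal because the provenance of legacy
weight tables is rarely stated; the package therefore treats 0.01 g/mol as
the meaningful agreement level for average masses and makes no claim of
digit-for-digit reproduction there.

Adduct m/z neglects the electron mass (0.00055 Da, below 4-decimal display
precision): `[M+H]+` is monoisotopic(M) plus 1.00783, and the neutral-loss
ion `[M-X+H]+` subtracts a sub-formula before protonation. Registry rows
with published `[M+H]+` values are checked against this arithmetic in the
test suite; source values that are internally inconsistent (a `[2M+Na]+`
that cannot equal 2M+23, a fragment ion matching no sub-formula loss) are
recorded in a shipped known-discrepancies table rather than silently
corrected or skipped.

## Activity analytics

The selectivity index is IC50(BChE)/IC50(AChE); the direction is fixed by
the two published anchors (5.19 for the AChE-selective 5n, 0.04 for the
BChE-selective 6aa). Free energies use ΔG = RT ln IC50 with the Ki ≈ IC50
approximation and T = 298.15 K. The approximation is deliberate: the assay
conditions needed for a Cheng–Prusoff correction are not part of the data
model, and the consensus stage consumes ΔGexpt only through an ordinary
least-squares fit whose R² is invariant under monotone-affine distortions
of the scale, so only relative ordering matters. Rule-of-five flags use
strict inequalities (MW > 500, logP > 5, donors > 5, acceptors > 10);
boundary values comply. Descriptors are inputs — the package predicts
none of them.

Only the IC50 values published as numbers ship with the package (5n
against both enzymes, 6aa against BChE, galantamine against BChE, plus
6aa's AChE value back-derived from its selectivity index and flagged as
derived). Missing measurements stay missing; nothing is imputed.

## Inhibition kinetics

All mechanisms are parameterized by one nested rate law,
v = Vmax·S / (Km·(1 + I/Ki) + S·(1 + I/Ki′)), with terms dropped per
mechanism. Nesting is what makes AICc comparison meaningful: competitive
is the Ki′ → ∞ boundary of mixed, noncompetitive its Ki = Ki′ ridge.

Fitting is Levenberg–Marquardt on log-transformed parameters (enforcing
positivity) from a 3×3 multi-start grid: Km from the zero-inhibitor
Lineweaver–Burk line, Vmax from 1.2·max(v), Ki from the midpoint of the
positive inhibitor range, each perturbed by factors {0.5, 1, 2}. The best
converged start by SSR wins; the fit is deterministic for given data.
Residuals are relative, (v − v̂)/v̂, by default: absorbance-rate noise
scales with signal (the generator's multiplicative-noise model states the
same assumption), and unweighted least squares under that heteroscedastic
structure inflates the apparent gain of the extra mixed-model parameter,
distorting AICc selection. Absolute residuals remain available as an
option. AICc is n·ln(SSR/n) + 2p + 2p(p+1)/(n−p−1) with p the number of
kinetic parameters; the mechanism call takes the minimum-AICc model and
declares ambiguity below a ΔAICc of 2, the conventional evidence
threshold. Because competitive sits on the boundary of mixed, the
likelihood-ratio statistic under a competitive truth behaves like a ½·0 +
½·χ²(1) mixture, so the correct mechanism should win in roughly 93% of
2%-CV datasets — the recovery experiments observe exactly that range.

Dose-response fitting uses the four-parameter logistic in log
concentration with box constraints 0 ≤ bottom < top ≤ 100 and hill ∈
[0.05, 20]; IC50 is the inflection concentration. Fits refuse inhibition
spans under 30 percentage points (IC50 is unidentified there) and warn
when inhibition drops more than 10 points between successive
concentrations, which no plausible noise level explains.

## Consensus binding-mode selection

Poses are compared by scaffold RMSD over a user-supplied core atom map
(THQ ring, pyrrolidone, methylene bridge, isoxazole/isoxazoline core):
no superposition — poses live in one pre-aligned receptor frame, verified
by warning when receptor Cα RMSD reaches 1 Å — and no symmetry correction,
since atom names define the correspondence. This keeps an exact
direct-sum oracle available for testing.

Clustering is deterministic leader clustering within chirality partitions:
poses visited by (rescored energy ascending, ligand id, pose index), each
joining the first cluster whose leader is within the 2.0 Å threshold, else
founding one. The visit order is a property of the data, not the file, so
permuting input records cannot change the partition. Average-linkage
hierarchical clustering (cut at the same threshold) is provided as an
alternative; both must recover planted modes exactly on well-separated
ensembles. Defaults mirror ensemble-docking practice: 2.0 Å threshold,
top 5 clusters, at least 10 member poses per covered ligand, 100 poses
retained per ligand upstream.

Two readings of "at least ten poses per ligand" exist; the package
implements the per-covered-ligand minimum and exposes the weaker
total-population reading behind a flag (`per_ligand_rule = FALSE`) rather
than choosing silently. Representatives default to the lowest rescored
energy per ligand (ties to the lower pose index). The alternative
best-fit-greedy mode — swapping single representatives while R² against
ΔGexpt strictly improves — conditions pose selection on the experimental
values it is later correlated with, inflating apparent agreement; it is
an explicit opt-in and never used in the acceptance experiments. Clusters
are ranked by R² of the ΔGexpt-on-ΔGpred regression (ties: population,
then cluster id); ligands without experimental values cluster normally
but stay out of the fit, and clusters with fewer than three fittable
ligands rank last with NA fit.

## Interaction fingerprints

Ring geometry comes from the least-squares plane (SVD of centered
coordinates), with coplanarity enforced at 0.3 Å maximum out-of-plane
deviation and the normal sign canonicalized (+z, ties +x then +y).
π-stacking classes use centroid distance d, interplanar angle θ folded to
[0°, 90°], and lateral offset: sandwich (θ ≤ 30°, d ≤ 5.5 Å, offset ≤
1.5 Å), parallel-displaced (same but offset ≤ 4.0 Å), T-shaped (60° ≤ θ ≤
90°, d ≤ 6.0 Å). The offset is the mean of the displacement projections
into the two ring planes — the single-plane convention is asymmetric in
its arguments for tilted pairs, and symmetry of the parallel classes is a
property the package guarantees and tests. Hydrogen bonds use rule-based
typing (N/O with an explicit hydrogen within 1.2 Å donate, N/O accept,
aromatic C–H as weak donors): conventional bonds at donor–acceptor ≤
3.5 Å and D–H···A ≥ 120°, weak bonds at H···A ≤ 3.0 Å and ≥ 110°. Because
published tables rarely state which convention a distance uses, every
contact record carries both distances plus an explicit convention flag.
Cation–π requires centroid distance ≤ 6.0 Å and ≤ 45° between the
centroid-to-cation vector and the ring normal (either face). All cutoffs
live in one overridable config block; they follow common published
fingerprinting conventions, and reported literature distances for this
compound class (3.56, 4.10, 4.55, 4.92, 3.17, 2.68, 1.99 Å) all fall
inside the chosen windows — asserted as a sanity test. Detection criteria
themselves are not reported alongside published distance tables, so exact
reproduction of any specific study's contact table is out of scope.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, each a pure
function of (config, seed) with a ground-truth sidecar, so recovery can be
scored without re-deriving labels. The pose generator emulates the
*statistical* structure of an ensemble-docking campaign: multi-modal pose
clouds (mode templates translated 8 Å apart, isotropic 0.3 Å jitter) whose
true-mode rescoring energies follow a·ΔGexpt + b plus noise. Activity
panels use the published IC50 values where they exist and pad with
log-uniform draws from 1–100 µM, the potency range the assayed series
spans. The energy noise is split into a per-ligand component shared by a
ligand's true-mode poses and a small per-pose component (0.05 kcal/mol):
rescoring error is dominated by ligand-specific systematics, and under
lowest-energy representative selection a purely per-pose noise term would
shrink as a minimum order statistic, silently tightening the recovered
correlation past the planted one. The per-ligand sd is calibrated so the
planted population R² equals the preset's target (0.85 by default),
against the realized spread of the drawn ΔGexpt.

Pose geometry is abstract — ten named scaffold atoms, not conformers; no
force field, no receptor-dependent distortion, no docking-score physics.
Passing recovery tests therefore demonstrates that the *post-processing*
(clustering, filtering, representative selection, ranking) is correct
under its stated assumptions, not that any docking engine's output would
show the same separations or correlations. The kinetics generator mirrors
the published assay design — eight substrate levels log-spaced over
3.75×10⁻³–0.48 mM, inhibitor levels at 0/half/full probe IC50
(0/2.12/4.24 µM or 0/1.985/3.97 µM), triplicates, 2% multiplicative noise
— but real Ellman assays add systematic drifts and substrate depletion the
model omits. Scene generation places each planted contact in its own
spatial sector with distractors far outside every cutoff, so detector
agreement is exact by construction; crowded real binding sites are harder
only in volume, not in kind, which is why the detectors are additionally
checked against exhaustive pair scans on dense random scenes.

## Problem sizes and determinism

The recovery experiments use 12 ligands × 100 poses over 2 receptors and
2 binding modes (50 seeds), 8×3×3 kinetics designs (50 seeds per truth),
100 dose-response curves, and 100 random interaction scenes — sizes at
which every planted effect is identifiable with comfortable margin while
a full run stays in the tens of seconds. The planted-R² check uses the
Fisher-z 95% interval around the target R² at n = 12 ligands. All
generators save and restore the caller's RNG state; identical seeds give
byte-identical output files (the SDF header carries a config hash), and
pipeline reruns with unchanged inputs produce byte-identical reports
(timestamps go to the log stream, never into reports).

## Known limitations

Docking, MM/GBSA rescoring, protonation, and descriptor prediction are out
of scope by design; published engine scores are not reproducible here.
Atom names — which drive the cross-ligand correspondence — are not
representable in bare SDF V2000 atom blocks, so pose files carry them in
an `atom_names` data field; SDF from other tools needs that field added.
Scaffold RMSD without symmetry correction is the standard choice for named
ensembles but will overstate distances if atom naming is inconsistent
across ligands. The kinetics module fits initial-rate data only: no
progress curves, substrate inhibition, or tight-binding corrections.
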