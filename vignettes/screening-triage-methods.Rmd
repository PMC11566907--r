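---
title: "Methods: synthetic screen triage from raw plates to ranked scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic screen triage from raw plates to ranked scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screentriage)
```

`screentriage` implements the computational side of a prospective
hit-identification campaign against a kinase target (the design mirrors an
IRAK1 TR-FRET binding screen): plate-level quality control and
normalization of a 46,743-compound single-point screen, threshold hit
calling, structural clustering and diversified selection of hits,
dose-response triage, and the evaluation of virtual-screening rankings by
hit and scaffold discovery rates. Every stage runs on data from the
package's own synthetic generator, so the full pipeline is reproducible
and testable offline. This vignette records the models, the parameter
choices that matter, and the design decisions taken where the underlying
methods are conventionally under-specified.

## The synthetic screen

`sim_config()` fixes the study conditions. The defaults describe one
fixed campaign and are not intended to be tuned per analysis:

* **Library**: 46,743 unique structures drawn without replacement from a
  combinatorial grid of 14 kinase-inhibitor-like chemotype cores
  (benzamides, quinazolin-4-amines, diarylureas, aminopyrimidines, ...)
  with two substitution slots over a shared substituent set. Templates,
  not random graphs, because Tanimoto similarity and maximum common
  substructure on random graphs are degenerate: with templates, compounds
  sharing a core are genuinely similar and their MCS is a chemically
  meaningful scaffold. Substituents carry a known number of undefined
  stereocenters (0-3 each, so 0-6 per compound), which drives the
  stereoisomer-enumeration policy downstream.
* **Plates**: 16 x 24 wells; columns 1-2 hold the 32 negative (DMSO, no
  inhibition) controls, columns 23-24 the 32 positive (staurosporine,
  full inhibition) controls, samples sit in columns 3-22 (320 per plate,
  147 plates). Which control pair sits on which side is a package
  convention; the assay design only fixes the column blocks.
* **Signal**: raw ratio-channel fluorescence
  `neg_mu + (pos_mu - neg_mu) * inhibition/100 + N(0, well_sigma)` with
  `neg_mu = 10000`, `pos_mu = 2000` arbitrary units -- signal *decreases*
  with inhibition, as in a kinase-tracer displacement readout. The noise
  SD 400 a.u. is a choice the assay description does not pin down; it
  yields Z' around 0.70, a comfortably passing plate quality typical of a
  production-grade automated screen (the acceptance bound being 0.5).
* **Actives**: each compound is a true active with probability 0.0076
  (the realized ~0.7% hit rate of the emulated campaign); actives draw a
  true inhibition from N(85, 15) truncated to [0, 120]. The upper tail
  beyond 100% mirrors the over-inhibition tail real normalized data
  shows, and lets threshold sweeps above 100% behave gracefully.
  Inactives have true inhibition 0, so their normalized values are pure
  well noise.
* **Dose-response**: the 8-point ~4-fold dilution series
  30, 7.5, 1.875, 0.469, 0.117, 0.029, 0.007, 0.002 uM in triplicate,
  with Gaussian response noise of 2% -- the level at which the parameter
  recovery experiments below are run. True potencies for assayed hits are
  drawn from a micromolar / high-nanomolar / nanomolar mixture
  (0.894 / 0.088 / 0.018) with log-uniform inflection within each class's
  concentration band.
* **Method scores**: a virtual-screening method with enrichment `e`
  scores compound `i` as `e * a_i + (1 - e) * U(0,1)`, `a_i` the true
  inhibition rescaled to [0, 1]. Under this model the expected top-1%
  hit discovery is approximately `0.01 + e * a / (1 - e)`, which is how
  the default strengths (deeplearn 0.30, docking 0.10, qsar 0.12,
  pharmacophore 0.01) were chosen: a strong structure-based deep-learning
  method finding roughly a third of all hits in its top 1%, docking and
  QSAR a few-fold weaker, a bare pharmacophore match barely above random.
  `e = 0` is exactly an exchangeable random ranking and `e = 1` sorts by
  true activity; both limits are exercised in the tests.

One master seed drives independent per-stage substreams (library, screen,
dose-response, scores), so any stage can be regenerated bitwise
identically without replaying the others. `rescreen()` redraws only the
measurement noise around the same ground truth -- that is what a replicate
confirmation experiment measures.

### What the generator does not emulate

Spatial plate artifacts (edge effects, dispense gradients), compound
interference (autofluorescence, aggregation), plate-to-plate drift, and --
importantly -- the scaffold diversity of a real diversity library: 14
cores yield ~40 Louvain communities from ~320 hits, where the emulated
campaign found 200 clusters (160 singletons) among 353 hits. Passing
tests therefore demonstrate the correctness of the computations, not that
real screens are this clean; cluster *counts* in particular scale with
the generator's template diversity and are treated as a calibration
experiment (below), never as a validated quantity.

## Plate processing

Per plate, control means and sample SDs (n-1 denominator; the estimator
choice matters little at n = 32 but is stated for reproducibility) give

$$Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|},$$

with plates accepted at $Z' \ge 0.5$. Z' is affine-invariant in the raw
signal and equals 1 exactly when both control SDs vanish; both properties
are tested. Normalization maps each well to relative inhibition in
percent,

$$k_{norm} = 100\cdot\frac{k_{raw} - \mu_{neg}}{\mu_{pos} - \mu_{neg}},$$

so 0% is the DMSO level and 100% the staurosporine level. Values outside
[0, 100] are preserved -- clipping would bias threshold sweeps and hide
over-inhibition. Hit confirmation uses set-based definitions: confirmed =
primary hits present in every replicate; precision = confirmed / primary;
recall = confirmed / (confirmed + consensus hits new in replicates). The
denominators are stated explicitly because replicate-counting conventions
differ between labs and are rarely reported precisely enough to
reproduce.

## Hit triage

Hits are `k_norm >= threshold` (boundary inclusive; 50% default, chosen
in the emulated campaign to size the secondary assay). Fingerprints are
hashed Morgan-style circular substructures, radius 2 over 2048 bits --
the ECFP4-equivalent setting -- computed over the package's own molecular
graphs. The similarity graph connects pairs with Tanimoto similarity at
or above the edge threshold, weighted by similarity, and is clustered
with seeded Louvain modularity maximization (igraph); isolated vertices
are singletons.

The edge threshold is the one genuinely open parameter: the emulated
campaign does not report it. The default 0.4 matches the lowest cut of
the novelty analysis and common practice. `analysis/03_hit_triage.R`
runs the calibration sweep; on the synthetic screen, thresholds
0.3/0.4/0.5/0.6 give 11/39/159/274 clusters -- the counts are strongly
threshold- and library-dependent, which is exactly why cluster counts are
excluded from validation.

Each cluster's scaffold is the maximum common substructure of its
members, computed by branch-and-bound search over atom correspondences
(element + aromaticity + bond-type matched, connected), folded pairwise
across members; a wall-clock budget bounds each pairwise search with the
best-so-far returned, and scaffolds below 3 heavy atoms are reported
empty. Singletons use the compound's Bemis-Murcko-style framework (rings
plus linkers). Diversified selection takes the top
`min(5, cluster size)` members per cluster by the ligand-efficiency
proxy `k_norm / MW` (percent-mol/g), ties broken by compound id so the
selection is deterministic. Novelty against a reference set counts hits
whose nearest reference neighbor exceeds each Tanimoto threshold
(strictly), plus the distinct clusters containing such hits.

## Dose-response

The four-parameter logistic

$$f(x) = A + \frac{D - A}{1 + (x/C)^B}$$

($D$ the response as $x \to 0$, $A$ as $x \to \infty$, $B$ the Hill
slope, $C$ the inflection) is fitted by Levenberg-Marquardt least squares
over all replicate points jointly. Initialization is analytic (asymptotes
from the extreme-dose means, $C$ at the half-range crossing, $B = 1$)
with two perturbed restarts, keeping the best residual. A fit with
negative $B$ is re-expressed by swapping $A$ and $D$, which leaves the
curve unchanged. Iteration-capped terminations keep their best-found
parameters: Levenberg-Marquardt decreases the residual monotonically, so
the last iterate is the best available; "erroneous" is reserved for fits
that produce nothing, for inflections above the top tested dose, and for
near-flat fitted curves (dynamic range below 10% of the observed response
spread), all of which report the top concentration, 30 uM. IC50 is capped
into the measured range on both sides -- reporting potency beyond the
tested concentrations would attribute resolution the assay does not have
-- giving the characteristic pIC50 floor at $-\log_{10}(30\,\mu M) =
4.523$. Potency classes: micromolar pIC50 < 6, high nanomolar
[6, 7), nanomolar >= 7; scaffolds inherit the class of their most active
assayed member.

Parameter recovery at the study's assay design (8-point series,
triplicates, 2% noise, 500 compounds with log-uniform potency across the
measurable range) shows log10-IC50 bias below 0.01 and median absolute
error near 0.02 log units; the tests assert the looser bounds +/-0.05 and
0.15 so they are robust to seed choice.

## Ranking evaluation

A ranking orders compounds by descending score with ties broken by
compound id (the tie rule is recorded because it makes every curve
deterministic). At library fraction `f`, the top `ceiling(f * N)`
compounds are taken -- ceiling chosen so that "top 1%" of 46,743 means
468 compounds, matching the convention of rounding the selection up; a
fixed integer cutoff is available via the fraction grid. The hit
discovery curve reports the fraction of all hits in that prefix; the
scaffold discovery curve counts clusters with at least one member in the
prefix, optionally restricted to potency labels. Both are monotone and
reach their totals at `f = 1` by construction, and are verified against a
direct prefix-enumeration oracle for small N. Method comparison adds a
random-screening baseline (value = fraction screened -- the expected
curve of an unordered HTS) and pairwise fold-ratios per fraction.

## Score aggregation

Stereoisomer policy: compounds with up to 4 undefined stereocenters
enumerate all $2^n$ stereoisomers (at most 16); beyond 4, exactly 16 are
sampled without replacement from a per-compound substream, so the subset
is reproducible and independent of processing order. Since the assay
measures racemic material, per-isomer scores collapse by the arithmetic
mean.

Pose ensembles collapse by a Boltzmann-like average: a softmax-weighted
mean with weights $\propto \exp(s_i/\tau)$, default $\tau = 1$ on the
score scale. The functional form is this package's definition -- the
referenced scoring approach names such an average without defining it --
so only its boundary properties are treated as normative: bounded by the
min and max pose score, arithmetic mean as $\tau \to \infty$, maximum as
$\tau \to 0^+$, shift-invariant (implemented with max-subtraction so
large scores cannot overflow), and monotone in every input. The docking
baseline takes the most favorable (most negative) free energy over the
ensemble, sign-flipped so that every method ranks higher-is-better; the
alternative literal reading ("largest" = least negative) would rank
actives last and contradicts how docking baselines behave.

## Pharmacophore subset scoring

A hypothesis is a set of typed feature points (donor/acceptor/aromatic/
hydrophobic/positive/negative) with per-point tolerance radii (default
1.0 A). A conformer matches a sub-hypothesis when an injective,
type-compatible assignment of points to conformer features admits one
rigid superposition (Kabsch) placing every feature within its point's
radius; the search prunes assignments by pairwise-distance compatibility
and is verified against an exhaustive-assignment oracle. Reflections are
correctly rejected: the rotation determinant is constrained to +1.

The continuous score combines subset matches: with `K` the largest
matched subset size and `m_K` the number of matched size-`K` subsets,

$$\text{score} = \frac{K + m_K/\binom{n}{K} - 1}{n}$$

for `K >= min_size` (default 3), else 0. The combiner is this package's
definition; the property it encodes -- rank by deepest partial match,
refined by breadth at that depth, with 1 attained only on a full match --
is the normative intent, and monotonicity (a new matched subset never
lowers the score) is tested. Conformer generation is out of scope;
synthetic ensembles are perturbed rigid copies of the hypothesis with
feature drops and decoys.

## Problem sizes and reproducibility

The analysis scripts run the full 46,743-compound campaign (seconds per
stage); unit tests use 320-2,000-compound screens, 60-500-compound
fitting cohorts, 300-1,000 permutation/oracle replicates -- sizes chosen
so the whole suite completes in well under a minute while keeping
Monte-Carlo bands tight. All randomness flows from explicit seeds;
`scripts/acceptance.R --seed N --out f.json` recomputes every headline
quantity from scratch under seed `N`.

## Known limitations

* The SMILES dialect covers the generator's output (organic subset,
  aromatic rings, branches, ring closures; no charges, isotopes or
  stereo-annotated atoms); arbitrary external SMILES may be rejected.
* MCS is exact only within its time budget; on large dissimilar pairs the
  best-so-far common substructure is returned and flagged.
* Louvain determinism is per seed and igraph version; modularity ties can
  resolve differently across igraph releases.
* Scaffold SMILES of partial-ring common substructures are fragment
  strings (aromatic atoms without closed rings) rather than valid
  standalone molecules; they identify the scaffold but are not meant for
  re-parsing into a compound.
* The confirmation experiment's precision is near 100% on synthetic data
  because noise is symmetric and plate-independent; real screens show
  systematic replicate disagreement the generator does not model.
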