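---
title: "Methods: signature-based substrate specificity prediction for NRPS adenylation domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based substrate specificity prediction for NRPS adenylation domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Nonribosomal peptide synthetases (NRPSs) are modular enzymes whose
adenylation (A) domains each select and activate one amino-acid (or
related) substrate. Substrate choice is concentrated in the residues
lining the binding pocket: the classical 10-residue Stachelhaus code and
its 34-residue extension (all residues within 8 Å of the phenylalanine
substrate in the reference crystal structure of a Phe-activating A
domain). `adomain` predicts the substrate of an A domain from those
signature residues, optionally augmented by structural pocket features,
and attributes predictions back to individual residues.

Two complementary models are provided. The *substrate classifier* is a
single-label random forest over the signature features: one prediction
per domain, with a confidence equal to the fraction of trees voting for
the winning substrate, and no abstention. The *interaction model* is a
binary random forest over concatenated (domain, substrate) features that
scores any domain–substrate pair; ranking a substrate library (or novel
SMILES) by interaction probability handles promiscuous domains and
substrates absent from training, which a closed-class classifier cannot.

## Signature extraction

Detection uses profile HMMs through HMMER3: an ordered list of
N-subdomain profiles (an NRPS-specific profile first, general AMP-binding
family profiles as fallback — some divergent, e.g. fungal, domains only
match the general profiles) plus an optional C-subdomain profile. Split
envelope hits within `merge_gap` (default 100 residues, small relative to
the ~500-residue spacing of tandem A domains) are merged; each N match is
paired with its nearest unclaimed downstream C match. The minimum
per-domain bit score defaults to 25; a curated gathering threshold should
be used where a profile provides one.

Position mapping aligns the query and the reference scaffold to the same
profile (`phmm` mode) or to a profile built from a user-supplied guide
alignment (`guided` mode, for externally computed structure-guided
alignments; the package never computes structural alignments). Every
scaffold position then maps to exactly one query position or to gap, and
the 34- and 10-residue signatures are read off. Ambiguous residues
(X/B/Z/U) are kept verbatim in signature strings but featurise as gaps.

The scaffold itself — reference sequence, the 34 extended positions, the
10 Stachelhaus positions — is configuration data, serialisable as TSV. In
the default configuration the first nine Stachelhaus positions are a
subset of the 34 and the tenth is the conserved terminal lysine, which
lies beyond the N-terminal subdomain and is therefore allowed to break
position monotonicity as the final element only. Coordinates are 1-based
and inclusive throughout, the R/Bioconductor convention.

## Featurisation

Each of the 34 signature residues is encoded by 15 physicochemical
properties covering hydrophobicity, size, electronic state,
hydrogen-bond donors, polarity, helix/sheet/turn propensity and
isoelectric point, concatenated residue-major into a 510-vector. Every
property column is min–max normalised so its minimum is exactly 0 and
maximum exactly 1 over the 20 canonical amino acids; gaps map to the
all-zero vector, which keeps unaligned positions neutral. Three of the
fifteen hydrophobicity slots have no publicly resolvable source scale,
so they ship as documented stand-ins (Kyte–Doolittle, Hopp–Woods,
Eisenberg); the whole table is replaceable via `property_table()` and a
replacement changes nothing about the pipeline contract.

Substrates are 1024-bit ECFP-4 fingerprints computed with RDKit from
SMILES; because the fingerprint is derived from the parsed molecular
graph, any SMILES spelling of the same molecule yields identical bits —
which is what makes querying novel substrates sound.

Structural featurisation counts atoms of superposed models in a cubic
voxel grid (default 16 Å edge, 20 voxels per axis, i.e. 0.8 Å voxels)
centred on the pocket, with 7 channels: aromatic ring carbons of
Phe/Tyr/Trp/His; all other carbons as hydrophobic; carboxylate and
terminal oxygens as charged, others noncharged; Lys/Arg side-chain
nitrogens as charged, others noncharged; sulphur. Hydrogens, metals and
phosphorus are unclassified and dropped, so total counts equal the number
of classified in-grid atoms. Voxel intervals are half-open `[lo, hi)`,
making boundary assignment deterministic. Raw counts (not binarised) go
into one PCA per substrate category plus one over all data; each
projection keeps the number of components at the knee of its explained-
variance scree curve, located as the point of maximum distance to the
first–last chord (the kneedle construction); a projection always keeps at
least one component, and groups with fewer than two members are skipped
with a warning.

## Training

The classifier trains on one row per domain labelled with its
first-listed substrate — by curation convention the predominant one —
after dropping substrates with fewer than `inclusion_cutoff` occurrences
(default 10; a cutoff of 1 is the "all substrates" mode). Class imbalance
is handled at the bootstrap: the default draws observations with
inverse-class-frequency sampling weights, and a balanced per-class
bootstrap (`balance = "bootstrap"`) is the stronger alternative when
imbalance is extreme. Forests are 1000 trees (ranger defaults otherwise),
single-threaded and seeded: seeds are mandatory arguments and are
recorded in the model, and two runs with the same seed are bit-identical.
Vote ties break alphabetically by substrate name and are flagged.

The interaction model trains on pairs: positives are every (domain,
listed substrate) pair; negatives are (domain, other library substrate)
pairs, randomly under-sampled to exactly the positive count — realistic
substrate libraries make the raw ratio roughly 1:30, and the exact 1:1
after undersampling is asserted, not assumed. Sampling is global across
domains by default (`scope = "per_domain"` balances within each domain);
an exclusion list keeps curated minor substrates out of the negative
pool when desired. An advisory probability cutoff (midpoint of the median
in-sample interaction probabilities of true positives and of false
positives) is stored and reported with rankings, never enforced.

## Splitting and evaluation

The taxonomy split assigns whole taxonomic families to one side, probing
generalisation to phylogenetically distant sequences. The assignment is
greedy: first coverage (≥ 1 example of every in-scope substrate on each
side, built from the rarest substrate up using the smallest holding
families), then remaining families largest-first, each placed to minimise
the summed absolute deviation of per-substrate train fractions from the
3:1 target, ties to train. Absolute (not squared) deviation is used; on
fixtures constructed to admit an exact 3:1 the greedy procedure attains
it. A substrate whose examples all sit in one family triggers a warning
and a relaxed constraint. Domains of unknown origin form the
pseudo-family "None".

The substrate split stratifies on the first label (single-label mode) or
runs iterative multilabel stratification: examples of the currently
rarest remaining label are placed where that label's remaining desired
count is largest, ties by overall remaining capacity, then seeded
randomness. Labels with one example go to train with a warning.

Scoring treats a prediction as correct if it appears anywhere in the
domain's substrate list (`any_match`, the convention for single-label
evaluation of multi-substrate domains) or only if it equals the
predominant substrate (`top1`). Promiscuity is scored by exact top-x set
matching with x the number of annotated substrates; partial credit
requires at least one shared substrate. Benchmark verdicts follow the
four-way scheme — correct, incorrect, no call (tool returned nothing),
not in model (no true substrate among the tool's classes) — and folded
accuracy counts the last two as incorrect. Tool comparison bootstraps
accuracy (1000 iterations), tests the omnibus with Kruskal–Wallis, and
only then runs pairwise Mann–Whitney tests, Bonferroni-corrected over
the number of comparisons actually performed (reported in the output).
Bootstrap resampling is independent per tool.

## Feature inference

Overall importance reuses the forest's impurity-based feature
importances, summed over the 15 features of each residue; the 34 values
partition the total importance mass exactly.

Substrate-specific importance replays each tree's in-bag training sample
(with bootstrap multiplicities) through its splits and evaluates, at
every internal node that saw at least one domain of substrate S, the
binary entropy gain for S-vs-rest. Gains are averaged at node level
(not per tree) over all qualifying nodes splitting on a feature; the
aggregation level is recorded in the CLI output. Feature usage is
counted as the number of qualifying nodes splitting on the feature, and
features below `min_usage` are zeroed — rarely used features that happen
to resolve a leaf otherwise carry inflated gains; raising the threshold
can only shrink profiles, a monotonicity the tests assert. Per-residue
values are the mean of each residue's 15 feature gains, and
cross-substrate comparison max-normalises the residue×substrate matrix
so its largest cell is 1. The entropy convention `0·log2 0 = 0` makes
pure nodes zero-entropy; gains are non-negative up to rounding.

## The synthetic generator

`make_scaffold()` + `make_dataset()` emulate the *shape* of real inputs:
a ~450-residue A-domain-like scaffold with designated signature
positions and profile HMMs built from its mutant family; domains whose
two determinant signature residues (positions 7 and 17 of the extended
signature by default) deterministically encode the substrate class, with
a configurable noise rate that scrambles determinants without touching
labels (noise 1.0 severs the link completely, giving the 1/k null);
family-level taxonomy; genuine proteinogenic amino-acid SMILES so
fingerprints are chemically meaningful; and flanking sequence with
recorded true coordinates. Defaults are 200 domains, 4 classes, noise 0,
promiscuity 0, 8 families — small enough to run everywhere, large enough
that forests and splits behave non-trivially.

What the generator does *not* emulate: real signature–substrate maps are
not two-residue codes; real families are phylogenetically correlated
with specificity rather than independent; real data contain annotation
errors, truncations and class imbalance far beyond the fixture's. A
passing fixture suite therefore demonstrates that the machinery is
correct (extraction recovers planted residues, models learn a learnable
rule, attribution finds the true determinants, splits meet their
contracts), not that any particular accuracy will transfer to real
A domains.

## Problem sizes and runtime choices

Tests and the acceptance script use 120–200 domains, 4 substrate
classes, 1000-tree forests for study-condition checks and 200–300 trees
for auxiliary ones, and a 3-tree forest for exhaustive node-level oracle
comparison. These sizes make the full suite run in well under a minute
on one CPU while keeping vote fractions at 1000-tree resolution where
confidences are asserted.

## Known limitations

* Real reference data (the GrsA scaffold sequence, its 34 crystallographic
  positions, curated training tables) are not bundled; the scaffold is
  configuration the user supplies, and the shipped default is synthetic.
* Structure features consume superposed models; superposition itself,
  structure prediction and structural guide alignments are out of scope.
* Fingerprinting shells out to Python/RDKit; without it, sequence-only
  workflows still run but substrate featurisation errors out.
* The interaction model's probabilities are tree-vote fractions, not
  calibrated probabilities; the advisory cutoff is descriptive.
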