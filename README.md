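# adomain

Substrate specificity prediction for nonribosomal peptide synthetase (NRPS)
adenylation (A) domains, in R.

NRPSs are modular assembly lines that build peptide natural products —
antibiotics, siderophores, immunosuppressants — outside the ribosome. In
each module, the adenylation domain selects one amino (or aryl) acid and
activates it as an aminoacyl adenylate, so the substrate preference of the
A domains determines the product. Predicting that preference from sequence
is a central step in genome mining of biosynthetic gene clusters. This
package is for computational natural-product researchers who want a
transparent, scriptable pipeline from protein sequence to ranked substrate
predictions, and down to the active-site residues driving them.

## What it does

* **Detection and signature extraction.** A domains are located with
  profile HMMs (HMMER3) for the N- and C-terminal A subdomains. For each
  domain, the 34-residue *extended signature* (the residues lining the
  substrate pocket — within 8 Å of the bound phenylalanine in the
  reference crystal structure of the GrsA Phe-activating domain) and the
  classical 10-residue *Stachelhaus code* are read off through a profile
  alignment onto a reference scaffold. The scaffold (reference sequence +
  position lists) is explicit configuration, so the footprint is
  swappable and fully testable.
* **Featurisation.** Each signature residue is encoded by 15 min–max
  normalised physicochemical properties (hydrophobicity, size, electronic
  state, H-bond donors, polarity, secondary-structure propensity,
  isoelectric point), giving vectors of length 510 = 34 × 15. Substrates
  are encoded as 1024-bit ECFP-4 (Morgan, radius 2) fingerprints from
  SMILES. Superposed structures can additionally be voxelised on a
  20×20×20 pocket-centred grid with 7 atom-type channels (56,000 counts),
  compressed by per-substrate-category PCA truncated at the scree knee.
* **Two random-forest predictors** (1000 trees, seeded, balanced
  sampling):
  * a **single-label substrate classifier** — domain features → one
    substrate, with a confidence equal to the fraction of trees voting for
    it (it never abstains);
  * a **domain×substrate interaction model** — (domain features ∥
    substrate fingerprint) → interaction probability, trained on pairs
    under-sampled to exactly 1:1 positives:negatives, and queryable with
    *any* substrate, including ones never seen in training.
* **Stratified evaluation.** Taxonomy-atomic train/test splits (whole
  families on one side, per-substrate ratios pushed to 3:1), single-label
  and iterative multilabel substrate stratification, any-match/top-1
  scoring, top-k accuracy, promiscuity scoring by exact top-x set
  matching, benchmark verdicts (correct / incorrect / no call / not in
  model) and bootstrap tool comparison (Kruskal–Wallis, then pairwise
  Mann–Whitney with Bonferroni).
* **Feature inference.** Per-substrate attribution by per-node
  information gain: for substrate S at tree node t,
  `gain = H(t) − [n_L/n_t · H(t_L) + n_R/n_t · H(t_R)]` with
  `H(t) = −[p_S log2 p_S + p_NS log2 p_NS]`, averaged over all nodes
  splitting on a feature, thresholded by feature usage, and aggregated
  from 510 features to 34 residues.
* **Synthetic fixtures.** A generator that plants a known
  signature→substrate rule (two determinant residues), taxonomy, noise and
  promiscuity into scaffold proteins, with all ground truth recorded — so
  the whole pipeline is testable end to end without external data.

## Worked example

```r
library(adomain)

scaffold_fx <- make_scaffold(seed = 42)            # synthetic reference + profiles
fx <- make_dataset(fixture_spec(n_domains = 120, n_substrate_classes = 4,
                                seed = 7), scaffold_fx)
plan  <- substrate_split(fx$dataset, 0.25, multilabel = FALSE, seed = 3)
train <- dataset_subset(fx$dataset, plan$train_ids)
test  <- dataset_subset(fx$dataset, plan$test_ids)

trn   <- build_classifier_training(train, inclusion_cutoff = 1)
model <- train_substrate_classifier(trn$X, trn$y, n_trees = 1000, seed = 11)
head(predict_substrate(model, test$features), 3)
#>    domain_id         label confidence   tie
#> 1 SYN0004.A1        serine      0.905 FALSE
#> 2 SYN0011.A1 phenylalanine      0.922 FALSE
#> 3 SYN0012.A1        serine      0.932 FALSE
```

The label is the plurality vote of the 1000 trees; the confidence is the
vote fraction (0.905 = 905 trees). On this noise-free fixture the held-out
any-match accuracy is 1.0. The interaction model ranks every substrate in
a library (or any novel SMILES) for one domain:

```r
lib    <- substrate_library(fx$substrates$name, fx$substrates$smiles)
pairs  <- build_interaction_pairs(train, lib, seed = 5)
imodel <- train_interaction_model(pairs$X, pairs$y, library = lib,
                                  n_trees = 1000, seed = 13)
predict_interactions(imodel, test$features[1, ], lib)
#> <interaction_ranking: 4 substrates, advisory cutoff 0.35>
#>       substrate probability
#> 1        serine       0.646
#> 2 phenylalanine       0.575
#> 3    tryptophan       0.547
#> 4        valine       0.466
```

Serine tops the ranking, agreeing with the classifier; the advisory
cutoff (estimated from the training true/false-positive probability
distributions) is reported, never enforced. Finally, attribution
recovers the residues that encode specificity — here the fixture's two
planted determinants, extended-signature residues 7 and 17:

```r
st <- forest_node_stats(model)
pr <- per_residue_importance(substrate_importance(st, "tryptophan"))
round(sort(pr, decreasing = TRUE)[1:4], 3)
#> res07 res17 res02 res34
#> 0.573 0.455 0.425 0.420
```

A thin command-line interface wraps the same functions
(`inst/scripts/adomain.R`: `fixtures`, `detect`, `featurise`,
`fingerprint`, `split`, `train`, `predict`, `infer`); every subcommand
writes a run manifest next to its output.

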