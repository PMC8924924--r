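# poserank

Reranking docked protein–ligand poses with a directional message-passing
graph network.

## Why

Docking engines sample binding poses well but rank them poorly: the pose
closest to the native binding mode is frequently buried below decoys, which
caps the hit rate of structure-based virtual screens. `poserank` trains a
learned rescorer that takes a receptor conformation plus one docked ligand
pose and emits a ranking logit, so the near-native pose ("hit",
symmetry-corrected RMSD ≤ 2.5 Å to the native pose) rises above wrong
placements ("miss", RMSD > 4 Å). It is aimed at computational chemists who
already have docked pose sets and want a better intra-target ranking, and
at method developers who want a self-contained, fully testable
implementation of this model class.

## What is inside

* **The network.** Atoms are nodes typed by one-hot SYBYL atom types
  (ligand and receptor blocks disjoint, all metals collapsed to one type);
  no covalent edges. A routing string like `l->l->r->l->r->l` configures
  which atom set sends and which receives messages at each layer; edges
  connect pairs with d < R_c (4 Å intra-entity, 5 Å cross-entity by
  default). Each block is a continuous-filter convolution
  f_i ← MLP(Σ_j W(d_ij) ⊙ h_j + skip_i) whose filters are learned
  combinations of spherical Bessel functions
  b_n(d) = √(2/R_c)·sin(nπd/R_c)/(nπd/R_c), which vanish exactly at the
  cutoff. Bottleneck projections of concatenated earlier layers serve as
  source features and skip connections; per-layer ligand/receptor sum
  pooling plus a small MLP yields the logit. Forward *and* analytic
  backward passes are implemented in base R and verified against finite
  differences.
* **Labels.** `symmetry_rmsd()` minimises RMSD over all element- and
  bond-preserving ligand automorphisms (no re-superposition);
  `label_pose()` applies the hit ≤ 2.5 Å < gap ≤ 4 Å < miss rule. Gap
  poses are dropped from training, kept in test sets.
* **Cross-docking curation.** Kabsch superposition of same-target
  receptors (5 Å exclusion), binding-site clustering of ligand centers of
  mass (DBSCAN, eps = 5 Å, min_samples = 1), capping at five
  representatives per site, and the positive-pose filter.
* **Splits.** `uniprot`, `seqsim70` and `seqsim50` train/test splits with
  an exhaustively checkable boundary-identity guarantee.
* **Metrics.** Exact Mann–Whitney ROC AUC, average-precision PR AUC,
  top-n pose enrichment curves, compound enrichment factors
  ef(ν) = (ap)⁻¹·a(ν)/n(ν).
* **Synthetic studies.** A generator that plants a known interfacial
  signal (type-complementary contacts within the cross-entity cutoff) in
  pocket-shaped pseudo-receptors, with the 5.0/15.5/79.5 % hit/gap/miss
  pose mixture, ≥ 1 Å pose separation, and ~1.6 Å receptor ensembles —
  so the whole pipeline trains and evaluates in minutes with no
  downloads.

I/O: receptors as PDB (via bio3d), ligands/poses as SYBYL Mol2 and SDF,
studies as JSON-lines manifests; model checkpoints round-trip bit-exactly.

## Worked example

```r
library(poserank)

spec  <- synthetic_spec(seed = 1)            # 20 targets x 4 x 64 poses
study <- gen_study(spec)
cd    <- crossdock_build(study)              # superpose, cluster, filter
split <- study_split(study, kind = "uniprot", train_fraction = 0.75,
                     seed = 2)
se    <- study_examples(study, split, attempts = cd$attempts)

cfg <- parse_layer_config("l->l->r->l->r->l")
fit <- train_graphite(se$train, cfg,
                      train_cfg = training_config(epochs = 30, seed = 3))

y <- vapply(se$test, function(e) e$label, "") == "hit"
roc_auc(score_examples(se$test, fit), y)
rep <- evaluate_model(se$test, fit)
rep$topn_model$fraction[1]      # top-1 pose enrichment, reranked
rep$topn_docking$fraction[1]    # top-1 pose enrichment, docking order
```

On this synthetic study (seed 1 throughout, ~5 minutes on one core) the
run prints a held-out hit-vs-rest ROC AUC of **0.977**, and the reranker
lifts the fraction of held-out attempts whose top-1 pose is a hit from
**0.61** (docking order) to **0.83**. Swapping the routing string for the
ligand-only `l->l->l->l->l->l` collapses the test AUC to chance
(**0.455**): by construction every decoy is a rigid motion of the same
conformer, so only layers that cross the interface can rank poses. That
contrast — interface ≥ 0.9, ligand-only ≈ 0.5 — is the desk-scale analog
of the layer-configuration ablation observed on real docking data.

A thin CLI wraps the same functions
(`inst/cli/poserank synth|train|rescore|eval`).

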