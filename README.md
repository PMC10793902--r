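# lgn: ligand-aware graph network scoring of protein-ligand binding affinity

Structure-based scoring functions estimate how strongly a small molecule
binds a protein from the 3D structure of their complex — the quantity that
ranks candidate compounds in virtual screening. `lgn` implements a fusion
graph-network scoring function for people who want a transparent, fully
reproducible R implementation of this model family: computational chemists
studying what such models actually learn, and method developers who need a
reference pipeline with every component testable offline.

## The model

A complex with pocket atoms and ligand atoms is encoded twice:

- **Complex graph** `G_c`: all heavy atoms; nodes carry 41 features
  (element, degree, formal charge, chirality, implicit H, hybridization,
  aromatic/ring flags, protein-vs-ligand source), edges carry 21 features
  (covalent flags plus a 14-center Gaussian radial basis of distance).
  Covalent bonds and all protein–ligand atom pairs within 5 Å are edges.
  Encoder: 4 rounds of attention-weighted message passing with GRU state
  updates, attention-pooled to an embedding `h_c = GNN(G_c)`.
- **Ligand graph** `G_l`: ligand atoms only (27 node features, no edge
  features), encoded by a 3-layer graph isomorphism network with sum
  pooling: `h_l = GIN(G_l)`.
- **Interaction fingerprints** (optional): SIFP (168 counts: 21 residue
  entries × 8 interaction types), ECIF (1746 typed atom-pair counts), CFP
  (2048-bit circular ligand fingerprint), passed through one linear layer.

The prediction is a single linear map of the concatenation,

    pK = w' [h_c ; h_l ; h_fp] + b,

trained with Adam (lr 1e-4, weight decay 1e-6, batches of 128, ≤ 200
epochs, dropout 0.1) under MSE, smooth-L1 or a correlation/RMSE compromise
loss, and evaluated by Pearson correlation (Rp), RMSE and MAE. A bagging
ensemble (members trained on random 80% subsets, predictions averaged)
and a similarity-controlled data-splitting protocol (protein sequence
identity > 0.9, ligand Tanimoto > 0.4, interaction-fingerprint Tanimoto
> 0.65; fixed-size 3000-sample mixtures) complete the toolkit.

Because real affinity corpora (PDBbind) are licensed, the package ships a
synthetic-complex generator that plants a learnable structural affinity
signal (contact counts + H-bond donors + noise), so every module runs and
is tested fully offline.

## Worked example

```r
library(lgn)

ds  <- gen_dataset(synthetic_spec(n_complexes = 150, seed = 1))
cfg <- model_config()                 # fusion, 128:32, no fingerprints
s   <- featurize_dataset(ds, cfg)
lab <- attr(s, "labels")

tr <- s[1:100];   attr(tr, "labels") <- lab[1:100]
va <- s[101:120]; attr(va, "labels") <- lab[101:120]
te <- s[121:150]; attr(te, "labels") <- lab[121:150]

fit <- train_model(tr, va, cfg,
                   train_config(max_epochs = 30, seed = 1),
                   loss_config("mse"))
compute_metrics(predict(fit$model, te), lab[121:150])
#> Rp 0.6971  RMSE 1.5947  MAE 1.2782
```

The printed metrics say: on 30 held-out synthetic complexes the fused
model's predicted pK correlates 0.70 with the planted affinity, with a
root-mean-square error of 1.59 pK units — the planted contact signal is
recovered after 30 epochs, while an untrained model scores Rp ≈ 0 and
RMSE ≈ the held-out label standard deviation (1.88).

One complex at a time:

```r
cx  <- ds$complexes[[1]]
g   <- build_complex_graph(cx$pocket, cx$ligand)   # 41/21-dim features
fp  <- compute_fingerprints(cx$pocket, cx$ligand)  # $sifp $ecif $cfp
```

Real structures enter through `read_pocket("*_pocket.pdb")`,
`read_ligand("*.sdf" | "*.mol2")` and `parse_index()` (PDBbind dialect).
A thin CLI wraps the common steps:
`inst/exec/lgn featurize --pocket P.pdb --ligand L.sdf --out graph.rds`.

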