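# equippis

Partner-independent prediction of protein–protein interaction (PPI) sites
from a single-chain structure with an E(3)-equivariant graph neural
network, in R.

Interface residues — the sites through which a protein binds its partners
— must often be predicted from the isolated monomer, with no knowledge of
the partner. `equippis` treats this as node classification on a residue
graph: the chain becomes a graph whose nodes are residues (connected when
their Cα atoms lie within 14 Å at sequence separation ≥ 6, each edge
carrying a\_ij = log|i−j| / ‖x\_i − x\_j‖), every residue carries a
118-channel feature vector (residue identity, sigmoid-normalized sequence
profile and language-model embedding, secondary structure and solvent
accessibility one-hots, backbone geometry, orientation vectors, convex-hull
surface area, contact counts), and a stack of equivariant graph
convolution layers (EGCL) classifies each node. One layer updates node
embeddings h and coordinate embeddings x jointly:

    m_ij    = φ_e(h_i, h_j, ‖x_i − x_j‖², a_ij)
    x_i^l+1 = x_i^l + C Σ_j (x_i − x_j) φ_x(m_ij),   C = 1/(M−1)
    m_i     = Σ_j m_ij ;  m_i ← σ(φ_a(m_i)) ⊙ m_i   (attention gate)
    h_i^l+1 = h_i^l + φ_h(h_i ‖ m_i)

followed by a linear squeeze and a sigmoid giving the per-residue
interface probability p\_i. Coordinates enter only through distances, so
predictions are invariant — and the coordinate embeddings equivariant —
under every rotation, translation and reflection of the input, to
floating-point accuracy. The forward pass, backpropagation, Adam and the
cosine-annealed learning-rate schedule are implemented in vectorized base
R; no deep-learning framework is required. Ablation variants (invariant
network without coordinate updates; no-attention network) are
configuration flags.

The package also provides the confusion-matrix and ranking metrics
(accuracy, precision, recall, F1, MCC, ROC-AUC, PR-AUC), a paired 70 %
resampling significance procedure (Anderson–Darling normality, then paired
t or Wilcoxon), PSI-BLAST ASCII PSSM and DSSP readers with internal
fallbacks, and a synthetic-complex generator so that every stage is
testable without downloads.

## Worked example

Train a small model on synthetic labeled complexes and predict sites for a
new structure:

```r
library(equippis)

ds  <- generate_dataset(26, seed = 7)        # synthetic labeled complexes
fit <- equippis_fit(ds[1:16], ds[17:20],     # train / validation
                    n_layers = 2, hidden_dim = 32,
                    lr = 5e-3, max_epochs = 20, seed = 1)
print(fit)
#> E(3)-equivariant interface-site classifier
#>   layers: 2  hidden: 32  attention: TRUE  coordinate updates: TRUE
#>   trained 20 epoch(s) on 16 graph(s); selected epoch 5 (val PR-AUC 0.817)

summary(fit)
#> EGNN with 2 layer(s), hidden 32, 20803 parameters
#> selected epoch 5; final train BCE 0.0003
#> training-set metrics (threshold 0.234):
#> TP 33 FP 1 TN 563 FN 3 | acc 0.993 prec 0.971 rec 0.917 F1 0.943 MCC 0.940
#>   ROC-AUC 0.999  PR-AUC 0.983

ev <- evaluate_model(coef(fit), fit$checkpoint$model_cfg, ds[21:26])
sprintf("held-out ROC-AUC %.3f  PR-AUC %.3f", ev$roc_auc, ev$pr_auc)
#> "held-out ROC-AUC 0.906  PR-AUC 0.646"

# predict for a structure on disk (mock providers stand in for a real
# PSSM / embedding source)
cx   <- make_labeled_complex(30, 8, seed = 99)
prov <- mock_feature_providers(seed = 99)
write_pdb(cx$receptor, "receptor.pdb")
preds <- predict_sites(fit$checkpoint, "receptor.pdb", chain = "A",
                       profile_provider  = prov$profile,
                       embedding_provider = prov$embedding)
head(preds, 5)
#>   residue_index aa probability call
#> 1             1  S    9.49e-01    1
#> 2             2  A    1.14e-03    0
#> 3             3  N    1.27e-04    0
#> 4             4  D    1.14e-04    0
#> 5             5  L    1.92e-05    0
```

`probability` is the sigmoid output of the classification head per
residue; `call` thresholds it (0.5 by default). The validation PR-AUC
selects the checkpoint epoch; the held-out ROC-AUC ≈ 0.9 shows the network
recovering the generator's planted geometric interface. The fitted object
also supports `predict`, `fitted`, `residuals`, `simulate` (parametric
Bernoulli draws) and `plot` (training curves).

A command-line interface over the same functions is installed at
`inst/scripts/equippis.R` with subcommands `make-fixtures`, `train`,
`predict` and `evaluate`.

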