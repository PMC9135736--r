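# pepsite

Structure- and sequence-based prediction of **peptide-binding residues** on
proteins, built around a two-stream attention network with *reciprocal
attention*, plus the full data-engineering pipeline that such a model needs:
invariant residue-graph featurization, dataset filters, transfer-learning
training, a peptide-agnostic binder score, and evaluation metrics.

## Who this is for

Protein–peptide interactions drive a large share of cellular signalling
(SH3, PDZ, WW and other peptide-recognition modules), yet peptide-bound
complexes are scarce in the PDB and peptides often change conformation on
binding. `pepsite` is aimed at structural bioinformaticians who want to

- predict which surface residues of a receptor form a peptide-binding site,
  from a structure (`mode = "struct"`) or from sequence alone
  (`mode = "seq"`),
- scan proteins *without a known peptide partner* for intrinsic
  peptide-binding propensity, and
- build leakage-free training corpora of peptide and fragment complexes
  from structure files.

## The model

A protein is encoded as a k-nearest-neighbor residue graph that is invariant
to global rotations and translations. Each residue carries a local
orthonormal frame built by Gram–Schmidt from its backbone (C−CA, N−CA);
node features are the amino-acid one-hot, sin/cos backbone torsions
(φ, ψ, ω), and the side-chain centroid direction and RBF-encoded distance in
the local frame; edge features are the RBF-encoded CA–CA distance, the unit
direction in the source frame, the quaternion of the relative frame
rotation, and a clipped sequence-offset one-hot.

The network runs two residue streams — protein and peptide — through
`n_blocks` repetitions of: protein graph attention (dense self-attention in
seq mode), peptide self-attention, **reciprocal attention**, and
position-wise feed-forward layers, each wrapped post-norm with residuals and
dropout. Reciprocal attention projects protein embeddings to queries `Q` and
values `V_prot`, peptide embeddings to keys `K` and values `V_pep`, and uses
one scaled product both ways:

    Attention_prot = softmax(Q K' / sqrt(d_k)) V_pep
    Attention_pep  = softmax(K Q' / sqrt(d_k)) V_prot

so the unnormalized protein→peptide attention matrix is exactly the
transpose of the peptide→protein one — both binding partners update each
other symmetrically. A final two-class projection of the protein stream
gives per-residue binding probabilities. Defaults: `d_model = 64`,
`d_i = 64`, `d_k = 64`, `d_v = 128`, 6 heads, 6 blocks, dropout 0.2. The
forward *and* backward passes are written in plain R matrix code and the
gradients are verified against finite differences in the test suite.

For proteins with no known peptide partner, a poly-glycine probe (length 10)
yields peptide-agnostic probabilities, and a binder score combines them with
a Gaussian prior on the binding-site fraction:

    score = max over n of [ alpha * mean(top-n probabilities)
                            + (1 - alpha) * pdf(n / N) ]

with `alpha` calibrated so that scores correlate with per-protein prediction
quality (reference calibrations: 0.955 structure mode, 0.965 sequence mode).

## Worked example

Everything below runs offline on generated fixtures (ideal helices with a
planted contact patch) in about half a minute.

```r
library(pepsite)

# 1. a synthetic peptide-protein complex with known binding residues
rec <- make_complex(fixture_spec(seed = 1))
rec
#> <complex_record> fx_seed1: receptor A (40 aa), partner B (16 aa),
#>   15 binding residues, resolution 1.80 A, BSA 474 A^2

# 2. train a small structure-mode model on eight planted complexes
cfg <- model_config("struct", d_model = 32, d_i = 32, d_k = 16, d_v = 32,
                    heads = 2, n_blocks = 2, embedder = "mock")
model <- init_model(cfg, seed = 101)
train <- lapply(1:8,  function(s) make_complex(fixture_spec(seed = s, verify_bsa = FALSE)))
val   <- lapply(9:10, function(s) make_complex(fixture_spec(seed = s, verify_bsa = FALSE)))
fit <- train_model(model, train, val,
                   train_config("finetune", lr = 1e-3, max_iters = 500,
                                eval_every = 50, seed = 11), k = 12)
tail(fit$history, 3)
#>    iteration   train_loss    val_loss
#> 8        400 0.0005988939 0.002389026
#> 9        450 0.0006761771 0.001966154
#> 10       500 0.0002063082 0.001911561

# 3. per-residue predictions with the native peptide
pred <- predict_binding(fit$model, rec$receptor,
                        structure_sequence(rec$partner), k = 12)
m <- metric_report(pred$prob, rec$labels)
round(c(roc_auc = m$roc_auc, mcc = m$mcc), 3)
#> roc_auc     mcc
#>       1       1

# 4. peptide-agnostic binder score (poly-glycine probe)
prior <- fit_prior(lapply(train, `[[`, "labels"))
agnostic <- peptide_agnostic_predict(fit$model, rec$receptor, k = 12)
ss <- site_score(agnostic$prob, prior, alpha = 0.955)
round(c(score = ss$score, n_star = ss$n_star, N = ss$N), 3)
#>  score n_star      N
#>  1.403 14.000 40.000
```

The trained model separates binding from non-binding residues perfectly on
this planted task (ROC AUC and MCC of 1), and the binder score of a decoy
receptor with no contact patch comes out much lower (0.896 vs 1.403 here) —
the score maximizes over `n = 14` residues, close to the planted 15-residue
patch.

## Command line

The same pipeline is scriptable through `inst/cli/pepsite`
(`fixtures`, `featurize`, `build-dataset`, `train`, `predict`, `score`,
`evaluate`):

```sh
Rscript inst/cli/pepsite fixtures --preset binder --seed 7 --out fx/
Rscript inst/cli/pepsite predict --model model.rds --structure fx/binder_001.pdb \
        --peptide polyG:10 --out pred.tsv
```

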