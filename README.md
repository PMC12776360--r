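# dcgat

Drug–target interaction (DTI) prediction with a **dynamic cross-graph
attention** network, in R.

## The problem

Given real-valued embeddings of *m* proteins (`X ∈ R^{m×p}`, e.g. from a
protein language model applied to amino-acid sequences) and *n* drugs
(`Y ∈ R^{n×q}`, e.g. from a chemical language model applied to SMILES
strings), plus a table of known interacting (drug, protein) pairs, predict
the probability that an arbitrary pair interacts. Most graph-based DTI
models process the drug-drug and protein-protein similarity graphs
independently and fuse late; this package implements an encoder in which
the two graphs inform each other *at every layer*.

## The model

1. **Similarity graphs.** `G_P` and `G_D` connect entities whose embedding
   Euclidean distance is at or below a threshold `τ` (set per modality,
   by default as a percentile of the pairwise distances).
2. **Cross-neighborhood selection (CNS).** At each layer, a GCN over the
   *other* modality's graph contextualises its nodes and a pairwise scorer
   emits a two-way distribution ρ (select / not-select) for every
   (query, candidate) cross-modal pair. Binary selections are sampled with
   the **straight-through Gumbel-softmax** estimator at temperature `T`,
   so selection stays differentiable end to end.
3. **Dual attention.** Per head, a protein update is
   `p_i ← σ( Σ_{r∈E_P(i)} α_ir W1 p_r + Σ_{r∈N_P(i)} β_ir W2 d_r )`,
   where `α` are intra-graph attention coefficients
   (`softmax LeakyReLU(φᵀ[W p_i ‖ W p_r])`), `β` are cross-graph
   coefficients over the selected neighbors `N_P(i)`, and `σ = ELU`;
   drug nodes update symmetrically and head outputs are averaged.
4. **Prediction.** A pair is fused with residual connections,
   `Z = [(p_i + δ·x_i) ‖ (d_j + γ·y_j)]`, and scored by an MLP with
   sigmoid output. Training minimises
   `L = L_BCE + λ·L_contrastive`, the contrastive term being a supervised
   NT-Xent loss over the fused pair embeddings.

Because no deep-learning framework is available to plain R, the package
ships a small reverse-mode automatic-differentiation engine over dense
matrices (validated against finite differences in the test suite); the
whole model — CNS policies, straight-through sampling, attention, fusion,
head, and both losses — trains through it with Adam.

The package also provides warm / cold-drug / cold-protein splitting with
negative sampling, AUROC/AUPRC, virtual-screening metrics (enrichment
factor at arbitrary cutoffs, BEDROC), noise-robustness / batch-stability /
temperature diagnostics, a component ablation suite, a latent-factor
synthetic data generator, and a command line (`inst/cli/dcgat`).

## Worked example

```r
library(dcgat)

## synthetic dataset with planted cluster structure: 40 proteins, 60 drugs,
## 4 latent clusters, ~15% interaction prevalence
data <- synth_generate(synth_config(m = 40, n = 60, K = 4, seed = 42))
data$proteins
#> <dti_embeddings> protein: 40 entities x 16 dims
data$interactions[1:3, ]
#>   drug_id protein_id label
#> 1    D001       P009     1
#> 2    D001       P013     1
#> 3    D001       P021     1

## warm-start split, one sampled negative per positive
sp <- make_split(data$interactions, data$drugs$ids, data$proteins$ids,
                 strategy = "warm", negative_ratio = 1, seed = 1)
nrow(sp$train); nrow(sp$test)
#> [1] 562
#> [1] 142

## train the full model and evaluate on the held-out pairs
fit <- dti_train(data$proteins, data$drugs, sp$train, NULL,
                 dcgat_config(epochs = 30), seed = 1)
fit
#> <dcgat_fit> variant=full, 30 epochs trained, final loss 0.6229
ev <- evaluate_model(fit, data$proteins, data$drugs, sp$test)
unlist(ev$metrics)
#>     auroc     auprc     ef0.5       ef1       ef2    bedroc
#> 0.9827415 0.9805368 2.0000000 2.0000000 2.0000000 1.0000000
```

The test AUROC/AUPRC of ~0.98 say the model ranks held-out interacting
pairs almost perfectly on this separable instance; the enrichment factors
equal 2 because a balanced test set (prevalence 0.5) caps EF at
1/prevalence, and BEDROC 1.0 means every active is retrieved at the very
top of the ranking.

Real embeddings are read with `read_embeddings()` (tab-delimited,
ID-first), or produced from sequences via `encoder_adapter()` — external
pretrained encoders plug in through `register_encoder()`; a built-in
deterministic `"hash"` backend lets the pipeline run without any model
download.

## Command line

```sh
inst/cli/dcgat synth --config synth.yaml --out data/
inst/cli/dcgat run --proteins data/proteins.tsv --drugs data/drugs.tsv \
    --interactions data/interactions.tsv --split cold_drug --repeats 10 \
    --seed 1 --out runs/cold
inst/cli/dcgat probe noise --proteins ... --drugs ... --interactions ... \
    --checkpoint runs/cold/checkpoint.json --out runs/probe
inst/cli/dcgat ablate --proteins ... --drugs ... --interactions ... --out runs/ablate
```

Every run writes its fully resolved configuration (with an MD5 content
hash) next to its outputs and is deterministic given inputs and `--seed`.

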