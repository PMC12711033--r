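# dcmclust

Multi-omics cancer subtyping by **decoupled contrastive multi-view
clustering with adaptive false negative elimination (DCMC)**, in pure R.

Cancer cohorts are routinely profiled on several molecular layers at
once — mRNA expression, miRNA expression, DNA methylation — and the
subtypes that matter clinically are the ones supported jointly by those
layers. `dcmclust` learns a shared low-dimensional representation of
such multi-view data with a self-supervised model, clusters it, and
scores the resulting subtypes the way the subtyping literature does:
survival separation, clinical label enrichment, internal validity, and
(when ground truth exists) external clustering metrics.

## The model

Each view `v` has a Siamese encoder pair: an online encoder `g_a` trained
by backpropagation and a target encoder `g_b` updated only as an
exponential moving average,

    theta_b <- xi * theta_b + (1 - xi) * theta_a,

with stop-gradient on every target output (four fully connected layers,
batch norm + ReLU, L2-normalized embeddings). Cross-view decoders
`p(v->k)` map each view's embedding into every other view's space, so
inter-view consistency is enforced in view-specific spaces —
`Q(v->k) = p(v->k)(f_a(v))` — and a sample missing view `k` can be
recovered at inference from an observed view via `p(v->k)(f_b(v))`.

Within each mini-batch, **adaptive false negative elimination** screens
the "negatives" that probably share the anchor's cluster: a negative `j`
of anchor `i` is flagged when its relative similarity
`R[i,j] = |s_pos(i) - S[i,j]|` is below a threshold `t` *and* among the
`k` smallest of the row. Flagged pairs get adaptive weights

    alpha[i,m] = 1 - exp(S[i,m]) / sum_{j != i} exp(S[i,j]),

so the most similar candidates (the likeliest false negatives) count
least. The weights modulate a pseudo-target matrix
`T = Lambda ⊙ exp(S / tau)` that rectifies both the intra-view loss
(online vs target embeddings per view) and the inter-view loss (decoder
projections vs the destination view's target embeddings); the total loss
is their sum. Training runs mini-batch Adam with a linear warmup;
K-means on the concatenated target embeddings yields the subtypes, with
the cluster number chosen from {3, 4, 5} by log-rank survival
separation.

## Worked example

Simulate a 3-view cohort with a planted 3-cluster structure and
cluster-linked survival, then run the full pipeline:

```r
library(dcmclust)

spec <- synthetic_spec(n_samples = 150, n_clusters = 3,
                       view_dims = c(40, 30, 20), separation = 8,
                       seed = 42)
sim <- generate_multiview(spec)
clinical <- generate_survival(sim$truth, spec)

cfg <- pipeline_config(
  dataset = sim$dataset, clinical = clinical, truth = sim$truth$labels,
  count_like = FALSE, n_top = 40, seed = 42, k_candidates = 2:4,
  pac_reps = 50,
  train = list(epochs = 30, batch_size = 64, warmup_epochs = 3,
               runs = 1, base_lr = 1e-3, xi = 0.9,
               hidden_dims = c(128, 64, 32), embed_dim = 16))
res <- run_subtyping(cfg)
print(res)
#> <subtype_result> 150 samples in 4 clusters
#>   log-rank -log10 P: 3.69
#>   enriched clinical labels: 1
#>   silhouette: 0.144  PAC: 0.228
#>   ACC 0.867  NMI 0.817  ARI 0.816  purity 0.973
```

Reading the output: the cluster number is selected by survival
separation, not by the (normally unknown) ground truth — here the
log-rank criterion preferred splitting one planted cluster (k = 4,
−log10 P = 3.69, i.e. P ≈ 2·10⁻⁴ for survival differences across
subtypes). Purity 0.97 shows the found clusters are nearly pure subsets
of the planted ones; one synthetic clinical label (cluster-linked tumour
grade) is significantly enriched at p < 0.05; silhouette and PAC report
cohesion and consensus stability of the embedding clustering.

Ablations (`run_ablation(cfg, "no_decoder" | "no_rectification" | "fne"
| "shared_encoder")`) toggle one component each, mirroring the model's
component analysis.

A command-line front end for the same steps ships in
`inst/cli/dcmc.R` (subcommands `simulate`, `preprocess`, `train`,
`evaluate`, `run`, `ablate`).

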