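# pathnn — pathway-structured sparse neural networks for survival classification

`pathnn` builds and trains sparse neural networks whose architecture *is* a
biological pathway hierarchy. Instead of fully connected hidden layers, each
hidden node is a real entity — a gene or a curated pathway — and a connection
exists only where biology says it does: a gene connects to the pathways that
contain it, and a child pathway connects to its parents. The resulting model
classifies cancer patients into long-term survival (LTS, > 60 months) versus
short-term survival (non-LTS, died within 60 months) from per-gene somatic
mutation and discretized copy-number features, and — because every node is
nameable — can be interrogated after training to rank genes and pathways by
their contribution to the prediction.

It is aimed at computational biologists who want an interpretable
prognosis model over standard TCGA-style inputs (MAF-style mutation calls,
GISTIC-style five-level CNV calls, a clinical survival table) and a
Reactome-style pathway hierarchy (GMT gene sets, a parent-child relation
table, a pathway-name table).

## The model

Each layer computes a masked affine map followed by tanh:

    y = f((W ∘ M) x + b),   f = tanh

where `M` is a fixed binary mask: the gene-membership adjacency `A`
(`a_ij = 1` iff gene *j* belongs to pathway *i*) between the gene layer and
the first pathway layer, and the parent-child mask between consecutive
pathway layers. Masked weights are frozen at exactly zero through training.
The input encodes each gene as a (mutation, amplification, deletion) binary
triplet; the gene layer is *diagonal* — each gene node sees only its own
three features. Every hidden layer additionally carries a single-unit
sigmoid head (deep supervision); training minimizes the head-weighted binary
cross-entropy

    L = -(1/N) Σ_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]

with Adam under a step learning-rate schedule (0.001, halved every 100
epochs, 1000 epochs by default). On the published architecture
(11,460 genes / 1061 / 447 / 147 / 26 pathway nodes) the sparse model has
83,347 parameters where the dense equivalent `Σ_l n_l (n_{l-1} + 1)` would
have 406,710,826.

Trained models are interpreted by difference-from-reference contribution
propagation (DeepLIFT, rescale rule): with reference activation t⁰ under the
all-zero "no alteration" profile and Δt = t − t⁰, each node receives a
contribution C such that contributions at every layer sum exactly to Δt.

## Worked example

Everything below is synthetic and self-contained — the fixture generator
emits a toy pathway hierarchy in the Reactome file dialects plus a cohort of
1000 samples with three planted driver genes (log-odds +3 per mutation,
+2 per CNV call; ~80% non-LTS):

```r
library(pathnn)

man  <- fixture_manifest(seed = 42, n_samples = 1000)
dir  <- file.path(tempdir(), "demo")
fx   <- simulate_fixtures(man, dir)

hier <- select_sublayers(
  assign_layers(parse_relations(file.path(dir, "relations.tsv"))),
  parse_gmt(file.path(dir, "pathways.gmt")), k = 4)
hier
#> Selected pathway hierarchy: 4 pathway layers, 78 genes
#>   P1: 18 nodes, mask nnz 164
#>   P2: 10 nodes, mask nnz 18
#>   P3: 6 nodes, mask nnz 11
#>   P4: 2 nodes, mask nnz 6

prep  <- prepare_cohort(fx$cohort$mutation, fx$cohort$cnv,
                        fx$cohort$clinical, hier, seed = 42)
model <- init_model(hier, list(seed = 42, dropout = rep(0, 5)))
res   <- train_model(model, prep$features, prep$labels, prep$split,
                     training_config(epochs = 200, base_learning_rate = 0.01,
                                     seed = 42))

evaluate_model(res$model, prep$features, prep$labels, prep$split$test)
#> accuracy 0.780  AUC 0.672  AUPR 0.910  F1 0.875  precision 0.819  recall 0.939
#> confusion @0.50: TP 77  FP 17  TN 1  FN 5

att <- deeplift_scores(res$model, prep$features[prep$split$train, ])
head(rank_nodes(att, "genes"), 3)
#>    node     score rank
#> 1 G0056 36.607554    1
#> 2 G0050 14.962180    2
#> 3 G0087  7.015524    3
fx$cohort$truth$signal_genes
#> [1] "G0050" "G0056" "G0089"

round(att$feature_type, 2)
#>      mutation amplification      deletion
#>         47.00          2.92        -11.00
```

Two of the three planted drivers rank 1 and 2 out of 78 genes; the third
drew a weaker realized signal in this cohort and lands mid-list (rank 31) —
recovery of *all* planted genes into the top decile holds for 8+ of 10 seeds
(see `tests/testthat/test-acceptance.R`). The feature-type aggregate shows
mutation dominating the CNV channels, as planted. The same metrics table can
be produced for five classical baselines on identical data with
`run_baselines(prep$features, prep$labels, prep$split, seed = 42)`.

The parameter accounting of any model:

```r
count_sparse_params(model)
#>      layer     type output_size params
#>   h0_genes diagonal          78    312
#>      h1_P1   sparse          18    182
#>      ...
#> Total (sparse): 666
#> Dense equivalent: 20,025
#> Ratio: 0.0333
```

## Command line

The same pipeline is scriptable via the installed `exec/pathnn` entry point
(or `pathnn::cli_main()`):

```sh
pathnn simulate        --seed 1 --out fx/
pathnn build-hierarchy --relations fx/relations.tsv --gmt fx/pathways.gmt \
                       --names fx/names.tsv --layers 4 --out hier/
pathnn prepare         --mutations fx/mutations.tsv --cnv fx/cnv.tsv \
                       --clinical fx/clinical.csv --hierarchy hier/ --seed 1 --out prep/
pathnn train           --data prep/ --hierarchy hier/ --epochs 200 --seed 1 --out model/
pathnn evaluate        --model model/ --data prep/ --seed 1 --out report.tsv
pathnn attribute       --model model/ --data prep/ --out attr/
pathnn inspect-model   --model model/
```

## Documentation

The methods vignette (`vignettes/pathway-networks.Rmd`) describes the model
and its assumptions, the layerization and pruning rules, the attribution
scheme and its summation-to-delta guarantee, what the synthetic fixtures do
and do not emulate, and all numerical design choices.
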