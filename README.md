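# deepathnet

Pathway-guided transformer models for multiomic cancer prediction, in R.

Cancer drug response and tumor classification depend on signals spread
across mutation, copy-number, expression and protein layers. **deepathnet**
implements DeePathNet, a deep-learning architecture that uses curated
cancer pathways as its wiring: per-pathway affine encoders compress each
pathway's concatenated multiomic gene features into an embedding
("pathway token"), a transformer models interactions among the pathway
tokens with multi-head self-attention, and an MLP head predicts either
IC50 values for many drugs jointly (with missing entries masked out of the
loss) or cancer type/subtype probabilities. For a pathway with *n* genes
and *m* omic layers the encoder is the affine map

    A_encoded = A_omics W^T + B,    W: d x (m*n),  d = 512 by default

and the *p* pathway embeddings form an N x d x p tensor that two pre-norm
transformer blocks process as an unordered token set (no positional
encoding). Missing (gene, modality) measurements enter as exact zeros, so
their encoder weights receive exactly zero gradient and are never updated.

The package is aimed at computational biologists who want a transparent,
scriptable implementation: readers for delimited omic matrices, GMT gene
sets and response/label tables; the model with full S3 methods; an
explanation layer (epsilon-rule layer-wise relevance propagation at the
pathway level, permutation Shapley values at the gene-by-modality level);
an evaluation harness (repeated k-fold cross-validation with 95% CIs,
paired t tests, per-drug win/loss tables, confusion matrices); a
synthetic multiomic generator with known causal pathways; and ablation
controls (size-matched random rewiring, plain MLP, down-sampling curves).
The network, backpropagation and Adam are implemented in base R matrix
code with compiled transformer kernels — no deep-learning framework is
required.

## Worked example

Simulate a multiomic cohort with 6 causal pathways, fit the model with
early stopping, and ask it which pathways mattered:

```r
library(deepathnet)

sim <- simulate_dataset(sim_config(seed = 1))   # 600 samples, 30 pathways
ds  <- sim$dataset
ds
#> multiomic_dataset: 600 samples | modalities: mutation, CNV, RNA | 30 pathways | targets: regression (8 drugs)

sp <- list(test = ds$sample_ids[481:600], val = ds$sample_ids[385:480],
           train = ds$sample_ids[1:384])
st  <- study_config(seed = 1)   # compact settings for this data scale
fit <- deepathnet(subset_dataset(ds, sp$train),
                  st$config, st$control,
                  validation = subset_dataset(ds, sp$val),
                  calibrate = TRUE)
fit
#> deepathnet model (regression): 30 pathways, 3 modalities, d=32, 2 block(s), 92,264 params

head(per_drug_test_metrics(fit, subset_dataset(ds, sp$test)), 3)
#>   drug   n        r2      mae   pearson
#> 1  D01 109 0.5966109 1.091954 0.7934003
#> 2  D02 104 0.6485753 1.347041 0.8300493
#> 3  D03 103 0.6124636 1.221419 0.7899004

imp <- pathway_importance(fit, ds, target = "D01")
head(imp, 3)
#>   pathway     score
#> 1     P06 0.7402982
#> 2     P02 0.6886530
#> 3     P16 0.5024150
sim$truth$causal   # ground truth: pathways 1..6 drive the responses
#> [1] 1 2 3 4 5 6
```

Held-out per-drug R² around 0.6 sits close under the simulation's Bayes
ceiling of roughly 0.8 at unit noise, and the relevance ranking places
planted causal pathways at the top (across all drugs the causal-vs-rest
ranking AUROC is about 0.9; single-drug rankings are noisier, as the P16
entry shows). The same objects
work for classification (`sim_config(task = "classification")`), repeated
cross-validation (`repeated_cv`), ablations (`run_ablation`,
`downsample_curve`) and gene-level attribution (`gene_importance`).

A command-line interface covering simulate / train / predict / evaluate /
explain / ablate lives at `inst/cli/deepathnet.R`, driven by a YAML
config and a single root seed; identical configs and seeds reproduce
artifacts checksum-for-checksum.

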