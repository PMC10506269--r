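# cacnet

Multi-label classification of DNA sequences — which transcription factors
would occupy a given fixed-length window — with a network whose feature
layers concatenate parallel **attention-augmented convolution** branches.
The package is aimed at regulatory-genomics researchers who want a fully
inspectable, dependency-light implementation of this architecture in R:
every forward pass, every gradient, the SGD training loop, the evaluation
metrics and a seeded motif simulator are implemented in the package and
cross-checked against independent oracles in the test suite.

## The model

A sequence is one-hot encoded as an L x 4 matrix over (A, C, G, T). A *CAC
layer* with D output channels runs i = 3 branches in parallel on the same
input X and concatenates their activated outputs:

    H(X) = Concat[ σ(branch_1(X)), ..., σ(branch_i(X)) ],   d_out = D / i

Each branch joins convolution and self-attention channels position-wise:

    branch(X) = Concat[ Conv(X), MHA(X) ],   d_conv = d_out − d_V

where `Conv` is a same-padded 1D convolution with d_conv filters and `MHA`
is multi-head scaled dot-product self-attention with d_V output channels:

    Head_j(X) = Softmax( (X W_Q)(X W_K)ᵀ / √d_k ) (X W_V)
    MHA(X)    = Concat[ Head_1(X), ..., Head_Nh(X) ] W^o

Three CAC layers with max pooling (size 4, stride 4) after layers 1 and 2
feed a two-layer sigmoid classifier; training minimises multi-label binary
cross-entropy with SGD + momentum, early stopping on validation accuracy
(patience 20, max 200 epochs) and best-epoch checkpointing. With the default
1000-nt configuration the stage lengths are 1000 → 250 → 62 and the
flattened width is 62·192 = 11904.

## Worked example

Simulate a 2-class motif dataset, train a small network, evaluate:

```r
library(cacnet)

pwms <- make_default_pwms(C = 2, m = 8, sharpness = 8, seed = 11)
sim  <- simulate_dataset(sim_config(n = 600, length = 40, pwms = pwms,
                                    prevalence = 0.4, seed = 11))
ds   <- as_cac_dataset(sim, split_frac = 0.92)

cfg  <- model_config(input_length = 40, n_classes = 2, D = 24, i = 3,
                     n_heads = 2, d_v = 2, kernel_sizes = c(3, 5, 7),
                     n_layers = 2, fc_hidden = 32)
fit  <- train_network(build_model(cfg, seed = 11),
                      dataset_tensors(ds, ds$split$train_idx),
                      dataset_tensors(ds, ds$split$val_idx),
                      train_config(learning_rate = 0.05, batch_size = 32,
                                   max_epochs = 30, patience = 29, seed = 11))
va <- dataset_tensors(ds, ds$split$val_idx)
build_report(predict(fit$model, va$x),
             label_matrix(va$y, class_names = c("TF1", "TF2")))
```

```
#> <evaluation over 48 samples, 2 classes>
#>   macro AUC 0.9011 | macro AP 0.8531 | top-1 1.0000 | top-3 NA
#>  class    auc     ap
#>    TF1 0.9718 0.9557
#>    TF2 0.8304 0.7506
```

The two simulated motifs (8-mers embedded in 40-nt uniform background at 40%
prevalence) are recovered on the held-out 8%: per-class AUC 0.97 / 0.83, and
the top-scored class is a true label for every labelled validation window
(top-1 = 1.0). Per-motif difficulty differs — motifs without internal repeat
structure take longer to bootstrap under SGD; see the vignette for what such
a result does and does not establish.

The same pipeline runs from the command line with archived configs and logs.
The entry point installs to `exec/cacnet` inside the package library (put it
on your `PATH`, or call `cacnet::cac_cli()` directly):

```sh
CACNET=$(Rscript -e 'cat(system.file("exec", "cacnet", package = "cacnet"))')
$CACNET simulate --config config.json --out sim/
$CACNET train    --config config.json --data sim/dataset.rds --out fit/
$CACNET evaluate --model fit/checkpoint.rds --data sim/dataset.rds --out eval/
```

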