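# splitsim

Desk-scale simulation of **splitfed learning (SFL)** and **multi-head split
learning (MHSL)** for privacy-sensitive classification tasks, with an
analytic communication-cost model and a plug-in mutual-information estimate
of how much the transmitted activations leak about the raw inputs.

## The problem

In split learning a block-structured network *W* is partitioned at a **cut
layer** *c*: blocks 1..*c* (the client-side portion *W<sub>C</sub>*) stay on
each of *K* data-holding clients — think hospitals that may not export
records — and the remaining blocks plus the classifier head
(*W<sub>S</sub>*) run on a server.  Only the cut-layer activations (the
**smashed data** *A*) and their gradients cross the network.  Two protocol
variants are simulated:

* **SFL** (the splitfedv2 flavour): all clients train in parallel against a
  single server-side model; at the end of every global epoch a fed server
  replaces each client portion by the shard-size-weighted average
  (FedAvg) of all portions.
* **MHSL**: identical, except the client-side synchronization is removed —
  each client keeps an independent "head", and the final model concatenates
  any one head with the shared server portion.

Three quantities frame the comparison:

* **Accuracy** of the assembled model(s) on a shared test set, as the cut
  moves deeper into the network.
* **Communication**, per global epoch (in transferred elements):

  | mode | per client | total | training time |
  |------|-----------|-------|---------------|
  | SFL  | 2p\|A\|/K + 2β\|W\| | 2p\|A\| + 2βK\|W\| | T + 2p\|A\|/(KR) + 2β\|W\|/R + T<sub>fedavg</sub> |
  | MHSL | 2p\|A\|/K | 2p\|A\| | T + 2p\|A\|/(KR) |

  where *p* is the accumulated sample count, β the client-side fraction of
  the model, and *R* the transfer rate.  MHSL saves exactly 2βK|W| elements
  and T<sub>fedavg</sub> seconds per epoch.  The package reconciles these
  closed forms against element counters instrumented into every run.
* **Leakage**: an honest-but-curious server sees the smashed data.  The
  mutual information score between a flattened input channel *X* and the
  length-matched smashed data *Y*,

  I(X,Y) = Σ<sub>ij</sub> (n<sub>ij</sub>/N) · log( N·n<sub>ij</sub> / (n<sub>i·</sub> n<sub>·j</sub>) )   (nats),

  is estimated from the empirical contingency table each epoch (after
  bilinear resizing / interpolation / zero-padding brings *Y* to the length
  of *X*).

Everything runs on synthetic, seeded data — 5-class 1-D signal traces
emulating an ECG-beat task, and 1-/3-channel blob-pattern images emulating
grayscale/RGB image tasks — so no downloads and no GPU are needed.

## Worked example

```r
library(splitsim)

ds   <- gen_images(generator_config(n_classes = 10, channels = 3,
                                    noise_sd = 0.35, class_separation = 0.6,
                                    seed = 42, modality = "image"))
spec <- conv2d_small_spec()          # 6-block CNN, cut anywhere in 1..6

run_sfl  <- run_training(ds, spec, train_config(mode = "SFL",  K = 5,
                         cut_layer = 3, epochs = 5, lr = 0.05, seed = 42))
run_mhsl <- run_training(ds, spec, train_config(mode = "MHSL", K = 5,
                         cut_layer = 3, epochs = 5, lr = 0.05, seed = 42))
run_sfl; run_mhsl
#> <split_run> SFL, K=5, cut=3, 5 epoch(s)
#>   final mean test accuracy: 0.3260
#>   final leakage score (nats): 1.5517
#> <split_run> MHSL, K=5, cut=3, 5 epoch(s)
#>   final mean test accuracy: 0.2600
#>   final leakage score (nats): 1.7216
```

After five (of an eventual ten) epochs at cut layer 3, synchronized SFL is
already ahead of MHSL on mean test accuracy (0.33 vs 0.26) — the
synchronization advantage that grows with cut depth — while its smashed
data here carries a *lower* mutual information score (1.55 vs 1.72 nats),
i.e. the two protocols also differ in how much the server can read off the
cut layer.  The cost model for this very run:

```r
cp <- cost_params_from_run(run_sfl)
cost_table(cp)
#>   mode comms_per_client_elements comms_total_elements comms_total_bytes training_time_s
#> 1  SFL                    468224              2341120           9364480        0.468224
#> 2 MHSL                    460800              2304000           9216000        0.460800

reconcile(run_sfl)[5, ]
#>   epoch smashed_elements sync_elements predicted_smashed predicted_sync smashed_match sync_match
#> 1     5          2304000         37120           2304000          37120          TRUE       TRUE
```

Every epoch moved exactly 2p|A| = 2·2000·576 = 2,304,000 smashed/gradient
elements, and SFL's synchronization added exactly 2βK|W| = 37,120 — the
measured counters match the closed forms element for element.

`tidy()` / `glance()` give per-epoch and one-row summaries as tibbles;
`autoplot(run_sfl, mhsl = run_mhsl)` plots the accuracy trajectories and
`plot_mis_trace(SFL = run_sfl, MHSL = run_mhsl)` the leakage traces.
Experiment grids (mode × cut × seed, with CSV/JSON artifacts) live in
`run_experiment()` and `sweep_cut_layers()`; a thin CLI with `datagen`,
`train`, `sweep` and `cost` subcommands is in `inst/cli/splitsim.R`.

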