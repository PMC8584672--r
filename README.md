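# prunebm

Activity-dependent synaptic pruning of stochastic binary encoder networks,
guided by local estimates of Fisher information.

During development, brains build far more neurons and synapses than the
mature circuit keeps. `prunebm` studies which *locally available* signals
could drive that reduction, using Bernoulli restricted Boltzmann machines
(RBMs) and two-hidden-layer deep Boltzmann machines (DBMs) as models of
sensory encoding. The energy of a joint binary state is

    E(v, h) = − Σᵢ bᵢᵛ vᵢ − Σⱼ bⱼʰ hⱼ − Σᵢⱼ wᵢⱼ vᵢ hⱼ,

with `p(v, h) ∝ exp(−E)`. For this family the Fisher information matrix is
the covariance of per-parameter statistics, and its diagonal weight entry
reduces to a Bernoulli variance of the pre–post coincidence,

    F(wᵢⱼ) = ⟨vᵢhⱼ⟩ (1 − ⟨vᵢhⱼ⟩),

a quantity a synapse could track from its own activity. A mean-field
heuristic goes further and reconstructs ⟨vᵢhⱼ⟩ from only the weight and the
two units' mean firing rates:

    ⟨vᵢhⱼ⟩ ≈ ⟨vᵢ⟩⟨hⱼ⟩ / (⟨vᵢ⟩ + (1 − ⟨vᵢ⟩) e^{−wᵢⱼ(1−⟨hⱼ⟩)}).

The package provides, as separately usable modules:

* **Synthetic data** — binary prototype mixtures with bit-flip noise,
  circular-patch masks (the radius-2 disk has the 13 pixels used by the
  single-layer experiments), clipped receptive-field connectivity
  (`20×20` grid, `5×5` windows → 8,836 of 160,000 connections), labelled
  toy digits with structurally silent borders, plus IDX/PNG readers.
* **Core models** — masked-weight RBMs/DBMs, energies, conditionals, Gibbs
  sampling, exact enumeration oracles, analytic visible marginals, JSON
  checkpoints.
* **Training** — CD-k, two-RBM pretraining with bias-averaged merging,
  damped mean-field inference, persistent-chain joint training with a
  spectral-norm cap.
* **Fisher information** — exact FIM, sampled variance estimate of the
  diagonal, the rate-based heuristic, leading-eigenvector importance.
* **Pruning** — percentile thresholding with deterministic tie-breaks, the
  zero-importance override, dead-unit cascades, random-unit budget
  matching, and the full prune–retrain loop over seven criteria.
* **Evaluation** — KL(data‖model) and log-probability matching against
  generated samples, classifier-based encoding quality, quality/diversity
  scores for generated patterns, hidden-activation monitoring.

## Worked example

Train the reference overcomplete patch model and prune it by the local
variance estimate of Fisher information:

```r
library(prunebm)

study <- patch_study(seed = 7)   # 13 visible x 70 hidden, 2,000 samples
study$net
#> <boltzmann_net> layers [13, 70], live weights [910]

evaluate_generative(study$net, study$data, seed = 7)$kl_data_model
#> [1] 0.484

report <- prune_loop(study$net, study$data,
                     prune_config(criterion = "variance_fi", seed = 7),
                     study$train_cfg)
report
#> <prune_run_report> criterion 'variance_fi', 3 iterations
#>  iteration n_units_removed n_disconnected_visible kl_before_retrain
#>          1               4                      0         0.5321453
#>          2              13                      0         1.8906775
#>          3              15                      0         5.9863160
#>  kl_after_retrain n_w_1 n_units_1 n_units_2
#>          1.387280   455        13        66
#>          1.257086   227        13        53
#>          1.409370   113        13        38
```

Reading the report: each iteration halves the live weights
(910 → 455 → 227 → 113), deletes hidden units that lost all their
connections (70 → 66 → 53 → 38 remain), and shows the divergence between
the data distribution and the model's generated patterns immediately after
pruning (`kl_before_retrain`, in nats — large right after a cut) and after
two epochs of retraining (`kl_after_retrain` — recovery to near the
unpruned fit). `compare_pruning_criteria()` repeats this across seeds and
criteria; `summarize()` aggregates the reports into mean ± sd tables.

A thin command-line wrapper is included for scripted runs:

```sh
Rscript inst/cli/prunebm.R run --config experiment.json
```

## Limitations

The synthetic fixtures demonstrate the machinery and the direction of the
main effects at desk scale. The unit-level concentration of Fisher
information that distinguishes FI-pruning from magnitude pruning on large
natural-image corpora does not emerge on the smallest fixtures; the methods
vignette (`vignettes/fisher-guided-pruning.Rmd`) analyses why and documents
every protocol choice.
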