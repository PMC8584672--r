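---
title: "Activity-dependent pruning of Boltzmann machines with local Fisher information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-dependent pruning of Boltzmann machines with local Fisher information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prunebm)
```

## The model and the question

Developing brains over-produce neurons and synapses and later remove a
large fraction of them. `prunebm` studies this process in a tractable model
class: Bernoulli restricted Boltzmann machines (RBMs) and their two-hidden-
layer deep extension (DBMs). An RBM assigns each joint state of binary
visible units $v$ and hidden units $h$ the energy

$$E(v, h) = -\sum_i b^v_i v_i - \sum_j b^h_j h_j - \sum_{ij} w_{ij} v_i h_j,$$

and the Boltzmann probability $p(v,h) = e^{-E(v,h)}/Z$ at unit temperature.
The bipartite connectivity makes units conditionally independent given the
opposite layer, with on-probabilities $\sigma(b + W^\top v)$ and
$\sigma(b + W h)$; a middle DBM layer sums the input from both neighbours.
A trained, deliberately overcomplete model of sensory patterns is then
pruned: weights deemed unimportant are fixed to zero, hidden units that
lose all incoming (or, in DBMs, all outgoing) weights are deleted, and the
survivor is retrained briefly. The scientific question is which *local*
importance signal lets this loop find a compact architecture that still
models the data.

## Importance estimates

The curvature of the model's fit under a perturbation of parameters is the
Fisher information matrix (FIM). For an RBM every entry is a covariance of
per-parameter sufficient statistics under the model distribution, e.g.
$F_{w_{ij}, w_{kl}} = \langle v_i h_j v_k h_l\rangle - \langle v_i
h_j\rangle \langle v_k h_l\rangle$. `fim_exact()` computes the full matrix
by state enumeration for networks of up to 24 units and is the oracle
everything else is tested against.

Because unit activations are binary, the diagonal weight entry collapses to
a Bernoulli variance of the pre-post coincidence,

$$F_{w_{ij}} = \langle v_i h_j\rangle\,(1 - \langle v_i h_j\rangle),$$

which a synapse could estimate from its own firing statistics
(`fim_diag_variance()` on `collect_stats()` output). A second, even more
frugal signal needs only the weight and the two mean rates:

$$\langle v_i h_j\rangle \approx
\frac{\langle v_i\rangle \langle h_j\rangle}
{\langle v_i\rangle + (1-\langle v_i\rangle)\,
e^{-w_{ij}(1-\langle h_j\rangle)}},$$

implemented in `heuristic_coincidence()`. It is exact at $w_{ij}=0$ and, on
random enumerable models, rank-correlates with the exact coincidences at
$\rho > 0.99$ (the test suite recomputes this). Finally, when the FIM is
dominated by its top eigenvalue it is close to rank one, so the magnitude
of each parameter in the leading eigenvector is itself an importance score
(`leading_eigen_importance()`).

Seven criteria are available to the pruning loop: the three FI-based scores,
absolute weight magnitude, *Anti-FI* (remove the most important weights —
a falsification control), random weights, and random whole units matched to
the same weight budget via `match_unit_budget()`.

## Tunable parameters and defaults

Training (`train_config()`) mirrors the conventions for this model family:
CD-1 gradients, two epochs with the learning rate decaying logarithmically
from 0.1 to 0.01, momentum 0.9, per-instance updates, Gaussian weight
initialisation with sd 0.1, hidden biases started at −2 to encourage sparse
latent activity, and visible biases at the data log-odds. For deep models,
two RBMs are pretrained, merged by averaging the shared layer's biases, and
trained jointly by mean-field variational inference with 100 persistent
Gibbs chains; each weight matrix's spectral norm is capped at 6. The
"decay rate 0.8" of hidden firing probabilities is realised as damping 0.8
on the mean-field updates; since fixed points are damping-invariant this
only affects the iteration path, and an undamped variant is available
through the same argument. Which matrix norm the cap refers to is an open
choice; we use the largest singular value as the most conservative of the
common operator norms.

Pruning (`prune_config()`) removes, per layer pair, the least important
live weights so that `floor((1 - percentile/100) * n_live)` survive —
halving 910 weights three times gives the 455/227/113 schedule. Ties are
broken by (importance, row, column) so runs are bit-reproducible. When an
FI criterion assigns exactly zero importance to more weights than the
percentile would remove, all zero-importance weights are pruned instead;
this mirrors the observation that sparse deep layers can have more than a
quartile of dead coincidences, and it accelerates unit removal. Anti-FI
does not use the override (zeros are the *least* attractive targets under
an inverted ranking).

Statistics for the FI criteria default to the storage protocol used
throughout: thinned Gibbs samples (every 200th sweep), as many samples as
training instances, run as many short parallel chains rather than one long
one — a standard MCMC variance-reduction choice that keeps the estimator
identical. For deep networks the diagonal is assembled layer-wise: the
data-clamped statistics score the visible pair, free-running samples score
the deeper pair.

## The synthetic data

Everything is testable offline through `generate_mixture()`: samples are
binary prototypes drawn with class weights and independent bit-flips. The
reference single-layer fixture (`patch_study()`) uses the 13-pixel
radius-2 disk (`circular_mask(2)`) with four geometric prototypes — left
half, right half, centre cross, outer ring — at flip probability 0.05 and
2,000 samples, and an overcomplete hidden layer of 70 units (910 weights).
The initial fit runs 10 epochs: at 2,000 samples this reaches the
convergence plateau that large-corpus training reaches within its first
epochs, which matters because pruning a half-trained model measures
recovery speed rather than importance. Retraining between pruning events
stays at 2 epochs.

The labelled fixture (`toy_digits()`) draws ten seven-segment glyphs on the
10×10 interior of a 12×12 grid whose one-pixel border is always zero, so an
importance-guided pruner should disconnect exactly the structurally
uninformative border pixels. `receptive_field_mask()` restricts the first
DBM weight matrix to clipped 5×5 windows (2,916 of 20,736 possible
connections on this grid; 8,836 of 160,000 on a 20×20 grid).

What the generator does *not* emulate: spatial correlation structure within
a latent cause (bit-flips are independent), graded pixel intensities before
binarisation, and the sheer pattern diversity of natural image corpora.
Passing tests therefore demonstrate the correctness of the machinery and
the direction of the main effects at desk scale, not quantitative agreement
with natural-image experiments.

## Evaluation

Generative fit is measured on the visible patterns: the empirical
distribution of free-running model samples is compared to the data
distribution by $D_{KL}(\text{data}\,\|\,\text{model})$ and by the mean
squared error between matched log-probabilities. Model-side probabilities
are floored at $1/(10\,n_{\text{samples}})$ — Laplace-style smoothing
scaled to the sample size — before renormalisation, so patterns the model
never produced contribute a finite, sample-aware penalty. For two-layer
models with at most 20 visible units, `rbm_visible_marginal()` gives the
*exact* marginal by analytic hidden-layer summation; the tests use it to
confirm the sampled estimates.

Encoding quality clamps the visible layer to each labelled instance,
samples the final hidden layer, and reports held-out accuracy of a
multinomial logistic classifier on an 80/20 stratified split (the split is
an open protocol choice; stratification keeps small fixtures balanced),
next to a raw-pixel baseline under the identical protocol. Generated
patterns are scored by a reference classifier trained on raw labelled data:
mean winning-class probability (quality) and the entropy of the assigned
class histogram (diversity, ceiling $\ln 10 \approx 2.30$ nats for ten
balanced classes). `activation_monitor()` tracks mean stimulus-evoked
hidden activity, whose rise across pruning iterations is a useful
stopping signal.

## Numerical choices

* Exact enumeration refuses networks above 24 total units; the analytic
  visible marginal refuses more than 20 visible units.
* Heuristic rates are clipped to $[10^{-6}, 1-10^{-6}]$; the expression
  then degenerates smoothly to the independence value at the boundaries.
* Gibbs updates sweep even-depth layers before odd-depth layers, so
  conditionally independent blocks update together; the update order is
  otherwise unconstrained.
* Mean-field iteration stops when the largest mean changes by less than
  `mf_tol` (default $10^{-5}$); non-convergence is flagged on the result,
  not thrown.
* One master seed fans out to named sub-streams (`sub_seed()`), so data
  generation, initialisation, sampling and evaluation can be re-run in
  isolation while the full pipeline stays bit-reproducible.
* All randomness flows through R's generator under `with_seed()`, which
  restores the caller's random state.

## Problem sizes

The test and reproduction workloads are sized for a single CPU: the
reference comparison runs ten replicates of the 13×70 fixture with three
criteria each (about six minutes), the sampled-versus-exact FIM check uses
$10^5$ thinned samples of a 3+2-unit model in twenty batches, and the deep
toy-digit pipeline trains a 144–144–40 network on a few hundred samples in
seconds.

## What the comparisons show — and a known limitation

At these desk-scale conditions the package reproduces the direction of the
architectural effects that motivate FI-guided pruning: Anti-FI pruning
strips the network of its most informative synapses, and random-unit
removal matches weight budgets exactly with zero variance. The headline
contrast between variance-FI and magnitude pruning, however, does **not**
reproduce at this scale: across the ten-replicate comparison the FI-pruned
models retain *more* hidden units (mean ≈ 52 of 70) than magnitude-pruned
ones (≈ 31), and their post-retraining divergence is statistically
indistinguishable from the Anti-FI control. The mechanism is visible in
the exact statistics: with a 13-pixel visible layer and few latent causes,
the silent hidden units' equilibrium activities are nearly homogeneous, so
the coincidence-variance ranking separates *pixels within units* (a
prototype's off-pixels score near zero) more strongly than it separates
units, and pruning leaves many partially connected units that brief
retraining re-activates. Unit-level concentration of Fisher information
appears to require data in which between-unit activity differences dominate
within-unit structure — a property of large natural-image patch corpora
that this generator cannot provide while simultaneously keeping stub
architectures unable to refit (the property the Anti-FI contrast relies
on). Users applying the package to richer data should check both effects
on their own corpus; `compare_pruning_criteria()` automates exactly this.
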