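#' Single-layer patch study conditions
#'
#' The package's reference single-layer experiment: an overcomplete RBM with
#' 13 visible units (the radius-2 disk) and 70 hidden units (910 weights)
#' fit to a four-prototype mixture with 5% bit-flip noise, then iteratively
#' pruned at the 50th percentile for three iterations with two retraining
#' epochs after each. These conditions are fixed; they define the fixture
#' every pruning-criterion comparison runs under.
#'
#' @param seed integer seed for this replicate.
#' @param n_samples training samples.
#' @param n_hidden hidden units of the overcomplete model.
#' @param flip_prob mixture bit-flip noise.
#' @param initial_epochs epochs of the initial (pre-pruning) fit; the
#'   default trains the small fixture to convergence.
#' @return list with `data` ([binary_dataset()]), `net` (trained
#'   [boltzmann_net()]) and `train_cfg` (the retraining [train_config()]).
#' @export
patch_study <- function(seed, n_samples = 2000, n_hidden = 70,
                        flip_prob = 0.05, initial_epochs = 10) {
  data <- generate_mixture(default_patch_prototypes(), n_samples,
                           flip_prob = flip_prob, seed = seed)
  net <- train_rbm(data, n_hidden,
                   train_config(epochs = initial_epochs, seed = seed))
  list(data = data, net = net, train_cfg = train_config(seed = seed))
}

#' Multi-seed comparison of pruning criteria
#'
#' Runs [prune_loop()] under several criteria on independent replicates of
#' the patch study ([patch_study()]) and tabulates, per seed, the final
#' remaining hidden units and the post-retraining divergence from the data
#' distribution. This is the harness behind the functional-ordering checks:
#' whether importance-guided pruning finds more compact architectures than
#' magnitude pruning at matched weight counts, and whether removing the
#' *least* important weights (variance FI) preserves the generative fit
#' better than removing the *most* important ones (Anti-FI).
#'
#' @param n_seeds number of independent replicates.
#' @param base_seed master seed; replicate `i` uses `sub_seed(base_seed, i)`.
#' @param criteria character vector of pruning criteria to compare.
#' @param percentile,n_iterations,retrain_epochs pruning schedule.
#' @param ... forwarded to [patch_study()].
#' @return data.frame with one row per (seed, criterion): final live
#'   weights, final hidden units, and KL(data||model) after retraining.
#' @export
compare_pruning_criteria <- function(n_seeds = 10, base_seed = 1,
                                     criteria = c("variance_fi",
                                                  "weight_magnitude",
                                                  "anti_fi"),
                                     percentile = 50, n_iterations = 3,
                                     retrain_epochs = 2, ...) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    seed <- sub_seed(base_seed, paste0("replicate", i))
    study <- patch_study(seed, ...)
    for (cr in criteria) {
      pc <- prune_config(criterion = cr, percentile = percentile,
                         n_iterations = n_iterations,
                         retrain_epochs = retrain_epochs, seed = seed)
      rep <- prune_loop(study$net, study$data, pc, study$train_cfg)
      last <- rep$records[nrow(rep$records), ]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = i, seed = seed, criterion = cr,
        n_w = last$n_w_1, n_hidden = last$n_units_2,
        kl_after_retrain = last$kl_after_retrain
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count pairwise wins between two criteria
#'
#' @param comparison output of [compare_pruning_criteria()].
#' @param metric column to compare (`"n_hidden"` or `"kl_after_retrain"`).
#' @param smaller,larger criterion names; a win is `smaller < larger` on the
#'   metric within a replicate.
#' @return integer number of replicates won.
#' @export
count_wins <- function(comparison, metric, smaller, larger) {
  by_rep <- split(comparison, comparison$replicate)
  sum(vapply(by_rep, function(d) {
    a <- d[[metric]][d$criterion == smaller]
    b <- d[[metric]][d$criterion == larger]
    length(a) == 1 && length(b) == 1 && a < b
  }, logical(1)))
}
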