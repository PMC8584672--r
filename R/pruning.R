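#' Pruning configuration
#'
#' @param criterion one of `"variance_fi"`, `"heuristic_fi"`,
#'   `"first_eigenvector"`, `"weight_magnitude"`, `"anti_fi"`,
#'   `"random_weight"`, `"random_unit"`.
#' @param percentile removal percentile in `[0, 100]`, one value per layer
#'   pair (recycled). Defaults to 50: each iteration removes the less
#'   important half of the live weights.
#' @param n_iterations prune-retrain iterations (>= 1).
#' @param retrain_epochs training epochs after each pruning event.
#' @param zero_importance_override when more live weights have exactly zero
#'   importance than the percentile would remove, prune all zero-importance
#'   weights instead (FI criteria only).
#' @param stats_mode how activity statistics are collected for FI criteria:
#'   `"free"`, `"clamped"`, `"exact"`, or `"auto"` (free for two-layer
#'   networks; for deep networks clamped statistics for the first layer
#'   pair and free-running for the rest, computed layer-wise).
#' @param thin Gibbs thinning for sampled statistics and evaluation.
#' @param n_chains parallel chains for free-running sampling.
#' @param eval_n_samples generated-sample count per evaluation; defaults to
#'   the training-set size.
#' @param seed master seed for the pruning run.
#' @return list of class `prune_config`.
#' @export
prune_config <- function(criterion = "variance_fi", percentile = 50,
                         n_iterations = 3, retrain_epochs = 2,
                         zero_importance_override = TRUE,
                         stats_mode = "auto", thin = 200, n_chains = 100,
                         eval_n_samples = NULL, seed = NULL) {
  stopifnot(all(percentile >= 0), all(percentile <= 100), n_iterations >= 1)
  criterion <- match.arg(criterion,
    c("variance_fi", "heuristic_fi", "first_eigenvector", "weight_magnitude",
      "anti_fi", "random_weight", "random_unit"))
  structure(as.list(environment()), class = "prune_config")
}

#' Percentile-threshold pruning of one weight matrix
#'
#' Removes the live weights with the lowest importance so that
#' `floor((1 - percentile/100) * n_live)` survive, the percentile being
#' computed over currently-live entries only. Ties are broken
#' deterministically by (importance, row index, column index) so runs are
#' exactly reproducible. Surviving weights keep their values; halving 910
#' live weights three times leaves 455, 227, 113.
#'
#' @param mask {0,1} matrix of live connections.
#' @param importance matrix congruent to `mask`; only live entries are read.
#' @param percentile removal percentile in `[0, 100]`.
#' @return the new {0,1} mask.
#' @export
threshold_prune <- function(mask, importance, percentile) {
  if (percentile < 0 || percentile > 100) {
    stop("percentile must lie in [0, 100]", call. = FALSE)
  }
  live <- which(mask == 1, arr.ind = TRUE)
  n_live <- nrow(live)
  n_remove <- n_live - floor((1 - percentile / 100) * n_live)
  if (n_remove == 0) return(mask)
  vals <- importance[live]
  ord <- order(vals, live[, 1], live[, 2])
  drop_idx <- live[ord[seq_len(n_remove)], , drop = FALSE]
  mask[drop_idx] <- 0
  mask
}

#' Prune all zero-importance weights
#'
#' When the fraction of live weights carrying exactly zero importance
#' exceeds the configured percentile, all of them are removed (possibly
#' more than the percentile count); otherwise this falls back to
#' [threshold_prune()].
#'
#' @inheritParams threshold_prune
#' @param tol importance values at or below `tol` count as zero.
#' @return the new {0,1} mask.
#' @export
zero_importance_prune <- function(mask, importance, percentile, tol = 1e-12) {
  live <- which(mask == 1, arr.ind = TRUE)
  zero <- abs(importance[live]) <= tol
  if (mean(zero) > percentile / 100) {
    mask[live[zero, , drop = FALSE]] <- 0
    return(mask)
  }
  threshold_prune(mask, importance, percentile)
}

#' Remove dead hidden units
#'
#' A hidden unit is dead when all its incoming weights are pruned or — in a
#' deep network — when all its outgoing weights are pruned. Dead units are
#' deleted together with their remaining weights on the other side, so the
#' total number of deleted weights can exceed what the importance threshold
#' specified. Deletion cascades until a fixed point. Visible units with no
#' live weights are reported as disconnected but kept, preserving dataset
#' column indexing.
#'
#' @param net a [boltzmann_net()].
#' @return list with `net` (units dropped), `removed` (count per hidden
#'   layer, cumulated over the cascade), `cascade_rounds`, and
#'   `disconnected_visible` (logical vector over visible units).
#' @export
remove_dead_units <- function(net) {
  L <- n_layers(net)
  removed <- integer(L)
  rounds <- 0
  repeat {
    any_dead <- FALSE
    for (l in 2:L) {
      dead <- colSums(net$masks[[l - 1]]) == 0
      if (l < L) dead <- dead | rowSums(net$masks[[l]]) == 0
      if (any(dead)) {
        any_dead <- TRUE
        keep <- !dead
        removed[l] <- removed[l] + sum(dead)
        net$weights[[l - 1]] <- net$weights[[l - 1]][, keep, drop = FALSE]
        net$masks[[l - 1]] <- net$masks[[l - 1]][, keep, drop = FALSE]
        if (l < L) {
          net$weights[[l]] <- net$weights[[l]][keep, , drop = FALSE]
          net$masks[[l]] <- net$masks[[l]][keep, , drop = FALSE]
        }
        net$biases[[l]] <- net$biases[[l]][keep]
        net$layers[l] <- sum(keep)
        if (net$layers[l] == 0) {
          stop("a hidden layer lost all of its units", call. = FALSE)
        }
      }
    }
    rounds <- rounds + 1
    if (!any_dead) break
  }
  list(
    net = net,
    removed = removed[-1],
    cascade_rounds = rounds,
    disconnected_visible = rowSums(net$masks[[1]]) == 0
  )
}

#' Unit count matching a pruned weight budget
#'
#' For the random-unit control, whole units are removed instead of single
#' weights while keeping a comparable number of weights: the smallest unit
#' count whose total weight count reaches the budget,
#' `ceiling(weight_budget / fan_per_unit)`, capped at `n_units`.
#'
#' @param n_units available units.
#' @param fan_per_unit live weights per unit.
#' @param weight_budget target number of remaining weights.
#' @return integer number of units to keep.
#' @export
match_unit_budget <- function(n_units, fan_per_unit, weight_budget) {
  stopifnot(n_units > 0, fan_per_unit > 0, weight_budget > 0)
  min(n_units, as.integer(ceiling(weight_budget / fan_per_unit)))
}

## Randomly keep n_keep hidden units of layer l (mask-level removal; the
## dead-unit pass performs the actual deletion).
random_unit_prune <- function(net, l, n_keep) {
  n_h <- net$layers[l]
  keep <- sort(sample.int(n_h, n_keep))
  drop <- setdiff(seq_len(n_h), keep)
  net$masks[[l - 1]][, drop] <- 0
  if (l < n_layers(net)) net$masks[[l]][drop, ] <- 0
  net
}

collect_stats_for_pruning <- function(net, data, cfg, seed) {
  mode <- cfg$stats_mode
  n <- nrow(data$patterns)
  if (mode == "auto") {
    if (n_layers(net) == 2) mode <- "free" else mode <- "layerwise"
  }
  if (mode == "layerwise") {
    # first pair from clamped data statistics, deeper pairs from
    # free-running samples; layer-wise, assuming weakly correlated units
    clamped <- collect_stats(net, "clamped", data = data, seed = seed)
    free <- collect_stats(net, "free", n_samples = n, thin = cfg$thin,
                          n_chains = cfg$n_chains,
                          seed = sub_seed(seed, "free"))
    stats <- clamped
    for (l in 2:(n_layers(net) - 1)) {
      stats$coincidence[[l]] <- free$coincidence[[l]]
      stats$mean[[l + 1]] <- free$mean[[l + 1]]
    }
    stats$source <- "layerwise"
    return(stats)
  }
  collect_stats(net, mode, data = data, n_samples = n, thin = cfg$thin,
                n_chains = cfg$n_chains, seed = seed)
}

apply_pruning_step <- function(net, data, cfg, iter_seed) {
  if (cfg$criterion == "random_unit") {
    pct <- rep_len(cfg$percentile, n_layers(net) - 1)
    with_seed(sub_seed(iter_seed, "unit"), {
      for (l in 2:n_layers(net)) {
        m <- net$masks[[l - 1]]
        live <- sum(m)
        budget <- live - floor(pct[l - 1] / 100 * live)
        fan <- live / net$layers[l]
        n_keep <- match_unit_budget(net$layers[l], fan, budget)
        net <- random_unit_prune(net, l, n_keep)
      }
    })
    return(net)
  }
  needs_stats <- cfg$criterion %in% c("variance_fi", "heuristic_fi", "anti_fi")
  stats <- if (needs_stats) {
    collect_stats_for_pruning(net, data, cfg, sub_seed(iter_seed, "stats"))
  } else NULL
  imp <- weight_importance(net, cfg$criterion, stats = stats,
                           seed = sub_seed(iter_seed, "rand"))
  pct <- rep_len(cfg$percentile, n_layers(net) - 1)
  fi_based <- cfg$criterion %in% c("variance_fi", "heuristic_fi", "first_eigenvector")
  for (l in seq_len(n_layers(net) - 1)) {
    vals <- imp$values[[l]]
    vals[is.na(vals)] <- Inf  # masked entries never compete
    net$masks[[l]] <- if (cfg$zero_importance_override && fi_based) {
      zero_importance_prune(net$masks[[l]], vals, pct[l])
    } else {
      threshold_prune(net$masks[[l]], vals, pct[l])
    }
    net$weights[[l]] <- net$weights[[l]] * net$masks[[l]]
  }
  net
}

retrain_net <- function(net, data, train_cfg, epochs, seed) {
  cfg <- train_cfg
  cfg$epochs <- epochs
  cfg$seed <- seed
  if (n_layers(net) == 2) train_rbm(data, cfg = cfg, net = net)
  else pcd_train(net, data, cfg)
}

#' Iterative prune-retrain loop
#'
#' Orchestrates the full procedure: per iteration, score every live weight
#' under the configured criterion, prune at the percentile (with the
#' zero-importance override for FI criteria, or the unit-budget path for
#' the random-unit control), delete dead hidden units, evaluate, retrain
#' for `retrain_epochs` with the surviving parameter values unchanged, and
#' evaluate again. Pruned weights never return.
#'
#' @param net a trained [boltzmann_net()].
#' @param data the training [binary_dataset()].
#' @param prune_cfg a [prune_config()].
#' @param train_cfg a [train_config()] used for retraining.
#' @return object of class `prune_run_report`: `records` data.frame (one
#'   row per iteration: live weights per pair, units per layer, KL before
#'   and after retraining), `final_net`, `criterion`, `seed`, and a
#'   `stopped_early` flag set when the network disconnected completely.
#' @export
prune_loop <- function(net, data, prune_cfg = prune_config(),
                       train_cfg = train_config()) {
  seed <- prune_cfg$seed %||% 0L
  records <- list()
  stopped_early <- FALSE
  eval_n <- prune_cfg$eval_n_samples %||% nrow(data$patterns)
  eval_kl <- function(net, tag) {
    evaluate_generative(net, data, n_samples = eval_n, thin = prune_cfg$thin,
                        n_chains = prune_cfg$n_chains,
                        seed = sub_seed(seed, tag))$kl_data_model
  }
  for (iter in seq_len(prune_cfg$n_iterations)) {
    iter_seed <- sub_seed(seed, paste0("iter", iter))
    net <- tryCatch(
      apply_pruning_step(net, data, prune_cfg, iter_seed),
      error = function(e) e
    )
    if (inherits(net, "error")) { stopped_early <- TRUE; break }
    dead <- tryCatch(remove_dead_units(net), error = function(e) e)
    if (inherits(dead, "error")) { stopped_early <- TRUE; break }
    net <- dead$net
    if (n_live_weights(net) == 0) { stopped_early <- TRUE; break }
    kl_before <- eval_kl(net, paste0("eval_pre", iter))
    net <- retrain_net(net, data, train_cfg, prune_cfg$retrain_epochs,
                       sub_seed(iter_seed, "retrain"))
    kl_after <- eval_kl(net, paste0("eval_post", iter))
    nw <- vapply(net$masks, sum, numeric(1))
    rec <- data.frame(
      iteration = iter,
      n_units_removed = sum(dead$removed),
      n_disconnected_visible = sum(dead$disconnected_visible),
      kl_before_retrain = kl_before,
      kl_after_retrain = kl_after
    )
    for (l in seq_along(nw)) rec[[paste0("n_w_", l)]] <- nw[l]
    for (l in seq_along(net$layers)) rec[[paste0("n_units_", l)]] <- net$layers[l]
    records[[iter]] <- rec
  }
  structure(
    list(
      records = if (length(records)) do.call(rbind, records) else NULL,
      final_net = if (inherits(net, "error")) NULL else net,
      criterion = prune_cfg$criterion,
      seed = seed,
      stopped_early = stopped_early
    ),
    class = "prune_run_report"
  )
}

#' @export
print.prune_run_report <- function(x, ...) {
  cat(sprintf("<prune_run_report> criterion '%s', %d iterations%s\n",
              x$criterion,
              if (is.null(x$records)) 0L else nrow(x$records),
              if (x$stopped_early) " (stopped early)" else ""))
  if (!is.null(x$records)) print(x$records, row.names = FALSE)
  invisible(x)
}
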