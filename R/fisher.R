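#' Activity statistics for importance estimation
#'
#' Collects per-layer mean activations and pre-post coincidence rates, the
#' locally-available statistics from which the variance estimate of the
#' Fisher information diagonal is computed.
#'
#' In free mode, samples come from the model's equilibrium distribution via
#' thinned Gibbs sampling (many independent parallel chains). In clamped
#' mode the visible layer is fixed to the supplied data, one hidden sample
#' per instance. In exact mode the statistics are computed from the
#' enumerated distribution (small networks only).
#'
#' @param net a [boltzmann_net()].
#' @param mode `"free"`, `"clamped"` or `"exact"`.
#' @param data a [binary_dataset()] (required for clamped mode; supplies the
#'   default sample count otherwise, matching the convention that the number
#'   of samples per layer equals the number of training instances).
#' @param n_samples Monte-Carlo sample count; defaults to `nrow(data)`.
#' @param thin Gibbs sweeps between stored free-running samples.
#' @param n_chains parallel chains for free-running sampling.
#' @param seed integer seed.
#' @return object of class `activity_stats`: `mean` (list per layer),
#'   `coincidence` (list per layer pair), `n_samples`, `source`, and a
#'   `low_n` flag set when fewer than 100 samples were used.
#' @export
collect_stats <- function(net, mode = c("free", "clamped", "exact"),
                          data = NULL, n_samples = NULL, thin = 200,
                          n_chains = 100, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    d <- exact_distribution(net)
    means <- lapply(d$layer_blocks, function(b) as.numeric(crossprod(b, d$prob)))
    coinc <- lapply(seq_len(n_layers(net) - 1), function(l) {
      crossprod(d$layer_blocks[[l]] * d$prob, d$layer_blocks[[l + 1]])
    })
    return(structure(list(mean = means, coincidence = coinc,
                          n_samples = Inf, source = "exact", low_n = FALSE),
                     class = "activity_stats"))
  }
  if (mode == "clamped" && is.null(data)) {
    stop("clamped mode requires a dataset", call. = FALSE)
  }
  n_samples <- n_samples %||% (if (!is.null(data)) nrow(data$patterns) else 10000L)
  samples <- with_seed(seed, {
    if (mode == "free") {
      sample_states(net, n_samples, thin = thin, n_chains = n_chains)
    } else {
      idx <- if (nrow(data$patterns) == n_samples) seq_len(n_samples)
             else sample.int(nrow(data$patterns), n_samples, replace = TRUE)
      sample_clamped(net, data$patterns[idx, , drop = FALSE])
    }
  })
  n <- nrow(samples[[1]])
  means <- lapply(samples, colMeans)
  coinc <- lapply(seq_len(n_layers(net) - 1), function(l) {
    crossprod(samples[[l]], samples[[l + 1]]) / n
  })
  structure(list(mean = means, coincidence = coinc, n_samples = n,
                 source = mode, low_n = n < 100),
            class = "activity_stats")
}

## Parameter index table for the full FIM of an enumerable network:
## live weights (pair by pair, column-major within each pair), then biases
## layer by layer.
fim_param_table <- function(net) {
  rows <- list()
  for (l in seq_len(n_layers(net) - 1)) {
    live <- which(net$masks[[l]] == 1, arr.ind = TRUE)
    if (nrow(live) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        type = "weight", pair = l, layer = NA_integer_,
        i = live[, 1], j = live[, 2]
      )
    }
  }
  for (l in seq_len(n_layers(net))) {
    rows[[length(rows) + 1]] <- data.frame(
      type = "bias", pair = NA_integer_, layer = l,
      i = seq_len(net$layers[l]), j = NA_integer_
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact Fisher information matrix by enumeration
#'
#' Computes every FIM entry in covariance form: for each parameter the
#' sufficient statistic is the product of the adjacent unit states
#' (`v_i h_j` for a weight, the unit state itself for a bias), and
#' `F[a, b] = <x_a x_b> - <x_a><x_b>` under the exact model distribution.
#' Only live (unmasked) weights are scored. The result is symmetric and
#' positive semi-definite up to numerical error.
#'
#' @param net an enumerable [boltzmann_net()] (at most 24 units).
#' @return list with `F` (matrix), `params` (index table: type, layer pair,
#'   i, j per row/column of `F`).
#' @export
fim_exact <- function(net) {
  d <- exact_distribution(net)
  params <- fim_param_table(net)
  n_states <- nrow(d$states)
  G <- matrix(0, n_states, nrow(params))
  for (r in seq_len(nrow(params))) {
    if (params$type[r] == "weight") {
      l <- params$pair[r]
      G[, r] <- d$layer_blocks[[l]][, params$i[r]] *
        d$layer_blocks[[l + 1]][, params$j[r]]
    } else {
      G[, r] <- d$layer_blocks[[params$layer[r]]][, params$i[r]]
    }
  }
  m <- as.numeric(crossprod(G, d$prob))
  F_mat <- crossprod(G, G * d$prob) - tcrossprod(m)
  F_mat <- (F_mat + t(F_mat)) / 2
  list(F = F_mat, params = params)
}

new_importance <- function(values, criterion, bias_values = NULL) {
  structure(list(values = values, bias_values = bias_values,
                 criterion = criterion),
            class = "importance_estimate")
}

#' @export
print.importance_estimate <- function(x, ...) {
  n <- sum(vapply(x$values, function(v) sum(!is.na(v)), numeric(1)))
  cat(sprintf("<importance_estimate> criterion '%s', %d scored weights\n",
              x$criterion, n))
  invisible(x)
}

#' Variance estimate of the Fisher information diagonal
#'
#' The diagonal FIM entry of a weight reduces to a Bernoulli variance of the
#' pre-post coincidence, `F_w = <vh>(1 - <vh>)`, because unit activations
#' are binary. Bias importances are the firing-rate variances
#' `<x>(1 - <x>)`. These quantities are locally available to each synapse
#' and neuron.
#'
#' @param stats an `activity_stats` object from [collect_stats()].
#' @param net the [boltzmann_net()] the statistics were collected from (for
#'   mask congruence); masked weights are reported as `NA`.
#' @return an `importance_estimate` with `values` (list of matrices per
#'   layer pair, `NA` at masked entries) and `bias_values` (list per layer).
#' @export
fim_diag_variance <- function(stats, net) {
  stopifnot(inherits(stats, "activity_stats"))
  vals <- lapply(seq_len(n_layers(net) - 1), function(l) {
    co <- stats$coincidence[[l]]
    if (!all(dim(co) == dim(net$weights[[l]]))) {
      stop("statistics do not match the network shape", call. = FALSE)
    }
    v <- co * (1 - co)
    v[net$masks[[l]] == 0] <- NA_real_
    v
  })
  bias_vals <- lapply(stats$mean, function(m) m * (1 - m))
  new_importance(vals, "variance_fi", bias_vals)
}

#' Mean-field heuristic for the pre-post coincidence
#'
#' Approximates `<vh>` from the synaptic weight and the two units' mean
#' firing rates alone:
#' `<vh> ~ <v><h> / (<v> + (1 - <v>) exp(-w (1 - <h>)))`.
#' At `w = 0` this reduces exactly to the independence value `<v><h>`.
#' Rates are clipped to `[1e-6, 1 - 1e-6]` so the implicit log-odds
#' inversion stays defined at the boundaries, where the expression
#' degenerates to the independence value.
#'
#' @param w weight value(s); recycled against the rates.
#' @param mean_v presynaptic mean rate(s) in `[0, 1]`.
#' @param mean_h postsynaptic mean rate(s) in `[0, 1]`.
#' @return approximate coincidence rate(s), same shape as the broadcast input.
#' @export
heuristic_coincidence <- function(w, mean_v, mean_h) {
  v <- pmin(pmax(mean_v, 1e-6), 1 - 1e-6)
  h <- pmin(pmax(mean_h, 1e-6), 1 - 1e-6)
  v * h / (v + (1 - v) * exp(-w * (1 - h)))
}

#' Heuristic Fisher information importance for all weights
#'
#' Plugs the mean-field coincidence of [heuristic_coincidence()] into the
#' Bernoulli variance `c(1-c)`, giving a weight-importance estimate that a
#' synapse could compute from its own weight and the mean rates of the two
#' neurons it connects.
#'
#' @param net a [boltzmann_net()].
#' @param stats an `activity_stats` (only the layer means are used).
#' @return an `importance_estimate` (criterion `"heuristic_fi"`).
#' @export
heuristic_importance <- function(net, stats) {
  vals <- lapply(seq_len(n_layers(net) - 1), function(l) {
    co <- heuristic_coincidence(
      net$weights[[l]],
      matrix(stats$mean[[l]], net$layers[l], net$layers[l + 1]),
      matrix(stats$mean[[l + 1]], net$layers[l], net$layers[l + 1], byrow = TRUE)
    )
    v <- co * (1 - co)
    v[net$masks[[l]] == 0] <- NA_real_
    v
  })
  bias_vals <- lapply(stats$mean, function(m) m * (1 - m))
  new_importance(vals, "heuristic_fi", bias_vals)
}

#' Importance from the leading eigenvector of the FIM
#'
#' When the FIM is dominated by its largest eigenvalue it is approximately
#' the rank-1 outer product of its leading eigenvector `u`, so the diagonal
#' is proportional to `u^2` and the magnitude `|u|` assigned to each
#' parameter measures its importance.
#'
#' @param fim result of [fim_exact()] (or a list with symmetric `F` and
#'   `params`).
#' @return list with `importance` (an `importance_estimate` over weights,
#'   criterion `"first_eigenvector"`), `bias_importance` (named by layer),
#'   `lambda` (two leading eigenvalues), and `u` (the leading eigenvector).
#' @export
leading_eigen_importance <- function(fim) {
  F_mat <- fim$F
  if (max(abs(F_mat - t(F_mat))) > 1e-8) {
    stop("FIM must be symmetric", call. = FALSE)
  }
  eg <- eigen((F_mat + t(F_mat)) / 2, symmetric = TRUE)
  u <- eg$vectors[, 1]
  imp <- abs(u)
  params <- fim$params
  # scatter the weight entries back into per-pair matrices
  pairs <- sort(unique(params$pair[params$type == "weight"]))
  vals <- lapply(pairs, function(l) {
    rows <- params$type == "weight" & params$pair == l
    m <- matrix(NA_real_, max(params$i[rows]), max(params$j[rows]))
    m[cbind(params$i[rows], params$j[rows])] <- imp[rows]
    m
  })
  bias_vals <- lapply(sort(unique(params$layer[params$type == "bias"])), function(l) {
    rows <- params$type == "bias" & params$layer == l
    imp[rows][order(params$i[rows])]
  })
  list(
    importance = new_importance(vals, "first_eigenvector", bias_vals),
    lambda = eg$values[1:2],
    u = u
  )
}

#' Score all weights under a named pruning criterion
#'
#' Dispatcher used by the pruning loop. FI-based criteria use activity
#' statistics; `weight_magnitude` uses `|w|`; `anti_fi` negates the variance
#' FI ranking so the *most* important weights are removed first;
#' `random_weight` assigns i.i.d. uniform scores.
#'
#' @param net a [boltzmann_net()].
#' @param criterion one of `"variance_fi"`, `"heuristic_fi"`,
#'   `"first_eigenvector"`, `"weight_magnitude"`, `"anti_fi"`,
#'   `"random_weight"`.
#' @param stats an `activity_stats` (required for the FI criteria).
#' @param seed seed for `random_weight`.
#' @return an `importance_estimate`.
#' @export
weight_importance <- function(net, criterion, stats = NULL, seed = NULL) {
  masked_na <- function(vals) {
    lapply(seq_along(vals), function(l) {
      v <- vals[[l]]
      v[net$masks[[l]] == 0] <- NA_real_
      v
    })
  }
  switch(criterion,
    variance_fi = fim_diag_variance(stats, net),
    heuristic_fi = heuristic_importance(net, stats),
    first_eigenvector = leading_eigen_importance(fim_exact(net))$importance,
    weight_magnitude = new_importance(masked_na(lapply(net$weights, abs)),
                                      "weight_magnitude"),
    anti_fi = {
      base <- fim_diag_variance(stats, net)
      new_importance(lapply(base$values, function(v) -v), "anti_fi",
                     base$bias_values)
    },
    random_weight = with_seed(seed, new_importance(
      masked_na(lapply(net$weights, function(w) {
        matrix(stats::runif(length(w)), nrow(w), ncol(w))
      })), "random_weight")),
    stop(sprintf("unknown criterion '%s'", criterion), call. = FALSE)
  )
}

#' Export an importance estimate as a tidy table
#'
#' @param imp an `importance_estimate`.
#' @return data.frame with columns `layer_pair`, `i`, `j`, `criterion`,
#'   `value` (live weights only).
#' @export
importance_table <- function(imp) {
  out <- lapply(seq_along(imp$values), function(l) {
    v <- imp$values[[l]]
    live <- which(!is.na(v), arr.ind = TRUE)
    data.frame(layer_pair = l, i = live[, 1], j = live[, 2],
               criterion = imp$criterion, value = v[live])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
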