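#' Training configuration
#'
#' Bundles every tunable of the contrastive-divergence and mean-field
#' training procedures. The defaults mirror the single-layer patch
#' experiments: CD-1, 2 epochs, learning rate decaying logarithmically from
#' 0.1 to 0.01, momentum 0.9, per-instance updates, Gaussian weight
#' initialisation with sd 0.1, hidden biases -2 (to encourage sparse hidden
#' activity) and data-driven visible biases `log[p/(1-p)]`.
#'
#' @param k number of contrastive-divergence Gibbs steps (>= 1).
#' @param epochs training epochs.
#' @param lr_start,lr_end learning-rate schedule endpoints; the rate decays
#'   on a logarithmic scale across epochs.
#' @param momentum momentum after the switch epoch.
#' @param momentum_start initial momentum (used until `momentum_switch`).
#' @param momentum_switch epoch at which momentum switches to `momentum`.
#' @param batch_size minibatch size (1 = per-instance updates).
#' @param weight_init_sd sd of the Gaussian weight initialisation.
#' @param visible_bias_init `"data"` for the log-odds rule, or a number.
#' @param hidden_bias_init initial hidden-bias value.
#' @param weight_norm_cap optional cap on the spectral norm of each weight
#'   matrix (applied after every update); `NULL` disables it.
#' @param n_persistent_chains persistent Markov chains for [pcd_train()].
#' @param mf_damping damping coefficient in (0, 1] for mean-field updates.
#' @param mf_tol,mf_max_iter mean-field fixed-point stopping rule.
#' @param pcd_gibbs_steps Gibbs sweeps applied to the persistent chains per
#'   parameter update.
#' @param seed integer seed controlling all training randomness.
#' @return list of class `train_config`.
#' @export
train_config <- function(k = 1, epochs = 2, lr_start = 0.1, lr_end = 0.01,
                         momentum = 0.9, momentum_start = NULL,
                         momentum_switch = 5, batch_size = 1,
                         weight_init_sd = 0.1, visible_bias_init = "data",
                         hidden_bias_init = -2, weight_norm_cap = NULL,
                         n_persistent_chains = 100, mf_damping = 0.8,
                         mf_tol = 1e-5, mf_max_iter = 100,
                         pcd_gibbs_steps = 5, seed = NULL) {
  stopifnot(k >= 1, lr_start > 0, lr_end > 0, epochs >= 0,
            momentum >= 0, momentum < 1, batch_size >= 1,
            mf_damping > 0, mf_damping <= 1)
  structure(as.list(environment()), class = "train_config")
}

lr_schedule <- function(cfg, epoch) {
  if (cfg$epochs <= 1) return(cfg$lr_start)
  exp(seq(log(cfg$lr_start), log(cfg$lr_end), length.out = cfg$epochs))[epoch]
}

momentum_at <- function(cfg, epoch) {
  if (is.null(cfg$momentum_start) || epoch >= cfg$momentum_switch) cfg$momentum
  else cfg$momentum_start
}

zero_velocity <- function(net) {
  list(
    weights = lapply(net$weights, function(w) w * 0),
    biases = lapply(net$biases, function(b) b * 0)
  )
}

cap_weight_norm <- function(net, cap) {
  if (is.null(cap)) return(net)
  for (l in seq_along(net$weights)) {
    s <- norm(net$weights[[l]], type = "2")
    if (s > cap) net$weights[[l]] <- net$weights[[l]] * (cap / s)
  }
  net
}

apply_update <- function(net, velocity, grads, lr, momentum) {
  for (l in seq_along(net$weights)) {
    velocity$weights[[l]] <- momentum * velocity$weights[[l]] +
      lr * grads$weights[[l]] * net$masks[[l]]
    net$weights[[l]] <- (net$weights[[l]] + velocity$weights[[l]]) * net$masks[[l]]
  }
  for (l in seq_along(net$biases)) {
    velocity$biases[[l]] <- momentum * velocity$biases[[l]] + lr * grads$biases[[l]]
    net$biases[[l]] <- net$biases[[l]] + velocity$biases[[l]]
  }
  list(net = net, velocity = velocity)
}

## One CD-k gradient estimate on a batch. Sampling order (relevant for
## reproducibility): h0 ~ Bern(p(h|v0)); then k times v ~ Bern(p(v|h)),
## h ~ Bern(p(h|v)) except the final hidden update keeps the probability.
cd_gradient <- function(net, v0, k) {
  n <- nrow(v0)
  ph0 <- sigmoid(matrix(net$biases[[2]], n, net$layers[2], byrow = TRUE) +
                   v0 %*% net$weights[[1]])
  h <- sample_bernoulli(ph0)
  for (step in seq_len(k)) {
    pv <- sigmoid(matrix(net$biases[[1]], n, net$layers[1], byrow = TRUE) +
                    tcrossprod(h, net$weights[[1]]))
    v <- sample_bernoulli(pv)
    ph <- sigmoid(matrix(net$biases[[2]], n, net$layers[2], byrow = TRUE) +
                    v %*% net$weights[[1]])
    if (step < k) h <- sample_bernoulli(ph)
  }
  list(
    weights = list((crossprod(v0, ph0) - crossprod(v, ph)) / n),
    biases = list(colMeans(v0) - colMeans(v), colMeans(ph0) - colMeans(ph)),
    reconstruction = v
  )
}

#' One contrastive-divergence parameter update
#'
#' Estimates the likelihood gradient as the difference between the data
#' statistics `<v h>` and the statistics of a k-step Gibbs reconstruction
#' started from the data, then applies a learning-rate/momentum update.
#' Masked weight entries receive no update and stay exactly zero.
#'
#' @param net a two-layer [boltzmann_net()].
#' @param batch a [binary_dataset()] or {0,1} matrix of visible patterns.
#' @param cfg a [train_config()].
#' @param lr,momentum override the schedule (used by [train_rbm()]).
#' @param velocity optional momentum state from a previous call.
#' @param seed integer seed for the stochastic reconstruction.
#' @return list with the updated `net` and `velocity`.
#' @export
cd_update <- function(net, batch, cfg = train_config(), lr = NULL,
                      momentum = NULL, velocity = NULL, seed = NULL) {
  if (n_layers(net) != 2) stop("cd_update expects a single RBM pair", call. = FALSE)
  v0 <- if (inherits(batch, "binary_dataset")) batch$patterns else as.matrix(batch)
  if (ncol(v0) != net$layers[1]) stop("batch width does not match the visible layer",
                                      call. = FALSE)
  lr <- lr %||% cfg$lr_start
  momentum <- momentum %||% cfg$momentum
  velocity <- velocity %||% zero_velocity(net)
  grads <- with_seed(seed, cd_gradient(net, v0, cfg$k))
  upd <- apply_update(net, velocity, grads, lr, momentum)
  upd$net <- cap_weight_norm(upd$net, cfg$weight_norm_cap)
  upd
}

init_rbm <- function(data, n_hidden, cfg, mask = NULL) {
  n_v <- ncol(data$patterns)
  bv <- if (identical(cfg$visible_bias_init, "data")) {
    p <- pmin(pmax(colMeans(data$patterns), 1e-3), 1 - 1e-3)
    logit(p)
  } else {
    rep(cfg$visible_bias_init, n_v)
  }
  boltzmann_net(
    c(n_v, n_hidden),
    biases = list(bv, rep(cfg$hidden_bias_init, n_hidden)),
    masks = if (is.null(mask)) NULL else list(mask),
    weight_init_sd = cfg$weight_init_sd,
    seed = sub_seed(cfg$seed %||% 0L, "init")
  )
}

#' Train an RBM with k-step contrastive divergence
#'
#' Runs `cfg$epochs` passes over the data with per-instance (or minibatch)
#' CD-k updates, a logarithmically decaying learning rate and momentum.
#' Training is bit-reproducible given `(seed, config, data)`.
#'
#' @param data a [binary_dataset()].
#' @param n_hidden hidden layer size (ignored when `net` is supplied).
#' @param cfg a [train_config()].
#' @param net optional pre-built [boltzmann_net()] to continue training.
#' @param mask optional {0,1} connectivity matrix for a fresh network.
#' @return the trained [boltzmann_net()], with a `log` attribute holding a
#'   data.frame (epoch, reconstruction error, mean hidden activation).
#' @export
train_rbm <- function(data, n_hidden = NULL, cfg = train_config(), net = NULL,
                      mask = NULL) {
  stopifnot(inherits(data, "binary_dataset"))
  if (is.null(net)) net <- init_rbm(data, n_hidden, cfg, mask)
  n <- nrow(data$patterns)
  velocity <- zero_velocity(net)
  log_rows <- list()
  with_seed(sub_seed(cfg$seed %||% 0L, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_schedule(cfg, epoch)
      mom <- momentum_at(cfg, epoch)
      ord <- sample.int(n)
      recon_err <- 0
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        v0 <- data$patterns[idx, , drop = FALSE]
        grads <- cd_gradient(net, v0, cfg$k)
        upd <- apply_update(net, velocity, grads, lr, mom)
        net <- cap_weight_norm(upd$net, cfg$weight_norm_cap)
        velocity <- upd$velocity
        recon_err <- recon_err + sum((v0 - grads$reconstruction)^2)
      }
      ph <- sigmoid(matrix(net$biases[[2]], n, net$layers[2], byrow = TRUE) +
                      data$patterns %*% net$weights[[1]])
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        reconstruction_error = recon_err / (n * net$layers[1]),
        mean_hidden_activation = mean(ph)
      )
    }
  })
  attr(net, "log") <- do.call(rbind, log_rows)
  net
}

#' Pretrain a two-RBM stack and merge it into a deep network
#'
#' Trains a first RBM (optionally with a receptive-field mask) on the data,
#' samples its hidden layer with the visible layer clamped to each training
#' instance, trains a second RBM on those binary codes, and merges the two
#' into a three-layer network. The shared layer's bias is the average of the
#' first RBM's hidden bias and the second RBM's visible bias.
#'
#' @param data a [binary_dataset()].
#' @param n_hidden integer vector `c(n_h1, n_h2)`.
#' @param cfg1,cfg2 [train_config()]s for the two RBMs.
#' @param mask1 optional {0,1} connectivity for the first weight matrix,
#'   e.g. from [receptive_field_mask()].
#' @return a three-layer [boltzmann_net()].
#' @export
pretrain_stack <- function(data, n_hidden, cfg1 = train_config(),
                           cfg2 = train_config(), mask1 = NULL) {
  stopifnot(length(n_hidden) == 2)
  rbm1 <- train_rbm(data, n_hidden[1], cfg1, mask = mask1)
  codes <- with_seed(sub_seed(cfg1$seed %||% 0L, "codes"), {
    sample_clamped(rbm1, data$patterns)[[2]]
  })
  code_data <- binary_dataset(codes)
  rbm2 <- train_rbm(code_data, n_hidden[2], cfg2)
  boltzmann_net(
    c(ncol(data$patterns), n_hidden),
    weights = list(rbm1$weights[[1]], rbm2$weights[[1]]),
    biases = list(rbm1$biases[[1]],
                  (rbm1$biases[[2]] + rbm2$biases[[1]]) / 2,
                  rbm2$biases[[2]]),
    masks = list(rbm1$masks[[1]], rbm2$masks[[1]])
  )
}

#' Mean-field inference of hidden activations
#'
#' Damped fixed-point iteration of the layer means
#' `mu_l = sigmoid(b_l + masked-weighted input of adjacent means)` with the
#' visible layer clamped, until the largest absolute change falls below
#' `tol` or `max_iter` sweeps. The fixed point does not depend on the
#' damping coefficient; damping only stabilises the iteration.
#'
#' @param net a [boltzmann_net()] with at least one hidden layer.
#' @param v clamped visible pattern(s): vector or matrix (rows = instances).
#' @param tol convergence tolerance on the means.
#' @param max_iter maximum sweeps; non-convergence is flagged, not an error.
#' @param damping damping coefficient in (0, 1]; 1 = undamped.
#' @return list with `mu` (list of mean matrices per layer, the visible one
#'   being the clamped data), `converged`, `iterations`.
#' @export
mean_field_infer <- function(net, v, tol = 1e-5, max_iter = 100, damping = 0.8) {
  v <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  n <- nrow(v)
  L <- n_layers(net)
  mu <- c(list(v), lapply(net$layers[-1], function(sz) matrix(0.5, n, sz)))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    delta <- 0
    for (l in 2:L) {
      target <- layer_conditional(net, l, mu)
      new_mu <- damping * target + (1 - damping) * mu[[l]]
      delta <- max(delta, max(abs(new_mu - mu[[l]])))
      mu[[l]] <- new_mu
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  list(mu = mu, converged = converged, iterations = iter)
}

#' Joint deep-network training with persistent chains
#'
#' Mean-field variational training: the positive phase replaces hidden
#' samples by their mean-field expectations with the visible layer clamped
#' to the data; the negative phase draws model statistics from
#' `n_persistent_chains` free-running Gibbs chains that persist across
#' updates. After every update each weight matrix's spectral norm is capped
#' at `cfg$weight_norm_cap` (when set) to prevent extreme values.
#'
#' @param net a three-layer [boltzmann_net()] (e.g. from [pretrain_stack()]).
#' @param data a [binary_dataset()].
#' @param cfg a [train_config()]; `batch_size`, `epochs`, the learning-rate
#'   and momentum schedules, `mf_damping` and `weight_norm_cap` apply.
#' @return the trained [boltzmann_net()] with a `log` attribute.
#' @export
pcd_train <- function(net, data, cfg = train_config()) {
  n <- nrow(data$patterns)
  velocity <- zero_velocity(net)
  log_rows <- list()
  with_seed(sub_seed(cfg$seed %||% 0L, "pcd"), {
    chains <- random_states(net, cfg$n_persistent_chains)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_schedule(cfg, epoch)
      mom <- momentum_at(cfg, epoch)
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        v0 <- data$patterns[idx, , drop = FALSE]
        mf <- mean_field_infer(net, v0, tol = cfg$mf_tol,
                               max_iter = cfg$mf_max_iter,
                               damping = cfg$mf_damping)
        for (g in seq_len(cfg$pcd_gibbs_steps)) {
          chains <- gibbs_sweep(net, chains)
        }
        nb <- length(idx)
        nc <- cfg$n_persistent_chains
        grads <- list(
          weights = lapply(seq_len(n_layers(net) - 1), function(l) {
            crossprod(mf$mu[[l]], mf$mu[[l + 1]]) / nb -
              crossprod(chains[[l]], chains[[l + 1]]) / nc
          }),
          biases = lapply(seq_len(n_layers(net)), function(l) {
            colMeans(mf$mu[[l]]) - colMeans(chains[[l]])
          })
        )
        upd <- apply_update(net, velocity, grads, lr, mom)
        net <- cap_weight_norm(upd$net, cfg$weight_norm_cap)
        velocity <- upd$velocity
      }
      mf_all <- mean_field_infer(net, data$patterns, tol = cfg$mf_tol,
                                 max_iter = cfg$mf_max_iter,
                                 damping = cfg$mf_damping)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        mean_h1_activation = mean(mf_all$mu[[2]]),
        mean_h2_activation = if (n_layers(net) > 2) mean(mf_all$mu[[3]]) else NA_real_
      )
    }
  })
  attr(net, "log") <- do.call(rbind, log_rows)
  net
}
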