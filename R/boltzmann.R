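#' Construct a masked Bernoulli Boltzmann machine
#'
#' Represents a restricted Boltzmann machine (two layers) or a deep
#' Boltzmann machine (three layers) with binary units, symmetric weights
#' between consecutive layers, per-layer biases, and a {0,1} mask congruent
#' to each weight matrix. Pruning edits masks; masked entries of the stored
#' weights are kept at exactly zero so they never contribute to energies,
#' conditionals, or gradients.
#'
#' @param layers integer vector of layer sizes, visible first; length 2 or 3.
#' @param weights optional list of weight matrices `W[[l]]` of shape
#'   `(layers[l], layers[l+1])`; default Gaussian `N(0, weight_init_sd^2)`.
#' @param biases optional list of bias vectors per layer; default zeros.
#' @param masks optional list of {0,1} matrices congruent to `weights`;
#'   default all ones (full connectivity).
#' @param weight_init_sd standard deviation for the default weight draw.
#' @param seed integer seed for the default weight draw.
#' @return an object of class `boltzmann_net`.
#' @export
boltzmann_net <- function(layers, weights = NULL, biases = NULL, masks = NULL,
                          weight_init_sd = 0.1, seed = NULL) {
  layers <- as.integer(layers)
  if (length(layers) < 2 || length(layers) > 3) {
    stop("supported networks have one visible and one or two hidden layers",
         call. = FALSE)
  }
  if (any(layers < 1)) stop("layer sizes must be positive", call. = FALSE)
  np <- length(layers) - 1
  if (is.null(masks)) {
    masks <- lapply(seq_len(np), function(l) matrix(1, layers[l], layers[l + 1]))
  }
  if (is.null(weights)) {
    weights <- with_seed(seed, lapply(seq_len(np), function(l) {
      matrix(stats::rnorm(layers[l] * layers[l + 1], 0, weight_init_sd),
             layers[l], layers[l + 1])
    }))
  }
  if (is.null(biases)) biases <- lapply(layers, function(n) rep(0, n))
  biases <- lapply(biases, as.numeric)
  for (l in seq_len(np)) {
    weights[[l]] <- as.matrix(weights[[l]])
    masks[[l]] <- as.matrix(masks[[l]])
    if (!all(dim(weights[[l]]) == c(layers[l], layers[l + 1])) ||
        !all(dim(masks[[l]]) == c(layers[l], layers[l + 1]))) {
      stop("weight/mask shapes must chain consistently across layers",
           call. = FALSE)
    }
    stop_if_not_binary(masks[[l]], "masks")
    weights[[l]] <- weights[[l]] * masks[[l]]
  }
  for (l in seq_along(layers)) {
    if (length(biases[[l]]) != layers[l]) {
      stop("bias lengths must match layer sizes", call. = FALSE)
    }
  }
  structure(
    list(layers = layers, weights = weights, biases = biases, masks = masks),
    class = "boltzmann_net"
  )
}

#' @export
print.boltzmann_net <- function(x, ...) {
  nw <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<boltzmann_net> layers [%s], live weights [%s]\n",
              paste(x$layers, collapse = ", "),
              paste(format(nw, trim = TRUE), collapse = ", ")))
  invisible(x)
}

n_layers <- function(net) length(net$layers)

#' Number of live (unmasked) weights
#'
#' @param net a [boltzmann_net()].
#' @param pair optional layer-pair index; default sums over all pairs.
#' @return integer count.
#' @export
n_live_weights <- function(net, pair = NULL) {
  if (is.null(pair)) sum(vapply(net$masks, sum, numeric(1)))
  else sum(net$masks[[pair]])
}

check_state <- function(net, state) {
  if (!is.list(state) || length(state) != n_layers(net)) {
    stop("state must supply one binary vector per layer", call. = FALSE)
  }
  for (l in seq_along(state)) {
    if (length(state[[l]]) != net$layers[l]) {
      stop("state/layer size mismatch", call. = FALSE)
    }
    stop_if_not_binary(state[[l]], "state")
  }
  invisible(TRUE)
}

#' Energy of a network state
#'
#' `E = - sum_l b_l . s_l - sum_l s_l' W_l s_{l+1}` over consecutive layer
#' pairs, using masked weights. Lower energy means higher probability under
#' the Boltzmann distribution at unit temperature.
#'
#' @param net a [boltzmann_net()].
#' @param state list of {0,1} vectors, one per layer (visible first).
#' @return scalar energy.
#' @export
energy <- function(net, state) {
  check_state(net, state)
  e <- 0
  for (l in seq_along(net$layers)) e <- e - sum(net$biases[[l]] * state[[l]])
  for (l in seq_len(n_layers(net) - 1)) {
    e <- e - as.numeric(state[[l]] %*% net$weights[[l]] %*% state[[l + 1]])
  }
  e
}

## Conditional on-probabilities for layer l given neighbour layer matrices
## (n_chains x size each). `neighbors` is a list indexed like layers; only
## l-1 and l+1 are read.
layer_conditional <- function(net, l, neighbors) {
  n <- if (l > 1) nrow(neighbors[[l - 1]]) else nrow(neighbors[[l + 1]])
  act <- matrix(rep(net$biases[[l]], each = n), n, net$layers[l])
  if (l > 1) {
    if (is.null(neighbors[[l - 1]])) stop("missing neighbor state", call. = FALSE)
    act <- act + neighbors[[l - 1]] %*% net$weights[[l - 1]]
  }
  if (l < n_layers(net)) {
    if (is.null(neighbors[[l + 1]])) stop("missing neighbor state", call. = FALSE)
    act <- act + tcrossprod(neighbors[[l + 1]], net$weights[[l]])
  }
  sigmoid(act)
}

#' Conditional on-probabilities of one layer
#'
#' Element-wise sigmoid of the bias plus masked-weighted input from all
#' adjacent layers. Within a layer, units are conditionally independent
#' given the neighbouring layers; the middle layer of a deep network
#' receives input from both sides.
#'
#' @param net a [boltzmann_net()].
#' @param layer_index which layer to compute (1 = visible).
#' @param neighbor_states list indexed like layers; entries
#'   `layer_index - 1` and `layer_index + 1` must hold {0,1} vectors (others
#'   may be `NULL`).
#' @return numeric vector of on-probabilities for the layer's units.
#' @export
conditional_on <- function(net, layer_index, neighbor_states) {
  nb <- lapply(neighbor_states, function(s) if (is.null(s)) NULL else matrix(s, nrow = 1))
  as.numeric(layer_conditional(net, layer_index, nb))
}

## One full Gibbs sweep over a list of state matrices (n_chains x size).
## Layers at even depth (0-based: visible and second hidden) update first,
## then odd depth, so conditionally-independent blocks update together.
## clamp_visible: keep layer 1 fixed.
gibbs_sweep <- function(net, states, clamp_visible = FALSE) {
  order0 <- seq_along(net$layers)
  evens <- order0[(order0 - 1) %% 2 == 0]
  odds <- order0[(order0 - 1) %% 2 == 1]
  for (l in c(evens, odds)) {
    if (l == 1 && clamp_visible) next
    states[[l]] <- sample_bernoulli(layer_conditional(net, l, states))
  }
  states
}

random_states <- function(net, n_chains) {
  lapply(net$layers, function(sz) {
    matrix((stats::runif(n_chains * sz) < 0.5) * 1, n_chains, sz)
  })
}

#' Run a Gibbs chain and store thinned states
#'
#' Alternating layer-wise resampling from the conditionals, storing every
#' `thin`-th sweep. The default `thin = 200` matches the storage protocol
#' used throughout the package so that consecutive stored states are close
#' to uncorrelated.
#'
#' @param net a [boltzmann_net()].
#' @param init_state optional initial state (list of {0,1} vectors); default
#'   uniform random.
#' @param n_steps number of stored states (>= 1).
#' @param thin Gibbs sweeps between stored states (>= 1).
#' @param seed integer seed.
#' @return list with `layers`: a list of `(n_steps x size)` {0,1} matrices,
#'   one per layer.
#' @export
gibbs_chain <- function(net, init_state = NULL, n_steps = 100, thin = 200,
                        seed = NULL) {
  stopifnot(n_steps >= 1, thin >= 1)
  with_seed(seed, {
    states <- if (is.null(init_state)) {
      random_states(net, 1)
    } else {
      check_state(net, init_state)
      lapply(init_state, function(s) matrix(s, nrow = 1))
    }
    out <- lapply(net$layers, function(sz) matrix(0, n_steps, sz))
    for (t in seq_len(n_steps)) {
      for (s in seq_len(thin)) states <- gibbs_sweep(net, states)
      for (l in seq_along(states)) out[[l]][t, ] <- states[[l]]
    }
    list(layers = out, n_stored = n_steps)
  })
}

## Draw n_samples thinned equilibrium samples using n_chains parallel chains
## (vectorised); returns list of (n_samples x size) matrices. Chains start
## random and are burned in burn_in sweeps. Must be called inside an
## established RNG context (use with_seed at the call site).
sample_states <- function(net, n_samples, thin = 200, n_chains = 100,
                          burn_in = 50) {
  n_chains <- min(n_chains, n_samples)
  states <- random_states(net, n_chains)
  for (s in seq_len(burn_in)) states <- gibbs_sweep(net, states)
  rounds <- ceiling(n_samples / n_chains)
  out <- lapply(net$layers, function(sz) matrix(0, rounds * n_chains, sz))
  for (r in seq_len(rounds)) {
    for (s in seq_len(thin)) states <- gibbs_sweep(net, states)
    idx <- ((r - 1) * n_chains + 1):(r * n_chains)
    for (l in seq_along(states)) out[[l]][idx, ] <- states[[l]]
  }
  lapply(out, function(m) m[seq_len(n_samples), , drop = FALSE])
}

## Sample hidden layers with the visible layer clamped to data rows.
## For an RBM one exact conditional draw suffices; deeper networks run
## `sweeps` Gibbs sweeps over the hidden layers.
sample_clamped <- function(net, patterns, sweeps = 20) {
  n <- nrow(patterns)
  states <- random_states(net, n)
  states[[1]] <- patterns
  if (n_layers(net) == 2) {
    states[[2]] <- sample_bernoulli(layer_conditional(net, 2, states))
  } else {
    for (s in seq_len(sweeps)) states <- gibbs_sweep(net, states, clamp_visible = TRUE)
  }
  states
}

## Enumerate all joint binary states as a matrix (2^n x n), units ordered
## visible-first then hidden layers.
enumerate_states <- function(n) {
  if (n > 24) stop("model too large for exact enumeration (> 24 units)",
                   call. = FALSE)
  i <- 0:(2^n - 1)
  vapply(seq_len(n) - 1L, function(b) bitwAnd(bitwShiftR(i, b), 1L),
         integer(length(i))) * 1
}

split_layers <- function(net, S) {
  bounds <- c(0, cumsum(net$layers))
  lapply(seq_along(net$layers), function(l) {
    S[, (bounds[l] + 1):bounds[l + 1], drop = FALSE]
  })
}

#' Exact Boltzmann distribution by enumeration
#'
#' Enumerates all joint states of a small network (at most 24 units) and
#' returns their exact probabilities `exp(-E)/Z`. This is the oracle used to
#' validate samplers and Fisher-information estimates.
#'
#' @param net a [boltzmann_net()].
#' @return list of class `bm_distribution` with `states` (matrix of joint
#'   {0,1} states, visible units first), per-layer column blocks in
#'   `layer_blocks`, `prob`, `log_prob` and `log_z`.
#' @export
exact_distribution <- function(net) {
  n <- sum(net$layers)
  S <- enumerate_states(n)
  blocks <- split_layers(net, S)
  e <- -(S %*% unlist(net$biases))
  for (l in seq_len(n_layers(net) - 1)) {
    e <- e - rowSums((blocks[[l]] %*% net$weights[[l]]) * blocks[[l + 1]])
  }
  e <- as.numeric(e)
  log_z <- logsumexp(-e)
  lp <- -e - log_z
  structure(
    list(states = S, layer_blocks = blocks, prob = exp(lp), log_prob = lp,
         log_z = log_z, layers = net$layers),
    class = "bm_distribution"
  )
}

#' Exact marginal over visible patterns
#'
#' Sums the exact joint distribution over hidden states, giving `p(v)` for
#' every visible pattern of an enumerable network.
#'
#' @param net a [boltzmann_net()].
#' @return named numeric vector of probabilities; names are the visible
#'   patterns as 0/1 strings, of class `pattern_distribution`.
#' @export
exact_visible_marginal <- function(net) {
  d <- exact_distribution(net)
  keys <- apply(d$layer_blocks[[1]], 1, paste0, collapse = "")
  p <- tapply(d$prob, keys, sum)
  out <- as.numeric(p)
  names(out) <- names(p)
  out <- out[order(names(out))]
  structure(out, class = "pattern_distribution", n_units = net$layers[1],
            n_samples = Inf)
}

#' Analytic visible marginal of a two-layer network
#'
#' For a restricted (two-layer) network the hidden layer can be summed out
#' in closed form, `p(v) ~ exp(b_v . v) prod_j (1 + exp(b_j + v . W_j))`,
#' so the exact visible marginal is tractable whenever the visible layer is
#' enumerable (at most 20 units) regardless of the hidden layer size. This
#' is the preferred evaluation oracle for the small-patch models, free of
#' Monte-Carlo noise.
#'
#' @param net a two-layer [boltzmann_net()] with `layers[1] <= 20`.
#' @return named probability vector of class `pattern_distribution` over all
#'   `2^n_v` visible patterns.
#' @export
rbm_visible_marginal <- function(net) {
  if (n_layers(net) != 2) {
    stop("analytic marginal requires a two-layer network", call. = FALSE)
  }
  if (net$layers[1] > 20) {
    stop("visible layer too large for enumeration (> 20 units)", call. = FALSE)
  }
  V <- enumerate_states(net$layers[1])
  act <- sweep(V %*% net$weights[[1]], 2, net$biases[[2]], "+")
  lp <- as.numeric(V %*% net$biases[[1]]) + rowSums(log1p(exp(act)))
  lp <- lp - logsumexp(lp)
  out <- exp(lp)
  names(out) <- apply(V, 1, paste0, collapse = "")
  out <- out[order(names(out))]
  structure(out, class = "pattern_distribution",
            n_units = net$layers[1], n_samples = Inf)
}

#' Save / load a model checkpoint
#'
#' Checkpoints contain layer sizes, weights, biases, masks and an optional
#' history list, serialised as JSON with 17 significant digits so doubles
#' round-trip exactly.
#'
#' @param net a [boltzmann_net()].
#' @param path file path.
#' @param history optional list stored alongside the parameters.
#' @export
write_checkpoint <- function(net, path, history = NULL) {
  flatten <- function(m) list(dim = dim(m), data = as.numeric(m))
  obj <- list(
    format = "prunebm-checkpoint-v1",
    layers = net$layers,
    weights = lapply(net$weights, flatten),
    biases = net$biases,
    masks = lapply(net$masks, flatten),
    history = history
  )
  json <- jsonlite::toJSON(obj, digits = I(17), null = "null", auto_unbox = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- as.integer(unlist(obj$layers))
  rebuild <- function(x) {
    d <- as.integer(unlist(x$dim))
    matrix(as.numeric(unlist(x$data)), d[1], d[2])
  }
  net <- boltzmann_net(
    layers,
    weights = lapply(obj$weights, rebuild),
    biases = lapply(obj$biases, function(b) as.numeric(unlist(b))),
    masks = lapply(obj$masks, rebuild)
  )
  attr(net, "history") <- obj$history
  net
}
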