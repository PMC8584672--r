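# Small fixture builders shared across test files. Everything is generated
# in code under fixed seeds; no stored fixtures.

tiny_rbm <- function(n_v = 3, n_h = 2, seed = 42, w_sd = 0.8, b_sd = 0.5) {
  with_seed(seed, boltzmann_net(
    c(n_v, n_h),
    weights = list(matrix(rnorm(n_v * n_h, 0, w_sd), n_v, n_h)),
    biases = list(rnorm(n_v, 0, b_sd), rnorm(n_h, 0, b_sd))
  ))
}

tiny_dbm <- function(sizes = c(2, 2, 2), seed = 7, w_sd = 0.6) {
  with_seed(seed, boltzmann_net(
    sizes,
    weights = list(matrix(rnorm(sizes[1] * sizes[2], 0, w_sd), sizes[1], sizes[2]),
                   matrix(rnorm(sizes[2] * sizes[3], 0, w_sd), sizes[2], sizes[3])),
    biases = lapply(sizes, function(n) rnorm(n, 0, 0.3))
  ))
}

# Total-variation distance between an empirical joint-state sample and an
# exact bm_distribution.
tv_to_exact <- function(sample_layers, dist) {
  keys <- apply(do.call(cbind, sample_layers), 1, paste0, collapse = "")
  exact_keys <- apply(dist$states, 1, paste0, collapse = "")
  emp <- table(factor(keys, levels = exact_keys)) / length(keys)
  sum(abs(as.numeric(emp) - dist$prob)) / 2
}

# Exact pre-post coincidences straight from the enumerated distribution,
# written independently of collect_stats.
exact_coincidence <- function(net, pair = 1) {
  d <- exact_distribution(net)
  crossprod(d$layer_blocks[[pair]] * d$prob, d$layer_blocks[[pair + 1]])
}
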