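#' Empirical distribution over binary patterns
#'
#' Normalised frequency of each distinct pattern, keyed by its 0/1 string.
#'
#' @param patterns {0,1} matrix (rows = samples) or a [binary_dataset()].
#' @return named numeric vector of class `pattern_distribution` with an
#'   `n_samples` attribute.
#' @export
empirical_distribution <- function(patterns) {
  if (inherits(patterns, "binary_dataset")) patterns <- patterns$patterns
  keys <- apply(patterns, 1, paste0, collapse = "")
  tab <- table(keys)
  out <- as.numeric(tab) / length(keys)
  names(out) <- names(tab)
  structure(out, class = "pattern_distribution",
            n_units = ncol(patterns), n_samples = nrow(patterns))
}

default_epsilon <- function(model_dist) {
  n <- attr(model_dist, "n_samples")
  if (is.null(n) || !is.finite(n)) 1e-6 else 1 / (10 * n)
}

align_support <- function(p, q) {
  keys <- union(names(p), names(q))
  list(
    p = stats::setNames(ifelse(keys %in% names(p), p[keys], 0), keys),
    q = stats::setNames(ifelse(keys %in% names(q), q[keys], 0), keys)
  )
}

#' Kullback-Leibler divergence from data to model
#'
#' `D_KL(data || model) = sum_x p(x) log(p(x)/q(x))` over the union support,
#' with model-side probabilities floored at `epsilon` and renormalised so
#' patterns the model never generated contribute a finite, sample-size-aware
#' penalty.
#'
#' @param data_dist,model_dist `pattern_distribution` objects (or named
#'   probability vectors over pattern strings).
#' @param epsilon model-probability floor; defaults to
#'   `1 / (10 * n_model_samples)`.
#' @return divergence in nats (>= 0 up to the flooring).
#' @export
kl_data_model <- function(data_dist, model_dist, epsilon = NULL) {
  epsilon <- epsilon %||% default_epsilon(model_dist)
  al <- align_support(data_dist, model_dist)
  q <- pmax(al$q, epsilon)
  q <- q / sum(q)
  p <- al$p
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

#' Mean squared error of log-probability matching
#'
#' Mean over data-observed patterns of the squared difference between the
#' data log-probability and the model log-probability, the model side
#' floored at `epsilon` for patterns it never generated.
#'
#' @inheritParams kl_data_model
#' @return mean squared log-probability error (squared nats).
#' @export
logprob_match_mse <- function(data_dist, model_dist, epsilon = NULL) {
  epsilon <- epsilon %||% default_epsilon(model_dist)
  al <- align_support(data_dist, model_dist)
  keep <- al$p > 0
  q <- pmax(al$q[keep], epsilon)
  mean((log(al$p[keep]) - log(q))^2)
}

#' Sample the model and score its generative fit
#'
#' Generates visible patterns by free-running thinned Gibbs sampling and
#' compares their empirical distribution to the data distribution. The
#' default sample count equals the training-set size. The model is never
#' mutated.
#'
#' @param net a [boltzmann_net()].
#' @param data a [binary_dataset()].
#' @param n_samples generated samples; default `nrow(data$patterns)`.
#' @param thin Gibbs sweeps between stored samples.
#' @param n_chains parallel chains.
#' @param epsilon model-probability floor (see [kl_data_model()]).
#' @param seed integer seed.
#' @return list with `kl_data_model` (nats), `logprob_mse` (squared nats),
#'   and the two `pattern_distribution`s.
#' @export
evaluate_generative <- function(net, data, n_samples = NULL, thin = 200,
                                n_chains = 100, epsilon = NULL, seed = NULL) {
  n_samples <- n_samples %||% nrow(data$patterns)
  samples <- with_seed(seed, sample_states(net, n_samples, thin = thin,
                                           n_chains = n_chains))
  data_dist <- empirical_distribution(data)
  model_dist <- empirical_distribution(samples[[1]])
  list(
    kl_data_model = kl_data_model(data_dist, model_dist, epsilon),
    logprob_mse = logprob_match_mse(data_dist, model_dist, epsilon),
    data_dist = data_dist,
    model_dist = model_dist
  )
}

multinom_frame <- function(x, labels = NULL) {
  df <- as.data.frame(x)
  names(df) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(labels)) df$.class <- factor(labels)
  df
}

#' Train the multinomial logistic reference classifier
#'
#' A plain multinomial logistic regression used as a measuring instrument
#' for encoding quality and generated-pattern quality/diversity.
#'
#' @param x feature matrix (rows = samples).
#' @param labels integer class labels.
#' @param max_iter optimiser iteration cap.
#' @return a fitted `nnet::multinom` object (trace suppressed).
#' @export
train_classifier <- function(x, labels, max_iter = 200) {
  df <- multinom_frame(x, labels)
  nnet::multinom(.class ~ ., data = df, maxit = max_iter, trace = FALSE,
                 MaxNWts = 100000)
}

classifier_probs <- function(clf, x) {
  p <- stats::predict(clf, newdata = multinom_frame(x), type = "probs")
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # two-class case
  p
}

#' Encoding quality of the latent representation
#'
#' Samples final-hidden-layer states with the visible layer clamped to each
#' instance, trains a multinomial logistic classifier on a stratified train
#' split of those codes, and reports held-out accuracy. A baseline
#' classifier trained on the raw patterns under the identical protocol is
#' returned alongside.
#'
#' @param net a [boltzmann_net()].
#' @param data a labeled [binary_dataset()].
#' @param train_frac training fraction of the stratified split.
#' @param seed integer seed (sampling of codes and split).
#' @return list with `accuracy`, `baseline_accuracy`, `n_train`, `n_test`.
#' @export
encoding_quality <- function(net, data, train_frac = 0.8, seed = NULL) {
  if (is.null(data$labels)) stop("labeled data required", call. = FALSE)
  labels <- data$labels
  if (length(unique(labels)) < 2) {
    stop("at least two classes are required", call. = FALSE)
  }
  with_seed(seed, {
    codes <- sample_clamped(net, data$patterns)[[n_layers(net)]]
    n <- nrow(codes)
    train_idx <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      sample(idx, max(1, floor(train_frac * length(idx))))
    }), use.names = FALSE)
    test_idx <- setdiff(seq_len(n), train_idx)
    acc <- function(features) {
      clf <- train_classifier(features[train_idx, , drop = FALSE], labels[train_idx])
      pred <- stats::predict(clf, newdata = multinom_frame(features[test_idx, , drop = FALSE]))
      mean(as.integer(as.character(pred)) == labels[test_idx])
    }
    list(
      accuracy = acc(codes),
      baseline_accuracy = acc(data$patterns),
      n_train = length(train_idx),
      n_test = length(test_idx)
    )
  })
}

#' Quality and diversity of generated patterns
#'
#' Generates visible patterns by free-running thinned Gibbs sampling and
#' classifies each with a reference classifier trained on raw labeled data.
#' Quality is the mean winning-class probability (classifier confidence);
#' diversity is the Shannon entropy in nats of the argmax class histogram,
#' with ceiling `ln(n_classes)` for perfectly balanced classes (about 2.30
#' nats for ten classes).
#'
#' @param net a [boltzmann_net()].
#' @param reference_classifier a classifier from [train_classifier()] fitted
#'   on raw patterns.
#' @param n_samples generated samples to score.
#' @param thin,n_chains Gibbs sampling protocol.
#' @param seed integer seed.
#' @return list with `quality_score`, `diversity_entropy`, `class_histogram`,
#'   and `low_n` flag when `n_samples` is below the class count.
#' @export
generative_scores <- function(net, reference_classifier, n_samples = 1000,
                              thin = 200, n_chains = 100, seed = NULL) {
  samples <- with_seed(seed, sample_states(net, n_samples, thin = thin,
                                           n_chains = n_chains))[[1]]
  probs <- classifier_probs(reference_classifier, samples)
  win <- apply(probs, 1, which.max)
  quality <- mean(probs[cbind(seq_len(nrow(probs)), win)])
  list(
    quality_score = quality,
    diversity_entropy = diversity_entropy(win, ncol(probs)),
    class_histogram = table(factor(win, levels = seq_len(ncol(probs)))),
    low_n = n_samples < ncol(probs)
  )
}

#' Shannon entropy of a class-assignment histogram
#'
#' Diversity measure for generated patterns: the entropy (nats) of the
#' distribution of assigned classes. A perfectly balanced assignment over
#' `n_classes` reaches the ceiling `ln(n_classes)` — about 2.30 nats for
#' ten classes. Invariant under relabelling of the classes.
#'
#' @param assignments integer vector of class assignments.
#' @param n_classes total number of classes (defaults to the observed max).
#' @return entropy in nats, in `[0, ln(n_classes)]`.
#' @export
diversity_entropy <- function(assignments, n_classes = max(assignments)) {
  counts <- tabulate(assignments, nbins = n_classes)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mean stimulus-evoked hidden activation
#'
#' Average firing probability of the remaining hidden units when the
#' visible layer is clamped to the data (mean-field for deep networks,
#' exact conditionals for two-layer networks). A rise of this monitor over
#' pruning iterations signals that the model is approaching its optimal
#' size.
#'
#' @param net a [boltzmann_net()].
#' @param data a [binary_dataset()].
#' @return list with `per_unit` (list of per-unit mean activations per
#'   hidden layer) and `per_layer` (scalar means).
#' @export
activation_monitor <- function(net, data) {
  if (n_layers(net) == 2) {
    states <- list(data$patterns, NULL)
    ph <- layer_conditional(net, 2, states)
    mu <- list(ph)
  } else {
    mf <- mean_field_infer(net, data$patterns)
    mu <- mf$mu[-1]
  }
  list(
    per_unit = lapply(mu, colMeans),
    per_layer = vapply(mu, mean, numeric(1))
  )
}
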