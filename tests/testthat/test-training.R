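test_that("a zero learning rate leaves parameters untouched", {
  net <- tiny_rbm(3, 2, seed = 1)
  batch <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3, byrow = TRUE)
  upd <- cd_update(net, batch, train_config(), lr = 0, seed = 5)
  expect_identical(upd$net$weights, net$weights)
  expect_identical(upd$net$biases, net$biases)
})

test_that("one CD-1 update matches a hand-replicated sampled reconstruction", {
  w <- 0.8; bv <- -0.2; bh <- 0.4
  net <- boltzmann_net(c(1, 1), weights = list(matrix(w, 1, 1)),
                       biases = list(bv, bh))
  v0 <- matrix(1, 1, 1)
  lr <- 0.5
  seed <- 123
  # replicate the sampler's draw sequence: h0 then v1; final hidden update
  # keeps the probability
  sig <- function(x) 1 / (1 + exp(-x))
  ph0 <- sig(bh + w * 1)
  draws <- with_seed(seed, runif(2))
  h0 <- as.numeric(draws[1] < ph0)
  pv1 <- sig(bv + w * h0)
  v1 <- as.numeric(draws[2] < pv1)
  ph1 <- sig(bh + w * v1)
  expected_w <- w + lr * (1 * ph0 - v1 * ph1)
  expected_bv <- bv + lr * (1 - v1)
  expected_bh <- bh + lr * (ph0 - ph1)
  upd <- cd_update(net, v0, train_config(k = 1), lr = lr, momentum = 0,
                   seed = seed)
  expect_equal(upd$net$weights[[1]][1, 1], expected_w, tolerance = 1e-12)
  expect_equal(upd$net$biases[[1]], expected_bv, tolerance = 1e-12)
  expect_equal(upd$net$biases[[2]], expected_bh, tolerance = 1e-12)
})

test_that("parameter change is first-order in the learning rate without momentum", {
  net <- tiny_rbm(4, 3, seed = 2)
  batch <- generate_mixture(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), 8,
                            flip_prob = 0.1, seed = 3)$patterns
  d1 <- cd_update(net, batch, train_config(), lr = 1e-4, momentum = 0,
                  seed = 7)$net$weights[[1]] - net$weights[[1]]
  d2 <- cd_update(net, batch, train_config(), lr = 2e-4, momentum = 0,
                  seed = 7)$net$weights[[1]] - net$weights[[1]]
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("masked weights receive no updates during training", {
  mask <- receptive_field_mask(2, 2, 1, 1)  # 1x1 fields: diagonal mask
  data <- generate_mixture(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), 60,
                           flip_prob = 0.1, seed = 4, layout = c(2, 2))
  net <- train_rbm(data, 4, train_config(epochs = 2, seed = 4), mask = mask)
  expect_true(all(net$weights[[1]][mask == 0] == 0))
  expect_true(any(net$weights[[1]][mask == 1] != 0))
})

test_that("training is bit-reproducible given seed, config and data", {
  data <- generate_mixture(rbind(c(1, 0, 1), c(0, 1, 0)), 40,
                           flip_prob = 0.15, seed = 5)
  cfg <- train_config(epochs = 2, seed = 11)
  a <- train_rbm(data, 3, cfg)
  b <- train_rbm(data, 3, cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(a$biases, b$biases)
})

test_that("stacking merges the shared layer by averaging its biases", {
  data <- generate_mixture(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), 50,
                           flip_prob = 0.1, seed = 6, layout = c(2, 2))
  # zero-epoch configs freeze both RBMs at initialisation, so the merged
  # bias is exactly (hidden_init + visible_init) / 2
  cfg1 <- train_config(epochs = 0, hidden_bias_init = -2, seed = 6)
  cfg2 <- train_config(epochs = 0, visible_bias_init = -1,
                       hidden_bias_init = -2, seed = 7)
  dbm <- pretrain_stack(data, c(3, 2), cfg1, cfg2)
  expect_equal(dbm$layers, c(4L, 3L, 2L))
  expect_equal(dbm$biases[[2]], rep((-2 + -1) / 2, 3))
  # a receptive-field mask survives stacking with its connection count
  mask <- receptive_field_mask(2, 2, 1, 1)
  dbm2 <- pretrain_stack(data, c(4, 2), cfg1, cfg2, mask1 = mask)
  expect_equal(sum(dbm2$masks[[1]]), sum(mask))
  # the merged model's energy is the two pairwise terms plus biases
  s <- list(c(1, 0, 1, 0), c(1, 1, 0), c(0, 1))
  manual <- -sum(dbm$biases[[1]] * s[[1]]) - sum(dbm$biases[[2]] * s[[2]]) -
    sum(dbm$biases[[3]] * s[[3]]) -
    as.numeric(s[[1]] %*% dbm$weights[[1]] %*% s[[2]]) -
    as.numeric(s[[2]] %*% dbm$weights[[2]] %*% s[[3]])
  expect_equal(energy(dbm, s), manual)
})

test_that("mean-field inference solves the damped fixed point", {
  # decoupled units converge to sigmoid(bias) immediately
  flat <- tiny_dbm(c(2, 2, 2), seed = 8)
  flat$weights <- lapply(flat$weights, function(w) w * 0)
  mf <- mean_field_infer(flat, c(1, 0), damping = 1)
  expect_equal(as.numeric(mf$mu[[2]]), as.numeric(1 / (1 + exp(-flat$biases[[2]]))),
               tolerance = 1e-12)
  expect_true(mf$converged)

  # 1-1-1 chain: compare against a root-finding oracle for the scalar
  # fixed point mu1 = sigma(b1 + w1 v + w2 * sigma(b2 + w2 mu1))
  w1 <- 1.2; w2 <- -0.7; b1 <- 0.3; b2 <- -0.4; v <- 1
  net <- boltzmann_net(c(1, 1, 1),
                       weights = list(matrix(w1, 1, 1), matrix(w2, 1, 1)),
                       biases = list(0, b1, b2))
  sig <- function(x) 1 / (1 + exp(-x))
  root <- uniroot(function(m) m - sig(b1 + w1 * v + w2 * sig(b2 + w2 * m)),
                  c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  mf <- mean_field_infer(net, v, tol = 1e-12, max_iter = 500, damping = 0.8)
  expect_equal(as.numeric(mf$mu[[2]]), root, tolerance = 1e-8)

  # the fixed point does not depend on the damping coefficient
  for (seed in 1:5) {
    net <- tiny_dbm(c(3, 3, 2), seed = seed)
    v <- with_seed(seed, rbinom(3, 1, 0.5))
    a <- mean_field_infer(net, v, tol = 1e-10, max_iter = 1000, damping = 1)
    b <- mean_field_infer(net, v, tol = 1e-10, max_iter = 1000, damping = 0.8)
    expect_equal(a$mu[[3]], b$mu[[3]], tolerance = 1e-6)
  }

  # non-convergence is flagged, not thrown
  mf <- mean_field_infer(net, v, tol = 0, max_iter = 3)
  expect_false(mf$converged)
})

test_that("persistent-chain training respects null updates and the norm cap", {
  data <- generate_mixture(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), 40,
                           flip_prob = 0.1, seed = 9, layout = c(2, 2))
  dbm <- pretrain_stack(data, c(3, 2), train_config(epochs = 0, seed = 1),
                        train_config(epochs = 0, seed = 2))
  frozen <- pcd_train(dbm, data, train_config(epochs = 1, lr_start = 1e-12,
                                              lr_end = 1e-12, momentum = 0,
                                              n_persistent_chains = 5, seed = 3))
  expect_equal(frozen$weights, dbm$weights, tolerance = 1e-9)
  capped <- pcd_train(dbm, data, train_config(epochs = 2, lr_start = 2,
                                              lr_end = 2, momentum = 0,
                                              weight_norm_cap = 0.7,
                                              n_persistent_chains = 5, seed = 3))
  norms <- vapply(capped$weights, norm, numeric(1), type = "2")
  expect_true(all(norms <= 0.7 + 1e-9))
  expect_equal(max(norms), 0.7, tolerance = 1e-6)
})

test_that("joint training improves the generative fit of a stacked model", {
  protos <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  data <- generate_mixture(protos, 300, flip_prob = 0.05, seed = 10)
  improved <- 0
  for (seed in 1:3) {
    dbm0 <- pretrain_stack(data, c(4, 2),
                           train_config(epochs = 0, seed = seed),
                           train_config(epochs = 0, seed = seed + 50))
    kl0 <- evaluate_generative(dbm0, data, n_samples = 500, thin = 20,
                               seed = seed)$kl_data_model
    dbm <- pcd_train(dbm0, data, train_config(epochs = 10, lr_start = 0.1,
                                              lr_end = 0.02, momentum = 0.5,
                                              batch_size = 10,
                                              weight_norm_cap = 6, seed = seed))
    kl1 <- evaluate_generative(dbm, data, n_samples = 500, thin = 20,
                               seed = seed)$kl_data_model
    improved <- improved + (kl1 < kl0)
  }
  expect_gte(improved, 2)
})
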