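test_that("exact FIM entries match covariance identities", {
  # independent units at zero weights: F_ww = <v><h>(1 - <v><h>)
  net <- boltzmann_net(c(2, 2), weights = list(matrix(0, 2, 2)),
                       biases = list(c(0.4, -0.3), c(0.2, -1)))
  fim <- fim_exact(net)
  st <- collect_stats(net, "exact")
  w_rows <- which(fim$params$type == "weight")
  for (r in w_rows) {
    i <- fim$params$i[r]; j <- fim$params$j[r]
    p <- st$mean[[1]][i] * st$mean[[2]][j]
    expect_equal(fim$F[r, r], p * (1 - p), tolerance = 1e-12)
  }
  # bias-bias cross entries equal <v h> - <v><h> for any parameters
  net2 <- tiny_rbm(2, 2, seed = 3)
  fim2 <- fim_exact(net2)
  st2 <- collect_stats(net2, "exact")
  bv <- which(fim2$params$type == "bias" & fim2$params$layer == 1)
  bh <- which(fim2$params$type == "bias" & fim2$params$layer == 2)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(fim2$F[bv[i], bh[j]],
                 st2$coincidence[[1]][i, j] - st2$mean[[1]][i] * st2$mean[[2]][j],
                 tolerance = 1e-12)
  }
})

test_that("exact FIMs are symmetric positive semi-definite", {
  for (seed in 1:50) {
    fim <- fim_exact(tiny_rbm(2, 2, seed = seed, w_sd = 1.2, b_sd = 0.8))
    expect_equal(fim$F, t(fim$F))
    expect_gt(min(eigen(fim$F, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
  }
})

test_that("the FIM diagonal is the Bernoulli variance of the coincidence", {
  net <- tiny_rbm(3, 2, seed = 4)
  st <- collect_stats(net, "exact")
  imp <- fim_diag_variance(st, net)
  fim <- fim_exact(net)
  w_rows <- which(fim$params$type == "weight")
  expect_equal(
    imp$values[[1]][cbind(fim$params$i[w_rows], fim$params$j[w_rows])],
    diag(fim$F)[w_rows], tolerance = 1e-12
  )
  # a silent presynaptic unit contributes zero importance
  st$coincidence[[1]][1, ] <- 0
  imp0 <- fim_diag_variance(st, net)
  expect_true(all(imp0$values[[1]][1, ] == 0))
  # the variance is maximal at coincidence 1/2
  st$coincidence[[1]][2, 1] <- 0.5
  expect_equal(fim_diag_variance(st, net)$values[[1]][2, 1], 0.25)
})

test_that("importance of masked weights is neither computed nor exported", {
  net <- tiny_rbm(3, 3, seed = 5)
  net$masks[[1]][c(1, 5)] <- 0
  net$weights[[1]] <- net$weights[[1]] * net$masks[[1]]
  st <- collect_stats(net, "exact")
  for (imp in list(fim_diag_variance(st, net), heuristic_importance(net, st))) {
    expect_true(all(is.na(imp$values[[1]][net$masks[[1]] == 0])))
    expect_false(anyNA(imp$values[[1]][net$masks[[1]] == 1]))
    tab <- importance_table(imp)
    expect_equal(nrow(tab), sum(net$masks[[1]]))
  }
})

test_that("the mean-field coincidence heuristic has the right limits", {
  # independence at zero weight, exactly
  expect_identical(heuristic_coincidence(0, 0.3, 0.7), 0.3 * 0.7)
  # saturating weight at half-half rates approaches the postsynaptic rate
  expect_equal(heuristic_coincidence(50, 0.5, 0.5), 0.5, tolerance = 1e-9)
  # boundary rates degenerate to the independence value without error
  expect_equal(heuristic_coincidence(2, 0, 0.4), 0, tolerance = 1e-5)
  expect_equal(heuristic_coincidence(2, 1, 0.4), 0.4, tolerance = 1e-4)
  expect_equal(heuristic_coincidence(-30, 0.5, 0.25), 0, tolerance = 1e-6)
})

test_that("heuristic equals the variance estimate when all weights vanish", {
  net <- boltzmann_net(c(3, 2), weights = list(matrix(0, 3, 2)),
                       biases = list(c(0.5, -0.2, 0), c(-1, 0.3)))
  st <- collect_stats(net, "exact")
  expect_equal(heuristic_importance(net, st)$values,
               fim_diag_variance(st, net)$values, tolerance = 1e-12)
})

test_that("leading-eigenvector importance reports magnitudes and eigenvalues", {
  f <- list(F = diag(c(2, 1)),
            params = data.frame(type = "weight", pair = 1,
                                layer = NA, i = c(1, 1), j = c(1, 2)))
  out <- leading_eigen_importance(f)
  expect_equal(out$lambda, c(2, 1))
  expect_equal(abs(out$u), c(1, 0))
  expect_gt(out$importance$values[[1]][1, 1], out$importance$values[[1]][1, 2])
  expect_error(leading_eigen_importance(list(F = matrix(1:4, 2, 2))),
               "symmetric")
})

test_that("eigenvector importance tracks the diagonal on a trained model", {
  data <- generate_mixture(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), 300,
                           flip_prob = 0.1, seed = 6)
  net <- train_rbm(data, 3, train_config(epochs = 3, seed = 6))
  fim <- fim_exact(net)
  out <- leading_eigen_importance(fim)
  w_rows <- which(fim$params$type == "weight")
  u2 <- (out$u[w_rows])^2
  expect_gt(cor(u2, diag(fim$F)[w_rows], method = "spearman"), 0.9)
})

test_that("sampled statistics respect clamping and flag tiny samples", {
  flat <- boltzmann_net(c(3, 2), weights = list(matrix(0, 3, 2)))
  st <- collect_stats(flat, "free", n_samples = 1e4, thin = 2, seed = 8)
  expect_true(all(abs(unlist(st$mean) - 0.5) < 0.02))
  expect_true(all(abs(st$coincidence[[1]] - 0.25) < 0.02))
  data <- generate_mixture(rbind(c(1, 0, 1), c(0, 1, 0)), 120,
                           flip_prob = 0.2, seed = 9)
  net <- tiny_rbm(3, 2, seed = 9)
  cl <- collect_stats(net, "clamped", data = data, seed = 9)
  expect_equal(cl$mean[[1]], colMeans(data$patterns))
  expect_false(cl$low_n)
  small <- collect_stats(net, "free", n_samples = 50, thin = 1, seed = 1)
  expect_true(small$low_n)
  expect_error(collect_stats(net, "clamped"), "dataset")
})

test_that("exact statistics satisfy the Frechet coincidence bounds", {
  for (seed in 1:10) {
    net <- tiny_rbm(2, 3, seed = seed, w_sd = 1)
    st <- collect_stats(net, "exact")
    co <- st$coincidence[[1]]
    mv <- st$mean[[1]]; mh <- st$mean[[2]]
    lower <- pmax(0, outer(mv, mh, `+`) - 1)
    upper <- outer(mv, mh, pmin)
    expect_true(all(co >= lower - 1e-12))
    expect_true(all(co <= upper + 1e-12))
  }
})

test_that("criterion dispatch covers the documented pruning criteria", {
  net <- tiny_rbm(3, 2, seed = 10)
  st <- collect_stats(net, "exact")
  vfi <- weight_importance(net, "variance_fi", stats = st)
  anti <- weight_importance(net, "anti_fi", stats = st)
  expect_equal(anti$values[[1]], -vfi$values[[1]])
  wm <- weight_importance(net, "weight_magnitude")
  expect_equal(wm$values[[1]], abs(net$weights[[1]]))
  r1 <- weight_importance(net, "random_weight", seed = 2)
  r2 <- weight_importance(net, "random_weight", seed = 2)
  expect_identical(r1$values, r2$values)
  expect_error(weight_importance(net, "nonsense"), "criterion")
})
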