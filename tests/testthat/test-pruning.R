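test_that("percentile pruning keeps the floor of the surviving fraction", {
  mask <- matrix(1, 13, 70)
  imp <- matrix(with_seed(1, runif(13 * 70)), 13, 70)
  half <- threshold_prune(mask, imp, 50)
  expect_equal(sum(half), 455)
  expect_equal(sum(threshold_prune(half, imp, 50)), 227)
  expect_identical(threshold_prune(mask, imp, 0), mask)
  expect_equal(sum(threshold_prune(mask, imp, 100)), 0)
  expect_error(threshold_prune(mask, imp, 101), "percentile")
  # survivors are exactly the highest-importance entries
  kept <- imp[half == 1]
  removed <- imp[half == 0]
  expect_gt(min(kept), max(removed))
})

test_that("ties at the threshold break deterministically by index order", {
  mask <- matrix(1, 4, 4)
  imp <- matrix(1, 4, 4)  # all equal
  pruned <- threshold_prune(mask, imp, 50)
  expect_equal(sum(pruned), 8)
  # lexicographic (row, column) order: rows 1 and 2 go first
  expect_true(all(pruned[1:2, ] == 0))
  expect_true(all(pruned[3:4, ] == 1))
  expect_identical(threshold_prune(mask, imp, 50), pruned)
})

test_that("zero-importance pruning removes all zeros when they dominate", {
  mask <- matrix(1, 10, 10)
  imp <- matrix(runif(100, 0.1, 1), 10, 10)
  imp[1:3, ] <- 0  # 30% zeros
  pruned <- zero_importance_prune(mask, imp, 25)
  expect_equal(sum(pruned == 0), 30)
  expect_true(all(pruned[1:3, ] == 0))
  # with no zeros it falls back to the percentile threshold
  imp2 <- matrix(runif(100, 0.1, 1), 10, 10)
  expect_identical(zero_importance_prune(mask, imp2, 25),
                   threshold_prune(mask, imp2, 25))
})

test_that("dead hidden units are removed and cascades reach a fixed point", {
  # an all-masked incoming column drops that unit
  net <- tiny_rbm(3, 3, seed = 1)
  net$masks[[1]][, 2] <- 0
  net$weights[[1]] <- net$weights[[1]] * net$masks[[1]]
  out <- remove_dead_units(net)
  expect_equal(out$net$layers[2], 2L)
  expect_equal(sum(out$removed), 1)

  # a middle unit with live incoming but all-masked outgoing weights is
  # deleted together with its incoming weights
  dbm <- tiny_dbm(c(2, 3, 2), seed = 2)
  dbm$masks[[2]][2, ] <- 0
  dbm$weights[[2]] <- dbm$weights[[2]] * dbm$masks[[2]]
  before <- n_live_weights(dbm)
  out <- remove_dead_units(dbm)
  expect_equal(out$net$layers[2], 2L)
  expect_lt(n_live_weights(out$net), before)  # extra incoming weights lost

  # cascading: removing a middle unit strands a top unit that only it fed
  dbm <- tiny_dbm(c(2, 2, 2), seed = 3)
  dbm$masks[[1]][, 1] <- 0            # middle unit 1 loses all input
  dbm$masks[[2]][2, 2] <- 0
  dbm$masks[[2]][1, 1] <- 0           # top unit 2 fed only by middle unit 1
  for (l in 1:2) dbm$weights[[l]] <- dbm$weights[[l]] * dbm$masks[[l]]
  out <- remove_dead_units(dbm)
  expect_equal(out$net$layers, c(2L, 1L, 1L))
  # brute-force fixpoint check: no dead unit remains
  m <- out$net$masks
  expect_true(all(colSums(m[[1]]) > 0))
  expect_true(all(rowSums(m[[2]]) > 0))
  expect_true(all(colSums(m[[2]]) > 0))
})

test_that("disconnected visible units are flagged but retained", {
  net <- tiny_rbm(4, 2, seed = 4)
  net$masks[[1]][3, ] <- 0
  net$weights[[1]] <- net$weights[[1]] * net$masks[[1]]
  out <- remove_dead_units(net)
  expect_equal(out$net$layers[1], 4L)
  expect_equal(which(out$disconnected_visible), 3L)
})

test_that("unit budgets match the printed random-unit control counts", {
  expect_equal(match_unit_budget(70, 13, 455), 35L)
  expect_equal(match_unit_budget(35, 13, 227), 18L)
  expect_equal(match_unit_budget(18, 13, 113), 9L)
  expect_equal(match_unit_budget(70, 13, 910), 70L)
  expect_equal(match_unit_budget(10, 5, 500), 10L)  # over-budget saturates
})

test_that("the prune loop tracks the floor-halving weight schedule", {
  data <- generate_mixture(default_patch_prototypes(), 300,
                           flip_prob = 0.05, seed = 5)
  net <- train_rbm(data, 70, train_config(epochs = 1, seed = 5))
  rep <- prune_loop(net, data,
                    prune_config(criterion = "weight_magnitude",
                                 percentile = 50, n_iterations = 3,
                                 retrain_epochs = 1, thin = 20,
                                 eval_n_samples = 300, seed = 5),
                    train_config(seed = 5))
  expect_equal(rep$records$n_w_1, c(455, 227, 113))
  expect_false(rep$stopped_early)
  # weight bookkeeping matches the final network's masks exactly
  expect_equal(rep$records$n_w_1[3], n_live_weights(rep$final_net))
  # unit counts never increase
  expect_true(all(diff(rep$records$n_units_2) <= 0))
})

test_that("random-weight pruning is reproducible and random-unit pruning hits its budget", {
  data <- generate_mixture(default_patch_prototypes(), 200,
                           flip_prob = 0.05, seed = 6)
  net <- train_rbm(data, 20, train_config(epochs = 1, seed = 6))
  cfg <- prune_config(criterion = "random_weight", percentile = 50,
                      n_iterations = 2, retrain_epochs = 0, thin = 10,
                      eval_n_samples = 200, seed = 7)
  a <- prune_loop(net, data, cfg, train_config(seed = 6))
  b <- prune_loop(net, data, cfg, train_config(seed = 6))
  expect_identical(a$final_net$masks, b$final_net$masks)

  cfg$criterion <- "random_unit"
  r <- prune_loop(net, data, cfg, train_config(seed = 6))
  # 260 weights -> keep ceil(130/13) = 10 units, then ceil(65/13) = 5
  expect_equal(r$records$n_units_2, c(10, 5))
  expect_equal(r$records$n_w_1, c(130, 65))
})

test_that("anti-importance removal is the set complement of importance removal", {
  mask <- matrix(1, 6, 5)
  imp <- matrix(with_seed(8, runif(30)), 6, 5)  # no ties
  low <- threshold_prune(mask, imp, 50)
  high <- threshold_prune(mask, -imp, 50)
  expect_true(all(low + high == 1))
})

test_that("pruned weights never return across iterations", {
  data <- generate_mixture(default_patch_prototypes(), 200,
                           flip_prob = 0.05, seed = 9)
  net <- train_rbm(data, 15, train_config(epochs = 1, seed = 9))
  masks <- list()
  cur <- net
  for (iter in 1:3) {
    st <- collect_stats(cur, "free", n_samples = 200, thin = 10,
                        seed = iter)
    imp <- fim_diag_variance(st, cur)
    vals <- imp$values[[1]]; vals[is.na(vals)] <- Inf
    cur$masks[[1]] <- threshold_prune(cur$masks[[1]], vals, 30)
    cur$weights[[1]] <- cur$weights[[1]] * cur$masks[[1]]
    masks[[iter]] <- cur$masks[[1]]
  }
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})
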