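# MLP engine and the hierarchical step-trace-person model.

test_that("backpropagation matches finite-difference gradients", {
  net <- floorgait:::mlp_init(4, c(5, 3), 3, seed = 2)
  withr::with_seed(3, {
    X <- matrix(rnorm(8 * 4), 8, 4)
    y <- sample(1:3, 8, replace = TRUE)
  })
  loss_at <- function(net) {
    floorgait:::cross_entropy(floorgait:::mlp_forward(net, X)$probs, y)
  }
  fwd <- floorgait:::mlp_forward(net, X)
  Y <- matrix(0, 8, 3); Y[cbind(1:8, y)] <- 1
  bwd <- floorgait:::mlp_backward(net, fwd,
                                  grad_logits = (fwd$probs - Y) / 8)
  eps <- 1e-6
  for (l in 1:3) {
    for (k in 1:3) {
      i <- ((k * 7) %% nrow(net$layers[[l]]$W)) + 1
      j <- ((k * 5) %% ncol(net$layers[[l]]$W)) + 1
      plus <- net; plus$layers[[l]]$W[i, j] <- plus$layers[[l]]$W[i, j] + eps
      minus <- net; minus$layers[[l]]$W[i, j] <- minus$layers[[l]]$W[i, j] - eps
      num <- (loss_at(plus) - loss_at(minus)) / (2 * eps)
      expect_equal(bwd$grads[[l]]$W[i, j], num, tolerance = 1e-4)
    }
  }
  # gradient with respect to the input (used for hierarchy fine-tuning)
  i <- 3; j <- 2
  Xp <- X; Xp[i, j] <- Xp[i, j] + eps
  Xm <- X; Xm[i, j] <- Xm[i, j] - eps
  num <- (floorgait:::cross_entropy(floorgait:::mlp_forward(net, Xp)$probs, y) -
          floorgait:::cross_entropy(floorgait:::mlp_forward(net, Xm)$probs, y)) /
    (2 * eps)
  expect_equal(bwd$dX[i, j], num, tolerance = 1e-4)
})

test_that("aggregation and input assembly contracts", {
  expect_equal(aggregate_mean(rbind(c(0, 2), c(2, 0))), c(1, 1))
  expect_equal(aggregate_mean(c(3, 4)), c(3, 4))      # single member
  m <- rbind(c(1, 2), c(5, 6), c(3, 1))
  expect_equal(aggregate_mean(m), aggregate_mean(m[c(3, 1, 2), ]))
  expect_error(aggregate_mean(m[0, ]))

  probs <- rbind(c(0.7, 0.1, 0.05, 0.05, 0.05, 0.05),
                 c(0.2, 0.5, 0.1, 0.1, 0.05, 0.05))
  ti <- build_trace_input(probs, rnorm(14))
  expect_length(ti, 20)
  expect_equal(sum(ti[1:6]), 1)                      # mean of simplex rows
  one <- build_trace_input(probs[1, ], rnorm(14))
  expect_equal(one[1:6], unname(probs[1, ]))
  expect_error(build_trace_input(probs[0, , drop = FALSE], rnorm(14)))

  df <- as.data.frame(matrix(rnorm(24), 2))
  names(df) <- floorgait:::step_feature_names
  expect_equal(dim(assemble_step_features(df)), c(2L, 12L))
  expect_error(assemble_step_features(df[, -1]), "missing step features")
  df$step_time[1] <- NA
  expect_error(assemble_step_features(df), "non-finite")
})

test_that("level pretraining learns separable classes deterministically", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(120, -2), 30), matrix(rnorm(120, 2), 30))
    y <- rep(c(0, 3), each = 30)
  })
  net <- pretrain_level("trace", cbind(X, matrix(0, 60, 16)), y,
                        config = list(epochs = 80), seed = 4)
  probs <- level_probs(net, cbind(X, matrix(0, 60, 16)))
  expect_equal(unname(rowSums(probs)), rep(1, 60), tolerance = 1e-9)
  expect_gte(mean((max.col(probs) - 1) == y), 0.95)
  net2 <- pretrain_level("trace", cbind(X, matrix(0, 60, 16)), y,
                         config = list(epochs = 80), seed = 4)
  expect_identical(net, net2)
  expect_error(pretrain_level("trace", X, rep(1, 60)), "2 distinct")
})

test_that("hierarchical training recovers stages on a toy cohort", {
  feats <- toy_cohort_features(seed = 8)
  model <- train_hierarchical(feats, config = list(epochs = 120,
                                                   finetune_epochs = 15),
                              seed = 2)
  ev <- evaluate_hierarchical(model, feats)
  expect_gte(ev$person, 0.9)
  expect_gte(ev$person, ev$step)
  pred <- predict_stage(model, feats[[1]])
  expect_equal(sum(pred$probabilities), 1, tolerance = 1e-9)
  expect_true(pred$stage %in% 0:5)
  # inference is deterministic (dropout off) and invariant to duplicating
  # a person's traces (mean aggregation)
  pred2 <- predict_stage(model, feats[[1]])
  expect_identical(pred, pred2)
  dup <- feats[[1]]
  dup$traces <- c(dup$traces, dup$traces)
  expect_equal(predict_stage(model, dup)$probabilities,
               pred$probabilities, tolerance = 1e-9)
})

test_that("standardization statistics come only from training footsteps", {
  feats <- toy_cohort_features(seed = 9)
  cfg <- list(epochs = 30, finetune_epochs = 5)
  model <- train_hierarchical(feats, config = cfg, seed = 6)
  # corrupt the held-out footsteps only; the same seed reproduces the same
  # split, so training must be unaffected (no leakage of test rows)
  flat <- floorgait:::flatten_cohort(feats)
  test_rows <- which(model$test_step)
  corrupt <- feats
  row <- 0
  for (k in seq_along(corrupt)) {
    for (j in seq_along(corrupt[[k]]$traces)) {
      n <- nrow(corrupt[[k]]$traces[[j]]$steps)
      local_rows <- row + seq_len(n)
      bad <- intersect(local_rows, test_rows) - row
      if (length(bad) > 0) {
        corrupt[[k]]$traces[[j]]$steps[bad, ] <-
          corrupt[[k]]$traces[[j]]$steps[bad, ] + 100
      }
      row <- row + n
    }
  }
  model2 <- train_hierarchical(corrupt, config = cfg, seed = 6)
  expect_identical(model2$step_std, model$step_std)
  expect_identical(model2$step_net, model$step_net)
  expect_identical(model2$trace_net, model$trace_net)
  expect_identical(model2$person_net, model$person_net)
})

test_that("training rejects single-stage cohorts", {
  feats <- toy_cohort_features(stages = 2, n_per_stage = 3, seed = 10)
  expect_error(train_hierarchical(feats), "2 distinct stages")
})
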