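test_that("dataset splitting rotates disjoint 4:1 folds deterministically", {
  ids <- as.list(seq_len(840))
  tc <- train_config(seed = 3)
  folds <- split_dataset(ids, tc)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$train, 672)
    expect_length(f$validation, 168)
    expect_length(intersect(f$train, f$validation), 0)
  }
  vals <- lapply(folds, `[[`, "validation")
  expect_equal(sort(unlist(vals)), 1:840)                    # union is everything
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(vals[[i]], vals[[j]]), 0)        # pairwise disjoint

  small <- split_dataset(as.list(1:10), tc)
  expect_true(all(vapply(small, function(f) length(f$validation), integer(1)) == 2L))
  expect_identical(split_dataset(ids, tc), folds)            # same seed, same folds
  expect_error(split_dataset(as.list(1:3), tc), "at least")
})

test_that("AdaGrad training reduces the objective", {
  pc <- phantom_config(ct_size = 32, seed = 21)
  pairs <- lapply(generate_dataset(6, pc), phantom_to_pair)
  tc <- train_config(learning_rate = 0.02, epochs = 3, batch_size = 2,
                     lambda = 0, seed = 1)
  fit <- train(pairs, tiny_model_config(), tc)
  rec <- fit$records
  first <- mean(rec$total[rec$epoch == 1])
  last <- mean(rec$total[rec$epoch == max(rec$epoch)])
  expect_lt(last, first)
  expect_true(all(diff(rec$step) > 0))                       # monotone trace
  expect_true(all(is.finite(rec$total)))
})

test_that("a large L1 weight shrinks the parameter norm", {
  pc <- phantom_config(ct_size = 32, seed = 22)
  pairs <- lapply(generate_dataset(2, pc), phantom_to_pair)
  cfg <- tiny_model_config()
  fit0 <- train(pairs, cfg, train_config(learning_rate = 0.02, epochs = 2,
                                         batch_size = 2, lambda = 0, seed = 2))
  fitL <- train(pairs, cfg, train_config(learning_rate = 0.02, epochs = 2,
                                         batch_size = 2, lambda = 10, seed = 2))
  expect_lt(l1_norm(fitL$params), l1_norm(fit0$params))
})

test_that("the full training gradient matches central finite differences on a 2-pair batch", {
  pc <- phantom_config(ct_size = 16, seed = 23)
  cfg <- model_config(stem_channels = 8, mlp_reduction = 4, spp_scales = c(4, 2, 1),
                      branch_channels = 4, decoder_channels = c(8, 4, 1))
  pairs <- lapply(generate_dataset(2, pc), phantom_to_pair)
  params <- init_parameters(cfg, 9)
  batch_loss <- function(p) {
    mean(vapply(pairs, function(pr)
      fusion_loss(pr$ct, pr$pet, fuse(pr, p), lambda = 0)$total, numeric(1)))
  }
  g <- spfn:::zero_grads(params)
  for (pr in pairs) {
    pl <- spfn:::pair_loss_grads(pr, params)
    for (nm in names(g)) g[[nm]] <- g[[nm]] + pl$grads[[nm]] / 2
  }
  eps <- 1e-5
  for (probe in list(c("dec2_W", 17L), c("dec3_b", 1L), c("stem_W", 5L))) {
    nm <- probe[1]; idx <- as.integer(probe[2])
    pp <- params; pp$tensors[[nm]][idx] <- pp$tensors[[nm]][idx] + eps
    pm <- params; pm$tensors[[nm]][idx] <- pm$tensors[[nm]][idx] - eps
    fd <- (batch_loss(pp) - batch_loss(pm)) / (2 * eps)
    expect_equal(g[[nm]][idx], fd, tolerance = 1e-3)
  }
})

test_that("cross-validation bookkeeping covers every fold with all seven metrics", {
  pc <- phantom_config(ct_size = 48, seed = 24)
  pairs <- lapply(generate_dataset(10, pc), phantom_to_pair)
  tc <- train_config(learning_rate = 0.02, epochs = 1, batch_size = 4,
                     lambda = 1e-4, seed = 4)
  cv <- run_cross_validation(pairs, tiny_model_config(), tc)
  expect_equal(nrow(cv$folds), 5L)
  expect_true(all(cv$folds$n_validation == 2L))
  expect_true(all(c("mean", "std", "ag", "ent", "rmse", "nmi", "vif") %in%
                    names(cv$folds)))
  expect_identical(cv$summary$metric,
                   c("mean", "std", "ag", "ent", "rmse", "nmi", "vif"))
  expect_true(all(is.finite(cv$summary$mean)))
})

test_that("training is reproducible and non-global SSIM modes are rejected", {
  pc <- phantom_config(ct_size = 32, seed = 25)
  pairs <- lapply(generate_dataset(2, pc), phantom_to_pair)
  tc <- train_config(learning_rate = 0.02, epochs = 1, batch_size = 1, seed = 5)
  f1 <- train(pairs, tiny_model_config(), tc)
  f2 <- train(pairs, tiny_model_config(), tc)
  expect_identical(f1$params$tensors, f2$params$tensors)
  expect_equal(f1$records$total, f2$records$total)
  expect_error(train(pairs, tiny_model_config(),
                     train_config(ssim_mode = "windowed")), "global")
})
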