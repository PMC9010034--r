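#' Training configuration
#'
#' Protocol and optimizer settings. The optimizer is AdaGrad (per-parameter
#' accumulated squared gradients); weights are Xavier-initialized. The
#' dataset protocol is a 4:1 train/validation split rotated five times
#' (5-fold cross-validation), the split used at full scale (840 pairs ->
#' 672 training / 168 validation per fold).
#'
#' @param learning_rate AdaGrad learning rate (> 0).
#' @param epochs Training epochs (>= 1).
#' @param batch_size Pairs per gradient step.
#' @param lambda L1 regularization weight of the objective.
#' @param seed Seed for initialization and batch shuffling.
#' @param n_repeats Number of fold rotations (5, matching the 4:1 ratio).
#' @param ssim_mode SSIM mode of the objective; the analytic training
#'   gradient is implemented for `"global"` (the default objective).
#' @param adagrad_epsilon Numerical floor inside the AdaGrad update.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 100L, batch_size = 4L,
                         lambda = 1e-4, seed = 0L, n_repeats = 5L,
                         ssim_mode = "global", adagrad_epsilon = 1e-8) {
  if (learning_rate <= 0 || epochs < 1L || batch_size < 1L || lambda < 0)
    stop("train_config: invalid learning_rate/epochs/batch_size/lambda",
         call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda = lambda,
                 seed = as.integer(seed), n_repeats = as.integer(n_repeats),
                 split_ratio = c(4L, 1L), ssim_mode = ssim_mode,
                 adagrad_epsilon = adagrad_epsilon),
            class = "train_config")
}

#' Rotated 4:1 train/validation folds
#'
#' Shuffles the pairs once (seeded), partitions them into `n_repeats` equal
#' validation blocks, and returns one fold per rotation: validation block k
#' against the remaining 4/5 as training. Validation folds are pairwise
#' disjoint and their union is the whole dataset.
#'
#' @param pairs A list (of `image_pair`s, phantom pairs, or ids).
#' @param cfg A [train_config()] supplying `n_repeats` and `seed`.
#' @return A list of `n_repeats` folds, each `list(train =, validation =)`
#'   index vectors into `pairs`.
#' @export
split_dataset <- function(pairs, cfg = train_config()) {
  n <- length(pairs)
  k <- cfg$n_repeats
  if (n < k)
    stop(sprintf("split_dataset: need at least %d pairs for %d folds", k, k),
         call. = FALSE)
  perm <- with_seed(cfg$seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[starts[i]:ends[i]])
    list(train = sort(setdiff(perm, val)), validation = val)
  })
}

#' Train the fusion network
#'
#' Xavier-initializes the parameters, then minimizes the two-source SSIM +
#' L1 objective with AdaGrad over shuffled mini-batches of whole image pairs
#' (the network is fully convolutional; each registered pair is one sample).
#' Deterministic given the seeds.
#'
#' @param dataset A list of `image_pair` objects (the training fold).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param params Optional starting parameters (default: fresh
#'   [init_parameters()] at `train_cfg$seed`).
#' @return `list(params, records)`: the final parameters and a data.frame
#'   trace with one row per step (`epoch, step, total, ssim_ct, ssim_pet,
#'   l1_term, wall`).
#' @export
train <- function(dataset, model_cfg = model_config(),
                  train_cfg = train_config(), params = NULL) {
  if (length(dataset) == 0L)
    stop("train: empty training fold", call. = FALSE)
  if (train_cfg$ssim_mode != "global")
    stop("train: the analytic training gradient supports ssim_mode = 'global'",
         call. = FALSE)
  loss_cfg <- ssim_config(mode = "global")
  if (is.null(params)) params <- init_parameters(model_cfg, train_cfg$seed)
  accum <- lapply(params$tensors, function(t) array(0, dim(as.array(t))))
  records <- list()
  step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    order <- with_seed(train_cfg$seed + 7919L * epoch,
                       sample.int(length(dataset)))
    batches <- split(order, ceiling(seq_along(order) / train_cfg$batch_size))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      grads <- zero_grads(params)
      tot <- 0; s_ct <- 0; s_pet <- 0
      for (i in idx) {
        pl <- pair_loss_grads(dataset[[i]], params, loss_cfg)
        tot <- tot + pl$loss; s_ct <- s_ct + pl$ssim_ct; s_pet <- s_pet + pl$ssim_pet
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + pl$grads[[nm]]
      }
      nb <- length(idx)
      l1 <- l1_norm(params)
      total <- tot / nb + train_cfg$lambda * l1
      if (!is.finite(total))
        stop(sprintf("train: non-finite loss at epoch %d batch %d (pairs %s)",
                     epoch, bi, paste(idx, collapse = ",")), call. = FALSE)
      for (nm in names(grads)) {
        g <- grads[[nm]] / nb + train_cfg$lambda * sign(params$tensors[[nm]])
        accum[[nm]] <- accum[[nm]] + g^2
        params$tensors[[nm]] <- params$tensors[[nm]] -
          train_cfg$learning_rate * g / (sqrt(accum[[nm]]) + train_cfg$adagrad_epsilon)
      }
      step <- step + 1L
      records[[step]] <- data.frame(epoch = epoch, step = step, total = total,
                                    ssim_ct = s_ct / nb, ssim_pet = s_pet / nb,
                                    l1_term = l1,
                                    wall = as.numeric(Sys.time()))
    }
  }
  list(params = params, records = do.call(rbind, records))
}

#' Cross-validated training and evaluation
#'
#' Trains one model per rotated fold and evaluates every validation pair with
#' the seven-metric suite, returning per-fold means and the overall
#' mean +/- sd per metric.
#'
#' @inheritParams train
#' @return `list(folds, summary)`: `folds` a data.frame of per-fold metric
#'   means, `summary` a data.frame with one `mean` and `sd` row per metric.
#' @export
run_cross_validation <- function(dataset, model_cfg = model_config(),
                                 train_cfg = train_config()) {
  folds <- split_dataset(dataset, train_cfg)
  metric_cols <- c("mean", "std", "ag", "ent", "rmse", "nmi", "vif")
  per_fold <- lapply(seq_along(folds), function(k) {
    cfg_k <- train_cfg
    cfg_k$seed <- train_cfg$seed + k
    fit <- train(dataset[folds[[k]]$train], model_cfg, cfg_k)
    reps <- lapply(dataset[folds[[k]]$validation], function(p)
      evaluate_pair(p, fuse(p, fit$params)))
    vals <- vapply(metric_cols, function(cn)
      mean(vapply(reps, function(r) r[[cn]], numeric(1))), numeric(1))
    data.frame(fold = k, n_validation = length(folds[[k]]$validation),
               t(vals))
  })
  folds_df <- do.call(rbind, per_fold)
  summary_df <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cn) mean(folds_df[[cn]]), numeric(1)),
    sd = vapply(metric_cols, function(cn) stats::sd(folds_df[[cn]]), numeric(1)))
  list(folds = folds_df, summary = summary_df)
}

#' Write a training trace as JSON lines
#'
#' One JSON object per optimization step with the loss components.
#'
#' @param records The `records` data.frame returned by [train()].
#' @param path Destination file.
#' @export
write_train_log <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records)))
    writeLines(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
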