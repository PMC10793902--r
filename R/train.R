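#' Regression metrics
#'
#' Pearson correlation (Rp), root-mean-square error and mean absolute error
#' between predictions and labels.
#'
#' @param preds,labels equal-length numeric vectors (n >= 2 for Rp)
#' @return list with `rp`, `rmse`, `mae` (class `lgn_metrics`)
#' @export
compute_metrics <- function(preds, labels) {
  if (length(preds) != length(labels)) lgn_stop("preds and labels differ in length")
  n <- length(preds)
  if (n < 2) lgn_stop("at least two observations are required for Rp")
  if (stats::sd(preds) == 0 || stats::sd(labels) == 0) {
    lgn_stop("Rp undefined: constant predictions or labels")
  }
  structure(
    list(
      rp = stats::cor(preds, labels),
      rmse = sqrt(mean((labels - preds)^2)),
      mae = mean(abs(labels - preds))
    ),
    class = "lgn_metrics"
  )
}

#' @export
print.lgn_metrics <- function(x, ...) {
  cat(sprintf("Rp %.4f  RMSE %.4f  MAE %.4f\n", x$rp, x$rmse, x$mae))
  invisible(x)
}

#' Loss functions
#'
#' `loss_mse` is the mean squared error; `loss_smooth_l1` the Huber-style
#' smooth L1 (quadratic below residual 1, linear above); `loss_custom` the
#' correlation-error compromise `alpha * (1 - Rp) + (1 - alpha) * RMSE` in
#' its minimizable form. `loss_custom_printed` reports the literal
#' combination `alpha * Rp + (1 - alpha) * RMSE`.
#'
#' @param preds,labels numeric vectors
#' @param alpha weight in `[0, 1]` of the correlation term
#' @return scalar loss
#' @export
loss_mse <- function(preds, labels) mean((labels - preds)^2)

#' @rdname loss_mse
#' @export
loss_smooth_l1 <- function(preds, labels) {
  r <- abs(labels - preds)
  mean(ifelse(r < 1, 0.5 * r^2, r - 0.5))
}

#' @rdname loss_mse
#' @export
loss_custom <- function(preds, labels, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    lgn_stop("alpha must be in [0, 1], got %s", alpha)
  }
  m <- compute_metrics(preds, labels)
  alpha * (1 - m$rp) + (1 - alpha) * m$rmse
}

#' @rdname loss_mse
#' @export
loss_custom_printed <- function(preds, labels, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    lgn_stop("alpha must be in [0, 1], got %s", alpha)
  }
  m <- compute_metrics(preds, labels)
  alpha * m$rp + (1 - alpha) * m$rmse
}

#' Loss configuration
#'
#' @param kind `"mse"` (default; best in practice), `"smooth_l1"`, or
#'   `"custom"`
#' @param alpha correlation weight, used only for `kind = "custom"`
#' @return a `LossConfig` object
#' @export
loss_config <- function(kind = c("mse", "smooth_l1", "custom"), alpha = 0.5) {
  kind <- match.arg(kind)
  if (kind == "custom" && (!is.finite(alpha) || alpha < 0 || alpha > 1)) {
    lgn_stop("alpha must be in [0, 1], got %s", alpha)
  }
  structure(list(kind = kind, alpha = alpha), class = "LossConfig")
}

# Loss value and gradient w.r.t. predictions for a batch.
loss_and_grad <- function(preds, labels, lc) {
  n <- length(preds)
  r <- preds - labels
  switch(lc$kind,
    mse = list(value = mean(r^2), grad = 2 * r / n),
    smooth_l1 = list(
      value = loss_smooth_l1(preds, labels),
      grad = ifelse(abs(r) < 1, r, sign(r)) / n
    ),
    custom = {
      u <- preds - mean(preds)
      v <- labels - mean(labels)
      A <- sum(u * v); B <- sum(u^2); C <- sum(v^2)
      if (B == 0 || C == 0) lgn_stop("custom loss undefined on constant batch")
      rp <- A / sqrt(B * C)
      rmse <- sqrt(mean(r^2))
      drp <- (v - (A / B) * u) / sqrt(B * C)
      drmse <- if (rmse > 0) r / (n * rmse) else numeric(n)
      list(
        value = lc$alpha * (1 - rp) + (1 - lc$alpha) * rmse,
        grad = -lc$alpha * drp + (1 - lc$alpha) * drmse
      )
    }
  )
}

#' Training configuration
#'
#' Defaults follow the model's standard training recipe: Adam at learning
#' rate 1e-4 with weight decay 1e-6, mini-batches of 128, at most 200
#' epochs, early stopping on validation RMSE with patience 30.
#'
#' @param max_epochs maximum number of epochs
#' @param lr Adam learning rate
#' @param weight_decay L2 penalty added to gradients
#' @param batch_size mini-batch size
#' @param seed integer seed driving every shuffle and initialization
#' @param patience epochs without validation-RMSE improvement before stopping
#' @return a `TrainConfig` object
#' @export
train_config <- function(max_epochs = 200L, lr = 1e-4, weight_decay = 1e-6,
                         batch_size = 128L, seed = 1L, patience = 30L) {
  stopifnot(max_epochs >= 1, lr >= 0, weight_decay >= 0, batch_size >= 1,
            patience >= 1)
  structure(
    list(max_epochs = as.integer(max_epochs), lr = lr,
         weight_decay = weight_decay, batch_size = as.integer(batch_size),
         seed = as.integer(seed), patience = as.integer(patience)),
    class = "TrainConfig"
  )
}

#' Train the fusion model
#'
#' Adam optimization with the configured loss over mini-batches, gradient
#' clipping at global norm 5, and early stopping on validation RMSE. The
#' model with the best validation RMSE is returned. Labels are standardized
#' internally by the training-set mean and standard deviation (stored on the
#' model); predictions are always reported in pK units.
#'
#' @param train_samples,val_samples featurized samples from
#'   [featurize_dataset()] (with `labels` attributes)
#' @param config a [model_config()]
#' @param tc a [train_config()]
#' @param lc a [loss_config()]
#' @param verbose print per-epoch progress
#' @return list with `model` (best checkpoint) and `history` (one row per
#'   epoch: train loss, validation Rp/RMSE/MAE), class `lgn_fit`
#' @export
train_model <- function(train_samples, val_samples, config = model_config(),
                        tc = train_config(), lc = loss_config(),
                        verbose = FALSE) {
  y_train <- attr(train_samples, "labels")
  y_val <- attr(val_samples, "labels")
  if (length(train_samples) == 0 || length(val_samples) == 0) {
    lgn_stop("empty training or validation set")
  }
  with_seed(tc$seed, {
    model <- init_model(config, seed = tc$seed)
    model$label_center <- mean(y_train)
    model$label_scale <- if (stats::sd(y_train) > 0) stats::sd(y_train) else 1
    opt <- adam_state(model$params)
    val_batch <- collate_batch(val_samples)
    n <- length(train_samples)
    best <- list(rmse = Inf, params = model$params, epoch = 0L)
    hist <- vector("list", tc$max_epochs)
    # mini-batches are collated once from a seeded shuffle; every epoch
    # revisits them in a freshly shuffled order
    idx <- sample.int(n)
    starts <- seq(1, n, by = tc$batch_size)
    batches <- lapply(starts, function(start) {
      bi <- idx[start:min(start + tc$batch_size - 1, n)]
      list(batch = collate_batch(train_samples[bi]), labels = y_train[bi])
    })
    for (epoch in seq_len(tc$max_epochs)) {
      losses <- numeric(0)
      for (b in batches[sample.int(length(batches))]) {
        batch <- b$batch
        fw <- forward_model(model, batch, training = TRUE)
        lg <- loss_and_grad(fw$preds, b$labels, lc)
        if (!is.finite(lg$value)) {
          lgn_stop("training diverged at epoch %d (loss %s)", epoch, lg$value)
        }
        losses <- c(losses, lg$value)
        grads <- backward_model(model, batch, fw, lg$grad)
        grads <- add_weight_decay(grads, model$params, tc$weight_decay)
        grads <- clip_global_norm(grads, 5)
        upd <- adam_step(opt, model$params, grads, tc$lr)
        opt <- upd$state
        model$params <- upd$params
      }
      vp <- forward_model(model, val_batch, training = FALSE)$preds
      vm <- tryCatch(compute_metrics(vp, y_val),
                     error = function(e) list(rp = NA_real_,
                                              rmse = sqrt(mean((y_val - vp)^2)),
                                              mae = mean(abs(y_val - vp))))
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(losses), val_rp = vm$rp,
        val_rmse = vm$rmse, val_mae = vm$mae
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val Rp %.3f RMSE %.3f",
                        epoch, mean(losses), vm$rp, vm$rmse))
      }
      if (vm$rmse < best$rmse) {
        best <- list(rmse = vm$rmse, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= tc$patience) {
        break
      }
    }
    model$params <- best$params
    structure(
      list(model = model, history = do.call(rbind, hist),
           best_epoch = best$epoch),
      class = "lgn_fit"
    )
  })
}

adam_state <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

add_weight_decay <- function(grads, params, wd) {
  if (wd == 0) return(grads)
  for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + wd * params[[nm]]
  grads
}

clip_global_norm <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  }
  grads
}

#' Balanced fold assignment
#'
#' Seeded shuffle into `k` disjoint folds whose sizes differ by at most one.
#'
#' @param n number of items
#' @param k number of folds (2..n)
#' @param seed integer seed
#' @return integer vector of fold labels (1..k)
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 2) lgn_stop("k must be at least 2")
  if (k > n) lgn_stop("k exceeds the dataset size")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' k-fold cross-validation
#'
#' Featurizes the dataset once, then trains one model per fold (each fold
#' serving once as validation) and summarizes the per-fold metrics.
#'
#' @param dataset result of [gen_dataset()] or equivalent
#' @param k number of folds
#' @param config a [model_config()]
#' @param tc a [train_config()]
#' @param lc a [loss_config()]
#' @param seed seed for the fold assignment
#' @return list with `per_fold` (data.frame), `mean` and `sd` rows
#' @export
kfold_cv <- function(dataset, k = 10L, config = model_config(),
                     tc = train_config(), lc = loss_config(), seed = 1L) {
  n <- length(dataset$complexes)
  if (n < k) lgn_stop("dataset smaller than k")
  samples <- featurize_dataset(dataset, config)
  labels <- attr(samples, "labels")
  folds <- make_folds(n, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- which(folds != f)
    va <- which(folds == f)
    tr_s <- samples[tr]; attr(tr_s, "labels") <- labels[tr]
    va_s <- samples[va]; attr(va_s, "labels") <- labels[va]
    fit <- train_model(tr_s, va_s, config, tc, lc)
    preds <- predict(fit$model, va_s)
    m <- tryCatch(compute_metrics(preds, labels[va]),
                  error = function(e) list(rp = NA_real_,
                                           rmse = sqrt(mean((labels[va] - preds)^2)),
                                           mae = mean(abs(labels[va] - preds))))
    data.frame(fold = f, n_val = length(va), rp = m$rp, rmse = m$rmse,
               mae = m$mae)
  })
  per_fold <- do.call(rbind, rows)
  list(
    per_fold = per_fold,
    mean = colMeans(per_fold[, c("rp", "rmse", "mae")]),
    sd = apply(per_fold[, c("rp", "rmse", "mae")], 2, stats::sd)
  )
}
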