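#' Bagging ensemble specification
#'
#' Independent models trained on seeded random subsets of the training set,
#' aggregated by the arithmetic mean of their predictions - bagging, the
#' variance-reduction companion of the fusion model.
#'
#' @param n_models number of members (40 by default)
#' @param subset_fraction fraction of the training set each member sees,
#'   sampled without replacement
#' @param base_seed member i trains with seed `base_seed + i`
#' @param config a [model_config()]
#' @param tc a [train_config()]
#' @param lc a [loss_config()]
#' @return an `EnsembleSpec` object
#' @export
ensemble_spec <- function(n_models = 40L, subset_fraction = 0.8,
                          base_seed = 1L, config = model_config(),
                          tc = train_config(), lc = loss_config()) {
  stopifnot(n_models >= 1, subset_fraction > 0, subset_fraction <= 1)
  structure(
    list(n_models = as.integer(n_models), subset_fraction = subset_fraction,
         base_seed = as.integer(base_seed), config = config, tc = tc, lc = lc),
    class = "EnsembleSpec"
  )
}

#' Train a bagging ensemble
#'
#' Member `i` trains on a seeded (`base_seed + i`) random subset of
#' `round(subset_fraction * n)` training samples without replacement; all
#' members share the validation set. The manifest records each member's
#' subset IDs, so a run is bit-reproducible.
#'
#' @param train_samples,val_samples featurized samples from
#'   [featurize_dataset()]
#' @param spec an [ensemble_spec()]
#' @param verbose print member progress
#' @return list with `models`, `manifest` and `spec`, class `lgn_ensemble`
#' @export
train_ensemble <- function(train_samples, val_samples, spec, verbose = FALSE) {
  n <- length(train_samples)
  labels <- attr(train_samples, "labels")
  ids <- attr(train_samples, "complex_id") %||% as.character(seq_len(n))
  n_sub <- round(spec$subset_fraction * n)
  if (n_sub < spec$tc$batch_size) {
    lgn_stop("member subset size %d is below the batch size %d",
             n_sub, spec$tc$batch_size)
  }
  models <- vector("list", spec$n_models)
  manifest <- vector("list", spec$n_models)
  for (i in seq_len(spec$n_models)) {
    seed_i <- spec$base_seed + i
    sub <- with_seed(seed_i, sample.int(n, n_sub))
    tr <- train_samples[sub]
    attr(tr, "labels") <- labels[sub]
    tc_i <- spec$tc
    tc_i$seed <- seed_i
    if (verbose) message(sprintf("training ensemble member %d/%d", i, spec$n_models))
    fit <- train_model(tr, val_samples, spec$config, tc_i, spec$lc)
    models[[i]] <- fit$model
    manifest[[i]] <- list(member = i, seed = seed_i, subset_ids = ids[sub])
  }
  structure(list(models = models, manifest = manifest, spec = spec),
            class = "lgn_ensemble")
}

#' Ensemble prediction
#'
#' Arithmetic mean of the member predictions. All members must share the
#' featurization version.
#'
#' @param ensemble an `lgn_ensemble` (or plain list of `lgn_model`s)
#' @param samples featurized samples
#' @return numeric vector of pK predictions
#' @export
ensemble_predict <- function(ensemble, samples) {
  models <- if (inherits(ensemble, "lgn_ensemble")) ensemble$models else ensemble
  if (length(models) == 0) lgn_stop("ensemble has no members")
  vers <- vapply(models, function(m) m$featurization, character(1))
  if (length(unique(vers)) != 1) {
    lgn_stop("ensemble members disagree on featurization version")
  }
  preds <- vapply(models, function(m) predict(m, samples),
                  numeric(length(samples)))
  if (length(samples) == 1) return(mean(preds))
  rowMeans(preds)
}
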