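# Orchestration of the three experimental tasks: preprocessing comparison,
# cross-variety generalization, and transfer learning across vintages.

# Split a dataset, fit the preprocessing on the training split only, and
# apply it to all three roles (leakage-safe).
prepare_split_sets <- function(dataset, split, config) {
  train_raw <- subset_dataset(dataset, split$train_ids)
  fitted <- fit_preprocessing(train_raw, config)
  list(train = apply_preprocessing(train_raw, config, fitted),
       val = apply_preprocessing(subset_dataset(dataset, split$val_ids),
                                 config, fitted),
       test = apply_preprocessing(subset_dataset(dataset, split$test_ids),
                                  config, fitted),
       fitted = fitted)
}

# Reapply a trained model's stored preprocessing provenance to a new raw
# dataset (e.g. other varieties or a new vintage).
preprocess_like_model <- function(dataset, model) {
  prov <- model$preprocessing
  if (is.null(prov)) return(dataset)
  apply_preprocessing(dataset, prov$config, prov$fitted_state)
}

#' Compare spectral preprocessing methods on one dataset
#'
#' For each method, the dataset is split (stratified per vintage), the
#' preprocessing is fit on the training split and applied to all roles, a
#' model is trained — with hyperparameters either given or tuned by
#' [bogp_optimize()] on the validation objective — and RMSEV/RMSEP are
#' reported. With `n_repeats > 1` the split/train/evaluate cycle is repeated
#' over fresh stratified splits and the per-repeat RMSEPs are reported as a
#' distribution.
#'
#' @param dataset a raw `spec_dataset`.
#' @param target `"sugar"` or `"ph"`.
#' @param methods preprocessing methods to compare.
#' @param hp fixed [hyperparams()] (skips tuning) or `NULL` to tune.
#' @param train_cfg a [train_config()].
#' @param split_seed seed of the (shared) stratified split.
#' @param tune_budget `c(random, gp)` evaluations when tuning.
#' @param n_repeats repeated-split evaluations (1 = single split).
#' @param seed seed for tuning and training.
#' @return list with `results` (data.frame: method, rmsev, rmsep,
#'   best_epoch), `models`, `reports` and (if repeated) `repeats`.
#' @export
run_preprocessing_comparison <- function(dataset, target = "sugar",
                                         methods = c("MSC", "NORM", "SG"),
                                         hp = NULL,
                                         train_cfg = train_config(120L, 20L),
                                         split_seed = 1L,
                                         tune_budget = c(random = 8L, gp = 12L),
                                         n_repeats = 1L, seed = 1L) {
  stopifnot(inherits(dataset, "spec_dataset"))
  split <- stratified_partition(dataset, target, seed = split_seed)
  results <- data.frame()
  models <- list()
  reports <- list()
  repeats <- list()
  for (method in methods) {
    res <- tryCatch({
      config <- preprocess_config(method)
      sets <- prepare_split_sets(dataset, split, config)
      hp_m <- hp
      if (is.null(hp_m)) {
        objective <- function(h) {
          m <- build_model(h, dataset$grid$n_bands, target = target,
                           seed = seed)
          m <- train(m, sets$train, sets$val, train_cfg)
          sqrt(min(m$history$val_mse))
        }
        tuned <- bogp_optimize(objective, n_random = tune_budget[[1]],
                               n_gp_iter = tune_budget[[2]], seed = seed)
        hp_m <- tuned$best_hp
      }
      model <- build_model(hp_m, dataset$grid$n_bands, target = target,
                           seed = seed)
      model <- train(model, sets$train, sets$val, train_cfg)
      rep_val <- evaluate(model, sets$val, role = "validation")
      rep_test <- evaluate(model, sets$test, role = "test")
      rep_rmseps <- numeric(0)
      if (n_repeats > 1L) {
        splits <- repeated_splits(dataset, target, n_repeats,
                                  base_seed = split_seed)
        rep_rmseps <- vapply(splits, function(sp) {
          st <- prepare_split_sets(dataset, sp, config)
          m <- build_model(hp_m, dataset$grid$n_bands, target = target,
                           seed = seed)
          m <- train(m, st$train, st$val, train_cfg)
          evaluate(m, st$test, role = "test")$rmse
        }, numeric(1))
      }
      list(model = model, rep_val = rep_val, rep_test = rep_test,
           rep_rmseps = rep_rmseps)
    }, error = function(e) {
      warning("method ", method, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    results <- rbind(results, data.frame(
      method = method, rmsev = res$rep_val$rmse, rmsep = res$rep_test$rmse,
      best_epoch = res$model$best_epoch, stringsAsFactors = FALSE))
    models[[method]] <- res$model
    reports[[method]] <- list(validation = res$rep_val, test = res$rep_test)
    if (n_repeats > 1L) repeats[[method]] <- res$rep_rmseps
  }
  out <- list(results = results, models = models, reports = reports,
              split = split, target = target)
  if (n_repeats > 1L) out$repeats <- repeats
  out
}

#' Evaluate a trained model on varieties unseen during training
#'
#' Applies the model's stored preprocessing provenance to the new-variety
#' dataset and evaluates without any weight update, reporting pooled and
#' per-variety RMSEP.
#'
#' @param model a trained `cnn_model`.
#' @param other_varieties_dataset raw `spec_dataset` of the held-out
#'   varieties.
#' @return an `eval_report` with per-variety sub-reports.
#' @export
run_cross_variety_eval <- function(model, other_varieties_dataset) {
  stopifnot(inherits(model, "cnn_model"))
  if (!model$trained) stop("model must be trained")
  prepped <- preprocess_like_model(other_varieties_dataset, model)
  evaluate(model, prepped, role = "test", group_by = "variety")
}

#' Transfer-learning experiment across vintages
#'
#' Mirrors the vintage-generalization design: a base model is trained on
#' all source + fine-tune vintages pooled; a transfer model is pretrained
#' on the source vintages only, then fine-tuned on the newest training
#' vintage; both are evaluated on the held-out vintage, and the relative
#' RMSE improvement of the transfer model is reported.
#'
#' @param source_data raw `spec_dataset` of the source vintages.
#' @param finetune_data raw `spec_dataset` of the fine-tune vintage.
#' @param test_data raw `spec_dataset` of the held-out vintage.
#' @param target `"sugar"` or `"ph"`.
#' @param hp [hyperparams()] shared by both models.
#' @param preprocess a [preprocess_config()].
#' @param pretrain_cfg,finetune_cfg [train_config()] for the two stages.
#' @param split_seed,seed split / init+training seeds.
#' @return list with `base_report`, `tl_report`, `improvement_pct`, and the
#'   two models.
#' @export
run_transfer_experiment <- function(source_data, finetune_data, test_data,
                                    target = "sugar", hp = hyperparams(),
                                    preprocess = preprocess_config("SG"),
                                    pretrain_cfg = train_config(120L, 20L),
                                    finetune_cfg = train_config(60L, 15L),
                                    split_seed = 1L, seed = 1L) {
  B <- source_data$grid$n_bands
  # base: source + fine-tune vintages pooled
  pooled <- bind_datasets(source_data, finetune_data)
  sp_pool <- stratified_partition(pooled, target, seed = split_seed)
  sets_pool <- prepare_split_sets(pooled, sp_pool, preprocess)
  base_model <- build_model(hp, B, target = target, seed = seed)
  base_model <- train(base_model, sets_pool$train, sets_pool$val,
                      pretrain_cfg)
  test_base <- preprocess_like_model(test_data, base_model)
  base_report <- evaluate(base_model, test_base, role = "test")

  # transfer: pretrain on source, fine-tune on the new vintage
  sp_src <- stratified_partition(source_data, target, seed = split_seed)
  sets_src <- prepare_split_sets(source_data, sp_src, preprocess)
  pre_model <- build_model(hp, B, target = target, seed = seed)
  pre_model <- train(pre_model, sets_src$train, sets_src$val, pretrain_cfg)
  sp_ft <- stratified_partition(finetune_data, target, seed = split_seed)
  sets_ft <- list(
    train = preprocess_like_model(subset_dataset(finetune_data,
                                                 sp_ft$train_ids), pre_model),
    val = preprocess_like_model(subset_dataset(finetune_data,
                                               sp_ft$val_ids), pre_model))
  tl_model <- init_from_pretrained(
    build_model(hp, B, target = target, seed = seed), pre_model)
  tl_model <- fine_tune(tl_model, sets_ft$train, sets_ft$val, finetune_cfg)
  test_tl <- preprocess_like_model(test_data, tl_model)
  tl_report <- evaluate(tl_model, test_tl, role = "test")

  list(base_report = base_report, tl_report = tl_report,
       improvement_pct = relative_improvement(base_report$rmse,
                                              tl_report$rmse),
       base_model = base_model, tl_model = tl_model,
       pretrained_model = pre_model)
}
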