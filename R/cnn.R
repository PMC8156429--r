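# Construction, training, prediction and transfer-learning fine-tuning of
# the 1D-CNN regressor. The compiled kernel lives in src/cnn.cpp; this file
# owns hyperparameter validation, Glorot initialization, the model object
# and its artifact format.

#' Tunable hyperparameters of the 1D CNN
#'
#' The nine values the Bayesian optimizer searches. Each is validated
#' against the search range: filters 5-256, kernel sizes 3-100, dense
#' neurons 4-256, dropout rates 0.1-0.6, learning rate 0.01-0.06, batch
#' size 8-260.
#'
#' @param filters1,filters2 number of filters of the two convolution layers.
#' @param kernel1,kernel2 kernel sizes of the two convolution layers.
#' @param neurons size of the hidden dense layer.
#' @param dropout1 dropout rate after the last pooling layer.
#' @param dropout2 dropout rate before the output neuron.
#' @param lr Adadelta learning rate.
#' @param batch_size minibatch size.
#' @return an object of class `hyperparams`.
#' @export
hyperparams <- function(filters1 = 60L, kernel1 = 50L, filters2 = 60L,
                        kernel2 = 3L, neurons = 128L, dropout1 = 0.4,
                        dropout2 = 0.2, lr = 0.033, batch_size = 8L) {
  hp <- list(filters1 = as.integer(filters1), kernel1 = as.integer(kernel1),
             filters2 = as.integer(filters2), kernel2 = as.integer(kernel2),
             neurons = as.integer(neurons), dropout1 = dropout1,
             dropout2 = dropout2, lr = lr, batch_size = as.integer(batch_size))
  sp <- hyperparam_space()
  for (i in seq_len(nrow(sp))) {
    v <- hp[[sp$name[i]]]
    if (length(v) != 1L || is.na(v) || v < sp$lower[i] || v > sp$upper[i])
      stop("validation error: ", sp$name[i], " = ", v,
           " outside [", sp$lower[i], ", ", sp$upper[i], "]")
  }
  structure(hp, class = "hyperparams")
}

#' Hyperparameter search space
#'
#' Per-dimension bounds and type of the nine tunables, as used by both
#' [hyperparams()] validation and the Bayesian optimizer.
#'
#' @return data.frame with columns `name`, `lower`, `upper`, `integer`.
#' @export
hyperparam_space <- function() {
  data.frame(
    name = c("filters1", "kernel1", "filters2", "kernel2", "neurons",
             "dropout1", "dropout2", "lr", "batch_size"),
    lower = c(5, 3, 5, 3, 4, 0.1, 0.1, 0.01, 8),
    upper = c(256, 100, 256, 100, 256, 0.6, 0.6, 0.06, 260),
    integer = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Fixed architecture constants
#'
#' The non-tunable topology: stride 1, 'same' padding, ReLU activations,
#' batch normalization after each convolution block, max-pool sizes 2 then
#' 5 (non-divisible lengths truncate), dropout after the last pooling layer
#' and before the output, one hidden dense layer, a single linear output
#' neuron, Glorot-uniform initialization.
#'
#' @return a list of constants, class `architecture_spec`.
#' @export
architecture_spec <- function() {
  structure(list(stride = 1L, padding = "same", activation = "relu",
                 pool1 = 2L, pool2 = 5L, batch_norm = TRUE,
                 hidden_layers = 1L, output = "linear",
                 init = "glorot_uniform",
                 optimizer = "adadelta", adadelta_rho = 0.95,
                 adadelta_eps = 1e-7, loss = "mse"),
            class = "architecture_spec")
}

#' Flattened feature length of the architecture
#'
#' After pooling by 2 and then 5 (floor truncation) the feature maps are
#' `filters2 x floor(floor(B/2)/5)`, flattened to their product.
#'
#' @param n_bands input band count B.
#' @param filters2 filters of the second convolution layer.
#' @return integer flattened length.
#' @export
flatten_length <- function(n_bands, filters2) {
  as.integer((n_bands %/% 2L) %/% 5L) * as.integer(filters2)
}

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Build an (untrained) 1D CNN regression model
#'
#' Layer stack: input (B x 1) -> conv1(filters1, kernel1) + ReLU -> batch
#' norm -> max-pool 2 -> conv2(filters2, kernel2) + ReLU -> batch norm ->
#' max-pool 5 -> dropout(dropout1) -> flatten -> dense(neurons) + ReLU ->
#' dropout(dropout2) -> dense(1, linear). Weights are Glorot-uniform
#' initialized, reproducibly under `seed`.
#'
#' @param hp a [hyperparams()] object.
#' @param n_bands input band count (>= 10).
#' @param target `"sugar"` or `"ph"` (one model per target).
#' @param seed integer init seed.
#' @return an object of class `cnn_model` (untrained).
#' @export
build_model <- function(hp, n_bands, target = c("sugar", "ph"), seed = 1L) {
  stopifnot(inherits(hp, "hyperparams"))
  target <- match.arg(target)
  n_bands <- as.integer(n_bands)
  if (n_bands < 10L) stop("n_bands must be >= 10")
  local_seed(seed)
  flat <- flatten_length(n_bands, hp$filters2)
  params <- list(
    W1 = array(glorot_uniform(hp$kernel1, hp$filters1 * hp$kernel1,
                              hp$filters1 * hp$kernel1),
               dim = c(hp$filters1, 1L, hp$kernel1)),
    b1 = numeric(hp$filters1),
    g1 = rep(1, hp$filters1), be1 = numeric(hp$filters1),
    rm1 = numeric(hp$filters1), rv1 = rep(1, hp$filters1),
    W2 = array(glorot_uniform(hp$filters1 * hp$kernel2,
                              hp$filters2 * hp$kernel2,
                              hp$filters2 * hp$filters1 * hp$kernel2),
               dim = c(hp$filters2, hp$filters1, hp$kernel2)),
    b2 = numeric(hp$filters2),
    g2 = rep(1, hp$filters2), be2 = numeric(hp$filters2),
    rm2 = numeric(hp$filters2), rv2 = rep(1, hp$filters2),
    W3 = matrix(glorot_uniform(flat, hp$neurons, hp$neurons * flat),
                nrow = hp$neurons, ncol = flat),
    b3 = numeric(hp$neurons),
    W4 = matrix(glorot_uniform(hp$neurons, 1L, hp$neurons), nrow = 1L),
    b4 = numeric(1L))
  structure(list(params = params, hp = hp, arch = architecture_spec(),
                 n_bands = n_bands, target = target, seed = as.integer(seed),
                 preprocessing = NULL, history = NULL, best_epoch = NULL,
                 trained = FALSE),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> target ", x$target, ", ", x$n_bands, " bands, ",
      format(count_parameters(x), big.mark = ","), " parameters",
      if (x$trained) sprintf(", trained (best epoch %d)", x$best_epoch)
      else ", untrained", "\n", sep = "")
  invisible(x)
}

#' Total parameter count of a model
#'
#' Closed-form sum over layers: convolution `kernel x in x out + out`, batch
#' norm `4 x channels` (scale, shift, running mean, running variance), dense
#' `in x out + out`.
#'
#' @param model a `cnn_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  hp <- model$hp
  flat <- flatten_length(model$n_bands, hp$filters2)
  conv1 <- hp$kernel1 * 1L * hp$filters1 + hp$filters1
  bn1 <- 4L * hp$filters1
  conv2 <- hp$kernel2 * hp$filters1 * hp$filters2 + hp$filters2
  bn2 <- 4L * hp$filters2
  dense <- flat * hp$neurons + hp$neurons
  out <- hp$neurons + 1L
  as.integer(conv1 + bn1 + conv2 + bn2 + dense + out)
}

#' Training configuration
#'
#' @param max_epochs epoch budget (default 500).
#' @param patience early-stopping patience on validation MSE (default 50;
#'   must be < `max_epochs`).
#' @param seed seed for shuffling and dropout masks.
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 500L, patience = 50L, seed = 1L) {
  max_epochs <- as.integer(max_epochs)
  patience <- as.integer(patience)
  if (max_epochs > 0L && patience >= max_epochs)
    stop("patience must be < max_epochs")
  structure(list(max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

.training_xy <- function(set, model) {
  if (inherits(set, "spec_dataset")) {
    list(x = set$spectra, y = as.numeric(set$references[[model$target]]))
  } else if (is.list(set) && !is.null(set$x)) {
    list(x = as.matrix(set$x), y = as.numeric(set$y))
  } else stop("training set must be a spec_dataset or list(x, y)")
}

#' Train a 1D CNN
#'
#' Minimizes MSE with Adadelta (rho 0.95, epsilon 1e-7, learning rate and
#' batch size from the model's hyperparameters), stopping early when the
#' validation MSE has not improved for `patience` epochs and restoring the
#' best-epoch weights. The output bias starts at the training-target mean so
#' the network learns deviations rather than the gross offset. Targets stay
#' in natural units throughout.
#'
#' @param model an (untrained or pretrained) `cnn_model`.
#' @param train_set,val_set `spec_dataset` objects (preprocessed identically)
#'   or `list(x, y)` pairs.
#' @param cfg a [train_config()].
#' @param init_output_bias set the output bias to `mean(train y)` before
#'   training (skipped automatically when fine-tuning pretrained weights).
#' @return the trained `cnn_model`, with `history` (per-epoch train/val MSE)
#'   and `best_epoch`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(),
                  init_output_bias = !model$trained) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  tr <- .training_xy(train_set, model)
  va <- .training_xy(val_set, model)
  if (nrow(tr$x) == 0L || nrow(va$x) == 0L)
    stop("empty training or validation set")
  if (ncol(tr$x) != model$n_bands || ncol(va$x) != model$n_bands)
    stop("shape error: band count does not match the model")
  if (inherits(train_set, "spec_dataset"))
    model$preprocessing <- train_set$preprocessing
  if (cfg$max_epochs == 0L) return(model)
  if (init_output_bias) model$params$b4 <- mean(tr$y)
  local_seed(cfg$seed)
  fit <- cnn_train_cpp(model$params, tr$x, tr$y, va$x, va$y,
                       lr = model$hp$lr, rho = model$arch$adadelta_rho,
                       eps = model$arch$adadelta_eps,
                       batch_size = model$hp$batch_size,
                       max_epochs = cfg$max_epochs, patience = cfg$patience,
                       dropout1 = model$hp$dropout1,
                       dropout2 = model$hp$dropout2)
  if (isTRUE(fit$diverged))
    stop("divergence error: non-finite loss at epoch ", fit$diverged_epoch)
  model$params <- .as_param_arrays(fit$params, model$hp)
  model$history <- data.frame(epoch = seq_along(fit$train_history),
                              train_mse = as.numeric(fit$train_history),
                              val_mse = as.numeric(fit$val_history))
  model$best_epoch <- as.integer(fit$best_epoch)
  model$stopped_epoch <- as.integer(fit$stopped_epoch)
  model$train_seed <- cfg$seed
  model$trained <- TRUE
  model
}

# Rcpp returns cubes as 3-d arrays and vecs as plain vectors; keep the
# canonical shapes so repeated train calls round-trip.
.as_param_arrays <- function(p, hp) {
  p$W1 <- array(p$W1, dim = c(hp$filters1, 1L, hp$kernel1))
  p$W2 <- array(p$W2, dim = c(hp$filters2, hp$filters1, hp$kernel2))
  p$W3 <- matrix(p$W3, nrow = hp$neurons)
  p$W4 <- matrix(p$W4, nrow = 1L)
  for (nm in c("b1", "g1", "be1", "rm1", "rv1", "b2", "g2", "be2", "rm2",
               "rv2", "b3", "b4"))
    p[[nm]] <- as.numeric(p[[nm]])
  p
}

#' Predict targets for new spectra
#'
#' @param object a `cnn_model`.
#' @param newdata a `spec_dataset` or a samples-by-bands matrix, preprocessed
#'   with the model's stored provenance.
#' @param ... unused.
#' @return numeric vector of predictions in natural units (°Brix or pH).
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spec_dataset")) newdata$spectra
       else as.matrix(newdata)
  if (ncol(X) != object$n_bands)
    stop("shape error: expected ", object$n_bands, " bands, got ", ncol(X))
  as.numeric(cnn_predict_cpp(object$params, X))
}

#' Initialize a model from pretrained weights
#'
#' Copies every weight (including batch-norm running statistics) from a
#' trained source model into an architecturally identical model; before any
#' fine-tuning step, predictions equal the source's exactly.
#'
#' @param new_model target `cnn_model` (same hyperparameters and band count).
#' @param source trained `cnn_model` supplying the weights.
#' @return `new_model` carrying the source weights.
#' @export
init_from_pretrained <- function(new_model, source) {
  stopifnot(inherits(new_model, "cnn_model"), inherits(source, "cnn_model"))
  if (!identical(unclass(new_model$hp), unclass(source$hp)) ||
      new_model$n_bands != source$n_bands)
    stop("incompatibility error: hyperparameters or band count differ")
  new_model$params <- source$params
  new_model$pretrained_from <- list(best_epoch = source$best_epoch,
                                    seed = source$seed)
  new_model$trained <- source$trained
  new_model$preprocessing <- source$preprocessing
  new_model
}

#' Fine-tune a pretrained model on new data
#'
#' Transfer learning across vintages: all layers stay trainable and training
#' follows the [train()] contract, starting from the pretrained weights.
#' `max_epochs = 0` returns the model unchanged.
#'
#' @param pretrained a trained `cnn_model`.
#' @param new_train,new_val datasets (or `list(x, y)`) of the new vintage.
#' @param cfg a [train_config()].
#' @return the fine-tuned `cnn_model`.
#' @export
fine_tune <- function(pretrained, new_train, new_val, cfg = train_config()) {
  stopifnot(inherits(pretrained, "cnn_model"))
  if (!pretrained$trained) stop("fine_tune requires a trained source model")
  train(pretrained, new_train, new_val, cfg, init_output_bias = FALSE)
}

#' Save a trained model artifact
#'
#' Writes `<stem>_weights.rds` (the weight container) and `<stem>.json`
#' (hyperparameters, architecture constants, preprocessing provenance,
#' training history, seeds).
#'
#' @param model a `cnn_model`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
save_model <- function(model, stem) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model$params, paste0(stem, "_weights.rds"))
  side <- list(
    hyperparams = unclass(model$hp),
    architecture = unclass(model$arch),
    n_bands = model$n_bands, target = model$target,
    seed = model$seed, train_seed = model$train_seed,
    best_epoch = model$best_epoch,
    history = model$history,
    preprocessing = if (!is.null(model$preprocessing))
      list(method = model$preprocessing$method,
           config = unclass(model$preprocessing$config),
           msc_reference =
             model$preprocessing$fitted_state$reference_spectrum))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Load a model artifact written by [save_model()]
#' @param stem path stem.
#' @return a `cnn_model`.
#' @export
load_model <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  hp <- do.call(hyperparams, as.list(side$hyperparams))
  model <- build_model(hp, side$n_bands, target = side$target,
                       seed = side$seed %||% 1L)
  model$params <- .as_param_arrays(readRDS(paste0(stem, "_weights.rds")), hp)
  model$best_epoch <- side$best_epoch
  model$history <- side$history
  model$trained <- !is.null(side$best_epoch)
  if (!is.null(side$preprocessing)) {
    cfgl <- side$preprocessing$config
    cfg <- preprocess_config(cfgl$method, cfgl$sg_window, cfgl$sg_polyorder,
                             cfgl$sg_deriv)
    fitted <- if (!is.null(side$preprocessing$msc_reference))
      structure(list(reference_spectrum =
                       as.numeric(side$preprocessing$msc_reference),
                     provenance = "restored"),
                class = "msc_reference")
    model$preprocessing <- list(method = side$preprocessing$method,
                                config = cfg, fitted_state = fitted)
  }
  model
}
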