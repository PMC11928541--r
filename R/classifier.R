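# Backbone registry -----------------------------------------------------------

.backbone_registry <- new.env(parent = emptyenv())

#' Register a tile-classifier backbone
#'
#' A backbone is a factory producing the contract used by
#' [train_classifier()]: a featurizer mapping a `size x size x 3` RGB tile to
#' a fixed-length numeric vector, and a linear-in-parameters forward map from
#' features to 3 logits (Aggregate, Non-GC, GC).
#'
#' @param name backbone identifier.
#' @param factory `function(pretrained_source, weights_file)` returning a
#'   `tls_backbone` object.
#' @export
register_backbone <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(name, factory, envir = .backbone_registry)
  invisible(name)
}

#' @rdname register_backbone
#' @export
list_backbones <- function() sort(ls(.backbone_registry))

new_backbone <- function(name, featurize, n_features, init, forward, n_params,
                         pretrained_source = "none") {
  structure(list(name = name, featurize = featurize, n_features = n_features,
                 init = init, forward = forward, n_params = n_params,
                 pretrained_source = pretrained_source),
            class = "tls_backbone")
}

#' @export
print.tls_backbone <- function(x, ...) {
  cat(sprintf("tls backbone '%s': %d features -> 3 logits, %d parameters (pretrained: %s)\n",
              x$name, x$n_features, x$n_params, x$pretrained_source))
  invisible(x)
}

# Mean of gs x gs pixel blocks of a matrix whose side is divisible by gs.
block_means <- function(mat, grid = 8L) {
  n <- nrow(mat)
  bs <- n %/% grid
  a <- array(mat, c(bs, grid, bs, grid))
  apply(a, c(2L, 4L), mean)
}

reference_small_featurize <- function(img, grid = 8L) {
  d <- dim(img)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 3L || d[1] %% grid != 0L) {
    stopf("reference-small backbone expects square RGB tiles with side divisible by %d, got %s",
          grid, paste(d, collapse = "x"))
  }
  v <- c(block_means(img[, , 1], grid), block_means(img[, , 2], grid),
         block_means(img[, , 3], grid),
         stats::sd(img[, , 1]), stats::sd(img[, , 2]), stats::sd(img[, , 3]))
  as.numeric(v)
}

reference_small_factory <- function(pretrained_source = "none",
                                    weights_file = NULL) {
  if (!identical(pretrained_source, "none")) {
    stopf(paste0("no pretrained weights exist for backbone 'reference-small'",
                 " (requested '%s'); use pretrained_source = 'none'"),
          pretrained_source)
  }
  grid <- 8L
  p <- 3L * grid^2 + 3L
  new_backbone(
    name = "reference-small",
    featurize = function(img) reference_small_featurize(img, grid),
    n_features = p,
    init = function(seed) {
      with_seed(seed, matrix(stats::rnorm(3L * (p + 1L), 0, 0.01), nrow = 3L))
    },
    forward = function(params, X) cbind(1, X) %*% t(params),
    n_params = 3L * (p + 1L))
}

# Adapter for externally trained deep backbones (residual-network-50-class,
# large vision-transformer-class).  No weights are distributed with the
# package: the user must supply an RDS file providing `featurize` (tile ->
# feature vector) and `n_features`; the linear classification head is then
# trained here.  Requesting pretrained weights without a file is an error,
# never a silent random initialization.
external_adapter_factory <- function(name, approx_params) {
  function(pretrained_source = "imagenet", weights_file = NULL) {
    if (is.null(weights_file)) {
      stopf(paste0("backbone '%s' (pretrained: %s) needs user-supplied weights: ",
                   "pass weights_file = <RDS with $featurize and $n_features>; ",
                   "no weights are distributed with this package"),
            name, pretrained_source)
    }
    if (!file.exists(weights_file)) {
      stopf("weights file not found for backbone '%s': %s", name, weights_file)
    }
    w <- readRDS(weights_file)
    if (!is.function(w$featurize) || is.null(w$n_features)) {
      stopf("weights file for '%s' must provide $featurize and $n_features",
            name)
    }
    p <- as.integer(w$n_features)
    new_backbone(
      name = name, featurize = w$featurize, n_features = p,
      init = function(seed) {
        with_seed(seed, matrix(stats::rnorm(3L * (p + 1L), 0, 0.01), nrow = 3L))
      },
      forward = function(params, X) cbind(1, X) %*% t(params),
      n_params = approx_params,
      pretrained_source = pretrained_source)
  }
}

register_builtin_backbones <- function() {
  register_backbone("reference-small", reference_small_factory)
  register_backbone("resnet50-class",
                    external_adapter_factory("resnet50-class", 25557032L))
  register_backbone("vit-large-class",
                    external_adapter_factory("vit-large-class", 304326632L))
}

#' Construct a tile-classifier backbone
#'
#' @param name registered backbone name; see [list_backbones()].  The
#'   built-ins are `reference-small` (a CPU-trainable backbone: 8x8 block
#'   color means + channel dispersions feeding a linear 3-logit head) and
#'   adapters `resnet50-class` / `vit-large-class` for externally computed
#'   deep features (require `weights_file`).
#' @param pretrained_source `"none"`, `"imagenet"` or `"pathology-foundation"`.
#' @param weights_file optional RDS path for adapter backbones.
#' @return a `tls_backbone` object.
#' @export
make_backbone <- function(name, pretrained_source = "none",
                          weights_file = NULL) {
  if (!exists(name, envir = .backbone_registry)) {
    stopf("unknown backbone '%s'; available: %s", name,
          paste(list_backbones(), collapse = ", "))
  }
  get(name, envir = .backbone_registry)(pretrained_source, weights_file)
}

# Training configuration -------------------------------------------------------

#' Training configuration for the tile classifier
#'
#' Captures the training contract: cross-entropy-with-logits loss, SGD with
#' momentum, a step-decay (StepLR) learning-rate schedule
#' `lr * lr_gamma^floor((epoch - 1) / lr_step_size)`, and a fixed seed making
#' the run bit-reproducible in single-threaded execution.
#'
#' @param backbone_name registered backbone identifier.
#' @param pretrained_source passed to [make_backbone()].
#' @param epochs number of training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate initial learning rate (> 0).
#' @param lr_step_size epochs between learning-rate decays.
#' @param lr_gamma decay factor in `(0, 1]`.
#' @param momentum SGD momentum coefficient.
#' @param seed integer seed for initialization and batch shuffling.
#' @param class_weights optional 3-vector of per-class loss weights
#'   (Aggregate, Non-GC, GC); `NULL` for unweighted loss.
#' @param weights_file optional backbone weights file.
#' @return object of class `training_config`.
#' @export
training_config <- function(backbone_name = "reference-small",
                            pretrained_source = "none",
                            epochs = 10, batch_size = 32,
                            learning_rate = 0.1, lr_step_size = 4,
                            lr_gamma = 0.5, momentum = 0.9, seed = 1,
                            class_weights = NULL, weights_file = NULL) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (lr_gamma <= 0 || lr_gamma > 1) stop("lr_gamma must lie in (0, 1]", call. = FALSE)
  if (lr_step_size < 1) stop("lr_step_size must be >= 1", call. = FALSE)
  if (!is.null(class_weights) &&
      (length(class_weights) != 3L || any(class_weights <= 0))) {
    stop("class_weights must be 3 positive numbers", call. = FALSE)
  }
  structure(list(backbone_name = backbone_name,
                 pretrained_source = pretrained_source,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_step_size = as.integer(lr_step_size), lr_gamma = lr_gamma,
                 momentum = momentum, seed = as.integer(seed),
                 class_weights = class_weights, weights_file = weights_file),
            class = "training_config")
}

#' Step-decay learning-rate schedule
#'
#' @param config a [training_config()].
#' @return numeric vector of per-epoch learning rates,
#'   `lr * gamma^floor((epoch - 1) / step)`.
#' @export
lr_schedule <- function(config) {
  e <- seq_len(config$epochs)
  config$learning_rate * config$lr_gamma^((e - 1L) %/% config$lr_step_size)
}

# Feature loading ---------------------------------------------------------------

# Build the n x p feature matrix for a manifest: uses the `pixels`
# list-column when present, else reads `tile_path` images.
manifest_features <- function(manifest, backbone) {
  n <- nrow(manifest)
  X <- matrix(0, n, backbone$n_features)
  for (i in seq_len(n)) {
    img <- if (!is.null(manifest$pixels)) manifest$pixels[[i]]
           else read_image(manifest$tile_path[i])
    f <- tryCatch(backbone$featurize(img), error = function(e) {
      stopf("tile '%s': %s", manifest$tile_id[i], conditionMessage(e))
    })
    X[i, ] <- f
  }
  X
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted cross-entropy-with-logits; `w` are per-sample weights (normalized
# to mean 1 so uniform weights reproduce the unweighted loss exactly).
ce_loss <- function(logits, y, w) {
  p <- softmax(logits)
  -sum(w * log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12))) / sum(w)
}

# Model fitting -----------------------------------------------------------------

#' Train the three-class tile classifier
#'
#' Fits the backbone's linear head by minibatch stochastic gradient descent
#' with momentum on the cross-entropy-with-logits loss, with a StepLR
#' learning-rate schedule.  Features are standardized using training-set
#' statistics.  The checkpoint keeps the weights of the epoch with the best
#' validation accuracy (earliest epoch on ties).  With a fixed
#' `config$seed`, the run is bit-reproducible in single-threaded execution.
#'
#' @param train,val tile manifests: data.frames with `true_class` and either
#'   a `pixels` list-column or a `tile_path` column; `patient_id`, when
#'   present in both, is checked for patient-level leakage.
#' @param config a [training_config()].
#' @return an object of class `tls_classifier` with components `weights`
#'   (best-epoch head), `history` (per-epoch data.frame: `epoch`, `lr`,
#'   `train_loss`, `val_loss`, `val_accuracy`), `best_epoch`, `config`,
#'   standardization constants and the backbone.  Methods: `print`,
#'   `summary`, `coef`, `plot`, `predict`.
#' @seealso [predict_tiles()], [save_checkpoint()]
#' @export
train_classifier <- function(train, val, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (!nrow(train)) stop("training manifest is empty", call. = FALSE)
  if (!all(0:2 %in% class_code(train$true_class))) {
    missing_cls <- setdiff(0:2, class_code(train$true_class))
    stopf("class(es) absent from training data: %s (loss weighting undefined)",
          paste(class_label(missing_cls), collapse = ", "))
  }
  if (!is.null(train$patient_id) && !is.null(val$patient_id)) {
    overlap <- intersect(unique(train$patient_id), unique(val$patient_id))
    if (length(overlap)) {
      stopf("patient-level leakage: patient(s) %s appear in both train and validation manifests",
            paste(overlap, collapse = ", "))
    }
  }

  backbone <- make_backbone(config$backbone_name, config$pretrained_source,
                            config$weights_file)
  Xtr <- manifest_features(train, backbone)
  ytr <- class_code(train$true_class)
  Xva <- manifest_features(val, backbone)
  yva <- class_code(val$true_class)

  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, stats::sd)
  scl[scl < 1e-8] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, "/")
  Xva <- sweep(sweep(Xva, 2L, ctr), 2L, scl, "/")

  cw <- if (is.null(config$class_weights)) rep(1, 3) else config$class_weights
  wtr <- cw[ytr + 1L]
  wva <- cw[yva + 1L]
  Ytr <- matrix(0, nrow(Xtr), 3L)
  Ytr[cbind(seq_len(nrow(Xtr)), ytr + 1L)] <- 1

  W <- backbone$init(config$seed)
  V <- W * 0
  lrs <- lr_schedule(config)
  epoch_seeds <- derive_seeds(config$seed + 1L, config$epochs)
  n <- nrow(Xtr)
  hist_rows <- vector("list", config$epochs)
  best <- list(acc = -Inf, W = W, epoch = 0L)

  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(n))
    lr <- lrs[ep]
    batch_losses <- c()
    for (start in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- Xtr[idx, , drop = FALSE]
      Zb <- backbone$forward(W, Xb)
      Pb <- softmax(Zb)
      wb <- wtr[idx]
      batch_losses <- c(batch_losses, ce_loss(Zb, ytr[idx], wb))
      G <- (Pb - Ytr[idx, , drop = FALSE]) * (wb / sum(wb))
      grad <- t(G) %*% cbind(1, Xb)
      V <- config$momentum * V - lr * grad
      W <- W + V
    }
    Zva <- backbone$forward(W, Xva)
    val_acc <- mean(max.col(Zva, ties.method = "last") - 1L == yva)
    hist_rows[[ep]] <- data.frame(
      epoch = ep, lr = lr, train_loss = mean(batch_losses),
      val_loss = ce_loss(Zva, yva, wva), val_accuracy = val_acc)
    if (val_acc > best$acc) best <- list(acc = val_acc, W = W, epoch = ep)
  }

  structure(list(backbone_name = config$backbone_name,
                 backbone = backbone, weights = best$W, final_weights = W,
                 best_epoch = best$epoch,
                 history = do.call(rbind, hist_rows),
                 config = config, feature_center = ctr, feature_scale = scl),
            class = "tls_classifier")
}

#' @export
print.tls_classifier <- function(x, ...) {
  h <- x$history
  cat(sprintf("TLS tile classifier (backbone '%s', %d epochs)\n",
              x$backbone_name, nrow(h)))
  cat(sprintf("  best epoch %d: validation accuracy %.3f\n",
              x$best_epoch, h$val_accuracy[x$best_epoch]))
  invisible(x)
}

#' @export
summary.tls_classifier <- function(object, ...) {
  cat(sprintf("TLS tile classifier\n  backbone: %s (%d parameters)\n",
              object$backbone_name, object$backbone$n_params))
  cat(sprintf("  loss: cross-entropy with logits%s\n",
              if (is.null(object$config$class_weights)) " (unweighted)"
              else " (class-weighted)"))
  cat(sprintf("  schedule: StepLR lr=%g, step=%d, gamma=%g; momentum %g; seed %d\n",
              object$config$learning_rate, object$config$lr_step_size,
              object$config$lr_gamma, object$config$momentum,
              object$config$seed))
  cat("  training history:\n")
  print(object$history, row.names = FALSE, digits = 4)
  invisible(object$history)
}

#' @export
coef.tls_classifier <- function(object, ...) object$weights

#' @export
plot.tls_classifier <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(h)
}

#' Predict class probabilities for tiles
#'
#' @param object a fitted [train_classifier()] model.
#' @param newdata a tile manifest (data.frame with `pixels` or `tile_path`).
#' @param type `"prob"` returns the full prediction frame, `"class"` the
#'   integer class codes.
#' @param ... unused.
#' @return for `type = "prob"`, a data.frame with one row per manifest row
#'   (same order): `tile_id`, `tls_id` (if available), `p_aggregate`,
#'   `p_nongc`, `p_gc`, `pred_class`, `confidence`; probabilities sum to 1.
#' @export
predict.tls_classifier <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!nrow(newdata)) {
    out <- data.frame(tile_id = character(0), p_aggregate = numeric(0),
                      p_nongc = numeric(0), p_gc = numeric(0),
                      pred_class = integer(0), confidence = numeric(0),
                      stringsAsFactors = FALSE)
    if (!is.null(newdata$tls_id)) out$tls_id <- character(0)
    return(if (type == "class") integer(0) else out)
  }
  X <- manifest_features(newdata, object$backbone)
  X <- sweep(sweep(X, 2L, object$feature_center), 2L, object$feature_scale, "/")
  P <- softmax(object$backbone$forward(object$weights, X))
  pred <- max.col(P, ties.method = "last") - 1L  # ties toward more mature
  if (type == "class") return(pred)
  out <- data.frame(
    tile_id = if (!is.null(newdata$tile_id)) newdata$tile_id
              else sprintf("tile_%06d", seq_len(nrow(newdata))),
    p_aggregate = P[, 1], p_nongc = P[, 2], p_gc = P[, 3],
    pred_class = pred, confidence = apply(P, 1L, max),
    stringsAsFactors = FALSE)
  if (!is.null(newdata$tls_id)) out$tls_id <- newdata$tls_id
  out
}

#' @rdname predict.tls_classifier
#' @param checkpoint a `tls_classifier` object (or path to a saved
#'   checkpoint).
#' @param manifest tile manifest data.frame.
#' @export
predict_tiles <- function(checkpoint, manifest) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  stopifnot(inherits(checkpoint, "tls_classifier"))
  predict(checkpoint, manifest, type = "prob")
}

# Checkpoint serialization -------------------------------------------------------

#' Save and load classifier checkpoints
#'
#' Checkpoints are JSON files embedding the configuration snapshot, the full
#' training history, the feature standardization constants and the linear
#' head weights (best epoch and final).  Adapter backbones are reconstructed
#' through [make_backbone()] on load, so external weight files must still be
#' available for adapter-based checkpoints.
#'
#' @param model a `tls_classifier`.
#' @param path JSON file path.
#' @param fold_id optional fold label stored alongside the config.
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: a
#'   `tls_classifier`.
#' @export
save_checkpoint <- function(model, path, fold_id = NULL) {
  stopifnot(inherits(model, "tls_classifier"))
  cfg <- unclass(model$config)
  obj <- list(format = "tlsmat-checkpoint-v1",
              backbone_name = model$backbone_name,
              fold_id = fold_id,
              config = cfg,
              best_epoch = model$best_epoch,
              history = model$history,
              feature_center = model$feature_center,
              feature_scale = model$feature_scale,
              weights = as.vector(model$weights),
              final_weights = as.vector(model$final_weights),
              weights_dim = dim(model$weights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "tlsmat-checkpoint-v1")) {
    stopf("'%s' is not a tlsmat checkpoint", path)
  }
  cfg <- obj$config
  # jsonlite maps NULL to {}: normalize empty fields back to NULL
  cfg$class_weights <- if (length(cfg$class_weights) != 3L) NULL
                       else as.numeric(cfg$class_weights)
  if (!length(cfg$weights_file)) cfg$weights_file <- NULL
  config <- do.call(training_config, cfg)
  backbone <- make_backbone(config$backbone_name, config$pretrained_source,
                            config$weights_file)
  structure(list(backbone_name = obj$backbone_name, backbone = backbone,
                 weights = matrix(obj$weights, obj$weights_dim[1],
                                  obj$weights_dim[2]),
                 final_weights = matrix(obj$final_weights, obj$weights_dim[1],
                                        obj$weights_dim[2]),
                 best_epoch = obj$best_epoch,
                 history = as.data.frame(obj$history),
                 config = config,
                 feature_center = as.numeric(obj$feature_center),
                 feature_scale = as.numeric(obj$feature_scale)),
            class = "tls_classifier")
}
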