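# Two-stage training: the depth predictor is trained first (masked L1 in
# cm, Adam with cosine-annealed learning rate); the fusion network is
# trained second (geometric combination of the five per-task L1 losses,
# Adam with exponential learning-rate decay), with the depth module frozen
# when it supplies the depth input. Desk-scale defaults; the full-scale reference
# recipes live in inst/configs/*_full.yaml.

#' Train the depth prediction stage
#'
#' Optimizes the depth model with the masked L1 loss (cm) over the training
#' split using Adam and a cosine-annealed learning rate. When the dataset
#' has a test split, validation AbsRel is tracked and the best parameters
#' are kept.
#'
#' @param dataset a `nutrition_dataset` whose samples carry depth maps
#' @param model_config a [depth_model_config()]
#' @param steps number of optimizer steps
#' @param batch_size dishes per step
#' @param lr initial Adam learning rate
#' @param lr_min final learning rate of the cosine schedule
#' @param seed seed for weight init and batch sampling
#' @param validate_every validation cadence in steps (0 disables)
#' @return a `depth_checkpoint`: list(model, history, best_val_absrel)
#' @export
train_depth_stage <- function(dataset, model_config = depth_model_config(),
                              steps = 500, batch_size = 8, lr = 2e-3,
                              lr_min = lr / 10, seed = 1L,
                              validate_every = 100) {
  train <- dataset_subset(dataset, "train")$samples
  if (!length(train)) stop("train_depth_stage: empty training split")
  if (is.null(train[[1]]$depth)) stop("train_depth_stage: no depth maps in dataset")
  test <- dataset_subset(dataset, "test")$samples
  model <- build_depth_model(model_config, seed = seed)
  params <- collect_params(model)
  opt <- adam_init(params)
  history <- numeric(steps)
  best <- list(absrel = Inf, flat = NULL)
  order_seed <- seed + 1L
  batches <- with_seed(order_seed, lapply(seq_len(steps), function(i)
    sample.int(length(train), min(batch_size, length(train)),
               replace = length(train) < batch_size)))
  for (step in seq_len(steps)) {
    idx <- batches[[step]]
    ag_zero_grad(params)
    total <- 0
    for (i in idx) {
      s <- train[[i]]
      pred <- depth_forward(model, s$rgb)
      loss <- ag_masked_l1(pred, s$depth, mask = s$depth > 0)
      ag_backward(loss, seed = 1 / length(idx))
      total <- total + loss$value / length(idx)
    }
    opt <- adam_step(opt, params, lr_cosine(step, steps, lr, lr_min))
    history[step] <- total
    if (validate_every > 0 && length(test) &&
        (step %% validate_every == 0 || step == steps)) {
      ar <- mean(vapply(test, function(s) {
        depth_metrics(predict_depth(model, s$rgb), s$depth,
                      mask = s$depth > 0)$absrel
      }, 0))
      if (ar < best$absrel) best <- list(absrel = ar, flat = params_flatten(params))
    }
  }
  if (!is.null(best$flat)) params_unflatten(params, best$flat)
  structure(list(model = model, history = history,
                 best_val_absrel = if (is.finite(best$absrel)) best$absrel else NA_real_),
            class = "depth_checkpoint")
}

# resolve the depth input for every sample of a dataset; `predicted` runs
# the frozen depth model once per dish and caches the result
resolve_depths <- function(samples, depth_source, depth_model = NULL) {
  if (depth_source == "sensor") {
    depths <- lapply(samples, `[[`, "depth")
    if (any(vapply(depths, is.null, TRUE)))
      stop("depth_source = 'sensor' requires stored depth maps")
    return(depths)
  }
  if (is.null(depth_model))
    stop("depth_source = 'predicted' requires a depth model or checkpoint")
  if (inherits(depth_model, "depth_checkpoint")) depth_model <- depth_model$model
  lapply(samples, function(s) predict_depth(depth_model, s$rgb))
}

#' Train the RGB-D fusion stage
#'
#' Optimizes the fusion model with the geometric combination of the five
#' per-task L1 losses, Adam, and per-epoch exponential learning-rate decay.
#' Targets are internally normalized by their training-split means (stored
#' in the returned model as `y_scale`), so the five tasks are trained on a
#' common scale and predictions are reported back in original units. Random
#' horizontal flips are applied to the RGB image and the depth map of a
#' dish together, never independently. The depth module, when used as the
#' depth source, is frozen: only fusion parameters receive updates.
#'
#' @param dataset a `nutrition_dataset`
#' @param model_config a [fusion_model_config()]
#' @param steps number of optimizer steps
#' @param batch_size dishes per step
#' @param lr initial Adam learning rate
#' @param lr_decay exponential decay per epoch
#' @param seed seed for weight init, batch sampling and augmentation
#' @param depth_source `"sensor"` (stored depth maps) or `"predicted"`
#'   (frozen depth model, end-to-end monocular pipeline)
#' @param depth_model depth model or checkpoint for `"predicted"`
#' @param augment `"dihedral"` (random horizontal flips and 90-degree
#'   rotations, valid for square top-down scenes and applied to the RGB
#'   image and depth map of a dish together), `"flip"` (flips only) or
#'   `"none"`
#' @param loss_floor clamp floor for the per-task losses inside the
#'   geometric combination, in normalized target units (fraction of the
#'   task's training mean). A task whose loss falls below the floor is
#'   treated as solved and stops contributing gradient, which keeps the
#'   product's `L/L_k` factors of near-zero tasks from drowning the
#'   still-unsolved ones
#' @param stop_pmae optional early-stopping target: every `stop_every` steps
#'   the training-split mean PMAE is computed and training stops once it
#'   falls below this value (percent)
#' @param stop_every cadence (steps) of the early-stopping check
#' @return a `fusion_checkpoint`: list(model, history, depth_source)
#' @export
train_fusion_stage <- function(dataset, model_config = fusion_model_config(),
                               steps = 500, batch_size = 8, lr = 2e-3,
                               lr_decay = 0.98, seed = 1L,
                               depth_source = c("sensor", "predicted"),
                               depth_model = NULL,
                               augment = c("dihedral", "flip", "none"),
                               loss_floor = 1e-2, stop_pmae = NULL,
                               stop_every = 50) {
  depth_source <- match.arg(depth_source)
  augment <- match.arg(augment)
  train <- dataset_subset(dataset, "train")$samples
  if (!length(train)) stop("train_fusion_stage: empty training split")
  needs_depth <- model_config$streams != "rgb"
  depths <- if (needs_depth) resolve_depths(train, depth_source, depth_model)
            else vector("list", length(train))

  model <- build_fusion_model(model_config, seed = seed)
  labels <- t(vapply(train, function(s) s$label, numeric(5)))
  model$y_scale <- pmax(colMeans(labels), 1e-6)
  # start each head at the training-mean target (normalized target is ~1)
  for (k in 1:5) {
    hd <- model$heads[[k]]
    if (model_config$shared_head) hd$b$value <- 1 else hd$out$b$value <- 1
  }
  targets <- sweep(labels, 2L, model$y_scale, `/`)

  params <- collect_params(model)
  opt <- adam_init(params)
  epoch_len <- max(1L, length(train) %/% batch_size)
  history <- data.frame(step = seq_len(steps), loss = NA_real_)
  plan <- with_seed(seed + 1L, lapply(seq_len(steps), function(i) {
    idx <- sample.int(length(train), min(batch_size, length(train)),
                      replace = length(train) < batch_size)
    list(idx = idx,
         flip = stats::runif(length(idx)) < 0.5,
         rot = sample(0:3, length(idx), replace = TRUE))
  }))
  for (step in seq_len(steps)) {
    idx <- plan[[step]]$idx
    flips <- plan[[step]]$flip & augment != "none"
    rots <- plan[[step]]$rot * (augment == "dihedral")
    ag_zero_grad(params)
    task_nodes <- vector("list", 5)
    for (j in seq_along(idx)) {
      i <- idx[j]
      aug <- augment_pair(train[[i]]$rgb, depths[[i]], flips[j], rots[j])
      outs <- fusion_forward(model, aug$rgb, aug$depth)
      for (k in 1:5) {
        e <- ag_abs(ag_sub(outs[[k]], targets[i, k]))
        task_nodes[[k]] <- if (is.null(task_nodes[[k]])) e
                           else ag_add(task_nodes[[k]], e)
      }
    }
    task_losses <- lapply(task_nodes, function(n) ag_scale(n, 1 / length(idx)))
    total <- ag_geometric_mean(task_losses, eps = loss_floor, warn = FALSE)
    ag_backward(total)
    epoch <- (step - 1L) %/% epoch_len
    opt <- adam_step(opt, params, lr_exponential(epoch, lr, lr_decay))
    history$loss[step] <- as.numeric(total$value)
    if (!is.null(stop_pmae) && step %% stop_every == 0) {
      preds <- t(vapply(seq_along(train), function(i)
        predict_nutrition(model, train[[i]]$rgb, depths[[i]]), numeric(5)))
      colnames(preds) <- NUTRIENTS
      truth <- as.data.frame(labels)
      colnames(truth) <- NUTRIENTS
      if (build_report(as.data.frame(preds), truth)$mean_pmae < stop_pmae) {
        history <- history[seq_len(step), , drop = FALSE]
        break
      }
    }
  }
  structure(list(model = model, history = history, depth_source = depth_source),
            class = "fusion_checkpoint")
}

# flip an (H, W) or (H, W, C) array left-right
flip_horizontal <- function(x) {
  if (length(dim(x)) == 2L) x[, ncol(x):1, drop = FALSE]
  else x[, dim(x)[2]:1, , drop = FALSE]
}

# rotate an (H, W) or (H, W, C) array by k*90 degrees counter-clockwise
# (square images only); top-down dish scenes are rotation-invariant, so
# rotations are label-preserving augmentations
rot90_array <- function(x, k) {
  k <- k %% 4L
  if (k == 0L) return(x)
  two_d <- length(dim(x)) == 2L
  if (two_d) x <- array(x, dim = c(dim(x), 1L))
  for (i in seq_len(k)) {
    d <- dim(x)
    x <- aperm(x, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  if (two_d) matrix(x, dim(x)[1], dim(x)[2]) else x
}

# apply one sampled dihedral-group element (flip + rotation) to a sample
augment_pair <- function(rgb, depth, flip, rot) {
  if (flip) {
    rgb <- flip_horizontal(rgb)
    if (!is.null(depth)) depth <- flip_horizontal(depth)
  }
  if (rot > 0L && dim(rgb)[1] == dim(rgb)[2]) {
    rgb <- rot90_array(rgb, rot)
    if (!is.null(depth)) depth <- rot90_array(depth, rot)
  }
  list(rgb = rgb, depth = depth)
}

#' Evaluate a fusion checkpoint on a dataset split
#'
#' Runs the model over the requested split and aggregates dataset-level
#' MAE/PMAE per nutrient plus mean PMAE into a [build_report()] report.
#'
#' @param checkpoint a `fusion_checkpoint` (or bare `fusion_model`)
#' @param dataset a `nutrition_dataset`
#' @param split `"test"` or `"train"`
#' @param depth_source `"sensor"` or `"predicted"`; defaults to the
#'   checkpoint's training source
#' @param depth_model depth model/checkpoint for `"predicted"`
#' @return a `nutrition_report`
#' @export
evaluate_model <- function(checkpoint, dataset, split = "test",
                           depth_source = NULL, depth_model = NULL) {
  model <- if (inherits(checkpoint, "fusion_checkpoint")) checkpoint$model
           else checkpoint
  depth_source <- depth_source %||%
    (if (inherits(checkpoint, "fusion_checkpoint")) checkpoint$depth_source
     else "sensor")
  part <- dataset_subset(dataset, split)$samples
  if (!length(part)) stop("evaluate_model: empty ", split, " split")
  needs_depth <- model$config$streams != "rgb"
  depths <- if (needs_depth) resolve_depths(part, depth_source, depth_model)
            else vector("list", length(part))
  preds <- t(vapply(seq_along(part), function(i)
    predict_nutrition(model, part[[i]]$rgb, depths[[i]]), numeric(5)))
  colnames(preds) <- NUTRIENTS
  truths <- dataset_labels(structure(list(samples = part), class = "nutrition_dataset"))
  colnames(truths) <- NUTRIENTS
  build_report(as.data.frame(preds), as.data.frame(truths))
}

#' Save a model checkpoint
#'
#' Writes serialized weights (`<path>.rds`: flattened parameter vector +
#' configuration) and a YAML fingerprint (`<path>.yaml`: configuration,
#' parameter count and checksum).
#'
#' @param checkpoint a `depth_checkpoint` or `fusion_checkpoint`
#' @param path output path without extension
#' @return invisible path
#' @export
save_checkpoint <- function(checkpoint, path) {
  model <- checkpoint$model
  kind <- if (inherits(checkpoint, "depth_checkpoint")) "depth" else "fusion"
  params <- collect_params(model)
  flat <- params_flatten(params)
  payload <- list(kind = kind, config = unclass(model$config), params = flat,
                  y_scale = model$y_scale %||% NULL,
                  depth_source = checkpoint$depth_source %||% NULL)
  saveRDS(payload, paste0(path, ".rds"))
  yaml::write_yaml(list(kind = kind, config = unclass(model$config),
                        n_params = length(flat),
                        checksum = sprintf("%.10e", sum(flat))),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path path without extension
#' @return a `depth_checkpoint` or `fusion_checkpoint`
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(paste0(path, ".rds"))
  if (payload$kind == "depth") {
    cfg <- do.call(depth_model_config, payload$config)
    model <- build_depth_model(cfg, seed = 1L)
    params_unflatten(collect_params(model), payload$params)
    structure(list(model = model, history = NULL, best_val_absrel = NA_real_),
              class = "depth_checkpoint")
  } else {
    cfg <- do.call(fusion_model_config, payload$config)
    model <- build_fusion_model(cfg, seed = 1L)
    params_unflatten(collect_params(model), payload$params)
    if (!is.null(payload$y_scale)) model$y_scale <- payload$y_scale
    structure(list(model = model, history = NULL,
                   depth_source = payload$depth_source %||% "sensor"),
              class = "fusion_checkpoint")
  }
}
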