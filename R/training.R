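#' Lesion-grouped stratified train/validation/test split
#'
#' Splits a metadata table into train/validation/test subsets, stratified by
#' diagnosis class so each subset keeps the overall class distribution, and
#' grouped by `lesion_id` so that all images of one lesion (follow-ups) land
#' in the same subset — preventing near-duplicate leakage across subsets.
#'
#' @param metadata data.frame with columns `image_id`, `lesion_id`, `dx`.
#' @param ratios Numeric length-3 vector summing to 1; default `c(.8,.1,.1)`.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A `split_spec`: list with `table` (metadata plus a `subset`
#'   column), `assignment` (named character vector lesion_id -> subset),
#'   `ratios`, `seed`.
#' @export
stratified_split <- function(metadata, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(nrow(metadata) > 0, length(ratios) == 3,
            abs(sum(ratios) - 1) < 1e-9)
  subsets <- c("train", "validation", "test")
  with_seed_local(derive_seed(seed, 17, 3), {
    assignment <- character(0)
    for (cls in unique(metadata$dx)) {
      md_c <- metadata[metadata$dx == cls, ]
      lesions <- unique(md_c$lesion_id)
      n_img <- nrow(md_c)
      if (n_img < length(subsets)) {
        warning("class '", cls, "' has fewer images (", n_img,
                ") than subsets; kept whole in train")
        assignment[lesions] <- "train"
        next
      }
      lesions <- sample(lesions)
      sizes <- as.numeric(table(md_c$lesion_id)[lesions])
      cum <- cumsum(sizes)
      cut1 <- ratios[1] * n_img
      cut2 <- (ratios[1] + ratios[2]) * n_img
      sub <- ifelse(cum <= cut1 + 1e-9, "train",
                    ifelse(cum <= cut2 + 1e-9, "validation", "test"))
      assignment[lesions] <- sub
    }
    table <- metadata
    table$subset <- unname(assignment[table$lesion_id])
    structure(list(table = table, assignment = assignment,
                   ratios = ratios, seed = as.integer(seed)),
              class = "split_spec")
  })
}

#' Images belonging to one subset of a split
#' @param split A `split_spec`.
#' @param subset `"train"`, `"validation"` or `"test"`.
#' @return Character vector of image ids.
#' @export
split_image_ids <- function(split, subset) {
  stopifnot(inherits(split, "split_spec"),
            subset %in% c("train", "validation", "test"))
  split$table$image_id[split$table$subset == subset]
}

#' Focal-loss parameters
#'
#' @param alpha Per-class weights (length 7, all > 0), or a single number
#'   recycled. See [alpha_from_frequencies()] for inverse-frequency weights.
#' @param gamma Focusing exponent (>= 0). `gamma = 0` with unit `alpha`
#'   reduces the loss to categorical cross-entropy.
#' @return A `focal_loss_params` list.
#' @export
focal_loss_params <- function(alpha = 1, gamma = 2) {
  if (length(alpha) == 1) alpha <- rep(alpha, n_lesion_classes())
  stopifnot(all(alpha > 0), gamma >= 0)
  structure(list(alpha = alpha, gamma = gamma), class = "focal_loss_params")
}

#' Frequency-based focal-loss class weights, normalised to mean 1
#'
#' Weights are `(1/frequency)^power`. The default `power = 0.5`
#' (square-root inverse frequency) tempers the weights: with a 67:1
#' nevus-to-dermatofibroma imbalance, raw inverse frequency hands the rare
#' classes weights large enough to push the classifier off the majority
#' class at small training sizes, while the square root keeps the
#' rebalancing effective but bounded. `power = 1` gives plain
#' inverse-frequency weights.
#'
#' @param metadata data.frame with a `dx` column (only classes present get
#'   their empirical frequency; absent classes get the mean weight).
#' @param power Exponent on the inverse frequency, in \[0, 1\].
#' @return Numeric vector of length 7 in [lesion_classes()] order.
#' @export
alpha_from_frequencies <- function(metadata, power = 0.5) {
  stopifnot(power >= 0, power <= 1)
  classes <- lesion_classes()
  freq <- table(factor(metadata$dx, levels = classes))
  w <- ifelse(freq > 0, (1 / pmax(freq, 1))^power, NA)
  w[is.na(w)] <- mean(w, na.rm = TRUE)
  as.numeric(w / mean(w))
}

#' Multiclass focal loss of one prediction
#'
#' `L = -alpha_t * (1 - p_t)^gamma * log(p_t)` where `p_t` is the softmax
#' probability assigned to the true class. The modulating factor
#' `(1 - p_t)^gamma` down-weights easy (confident, correct) examples so that
#' training attends to hard and minority-class examples. `p_t` is clamped at
#' `1e-12` before the logarithm.
#'
#' @param prediction Probability vector over the 7 classes (in
#'   [lesion_classes()] order or named), or the list returned by
#'   [classify_image()].
#' @param true_class Class code of the ground truth.
#' @param params A [focal_loss_params()].
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' p <- c(akiec=.05,bcc=.05,bkl=.1,df=.05,mel=.5,nv=.2,vasc=.05)
#' focal_loss(p, "mel", focal_loss_params(alpha = 1, gamma = 0)) # -log(0.5)
focal_loss <- function(prediction, true_class, params = focal_loss_params()) {
  if (is.list(prediction)) prediction <- prediction$probabilities
  assert_class_code(true_class)
  stopifnot(inherits(params, "focal_loss_params"),
            length(prediction) == n_lesion_classes())
  if (any(prediction < -1e-9) || abs(sum(prediction) - 1) > 1e-6)
    stop("prediction is not a valid probability vector", call. = FALSE)
  ti <- match(true_class, lesion_classes())
  pt <- max(prediction[ti], 1e-12)
  -params$alpha[ti] * (1 - pt)^params$gamma * log(pt)
}

# batch focal loss + gradient w.r.t. logits.
# P: n x M softmax probabilities; tidx: true-class indices
focal_loss_batch <- function(P, tidx, alpha, gamma) {
  n <- nrow(P)
  pt <- pmax(P[cbind(seq_len(n), tidx)], 1e-12)
  at <- alpha[tidx]
  omp <- pmax(1 - pt, 1e-12)
  loss <- -at * omp^gamma * log(pt)
  # dL/dp_t, then chain through softmax: dz = g * p_t * (onehot - p)
  g <- at * (gamma * omp^(gamma - 1) * log(pt) - omp^gamma / pt)
  dlogits <- -P * (g * pt)
  dlogits[cbind(seq_len(n), tidx)] <-
    dlogits[cbind(seq_len(n), tidx)] + g * pt
  list(loss = loss, dlogits = dlogits / n)
}

#' Learning-rate schedule
#'
#' Per-parameter-group schedule: a linear ramp-up from 10% of the group's
#' base rate to the base rate over `rampup_epochs`, followed by exponential
#' decay `base * decay_rate^(epoch - rampup_epochs)`. The two groups are the
#' backbone ("pretrained") layers and the head ("new"/adapted) layers; stage
#' defaults follow the two-stage transfer-learning convention: stage 1
#' backbone 5e-5 / head 1e-2, stage 2 backbone 1e-5 / head 1e-3.
#'
#' @param base_rate_backbone,base_rate_head Base rates (>= 0).
#' @param rampup_epochs Ramp length; must be < `total_epochs`.
#' @param decay_rate Multiplicative decay per post-ramp epoch, in (0, 1].
#' @param total_epochs Schedule horizon.
#' @return An `lr_schedule`.
#' @export
lr_schedule <- function(base_rate_backbone, base_rate_head,
                        rampup_epochs = 5L, decay_rate = 0.95,
                        total_epochs = 40L) {
  stopifnot(base_rate_backbone >= 0, base_rate_head >= 0,
            decay_rate > 0, decay_rate <= 1,
            rampup_epochs >= 0, rampup_epochs < total_epochs)
  structure(list(base_rate_backbone = base_rate_backbone,
                 base_rate_head = base_rate_head,
                 rampup_epochs = as.integer(rampup_epochs),
                 decay_rate = decay_rate,
                 total_epochs = as.integer(total_epochs)),
            class = "lr_schedule")
}

default_schedule <- function(stage, total_epochs = 40L, rampup_epochs = 5L) {
  if (stage == 1)
    lr_schedule(5e-5, 1e-2, rampup_epochs, 0.95, total_epochs)
  else
    lr_schedule(1e-5, 1e-3, rampup_epochs, 0.95, total_epochs)
}

#' Learning rate at a given epoch
#'
#' @param epoch Zero-based epoch index, `< params$total_epochs`.
#' @param group `"pretrained"` (backbone) or `"new_layers"` (head; alias
#'   `"adapted"`).
#' @param stage 1 or 2; selects the default schedule when `params` is NULL.
#' @param params An [lr_schedule()]; default depends on `stage`.
#' @return Positive scalar rate.
#' @export
#' @examples
#' learning_rate(5, "pretrained", stage = 1)   # 5e-5 at end of ramp-up
learning_rate <- function(epoch, group = c("pretrained", "new_layers",
                                           "adapted"),
                          stage = 1, params = NULL) {
  group <- match.arg(group)
  if (is.null(params)) params <- default_schedule(stage)
  stopifnot(inherits(params, "lr_schedule"))
  if (epoch < 0 || epoch >= params$total_epochs)
    stop("epoch ", epoch, " outside schedule horizon [0, ",
         params$total_epochs, ")", call. = FALSE)
  base <- if (group == "pretrained") params$base_rate_backbone
          else params$base_rate_head
  r <- params$rampup_epochs
  if (r > 0 && epoch < r) base * (0.1 + 0.9 * epoch / r)
  else base * params$decay_rate^(epoch - r)
}

# ---- augmentation ---------------------------------------------------------

#' Augmentation configuration
#'
#' Stage 1 applies geometric symmetries, sinusoidal distortion, Gaussian
#' noise, brightness/contrast, per-channel colour scaling, resize +
#' random crop to the target resolution, and coarse dropout. Stage 2 applies
#' only random flips/rotations (the 8 dihedral symmetries) plus resize.
#'
#' @param stage 1 or 2.
#' @param p Named list overriding individual transform probabilities
#'   (`geom`, `distort`, `noise`, `brightness`, `color`, `crop`, `coarse`).
#' @return An `augment_config`.
#' @export
augment_config <- function(stage = 1, p = list()) {
  defaults <- if (stage == 1) {
    list(geom = 0.5, distort = 0.3, noise = 0.5, brightness = 0.5,
         color = 0.5, crop = 0.8, coarse = 0.3)
  } else {
    list(geom = 1, distort = 0, noise = 0, brightness = 0,
         color = 0, crop = 0, coarse = 0)
  }
  defaults[names(p)] <- p
  structure(c(defaults, list(stage = stage)), class = "augment_config")
}

# one of the 8 dihedral symmetries applied channel-wise
dihedral_transform <- function(arr, k) {
  rot <- k %% 4
  flip <- k >= 4
  tf <- function(M) {
    if (flip) M <- M[, rev(seq_len(ncol(M))), drop = FALSE]
    for (i in seq_len(rot)) M <- t(M[rev(seq_len(nrow(M))), , drop = FALSE])
    M
  }
  out <- NULL
  for (ch in seq_len(dim(arr)[3])) {
    M <- tf(arr[, , ch])
    if (is.null(out)) out <- array(0, dim = c(dim(M), dim(arr)[3]))
    out[, , ch] <- M
  }
  out
}

resize_image <- function(arr, size) {
  was_mat <- is.matrix(arr)
  if (was_mat) arr <- array(arr, dim = c(dim(arr), 1L))
  if (dim(arr)[1] == size && dim(arr)[2] == size) {
    return(if (was_mat) arr[, , 1] else arr)
  }
  out <- array(0, dim = c(size, size, dim(arr)[3]))
  for (ch in seq_len(dim(arr)[3]))
    out[, , ch] <- as.matrix(EBImage::resize(arr[, , ch], w = size,
                                             h = size))
  if (was_mat) out[, , 1] else out
}

#' Augment one image
#'
#' @param image A `labeled_image` or an H x W x C array in \[0,1\].
#' @param stage 1 (full augmentation) or 2 (flips/rotations only).
#' @param seed Integer seed; the augmented output is deterministic in
#'   `(image, stage, seed, config)`.
#' @param target_size Output resolution (pixels per side); default 64.
#' @param config An [augment_config()]; defaults to the stage's default.
#' @return Same type as `image` with pixels (and mask, when present)
#'   transformed; pixel range stays in \[0,1\].
#' @export
augment <- function(image, stage = 1, seed = 1L, target_size = 64L,
                    config = augment_config(stage)) {
  is_li <- inherits(image, "labeled_image")
  arr <- if (is_li) image$pixels else image
  stopifnot(length(dim(arr)) == 3)
  out <- with_seed_local(derive_seed(seed, 37, stage), {
    if (stage == 2) {
      k <- sample(0:7, 1)
      arr <- dihedral_transform(arr, k)
      arr <- resize_image(arr, target_size)
    } else {
      if (runif(1) < config$geom)
        arr <- dihedral_transform(arr, sample(0:7, 1))
      if (runif(1) < config$distort) {
        amp <- sample(1:2, 1); frq <- runif(1, 1, 3); ph <- runif(1, 0, 2*pi)
        n <- nrow(arr)
        sh <- round(amp * sin(2 * pi * frq * seq_len(n) / n + ph))
        for (r in seq_len(n)) {
          if (sh[r] != 0) {
            idx <- pmin(pmax(seq_len(ncol(arr)) - sh[r], 1), ncol(arr))
            arr[r, , ] <- arr[r, idx, ]
          }
        }
      }
      if (runif(1) < config$noise)
        arr <- arr + array(rnorm(length(arr), 0, 0.02), dim = dim(arr))
      if (runif(1) < config$brightness) {
        ctr <- runif(1, 0.85, 1.15); br <- runif(1, -0.08, 0.08)
        arr <- (arr - 0.5) * ctr + 0.5 + br
      }
      if (runif(1) < config$color) {
        for (ch in seq_len(min(3, dim(arr)[3])))
          arr[, , ch] <- arr[, , ch] * runif(1, 0.92, 1.08)
      }
      # resize slightly above target, then crop back to target
      big <- as.integer(ceiling(target_size * 1.15))
      arr <- resize_image(arr, big)
      margin <- big - target_size
      if (runif(1) < config$crop) {
        r0 <- sample.int(margin + 1, 1); c0 <- sample.int(margin + 1, 1)
      } else {
        r0 <- floor(margin / 2) + 1; c0 <- floor(margin / 2) + 1
      }
      arr <- arr[r0:(r0 + target_size - 1), c0:(c0 + target_size - 1), ,
                 drop = FALSE]
      if (runif(1) < config$coarse) {
        for (i in seq_len(sample(1:3, 1))) {
          side <- sample.int(max(2, round(target_size * 0.16)), 1) + 1
          r0 <- sample.int(target_size - side, 1)
          c0 <- sample.int(target_size - side, 1)
          fill <- mean(arr)
          arr[r0:(r0 + side), c0:(c0 + side), ] <- fill
        }
      }
    }
    arr[arr < 0] <- 0; arr[arr > 1] <- 1
    arr
  })
  if (is_li) { image$pixels <- out; image } else out
}

# ---- training loops -------------------------------------------------------

# shared minibatch trainer over prepared input arrays.
# xs: list of H x W x C arrays at native size; augmentation brings them to
# the model resolution. Returns the best-validation-loss checkpoint.
fit_classifier <- function(model, xs, ys, val_xs, val_ys, stage,
                           loss_params, schedule, epochs, batch_size = 32L,
                           seed = 1L, verbose = FALSE) {
  res <- model$config$input_resolution
  alpha <- loss_params$alpha; gamma <- loss_params$gamma
  params <- model_params(model)
  opt <- adam_init(params)
  n <- length(xs)
  stopifnot(n > 0)
  # pre-resize once (no augmentation): validation inputs, and the training
  # inputs used to calibrate batch-norm inference statistics
  val_prep <- lapply(val_xs, resize_image, size = res)
  train_prep <- lapply(xs, resize_image, size = res)
  log <- data.frame()
  best <- list(loss = Inf, params = params, bn = model$bn, epoch = -1L)
  for (epoch in seq_len(epochs) - 1L) {
    lr <- list(backbone = learning_rate(epoch, "pretrained", stage, schedule),
               head = learning_rate(epoch, "new_layers", stage, schedule))
    epoch_loss <- 0; epoch_correct <- 0
    with_seed_local(derive_seed(seed, 1009, epoch), {
      ord <- sample.int(n)
      nb <- ceiling(n / batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size, n)]
        if (length(idx) < 2 && nb > 1) next  # batch norm needs >= 2
        model <- set_model_params(model, params)
        bs <- length(idx)
        feats <- matrix(0, bs, model$config$feature_dim)
        caches <- vector("list", bs)
        xb <- vector("list", bs)
        for (j in seq_len(bs)) {
          xb[[j]] <- augment(xs[[idx[j]]], stage = stage,
                             seed = sample.int(2^30, 1), target_size = res)
          bf <- backbone_forward(model, xb[[j]], keep_cache = TRUE)
          feats[j, ] <- bf$feat
          caches[[j]] <- bf$cache
        }
        hf <- head_forward(model, feats, training = TRUE)
        fl <- focal_loss_batch(hf$probs, ys[idx], alpha, gamma)
        if (!all(is.finite(fl$loss)))
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        epoch_loss <- epoch_loss + sum(fl$loss)
        epoch_correct <- epoch_correct +
          sum(max.col(hf$probs) == ys[idx])
        hb <- head_backward(model, hf$cache, fl$dlogits)
        grads <- list(bn_gamma = hb$grads$bn$dgamma,
                      bn_beta = hb$grads$bn$dbeta,
                      fc1_W = hb$grads$fc1$dW, fc1_b = hb$grads$fc1$db,
                      fc2_W = hb$grads$fc2$dW, fc2_b = hb$grads$fc2$db)
        for (j in seq_len(bs)) {
          bb <- backbone_backward(model, caches[[j]], hb$dF[j, ])
          for (li in seq_along(bb$grads)) {
            wn <- sprintf("conv%d_W", li); bn_ <- sprintf("conv%d_b", li)
            if (is.null(grads[[wn]])) {
              grads[[wn]] <- bb$grads[[li]]$dW
              grads[[bn_]] <- bb$grads[[li]]$db
            } else {
              grads[[wn]] <- grads[[wn]] + bb$grads[[li]]$dW
              grads[[bn_]] <- grads[[bn_]] + bb$grads[[li]]$db
            }
          }
        }
        st <- adam_step(params, grads, opt, lr)
        params <- st$params; opt <- st$state
      }
    })
    model <- set_model_params(model, params)
    # calibrate batch-norm inference statistics on the clean training set:
    # pooled features have small per-feature variance, so a momentum EMA over
    # shifting batch statistics is too stale to evaluate with
    model <- bn_calibrate(model, train_prep)
    val <- evaluate_classifier(model, val_prep, val_ys, alpha, gamma)
    log <- rbind(log, data.frame(
      epoch = epoch, lr_backbone = lr$backbone, lr_head = lr$head,
      train_loss = epoch_loss / n, train_acc = epoch_correct / n,
      val_loss = val$loss, val_acc = val$acc))
    if (verbose)
      message(sprintf("epoch %2d loss %.4f acc %.3f | val %.4f acc %.3f",
                      epoch, epoch_loss / n, epoch_correct / n,
                      val$loss, val$acc))
    if (is.finite(val$loss) && val$loss < best$loss) {
      best <- list(loss = val$loss, params = params, bn = model$bn,
                   epoch = epoch)
    }
  }
  model <- set_model_params(model, best$params)
  model$bn <- best$bn
  model$model_id <- model_fingerprint(model)
  model$training_log <- log
  model$best_epoch <- best$epoch
  model
}

# inference-mode loss/accuracy on prepared (model-resolution) arrays
evaluate_classifier <- function(model, xs, ys, alpha = rep(1, 7), gamma = 0) {
  if (length(xs) == 0) return(list(loss = NA_real_, acc = NA_real_))
  feats <- t(vapply(xs, function(x) backbone_forward(model, x)$feat,
                    numeric(model$config$feature_dim)))
  hf <- head_forward(model, feats, training = FALSE)
  fl <- focal_loss_batch(hf$probs, ys, alpha, gamma)
  list(loss = mean(fl$loss), acc = mean(max.col(hf$probs) == ys),
       probs = hf$probs)
}

prep_subset <- function(dataset, split, subset) {
  ids <- split_image_ids(split, subset)
  keep <- vapply(dataset$images, function(im) im$image_id %in% ids,
                 logical(1))
  imgs <- dataset$images[keep]
  list(xs = lapply(imgs, `[[`, "pixels"),
       ys = match(vapply(imgs, `[[`, "", "label"), lesion_classes()),
       ids = vapply(imgs, `[[`, "", "image_id"),
       images = imgs)
}

#' Train the stage-1 (3-channel RGB) classifier
#'
#' Minibatch training with the multiclass focal loss, per-group learning
#' rates (backbone vs head) under the ramp-up + exponential-decay schedule,
#' and stage-1 augmentation. Returns the checkpoint with the best validation
#' loss; the per-epoch log is attached as `$training_log`.
#'
#' @param dataset List with `images` and `metadata` (see
#'   [generate_dataset()]).
#' @param split A [stratified_split()] result.
#' @param model3 A 3-channel `secbir_model` to train.
#' @param loss_params [focal_loss_params()]; default gamma = 2 with
#'   inverse-frequency alpha from the training subset.
#' @param schedule [lr_schedule()]; default [default_schedule()] for stage 1.
#' @param epochs Number of epochs (default 20).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed controlling shuffling, augmentation and dropout.
#' @param verbose Print per-epoch progress.
#' @return The trained `secbir_model` (best validation checkpoint).
#' @export
train_stage1 <- function(dataset, split, model3, loss_params = NULL,
                         schedule = NULL, epochs = 20L, batch_size = 32L,
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model3, "secbir_model"),
            model3$config$in_channels == 3L)
  tr <- prep_subset(dataset, split, "train")
  va <- prep_subset(dataset, split, "validation")
  stopifnot(length(tr$xs) > 0)
  if (is.null(loss_params)) {
    md_tr <- split$table[split$table$subset == "train", ]
    loss_params <- focal_loss_params(alpha_from_frequencies(md_tr), 2)
  }
  if (is.null(schedule)) schedule <- default_schedule(1, epochs,
                                                      min(5L, epochs - 1L))
  fit_classifier(model3, tr$xs, tr$ys, va$xs, va$ys, stage = 1,
                 loss_params = loss_params, schedule = schedule,
                 epochs = epochs, batch_size = batch_size, seed = seed,
                 verbose = verbose)
}

#' Fine-tune the 4-channel (RGB + saliency) classifier (stage 2)
#'
#' Expands the trained stage-1 model to a 4-channel input, composes each
#' image with its saliency map, and fine-tunes with stage-2 augmentation
#' (flips/rotations only) and the stage-2 learning rates. Saliency maps are
#' computed once from the frozen stage-1 model and reused for all epochs.
#'
#' @param dataset,split As in [train_stage1()].
#' @param model3_trained The trained 3-channel stage-1 model.
#' @param saliency_maps Named list: `image_id` -> saliency matrix in \[0,1\]
#'   (see [saliency_for_dataset()]). A missing map for any train/validation
#'   image is an error naming the image id.
#' @param loss_params,schedule,epochs,batch_size,seed,verbose As in
#'   [train_stage1()]; `schedule` defaults to the stage-2 rates.
#' @param init_mode New-channel weight initialisation, see
#'   [expand_input_channels()].
#' @return The trained 4-channel `secbir_model`.
#' @export
train_stage2 <- function(dataset, split, model3_trained, saliency_maps,
                         loss_params = NULL, schedule = NULL, epochs = 20L,
                         batch_size = 32L, seed = 1L,
                         init_mode = "rgb_mean", verbose = FALSE) {
  stopifnot(inherits(model3_trained, "secbir_model"),
            model3_trained$config$in_channels == 3L)
  model4 <- expand_input_channels(model3_trained, init_mode = init_mode,
                                  seed = seed)
  tr <- prep_subset(dataset, split, "train")
  va <- prep_subset(dataset, split, "validation")
  compose_all <- function(sub) {
    lapply(seq_along(sub$xs), function(i) {
      id <- sub$ids[i]
      if (is.null(saliency_maps[[id]]))
        stop("missing saliency map for image '", id, "'", call. = FALSE)
      compose_four_channel(sub$xs[[i]], saliency_maps[[id]])
    })
  }
  tr4 <- compose_all(tr)
  va4 <- compose_all(va)
  if (is.null(loss_params)) {
    md_tr <- split$table[split$table$subset == "train", ]
    loss_params <- focal_loss_params(alpha_from_frequencies(md_tr), 2)
  }
  if (is.null(schedule)) schedule <- default_schedule(2, epochs,
                                                      min(5L, epochs - 1L))
  fit_classifier(model4, tr4, tr$ys, va4, va$ys, stage = 2,
                 loss_params = loss_params, schedule = schedule,
                 epochs = epochs, batch_size = batch_size, seed = seed,
                 verbose = verbose)
}
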