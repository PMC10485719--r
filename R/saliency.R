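#' Vanilla-gradient saliency map
#'
#' Computes the gradient of a class score with respect to the input pixels,
#' reduces it over the colour channels, and min-max normalises it to \[0,1\].
#' By default the gradient is taken on the pre-softmax score (logit) of the
#' model's predicted class: the logit avoids vanishing gradients at confident
#' predictions, and the predicted class needs no ground truth at query time.
#' A constant (e.g. all-zero) raw gradient maps to an all-zero saliency map.
#'
#' @param model A `secbir_model` (used in inference mode).
#' @param image Array matching the model's input contract.
#' @param target `"predicted"` (default), `"true"` (requires `true_class`),
#'   or an explicit class code.
#' @param true_class Ground-truth class, used when `target = "true"`.
#' @param reduction Channel reduction: `"max_abs"` (default) or `"mean_abs"`,
#'   applied over the colour channels.
#' @param score `"logit"` (default) or `"prob"` (gradient of the softmax
#'   probability instead).
#' @param image_id Optional id stored in the result.
#' @return A `saliency_map`: list with `values` (H x W matrix in \[0,1\]),
#'   `target_class`, `model_id`, `image_id`.
#' @export
vanilla_gradient <- function(model, image, target = "predicted",
                             true_class = NULL,
                             reduction = c("max_abs", "mean_abs"),
                             score = c("logit", "prob"),
                             image_id = NA_character_) {
  reduction <- match.arg(reduction)
  score <- match.arg(score)
  check_image_dims(model, image)
  bf <- backbone_forward(model, image, keep_cache = TRUE)
  hf <- head_forward(model, matrix(bf$feat, nrow = 1), training = FALSE)
  cls <- model$classes
  tclass <- if (identical(target, "predicted")) {
    cls[which.max(hf$probs)]
  } else if (identical(target, "true")) {
    if (is.null(true_class)) stop("target='true' requires true_class",
                                  call. = FALSE)
    true_class
  } else target
  ti <- match(tclass, cls)
  if (is.na(ti)) stop("unknown target class '", tclass, "'", call. = FALSE)
  dlogits <- matrix(0, 1, length(cls))
  if (score == "logit") {
    dlogits[1, ti] <- 1
  } else {
    p <- as.numeric(hf$probs)
    dlogits[1, ] <- -p[ti] * p
    dlogits[1, ti] <- dlogits[1, ti] + p[ti]
  }
  hb <- head_backward(model, hf$cache, dlogits)
  bb <- backbone_backward(model, bf$cache, hb$dF[1, ], need_dx = TRUE)
  g <- abs(bb$dX[, , seq_len(min(3, dim(bb$dX)[3])), drop = FALSE])
  values <- if (reduction == "max_abs") apply(g, c(1, 2), max)
            else apply(g, c(1, 2), mean)
  structure(list(image_id = image_id,
                 values = normalize_saliency(values),
                 target_class = tclass,
                 model_id = model$model_id),
            class = "saliency_map")
}

#' Min-max normalise a saliency grid to \[0,1\]
#'
#' Constant grids (zero gradient) map to all zeros. Idempotent on already
#' normalised grids.
#'
#' @param values Numeric matrix.
#' @return Matrix with values in \[0,1\]; max 1 unless constant.
#' @export
normalize_saliency <- function(values) {
  rng <- range(values)
  if (diff(rng) <= 0) return(values * 0)
  (values - rng[1]) / diff(rng)
}

#' Compose a 4-channel (RGB + saliency) input
#'
#' Channels are ordered R, G, B, S. If the saliency grid was computed at a
#' different resolution it is resized with bilinear interpolation to the
#' image's spatial size.
#'
#' @param image H x W x 3 array in \[0,1\] (or a `labeled_image`).
#' @param map A `saliency_map` or a numeric matrix in \[0,1\].
#' @return H x W x 4 array in \[0,1\].
#' @export
compose_four_channel <- function(image, map) {
  if (inherits(image, "labeled_image")) image <- image$pixels
  v <- if (inherits(map, "saliency_map")) map$values else map
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, is.matrix(v))
  if (!all(dim(v) == dim(image)[1:2]))
    v <- resize_image(v, dim(image)[1])
  if (!all(dim(v) == dim(image)[1:2]))
    stop("saliency map size ", paste(dim(v), collapse = "x"),
         " incompatible with image ", paste(dim(image)[1:2], collapse = "x"),
         call. = FALSE)
  v <- pmin(pmax(v, 0), 1)
  out <- array(0, dim = c(dim(image)[1:2], 4L))
  out[, , 1:3] <- image
  out[, , 4] <- v
  out
}

#' Render a heat-map overlay of a saliency map on its image
#'
#' Alpha-blends a colour-mapped saliency grid over the RGB image:
#' `opacity * heat + (1 - opacity) * image`, pixel-wise.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param map A `saliency_map` or matrix.
#' @param opacity Blend weight in \[0,1\]; 0 returns the image unchanged,
#'   1 the pure colour-mapped saliency.
#' @return H x W x 3 array in \[0,1\].
#' @export
render_overlay <- function(image, map, opacity = 0.5) {
  if (inherits(image, "labeled_image")) image <- image$pixels
  v <- if (inherits(map, "saliency_map")) map$values else map
  stopifnot(opacity >= 0, opacity <= 1, all(dim(v) == dim(image)[1:2]))
  ramp <- grDevices::colorRamp(c("black", "darkblue", "red", "yellow"))
  cols <- ramp(as.vector(v)) / 255
  heat <- array(cols, dim = c(dim(v), 3))
  opacity * heat + (1 - opacity) * image
}

#' Compute saliency maps for (a subset of) a dataset
#'
#' Images are resized to the model resolution, and one vanilla-gradient map
#' is computed per image from the frozen model. This is the discrete saliency
#' extraction step between classifier training and 4-channel fine-tuning.
#'
#' @param model Trained 3-channel `secbir_model`.
#' @param dataset Dataset list (`images`, `metadata`).
#' @param ids Image ids to process; default all.
#' @param target Gradient target, see [vanilla_gradient()].
#' @return Named list: image_id -> H x W saliency matrix (model resolution).
#' @export
saliency_for_dataset <- function(model, dataset, ids = NULL,
                                 target = "predicted") {
  if (is.null(ids)) ids <- vapply(dataset$images, `[[`, "", "image_id")
  res <- model$config$input_resolution
  maps <- list()
  for (im in dataset$images) {
    if (!(im$image_id %in% ids)) next
    x <- resize_image(im$pixels, res)
    sm <- vanilla_gradient(model, x, target = target,
                           true_class = im$label, image_id = im$image_id)
    maps[[im$image_id]] <- sm$values
  }
  maps
}

#' Persist saliency maps as single-channel PNGs with a JSON manifest
#'
#' @param maps Named list from [saliency_for_dataset()].
#' @param dir Output directory.
#' @param model_id Checkpoint fingerprint recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_saliency <- function(maps, dir, model_id = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(maps))
    png::writePNG(maps[[id]], file.path(dir, paste0(id, "_sal.png")))
  jsonlite::write_json(
    list(model_id = model_id, reduction = "max_abs",
         normalization = "per-image min-max", image_ids = names(maps)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_saliency
#' @export
read_saliency <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  maps <- lapply(man$image_ids, function(id) {
    m <- png::readPNG(file.path(dir, paste0(id, "_sal.png")))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  names(maps) <- man$image_ids
  maps
}
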