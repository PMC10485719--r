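#' Backbone configuration
#'
#' Two backbones are provided. `reference_b4` is the full-scale reference
#' specification: 380 x 380 input and a 1792-wide pooled feature tap, matching
#' the feature width of the EfficientNet-B4 family used for dermoscopy
#' classification; it is a stride-2 convolutional stack ending in a 1x1
#' convolution to 1792 channels. `tiny_test` is a desk-scale backbone
#' (64 x 64 input, 4 conv blocks, 64-wide features) for experiments and tests
#' on synthetic data.
#'
#' @param backbone_name `"reference_b4"` or `"tiny_test"`.
#' @param in_channels 3 (RGB) or 4 (RGB + saliency).
#' @param input_resolution Pixels per side; defaults to the backbone's native
#'   resolution (380 for `reference_b4`, 64 for `tiny_test`).
#' @param pretrained_init Reserved flag; the package initialises weights
#'   randomly (He initialisation) and never downloads weights.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(backbone_name = c("tiny_test", "reference_b4"),
                            in_channels = 3L,
                            input_resolution = NULL,
                            pretrained_init = FALSE) {
  backbone_name <- match.arg(backbone_name)
  if (!in_channels %in% c(3L, 4L))
    stop("in_channels must be 3 or 4", call. = FALSE)
  if (is.null(input_resolution))
    input_resolution <- if (backbone_name == "reference_b4") 380L else 64L
  stopifnot(input_resolution > 0)
  structure(list(backbone_name = backbone_name,
                 in_channels = as.integer(in_channels),
                 input_resolution = as.integer(input_resolution),
                 pretrained_init = isTRUE(pretrained_init)),
            class = "backbone_config")
}

backbone_plan <- function(name, in_channels) {
  switch(name,
    tiny_test = list(
      channels = c(in_channels, 16L, 32L, 64L, 64L),
      kernels = c(3L, 3L, 3L, 3L),
      strides = c(2L, 2L, 2L, 2L),
      pads = c(1L, 1L, 1L, 1L),
      feature_dim = 64L, head_width = 32L),
    reference_b4 = list(
      channels = c(in_channels, 48L, 96L, 192L, 336L, 672L, 1792L),
      kernels = c(3L, 3L, 3L, 3L, 3L, 1L),
      strides = c(2L, 2L, 2L, 2L, 2L, 1L),
      pads = c(1L, 1L, 1L, 1L, 1L, 0L),
      feature_dim = 1792L, head_width = 512L),
    stop("unsupported backbone '", name, "'", call. = FALSE))
}

#' Build a lesion classifier
#'
#' Assembles the convolutional backbone and the classification head: global
#' average pooling over the last convolutional feature map, batch
#' normalization, then two dropout + dense blocks, the final dense layer
#' ending in a softmax over the classes. Deep features for retrieval are
#' tapped at the pooled activations, just after the last convolutional layer
#' and before the classification head.
#'
#' @param config A [backbone_config()].
#' @param n_classes Number of output classes (>= 2); default 7.
#' @param seed Integer seed for weight initialisation.
#' @return A `secbir_model`.
#' @export
#' @examples
#' m <- build_classifier(backbone_config("tiny_test"), n_classes = 7)
#' m$config$feature_dim
build_classifier <- function(config, n_classes = n_lesion_classes(),
                             seed = 1L) {
  stopifnot(inherits(config, "backbone_config"), n_classes >= 2)
  plan <- backbone_plan(config$backbone_name, config$in_channels)
  with_seed_local(derive_seed(seed, 7, 5), {
    nl <- length(plan$kernels)
    conv <- vector("list", nl)
    for (i in seq_len(nl)) {
      conv[[i]] <- new_conv_layer(plan$channels[i], plan$channels[i + 1],
                                  k = plan$kernels[i],
                                  stride = plan$strides[i],
                                  pad = plan$pads[i])
    }
    D <- plan$feature_dim
    model <- list(
      config = list(backbone_name = config$backbone_name,
                    in_channels = config$in_channels,
                    input_resolution = config$input_resolution,
                    feature_dim = D,
                    head_width = plan$head_width,
                    dropout = c(0.3, 0.2),
                    n_classes = as.integer(n_classes)),
      conv = conv,
      bn = list(gamma = rep(1, D), beta = rep(0, D),
                rm = rep(0, D), rv = rep(1, D),
                eps = 1e-5, momentum = 0.9),
      fc1 = new_dense_layer(D, plan$head_width),
      fc2 = new_dense_layer(plan$head_width, n_classes),
      classes = if (n_classes == n_lesion_classes()) lesion_classes()
                else paste0("class", seq_len(n_classes))
    )
    model$model_id <- model_fingerprint(model)
    structure(model, class = "secbir_model")
  })
}

# cheap content fingerprint so indices can verify they match a model
model_fingerprint <- function(model) {
  s <- 0
  for (ly in model$conv) s <- s + sum(abs(ly$W)) + sum(abs(ly$b))
  s <- s + sum(abs(model$fc1$W)) + sum(abs(model$fc2$W))
  sprintf("%s-%08x", model$config$backbone_name,
          as.integer(round((s %% 1) * 2^28) + floor(s) %% 2^20))
}

check_image_dims <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != model$config$in_channels)
    stop("image must be H x W x ", model$config$in_channels,
         " for this model (got ", paste(d, collapse = "x"), ")",
         call. = FALSE)
  if (d[1] != model$config$input_resolution ||
      d[2] != model$config$input_resolution)
    stop("image spatial size ", d[1], "x", d[2],
         " does not match model input resolution ",
         model$config$input_resolution, call. = FALSE)
  invisible(TRUE)
}

#' Classify one image
#'
#' Runs the model in inference mode (dropout off, batch norm on running
#' statistics) and returns softmax class probabilities.
#'
#' @param model A `secbir_model`.
#' @param image H x W x C array matching the model's input contract.
#' @return List with `probabilities` (named numeric, sums to 1) and
#'   `predicted_class`.
#' @export
classify_image <- function(model, image) {
  check_image_dims(model, image)
  bf <- backbone_forward(model, image)
  hf <- head_forward(model, matrix(bf$feat, nrow = 1), training = FALSE)
  p <- as.numeric(hf$probs)
  names(p) <- model$classes
  list(probabilities = p,
       predicted_class = model$classes[which.max(p)])
}

#' Extract the deep-feature vector of an image
#'
#' The retrieval embedding: pooled activations after the last convolutional
#' layer, before any classification layer. Deterministic in inference mode.
#'
#' @param model A `secbir_model`.
#' @param image H x W x C array matching the model's input contract.
#' @return Numeric vector of length `model$config$feature_dim`.
#' @export
extract_features <- function(model, image) {
  check_image_dims(model, image)
  backbone_forward(model, image)$feat
}

#' Expand a 3-channel classifier to 4 input channels
#'
#' Appends a fourth input channel (the saliency map) to the first convolution.
#' Every parameter other than the new channel's first-convolution weights is
#' copied verbatim, so with `init_mode = "zero"` the expanded model's logits
#' on any RGB image are identical to the original's regardless of the saliency
#' channel content.
#'
#' @param model3 A 3-channel `secbir_model`.
#' @param init_mode Initialisation of the new channel's weights: `"rgb_mean"`
#'   (default; mean of the three copied RGB kernels), `"zero"`, or `"random"`.
#' @param seed Seed used only for `init_mode = "random"`.
#' @return A 4-channel `secbir_model`.
#' @export
expand_input_channels <- function(model3,
                                  init_mode = c("rgb_mean", "zero", "random"),
                                  seed = 1L) {
  init_mode <- match.arg(init_mode)
  stopifnot(inherits(model3, "secbir_model"))
  if (model3$config$in_channels != 3L)
    stop("model already has ", model3$config$in_channels,
         " input channels; expected 3", call. = FALSE)
  model <- model3
  ly <- model$conv[[1]]
  kk <- ly$k * ly$k
  # rows are channel-major blocks of kh*kw; append the 4th channel block
  blocks <- lapply(0:2, function(c) ly$W[c * kk + seq_len(kk), , drop = FALSE])
  W_new <- switch(init_mode,
    zero = matrix(0, kk, ly$out_ch),
    rgb_mean = (blocks[[1]] + blocks[[2]] + blocks[[3]]) / 3,
    random = with_seed_local(seed,
      matrix(rnorm(kk * ly$out_ch, sd = sqrt(2 / (kk * 4))), kk, ly$out_ch)))
  model$conv[[1]]$W <- rbind(ly$W, W_new)
  model$conv[[1]]$in_ch <- 4L
  model$config$in_channels <- 4L
  model$model_id <- model_fingerprint(model)
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is written with `saveRDS()`; a sidecar JSON
#' (`<path>.json`) records the backbone configuration, class vocabulary and
#' model id for provenance.
#'
#' @param model A `secbir_model`.
#' @param path Destination file.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(config = model$config, classes = model$classes,
                            model_id = model$model_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "secbir_model"))
  model
}

#' @export
print.secbir_model <- function(x, ...) {
  cat("<secbir_model> backbone:", x$config$backbone_name,
      "| in_channels:", x$config$in_channels,
      "| input:", x$config$input_resolution,
      "| feature_dim:", x$config$feature_dim,
      "| classes:", length(x$classes), "\n")
  invisible(x)
}
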