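# Internal CNN engine: convolutional backbone (RcppArmadillo kernels), pooled
# feature tap, batch-norm + dropout/dense head, Adam. All tensors are plain R
# arrays (H x W x C); batches are handled as lists of arrays with pooled
# features collected into an n x D matrix.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

new_conv_layer <- function(in_ch, out_ch, k = 3L, stride = 2L, pad = 1L) {
  fan_in <- k * k * in_ch
  list(W = matrix(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                  fan_in, out_ch),
       b = numeric(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

new_dense_layer <- function(d_in, d_out) {
  list(W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

# ---- backbone -------------------------------------------------------------

# forward through the conv stack; returns pooled feature vector and, if
# keep_cache, the per-layer inputs and post-ReLU outputs needed for backprop
backbone_forward <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$conv)) else NULL
  for (i in seq_along(model$conv)) {
    ly <- model$conv[[i]]
    z <- conv2d_forward(x, ly$W, ly$b, ly$k, ly$k, ly$stride, ly$pad)
    y <- relu(z)
    if (keep_cache) caches[[i]] <- list(X = x, Y = y)
    x <- y
  }
  feat <- apply(x, 3, mean)
  list(feat = feat, map = x, cache = caches)
}

# backprop a gradient w.r.t. the pooled features down the conv stack;
# returns per-layer dW/db and (optionally) the gradient w.r.t. the input image
backbone_backward <- function(model, cache, dfeat, need_dx = FALSE) {
  nl <- length(model$conv)
  last <- cache[[nl]]$Y
  hw <- dim(last)[1] * dim(last)[2]
  dY <- array(rep(dfeat / hw, each = hw), dim = dim(last))
  grads <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    ly <- model$conv[[i]]
    dZ <- dY * (cache[[i]]$Y > 0)
    need <- (i > 1L) || need_dx
    res <- conv2d_backward(cache[[i]]$X, ly$W, dZ, ly$k, ly$k,
                           ly$stride, ly$pad, need)
    grads[[i]] <- list(dW = res$dW, db = as.numeric(res$db))
    if (need) dY <- res$dX
  }
  list(grads = grads, dX = if (need_dx) dY else NULL)
}

# ---- head -----------------------------------------------------------------

# Fmat: n x D pooled features. Head: batch norm -> dropout -> dense+ReLU ->
# dropout -> dense -> softmax. Inverted dropout; masks drawn from the current
# RNG stream when training.
head_forward <- function(model, Fmat, training = FALSE) {
  bn <- model$bn
  n <- nrow(Fmat)
  if (training && n > 1) {
    mu <- colMeans(Fmat)
    cent <- sweep(Fmat, 2, mu)
    v <- colMeans(cent^2)
  } else {
    mu <- bn$rm; v <- bn$rv
    cent <- sweep(Fmat, 2, mu)
  }
  inv_std <- 1 / sqrt(v + bn$eps)
  xhat <- sweep(cent, 2, inv_std, `*`)
  h0 <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  p1 <- if (training) model$config$dropout[1] else 0
  p2 <- if (training) model$config$dropout[2] else 0
  m1 <- if (p1 > 0) matrix(runif(length(h0)) >= p1, n) / (1 - p1) else 1
  h0d <- h0 * m1
  a1 <- sweep(h0d %*% model$fc1$W, 2, model$fc1$b, `+`)
  h1 <- relu(a1)
  m2 <- if (p2 > 0) matrix(runif(length(h1)) >= p2, n) / (1 - p2) else 1
  h1d <- h1 * m2
  logits <- sweep(h1d %*% model$fc2$W, 2, model$fc2$b, `+`)
  probs <- softmax_rows(logits)
  list(logits = logits, probs = probs,
       cache = list(Fmat = Fmat, cent = cent, inv_std = inv_std, xhat = xhat,
                    mu = mu, v = v, m1 = m1, m2 = m2, h0d = h0d, a1 = a1,
                    h1d = h1d, training = training && n > 1))
}

head_backward <- function(model, cache, dlogits) {
  n <- nrow(dlogits)
  dW2 <- t(cache$h1d) %*% dlogits
  db2 <- colSums(dlogits)
  dh1d <- dlogits %*% t(model$fc2$W)
  dh1 <- dh1d * cache$m2
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- t(cache$h0d) %*% da1
  db1 <- colSums(da1)
  dh0d <- da1 %*% t(model$fc1$W)
  dh0 <- dh0d * cache$m1
  dgamma <- colSums(dh0 * cache$xhat)
  dbeta <- colSums(dh0)
  dxhat <- sweep(dh0, 2, model$bn$gamma, `*`)
  if (cache$training) {
    # batch-statistics batch-norm backward
    iv <- cache$inv_std
    dvar <- colSums(dxhat * cache$cent) * (-0.5) * iv^3
    dmu <- colSums(dxhat) * (-iv) + dvar * colMeans(-2 * cache$cent)
    dF <- sweep(dxhat, 2, iv, `*`) +
      sweep(cache$cent, 2, 2 * dvar / n, `*`) +
      matrix(dmu / n, n, length(dmu), byrow = TRUE)
  } else {
    dF <- sweep(dxhat, 2, cache$inv_std, `*`)
  }
  list(grads = list(fc2 = list(dW = dW2, db = db2),
                    fc1 = list(dW = dW1, db = db1),
                    bn = list(dgamma = dgamma, dbeta = dbeta)),
       dF = dF)
}

# set the batch-norm inference moments to the exact feature moments over a
# reference image list (the unaugmented training subset)
bn_calibrate <- function(model, xs) {
  if (!length(xs)) return(model)
  feats <- t(vapply(xs, function(x) backbone_forward(model, x)$feat,
                    numeric(model$config$feature_dim)))
  model$bn$rm <- colMeans(feats)
  cent <- sweep(feats, 2, model$bn$rm)
  model$bn$rv <- colMeans(cent^2)
  model
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- optimizer ------------------------------------------------------------

# flat named parameter list <-> model
model_params <- function(model) {
  p <- list()
  for (i in seq_along(model$conv)) {
    p[[sprintf("conv%d_W", i)]] <- model$conv[[i]]$W
    p[[sprintf("conv%d_b", i)]] <- model$conv[[i]]$b
  }
  p$bn_gamma <- model$bn$gamma
  p$bn_beta <- model$bn$beta
  p$fc1_W <- model$fc1$W; p$fc1_b <- model$fc1$b
  p$fc2_W <- model$fc2$W; p$fc2_b <- model$fc2$b
  p
}

set_model_params <- function(model, p) {
  for (i in seq_along(model$conv)) {
    model$conv[[i]]$W <- p[[sprintf("conv%d_W", i)]]
    model$conv[[i]]$b <- p[[sprintf("conv%d_b", i)]]
  }
  model$bn$gamma <- p$bn_gamma
  model$bn$beta <- p$bn_beta
  model$fc1$W <- p$fc1_W; model$fc1$b <- p$fc1_b
  model$fc2$W <- p$fc2_W; model$fc2$b <- p$fc2_b
  model
}

param_group <- function(name) {
  if (grepl("^conv", name)) "backbone" else "head"
}

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

# lr is a named list: lr$backbone, lr$head
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr[[param_group(nm)]] * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
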