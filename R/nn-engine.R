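# Minimal feed-forward / backprop engine used by the neural classifier
# backends. Batches are matrices (batch x features) or 3-D arrays
# (batch x time x channels). Each layer is a plain list with `params`,
# and type-dispatched nn_forward / nn_backward implementations returning
# caches and per-parameter gradients. Training is mini-batch Adam on a
# softmax cross-entropy loss. All randomness (init, shuffling, dropout)
# is drawn from R's RNG so a single set.seed() makes runs reproducible.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

nn_dense <- function(n_in, n_out) {
  list(type = "dense",
       params = list(W = glorot(n_in, n_out), b = numeric(n_out)))
}
nn_relu <- function() list(type = "relu", params = list())
nn_dropout <- function(rate) list(type = "dropout", rate = rate, params = list())
nn_flatten <- function() list(type = "flatten", params = list())
nn_global_avg_pool <- function() list(type = "gap", params = list())
nn_conv1d <- function(c_in, c_out, kernel = 3L) {
  list(type = "conv1d", kernel = as.integer(kernel), c_in = c_in, c_out = c_out,
       params = list(W = glorot(kernel * c_in, c_out), b = numeric(c_out)))
}
nn_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", momentum = momentum, eps = eps,
       run_mean = numeric(channels), run_var = rep(1, channels),
       params = list(gamma = rep(1, channels), beta = numeric(channels)))
}
nn_lstm <- function(n_in, n_hidden, return_sequences = FALSE) {
  s <- 1 / sqrt(n_hidden)
  list(type = "lstm", n_hidden = n_hidden, return_sequences = return_sequences,
       params = list(
         Wx = glorot(n_in, 4 * n_hidden),
         Wh = array(stats::runif(n_hidden * 4 * n_hidden, -s, s),
                    c(n_hidden, 4 * n_hidden)),
         b = numeric(4 * n_hidden)))
}
nn_mha <- function(d_model, n_heads = 4L) {
  stopifnot(d_model %% n_heads == 0L)
  list(type = "mha", d_model = d_model, n_heads = as.integer(n_heads),
       params = list(Wq = glorot(d_model, d_model), Wk = glorot(d_model, d_model),
                     Wv = glorot(d_model, d_model), Wo = glorot(d_model, d_model)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      out <- sweep(x %*% layer$params$W, 2, layer$params$b, `+`)
      list(out = out, cache = list(x = x))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array((stats::runif(length(x)) >= layer$rate) / (1 - layer$rate),
                      dim(x) %||% length(x))
        list(out = x * mask, cache = list(mask = mask))
      } else list(out = x, cache = list(mask = NULL))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], prod(d[-1])), cache = list(dims = d))
    },
    gap = {
      d <- dim(x)
      out <- matrix(0, d[1], d[3])
      for (c_ in seq_len(d[3]))
        out[, c_] <- rowMeans(matrix(x[, , c_], d[1], d[2]))
      list(out = out, cache = list(dims = d))
    },
    conv1d = forward_conv1d(layer, x),
    batchnorm = forward_batchnorm(layer, x, training),
    lstm = forward_lstm(layer, x),
    mha = forward_mha(layer, x),
    stop("unknown layer type ", layer$type)
  )
}

nn_backward <- function(layer, cache, g) {
  switch(layer$type,
    dense = list(
      gx = g %*% t(layer$params$W),
      grads = list(W = crossprod(cache$x, g), b = colSums(g))),
    relu = list(gx = g * cache$mask, grads = list()),
    dropout = {
      if (is.null(cache$mask)) list(gx = g, grads = list())
      else list(gx = g * cache$mask, grads = list())
    },
    flatten = list(gx = array(g, cache$dims), grads = list()),
    gap = {
      d <- cache$dims
      gx <- array(0, d)
      for (c_ in seq_len(d[3]))
        gx[, , c_] <- matrix(g[, c_], d[1], d[2]) / d[2]
      list(gx = gx, grads = list())
    },
    conv1d = backward_conv1d(layer, cache, g),
    batchnorm = backward_batchnorm(layer, cache, g),
    lstm = backward_lstm(layer, cache, g),
    mha = backward_mha(layer, cache, g),
    stop("unknown layer type ", layer$type)
  )
}

# ---- conv1d (valid padding, stride 1, im2col) --------------------------

forward_conv1d <- function(layer, x) {
  d <- dim(x)  # B, T, Cin
  k <- layer$kernel
  t_out <- d[2] - k + 1L
  stopifnot(t_out >= 1L)
  Xu <- matrix(0, d[1] * t_out, k * d[3])
  for (o in seq_len(k)) {
    sl <- x[, o:(o + t_out - 1), , drop = FALSE]
    Xu[, ((o - 1) * d[3] + 1):(o * d[3])] <- matrix(sl, d[1] * t_out, d[3])
  }
  out_mat <- sweep(Xu %*% layer$params$W, 2, layer$params$b, `+`)
  list(out = array(out_mat, c(d[1], t_out, layer$c_out)),
       cache = list(Xu = Xu, dims = d, t_out = t_out))
}

backward_conv1d <- function(layer, cache, g) {
  d <- cache$dims; k <- layer$kernel; t_out <- cache$t_out
  g_mat <- matrix(g, d[1] * t_out, layer$c_out)
  dW <- crossprod(cache$Xu, g_mat)
  db <- colSums(g_mat)
  dXu <- tcrossprod(g_mat, layer$params$W)
  gx <- array(0, d)
  for (o in seq_len(k)) {
    cols <- ((o - 1) * d[3] + 1):(o * d[3])
    gx[, o:(o + t_out - 1), ] <- gx[, o:(o + t_out - 1), , drop = FALSE] +
      array(dXu[, cols], c(d[1], t_out, d[3]))
  }
  list(gx = gx, grads = list(W = dW, b = db))
}

# ---- batch normalisation over batch and time, per channel --------------

forward_batchnorm <- function(layer, x, training) {
  d <- dim(x)  # B, T, C
  xm <- matrix(x, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(va + layer$eps), `/`)
  out <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2, layer$params$beta, `+`)
  list(out = array(out, d),
       cache = list(xhat = xhat, va = va, dims = d, training = training,
                    batch_mean = if (training) mu else NULL,
                    batch_var = if (training) va else NULL))
}

backward_batchnorm <- function(layer, cache, g) {
  d <- cache$dims
  gm <- matrix(g, d[1] * d[2], d[3])
  n <- d[1] * d[2]
  dgamma <- colSums(gm * cache$xhat)
  dbeta <- colSums(gm)
  dxhat <- sweep(gm, 2, layer$params$gamma, `*`)
  inv_sd <- 1 / sqrt(cache$va + layer$eps)
  if (!cache$training) {
    # inference mode: fixed affine transform with running statistics
    dx <- sweep(dxhat, 2, inv_sd, `*`)
    return(list(gx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta)))
  }
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat * n, 2, sum_dxhat) -
    sweep(cache$xhat, 2, sum_dxhat_xhat, `*`)
  dx <- sweep(dx, 2, inv_sd / n, `*`)
  list(gx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

# ---- LSTM (full BPTT) --------------------------------------------------

forward_lstm <- function(layer, x) {
  d <- dim(x)  # B, T, Cin
  H <- layer$n_hidden
  B <- d[1]; TT <- d[2]
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", TT)
  hs <- array(0, c(B, TT, H))
  for (t_ in seq_len(TT)) {
    xt <- matrix(x[, t_, ], B, d[3])
    z <- sweep(xt %*% layer$params$Wx + h %*% layer$params$Wh, 2,
               layer$params$b, `+`)
    i_ <- sigmoid(z[, 1:H, drop = FALSE])
    f_ <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g_ <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o_ <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f_ * cc + i_ * g_
    tc <- tanh(c_new)
    h_new <- o_ * tc
    steps[[t_]] <- list(xt = xt, hprev = h, cprev = cc, i = i_, f = f_,
                        g = g_, o = o_, c = c_new, tc = tc)
    h <- h_new; cc <- c_new
    hs[, t_, ] <- h
  }
  out <- if (layer$return_sequences) hs else h
  list(out = out, cache = list(steps = steps, dims = d))
}

backward_lstm <- function(layer, cache, g) {
  d <- cache$dims
  H <- layer$n_hidden; B <- d[1]; TT <- d[2]
  dWx <- array(0, dim(layer$params$Wx))
  dWh <- array(0, dim(layer$params$Wh))
  db <- numeric(4 * H)
  gx <- array(0, d)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t_ in rev(seq_len(TT))) {
    st <- cache$steps[[t_]]
    dh <- dh_next
    if (layer$return_sequences) dh <- dh + matrix(g[, t_, ], B, H)
    else if (t_ == TT) dh <- dh + g
    do_ <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$cprev
    dc_next <- dc * st$f
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$hprev, dz)
    db <- db + colSums(dz)
    gx[, t_, ] <- tcrossprod(dz, layer$params$Wx)
    dh_next <- tcrossprod(dz, layer$params$Wh)
  }
  list(gx = gx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- multi-head self-attention ----------------------------------------

forward_mha <- function(layer, x) {
  d <- dim(x)  # B, T, D
  B <- d[1]; TT <- d[2]; D <- d[3]
  h <- layer$n_heads; dk <- D / h
  out <- array(0, d)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    xb <- matrix(x[b, , ], TT, D)
    Q <- xb %*% layer$params$Wq
    K <- xb %*% layer$params$Wk
    V <- xb %*% layer$params$Wv
    heads <- vector("list", h)
    concat <- matrix(0, TT, D)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1) * dk + 1):(hh * dk)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      O <- A %*% V[, cols, drop = FALSE]
      concat[, cols] <- O
      heads[[hh]] <- list(A = A)
    }
    out[b, , ] <- concat %*% layer$params$Wo
    caches[[b]] <- list(xb = xb, Q = Q, K = K, V = V, heads = heads,
                        concat = concat)
  }
  list(out = out, cache = list(per_batch = caches, dims = d))
}

backward_mha <- function(layer, cache, g) {
  d <- cache$dims
  B <- d[1]; TT <- d[2]; D <- d[3]
  h <- layer$n_heads; dk <- D / h
  dWq <- matrix(0, D, D); dWk <- matrix(0, D, D)
  dWv <- matrix(0, D, D); dWo <- matrix(0, D, D)
  gx <- array(0, d)
  for (b in seq_len(B)) {
    cb <- cache$per_batch[[b]]
    gb <- matrix(g[b, , ], TT, D)
    dWo <- dWo + crossprod(cb$concat, gb)
    dconcat <- tcrossprod(gb, layer$params$Wo)
    dQ <- matrix(0, TT, D); dK <- matrix(0, TT, D); dV <- matrix(0, TT, D)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1) * dk + 1):(hh * dk)
      A <- cb$heads[[hh]]$A
      dO <- dconcat[, cols, drop = FALSE]
      dA <- tcrossprod(dO, cb$V[, cols, drop = FALSE])
      dV[, cols] <- dV[, cols] + crossprod(A, dO)
      # softmax backward, row-wise
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dk)
      dQ[, cols] <- dQ[, cols] + dS %*% cb$K[, cols, drop = FALSE]
      dK[, cols] <- dK[, cols] + crossprod(dS, cb$Q[, cols, drop = FALSE])
    }
    dWq <- dWq + crossprod(cb$xb, dQ)
    dWk <- dWk + crossprod(cb$xb, dK)
    dWv <- dWv + crossprod(cb$xb, dV)
    gx[b, , ] <- tcrossprod(dQ, layer$params$Wq) +
      tcrossprod(dK, layer$params$Wk) + tcrossprod(dV, layer$params$Wv)
  }
  list(gx = gx, grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

# ---- loss, optimiser, training loop -----------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# returns loss and gradient wrt logits; y is an integer class vector
softmax_ce <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n)
}

nn_predict_logits <- function(layers, x) {
  for (l in layers) x <- nn_forward(l, x, training = FALSE)$out
  x
}

#' @keywords internal
nn_train <- function(layers, x, y, epochs = 50L, batch_size = 32L, lr = 1e-3,
                     verbose = FALSE) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  adam <- lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  take_batch <- function(idx) {
    if (is.matrix(x)) x[idx, , drop = FALSE]
    else {
      d <- dim(x)
      array(x[idx, , , drop = FALSE], c(length(idx), d[2], d[3]))
    }
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- take_batch(idx); yb <- y[idx]
      caches <- vector("list", length(layers))
      out <- xb
      for (li in seq_along(layers)) {
        fw <- nn_forward(layers[[li]], out, training = TRUE)
        caches[[li]] <- fw$cache
        out <- fw$out
        # update batchnorm running stats during training
        if (layers[[li]]$type == "batchnorm" && !is.null(fw$cache$batch_mean)) {
          mom <- layers[[li]]$momentum
          layers[[li]]$run_mean <- mom * layers[[li]]$run_mean +
            (1 - mom) * fw$cache$batch_mean
          layers[[li]]$run_var <- mom * layers[[li]]$run_var +
            (1 - mom) * fw$cache$batch_var
        }
      }
      lo <- softmax_ce(out, yb)
      ep_loss <- ep_loss + lo$loss; nb <- nb + 1L
      g <- lo$grad
      step <- step + 1L
      for (li in rev(seq_along(layers))) {
        bw <- nn_backward(layers[[li]], caches[[li]], g)
        g <- bw$gx
        if (length(bw$grads)) {
          for (pn in names(bw$grads)) {
            st <- adam[[li]][[pn]]
            st$m <- beta1 * st$m + (1 - beta1) * bw$grads[[pn]]
            st$v <- beta2 * st$v + (1 - beta2) * bw$grads[[pn]]^2
            mhat <- st$m / (1 - beta1^step)
            vhat <- st$v / (1 - beta2^step)
            layers[[li]]$params[[pn]] <- layers[[li]]$params[[pn]] -
              lr * mhat / (sqrt(vhat) + eps)
            adam[[li]][[pn]] <- st
          }
        }
      }
    }
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss / nb))
  }
  layers
}
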