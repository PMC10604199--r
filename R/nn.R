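# Minimal seeded 3D conv-net engine backing the fusion model and the PET
# asymmetry block. Feature maps are (X, Y, Z, C) arrays; convolutions are
# lowered to GEMM through the vol2col/col2vol kernels in src/, pooling is
# ceil-mode max pooling, and all randomness (init, dropout, shuffling) goes
# through R's RNG so training is reproducible under set.seed().

nn_conv3d <- function(in_ch, out_ch, kernel = c(3L, 3L, 3L),
                      pad = as.integer(kernel) %/% 2L) {
  kernel <- as.integer(kernel); pad <- as.integer(pad)
  fan_in <- prod(kernel) * in_ch
  list(type = "conv3d",
       W = matrix(stats::rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)),
                  out_ch, fan_in),
       b = numeric(out_ch),
       kernel = kernel, pad = pad, in_ch = in_ch, out_ch = out_ch)
}

nn_relu <- function() list(type = "relu")

# Pooling: "avg" (default) suits regional intensity effects — hypometabolism
# shifts local means, and average pooling propagates dense gradients from tiny
# cohorts; "max" is available as the conventional alternative.
nn_pool <- function(pool = c(2L, 2L, 2L), mode = c("avg", "max"))
  list(type = "pool", pool = as.integer(pool), mode = match.arg(mode))

nn_dropout <- function(p = 0.5) list(type = "dropout", p = p)

nn_flatten <- function() list(type = "flatten")

nn_dense <- function(in_len, out_len) {
  list(type = "dense",
       W = matrix(stats::rnorm(out_len * in_len, 0, sqrt(2 / in_len)),
                  out_len, in_len),
       b = numeric(out_len), in_len = in_len, out_len = out_len)
}

# Batch normalisation adapted to batch-size-1 training: per-feature
# standardisation whose statistics are taken over the whole training set and
# refreshed at epoch boundaries by the trainer (gradients treat them as
# constants, as in inference-statistics BN), with the usual learnable affine
# rescaling. Whitening the concatenated branch features is what lets the
# head see image and clinical inputs on a common scale.
nn_featnorm <- function(len, sd_floor = 0.01, clip = 8) {
  list(type = "featnorm", gamma = rep(1, len), beta = numeric(len),
       mean = numeric(len), var = rep(1, len), sd = rep(1, len),
       sd_floor = sd_floor, clip = clip)
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv3d = {
      xdim <- dim(x)
      col <- vol2col(x, xdim, layer$kernel, layer$pad)
      om <- layer$W %*% col + layer$b
      od <- xdim[1:3] + 2L * layer$pad - layer$kernel + 1L
      out <- array(t(om), dim = c(od, layer$out_ch))
      list(out = out, cache = list(col = col, xdim = xdim, odim = od))
    },
    relu = {
      mask <- x > 0
      out <- x * mask
      list(out = out, cache = mask)
    },
    pool = {
      if (layer$mode == "avg") {
        out <- avgpool3d_fw(x, dim(x), layer$pool)
        list(out = out, cache = list(xdim = dim(x)))
      } else {
        r <- maxpool3d_fw(x, dim(x), layer$pool)
        list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)))
      }
    },
    dropout = {
      if (!training || layer$p <= 0) return(list(out = x, cache = NULL))
      mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
      out <- x * mask
      if (!is.null(dim(x))) dim(out) <- dim(x)
      list(out = out, cache = mask)
    },
    flatten = list(out = as.numeric(x), cache = dim(x)),
    dense = list(out = drop(layer$W %*% x) + layer$b, cache = x),
    featnorm = {
      xhat <- (x - layer$mean) / layer$sd
      # clip: features drift between statistic refreshes; saturating the
      # normalised value (zero gradient outside) keeps the loss bounded
      inside <- abs(xhat) <= layer$clip
      xhat <- pmin(pmax(xhat, -layer$clip), layer$clip)
      list(out = layer$gamma * xhat + layer$beta,
           cache = list(xhat = xhat, inside = inside))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv3d = {
      nvox <- prod(cache$odim)
      dm <- t(matrix(dout, nvox, layer$out_ch))
      dW <- dm %*% t(cache$col)
      db <- rowSums(dm)
      dcol <- crossprod(layer$W, dm)
      dx <- col2vol(dcol, cache$xdim, layer$kernel, layer$pad)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache, grads = NULL),
    pool = list(dx = if (layer$mode == "avg")
                        avgpool3d_bw(dout, cache$xdim, layer$pool)
                      else maxpool3d_bw(dout, cache$argmax, cache$xdim),
                grads = NULL),
    dropout = {
      if (is.null(cache)) return(list(dx = dout, grads = NULL))
      dx <- dout * cache
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache
      list(dx = dx, grads = NULL)
    },
    dense = list(dx = drop(crossprod(layer$W, dout)),
                 grads = list(W = outer(dout, cache), b = dout)),
    featnorm = list(dx = dout * layer$gamma / layer$sd * cache$inside,
                    grads = list(gamma = dout * cache$xhat, beta = dout)),
    stop("unknown layer type: ", layer$type))
}

seq_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x, training)
    x <- r$out
    caches[i] <- list(r$cache)  # not [[<-: NULL caches must not shrink the list
    if (!is.null(r$layer)) net[[i]] <- r$layer
  }
  list(out = x, caches = caches, net = net)
}

seq_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # not [[<-: NULL grads must not shrink the list
  }
  list(dx = dout, grads = grads)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

# Parameter update. Optimiser state (momentum velocities or Adam moments)
# lives alongside the parameters, so it travels with the network. "adam" is
# the default: the image and clinical branches produce gradients of vastly
# different magnitudes, which per-parameter adaptive steps absorb; "sgd"
# (with optional classical momentum) gives the plain protocol.
seq_update <- function(net, grads, lr, optimizer = "adam", t = 1L,
                       momentum = 0, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      if (weight_decay > 0 && nm == "W")  # decoupled decay on weights only
        net[[i]][[nm]] <- net[[i]][[nm]] * (1 - lr * weight_decay)
      if (optimizer == "adam") {
        mnm <- paste0("adam_m_", nm); vnm <- paste0("adam_v_", nm)
        m <- if (is.null(net[[i]][[mnm]])) 0 * g[[nm]] else net[[i]][[mnm]]
        v <- if (is.null(net[[i]][[vnm]])) 0 * g[[nm]] else net[[i]][[vnm]]
        m <- beta1 * m + (1 - beta1) * g[[nm]]
        v <- beta2 * v + (1 - beta2) * g[[nm]]^2
        net[[i]][[mnm]] <- m
        net[[i]][[vnm]] <- v
        mhat <- m / (1 - beta1^t)
        vhat <- v / (1 - beta2^t)
        net[[i]][[nm]] <- net[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      } else if (momentum > 0) {
        vnm <- paste0("sgd_v_", nm)
        v <- if (is.null(net[[i]][[vnm]])) g[[nm]]
             else momentum * net[[i]][[vnm]] + g[[nm]]
        net[[i]][[vnm]] <- v
        net[[i]][[nm]] <- net[[i]][[nm]] - lr * v
      } else {
        net[[i]][[nm]] <- net[[i]][[nm]] - lr * g[[nm]]
      }
    }
  }
  net
}

seq_param_fingerprint <- function(net) {
  s <- 0
  for (layer in net)
    for (nm in c("W", "b", "gamma", "beta"))
      if (!is.null(layer[[nm]])) s <- s + sum(abs(layer[[nm]]))
  s
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  p <- min(max(p, 1e-7), 1 - 1e-7)
  -(y * log(p) + (1 - y) * log(1 - p))
}
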