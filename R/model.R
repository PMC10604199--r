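#' Fusion-network architecture configuration
#'
#' The architecture follows a fixed layer plan: each enabled image modality
#' (MRI, PET) has its own branch of three 3D convolutional layers, three
#' pooling layers and a dropout layer; the branch outputs are concatenated
#' channel-wise and passed through a shared trunk of two 3D convolutional
#' layers, three pooling layers and a dropout layer; the clinical vector goes
#' through two 1D convolutional layers, two pooling layers and a dropout
#' layer; and the concatenated image/clinical features feed an integrated
#' head of two further (1x1) convolutional layers with batch normalisation
#' and dropout, ending in a sigmoid. Batch statistics do not exist at batch
#' size 1, so the head's normalisation standardises each feature with
#' training-population statistics refreshed at every epoch. Channel widths,
#' kernel size, pooling and dropout rate are tunable; the layer counts are
#' not.
#'
#' @param widths three channel widths for the per-modality image branch.
#' @param trunk_widths two channel widths for the post-concatenation trunk.
#' @param clin_widths two channel widths for the 1D clinical branch.
#' @param head_hidden width of the head's hidden layer.
#' @param dropout dropout probability used in every dropout layer.
#' @param kernel 3D convolution kernel size (image branches and trunk).
#' @param trunk_pools window sizes of the trunk's three pooling stages
#'   (a unit window is an identity stage that keeps a coarse spatial grid in
#'   the flattened image features).
#' @param cube_size edge length of the image input cubes in voxels.
#' @return A `model_config` list.
#' @export
model_config <- function(widths = c(8, 16, 32), trunk_widths = c(32, 32),
                         clin_widths = c(8, 8), head_hidden = 16,
                         dropout = 0.5, kernel = c(3, 3, 3),
                         trunk_pools = c(2, 2, 2), cube_size = 48L) {
  stopifnot(length(widths) == 3L, length(trunk_widths) == 2L,
            length(clin_widths) == 2L, length(trunk_pools) == 3L,
            dropout >= 0, dropout < 1)
  structure(list(widths = as.integer(widths),
                 trunk_widths = as.integer(trunk_widths),
                 clin_widths = as.integer(clin_widths),
                 head_hidden = as.integer(head_hidden), dropout = dropout,
                 kernel = as.integer(kernel),
                 trunk_pools = as.integer(trunk_pools),
                 cube_size = as.integer(cube_size)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference protocol — batch size 1, binary
#' cross-entropy, ReLU activations, 500 epochs, early stopping when the
#' training loss has not improved for 1000 iterations — except the
#' optimiser: plain SGD at learning rate 0.1 with batch size 1 routinely
#' diverges on this architecture, so the package defaults to Adam at 1e-3
#' with a head warm-up phase. Use [reference_train_config()] for the unmodified
#' protocol values.
#'
#' @param epochs maximum number of end-to-end passes over the training set;
#'   0 trains the head only (on frozen-branch features, see `head_warmup`).
#' @param optimizer `"adam"` (default; per-parameter adaptive steps absorb
#'   the large gradient-scale differences between image and clinical
#'   branches) or `"sgd"` for the plain protocol.
#' @param lr learning rate; defaults to 1e-3 for Adam, 0.01 for SGD.
#' @param momentum classical momentum coefficient for SGD (ignored by Adam).
#' @param head_warmup iterations of the head-only warm-up phase (a linear
#'   probe on frozen-branch features) run before end-to-end training; 0
#'   disables it.
#' @param branch_lr_scale learning-rate multiplier for everything below the
#'   head during end-to-end training. Fine-tuning the convolutional branches
#'   more slowly than the head keeps their features from outrunning the
#'   head's normalisation statistics between refreshes.
#' @param weight_decay decoupled (AdamW-style) L2 decay applied to weight
#'   matrices; regularises the head on small cohorts.
#' @param early_stop_patience iterations without training-loss improvement
#'   before stopping.
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 500L, optimizer = c("adam", "sgd"),
                         lr = NULL, momentum = 0, head_warmup = 400L,
                         branch_lr_scale = 0.05, weight_decay = 1,
                         early_stop_patience = 1000L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 1e-3 else 0.01
  stopifnot(epochs >= 0, lr > 0, momentum >= 0, momentum < 1,
            early_stop_patience >= 1, head_warmup >= 0, branch_lr_scale >= 0,
            branch_lr_scale <= 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = 1L,
                 optimizer = optimizer, lr = lr, momentum = momentum,
                 head_warmup = as.integer(head_warmup),
                 branch_lr_scale = branch_lr_scale,
                 weight_decay = weight_decay,
                 loss = "binary_cross_entropy", activation = "relu",
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @export
reference_train_config <- function(seed = 1L) {
  cfg <- train_config(epochs = 500L, optimizer = "sgd", lr = 0.1,
                      momentum = 0, head_warmup = 0L, branch_lr_scale = 1,
                      weight_decay = 0, early_stop_patience = 1000L,
                      seed = seed)
  cfg
}

image_branch_layers <- function(cfg) {
  w <- cfg$widths
  list(nn_conv3d(1L, w[1], cfg$kernel), nn_relu(), nn_pool(),
       nn_conv3d(w[1], w[2], cfg$kernel), nn_relu(), nn_pool(),
       nn_conv3d(w[2], w[3], cfg$kernel), nn_relu(), nn_pool(),
       nn_dropout(cfg$dropout))
}

# Assemble a block-diagonal conv from per-group convs: output-channel group
# g initially reads only input-channel group g. End-to-end training is free
# to repopulate the zeroed cross-modality blocks.
block_diag_conv <- function(parts, kernel, pad) {
  g <- length(parts)
  if (g == 1L) return(parts[[1]])
  n_in_g <- parts[[1]]$in_ch
  n_out_g <- nrow(parts[[1]]$W)
  kvol <- prod(parts[[1]]$kernel)
  W <- matrix(0, g * n_out_g, g * n_in_g * kvol)
  b <- numeric(g * n_out_g)
  for (k in seq_len(g)) {
    rows <- ((k - 1) * n_out_g + 1):(k * n_out_g)
    cols <- as.vector(outer(seq_len(kvol),
                            (((k - 1) * n_in_g + 1):(k * n_in_g) - 1) * kvol, `+`))
    W[rows, cols] <- parts[[k]]$W
    b[rows] <- parts[[k]]$b
  }
  out <- nn_conv3d(g * n_in_g, g * n_out_g, kernel, pad)
  out$W <- W
  out$b <- b
  out
}

# Post-concatenation trunk. With several image modalities the trunk is
# initialised modality-preservingly: each modality's channel group carries
# its own single-modality trunk weights (width trunk_widths per group), so
# the fused model starts from exactly the features the single-channel
# models would compute, and the total width scales with the number of
# modalities. seeds gives one deterministic init stream per group.
trunk_layers <- function(cfg, in_ch_per_group, groups = 1L, seeds = NULL) {
  tw <- cfg$trunk_widths
  tp <- lapply(seq_len(3), function(i) rep(cfg$trunk_pools[i], 3))
  conv1_parts <- vector("list", groups)
  conv2_parts <- vector("list", groups)
  for (k in seq_len(groups)) {
    if (!is.null(seeds)) set.seed(seeds[k])
    conv1_parts[[k]] <- nn_conv3d(in_ch_per_group, tw[1], cfg$kernel)
    conv2_parts[[k]] <- nn_conv3d(tw[1], tw[2], cfg$kernel)
  }
  list(block_diag_conv(conv1_parts, cfg$kernel, cfg$kernel %/% 2L),
       nn_relu(), nn_pool(tp[[1]]),
       block_diag_conv(conv2_parts, cfg$kernel, cfg$kernel %/% 2L),
       nn_relu(), nn_pool(tp[[2]]),
       nn_pool(tp[[3]]), nn_dropout(cfg$dropout), nn_flatten())
}

clinical_branch_layers <- function(cfg) {
  cw <- cfg$clin_widths
  k1 <- c(3L, 1L, 1L)
  p1 <- c(2L, 1L, 1L)
  list(nn_conv3d(1L, cw[1], k1, pad = c(1L, 0L, 0L)), nn_relu(), nn_pool(p1),
       nn_conv3d(cw[1], cw[2], k1, pad = c(1L, 0L, 0L)), nn_relu(), nn_pool(p1),
       nn_dropout(cfg$dropout), nn_flatten())
}

head_layers <- function(cfg, in_len) {
  list(nn_featnorm(in_len), nn_dense(in_len, cfg$head_hidden),
       nn_relu(), nn_dropout(cfg$dropout), nn_dense(cfg$head_hidden, 1L))
}

#' Build the multi-channel fusion model
#'
#' Constructs the network for any subset of the three input channels
#' (enabling the single-channel and image-only ablations). Weights are
#' initialised from the current RNG state, so `set.seed()` before building
#' gives reproducible parameters.
#'
#' @param cfg a [model_config()].
#' @param channels character subset of `c("mri", "pet", "clinical")`.
#' @param clin_len length of the standardised clinical vector (5, or 6 with
#'   the PET-positivity flag); ignored without the clinical channel.
#' @return An object of class `fusion_model`.
#' @export
build_model <- function(cfg = model_config(),
                        channels = c("mri", "pet", "clinical"),
                        clin_len = 5L) {
  if (length(channels) == 0L) stop("at least one input channel must be enabled",
                                   call. = FALSE)
  channels <- match.arg(channels, c("mri", "pet", "clinical"), several.ok = TRUE)
  img_ch <- intersect(c("mri", "pet"), channels)
  model <- list(cfg = cfg, channels = channels, clin_len = as.integer(clin_len),
                branches = NULL, trunk = NULL, clin_branch = NULL, head = NULL)
  feat_len <- 0L
  # one deterministic init stream per component, derived from the caller's
  # RNG state: a branch gets the same initial weights whether it is built
  # alone or inside the fused model, so ablations differ only by what is
  # present, not by draw order
  base_seed <- sample.int(2^30, 1L)
  part_seed <- function(nm)
    base_seed + match(nm, c("mri", "pet", "clinical", "trunk_mri", "trunk_pet",
                            "head"))
  if (length(img_ch) > 0L) {
    model$branches <- stats::setNames(lapply(img_ch, function(ch) {
      set.seed(part_seed(ch))
      image_branch_layers(cfg)
    }), img_ch)
    model$trunk <- trunk_layers(cfg, cfg$widths[3], groups = length(img_ch),
                                seeds = vapply(paste0("trunk_", img_ch),
                                               part_seed, numeric(1)))
    dummy <- array(0, c(rep(cfg$cube_size, 3), 1L))
    bo <- seq_forward(model$branches[[1]], dummy)$out
    tin <- array(0, c(dim(bo)[1:3], length(img_ch) * cfg$widths[3]))
    feat_len <- feat_len + length(seq_forward(model$trunk, tin)$out)
    model$img_feat_len <- length(seq_forward(model$trunk, tin)$out)
  }
  if ("clinical" %in% channels) {
    set.seed(part_seed("clinical"))
    model$clin_branch <- clinical_branch_layers(cfg)
    cin <- array(0, c(clin_len, 1L, 1L, 1L))
    model$clin_feat_len <- length(seq_forward(model$clin_branch, cin)$out)
    feat_len <- feat_len + model$clin_feat_len
  }
  set.seed(part_seed("head"))
  model$head <- head_layers(cfg, feat_len)
  class(model) <- "fusion_model"
  model
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> channels: %s; cube %d^3; widths %s\n",
              paste(x$channels, collapse = "+"), x$cfg$cube_size,
              paste(x$cfg$widths, collapse = ",")))
  invisible(x)
}

model_fingerprint <- function(model) {
  s <- 0
  for (part in c(model$branches, list(model$trunk, model$clin_branch, model$head)))
    if (!is.null(part)) s <- s + seq_param_fingerprint(part)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Concatenated head-input features (image trunk + clinical branch) per cube,
# in evaluation mode; used to set the head's normalisation statistics.
head_input_features <- function(model, sub) {
  img_ch <- intersect(c("mri", "pet"), model$channels)
  has_img <- length(img_ch) > 0L
  n_cubes <- if (has_img) length(sub[[img_ch[1]]]) else 1L
  fc <- if ("clinical" %in% model$channels)
    seq_forward(model$clin_branch,
                array(sub$clin, c(model$clin_len, 1L, 1L, 1L)))$out
  nfeat <- (model$img_feat_len %||% 0L) + length(fc)
  vapply(seq_len(n_cubes), function(i) {
    f_img <- NULL
    if (has_img) {
      bouts <- lapply(img_ch, function(ch)
        seq_forward(model$branches[[ch]],
                    array(sub[[ch]][[i]], c(dim(sub[[ch]][[i]]), 1L)))$out)
      cat_in <- array(unlist(bouts),
                      c(dim(bouts[[1]])[1:3], length(img_ch) * model$cfg$widths[3]))
      f_img <- seq_forward(model$trunk, cat_in)$out
    }
    c(f_img, fc)
  }, numeric(nfeat))
}

refresh_head_norm <- function(model, subjects) {
  if (model$head[[1]]$type != "featnorm") return(model)
  nfeat <- length(model$head[[1]]$mean)
  feats <- do.call(cbind, lapply(subjects, function(s)
    matrix(head_input_features(model, s), nrow = nfeat)))
  model$head[[1]]$mean <- rowMeans(feats)
  v <- apply(feats, 1, stats::var)
  model$head[[1]]$var <- ifelse(is.finite(v), v, 0)
  model$head[[1]]$sd <- pmax(sqrt(model$head[[1]]$var),
                             model$head[[1]]$sd_floor)
  model
}

# One forward pass over a prepared subject. Per-cube logits are averaged
# before the sigmoid so each subject yields a single probability regardless
# of how many cubes its volumes tile into.
forward_subject <- function(model, sub, training = FALSE, keep_caches = FALSE) {
  img_ch <- intersect(c("mri", "pet"), model$channels)
  has_img <- length(img_ch) > 0L
  n_cubes <- if (has_img) length(sub[[img_ch[1]]]) else 1L
  fc <- NULL; clin_caches <- NULL
  if ("clinical" %in% model$channels) {
    if (length(sub$clin) != model$clin_len)
      stop("clinical vector length ", length(sub$clin),
           " does not match model input length ", model$clin_len, call. = FALSE)
    r <- seq_forward(model$clin_branch, array(sub$clin, c(model$clin_len, 1L, 1L, 1L)),
                     training)
    fc <- r$out; clin_caches <- r$caches; model$clin_branch <- r$net
  }
  logits <- numeric(n_cubes)
  branch_caches <- vector("list", n_cubes)
  trunk_caches <- vector("list", n_cubes)
  head_caches <- vector("list", n_cubes)
  cs <- model$cfg$cube_size
  for (i in seq_len(n_cubes)) {
    f_img <- NULL
    if (has_img) {
      bcaches <- list()
      bouts <- list()
      for (ch in img_ch) {
        cube <- sub[[ch]][[i]]
        if (!identical(dim(cube), rep(cs, 3L)) && !identical(dim(cube), c(cs, cs, cs)))
          stop("cube shape ", paste(dim(cube), collapse = "x"),
               " does not match model cube size ", cs, call. = FALSE)
        r <- seq_forward(model$branches[[ch]], array(cube, c(dim(cube), 1L)), training)
        bouts[[ch]] <- r$out; bcaches[[ch]] <- r$caches
        model$branches[[ch]] <- r$net
      }
      cat_in <- array(unlist(bouts, use.names = FALSE),
                      c(dim(bouts[[1]])[1:3], length(img_ch) * model$cfg$widths[3]))
      rt <- seq_forward(model$trunk, cat_in, training)
      f_img <- rt$out; model$trunk <- rt$net
      if (keep_caches) {
        branch_caches[[i]] <- bcaches
        trunk_caches[[i]] <- rt$caches
      }
    }
    rh <- seq_forward(model$head, c(f_img, fc), training)
    logits[i] <- rh$out
    model$head <- rh$net
    if (keep_caches) head_caches[[i]] <- rh$caches
  }
  prob <- sigmoid_(mean(logits))
  list(prob = prob, logits = logits, model = model,
       caches = if (keep_caches) list(branch = branch_caches, trunk = trunk_caches,
                                      head = head_caches, clin = clin_caches))
}

# One SGD step (batch = one subject): forward with dropout, backprop the
# binary cross-entropy through every active part, accumulate per-cube
# gradients, update in place. Returns the updated model and the loss.
train_step <- function(model, sub, opt) {
  lr <- opt$lr; optimizer <- opt$optimizer; t <- opt$t; momentum <- opt$momentum
  lr_branch <- lr * opt$branch_lr_scale
  fw <- forward_subject(model, sub, training = TRUE, keep_caches = TRUE)
  model <- fw$model
  y <- sub$label
  loss <- bce_loss(fw$prob, y)
  img_ch <- intersect(c("mri", "pet"), model$channels)
  has_img <- length(img_ch) > 0L
  n_cubes <- length(fw$logits)
  dlogit <- (fw$prob - y) / n_cubes
  head_g <- NULL; trunk_g <- NULL; clin_dout <- NULL
  branch_g <- stats::setNames(vector("list", length(img_ch)), img_ch)
  w3 <- model$cfg$widths[3]
  for (i in seq_len(n_cubes)) {
    bh <- seq_backward(model$head, fw$caches$head[[i]], dlogit)
    head_g <- grads_add(head_g, bh$grads)
    dfeat <- bh$dx
    if (has_img) {
      nimg <- model$img_feat_len
      bt <- seq_backward(model$trunk, fw$caches$trunk[[i]], dfeat[seq_len(nimg)])
      trunk_g <- grads_add(trunk_g, bt$grads)
      dcat <- bt$dx
      for (j in seq_along(img_ch)) {
        ch <- img_ch[j]
        dch <- dcat[, , , ((j - 1L) * w3 + 1L):(j * w3), drop = FALSE]
        bb <- seq_backward(model$branches[[ch]], fw$caches$branch[[i]][[ch]], dch)
        branch_g[[ch]] <- grads_add(branch_g[[ch]], bb$grads)
      }
      dclin_part <- if (length(dfeat) > nimg) dfeat[(nimg + 1L):length(dfeat)]
    } else {
      dclin_part <- dfeat
    }
    if ("clinical" %in% model$channels)
      clin_dout <- if (is.null(clin_dout)) dclin_part else clin_dout + dclin_part
  }
  model$head <- seq_update(model$head, head_g, lr, optimizer, t, momentum,
                           opt$weight_decay)
  updb <- function(net, g) seq_update(net, g, lr_branch, optimizer, t, momentum)
  if (lr_branch > 0) {
    if (has_img) {
      model$trunk <- updb(model$trunk, trunk_g)
      for (ch in img_ch)
        model$branches[[ch]] <- updb(model$branches[[ch]], branch_g[[ch]])
    }
    if ("clinical" %in% model$channels) {
      bc <- seq_backward(model$clin_branch, fw$caches$clin, clin_dout)
      model$clin_branch <- updb(model$clin_branch, bc$grads)
    }
  }
  list(model = model, loss = loss)
}

# Head warm-up: with branch parameters frozen at their current values, the
# per-cube head inputs are computed once, whitened, and the head alone is
# trained to convergence on the cached features. This is the linear-probe
# stage of a probe-then-fine-tune schedule: it puts the head near its
# optimum before the expensive end-to-end phase, so the residual gradients
# reaching the convolutional branches are small and the whitening
# statistics stay valid between refreshes.
warmup_head <- function(model, subjects, cfg, iters) {
  model <- refresh_head_norm(model, subjects)
  nfeat <- length(model$head[[1]]$mean)
  feats <- lapply(subjects, function(s)
    matrix(head_input_features(model, s), nrow = nfeat))
  labs <- vapply(subjects, function(s) s$label, numeric(1))
  head <- model$head
  n <- length(subjects)
  # full-batch descent on the cached features: the probe sees every subject
  # each step, so it converges smoothly instead of chasing single samples
  for (t in seq_len(iters)) {
    g <- NULL
    for (i in seq_len(n)) {
      f <- feats[[i]]
      n_cubes <- ncol(f)
      outs <- vector("list", n_cubes)
      logits <- numeric(n_cubes)
      for (k in seq_len(n_cubes)) {
        r <- seq_forward(head, f[, k])
        outs[[k]] <- r$caches
        logits[k] <- r$out
      }
      p <- sigmoid_(mean(logits))
      for (k in seq_len(n_cubes))
        g <- grads_add(g, seq_backward(head, outs[[k]],
                                       (p - labs[i]) / (n_cubes * n))$grads)
    }
    head <- seq_update(head, g, cfg$lr * 3, cfg$optimizer, t, cfg$momentum,
                       cfg$weight_decay)
  }
  # reset head optimiser state so the main phase starts clean
  for (i in seq_along(head))
    head[[i]][grepl("^(adam|sgd)_", names(head[[i]]))] <- NULL
  model$head <- head
  model
}

#' Train the fusion model
#'
#' Seeded batch-size-1 training with binary cross-entropy on subject-level
#' probabilities, in two phases: a cheap head warm-up on frozen-branch
#' features (a linear probe, `head_warmup` iterations), then end-to-end
#' fine-tuning of all branches. Training stops after `epochs` passes or
#' earlier when the per-iteration training loss has not improved for
#' `early_stop_patience` consecutive iterations. The whole run
#' (initialisation via [build_model()] under the same seed, shuffling,
#' dropout) is reproducible given `cfg$seed`.
#'
#' @param model a [build_model()] result.
#' @param subjects list of prepared subjects (see [prepare_model_inputs()]),
#'   each with fields `label`, optional `mri`/`pet` cube lists and `clin`.
#' @param cfg a [train_config()].
#' @return List with the trained `model`, the per-iteration `loss_trace` and
#'   the number of `iterations` run.
#' @export
train_model <- function(model, subjects, cfg = train_config()) {
  labs <- vapply(subjects, function(s) s$label, numeric(1))
  if (length(unique(labs)) < 2L)
    stop("training set must contain both classes (EP and HC)", call. = FALSE)
  set.seed(cfg$seed)
  if (cfg$head_warmup > 0L)
    model <- warmup_head(model, subjects, cfg, cfg$head_warmup)
  trace <- numeric(0)
  best <- Inf; since <- 0L; it <- 0L
  for (ep in seq_len(cfg$epochs)) {
    model <- refresh_head_norm(model, subjects)
    ord <- sample(length(subjects))
    for (s in ord) {
      it <- it + 1L
      st <- train_step(model, subjects[[s]],
                       list(lr = cfg$lr, optimizer = cfg$optimizer, t = it,
                            momentum = cfg$momentum,
                            branch_lr_scale = cfg$branch_lr_scale,
                            weight_decay = cfg$weight_decay))
      model <- st$model
      if (!is.finite(st$loss))
        stop("training diverged (non-finite loss) at iteration ", it,
             "; lower the learning rate", call. = FALSE)
      trace[it] <- st$loss
      if (st$loss < best - 1e-9) { best <- st$loss; since <- 0L }
      else since <- since + 1L
      if (since >= cfg$early_stop_patience) {
        return(list(model = model, loss_trace = trace, iterations = it,
                    early_stopped = TRUE))
      }
    }
  }
  list(model = model, loss_trace = trace, iterations = it, early_stopped = FALSE)
}

#' Predict subject-level probabilities
#'
#' @param model a trained [build_model()] result.
#' @param subjects list of prepared subjects.
#' @param threshold decision threshold; probabilities at or above it are
#'   labelled EP (1).
#' @return A data.frame with `subject_id`, `probability`, `predicted_label`.
#' @export
predict_model <- function(model, subjects, threshold = 0.5) {
  probs <- vapply(subjects, function(s) forward_subject(model, s)$prob, numeric(1))
  ids <- vapply(subjects, function(s) {
    if (is.null(s$subject_id)) NA_character_ else as.character(s$subject_id)
  }, character(1))
  data.frame(subject_id = ids, probability = probs,
             predicted_label = as.integer(probs >= threshold))
}
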