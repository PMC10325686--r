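#' Network architecture configuration
#'
#' The classifier is a compact 2-D CNN for 85 x 85 single-channel patches:
#' four stages of 3 x 3 convolution (ReLU) -> 2 x 2 max-pooling ->
#' batch normalization, with 32, 64, 96 and 96 filters, followed by three
#' fully-connected layers of 256, 64 and 1 neurons. Dropout of 30% is
#' applied at the input of each fully-connected layer during training; the
#' output neuron is a sigmoid.
#'
#' @param conv_filters Filters per convolution stage.
#' @param fc_sizes Widths of the fully-connected layers; last must be 1.
#' @param dropout_rate Dropout probability in the FC head.
#' @param input_size Patch side length.
#' @param init_sd Standard deviation of the zero-mean normal weight init.
#' @return An `arch_config` list.
#' @export
arch_config <- function(conv_filters = c(32L, 64L, 96L, 96L),
                        fc_sizes = c(256L, 64L, 1L),
                        dropout_rate = 0.30,
                        input_size = 85L,
                        init_sd = 0.05) {
  stopifnot(length(conv_filters) == 4L, utils::tail(fc_sizes, 1) == 1L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = c(3L, 3L), pool = c(2L, 2L),
                 fc_sizes = as.integer(fc_sizes),
                 dropout_rate = dropout_rate,
                 batch_norm_after_pool = TRUE,
                 hidden_activation = "relu", output_activation = "sigmoid",
                 input_size = as.integer(input_size), init_sd = init_sd),
            class = "arch_config")
}

#' Training configuration
#'
#' Defaults: Adam with initial learning rate 1e-3 minimizing binary
#' cross-entropy; the rate is multiplied by 0.2 whenever the validation
#' loss has not improved for 6 consecutive epochs, and training stops once
#' it falls below 1e-7 or after 100 epochs; L2 weight penalty lambda = 0.01
#' on convolution and fully-connected weights; batch size 32.
#'
#' @param lr_initial Initial learning rate.
#' @param lr_factor Multiplicative reduction factor, in (0, 1).
#' @param lr_patience_epochs Epochs without improvement before a reduction.
#' @param lr_floor Training stops when the rate falls below this.
#' @param l2_lambda L2 penalty coefficient.
#' @param epochs_max Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param seed Seed for weight init, shuffling, dropout and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_initial = 1e-3, lr_factor = 0.2,
                         lr_patience_epochs = 6L, lr_floor = 1e-7,
                         l2_lambda = 0.01, epochs_max = 100L,
                         batch_size = 32L, seed = 1L) {
  stopifnot(lr_factor > 0, lr_factor < 1, lr_floor < lr_initial,
            epochs_max >= 1, batch_size >= 1)
  structure(list(loss = "binary_crossentropy", optimizer = "adam",
                 lr_initial = lr_initial, lr_factor = lr_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 lr_floor = lr_floor, l2_lambda = l2_lambda,
                 epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

conv_input_channels <- function(arch) c(1L, arch$conv_filters[1:3])

fc_input_size <- function(arch) {
  side <- arch$input_size
  for (i in 1:4) side <- side %/% 2L
  side * side * arch$conv_filters[4]
}

#' Build an (untrained) network
#'
#' Weights are initialized from a zero-mean normal distribution
#' (sd = `arch$init_sd`); biases start at zero, batch-norm scale at one.
#'
#' @param arch An [arch_config()].
#' @param seed Seed for the weight draw.
#' @return A `scar_cnn` object: `params` (named list of weight matrices),
#'   `bn_mean`/`bn_var` (running batch-norm statistics), `arch`.
#' @export
build_model <- function(arch = arch_config(), seed = 1L) {
  with_seed(seed, {
    params <- list()
    in_ch <- conv_input_channels(arch)
    for (s in 1:4) {
      oc <- arch$conv_filters[s]
      params[[paste0("Wc", s)]] <-
        matrix(stats::rnorm(oc * in_ch[s] * 9, 0, arch$init_sd), oc)
      params[[paste0("bc", s)]] <- numeric(oc)
      params[[paste0("gamma", s)]] <- rep(1, oc)
      params[[paste0("beta", s)]] <- numeric(oc)
    }
    sizes <- c(fc_input_size(arch), arch$fc_sizes)
    for (s in 1:3) {
      params[[paste0("Wf", s)]] <-
        matrix(stats::rnorm(sizes[s + 1] * sizes[s], 0, arch$init_sd),
               sizes[s + 1])
      params[[paste0("bf", s)]] <- numeric(sizes[s + 1])
    }
    bn0 <- lapply(arch$conv_filters, function(oc) numeric(oc))
    bn1 <- lapply(arch$conv_filters, function(oc) rep(1, oc))
    structure(list(params = params, bn_mean = bn0, bn_var = bn1,
                   arch = arch),
              class = "scar_cnn")
  })
}

#' Number of trainable parameters
#'
#' @param model A `scar_cnn`.
#' @return Integer parameter count (conv + batch-norm + FC).
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' Plateau learning-rate step
#'
#' Given the validation losses observed since the last rate change, reduce
#' the rate by `factor` when the best loss is at least `patience` epochs
#' old; signal a stop once the next rate falls below `lr_floor`.
#'
#' @param val_losses Numeric vector of validation losses (oldest first)
#'   since the last reduction.
#' @param current_lr Current learning rate.
#' @param patience Epochs without a new best before reducing.
#' @param factor Multiplicative factor in (0, 1).
#' @param lr_floor Stop threshold.
#' @return List with `next_lr` and `stop`.
#' @export
lr_step <- function(val_losses, current_lr, patience = 6L, factor = 0.2,
                    lr_floor = 1e-7) {
  stopifnot(length(val_losses) >= 1)
  since_best <- length(val_losses) - which.min(val_losses)
  next_lr <- if (since_best >= patience) current_lr * factor else current_lr
  list(next_lr = next_lr, stop = next_lr < lr_floor)
}

# One Adam update of all parameters; state carries first/second moments.
adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nmn in names(params)) {
    g <- grads[[nmn]]
    state$m[[nmn]] <- beta1 * state$m[[nmn]] + (1 - beta1) * g
    state$v[[nmn]] <- beta2 * state$v[[nmn]] + (1 - beta2) * g^2
    mhat <- state$m[[nmn]] / (1 - beta1^state$t)
    vhat <- state$v[[nmn]] / (1 - beta2^state$t)
    params[[nmn]] <- params[[nmn]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stack a list/array of patches into the (H, W, N) array the C++ core wants.
as_patch_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    # accept N x H x W (sample-major) and convert
    return(aperm(x, c(2, 3, 1)))
  }
  if (is.list(x)) {
    if (length(x) == 0)
      stop("patches must be non-empty", call. = FALSE)
    h <- nrow(x[[1]]); w <- ncol(x[[1]])
    out <- array(0, c(h, w, length(x)))
    for (i in seq_along(x)) out[, , i] <- x[[i]]
    return(out)
  }
  stop("patches must be a list of matrices or an N x H x W array",
       call. = FALSE)
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy plus the L2 weight penalty with Adam,
#' with the plateau learning-rate schedule of [lr_step()]. Batch-norm
#' running statistics are updated with momentum 0.9. When an
#' [augment_config()] is supplied, each training patch is randomly
#' transformed on the fly each epoch (stream seeded per epoch and sample).
#'
#' @param x_train,y_train Training patches (list of matrices or N x H x W
#'   array) and binary labels.
#' @param x_val,y_val Validation set for the scheduler.
#' @param arch An [arch_config()].
#' @param cfg A [train_config()].
#' @param augment_cfg Optional [augment_config()]; NULL disables
#'   augmentation.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained `scar_cnn`) and `history` (data frame
#'   epoch, train_loss, val_loss, lr) with attribute `stop_reason`
#'   (`"epochs_exhausted"` or `"lr_floor_reached"`).
#' @export
train_cnn <- function(x_train, y_train, x_val, y_val,
                      arch = arch_config(), cfg = train_config(),
                      augment_cfg = NULL, verbose = FALSE) {
  xt <- as_patch_array(x_train)
  xv <- as_patch_array(x_val)
  n <- dim(xt)[3]
  if (n == 0 || dim(xv)[3] == 0)
    stop("training and validation sets must be non-empty", call. = FALSE)
  y_train <- as.numeric(y_train)
  y_val <- as.numeric(y_val)
  stopifnot(length(y_train) == n)

  model <- build_model(arch, seed = cfg$seed)
  state <- list(t = 0L,
                m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  lr <- cfg$lr_initial
  momentum <- 0.9
  hist <- list()
  stop_reason <- "epochs_exhausted"
  best_val <- Inf
  wait <- 0L

  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$epochs_max)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xt[, , idx, drop = FALSE]
      if (!is.null(augment_cfg)) {
        for (k in seq_along(idx)) {
          sd_k <- (augment_cfg$seed + 131071L * epoch + idx[k]) %% 2147483647L
          xb[, , k] <- augment(xb[, , k], augment_cfg, seed = sd_k)
        }
      }
      step <- cnn_train_step_cpp(model$params, xb, y_train[idx],
                                 cfg$l2_lambda, arch$dropout_rate)
      for (s in 1:4) {
        model$bn_mean[[s]] <- momentum * model$bn_mean[[s]] +
          (1 - momentum) * step$batch_mean[[s]]
        model$bn_var[[s]] <- momentum * model$bn_var[[s]] +
          (1 - momentum) * step$batch_var[[s]]
      }
      upd <- adam_update(model$params, step$grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + step$loss
      nb <- nb + 1L
    }
    val_probs <- predict_cnn(model, xv)
    val_loss <- bce_loss(y_val, val_probs)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                val_loss = val_loss, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, ep_loss / nb, val_loss, lr))
    if (val_loss < best_val) {
      best_val <- val_loss
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= cfg$lr_patience_epochs) {
      lr <- lr * cfg$lr_factor
      wait <- 0L
      if (lr < cfg$lr_floor) {
        stop_reason <- "lr_floor_reached"
        break
      }
    }
  }
  model <- calibrate_bn(model, xt, cfg$batch_size)
  history <- do.call(rbind, hist)
  attr(history, "stop_reason") <- stop_reason
  list(model = model, history = history, stop_reason = stop_reason)
}

# Recompute the batch-norm running statistics from full passes over the
# training set with the final weights, pooling per-chunk channel means and
# variances. With short schedules the momentum-averaged running statistics
# are still dominated by their initialization; inference needs calibrated
# ones.
calibrate_bn <- function(model, xt, batch_size) {
  n <- dim(xt)[3]
  starts <- seq(1, n, by = batch_size)
  w <- numeric(0)
  mus <- list()
  vars <- list()
  for (bi in seq_along(starts)) {
    idx <- starts[bi]:min(starts[bi] + batch_size - 1L, n)
    st <- cnn_batch_stats_cpp(model$params, xt[, , idx, drop = FALSE])
    w[bi] <- length(idx)
    mus[[bi]] <- st$mean
    vars[[bi]] <- st$var
  }
  w <- w / sum(w)
  for (s in 1:4) {
    mu_s <- Reduce(`+`, Map(function(m, wi) wi * m[[s]], mus, w))
    ex2 <- Reduce(`+`, Map(function(v, m, wi) wi * (v[[s]] + m[[s]]^2),
                           vars, mus, w))
    model$bn_mean[[s]] <- mu_s
    model$bn_var[[s]] <- pmax(ex2 - mu_s^2, 0)
  }
  model
}

bce_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict scar probabilities
#'
#' Inference mode: dropout disabled, batch normalization uses the running
#' statistics; deterministic given fixed weights.
#'
#' @param model A `scar_cnn`.
#' @param x Patches (list of matrices or N x H x W array).
#' @param batch_size Patches per forward pass.
#' @return Numeric vector of sigmoid scores in (0, 1).
#' @export
predict_cnn <- function(model, x, batch_size = 64L) {
  xa <- if (is.array(x) && length(dim(x)) == 3L &&
            dim(x)[1] == model$arch$input_size &&
            dim(x)[2] == model$arch$input_size) x else as_patch_array(x)
  if (dim(xa)[1] != model$arch$input_size ||
      dim(xa)[2] != model$arch$input_size)
    stop("patch shape mismatch: expected ", model$arch$input_size, " x ",
         model$arch$input_size, call. = FALSE)
  n <- dim(xa)[3]
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- cnn_forward_cpp(model$params, xa[, , idx, drop = FALSE],
                                model$bn_mean, model$bn_var)
  }
  out
}
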