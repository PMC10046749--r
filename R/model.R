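#' CNN configuration
#'
#' Fixed compact architecture for binary classification of scalogram images:
#' `n_blocks` convolutional blocks, each `convs_per_block` 3x3 convolutions
#' (ReLU, same padding) followed by 2x2 max pooling and dropout, then a
#' dense ReLU layer, dropout, and a single sigmoid output unit trained with
#' binary cross-entropy.
#'
#' Convolutions use stride 1 by default: with stride-2 convolutions *and*
#' pooling in every block, four blocks would collapse a 224-pixel input
#' below one pixel before the flatten, so the four-block topology is only
#' geometrically possible with stride-1 convolutions.  `conv_stride = 2`
#' remains available (with fewer blocks) for comparison;
#' [build_cnn()] rejects any configuration whose spatial size collapses,
#' with a layer-by-layer shape trace.
#'
#' @param input_shape Image dimensions `c(height, width, channels)`.
#' @param n_blocks Number of convolutional blocks.
#' @param convs_per_block Convolutions per block.
#' @param filters Kernels per convolution layer.
#' @param kernel Square kernel side (odd).
#' @param conv_stride Convolution stride.
#' @param pool Max-pool window/stride.
#' @param block_dropout Dropout rate after each block.
#' @param fc_units Dense layer width.
#' @param fc_dropout Dropout rate after the dense layer.
#' @param optimizer `"adam"`, `"rmsprop"` or `"sgdm"` (stochastic gradient
#'   descent with momentum 0.9).
#' @param learning_rate Learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param validation_patience Early-stopping patience (epochs without
#'   validation-loss improvement).
#' @param seed Integer seed for weight initialization, shuffling and dropout.
#' @return An object of class `cnn_config`; all fields are echoed verbatim
#'   into the trained model's run report.
#' @export
cnn_config <- function(input_shape = c(224, 224, 3),
                       n_blocks = 4,
                       convs_per_block = 2,
                       filters = 64,
                       kernel = 3,
                       conv_stride = 1,
                       pool = 2,
                       block_dropout = 0.25,
                       fc_units = 128,
                       fc_dropout = 0.5,
                       optimizer = c("adam", "rmsprop", "sgdm"),
                       learning_rate = 1e-4,
                       batch_size = 32,
                       max_epochs = 50,
                       validation_patience = 10,
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (length(input_shape) != 3L || any(input_shape < 1)) {
    stop("`input_shape` must be c(height, width, channels)", call. = FALSE)
  }
  if (kernel %% 2 != 1) stop("`kernel` must be odd", call. = FALSE)
  if (block_dropout < 0 || block_dropout >= 1 ||
      fc_dropout < 0 || fc_dropout >= 1) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(input_shape = as.integer(input_shape),
         n_blocks = as.integer(n_blocks),
         convs_per_block = as.integer(convs_per_block),
         filters = as.integer(filters), kernel = as.integer(kernel),
         conv_stride = as.integer(conv_stride), pool = as.integer(pool),
         block_dropout = block_dropout, fc_units = as.integer(fc_units),
         fc_dropout = fc_dropout, optimizer = optimizer,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         validation_patience = as.integer(validation_patience),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

# ---- layer primitives (arrays are H x W x C x N) -------------------------

conv_out_dim <- function(n, k, stride) {
  p <- (k - 1L) %/% 2L
  (n + 2L * p - k) %/% stride + 1L
}

# im2col indices for one (H, W, C, N, k, stride) geometry.
im2col_index <- function(H, W, C, N, k, stride) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  Ho <- conv_out_dim(H, k, stride)
  Wo <- conv_out_dim(W, k, stride)
  corner <- outer((0:(Ho - 1L)) * stride + 1L, (0:(Wo - 1L)) * stride * Hp, "+")
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
  off_all <- as.vector(outer(off, (0:(C - 1L)) * (Hp * Wp), "+"))
  pos_n <- rep(as.vector(corner), times = N) +
    rep((0:(N - 1L)) * (Hp * Wp * C), each = Ho * Wo)
  list(idx = outer(pos_n, off_all, "+"),
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, p = p)
}

conv_forward <- function(X, W, b, stride) {
  d <- dim(X)
  k <- dim(W)[1]
  Cout <- dim(W)[4]
  geo <- im2col_index(d[1], d[2], d[3], d[4], k, stride)
  Xp <- array(0, c(geo$Hp, geo$Wp, d[3], d[4]))
  Xp[geo$p + (1:d[1]), geo$p + (1:d[2]), , ] <- X
  cols <- matrix(Xp[geo$idx], nrow = nrow(geo$idx))
  out <- cols %*% matrix(W, ncol = Cout)
  out <- out + rep(b, each = nrow(out))
  Y <- aperm(array(out, c(geo$Ho, geo$Wo, d[4], Cout)), c(1, 2, 4, 3))
  list(Y = Y, cache = list(cols = cols, geo = geo, dimX = d, Wdim = dim(W)))
}

conv_backward <- function(dY, W, cache) {
  d <- cache$dimX
  geo <- cache$geo
  Cout <- dim(W)[4]
  dY_mat <- matrix(aperm(dY, c(1, 2, 4, 3)), nrow = geo$Ho * geo$Wo * d[4])
  dW <- array(crossprod(cache$cols, dY_mat), dim = dim(W))
  db <- colSums(dY_mat)
  dcols <- dY_mat %*% t(matrix(W, ncol = Cout))
  dXp <- numeric(geo$Hp * geo$Wp * d[3] * d[4])
  for (cc in seq_len(ncol(geo$idx))) {
    i <- geo$idx[, cc]
    dXp[i] <- dXp[i] + dcols[, cc]
  }
  dXp <- array(dXp, c(geo$Hp, geo$Wp, d[3], d[4]))
  dX <- dXp[geo$p + (1:d[1]), geo$p + (1:d[2]), , , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

pool_forward <- function(X) {
  d <- dim(X)
  H2 <- 2L * (d[1] %/% 2L)
  W2 <- 2L * (d[2] %/% 2L)
  ro <- seq(1L, H2, 2L); re <- seq(2L, H2, 2L)
  co <- seq(1L, W2, 2L); ce <- seq(2L, W2, 2L)
  a <- X[ro, co, , , drop = FALSE]
  b <- X[re, co, , , drop = FALSE]
  cc <- X[ro, ce, , , drop = FALSE]
  dd <- X[re, ce, , , drop = FALSE]
  mx <- pmax(a, b, cc, dd)
  # gradient routed to the first maximal position (fixed a, b, c, d order)
  ma <- a == mx
  mb <- (b == mx) & !ma
  mc <- (cc == mx) & !ma & !mb
  md <- !ma & !mb & !mc
  list(Y = mx,
       cache = list(ma = ma, mb = mb, mc = mc, md = md, dimX = d,
                    ro = ro, re = re, co = co, ce = ce))
}

pool_backward <- function(dY, cache) {
  dX <- array(0, cache$dimX)
  dX[cache$ro, cache$co, , ] <- dY * cache$ma
  dX[cache$re, cache$co, , ] <- dY * cache$mb
  dX[cache$ro, cache$ce, , ] <- dY * cache$mc
  dX[cache$re, cache$ce, , ] <- dY * cache$md
  dX
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(prob, y) {
  eps <- 1e-12
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- model construction --------------------------------------------------

#' Build the CNN (untrained)
#'
#' Validates the spatial geometry (rejecting configurations that collapse
#' below 1x1 before the flatten, with a layer-by-layer shape trace in the
#' error message), then allocates fan-in-scaled random initial weights under
#' `cfg$seed`.
#'
#' @param cfg A [cnn_config()].
#' @return An object of class `cnn_model` with `params` (named list of
#'   arrays), the architecture, the shape trace, and the config echo.
#' @export
build_cnn <- function(cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]; C <- cfg$input_shape[3]
  trace <- sprintf("input: %dx%dx%d", H, W, C)
  arch <- list()
  shapes <- list(c(H, W, C))
  for (blk in seq_len(cfg$n_blocks)) {
    for (cv in seq_len(cfg$convs_per_block)) {
      nm <- sprintf("b%dc%d", blk, cv)
      H <- conv_out_dim(H, cfg$kernel, cfg$conv_stride)
      W <- conv_out_dim(W, cfg$kernel, cfg$conv_stride)
      trace <- c(trace, sprintf("%s conv(%dx%d, stride %d): %dx%dx%d",
                                nm, cfg$kernel, cfg$kernel, cfg$conv_stride,
                                H, W, cfg$filters))
      if (H < 1 || W < 1) {
        stop(paste(c("spatial size collapsed below 1x1:", trace),
                   collapse = "\n  "), call. = FALSE)
      }
      arch <- c(arch, list(list(op = "conv", name = nm, in_ch = C,
                                stride = cfg$conv_stride)),
                list(list(op = "relu")))
      C <- cfg$filters
    }
    H <- H %/% cfg$pool
    W <- W %/% cfg$pool
    trace <- c(trace, sprintf("b%d maxpool(%dx%d): %dx%dx%d",
                              blk, cfg$pool, cfg$pool, H, W, C))
    if (H < 1 || W < 1) {
      stop(paste(c("spatial size collapsed below 1x1:", trace),
                 collapse = "\n  "), call. = FALSE)
    }
    arch <- c(arch, list(list(op = "pool")),
              list(list(op = "dropout", rate = cfg$block_dropout)))
  }
  n_flat <- H * W * C
  trace <- c(trace, sprintf("flatten: %d", n_flat),
             sprintf("fc1: %d", cfg$fc_units), "fc2: 1 (sigmoid)")
  arch <- c(arch, list(list(op = "flatten")),
            list(list(op = "dense", name = "fc1", n_in = n_flat,
                      n_out = cfg$fc_units)),
            list(list(op = "relu")),
            list(list(op = "dropout", rate = cfg$fc_dropout)),
            list(list(op = "dense", name = "fc2", n_in = cfg$fc_units,
                      n_out = 1L)))

  params <- with_seed(derive_seed(cfg$seed, "init"), {
    p <- list()
    k <- cfg$kernel
    for (layer in arch) {
      if (identical(layer$op, "conv")) {
        fan_in <- k * k * layer$in_ch
        p[[paste0(layer$name, "_W")]] <- array(
          rnorm(k * k * layer$in_ch * cfg$filters, 0, sqrt(2 / fan_in)),
          dim = c(k, k, layer$in_ch, cfg$filters))
        p[[paste0(layer$name, "_b")]] <- numeric(cfg$filters)
      } else if (identical(layer$op, "dense")) {
        p[[paste0(layer$name, "_W")]] <- matrix(
          rnorm(layer$n_in * layer$n_out, 0, sqrt(2 / layer$n_in)),
          nrow = layer$n_in)
        p[[paste0(layer$name, "_b")]] <- numeric(layer$n_out)
      }
    }
    p
  })
  structure(
    list(cfg = cfg, arch = arch, params = params, shape_trace = trace,
         history = NULL, best_epoch = NA_integer_),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<cnn_model> %s, %s parameters%s\n",
              paste(x$cfg$input_shape, collapse = "x"),
              format(n_par, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epoch(s), best epoch %d",
                        nrow(x$history), x$best_epoch)))
  invisible(x)
}

cnn_forward <- function(model, X, training = FALSE) {
  params <- model$params
  caches <- vector("list", length(model$arch))
  cur <- X
  for (i in seq_along(model$arch)) {
    layer <- model$arch[[i]]
    if (layer$op == "conv") {
      res <- conv_forward(cur, params[[paste0(layer$name, "_W")]],
                          params[[paste0(layer$name, "_b")]], layer$stride)
      cur <- res$Y
      caches[[i]] <- res$cache
    } else if (layer$op == "relu") {
      caches[[i]] <- cur > 0
      cur <- cur * caches[[i]]
    } else if (layer$op == "pool") {
      res <- pool_forward(cur)
      cur <- res$Y
      caches[[i]] <- res$cache
    } else if (layer$op == "dropout") {
      if (training && layer$rate > 0) {
        mask <- (runif(length(cur)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(cur)
        caches[[i]] <- mask
        cur <- cur * mask
      }
    } else if (layer$op == "flatten") {
      d <- dim(cur)
      caches[[i]] <- d
      cur <- t(matrix(cur, nrow = prod(d[1:3])))
    } else if (layer$op == "dense") {
      caches[[i]] <- cur
      cur <- cur %*% params[[paste0(layer$name, "_W")]] +
        rep(params[[paste0(layer$name, "_b")]], each = nrow(cur))
    }
  }
  logit <- as.numeric(cur)
  list(logit = logit, prob = sigmoid(logit), caches = caches)
}

cnn_backward <- function(model, fwd, y) {
  params <- model$params
  grads <- list()
  n <- length(y)
  dcur <- matrix((fwd$prob - y) / n, ncol = 1L)  # d(BCE)/d(logit)
  for (i in rev(seq_along(model$arch))) {
    layer <- model$arch[[i]]
    if (layer$op == "dense") {
      Xin <- fwd$caches[[i]]
      grads[[paste0(layer$name, "_W")]] <- crossprod(Xin, dcur)
      grads[[paste0(layer$name, "_b")]] <- colSums(dcur)
      dcur <- dcur %*% t(params[[paste0(layer$name, "_W")]])
    } else if (layer$op == "flatten") {
      d <- fwd$caches[[i]]
      dcur <- array(t(dcur), dim = d)
    } else if (layer$op == "dropout") {
      if (!is.null(fwd$caches[[i]])) dcur <- dcur * fwd$caches[[i]]
    } else if (layer$op == "pool") {
      dcur <- pool_backward(dcur, fwd$caches[[i]])
    } else if (layer$op == "relu") {
      dcur <- dcur * fwd$caches[[i]]
    } else if (layer$op == "conv") {
      res <- conv_backward(dcur, params[[paste0(layer$name, "_W")]],
                           fwd$caches[[i]])
      grads[[paste0(layer$name, "_W")]] <- res$dW
      grads[[paste0(layer$name, "_b")]] <- res$db
      dcur <- res$dX
    }
  }
  grads
}

make_optimizer <- function(kind, lr, param_names) {
  state <- new.env(parent = emptyenv())
  state$t <- 0
  state$m <- setNames(vector("list", length(param_names)), param_names)
  state$v <- state$m
  list(
    step_begin = function() state$t <- state$t + 1,
    update = function(name, param, grad) {
      g <- as.numeric(grad)
      if (kind == "sgdm") {
        v <- state$v[[name]] %||% numeric(length(g))
        v <- 0.9 * v - lr * g
        state$v[[name]] <- v
        param_new <- as.numeric(param) + v
      } else if (kind == "rmsprop") {
        v <- state$v[[name]] %||% numeric(length(g))
        v <- 0.9 * v + 0.1 * g^2
        state$v[[name]] <- v
        param_new <- as.numeric(param) - lr * g / (sqrt(v) + 1e-8)
      } else {  # adam
        m <- state$m[[name]] %||% numeric(length(g))
        v <- state$v[[name]] %||% numeric(length(g))
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g^2
        state$m[[name]] <- m
        state$v[[name]] <- v
        mh <- m / (1 - 0.9^state$t)
        vh <- v / (1 - 0.999^state$t)
        param_new <- as.numeric(param) - lr * mh / (sqrt(vh) + 1e-8)
      }
      if (is.matrix(param) || is.array(param)) {
        dim(param_new) <- dim(param)
      }
      param_new
    }
  )
}

as_image_batch <- function(images, input_shape) {
  if (is.list(images)) {
    images <- array(unlist(images, use.names = FALSE),
                    dim = c(dim(images[[1]]), length(images)))
  }
  if (length(dim(images)) == 3L) {
    images <- array(images, dim = c(dim(images), 1L))
  }
  d <- dim(images)
  if (length(d) != 4L || !all(d[1:3] == input_shape)) {
    stop(sprintf("images must be %s (got %s)",
                 paste(input_shape, collapse = "x"),
                 paste(d, collapse = "x")), call. = FALSE)
  }
  images
}

#' Train the CNN
#'
#' Minimizes binary cross-entropy with the configured optimizer, learning
#' rate, batch size and epoch budget.  A stratified fraction of the training
#' images is held out for validation; training stops early once the
#' validation loss has not improved for `validation_patience` epochs, and
#' the best-validation-epoch weights are restored.  All randomness
#' (validation split, shuffling, dropout) is driven by `cfg$seed`.
#'
#' @param model A [build_cnn()] model.
#' @param images `H x W x C x N` array (or list of `H x W x C` arrays) with
#'   values in \[0, 1\].
#' @param labels Binary vector (1 = stressed); both classes must be present.
#' @param val_frac Fraction held out for validation (0 disables early
#'   stopping).
#' @param verbose Print per-epoch losses.
#' @return The trained `cnn_model`, with `history` (a data frame of epoch,
#'   train loss, validation loss/accuracy) and `best_epoch`.
#' @export
train_cnn <- function(model, images, labels, val_frac = 0.2,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$cfg
  X <- as_image_batch(images, cfg$input_shape)
  y <- as.numeric(labels)
  N <- dim(X)[4]
  if (length(y) != N) stop("labels do not match image count", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }

  val_idx <- integer(0)
  if (val_frac > 0) {
    val_idx <- with_seed(derive_seed(cfg$seed, "valsplit"), {
      idx <- unlist(lapply(unique(y), function(cl) {
        cand <- which(y == cl)
        sample(cand, max(1L, round(val_frac * length(cand))))
      }))
      sort(idx)
    })
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  Xval <- if (length(val_idx)) X[, , , val_idx, drop = FALSE] else NULL
  yval <- y[val_idx]

  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate, names(model$params))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  best_val <- Inf
  best_params <- model$params
  best_epoch <- 0L
  since_best <- 0L

  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      order_idx <- sample(tr_idx)
      batch_losses <- numeric(0)
      for (start in seq(1, length(order_idx), by = cfg$batch_size)) {
        bi <- order_idx[start:min(start + cfg$batch_size - 1, length(order_idx))]
        Xb <- X[, , , bi, drop = FALSE]
        fwd <- cnn_forward(model, Xb, training = TRUE)
        batch_losses <- c(batch_losses, bce_loss(fwd$prob, y[bi]))
        grads <- cnn_backward(model, fwd, y[bi])
        opt$step_begin()
        for (nm in names(grads)) {
          model$params[[nm]] <- opt$update(nm, model$params[[nm]], grads[[nm]])
        }
      }
      train_loss <- mean(batch_losses)
      if (length(val_idx)) {
        pv <- predict_cnn(model, Xval)
        val_loss <- bce_loss(pv, yval)
        val_acc <- mean((pv >= 0.5) == (yval == 1))
      } else {
        val_loss <- NA_real_
        val_acc <- NA_real_
      }
      history[nrow(history) + 1L, ] <- list(epoch, train_loss, val_loss,
                                            val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  val acc %.3f",
                        epoch, train_loss, val_loss, val_acc))
      }
      if (length(val_idx)) {
        if (val_loss < best_val - 1e-12) {
          best_val <- val_loss
          best_params <- model$params
          best_epoch <- epoch
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$validation_patience) break
        }
      } else {
        best_params <- model$params
        best_epoch <- epoch
      }
    }
  })
  model$params <- best_params
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

#' Predict stress probabilities
#'
#' Deterministic forward pass (dropout disabled); images are processed in
#' fixed-size chunks, and a batch prediction equals the concatenation of
#' single-image predictions.
#'
#' @param model A trained (or untrained) `cnn_model`.
#' @param images `H x W x C x N` array, single `H x W x C` image, or list of
#'   images.
#' @return Vector of probabilities in \[0, 1\] (probability of the stressed
#'   class).
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  X <- as_image_batch(images, model$cfg$input_shape)
  N <- dim(X)[4]
  probs <- numeric(N)
  for (start in seq(1, N, by = 64L)) {
    idx <- start:min(start + 63L, N)
    probs[idx] <- cnn_forward(model, X[, , , idx, drop = FALSE],
                              training = FALSE)$prob
  }
  probs
}

#' Augmentation configuration
#'
#' White-Gaussian-noise augmentation of scalogram images: each copy adds
#' noise with mean equal to `noise_mean_frac` of the image's mean intensity
#' and standard deviation `noise_sd_frac` of the image's intensity SD,
#' clipped back to \[0, 1\].
#'
#' @param noise_mean_frac Noise mean as a fraction of the per-image mean.
#' @param noise_sd_frac Noise SD as a fraction of the per-image SD.
#' @param copies Noisy copies per original image.
#' @param seed Integer seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(noise_mean_frac = 0.30, noise_sd_frac = 0.10,
                           copies = 1L, seed = 1L) {
  if (noise_mean_frac < 0 || noise_sd_frac < 0) {
    stop("noise fractions must be non-negative", call. = FALSE)
  }
  if (copies < 1) stop("`copies` must be >= 1", call. = FALSE)
  structure(
    list(noise_mean_frac = noise_mean_frac, noise_sd_frac = noise_sd_frac,
         copies = as.integer(copies), seed = as.integer(seed)),
    class = "augment_config"
  )
}

#' Enlarge a training set with noisy copies
#'
#' Originals are retained and each gains `copies` white-Gaussian-noise
#' copies with labels carried over, so the output size is
#' `(1 + copies) * N` (doubling, with the default single copy).
#'
#' @param images `H x W x C x N` array in \[0, 1\] (or list of images).
#' @param labels Length-N label vector.
#' @param cfg An [augment_config()].
#' @return A list with the enlarged `images` array and `labels` vector;
#'   originals come first, then the noisy copies in original order.
#' @export
augment_with_noise <- function(images, labels, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  if (is.list(images)) {
    images <- array(unlist(images, use.names = FALSE),
                    dim = c(dim(images[[1]]), length(images)))
  }
  d <- dim(images)
  N <- d[4]
  if (length(labels) != N) {
    stop("labels do not match image count", call. = FALSE)
  }
  out <- array(0, dim = c(d[1:3], N * (1L + cfg$copies)))
  out[, , , seq_len(N)] <- images
  out_labels <- rep(labels, 1L + cfg$copies)
  with_seed(derive_seed(cfg$seed, "augment"), {
    pos <- N
    for (cp in seq_len(cfg$copies)) {
      for (i in seq_len(N)) {
        img <- images[, , , i]
        mu <- cfg$noise_mean_frac * mean(img)
        sig <- cfg$noise_sd_frac * sd(img)
        noisy <- img + rnorm(length(img), mu, sig)
        out[, , , pos + 1L] <- pmin(pmax(noisy, 0), 1)
        pos <- pos + 1L
      }
    }
  })
  list(images = out, labels = out_labels)
}
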