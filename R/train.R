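# Training: AdamW/Adam optimizer, softmax cross-entropy, the cosine
# learning-rate schedule, and the `mmha_train()` fitting entry point
# returning a classed model object with predict/print/summary methods.

#' Cosine-annealing learning rate
#'
#' `eta_min + (eta_max - eta_min) * (1 + cos(pi * T_cur / T_max)) / 2`.
#'
#' @param cfg List with `eta_max` (default 1e-3), `eta_min` (default 0),
#'   `T_max` (total iterations) and `T_cur` (current iteration).
#' @return The learning rate at `T_cur`.
#' @export
cosine_lr <- function(cfg) {
  eta_max <- cfg$eta_max %||% 1e-3
  eta_min <- cfg$eta_min %||% 0
  abort_if(is.null(cfg$T_max) || cfg$T_max <= 0, "T_max must be positive")
  abort_if(eta_min < 0 || eta_min > eta_max, "need 0 <= eta_min <= eta_max")
  abort_if(cfg$T_cur < 0 || cfg$T_cur > cfg$T_max,
           "T_cur must be in [0, T_max]")
  eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(pi * cfg$T_cur / cfg$T_max))
}

# Softmax cross-entropy; y integer classes 1..K.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

ce_loss <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = d / n, p = p)
}

# AdamW step over a list of parameter-bearing layer environments.
# Weight decay is decoupled and applied to weight matrices only (not to
# biases or normalization parameters); optimizer = "adam" couples decay off.
adamw_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01, t = 1, optimizer = "adamw") {
  for (l in layers) {
    if (is.null(l$opt)) l$opt <- list(m = list(), v = list())
    for (pn in names(l$par)) {
      g <- l$gr[[pn]]
      if (is.null(g)) next
      if (is.null(l$opt$m[[pn]])) {
        l$opt$m[[pn]] <- 0 * l$par[[pn]]
        l$opt$v[[pn]] <- 0 * l$par[[pn]]
      }
      l$opt$m[[pn]] <- beta1 * l$opt$m[[pn]] + (1 - beta1) * g
      l$opt$v[[pn]] <- beta2 * l$opt$v[[pn]] + (1 - beta2) * g^2
      mhat <- l$opt$m[[pn]] / (1 - beta1^t)
      vhat <- l$opt$v[[pn]] / (1 - beta2^t)
      upd <- mhat / (sqrt(vhat) + eps)
      decay_this <- optimizer == "adamw" && weight_decay > 0 &&
        pn %in% c("W", "Wq", "Wk", "Wv", "Wo")
      if (decay_this) upd <- upd + weight_decay * l$par[[pn]]
      l$par[[pn]] <- l$par[[pn]] - lr * upd
    }
    l$gr <- list()
  }
  invisible(NULL)
}

# Forward + (optionally) backward one batch for a given method.  Returns
# logits; when `y` is given also loss, and runs the backward pass.
model_step <- function(model, method, topo, faces, y = NULL, train = FALSE) {
  if (method == "mmha") {
    te <- eeg_tokens_per_band(model, topo, train)
    mf <- model$face_trunk$forward(faces, train)
    tf_ <- model$face_head$forward(mf, train)
    out <- ffm_forward(model, te, tf_, train)
    logits <- out$logits
    if (!is.null(y)) {
      l <- ce_loss(logits, y)
      if (train) {
        db <- ffm_backward(model, l$dlogits, out$Te, out$Tf)
        eeg_tokens_per_band_backward(model, db$deeg, dim(topo))
        model$face_trunk$backward(model$face_head$backward(db$dface))
      }
      return(list(logits = logits, loss = l$loss, attn = out$attn))
    }
    return(list(logits = logits, attn = out$attn))
  }
  if (method %in% c("efem", "fefem")) {
    x <- if (method == "efem") topo else faces
    tok <- model$head$forward(model$trunk$forward(x, train), train)
    d <- dim(tok)
    pooled <- t(apply(tok, 3, colMeans))           # N x d_model
    logits <- model$classifier$forward(pooled, train)
    if (!is.null(y)) {
      l <- ce_loss(logits, y)
      if (train) {
        dp <- model$classifier$backward(l$dlogits)
        dtok <- array(rep(t(dp) / d[1], each = d[1]), d)
        model$trunk$backward(model$head$backward(dtok))
      }
      return(list(logits = logits, loss = l$loss))
    }
    return(list(logits = logits))
  }
  if (method == "concat") {
    te <- model$eeg$head$forward(model$eeg$trunk$forward(topo, train), train)
    tf_ <- model$face$head$forward(model$face$trunk$forward(faces, train), train)
    de <- dim(te); df_ <- dim(tf_)
    pe <- t(apply(te, 3, colMeans))
    pf <- t(apply(tf_, 3, colMeans))
    logits <- model$head$forward(cbind(pe, pf), train)
    if (!is.null(y)) {
      l <- ce_loss(logits, y)
      if (train) {
        dcat <- model$head$backward(l$dlogits)
        dpe <- dcat[, seq_len(de[2]), drop = FALSE]
        dpf <- dcat[, de[2] + seq_len(df_[2]), drop = FALSE]
        dte <- array(rep(t(dpe) / de[1], each = de[1]), de)
        dtf <- array(rep(t(dpf) / df_[1], each = df_[1]), df_)
        model$eeg$trunk$backward(model$eeg$head$backward(dte))
        model$face$trunk$backward(model$face$head$backward(dtf))
      }
      return(list(logits = logits, loss = l$loss))
    }
    return(list(logits = logits))
  }
  stop("unknown method: ", method)
}

build_model_for_method <- function(method, cfg, seed) {
  switch(method,
         mmha = build_fusion_model(cfg, seed = seed),
         efem = build_efem(cfg, in_ch = 5, seed = seed),
         fefem = build_fefem(cfg, seed = seed),
         concat = build_concat_model(cfg, seed = seed),
         stop("unknown method: ", method))
}

#' Train an emotion-recognition model
#'
#' Fits one of the network variants by mini-batch AdamW (optionally plain
#' Adam) with softmax cross-entropy and a cosine-annealed learning rate
#' (one schedule update per epoch by default, per-batch optional).
#'
#' @param data Prepared tensors as from [prepare_model_data()]: list with
#'   `topo` (H x W x 5 x N), `faces` (H x W x 3 x N), `y` (integer class
#'   1..4), and identifier vectors `subject`, `clip`, `window`.
#' @param method One of `"mmha"` (Transformer fusion), `"efem"` (EEG
#'   unimodal), `"fefem"` (face unimodal), `"concat"` (feature
#'   concatenation baseline).
#' @param cfg A `model_config` (default [desk_model_config()]).
#' @param epochs Training epochs (default 10).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Maximum learning rate eta_max (default 1e-3).
#' @param lr_min Minimum learning rate (default 0).
#' @param optimizer `"adamw"` (default) or `"adam"`.
#' @param schedule `"epoch"` (default: one cosine update per epoch with
#'   T_max = epochs) or `"batch"`.
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param verbose Print per-epoch progress.
#' @return An `mmha_model` with the trained network, training history and
#'   configuration.
#' @export
mmha_train <- function(data, method = c("mmha", "efem", "fefem", "concat"),
                       cfg = desk_model_config(), epochs = 10,
                       batch_size = 32, lr = 1e-3, lr_min = 0,
                       optimizer = c("adamw", "adam"),
                       schedule = c("epoch", "batch"), seed = 1,
                       verbose = FALSE) {
  method <- match.arg(method)
  optimizer <- match.arg(optimizer)
  schedule <- match.arg(schedule)
  n <- length(data$y)
  abort_if(n == 0, "empty training set")
  model <- build_model_for_method(method, cfg, seed)
  layers <- model_layers(model)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc = numeric(0), lr = numeric(0))
  t_adam <- 0
  with_seed(seed + 1000L, {
    n_batches <- ceiling(n / batch_size)
    T_max <- if (schedule == "epoch") epochs else epochs * n_batches
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_hit <- 0
      for (b in seq_len(n_batches)) {
        T_cur <- if (schedule == "epoch") ep - 1 else (ep - 1) * n_batches + b - 1
        lr_t <- cosine_lr(list(eta_max = lr, eta_min = lr_min,
                               T_max = T_max, T_cur = T_cur))
        idx <- ord[((b - 1) * batch_size + 1):min(b * batch_size, n)]
        st <- model_step(model, method,
                         data$topo[, , , idx, drop = FALSE],
                         data$faces[, , , idx, drop = FALSE],
                         y = data$y[idx], train = TRUE)
        t_adam <- t_adam + 1
        adamw_step(layers, lr_t, t = t_adam, optimizer = optimizer)
        ep_loss <- ep_loss + st$loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(st$logits, "first") == data$y[idx])
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / n,
                                  acc = 100 * ep_hit / n, lr = lr_t))
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  acc %.1f%%  lr %.2e",
                        ep, epochs, ep_loss / n, 100 * ep_hit / n, lr_t))
      }
    }
  })
  structure(list(network = model, method = method, cfg = cfg,
                 history = history, epochs = epochs,
                 batch_size = batch_size, lr = lr, optimizer = optimizer,
                 seed = seed, n_train = n),
            class = "mmha_model")
}

#' Predict emotions from a trained model
#'
#' @param object An `mmha_model`.
#' @param newdata Prepared tensors (as the training data).
#' @param type `"class"` (default), `"prob"`, or `"logits"`.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Class labels, probability matrix, or logits.
#' @export
predict.mmha_model <- function(object, newdata, type = c("class", "prob", "logits"),
                               batch_size = 64, ...) {
  type <- match.arg(type)
  n <- length(newdata$y %||% integer(0))
  if (n == 0) n <- dim(newdata$topo)[4]
  out <- matrix(0, n, object$cfg$n_classes)
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    st <- model_step(object$network, object$method,
                     newdata$topo[, , , idx, drop = FALSE],
                     newdata$faces[, , , idx, drop = FALSE], train = FALSE)
    out[idx, ] <- st$logits
  }
  switch(type,
         logits = out,
         prob = softmax_rows(out),
         class = factor(EMOTIONS[max.col(out, "first")], levels = EMOTIONS))
}

#' @export
print.mmha_model <- function(x, ...) {
  cat(sprintf("<mmha_model> method=%s  trained %d epochs on %d windows\n",
              x$method, x$epochs, x$n_train))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.4f, accuracy %.1f%%\n",
                last$loss, last$acc))
  }
  invisible(x)
}

#' @export
summary.mmha_model <- function(object, ...) {
  cnt <- count_params_flops(object$network)
  cat(sprintf("Model: %s\n", object$method))
  cat(sprintf("Trainable parameters: %s (%.2f M)\n",
              format(cnt$params, big.mark = ","), cnt$params / 1e6))
  cat(sprintf("MACs per sample: %.3f G\n", cnt$macs / 1e9))
  cat(sprintf("Optimizer: %s, lr %.1e, batch %d, %d epochs\n",
              object$optimizer, object$lr, object$batch_size, object$epochs))
  print(utils::tail(object$history, 3), row.names = FALSE)
  invisible(object)
}

#' Training-history plot
#'
#' @param x An `mmha_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mmha_model <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "b",
                 xlab = "epoch", ylab = "training loss",
                 main = paste("training loss:", x$method), ...)
  invisible(x)
}

#' Model coefficients (flattened trainable parameters)
#'
#' @param object An `mmha_model`.
#' @param ... Unused.
#' @return Named numeric vector of all trainable parameters.
#' @export
coef.mmha_model <- function(object, ...) {
  ls_ <- model_layers(object$network)
  unlist(lapply(seq_along(ls_), function(i) {
    p <- ls_[[i]]$par
    stats::setNames(unlist(p),
                    paste0("L", i, ".", rep(names(p), vapply(p, length, 0L))))
  }))
}
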