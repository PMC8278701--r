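# Minimal CNN engine in base R (BLAS-backed), sufficient for the two
# architectures used here:
#   depth-wise grouped conv (8 filters per input-type group, kernel 3 or 3x3)
#   -> max pool -> ReLU -> batch norm -> flatten -> FC -> batch norm -> ReLU
#   -> dropout(0.5) -> FC -> softmax, trained with Adam on cross-entropy.
# Internal layout: activations are arrays [C, H, W, N]; the 1-D case uses
# W = 1 with a (3, 1) kernel and (2, 1) pooling, so one code path serves both.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Build an untrained depth-wise grouped CNN
#'
#' @param input_shape integer c(C, H, W) of one example (time series: C
#'   channels, H = length, W = 1).
#' @param groups named list of channel-index vectors partitioning 1..C;
#'   each group gets its own filters (depth-wise grouping), so channel groups
#'   carrying different physical quantities (position vs velocity) are not
#'   mixed at the first layer.
#' @param kernel integer c(kh, kw); (3, 1) for time series, (3, 3) for images.
#' @param pool integer c(ph, pw); (2, 1) or (2, 2).
#' @param n_filters filters per group (default 8).
#' @param fc_hidden width of the first fully-connected layer (default 64).
#' @param n_classes output classes (default 5).
#' @param dropout dropout probability after the first FC layer (default 0.5).
#' @param seed seed for the He-initialized weights.
#' @return a `swayrate_net` list with `params` (trainable) and `buffers`
#'   (batch-norm running statistics).
#' @export
nn_build <- function(input_shape, groups, kernel = c(3L, 1L),
                     pool = c(2L, 1L), n_filters = 8L, fc_hidden = 64L,
                     n_classes = 5L, dropout = 0.5, seed = 1L) {
  C <- input_shape[1]; H <- input_shape[2]; W <- input_shape[3]
  stopifnot(sort(unlist(groups)) == seq_len(C))
  OH <- H - kernel[1] + 1L; OW <- W - kernel[2] + 1L
  if (OH < 1 || OW < 1) stop_domain("input smaller than the kernel")
  PH <- OH %/% pool[1]; PW <- OW %/% pool[2]
  if (PH < 1 || PW < 1) stop_domain("input too small to pool")
  ftot <- n_filters * length(groups)
  D <- ftot * PH * PW
  params <- with_seed(seed, {
    p <- list()
    for (g in seq_along(groups)) {
      cg <- length(groups[[g]])
      fan_in <- cg * kernel[1] * kernel[2]
      p[[paste0("convW_", g)]] <- array(
        stats::rnorm(n_filters * fan_in, 0, sqrt(2 / fan_in)),
        dim = c(n_filters, cg, kernel[1], kernel[2]))
      p[[paste0("convb_", g)]] <- numeric(n_filters)
    }
    p$bn1_gamma <- rep(1, ftot); p$bn1_beta <- numeric(ftot)
    p$fc1_W <- matrix(stats::rnorm(fc_hidden * D, 0, sqrt(2 / D)), fc_hidden, D)
    p$fc1_b <- numeric(fc_hidden)
    p$bn2_gamma <- rep(1, fc_hidden); p$bn2_beta <- numeric(fc_hidden)
    p$fc2_W <- matrix(stats::rnorm(n_classes * fc_hidden, 0, sqrt(2 / fc_hidden)),
                      n_classes, fc_hidden)
    p$fc2_b <- numeric(n_classes)
    p
  })
  structure(list(
    input_shape = as.integer(input_shape), groups = groups,
    kernel = as.integer(kernel), pool = as.integer(pool),
    n_filters = as.integer(n_filters), fc_hidden = as.integer(fc_hidden),
    n_classes = as.integer(n_classes), dropout = dropout,
    dims = list(OH = OH, OW = OW, PH = PH, PW = PW, ftot = ftot, D = D),
    params = params,
    buffers = list(bn1_mean = numeric(ftot), bn1_var = rep(1, ftot),
                   bn2_mean = numeric(fc_hidden), bn2_var = rep(1, fc_hidden))
  ), class = "swayrate_net")
}

# grouped valid convolution via im2col:
# Y[f, i, j, n] = b[f] + sum_{c,di,dj} W[f,c,di,dj] X[c, i+di-1, j+dj-1, n]
# The per-group column matrix [Cg*kh*kw, OH*OW*N] is cached for the backward
# weight gradient, so inputs are sliced only once per step.
conv_im2col <- function(net, X) {
  d <- net$dims; kh <- net$kernel[1]; kw <- net$kernel[2]
  N <- dim(X)[4]
  lapply(net$groups, function(idx) {
    cg <- length(idx)
    cols <- matrix(0, cg * kh * kw, d$OH * d$OW * N)
    Xg <- X[idx, , , , drop = FALSE]
    r <- 0L
    for (dj in seq_len(kw)) for (di in seq_len(kh)) {
      sl <- Xg[, di:(di + d$OH - 1L), dj:(dj + d$OW - 1L), , drop = FALSE]
      dim(sl) <- c(cg, d$OH * d$OW * N)
      cols[(r + 1L):(r + cg), ] <- sl
      r <- r + cg
    }
    cols
  })
}

conv_forward <- function(net, cols, N) {
  d <- net$dims
  Y <- array(0, c(d$ftot, d$OH, d$OW, N))
  for (g in seq_along(net$groups)) {
    cg <- length(net$groups[[g]])
    Wmat <- net$params[[paste0("convW_", g)]]  # [F, Cg, kh, kw]
    dim(Wmat) <- c(net$n_filters, cg * net$kernel[1] * net$kernel[2])
    rows <- ((g - 1L) * net$n_filters + 1L):(g * net$n_filters)
    Y[rows, , , ] <- Wmat %*% cols[[g]] + net$params[[paste0("convb_", g)]]
  }
  Y
}

conv_backward <- function(net, cols, dY) {
  d <- net$dims
  N <- dim(dY)[4]
  grads <- list()
  for (g in seq_along(net$groups)) {
    cg <- length(net$groups[[g]])
    rows <- ((g - 1L) * net$n_filters + 1L):(g * net$n_filters)
    dYg <- dY[rows, , , , drop = FALSE]
    dim(dYg) <- c(net$n_filters, d$OH * d$OW * N)
    dW <- tcrossprod(dYg, cols[[g]])
    dim(dW) <- c(net$n_filters, cg, net$kernel[1], net$kernel[2])
    grads[[paste0("convW_", g)]] <- dW
    grads[[paste0("convb_", g)]] <- rowSums(dYg)
  }
  grads
}

pool_forward <- function(net, Y) {
  d <- net$dims; ph <- net$pool[1]; pw <- net$pool[2]
  N <- dim(Y)[4]
  offs <- expand.grid(oi = seq_len(ph), oj = seq_len(pw))
  ih <- seq(1L, by = ph, length.out = d$PH)
  iw <- seq(1L, by = pw, length.out = d$PW)
  out <- NULL; idx <- NULL
  for (k in seq_len(nrow(offs))) {
    sl <- Y[, ih + offs$oi[k] - 1L, iw + offs$oj[k] - 1L, , drop = FALSE]
    if (k == 1) { out <- sl; idx <- array(1L, dim(sl)) }
    else { better <- sl > out; out[better] <- sl[better]; idx[better] <- k }
  }
  list(out = out, idx = idx, offs = offs, ih = ih, iw = iw)
}

pool_backward <- function(net, pf, dOut, dimY) {
  # pooling windows are disjoint (stride = size), so each offset's slice of dY
  # can be assigned directly
  dY <- array(0, dimY)
  for (k in seq_len(nrow(pf$offs))) {
    dY[, pf$ih + pf$offs$oi[k] - 1L, pf$iw + pf$offs$oj[k] - 1L, ] <-
      dOut * (pf$idx == k)
  }
  dY
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, training) {
  # x: matrix [features, samples]
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
  } else {
    mu <- run_mean; v <- run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (x - mu) * invstd
  list(y = gamma * xhat + beta, xhat = xhat, invstd = invstd, mu = mu, v = v)
}

bn_backward <- function(bnf, gamma, dy) {
  nb <- ncol(dy)
  dgamma <- rowSums(dy * bnf$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- bnf$invstd * (dxhat - rowMeans(dxhat) - bnf$xhat * rowMeans(dxhat * bnf$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Forward pass
#' @param net a `swayrate_net`.
#' @param X array `[C, H, W, N]`.
#' @param training logical; enables batch statistics and dropout (dropout mask
#'   is drawn from the current RNG stream).
#' @return list with `probs` (`n_classes x N`), `cache` (for backprop), and
#'   updated `buffers` when training.
#' @keywords internal
nn_forward <- function(net, X, training = FALSE) {
  d <- net$dims; N <- dim(X)[4]
  cols <- conv_im2col(net, X)
  conv <- conv_forward(net, cols, N)
  pf <- pool_forward(net, conv)
  relu1 <- pmax(pf$out, 0)
  xm <- relu1; dim(xm) <- c(d$ftot, d$PH * d$PW * N)
  # per-channel batch norm needs channel-major rows: [ftot, PH*PW*N] view of
  # the [ftot, PH, PW, N] array is exactly that (column-major layout)
  bn1 <- bn_forward(xm, net$params$bn1_gamma, net$params$bn1_beta,
                    net$buffers$bn1_mean, net$buffers$bn1_var, training)
  z <- bn1$y; dim(z) <- c(d$ftot, d$PH, d$PW, N); dim(z) <- c(d$D, N)
  a1 <- net$params$fc1_W %*% z + net$params$fc1_b
  bn2 <- bn_forward(a1, net$params$bn2_gamma, net$params$bn2_beta,
                    net$buffers$bn2_mean, net$buffers$bn2_var, training)
  relu2 <- pmax(bn2$y, 0)
  if (training && net$dropout > 0) {
    keep <- 1 - net$dropout
    dmask <- matrix(stats::rbinom(length(relu2), 1, keep) / keep,
                    nrow(relu2), ncol(relu2))
  } else dmask <- 1
  h <- relu2 * dmask
  logits <- net$params$fc2_W %*% h + net$params$fc2_b
  logits <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(logits)
  probs <- e / rep(colSums(e), each = nrow(e))
  buffers <- net$buffers
  if (training) {
    mom <- BN_MOMENTUM
    nb1 <- d$PH * d$PW * N; nb2 <- N
    buffers$bn1_mean <- (1 - mom) * buffers$bn1_mean + mom * bn1$mu
    buffers$bn1_var <- (1 - mom) * buffers$bn1_var +
      mom * bn1$v * nb1 / max(nb1 - 1, 1)
    buffers$bn2_mean <- (1 - mom) * buffers$bn2_mean + mom * bn2$mu
    buffers$bn2_var <- (1 - mom) * buffers$bn2_var +
      mom * bn2$v * nb2 / max(nb2 - 1, 1)
  }
  list(probs = probs,
       cache = list(cols = cols, conv = conv, pf = pf, bn1 = bn1,
                    z = z, bn2 = bn2, dmask = dmask, h = h),
       buffers = buffers)
}

nn_backward <- function(net, fw, y) {
  d <- net$dims; N <- ncol(fw$probs)
  onehot <- matrix(0, net$n_classes, N)
  onehot[cbind(y, seq_len(N))] <- 1
  dlogits <- (fw$probs - onehot) / N
  ca <- fw$cache
  grads <- list(
    fc2_W = tcrossprod(dlogits, ca$h),
    fc2_b = rowSums(dlogits)
  )
  dh <- crossprod(net$params$fc2_W, dlogits)
  drelu2 <- dh * ca$dmask
  drelu2[ca$bn2$y <= 0] <- 0
  b2 <- bn_backward(ca$bn2, net$params$bn2_gamma, drelu2)
  grads$bn2_gamma <- b2$dgamma; grads$bn2_beta <- b2$dbeta
  grads$fc1_W <- tcrossprod(b2$dx, ca$z)
  grads$fc1_b <- rowSums(b2$dx)
  dz <- crossprod(net$params$fc1_W, b2$dx)
  dim(dz) <- c(d$ftot, d$PH * d$PW * N)
  b1 <- bn_backward(ca$bn1, net$params$bn1_gamma, dz)
  grads$bn1_gamma <- b1$dgamma; grads$bn1_beta <- b1$dbeta
  drelu1 <- b1$dx
  dim(drelu1) <- c(d$ftot, d$PH, d$PW, N)
  drelu1[ca$pf$out <= 0] <- 0
  dconv <- pool_backward(net, ca$pf, drelu1, dim(ca$conv))
  c(grads, conv_backward(net, ca$cols, dconv))
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(y, seq_len(ncol(probs)))], 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a network with Adam on cross-entropy, snapshotting the best epoch
#'
#' After every epoch the validation macro-AUROC is evaluated (inference mode);
#' the returned network carries the parameter snapshot with the best
#' validation metric, together with the full per-epoch training log. When the
#' validation labels contain a single class (macro-AUROC undefined), the
#' negative validation loss is used as the selection metric instead.
#'
#' @param net a `swayrate_net` from [nn_build()].
#' @param X,y training inputs `[C, H, W, N]` and integer labels 1..n_classes.
#' @param Xval,yval validation inputs and labels (never augmented).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs training budget (default 2000).
#' @param weight_decay L2 coefficient added to gradients (default 0).
#' @param seed seed controlling shuffling, dropout and initialization order.
#' @return the trained net with elements `log` (data.frame epoch/loss/val
#'   metric) and `best_epoch`.
#' @export
nn_train <- function(net, X, y, Xval, yval, learning_rate = 1e-4,
                     batch_size = 32L, max_epochs = 2000L, weight_decay = 0,
                     seed = 1L) {
  N <- dim(X)[4]
  if (N < 1) stop_domain("empty training set")
  state <- adam_init(net$params)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_metric = numeric())
  best <- list(metric = -Inf, params = net$params, buffers = net$buffers,
               epoch = 0L)
  val_single_class <- length(unique(yval)) < 2
  with_seed(seed, {
    for (ep in seq_len(max_epochs)) {
      perm <- sample.int(N)
      losses <- numeric()
      for (b in seq(1L, N, by = batch_size)) {
        take <- perm[b:min(b + batch_size - 1L, N)]
        Xb <- X[, , , take, drop = FALSE]
        fw <- nn_forward(net, Xb, training = TRUE)
        net$buffers <- fw$buffers
        loss <- cross_entropy(fw$probs, y[take])
        if (!is.finite(loss))
          stop_domain("non-finite training loss at epoch %d", ep)
        losses <- c(losses, loss)
        grads <- nn_backward(net, fw, y[take])
        st <- adam_step(net$params, grads, state, learning_rate, weight_decay)
        net$params <- st$params; state <- st$state
      }
      valfw <- nn_forward(net, Xval, training = FALSE)
      metric <- if (val_single_class) -cross_entropy(valfw$probs, yval)
                else macro_auroc(t(valfw$probs), yval)
      log[ep, ] <- list(ep, mean(losses), metric)
      if (metric > best$metric) {
        best <- list(metric = metric, params = net$params,
                     buffers = net$buffers, epoch = ep)
      }
    }
  })
  net$params <- best$params
  net$buffers <- best$buffers
  net$log <- log
  net$best_epoch <- best$epoch
  net
}

#' Predict class probabilities with a trained network
#' @param net a trained `swayrate_net`.
#' @param X array `[C, H, W, N]`.
#' @return matrix `N x n_classes`; rows sum to 1 (dropout off, batch norm in
#'   inference mode).
#' @export
nn_predict <- function(net, X) {
  if (!identical(dim(X)[1:3], net$input_shape))
    stop_domain("input shape (%s) does not match the network (%s)",
                paste(dim(X)[1:3], collapse = "x"),
                paste(net$input_shape, collapse = "x"))
  t(nn_forward(net, X, training = FALSE)$probs)
}
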