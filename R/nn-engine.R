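# Minimal dense/recurrent/convolutional network engine: exact forward and
# backward passes for the three architecture specs, trained with Adam on
# categorical cross-entropy. Written against base matrix algebra so the
# instantiated weights can be audited against the closed-form parameter
# counts. Conventions follow the usual deep-learning defaults: LSTM gates
# ordered (input, forget, cell, output) with forget bias 1, Glorot-uniform
# kernels, orthogonal recurrent matrices, He-uniform convolution kernels,
# batch-norm epsilon 1e-3 with running statistics at decay 0.9 (so
# the inference-time statistics adapt within a single short epoch), Adam
# epsilon 1e-7.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

he_uniform <- function(nr, nc, fan_in) {
  l <- sqrt(6 / fan_in)
  matrix(runif(nr * nc, -l, l), nr, nc)
}

orthogonal_init <- function(u, gates = 4L) {
  # per-gate orthogonal u x u blocks
  do.call(cbind, lapply(seq_len(gates), function(g) {
    qr.Q(qr(matrix(rnorm(u * u), u, u)))
  }))
}

init_lstm <- function(units, input_dim = 1L) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1   # forget-gate bias
  list(W = glorot_uniform(input_dim, 4 * units),
       U = orthogonal_init(units),
       b = b)
}

init_dense <- function(in_dim, out_dim) {
  list(W = glorot_uniform(in_dim, out_dim), b = numeric(out_dim))
}

init_conv <- function(kernel, in_ch, filters) {
  K <- array(0, dim = c(kernel, in_ch, filters))
  for (j in seq_len(kernel)) K[j, , ] <- he_uniform(in_ch, filters, kernel * in_ch)
  list(K = K, b = numeric(filters))
}

init_bn <- function(channels) {
  list(gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels))
}

nn_init <- function(spec, seed = 1L) {
  with_seed(seed, {
    p <- switch(spec$name,
      lstm_sequential = {
        u <- spec$layers$config[[2]]$units
        list(lstm = init_lstm(u),
             dense_1 = init_dense(u, 128L),
             dense_2 = init_dense(128L, spec$n_classes))
      },
      bilstm = {
        u <- spec$layers$config[[2]]$units
        list(fwd = init_lstm(u), bwd = init_lstm(u),
             dense_1 = init_dense(2L * u, 256L),
             dense_2 = init_dense(256L, spec$n_classes))
      },
      lstm_fcn = {
        L <- spec$input_length
        u <- spec$layers$config[[which(spec$layers$layer == "lstm")]]$units
        list(conv_1 = init_conv(8L, L, 128L),  bn_1 = init_bn(128L),
             conv_2 = init_conv(5L, 128L, 256L), bn_2 = init_bn(256L),
             conv_3 = init_conv(3L, 256L, 128L), bn_3 = init_bn(128L),
             lstm = init_lstm(u),
             dense = init_dense(u + 128L, spec$n_classes))
      },
      stop_ecg(sprintf("No backend for architecture '%s'.", spec$name),
               class = "ecgbeat_validation_error"))
    structure(list(spec = spec, params = p), class = "nn_net")
  })
}

# Total number of instantiated scalars, including batch-norm running
# statistics; must agree with the closed-form parameter_count().
nn_count_params <- function(net) {
  sum(unlist(lapply(net$params, function(layer) vapply(layer, length, 1L))))
}

add_bias <- function(Z, b) sweep(Z, 2, b, "+")

lstm_forward <- function(X, p, keep_cache = TRUE) {
  B <- nrow(X); Tn <- ncol(X); u <- length(p$b) %/% 4L
  h <- matrix(0, B, u); cc <- matrix(0, B, u)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  gi <- seq_len(u); gf <- u + gi; gg <- 2L * u + gi; go <- 3L * u + gi
  for (t in seq_len(Tn)) {
    xt <- X[, t, drop = FALSE]
    z <- add_bias(xt %*% p$W + h %*% p$U, p$b)
    i <- sigmoid(z[, gi, drop = FALSE]); f <- sigmoid(z[, gf, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE]);    o <- sigmoid(z[, go, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    h_prev <- h
    h <- o * tanh(cc)
    if (keep_cache) {
      cache[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                         i = i, f = f, g = g, o = o, c = cc)
    }
  }
  list(h = h, cache = cache)
}

lstm_backward <- function(dh, p, cache) {
  Tn <- length(cache); u <- ncol(dh)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dc <- dh * 0
  for (t in rev(seq_len(Tn))) {
    s <- cache[[t]]
    tc <- tanh(s$c)
    do <- dh * tc
    dct <- dh * s$o * (1 - tc^2) + dc
    di <- dct * s$g; dg <- dct * s$i; df <- dct * s$c_prev
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dW <- dW + crossprod(s$xt, dz)
    dU <- dU + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(p$U)
    dc <- dct * s$f
  }
  list(W = dW, U = dU, b = db)
}

dense_forward <- function(X, p) add_bias(X %*% p$W, p$b)

dense_backward <- function(dY, X, p) {
  list(grads = list(W = crossprod(X, dY), b = colSums(dY)),
       dX = dY %*% t(p$W))
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# 'same'-padded 1-D convolution on a length-1 sequence: only the kernel tap
# aligned with the single valid position touches data, so the operation is a
# matrix product with that kernel slice. Gradients for the padded taps are
# exactly zero.
conv_tap <- function(kernel) (kernel - 1L) %/% 2L + 1L

conv1d_forward <- function(X, p) {
  tap <- conv_tap(dim(p$K)[1])
  add_bias(X %*% p$K[tap, , ], p$b)
}

conv1d_backward <- function(dY, X, p) {
  tap <- conv_tap(dim(p$K)[1])
  dK <- p$K * 0
  dK[tap, , ] <- crossprod(X, dY)
  list(grads = list(K = dK, b = colSums(dY)),
       dX = dY %*% t(p$K[tap, , ]))
}

bn_forward <- function(X, p, training, momentum = 0.9, eps = 1e-3) {
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    p$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
    p$run_var <- momentum * p$run_var + (1 - momentum) * va
  } else {
    mu <- p$run_mean; va <- p$run_var
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(X, 2, mu, "-"), 2, inv_std, "*")
  Y <- add_bias(sweep(xhat, 2, p$gamma, "*"), p$beta)
  list(Y = Y, p = p, cache = list(xhat = xhat, inv_std = inv_std))
}

bn_backward <- function(dY, p, cache) {
  B <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dX <- sweep(dY * B - outer(rep(1, B), dbeta) - cache$xhat *
                outer(rep(1, B), dgamma), 2,
              p$gamma * cache$inv_std / B, "*")
  list(grads = list(gamma = dgamma, beta = dbeta,
                    run_mean = p$run_mean * 0, run_var = p$run_var * 0),
       dX = dX)
}

dropout_mask <- function(nr, nc, rate) {
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

nn_forward <- function(net, X, training = FALSE, dropout_dense = 0) {
  p <- net$params
  switch(net$spec$name,
    lstm_sequential = {
      lf <- lstm_forward(X, p$lstm, keep_cache = training)
      a1 <- tanh(dense_forward(lf$h, p$dense_1))
      mask <- NULL
      a1d <- a1
      if (training && dropout_dense > 0) {
        mask <- dropout_mask(nrow(a1), ncol(a1), dropout_dense)
        a1d <- a1 * mask
      }
      logits <- dense_forward(a1d, p$dense_2)
      list(prob = softmax(logits), net = net,
           cache = list(lf = lf, a1 = a1, a1d = a1d, mask = mask))
    },
    bilstm = {
      lf <- lstm_forward(X, p$fwd, keep_cache = training)
      lb <- lstm_forward(X[, rev(seq_len(ncol(X))), drop = FALSE], p$bwd,
                         keep_cache = training)
      h <- cbind(lf$h, lb$h)
      a1 <- tanh(dense_forward(h, p$dense_1))
      mask <- NULL
      a1d <- a1
      if (training && dropout_dense > 0) {
        mask <- dropout_mask(nrow(a1), ncol(a1), dropout_dense)
        a1d <- a1 * mask
      }
      logits <- dense_forward(a1d, p$dense_2)
      list(prob = softmax(logits), net = net,
           cache = list(lf = lf, lb = lb, h = h, a1 = a1, a1d = a1d,
                        mask = mask))
    },
    lstm_fcn = {
      rate <- net$spec$layers$config[[which(net$spec$layers$layer == "dropout")]]$rate
      z1 <- conv1d_forward(X, p$conv_1)
      b1 <- bn_forward(z1, p$bn_1, training); net$params$bn_1 <- b1$p
      r1 <- pmax(b1$Y, 0)
      z2 <- conv1d_forward(r1, p$conv_2)
      b2 <- bn_forward(z2, p$bn_2, training); net$params$bn_2 <- b2$p
      r2 <- pmax(b2$Y, 0)
      z3 <- conv1d_forward(r2, p$conv_3)
      b3 <- bn_forward(z3, p$bn_3, training); net$params$bn_3 <- b3$p
      r3 <- pmax(b3$Y, 0)            # global average pool over length 1 = identity
      lf <- lstm_forward(X, p$lstm, keep_cache = training)
      mask <- NULL
      hd <- lf$h
      if (training && rate > 0) {
        mask <- dropout_mask(nrow(hd), ncol(hd), rate)
        hd <- hd * mask
      }
      z <- cbind(hd, r3)
      logits <- dense_forward(z, p$dense)
      list(prob = softmax(logits), net = net,
           cache = list(X = X, b1 = b1, r1 = r1, b2 = b2, r2 = r2, b3 = b3,
                        r3 = r3, lf = lf, mask = mask, z = z))
    })
}

# Gradient of mean categorical cross-entropy w.r.t. all parameters.
nn_backward <- function(net, X, Y, fwd) {
  p <- net$params
  B <- nrow(X)
  dlogits <- (fwd$prob - Y) / B
  cc <- fwd$cache
  switch(net$spec$name,
    lstm_sequential = {
      d2 <- dense_backward(dlogits, cc$a1d, p$dense_2)
      da1 <- d2$dX
      if (!is.null(cc$mask)) da1 <- da1 * cc$mask
      dz1 <- da1 * (1 - cc$a1^2)
      d1 <- dense_backward(dz1, cc$lf$h, p$dense_1)
      glstm <- lstm_backward(d1$dX, p$lstm, cc$lf$cache)
      list(lstm = glstm, dense_1 = d1$grads, dense_2 = d2$grads)
    },
    bilstm = {
      d2 <- dense_backward(dlogits, cc$a1d, p$dense_2)
      da1 <- d2$dX
      if (!is.null(cc$mask)) da1 <- da1 * cc$mask
      dz1 <- da1 * (1 - cc$a1^2)
      d1 <- dense_backward(dz1, cc$h, p$dense_1)
      u <- ncol(cc$lf$h)
      gf <- lstm_backward(d1$dX[, seq_len(u), drop = FALSE], p$fwd, cc$lf$cache)
      gb <- lstm_backward(d1$dX[, u + seq_len(u), drop = FALSE], p$bwd,
                          cc$lb$cache)
      list(fwd = gf, bwd = gb, dense_1 = d1$grads, dense_2 = d2$grads)
    },
    lstm_fcn = {
      dd <- dense_backward(dlogits, cc$z, p$dense)
      u <- ncol(cc$lf$h)
      dhd <- dd$dX[, seq_len(u), drop = FALSE]
      dr3 <- dd$dX[, u + seq_len(ncol(cc$r3)), drop = FALSE]
      if (!is.null(cc$mask)) dhd <- dhd * cc$mask
      glstm <- lstm_backward(dhd, p$lstm, cc$lf$cache)
      db3 <- bn_backward(dr3 * (cc$b3$Y > 0), p$bn_3, cc$b3$cache)
      dc3 <- conv1d_backward(db3$dX, cc$r2, p$conv_3)
      db2 <- bn_backward(dc3$dX * (cc$b2$Y > 0), p$bn_2, cc$b2$cache)
      dc2 <- conv1d_backward(db2$dX, cc$r1, p$conv_2)
      db1 <- bn_backward(dc2$dX * (cc$b1$Y > 0), p$bn_1, cc$b1$cache)
      dc1 <- conv1d_backward(db1$dX, cc$X, p$conv_1)
      list(conv_1 = dc1$grads, bn_1 = db1$grads,
           conv_2 = dc2$grads, bn_2 = db2$grads,
           conv_3 = dc3$grads, bn_3 = db3$grads,
           lstm = glstm, dense = dd$grads)
    })
}

adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# Batch-norm running statistics are carried on the parameter list but are
# not Adam-updated; their "gradients" are zeroed in bn_backward and Adam with
# zero gradient leaves them at the value written during the forward pass...
# except Adam momentum would still decay them, so they are restored after
# each step.
nn_fit <- function(spec, X, Y, config) {
  net <- nn_init(spec, config$seed)
  state <- adam_init(net$params)
  n <- nrow(X)
  history <- list()
  best_loss <- Inf; stale <- 0L
  bn_names <- grep("^bn_", names(net$params), value = TRUE)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c(); accs <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        fwd <- nn_forward(net, Xb, training = TRUE,
                          dropout_dense = config$dropout)
        net <- fwd$net   # batch-norm running stats advanced
        grads <- nn_backward(net, Xb, Yb, fwd)
        run_stats <- lapply(bn_names, function(nm) {
          net$params[[nm]][c("run_mean", "run_var")]
        })
        upd <- adam_step(net$params, grads, state, config$learning_rate)
        net$params <- upd$params; state <- upd$state
        for (j in seq_along(bn_names)) {
          net$params[[bn_names[j]]][c("run_mean", "run_var")] <- run_stats[[j]]
        }
        eps <- 1e-12
        losses <- c(losses, -mean(log(rowSums(fwd$prob * Yb) + eps)))
        accs <- c(accs, mean(max.col(fwd$prob) == max.col(Yb)))
      }
      history[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
                                 accuracy = mean(accs))
      if (mean(losses) < best_loss - 1e-5) {
        best_loss <- mean(losses); stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$early_stopping_patience) break
      }
    }
  })
  list(net = net, history = dplyr::bind_rows(history))
}

nn_predict_proba <- function(net, X, batch_size = 1024L) {
  out <- matrix(0, nrow(X), net$spec$n_classes)
  for (start in seq(1, nrow(X), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(X))
    out[idx, ] <- nn_forward(net, X[idx, , drop = FALSE],
                             training = FALSE)$prob
  }
  out
}
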