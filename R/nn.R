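# Neural-network engine for per-nucleotide segmentation.
#
# Layers operate on L x C matrices (rows = positions, columns = channels).
# Everything is plain matrix algebra: convolutions go through an im2col
# expansion, the LSTM loops over positions with the input projection hoisted
# out of the loop, dense layers are position-wise. Backpropagation is
# hand-derived per layer and verified against finite differences in the
# test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter construction ----------------------------------------------

init_layers <- function(spec, n_channels) {
  layers <- list()
  cin <- n_channels
  for (b in spec$blocks) {
    if (b$type == "conv") {
      for (j in seq_len(b$n_layers)) {
        k <- b$kernel_size[j]; cout <- b$n_kernels[j]
        layers[[length(layers) + 1]] <- list(
          type = "conv", k = k, cin = cin, cout = cout,
          relu = j < b$n_layers,
          par = list(
            W = matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                       nrow = k * cin, ncol = cout),
            b = numeric(cout)
          )
        )
        cin <- cout
      }
      if (b$channel_pool) {
        layers[[length(layers) + 1]] <- list(type = "chanpool", par = list())
        cin <- 1
      }
    } else if (b$type == "recurrent") {
      for (j in seq_len(b$n_layers)) {
        H <- b$hidden_size
        s <- 1 / sqrt(H)
        mk <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
        bias <- numeric(4 * H)
        bias[(H + 1):(2 * H)] <- 1  # forget-gate bias
        par <- list(Wx_f = mk(cin, 4 * H), Wh_f = mk(H, 4 * H), b_f = bias)
        if (b$bidirectional) {
          par$Wx_b <- mk(cin, 4 * H); par$Wh_b <- mk(H, 4 * H); par$b_b <- bias
        }
        layers[[length(layers) + 1]] <- list(
          type = "lstm", H = H, cin = cin, bidirectional = b$bidirectional,
          par = par
        )
        cin <- H * (1 + b$bidirectional)
      }
    } else if (b$type == "dense") {
      for (j in seq_len(b$n_layers)) {
        cout <- if (j == b$n_layers) 2L else b$hidden_size
        layers[[length(layers) + 1]] <- list(
          type = "dense", cin = cin, cout = cout,
          relu = j < b$n_layers, dropout = b$dropout,
          par = list(
            W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
            b = numeric(cout)
          )
        )
        cin <- cout
      }
    }
  }
  layers
}

# ---- conv -----------------------------------------------------------------

im2col <- function(X, k) {
  L <- nrow(X); C <- ncol(X)
  pad <- (k - 1) / 2
  Xp <- rbind(matrix(0, pad, C), X, matrix(0, pad, C))
  Z <- matrix(0, L, k * C)
  for (j in seq_len(k)) {
    Z[, ((j - 1) * C + 1):(j * C)] <- Xp[j:(j + L - 1), , drop = FALSE]
  }
  Z
}

conv_forward <- function(layer, X) {
  Z <- im2col(X, layer$k)
  Y <- Z %*% layer$par$W
  Y <- sweep(Y, 2, layer$par$b, "+")
  out <- if (layer$relu) pmax(Y, 0) else Y
  list(out = out, cache = list(Z = Z, Y = Y, L = nrow(X), C = ncol(X)))
}

conv_backward <- function(layer, cache, dOut) {
  dY <- if (layer$relu) dOut * (cache$Y > 0) else dOut
  grads <- list(W = crossprod(cache$Z, dY), b = colSums(dY))
  dZ <- tcrossprod(dY, layer$par$W)
  L <- cache$L; C <- cache$C; k <- layer$k
  pad <- (k - 1) / 2
  dXp <- matrix(0, L + 2 * pad, C)
  for (j in seq_len(k)) {
    dXp[j:(j + L - 1), ] <- dXp[j:(j + L - 1), , drop = FALSE] +
      dZ[, ((j - 1) * C + 1):(j * C), drop = FALSE]
  }
  list(dX = dXp[(pad + 1):(pad + L), , drop = FALSE], grads = grads)
}

# ---- channel max-pool -----------------------------------------------------

chanpool_forward <- function(layer, X) {
  idx <- max.col(X, ties.method = "first")
  out <- matrix(X[cbind(seq_len(nrow(X)), idx)], ncol = 1)
  list(out = out, cache = list(idx = idx, C = ncol(X)))
}

chanpool_backward <- function(layer, cache, dOut) {
  dX <- matrix(0, length(cache$idx), cache$C)
  dX[cbind(seq_along(cache$idx), cache$idx)] <- dOut[, 1]
  list(dX = dX, grads = list())
}

# ---- LSTM -----------------------------------------------------------------

lstm_dir_forward <- function(X, Wx, Wh, b) {
  L <- nrow(X); H <- ncol(Wh)
  H4 <- ncol(Wx)
  Hn <- H4 / 4
  G <- X %*% Wx
  I <- matrix(0, L, Hn); Fg <- matrix(0, L, Hn)
  Gg <- matrix(0, L, Hn); O <- matrix(0, L, Hn)
  Cc <- matrix(0, L, Hn); Hh <- matrix(0, L, Hn)
  h <- numeric(Hn); cc <- numeric(Hn)
  i1 <- 1:Hn; i2 <- (Hn + 1):(2 * Hn); i3 <- (2 * Hn + 1):(3 * Hn); i4 <- (3 * Hn + 1):(4 * Hn)
  for (t in seq_len(L)) {
    a <- G[t, ] + drop(h %*% Wh) + b
    it <- sigmoid(a[i1]); ft <- sigmoid(a[i2])
    gt <- tanh(a[i3]); ot <- sigmoid(a[i4])
    cc <- ft * cc + it * gt
    h <- ot * tanh(cc)
    I[t, ] <- it; Fg[t, ] <- ft; Gg[t, ] <- gt; O[t, ] <- ot
    Cc[t, ] <- cc; Hh[t, ] <- h
  }
  list(H = Hh, gates = list(I = I, Fg = Fg, Gg = Gg, O = O, Cc = Cc))
}

lstm_dir_backward <- function(X, Wx, Wh, fwd, dH) {
  L <- nrow(X); Hn <- ncol(fwd$H)
  g <- fwd$gates
  dA <- matrix(0, L, 4 * Hn)
  dh_next <- numeric(Hn); dc_next <- numeric(Hn)
  Cprev <- rbind(numeric(Hn), g$Cc[-L, , drop = FALSE])
  for (t in L:1) {
    dh <- dH[t, ] + dh_next
    tc <- tanh(g$Cc[t, ])
    do <- dh * tc
    dc <- dc_next + dh * g$O[t, ] * (1 - tc^2)
    di <- dc * g$Gg[t, ]
    dg <- dc * g$I[t, ]
    df <- dc * Cprev[t, ]
    dc_next <- dc * g$Fg[t, ]
    da <- c(di * g$I[t, ] * (1 - g$I[t, ]),
            df * g$Fg[t, ] * (1 - g$Fg[t, ]),
            dg * (1 - g$Gg[t, ]^2),
            do * g$O[t, ] * (1 - g$O[t, ]))
    dA[t, ] <- da
    dh_next <- drop(da %*% t(Wh))
  }
  Hprev <- rbind(numeric(Hn), fwd$H[-L, , drop = FALSE])
  list(
    dX = tcrossprod(dA, Wx),
    dWx = crossprod(X, dA),
    dWh = crossprod(Hprev, dA),
    db = colSums(dA)
  )
}

lstm_forward <- function(layer, X) {
  fwd <- lstm_dir_forward(X, layer$par$Wx_f, layer$par$Wh_f, layer$par$b_f)
  if (!layer$bidirectional) {
    return(list(out = fwd$H, cache = list(fwd = fwd)))
  }
  L <- nrow(X)
  Xr <- X[L:1, , drop = FALSE]
  bwd <- lstm_dir_forward(Xr, layer$par$Wx_b, layer$par$Wh_b, layer$par$b_b)
  out <- cbind(fwd$H, bwd$H[L:1, , drop = FALSE])
  list(out = out, cache = list(fwd = fwd, bwd = bwd, Xr = Xr))
}

lstm_backward <- function(layer, cache, dOut, X) {
  H <- layer$H
  bf <- lstm_dir_backward(X, layer$par$Wx_f, layer$par$Wh_f, cache$fwd,
                          dOut[, 1:H, drop = FALSE])
  grads <- list(Wx_f = bf$dWx, Wh_f = bf$dWh, b_f = bf$db)
  dX <- bf$dX
  if (layer$bidirectional) {
    L <- nrow(X)
    dHr <- dOut[L:1, (H + 1):(2 * H), drop = FALSE]
    bb <- lstm_dir_backward(cache$Xr, layer$par$Wx_b, layer$par$Wh_b, cache$bwd, dHr)
    grads$Wx_b <- bb$dWx; grads$Wh_b <- bb$dWh; grads$b_b <- bb$db
    dX <- dX + bb$dX[L:1, , drop = FALSE]
  }
  list(dX = dX, grads = grads)
}

# ---- dense ----------------------------------------------------------------

dense_forward <- function(layer, X, train) {
  mask <- NULL
  Xd <- X
  if (train && layer$dropout > 0) {
    mask <- matrix(
      (stats::runif(length(X)) >= layer$dropout) / (1 - layer$dropout),
      nrow(X), ncol(X)
    )
    Xd <- X * mask
  }
  Y <- Xd %*% layer$par$W
  Y <- sweep(Y, 2, layer$par$b, "+")
  out <- if (layer$relu) pmax(Y, 0) else Y
  list(out = out, cache = list(Xd = Xd, Y = Y, mask = mask))
}

dense_backward <- function(layer, cache, dOut) {
  dY <- if (layer$relu) dOut * (cache$Y > 0) else dOut
  grads <- list(W = crossprod(cache$Xd, dY), b = colSums(dY))
  dX <- tcrossprod(dY, layer$par$W)
  if (!is.null(cache$mask)) dX <- dX * cache$mask
  list(dX = dX, grads = grads)
}

# ---- network --------------------------------------------------------------

nn_forward <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  inputs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    inputs[[i]] <- X
    r <- switch(layer$type,
      conv = conv_forward(layer, X),
      chanpool = chanpool_forward(layer, X),
      lstm = lstm_forward(layer, X),
      dense = dense_forward(layer, X, train)
    )
    caches[[i]] <- r$cache
    X <- r$out
  }
  list(logits = X, caches = caches, inputs = inputs)
}

nn_backward <- function(layers, fwd, dLogits) {
  grads <- vector("list", length(layers))
  dX <- dLogits
  for (i in rev(seq_along(layers))) {
    layer <- layers[[i]]
    r <- switch(layer$type,
      conv = conv_backward(layer, fwd$caches[[i]], dX),
      chanpool = chanpool_backward(layer, fwd$caches[[i]], dX),
      lstm = lstm_backward(layer, fwd$caches[[i]], dX, fwd$inputs[[i]]),
      dense = dense_backward(layer, fwd$caches[[i]], dX)
    )
    grads[[i]] <- r$grads
    dX <- r$dX
  }
  list(grads = grads, dInput = dX)
}

softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

nn_probs <- function(layers, X) {
  softmax_rows(nn_forward(layers, X, train = FALSE)$logits)[, 2]
}

# Cross-entropy over the two output units; returns loss and dLoss/dLogits.
ce_loss <- function(logits, y) {
  P <- softmax_rows(logits)
  L <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(ifelse(y == 1, log(P[, 2] + eps), log(P[, 1] + eps)))
  dLogits <- (P - cbind(1 - y, y)) / L
  list(loss = loss, dLogits = dLogits)
}

# ---- optimiser ------------------------------------------------------------

rmsprop_init <- function(layers) {
  lapply(layers, function(l) lapply(l$par, function(p) p * 0))
}

# RMSprop update with optional proximal L1 (soft-thresholding after the
# gradient step, scaled like the step itself). The proximal form drives
# unnecessary weights to exact zeros, which the feature-pruning step relies
# on; biases are never penalised. `l1_first` applies to the first
# parameterised layer's weights, `l1_rest` to the remaining layers.
rmsprop_step <- function(layers, grads, cache, lr, rho = 0.9, eps = 1e-8,
                         l1_first = 0, l1_rest = 0) {
  first_seen <- FALSE
  for (i in seq_along(layers)) {
    pen <- l1_rest
    if (length(layers[[i]]$par) && !first_seen) {
      pen <- l1_first
      first_seen <- TRUE
    }
    for (nm in names(layers[[i]]$par)) {
      g <- grads[[i]][[nm]]
      cache[[i]][[nm]] <- rho * cache[[i]][[nm]] + (1 - rho) * g^2
      step_scale <- lr / (sqrt(cache[[i]][[nm]]) + eps)
      w <- layers[[i]]$par[[nm]] - step_scale * g
      if (pen > 0 && !startsWith(nm, "b")) {
        thr <- pen * step_scale
        w <- sign(w) * pmax(abs(w) - thr, 0)
      }
      layers[[i]]$par[[nm]] <- w
    }
  }
  list(layers = layers, cache = cache)
}

zero_grads <- function(layers) {
  lapply(layers, function(l) lapply(l$par, function(p) p * 0))
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

scale_grads <- function(a, s) {
  lapply(a, function(l) lapply(l, function(g) g * s))
}

l1_penalty_value <- function(layers, l1_first, l1_rest) {
  tot <- 0; first_seen <- FALSE
  for (l in layers) {
    pen <- l1_rest
    if (l$type %in% c("conv", "dense", "lstm") && !first_seen) {
      pen <- l1_first; first_seen <- TRUE
    }
    for (nm in names(l$par)) {
      if (startsWith(nm, "b")) next
      tot <- tot + pen * sum(abs(l$par[[nm]]))
    }
  }
  tot
}
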