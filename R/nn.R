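# Minimal neural-network engine: 1-D convolutions, residual blocks,
# layer norm, multi-head self-attention, nearest-neighbour upsampling and
# dense heads, with explicit backpropagation and an Adam optimizer.
# Batches are arrays of dim (N, L, C); dense heads operate on (N, C)
# matrices. Everything is plain R matrix algebra so training is exactly
# reproducible for a fixed seed.

mat3 <- function(x) matrix(x, dim(x)[1L] * dim(x)[2L], dim(x)[3L])
arr3 <- function(m, n, l) array(m, c(n, l, ncol(m)))

glorot <- function(fan_in, fan_out, dims) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fan_in + fan_out)), dims)
}

nn_conv1d <- function(in_ch, out_ch, kernel = 7L) {
  list(type = "conv", kernel = as.integer(kernel),
       W = glorot(in_ch * kernel, out_ch, c(kernel, in_ch, out_ch)),
       b = numeric(out_ch))
}
nn_relu <- function() list(type = "relu")
nn_maxpool <- function(m = 2L) list(type = "maxpool", m = as.integer(m))
nn_upsample <- function(m = 2L) list(type = "upsample", m = as.integer(m))
# sub-pixel upsampling: (N, L, C) -> (N, L*m, C/m), channel blocks becoming
# intra-block positions, so sub-token phase is directly representable
nn_subpixel <- function(m = 2L) list(type = "subpixel", m = as.integer(m))
nn_layernorm <- function(dim) list(type = "layernorm", gamma = rep(1, dim),
                                   beta = numeric(dim))
nn_posenc <- function() list(type = "posenc")
nn_meanpool <- function() list(type = "meanpool")
nn_dense <- function(in_dim, out_dim) {
  list(type = "dense", W = glorot(in_dim, out_dim, c(in_dim, out_dim)),
       b = numeric(out_dim))
}
nn_mha <- function(d_model, heads = 4L) {
  stopifnot(d_model %% heads == 0L)
  list(type = "mha", heads = as.integer(heads), d = d_model,
       Wq = glorot(d_model, d_model, c(d_model, d_model)),
       Wk = glorot(d_model, d_model, c(d_model, d_model)),
       Wv = glorot(d_model, d_model, c(d_model, d_model)),
       Wo = glorot(d_model, d_model, c(d_model, d_model)))
}
# out = x + sub(x): pre-norm residual wrapper around a sub-sequence.
nn_residual <- function(layers) list(type = "residual", layers = layers)

nn_transformer_block <- function(d_model, heads = 4L, d_ff = 4L * d_model) {
  list(nn_residual(list(nn_layernorm(d_model), nn_mha(d_model, heads))),
       nn_residual(list(nn_layernorm(d_model), nn_conv1d(d_model, d_ff, 1L),
                        nn_relu(), nn_conv1d(d_ff, d_model, 1L))))
}

sinusoidal_pe <- function(L, D) {
  pos <- seq_len(L) - 1L
  pe <- matrix(0, L, D)
  for (i in seq_len(ceiling(D / 2))) {
    freq <- 1 / 10000^(2 * (i - 1) / D)
    pe[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= D) pe[, 2L * i] <- cos(pos * freq)
  }
  pe
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      K <- layer$kernel
      n <- dim(x)[1L]; L <- dim(x)[2L]; cin <- dim(x)[3L]
      p <- (K - 1L) %/% 2L
      xp <- array(0, c(n, L + K - 1L, cin))
      xp[, p + seq_len(L), ] <- x
      y <- matrix(0, n * L, dim(layer$W)[3L])
      slices <- vector("list", K)
      for (k in seq_len(K)) {
        slices[[k]] <- mat3(xp[, k:(k + L - 1L), , drop = FALSE])
        Wk <- matrix(layer$W[k, , ], dim(layer$W)[2L], dim(layer$W)[3L])
        y <- y + slices[[k]] %*% Wk
      }
      y <- sweep(y, 2L, layer$b, "+")
      list(out = arr3(y, n, L), cache = list(slices = slices, n = n, L = L,
                                             cin = cin, p = p))
    },
    relu = list(out = pmax(x, 0), cache = x > 0),
    maxpool = {
      m <- layer$m
      n <- dim(x)[1L]; L <- dim(x)[2L]; C <- dim(x)[3L]
      Lo <- L %/% m
      x <- x[, seq_len(Lo * m), , drop = FALSE]
      best <- x[, seq(1L, Lo * m, m), , drop = FALSE]
      which_k <- array(1L, c(n, Lo, C))
      for (k in 2:m) {
        cand <- x[, seq(k, Lo * m, m), , drop = FALSE]
        gt <- cand > best
        best[gt] <- cand[gt]
        which_k[gt] <- k
      }
      list(out = best, cache = list(which_k = which_k, m = m, L = L))
    },
    upsample = {
      m <- layer$m
      n <- dim(x)[1L]; L <- dim(x)[2L]
      idx <- rep(seq_len(L), each = m)
      list(out = x[, idx, , drop = FALSE], cache = list(m = m, L = L))
    },
    subpixel = {
      m <- layer$m
      n <- dim(x)[1L]; L <- dim(x)[2L]; C <- dim(x)[3L]
      stopifnot(C %% m == 0L)
      co <- C %/% m
      y <- array(0, c(n, L * m, co))
      for (k in seq_len(m))
        y[, seq(k, L * m, m), ] <- x[, , (k - 1L) * co + seq_len(co),
                                     drop = FALSE]
      list(out = y, cache = list(m = m, L = L, co = co))
    },
    layernorm = {
      mu <- apply(x, c(1L, 2L), mean)
      cen <- x - as.vector(mu)
      v <- apply(cen^2, c(1L, 2L), mean)
      inv <- 1 / sqrt(as.vector(v) + 1e-5)
      xhat <- cen * inv
      y <- sweep(sweep(xhat, 3L, layer$gamma, "*"), 3L, layer$beta, "+")
      list(out = y, cache = list(xhat = xhat, inv = inv))
    },
    posenc = {
      pe <- sinusoidal_pe(dim(x)[2L], dim(x)[3L])
      y <- x + rep(pe, each = dim(x)[1L])
      list(out = y, cache = NULL)
    },
    meanpool = {
      L <- dim(x)[2L]
      list(out = apply(x, c(1L, 3L), mean), cache = list(L = L, n = dim(x)[1L],
                                                         C = dim(x)[3L]))
    },
    dense = list(out = sweep(x %*% layer$W, 2L, layer$b, "+"), cache = x),
    mha = mha_forward(layer, x),
    residual = {
      sub <- seq_forward(layer$layers, x)
      list(out = x + sub$out, cache = sub$caches)
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      K <- layer$kernel; n <- cache$n; L <- cache$L
      dy <- mat3(dout)
      dW <- array(0, dim(layer$W)); db <- colSums(dy)
      dxp <- array(0, c(n, L + K - 1L, cache$cin))
      for (k in seq_len(K)) {
        Wk <- matrix(layer$W[k, , ], dim(layer$W)[2L], dim(layer$W)[3L])
        dW[k, , ] <- crossprod(cache$slices[[k]], dy)
        dxp[, k:(k + L - 1L), ] <- dxp[, k:(k + L - 1L), , drop = FALSE] +
          arr3(tcrossprod(dy, Wk), n, L)
      }
      list(dx = dxp[, cache$p + seq_len(L), , drop = FALSE],
           grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache, grads = NULL),
    maxpool = {
      m <- cache$m; L <- cache$L
      n <- dim(dout)[1L]; Lo <- dim(dout)[2L]; C <- dim(dout)[3L]
      dx <- array(0, c(n, L, C))
      for (k in seq_len(m)) {
        mask <- cache$which_k == k
        sl <- array(0, c(n, Lo, C))
        sl[mask] <- dout[mask]
        dx[, seq(k, Lo * m, m), ] <- sl
      }
      list(dx = dx, grads = NULL)
    },
    upsample = {
      m <- cache$m; L <- cache$L
      n <- dim(dout)[1L]; C <- dim(dout)[3L]
      dx <- array(0, c(n, L, C))
      for (k in seq_len(m)) dx <- dx + dout[, seq(k, L * m, m), , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    subpixel = {
      m <- cache$m; L <- cache$L; co <- cache$co
      n <- dim(dout)[1L]
      dx <- array(0, c(n, L, co * m))
      for (k in seq_len(m))
        dx[, , (k - 1L) * co + seq_len(co)] <- dout[, seq(k, L * m, m), ,
                                                    drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    layernorm = {
      xhat <- cache$xhat; inv <- cache$inv
      C <- dim(dout)[3L]
      dgamma <- apply(dout * xhat, 3L, sum)
      dbeta <- apply(dout, 3L, sum)
      dxhat <- sweep(dout, 3L, layer$gamma, "*")
      m1 <- apply(dxhat, c(1L, 2L), mean)
      m2 <- apply(dxhat * xhat, c(1L, 2L), mean)
      dx <- (dxhat - as.vector(m1) - xhat * as.vector(m2)) * inv
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    posenc = list(dx = dout, grads = NULL),
    meanpool = {
      L <- cache$L
      dx <- array(rep(dout / L, times = L), c(cache$n, cache$C, L))
      list(dx = aperm(dx, c(1L, 3L, 2L)), grads = NULL)
    },
    dense = list(dx = tcrossprod(dout, layer$W),
                 grads = list(W = crossprod(cache, dout), b = colSums(dout))),
    mha = mha_backward(layer, dout, cache),
    residual = {
      sub <- seq_backward(layer$layers, dout, cache)
      list(dx = dout + sub$dx, grads = list(layers = sub$grads))
    },
    stop("unknown layer type ", layer$type))
}

mha_forward <- function(layer, x) {
  n <- dim(x)[1L]; L <- dim(x)[2L]; D <- layer$d
  h <- layer$heads; dh <- D %/% h
  out <- array(0, c(n, L, D))
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    X <- matrix(x[i, , ], L, D)
    Q <- X %*% layer$Wq; K <- X %*% layer$Wk; V <- X %*% layer$Wv
    O <- matrix(0, L, D)
    A_list <- vector("list", h)
    for (j in seq_len(h)) {
      cols <- (j - 1L) * dh + seq_len(dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1L, max)
      A <- exp(S); A <- A / rowSums(A)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      A_list[[j]] <- A
    }
    out[i, , ] <- O %*% layer$Wo
    caches[[i]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = A_list)
  }
  list(out = out, cache = caches)
}

mha_backward <- function(layer, dout, cache) {
  n <- dim(dout)[1L]; L <- dim(dout)[2L]; D <- layer$d
  h <- layer$heads; dh <- D %/% h
  dWq <- dWk <- dWv <- dWo <- matrix(0, D, D)
  dx <- array(0, c(n, L, D))
  for (i in seq_len(n)) {
    cc <- cache[[i]]
    dY <- matrix(dout[i, , ], L, D)
    dWo <- dWo + crossprod(cc$O, dY)
    dO <- tcrossprod(dY, layer$Wo)
    dQ <- dK <- dV <- matrix(0, L, D)
    for (j in seq_len(h)) {
      cols <- (j - 1L) * dh + seq_len(dh)
      A <- cc$A[[j]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    dWq <- dWq + crossprod(cc$X, dQ)
    dWk <- dWk + crossprod(cc$X, dK)
    dWv <- dWv + crossprod(cc$X, dV)
    dx[i, , ] <- tcrossprod(dQ, layer$Wq) + tcrossprod(dK, layer$Wk) +
      tcrossprod(dV, layer$Wv)
  }
  list(dx = dx, grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

seq_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- r$dx
    grads[i] <- list(r$grads)   # [[<- with NULL would drop the slot
  }
  list(dx = dout, grads = grads)
}

PARAM_NAMES <- c("W", "b", "gamma", "beta", "Wq", "Wk", "Wv", "Wo")

# Adam over a (possibly nested) list of layers, updating in place by value.
adam_init <- function() list(t = 0L)

adam_step <- function(layers, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(layers, grads, path) {
    for (i in seq_along(layers)) {
      g <- grads[[i]]
      if (is.null(g)) next
      if (layers[[i]]$type == "residual") {
        res <- walk(layers[[i]]$layers, g$layers, paste0(path, i, "."))
        layers[[i]]$layers <- res
        next
      }
      for (p in intersect(names(g), PARAM_NAMES)) {
        key <- paste0(path, i, ".", p)
        if (is.null(state[[key]]))
          state[[key]] <<- list(m = 0 * g[[p]], v = 0 * g[[p]])
        st <- state[[key]]
        st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
        st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
        state[[key]] <<- st
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    layers
  }
  layers <- walk(layers, grads, "")
  list(layers = layers, state = state)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy on logits; returns loss and d(loss)/d(logit).
bce_loss <- function(logits, y) {
  p <- sigmoid(logits)
  eps <- 1e-12
  list(loss = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
       dlogits = (p - y) / length(y))
}
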