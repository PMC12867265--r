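# Minimal neural-network engine in vectorized base R.
#
# Tensor conventions:
#  * "seq" tensors are (B*L) x C matrices, rows sample-major (sample b owns
#    rows (b-1)*L+1 .. b*L); L rides along in the forward context.
#  * "flat" tensors are B x F matrices.
#
# Every module is a plain list with fields `kind`, `params` (named list of
# numeric arrays), optionally `sub` (named list of child modules) and `buf`
# (an environment for non-trained buffers such as batch-norm running stats).
# `mod_forward()` returns the output plus a cache consumed by
# `mod_backward()`, which returns the input gradient and a gradient tree
# mirroring the module tree. Attention is vectorized over the batch with a
# loop over the 41 key positions only, so cost does not scale with R-level
# loop iterations per sample.


# Fast column-broadcast helpers (avoid sweep()/aperm in hot paths):
# add / multiply a length-ncol vector across all rows.
addv <- function(x, v) x + rep(v, rep.int(nrow(x), length(v)))
mulv <- function(x, v) x * rep(v, rep.int(nrow(x), length(v)))

new_mod <- function(kind, params = list(), sub = list(), ...) {
  list(kind = kind, params = params, sub = sub, extra = list(...),
       buf = new.env(parent = emptyenv()))
}

fanin_init <- function(nrow, ncol, fan_in) {
  bound <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -bound, bound), nrow, ncol)
}

## ---- leaf constructors -----------------------------------------------------

nn_embedding <- function(n_vocab, dim) {
  new_mod("embedding",
          params = list(W = matrix(stats::rnorm(n_vocab * dim), n_vocab, dim)),
          n_vocab = n_vocab, dim = dim)
}

nn_linear <- function(d_in, d_out, zero_init = FALSE) {
  W <- if (zero_init) matrix(0, d_in, d_out) else fanin_init(d_in, d_out, d_in)
  b <- if (zero_init) numeric(d_out) else
    stats::runif(d_out, -1 / sqrt(d_in), 1 / sqrt(d_in))
  new_mod("linear", params = list(W = W, b = b))
}

nn_conv1d <- function(c_in, c_out, kernel) {
  stopifnot(kernel %% 2L == 1L)
  fan_in <- c_in * kernel
  new_mod("conv1d",
          params = list(W = fanin_init(kernel * c_in, c_out, fan_in),
                        b = stats::runif(c_out, -1 / sqrt(fan_in),
                                         1 / sqrt(fan_in))),
          kernel = kernel, c_in = c_in, c_out = c_out)
}

nn_relu <- function() new_mod("relu")

nn_dropout <- function(rate) new_mod("dropout", rate = rate)

nn_flatten <- function() new_mod("flatten")

nn_maxpool_len <- function() new_mod("maxpool_len")        # k=2, s=2 over L

nn_maxpool_len_same <- function() new_mod("maxpool_len_same")  # k=3, s=1, same

nn_maxpool_feat <- function(kernel = 3L, stride = 2L) {
  new_mod("maxpool_feat", kernel = kernel, stride = stride)
}

nn_batchnorm <- function(dim, eps = 1e-5, momentum = 0.1) {
  m <- new_mod("batchnorm", params = list(gamma = rep(1, dim),
                                          beta = rep(0, dim)),
               eps = eps, momentum = momentum)
  m$buf$mean <- rep(0, dim)
  m$buf$var <- rep(1, dim)
  m
}

nn_layernorm <- function(dim, eps = 1e-5) {
  new_mod("layernorm", params = list(gamma = rep(1, dim), beta = rep(0, dim)),
          eps = eps)
}

nn_mha <- function(dim, heads) {
  stopifnot(dim %% heads == 0L)
  p <- list(Wq = fanin_init(dim, dim, dim), bq = numeric(dim),
            Wk = fanin_init(dim, dim, dim), bk = numeric(dim),
            Wv = fanin_init(dim, dim, dim), bv = numeric(dim),
            Wo = fanin_init(dim, dim, dim), bo = numeric(dim))
  new_mod("mha", params = p, heads = heads, dim = dim)
}

nn_rnn <- function(d_in, hidden, cell = c("rnn", "lstm")) {
  cell <- match.arg(cell)
  mult <- if (cell == "lstm") 4L else 1L
  b <- stats::runif(mult * hidden, -1 / sqrt(hidden), 1 / sqrt(hidden))
  if (cell == "lstm") b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  new_mod("rnncell",
          params = list(Wx = fanin_init(d_in, mult * hidden, d_in),
                        Wh = fanin_init(hidden, mult * hidden, hidden),
                        b = b),
          cell = cell, hidden = hidden)
}

nn_sequential <- function(...) {
  mods <- list(...)
  names(mods) <- sprintf("m%02d", seq_along(mods))
  new_mod("sequential", sub = mods)
}

## ---- forward / backward ----------------------------------------------------

# ctx: list(training = logical, B = batch size, L = current sequence length
# or NULL for flat tensors)

mod_forward <- function(mod, x, ctx) {
  switch(mod$kind,
    sequential = {
      caches <- vector("list", length(mod$sub))
      for (i in seq_along(mod$sub)) {
        r <- mod_forward(mod$sub[[i]], x, ctx)
        x <- r$y; ctx <- r$ctx; caches[[i]] <- r$cache
      }
      list(y = x, cache = caches, ctx = ctx)
    },
    embedding = {
      idx <- as.vector(t(x)) + 1L            # sample-major positions
      y <- mod$params$W[idx, , drop = FALSE]
      ctx$L <- ncol(x)
      list(y = y, cache = list(idx = idx, n = nrow(mod$params$W)), ctx = ctx)
    },
    linear = {
      y <- addv(x %*% mod$params$W, mod$params$b)
      list(y = y, cache = list(x = x), ctx = ctx)
    },
    relu = {
      y <- x * (x > 0)
      list(y = y, cache = list(mask = x > 0), ctx = ctx)
    },
    dropout = {
      if (ctx$training && !isTRUE(ctx$no_dropout) && mod$extra$rate > 0) {
        keep <- matrix(stats::runif(length(x)) >= mod$extra$rate,
                       nrow(x), ncol(x))
        scale <- 1 / (1 - mod$extra$rate)
        list(y = x * keep * scale, cache = list(keep = keep, scale = scale),
             ctx = ctx)
      } else {
        list(y = x, cache = NULL, ctx = ctx)
      }
    },
    flatten = {
      B <- ctx$B
      y <- matrix(t(x), nrow = B, byrow = TRUE)  # row b: pos-major channels
      ctx2 <- ctx; ctx2$L <- NULL
      list(y = y, cache = list(L = ctx$L, C = ncol(x)), ctx = ctx2)
    },
    conv1d = {
      r <- conv1d_forward(mod, x, ctx)
      list(y = r$y, cache = r$cache, ctx = ctx)
    },
    maxpool_len = {
      B <- ctx$B; L <- ctx$L; L2 <- L %/% 2L
      b <- rep(seq_len(B) - 1L, each = L2); i <- rep(seq_len(L2), B)
      r1 <- b * L + 2L * i - 1L; r2 <- r1 + 1L
      x1 <- x[r1, , drop = FALSE]; x2 <- x[r2, , drop = FALSE]
      m1 <- x1 >= x2
      ctx2 <- ctx; ctx2$L <- L2
      list(y = x1 * m1 + x2 * (!m1),
           cache = list(r1 = r1, r2 = r2, m1 = m1, n_in = nrow(x)),
           ctx = ctx2)
    },
    maxpool_len_same = {
      B <- ctx$B; L <- ctx$L; n <- nrow(x)
      pos <- rep(seq_len(L), B)
      xa <- rbind(x, -Inf)
      prev <- ifelse(pos > 1L, seq_len(n) - 1L, n + 1L)
      nxt <- ifelse(pos < L, seq_len(n) + 1L, n + 1L)
      xm <- xa[prev, , drop = FALSE]; xp <- xa[nxt, , drop = FALSE]
      y <- pmax(x, xm, xp)
      list(y = y,
           cache = list(prev = prev, nxt = nxt, mc = (y == x),
                        mm = (y == xm) & (y != x),
                        mp = (y == xp) & (y != x) & (y != xm), n = n),
           ctx = ctx)
    },
    maxpool_feat = {
      k <- mod$extra$kernel; s <- mod$extra$stride; D <- ncol(x)
      n_out <- (D - k) %/% s + 1L
      starts <- (seq_len(n_out) - 1L) * s + 1L
      y <- x[, starts, drop = FALSE]
      arg <- matrix(1L, nrow(x), n_out)
      for (o in seq_len(k - 1L)) {
        cand <- x[, starts + o, drop = FALSE]
        upd <- cand > y
        y[upd] <- cand[upd]
        arg[upd] <- o + 1L
      }
      list(y = y, cache = list(starts = starts, arg = arg, D = D), ctx = ctx)
    },
    batchnorm = {
      bn_forward(mod, x, ctx)
    },
    layernorm = {
      mu <- rowMeans(x)
      xc <- x - mu
      v <- rowMeans(xc^2)
      invstd <- 1 / sqrt(v + mod$extra$eps)
      xhat <- xc * invstd
      y <- addv(mulv(xhat, mod$params$gamma), mod$params$beta)
      list(y = y, cache = list(xhat = xhat, invstd = invstd), ctx = ctx)
    },
    mha = {
      mha_forward(mod, x, ctx)
    },
    rnncell = {
      rnn_forward(mod, x, ctx)
    },
    encoder = encoder_forward(mod, x, ctx),
    inception = inception_forward(mod, x, ctx),
    stop("unknown module kind: ", mod$kind)
  )
}

mod_backward <- function(mod, cache, dy, ctx) {
  switch(mod$kind,
    sequential = {
      grads <- vector("list", length(mod$sub))
      names(grads) <- names(mod$sub)
      for (i in rev(seq_along(mod$sub))) {
        r <- mod_backward(mod$sub[[i]], cache[[i]], dy, ctx)
        dy <- r$dx; grads[[i]] <- r$g
      }
      list(dx = dy, g = list(sub = grads))
    },
    embedding = {
      dW <- rowsum(dy, group = cache$idx)
      full <- matrix(0, cache$n, ncol(dy))
      full[as.integer(rownames(dW)), ] <- dW
      list(dx = NULL, g = list(params = list(W = full)))
    },
    linear = {
      list(dx = dy %*% t(mod$params$W),
           g = list(params = list(W = crossprod(cache$x, dy),
                                  b = colSums(dy))))
    },
    relu = list(dx = dy * cache$mask, g = list()),
    dropout = {
      if (is.null(cache)) list(dx = dy, g = list())
      else list(dx = dy * cache$keep * cache$scale, g = list())
    },
    flatten = {
      x_rows <- matrix(t(dy), ncol = cache$C, byrow = TRUE)
      list(dx = x_rows, g = list())
    },
    conv1d = conv1d_backward(mod, cache, dy),
    maxpool_len = {
      dx <- matrix(0, cache$n_in, ncol(dy))
      dx[cache$r1, ] <- dy * cache$m1
      dx[cache$r2, ] <- dy * (!cache$m1)
      list(dx = dx, g = list())
    },
    maxpool_len_same = {
      n <- cache$n
      dxa <- matrix(0, n + 1L, ncol(dy))
      dxa[seq_len(n), ] <- dy * cache$mc
      dxa[cache$prev, ] <- dxa[cache$prev, , drop = FALSE] + dy * cache$mm
      dxa[cache$nxt, ] <- dxa[cache$nxt, , drop = FALSE] + dy * cache$mp
      list(dx = dxa[seq_len(n), , drop = FALSE], g = list())
    },
    maxpool_feat = {
      dx <- matrix(0, nrow(dy), cache$D)
      for (o in seq_len(max(cache$arg))) {
        mask <- cache$arg == o
        if (!any(mask)) next
        idx_cols <- cache$starts + o - 1L
        contrib <- dy * mask
        dx[, idx_cols] <- dx[, idx_cols, drop = FALSE] + contrib
      }
      list(dx = dx, g = list())
    },
    batchnorm = bn_backward(mod, cache, dy),
    layernorm = {
      g <- mod$params$gamma
      dxhat <- mulv(dy, g)
      xhat <- cache$xhat
      dx <- cache$invstd *
        (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
      list(dx = dx,
           g = list(params = list(gamma = colSums(dy * xhat),
                                  beta = colSums(dy))))
    },
    mha = mha_backward(mod, cache, dy),
    rnncell = rnn_backward(mod, cache, dy),
    encoder = encoder_backward(mod, cache, dy, ctx),
    inception = inception_backward(mod, cache, dy, ctx),
    stop("unknown module kind: ", mod$kind)
  )
}

## ---- conv1d ----------------------------------------------------------------

conv1d_forward <- function(mod, x, ctx) {
  k <- mod$extra$kernel; p <- (k - 1L) %/% 2L
  if (k == 1L) {  # pointwise conv: plain linear map, no im2col
    y <- addv(x %*% mod$params$W, mod$params$b)
    return(list(y = y, cache = list(x = x, k = 1L)))
  }
  B <- ctx$B; L <- ctx$L; n <- nrow(x); c_in <- ncol(x)
  pos <- rep(seq_len(L), B)
  xa <- rbind(x, 0)
  offsets <- seq.int(-p, p)
  idx <- matrix(n + 1L, n, k)
  for (j in seq_along(offsets)) {
    src <- seq_len(n) + offsets[j]
    valid <- (pos + offsets[j] >= 1L) & (pos + offsets[j] <= L)
    idx[valid, j] <- src[valid]
  }
  xcol <- matrix(0, n, k * c_in)
  for (j in seq_len(k)) {
    xcol[, ((j - 1L) * c_in + 1L):(j * c_in)] <- xa[idx[, j], , drop = FALSE]
  }
  y <- addv(xcol %*% mod$params$W, mod$params$b)
  list(y = y, cache = list(xcol = xcol, idx = idx, n = n, c_in = c_in, k = k))
}

conv1d_backward <- function(mod, cache, dy) {
  if (cache$k == 1L) {
    return(list(dx = dy %*% t(mod$params$W),
                g = list(params = list(W = crossprod(cache$x, dy),
                                       b = colSums(dy)))))
  }
  dW <- crossprod(cache$xcol, dy)
  db <- colSums(dy)
  dxcol <- dy %*% t(mod$params$W)
  n <- cache$n; c_in <- cache$c_in; k <- cache$k
  dxa <- matrix(0, n + 1L, c_in)
  for (j in seq_len(k)) {
    block <- dxcol[, ((j - 1L) * c_in + 1L):(j * c_in), drop = FALSE]
    tgt <- cache$idx[, j]
    keep <- tgt <= n
    dxa[tgt[keep], ] <- dxa[tgt[keep], , drop = FALSE] +
      block[keep, , drop = FALSE]
  }
  list(dx = dxa[seq_len(n), , drop = FALSE],
       g = list(params = list(W = dW, b = db)))
}

## ---- batchnorm -------------------------------------------------------------

bn_forward <- function(mod, x, ctx) {
  eps <- mod$extra$eps
  if (ctx$training) {
    mu <- colMeans(x)
    xc <- addv(x, -mu)
    v <- colMeans(xc^2)
    mom <- ctx$bn_momentum %||% mod$extra$momentum
    n <- nrow(x)
    mod$buf$mean <- (1 - mom) * mod$buf$mean + mom * mu
    mod$buf$var <- (1 - mom) * mod$buf$var + mom * v * n / max(n - 1L, 1L)
  } else {
    mu <- mod$buf$mean
    v <- mod$buf$var
    xc <- addv(x, -mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- mulv(xc, invstd)
  y <- addv(mulv(xhat, mod$params$gamma), mod$params$beta)
  list(y = y, cache = list(xhat = xhat, invstd = invstd,
                           training = ctx$training), ctx = ctx)
}

bn_backward <- function(mod, cache, dy) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- mulv(dy, mod$params$gamma)
  if (cache$training) {
    t1 <- addv(dxhat, -colMeans(dxhat))
    t2 <- mulv_colwise <- xhat * rep(colMeans(dxhat * xhat),
                                     rep.int(nrow(dy), ncol(dy)))
    dx <- mulv(t1 - t2, cache$invstd)
  } else {
    dx <- mulv(dxhat, cache$invstd)
  }
  list(dx = dx, g = list(params = list(gamma = dgamma, beta = dbeta)))
}

## ---- multi-head self-attention --------------------------------------------

# Rows of seq tensors are sample-major; key position j of sample b sits at
# row (b-1)*L + j. The attention matrix is held as an (B*L) x L matrix: row
# (b,i) holds the weights of query position i of sample b over the L keys.

mha_forward <- function(mod, x, ctx) {
  p <- mod$params
  H <- mod$extra$heads
  B <- ctx$B; L <- ctx$L
  Q <- addv(x %*% p$Wq, p$bq)
  K <- addv(x %*% p$Wk, p$bk)
  V <- addv(x %*% p$Wv, p$bv)
  att <- attn_forward_cpp(Q, K, V, B, L, H)
  y <- addv(att$ctx %*% p$Wo, p$bo)
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, A = att$A,
                           ctx_out = att$ctx, B = B, L = L),
       ctx = ctx)
}

mha_backward <- function(mod, cache, dy) {
  p <- mod$params
  H <- mod$extra$heads
  dWo <- crossprod(cache$ctx_out, dy)
  dbo <- colSums(dy)
  dctx <- dy %*% t(p$Wo)
  bk <- attn_backward_cpp(cache$Q, cache$K, cache$V, cache$A, dctx,
                          cache$B, cache$L, H)
  x <- cache$x
  g <- list(params = list(
    Wq = crossprod(x, bk$dQ), bq = colSums(bk$dQ),
    Wk = crossprod(x, bk$dK), bk = colSums(bk$dK),
    Wv = crossprod(x, bk$dV), bv = colSums(bk$dV),
    Wo = dWo, bo = dbo))
  dx <- bk$dQ %*% t(p$Wq) + bk$dK %*% t(p$Wk) + bk$dV %*% t(p$Wv)
  list(dx = dx, g = g)
}

## ---- recurrent cells -------------------------------------------------------

# Consumes a seq tensor, emits the final hidden state (B x hidden): the
# recurrent branches summarize the sequence by their last step.

rnn_forward <- function(mod, x, ctx) {
  p <- mod$params
  Hd <- mod$extra$hidden
  cell <- mod$extra$cell
  B <- ctx$B; L <- ctx$L
  base <- (seq_len(B) - 1L) * L
  h <- matrix(0, B, Hd)
  c <- matrix(0, B, Hd)
  steps <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- x[base + t, , drop = FALSE]
    z <- addv(xt %*% p$Wx + h %*% p$Wh, p$b)
    if (cell == "rnn") {
      h_new <- tanh(z)
      steps[[t]] <- list(xt = xt, h_prev = h, h = h_new)
      h <- h_new
    } else {
      i <- sigmoid(z[, 1:Hd, drop = FALSE])
      f <- sigmoid(z[, (Hd + 1):(2 * Hd), drop = FALSE])
      g <- tanh(z[, (2 * Hd + 1):(3 * Hd), drop = FALSE])
      o <- sigmoid(z[, (3 * Hd + 1):(4 * Hd), drop = FALSE])
      c_new <- f * c + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      steps[[t]] <- list(xt = xt, h_prev = h, c_prev = c, i = i, f = f,
                         g = g, o = o, tc = tc)
      h <- h_new; c <- c_new
    }
  }
  ctx2 <- ctx; ctx2$L <- NULL
  list(y = h, cache = list(steps = steps, base = base, L = L,
                           d_in = ncol(x), n = nrow(x)),
       ctx = ctx2)
}

rnn_backward <- function(mod, cache, dy) {
  p <- mod$params
  Hd <- mod$extra$hidden
  cell <- mod$extra$cell
  L <- cache$L; base <- cache$base
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(length(p$b))
  dx <- matrix(0, cache$n, cache$d_in)
  dh <- dy
  dc <- matrix(0, nrow(dy), Hd)
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    if (cell == "rnn") {
      dz <- dh * (1 - st$h^2)
    } else {
      do_ <- dh * st$tc
      dct <- dh * st$o * (1 - st$tc^2) + dc
      di <- dct * st$g
      df <- dct * st$c_prev
      dg <- dct * st$i
      dc <- dct * st$f
      dz <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do_ * st$o * (1 - st$o))
    }
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dx[base + t, ] <- dz %*% t(p$Wx)
    dh <- dz %*% t(p$Wh)
  }
  list(dx = dx, g = list(params = list(Wx = dWx, Wh = dWh, b = db)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- parameter-tree utilities ----------------------------------------------

# Flatten a module tree (or a gradient tree of the same shape) into a named
# list of arrays keyed by path, and write a flat list back into a module.

flatten_params <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params)) {
    out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  }
  for (nm in names(mod$sub)) {
    out <- c(out, flatten_params(mod$sub[[nm]],
                                 prefix = paste0(prefix, nm, ".")))
  }
  out
}

flatten_grads <- function(g, prefix = "") {
  out <- list()
  for (nm in names(g$params)) {
    out[[paste0(prefix, nm)]] <- g$params[[nm]]
  }
  for (nm in names(g$sub)) {
    if (length(g$sub[[nm]]) == 0L) next
    out <- c(out, flatten_grads(g$sub[[nm]], prefix = paste0(prefix, nm, ".")))
  }
  out
}

set_params <- function(mod, flat, prefix = "") {
  for (nm in names(mod$params)) {
    key <- paste0(prefix, nm)
    if (!is.null(flat[[key]])) mod$params[[nm]] <- flat[[key]]
  }
  for (nm in names(mod$sub)) {
    mod$sub[[nm]] <- set_params(mod$sub[[nm]], flat,
                                prefix = paste0(prefix, nm, "."))
  }
  mod
}

## ---- Adam optimizer --------------------------------------------------------

adam_init <- function(flat) {
  list(step = 0L,
       m = lapply(flat, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(flat, function(p) array(0, dim = dim(p) %||% length(p))))
}

adam_update <- function(state, flat, grads, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1 ^ state$step
  bc2 <- 1 - beta2 ^ state$step
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) stop("missing gradient for parameter ", nm)
    gv <- as.numeric(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gv
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gv^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- lr * mhat / (sqrt(vhat) + eps)
    pnew <- as.numeric(flat[[nm]]) - upd
    if (is.matrix(flat[[nm]])) {
      flat[[nm]] <- matrix(pnew, nrow(flat[[nm]]), ncol(flat[[nm]]))
    } else {
      flat[[nm]] <- pnew
    }
  }
  list(state = state, flat = flat)
}

# Global gradient-norm clipping (the default reading of the "maximum L2
# norm 1" training constraint).
clip_grad_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(as.numeric(g)^2),
                           numeric(1))))
  if (is.finite(total) && total > max_norm && total > 0) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) g * sc)
  }
  grads
}

# Alternative reading: per-unit weight max-norm constraint applied after the
# optimizer step (columns of 2-D weights rescaled to at most `max_norm`).
apply_weight_maxnorm <- function(flat, max_norm) {
  for (nm in names(flat)) {
    p <- flat[[nm]]
    if (is.matrix(p)) {
      norms <- sqrt(colSums(p^2))
      over <- norms > max_norm
      if (any(over)) {
        p[, over] <- sweep(p[, over, drop = FALSE], 2L,
                           norms[over] / max_norm, `/`)
        flat[[nm]] <- p
      }
    }
  }
  flat
}
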