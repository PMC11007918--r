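# Internal neural-network machinery for the KO/non-KO classifier: explicit
# forward/backward passes for the MLP head and the LSTM/attention baseline
# architectures, binary cross-entropy loss, and an Adam optimizer. Kept
# deliberately small: desk-scale training only.

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

nn_init_params <- function(cfg, input_dim) {
  # caller is responsible for seeding
  if (cfg$architecture == "mlp") {
    h <- cfg$hidden_size
    list(
      W1 = rnorm_mat(input_dim, h, sqrt(2 / input_dim)), b1 = numeric(h),
      W2 = rnorm_mat(h, 1L, sqrt(1 / h)), b2 = 0
    )
  } else {
    e <- cfg$token_embed_dim
    f <- cfg$conv_filters
    k <- cfg$conv_kernel
    u <- cfg$recurrent_units
    p <- list(
      Emb = rnorm_mat(20L, e, 0.1),
      Wc = rnorm_mat(k * e, f, sqrt(2 / (k * e))), bc = numeric(f)
    )
    if (cfg$architecture == "lstm") {
      p$Wx <- rnorm_mat(f, 4L * u, sqrt(1 / f))
      p$bg <- numeric(4L * u)
    } else { # attention
      p$Wq <- rnorm_mat(f, u, sqrt(1 / f))
      p$Wk <- rnorm_mat(f, u, sqrt(1 / f))
      p$Wv <- rnorm_mat(f, u, sqrt(1 / f))
    }
    p$wo <- rnorm_mat(u, 1L, sqrt(1 / u))
    p$bo <- 0
    p
  }
}

# ---- MLP -------------------------------------------------------------------

nn_forward_mlp <- function(params, X) {
  Z1 <- sweep(X %*% params$W1, 2L, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  logit <- drop(A1 %*% params$W2) + params$b2
  list(logit = logit, cache = list(X = X, Z1 = Z1, A1 = A1))
}

nn_backward_mlp <- function(params, cache, dlogit) {
  dW2 <- crossprod(cache$A1, dlogit)
  db2 <- sum(dlogit)
  dA1 <- dlogit %*% t(params$W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  list(W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
       W2 = dW2, b2 = db2)
}

# ---- Sequence baselines (token embedding -> conv1d -> global max pool ->
# single-step LSTM / one-token attention -> sigmoid) -------------------------

seq_conv_forward <- function(params, tokens, cfg) {
  n <- length(tokens)
  e <- cfg$token_embed_dim
  k <- cfg$conv_kernel
  E <- matrix(0, n, e)
  nz <- which(tokens > 0L)
  if (length(nz)) E[nz, ] <- params$Emb[tokens[nz], , drop = FALSE]
  nwin <- n - k + 1L
  Xw <- do.call(cbind, lapply(seq_len(k), function(o) {
    E[o:(nwin + o - 1L), , drop = FALSE]
  }))
  C <- pmax(sweep(Xw %*% params$Wc, 2L, params$bc, `+`), 0)
  am <- max.col(t(C), ties.method = "first")  # argmax window per filter
  h <- C[cbind(am, seq_len(ncol(C)))]
  list(h = h, cache = list(tokens = tokens, Xw = Xw, C = C, am = am))
}

seq_conv_backward <- function(params, cache, dh, cfg) {
  e <- cfg$token_embed_dim
  k <- cfg$conv_kernel
  f <- cfg$conv_filters
  nwin <- nrow(cache$Xw)
  idx <- cbind(cache$am, seq_len(f))
  dC <- matrix(0, nwin, f)
  dC[idx] <- dh * (cache$C[idx] > 0)
  dWc <- crossprod(cache$Xw, dC)
  dbc <- colSums(dC)
  dXw <- dC %*% t(params$Wc)
  n <- length(cache$tokens)
  dE <- matrix(0, n, e)
  for (o in seq_len(k)) {
    rows <- o:(nwin + o - 1L)
    dE[rows, ] <- dE[rows, ] + dXw[, ((o - 1L) * e + 1L):(o * e), drop = FALSE]
  }
  dEmb <- matrix(0, 20L, e)
  nz <- which(cache$tokens > 0L)
  if (length(nz)) {
    agg <- rowsum(dE[nz, , drop = FALSE], group = cache$tokens[nz])
    dEmb[as.integer(rownames(agg)), ] <- agg
  }
  list(Wc = dWc, bc = dbc, Emb = dEmb)
}

nn_forward_seq_one <- function(params, tokens, cfg) {
  conv <- seq_conv_forward(params, tokens, cfg)
  x <- conv$h
  u <- cfg$recurrent_units
  if (cfg$architecture == "lstm") {
    z <- drop(x %*% params$Wx) + params$bg
    zi <- z[1:u]; zf <- z[(u + 1):(2 * u)]
    zo <- z[(2 * u + 1):(3 * u)]; zg <- z[(3 * u + 1):(4 * u)]
    i <- sigmoid(zi); o <- sigmoid(zo); g <- tanh(zg)
    cst <- i * g            # single step from zero state: forget gate idle
    hs <- o * tanh(cst)
  } else {
    # one-token attention: softmax over a single key is 1, so the context
    # vector is the value projection; query/key projections get no gradient
    hs <- drop(x %*% params$Wv)
    i <- o <- g <- cst <- NULL
  }
  logit <- drop(hs %*% params$wo) + params$bo
  list(logit = logit,
       cache = list(conv = conv, x = x, i = i, o = o, g = g, cst = cst,
                    hs = hs))
}

nn_backward_seq_one <- function(params, cache, dlogit, cfg) {
  hs <- cache$hs
  dwo <- matrix(hs * dlogit, ncol = 1L)
  dbo <- dlogit
  dhs <- drop(params$wo) * dlogit
  x <- cache$x
  if (cfg$architecture == "lstm") {
    i <- cache$i; o <- cache$o; g <- cache$g; cst <- cache$cst
    tc <- tanh(cst)
    do_ <- dhs * tc
    dc <- dhs * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    dz <- c(di * i * (1 - i), numeric(length(i)),  # forget gate: zero grad
            do_ * o * (1 - o), dg * (1 - g^2))
    dWx <- outer(x, dz)
    dbg <- dz
    dx <- drop(params$Wx %*% dz)
    grads <- list(Wx = dWx, bg = dbg, wo = dwo, bo = dbo)
  } else {
    dWv <- outer(x, dhs)
    dx <- drop(params$Wv %*% dhs)
    grads <- list(Wv = dWv,
                  Wq = matrix(0, nrow(params$Wq), ncol(params$Wq)),
                  Wk = matrix(0, nrow(params$Wk), ncol(params$Wk)),
                  wo = dwo, bo = dbo)
  }
  convg <- seq_conv_backward(params, cache$conv$cache, dx, cfg)
  c(grads, convg)
}

nn_forward <- function(params, X, cfg) {
  if (cfg$architecture == "mlp") {
    nn_forward_mlp(params, X)
  } else {
    out <- lapply(seq_len(nrow(X)), function(i) {
      nn_forward_seq_one(params, as.integer(X[i, ]), cfg)
    })
    list(logit = vapply(out, `[[`, numeric(1), "logit"),
         cache = lapply(out, `[[`, "cache"))
  }
}

nn_backward <- function(params, fw, dlogit, cfg) {
  if (cfg$architecture == "mlp") {
    nn_backward_mlp(params, fw$cache, matrix(dlogit, ncol = 1L))
  } else {
    total <- NULL
    for (i in seq_along(dlogit)) {
      g <- nn_backward_seq_one(params, fw$cache[[i]], dlogit[i], cfg)
      if (is.null(total)) total <- g
      else for (nm in names(total)) total[[nm]] <- total[[nm]] + g[[nm]]
    }
    total
  }
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
                      else numeric(length(p))
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
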