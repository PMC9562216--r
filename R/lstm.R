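# Bidirectional LSTM sequence labeller: batched forward pass,
# backpropagation through time, and Adam updates, in plain R on BLAS
# matrix products. Gate layout follows the common i|f|g|o column blocks:
#   z_t = x_t Wx + h_{t-1} Wh + b,   i,f,o = sigmoid, g = tanh
#   c_t = f * c_{t-1} + i * g,       h_t = o * tanh(c_t)
# Each layer runs one pass per direction; their hidden states are
# concatenated (2H channels) and fed to the next layer, with inverted
# dropout between layers during training. A per-frame linear map and
# sigmoid produce the event-probability curve.

sigmoid <- function(x) stats::plogis(x)

# Uniform(-k, k), k = 1 / sqrt(hidden): the conventional LSTM init.
init_bilstm_params <- function(n_input, n_layers, hidden, seed = NULL) {
  make <- function(nr, nc, k) matrix(runif(nr * nc, -k, k), nr, nc)
  build <- function() {
    k <- 1 / sqrt(hidden)
    layers <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      cin <- if (l == 1) n_input else 2L * hidden
      layers[[l]] <- list(
        fwd = list(Wx = make(cin, 4 * hidden, k), Wh = make(hidden, 4 * hidden, k),
                   b = runif(4 * hidden, -k, k)),
        bwd = list(Wx = make(cin, 4 * hidden, k), Wh = make(hidden, 4 * hidden, k),
                   b = runif(4 * hidden, -k, k))
      )
    }
    list(layers = layers,
         head = list(Wy = make(2L * hidden, 1L, k), by = runif(1, -k, k)),
         n_input = n_input, n_layers = n_layers, hidden = hidden)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# One direction of one layer. Xl: list over time of (B x Cin) matrices.
# ts_order: 1:T for the forward pass, T:1 for the backward-in-time pass.
# Returns hidden states aligned to the original time axis plus caches.
lstm_dir_forward <- function(Xl, p, ts_order, keep_cache = TRUE) {
  T_ <- length(Xl)
  B <- nrow(Xl[[1]])
  H <- nrow(p$Wh)
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  hs <- vector("list", T_)
  cache <- if (keep_cache) vector("list", T_) else NULL
  bmat <- matrix(p$b, B, 4 * H, byrow = TRUE)
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); oo <- (3 * H + 1):(4 * H)
  for (t in ts_order) {
    z <- Xl[[t]] %*% p$Wx + h %*% p$Wh + bmat
    i <- sigmoid(z[, ii, drop = FALSE])
    f <- sigmoid(z[, ff, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigmoid(z[, oo, drop = FALSE])
    c_prev <- c_
    c_ <- f * c_prev + i * g
    tc <- tanh(c_)
    h_prev <- h
    h <- o * tc
    hs[[t]] <- h
    if (keep_cache)
      cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                         tc = tc, h_prev = h_prev)
  }
  list(h = hs, cache = cache)
}

# BPTT for one direction. dHl: list over time of (B x H) gradients w.r.t.
# this direction's hidden states. Returns parameter grads and dX per frame.
lstm_dir_backward <- function(Xl, p, ts_order, fw, dHl) {
  T_ <- length(Xl)
  B <- nrow(Xl[[1]]); H <- nrow(p$Wh)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dXl <- vector("list", T_)
  dh_rec <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(ts_order)) {
    cc <- fw$cache[[t]]
    dh <- dHl[[t]] + dh_rec
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(Xl[[t]], dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh_rec <- dz %*% t(p$Wh)
    dXl[[t]] <- dz %*% t(p$Wx)
    dc <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, dXl = dXl)
}

# Full forward pass. X: array (B x T x C). Returns per-frame probabilities
# (B x T) and, when training, the caches needed for the backward pass.
bilstm_forward <- function(params, X, dropout = 0, training = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]; C <- dim(X)[3]
  Xl <- lapply(seq_len(T_), function(t) matrix(X[, t, ], B, C))
  caches <- vector("list", params$n_layers)
  inputs <- vector("list", params$n_layers)
  masks <- vector("list", params$n_layers)
  cur <- Xl
  for (l in seq_len(params$n_layers)) {
    inputs[[l]] <- cur
    pf <- params$layers[[l]]$fwd
    pb <- params$layers[[l]]$bwd
    fw <- lstm_dir_forward(cur, pf, 1:T_, keep_cache = training)
    bw <- lstm_dir_forward(cur, pb, T_:1, keep_cache = training)
    caches[[l]] <- list(fwd = fw, bwd = bw)
    cur <- lapply(seq_len(T_), function(t) cbind(fw$h[[t]], bw$h[[t]]))
    if (training && dropout > 0 && l < params$n_layers) {
      mask <- lapply(seq_len(T_), function(t)
        matrix(rbinom(B * 2 * params$hidden, 1, 1 - dropout),
               B, 2 * params$hidden) / (1 - dropout))
      masks[[l]] <- mask
      cur <- lapply(seq_len(T_), function(t) cur[[t]] * mask[[t]])
    }
  }
  Wy <- params$head$Wy; by <- params$head$by
  S <- vapply(seq_len(T_), function(t) as.numeric(cur[[t]] %*% Wy + by),
              numeric(B))
  S <- matrix(S, B, T_)  # logits
  P <- sigmoid(S)
  list(P = P, S = S,
       state = if (training) list(caches = caches, inputs = inputs,
                                  masks = masks, top = cur, T_ = T_, B = B)
              else NULL)
}

# Backward pass from dS (B x T, gradient w.r.t. logits). Returns grads with
# the same structure as params.
bilstm_backward <- function(params, fwd, dS) {
  st <- fwd$state
  T_ <- st$T_; B <- st$B; H <- params$hidden
  Wy <- params$head$Wy
  dWy <- matrix(0, 2 * H, 1); dby <- 0
  dCur <- vector("list", T_)
  for (t in seq_len(T_)) {
    ds_t <- matrix(dS[, t], B, 1)
    dWy <- dWy + crossprod(st$top[[t]], ds_t)
    dby <- dby + sum(ds_t)
    dCur[[t]] <- ds_t %*% t(Wy)
  }
  glayers <- vector("list", params$n_layers)
  for (l in rev(seq_len(params$n_layers))) {
    if (!is.null(st$masks[[l]]))
      dCur <- lapply(seq_len(T_), function(t) dCur[[t]] * st$masks[[l]][[t]])
    dHf <- lapply(dCur, function(m) m[, 1:H, drop = FALSE])
    dHb <- lapply(dCur, function(m) m[, (H + 1):(2 * H), drop = FALSE])
    gf <- lstm_dir_backward(st$inputs[[l]], params$layers[[l]]$fwd, 1:T_,
                            st$caches[[l]]$fwd, dHf)
    gb <- lstm_dir_backward(st$inputs[[l]], params$layers[[l]]$bwd, T_:1,
                            st$caches[[l]]$bwd, dHb)
    glayers[[l]] <- list(fwd = gf[c("Wx", "Wh", "b")],
                         bwd = gb[c("Wx", "Wh", "b")])
    dCur <- lapply(seq_len(T_), function(t) gf$dXl[[t]] + gb$dXl[[t]])
  }
  list(layers = glayers, head = list(Wy = dWy, by = dby))
}

# ---- flat parameter <-> list helpers for the optimiser ----------------

flatten_params <- function(p) {
  out <- list()
  for (l in seq_along(p$layers)) {
    for (d in c("fwd", "bwd")) {
      for (nm in c("Wx", "Wh", "b")) {
        out[[paste(l, d, nm, sep = ".")]] <- p$layers[[l]][[d]][[nm]]
      }
    }
  }
  out[["head.Wy"]] <- p$head$Wy
  out[["head.by"]] <- p$head$by
  out
}

unflatten_into <- function(p, flat) {
  for (l in seq_along(p$layers)) {
    for (d in c("fwd", "bwd")) {
      for (nm in c("Wx", "Wh", "b")) {
        p$layers[[l]][[d]][[nm]] <- flat[[paste(l, d, nm, sep = ".")]]
      }
    }
  }
  p$head$Wy <- flat[["head.Wy"]]
  p$head$by <- flat[["head.by"]]
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}
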