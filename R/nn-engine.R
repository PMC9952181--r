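# Minimal neural-network engine: dense / 1-D convolution / max-pool /
# global-average-pool / LSTM / BiLSTM layers, softmax cross-entropy, Adam.
# Arrays are batch-major: X is (batch, time, channels); dense layers see
# (batch, features). All randomness goes through the caller's RNG so a
# seeded training run is reproducible.

sigm <- function(x) 1 / (1 + exp(-x))

# He/Glorot-style init scaled by fan-in.
nn_mat <- function(nr, nc, scale = sqrt(2 / nr)) {
  matrix(rnorm(nr * nc, sd = scale), nr, nc)
}

nn_build <- function(arch, input_len, input_channels, n_classes) {
  layers <- list()
  L <- input_len
  C <- input_channels
  flat <- FALSE
  add <- function(layer) layers[[length(layers) + 1]] <<- layer
  for (spec in arch) {
    type <- spec$type
    if (type == "conv1d") {
      add(list(type = "conv1d", k = spec$k,
               W = nn_mat(spec$k * C, spec$filters,
                          scale = sqrt(2 / (spec$k * C))),
               b = rep(0, spec$filters)))
      L <- L - spec$k + 1
      C <- spec$filters
    } else if (type == "relu") {
      add(list(type = "relu"))
    } else if (type == "maxpool") {
      add(list(type = "maxpool"))
      L <- L %/% 2
    } else if (type == "gap") {
      add(list(type = "gap"))
      flat <- TRUE
    } else if (type == "flatten") {
      add(list(type = "flatten"))
      C <- L * C
      flat <- TRUE
    } else if (type == "lstm" || type == "bilstm") {
      H <- spec$units
      mk <- function() list(
        Wx = nn_mat(C, 4 * H, scale = sqrt(1 / C)),
        Wh = nn_mat(H, 4 * H, scale = sqrt(1 / H)),
        b = rep(0, 4 * H)
      )
      if (type == "lstm") {
        add(list(type = "lstm", H = H, fw = mk()))
        C <- H
      } else {
        add(list(type = "bilstm", H = H, fw = mk(), bw = mk()))
        C <- 2 * H
      }
      flat <- TRUE
    } else if (type == "dense") {
      stopifnot(flat)
      add(list(type = "dense",
               W = nn_mat(C, spec$units, scale = sqrt(2 / C)),
               b = rep(0, spec$units)))
      C <- spec$units
    } else {
      stop("unknown layer type: ", type)
    }
  }
  layers
}

# ---- per-layer forward/backward ------------------------------------------

conv1d_fwd <- function(layer, X) {
  list(out = .conv1d_fwd_cpp(X, layer$W, layer$b), cache = list(X = X))
}

conv1d_bwd <- function(layer, cache, dY) {
  r <- .conv1d_bwd_cpp(cache$X, layer$W, dY)
  list(dX = r$dX, grads = list(W = r$dW, b = r$db))
}

maxpool_fwd <- function(X) {
  r <- .maxpool_fwd_cpp(X)
  list(out = r$Y, cache = list(sel2 = r$sel2, L = dim(X)[2]))
}

maxpool_bwd <- function(cache, dY) {
  .maxpool_bwd_cpp(dY, cache$sel2, cache$L)
}

gap_fwd <- function(X) {
  d <- dim(X)
  Y <- colMeans(aperm(X, c(2, 1, 3)))  # (B, F)
  list(out = matrix(Y, d[1], d[3]), cache = list(dimX = d))
}

gap_bwd <- function(cache, dY) {
  d <- cache$dimX
  aperm(array(dY / d[2], dim = c(d[1], d[3], d[2])), c(1, 3, 2))
}

lstm_cell_fwd <- function(p, X, H, reverse = FALSE) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  ts <- if (reverse) rev(seq_len(L)) else seq_len(L)
  steps <- vector("list", L)
  for (s in seq_along(ts)) {
    t <- ts[s]
    xt <- matrix(X[, t, ], B, C)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2, p$b, "+")
    ig <- sigm(z[, 1:H, drop = FALSE])
    fg <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
    og <- sigm(z[, (2 * H + 1):(3 * H), drop = FALSE])
    gg <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- fg * cc + ig * gg
    tc <- tanh(cc)
    h <- og * tc
    steps[[s]] <- list(t = t, xt = xt, i = ig, f = fg, o = og, g = gg,
                       c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(h = h, steps = steps, dimX = d)
}

lstm_cell_bwd <- function(p, fwd, dh_last) {
  d <- fwd$dimX
  B <- d[1]; L <- d[2]; C <- d[3]
  H <- ncol(dh_last)
  dWx <- matrix(0, C, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  db <- rep(0, 4 * H)
  dX <- array(0, dim = d)
  dh <- dh_last
  dc <- matrix(0, B, H)
  for (s in rev(seq_len(L))) {
    st <- fwd$steps[[s]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dX[, st$t, ] <- dX[, st$t, , drop = FALSE] +
      array(tcrossprod(dz, p$Wx), dim = c(B, 1, C))
    dh <- tcrossprod(dz, p$Wh)
    dc <- dc * st$f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

nn_forward <- function(layers, X, training = TRUE) {
  caches <- vector("list", length(layers))
  out <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv1d") {
      r <- conv1d_fwd(ly, out)
      out <- r$out
      caches[[i]] <- r$cache
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = out > 0)
      out[out < 0] <- 0
    } else if (ly$type == "maxpool") {
      r <- maxpool_fwd(out)
      out <- r$out
      caches[[i]] <- r$cache
    } else if (ly$type == "gap") {
      r <- gap_fwd(out)
      out <- r$out
      caches[[i]] <- r$cache
    } else if (ly$type == "flatten") {
      d <- dim(out)
      caches[[i]] <- list(dimX = d)
      dim(out) <- c(d[1], prod(d[-1]))
    } else if (ly$type == "lstm") {
      r <- lstm_cell_fwd(ly$fw, out, ly$H)
      caches[[i]] <- if (training) list(fw = r) else NULL
      out <- r$h
    } else if (ly$type == "bilstm") {
      rf <- lstm_cell_fwd(ly$fw, out, ly$H, reverse = FALSE)
      rb <- lstm_cell_fwd(ly$bw, out, ly$H, reverse = TRUE)
      caches[[i]] <- if (training) list(fw = rf, bw = rb) else NULL
      out <- cbind(rf$h, rb$h)
    } else if (ly$type == "dense") {
      caches[[i]] <- list(X = out)
      out <- sweep(out %*% ly$W, 2, ly$b, "+")
    }
  }
  list(out = out, caches = caches)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "conv1d") {
      r <- conv1d_bwd(ly, ca, dout)
      dout <- r$dX
      grads[[i]] <- r$grads
    } else if (ly$type == "relu") {
      dout <- dout * ca$mask
    } else if (ly$type == "maxpool") {
      dout <- maxpool_bwd(ca, dout)
    } else if (ly$type == "gap") {
      dout <- gap_bwd(ca, dout)
    } else if (ly$type == "flatten") {
      dim(dout) <- ca$dimX
    } else if (ly$type == "lstm") {
      r <- lstm_cell_bwd(ly$fw, ca$fw, dout)
      dout <- r$dX
      grads[[i]] <- list(fw = r$grads)
    } else if (ly$type == "bilstm") {
      H <- ly$H
      rf <- lstm_cell_bwd(ly$fw, ca$fw, dout[, 1:H, drop = FALSE])
      rb <- lstm_cell_bwd(ly$bw, ca$bw,
                          dout[, (H + 1):(2 * H), drop = FALSE])
      dout <- rf$dX + rb$dX
      grads[[i]] <- list(fw = rf$grads, bw = rb$grads)
    } else if (ly$type == "dense") {
      grads[[i]] <- list(W = crossprod(ca$X, dout), b = colSums(dout))
      dout <- tcrossprod(dout, ly$W)
    }
  }
  grads
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# returns list(loss, dlogits, correct)
xent_loss <- function(logits, y_idx) {
  B <- nrow(logits)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(B), y_idx)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- P
  dl[cbind(seq_len(B), y_idx)] <- dl[cbind(seq_len(B), y_idx)] - 1
  list(loss = loss, dlogits = dl / B,
       correct = sum(max.col(P, ties.method = "first") == y_idx))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    zero_like <- function(p) lapply(p, function(m) m * 0)
    if (ly$type %in% c("conv1d", "dense")) {
      list(m = zero_like(ly[c("W", "b")]), v = zero_like(ly[c("W", "b")]))
    } else if (ly$type == "lstm") {
      list(fw = list(m = zero_like(ly$fw), v = zero_like(ly$fw)))
    } else if (ly$type == "bilstm") {
      list(fw = list(m = zero_like(ly$fw), v = zero_like(ly$fw)),
           bw = list(m = zero_like(ly$bw), v = zero_like(ly$bw)))
    } else NULL
  })
}

adam_apply <- function(p, g, st, lr, t, wd = 0, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(g)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - b1^t)
    vh <- st$v[[nm]] / (1 - b2^t)
    decay <- if (nm == "b") 0 else wd  # biases are not decayed
    p[[nm]] <- p[[nm]] - lr * (mh / (sqrt(vh) + eps) + decay * p[[nm]])
  }
  list(p = p, st = st)
}

adam_step <- function(layers, grads, opt, lr, t, wd = 0) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (ly$type %in% c("conv1d", "dense")) {
      r <- adam_apply(ly[c("W", "b")], g, opt[[i]], lr, t, wd)
      layers[[i]]$W <- r$p$W
      layers[[i]]$b <- r$p$b
      opt[[i]] <- r$st
    } else if (ly$type == "lstm") {
      r <- adam_apply(ly$fw, g$fw, opt[[i]]$fw, lr, t, wd)
      layers[[i]]$fw <- r$p
      opt[[i]]$fw <- r$st
    } else if (ly$type == "bilstm") {
      rf <- adam_apply(ly$fw, g$fw, opt[[i]]$fw, lr, t, wd)
      rb <- adam_apply(ly$bw, g$bw, opt[[i]]$bw, lr, t, wd)
      layers[[i]]$fw <- rf$p
      layers[[i]]$bw <- rb$p
      opt[[i]]$fw <- rf$st
      opt[[i]]$bw <- rb$st
    }
  }
  list(layers = layers, opt = opt)
}
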