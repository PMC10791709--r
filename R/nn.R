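# A compact convolutional-network engine sufficient for the slice-wise
# emphysema regressor: bias-free convolutions (batch norm follows every
# conv), residual basic blocks, max/global-average pooling, a linear head,
# and Adam with exponential learning-rate decay and L2 shrinkage.
# Batches are arrays (H, W, C, N); parameters live in a flat named list so
# the optimizer and gradient checks can treat the network generically.

pn <- function(...) paste(..., sep = ".")

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

# ---- layer forward/backward -------------------------------------------

conv_fw <- function(x, w, stride, pad) {
  d <- dim(x)
  k <- dim(w)[1]; cout <- dim(w)[4]
  cols <- im2col_batch(as.vector(x), d[1], d[2], d[3], d[4], k, stride, pad)
  wm <- matrix(w, nrow = k * k * d[3])
  out <- crossprod(wm, cols)             # Cout x (Ho*Wo*N)
  ho <- (d[1] + 2 * pad - k) %/% stride + 1
  wo <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- aperm(array(t(out), dim = c(ho, wo, d[4], cout)), c(1, 2, 4, 3))
  list(y = y, cache = list(cols = cols, w = w, dims = d, k = k,
                           stride = stride, pad = pad, ho = ho, wo = wo))
}

conv_bw <- function(dy, cache) {
  d <- cache$dims
  cout <- dim(cache$w)[4]
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = cout)
  dw <- array(cache$cols %*% t(dym), dim = dim(cache$w))
  wm <- matrix(cache$w, nrow = cache$k^2 * d[3])
  dcols <- wm %*% dym
  dx <- col2im_batch(dcols, d[1], d[2], d[3], d[4], cache$k,
                     cache$stride, cache$pad)
  list(dx = dx, dw = dw)
}

bn_fw <- function(x, gamma, beta, rm, rv, training, eps = 1e-5,
                  momentum = 0.1) {
  if (training) {
    mu <- apply(x, 3, mean)
    xc <- sweep(x, 3, mu)
    v <- apply(xc * xc, 3, mean)
    new_rm <- (1 - momentum) * rm + momentum * mu
    new_rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv
    xc <- sweep(x, 3, mu)
    new_rm <- rm; new_rv <- rv
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 3, ivar, "*")
  y <- sweep(sweep(xhat, 3, gamma, "*"), 3, beta, "+")
  list(y = y, rm = new_rm, rv = new_rv,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma))
}

bn_bw <- function(dy, cache) {
  xhat <- cache$xhat
  m <- prod(dim(dy)[-3])
  dgamma <- apply(dy * xhat, 3, sum)
  dbeta <- apply(dy, 3, sum)
  dxhat <- sweep(dy, 3, cache$gamma, "*")
  s1 <- apply(dxhat, 3, sum)
  s2 <- apply(dxhat * xhat, 3, sum)
  dx <- sweep(dxhat - sweep(xhat, 3, s2 / m, "*"), 3, s1 / m) |>
    sweep(3, cache$ivar, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bw <- function(dy, cache) dy * cache

gap_fw <- function(x) {
  d <- dim(x)
  z <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  list(y = z, cache = d)
}
gap_bw <- function(dz, d) {
  dx <- array(0, d)
  per <- dz / (d[1] * d[2])                 # C x N
  dx[] <- rep(as.vector(per), each = d[1] * d[2])
  dx
}

# ---- architecture ------------------------------------------------------

# A stage is `blocks` residual basic blocks; the first uses `stride` and a
# 1x1 projection when stride or width changes.
nn_arch <- function(variant, input_size) {
  if (variant == "full") {
    list(variant = "full", input_size = input_size,
         stem = list(k = 7, stride = 2, pad = 3, cin = 1, cout = 64),
         use_maxpool = TRUE,
         stages = list(
           list(blocks = 2, cout = 64, stride = 1),
           list(blocks = 2, cout = 128, stride = 2),
           list(blocks = 2, cout = 256, stride = 2),
           list(blocks = 2, cout = 512, stride = 2)))
  } else {
    list(variant = "reduced", input_size = input_size,
         stem = list(k = 3, stride = 2, pad = 1, cin = 1, cout = 8),
         use_maxpool = TRUE,
         stages = list(
           list(blocks = 1, cout = 8, stride = 1),
           list(blocks = 1, cout = 16, stride = 2),
           list(blocks = 1, cout = 32, stride = 2)))
  }
}

nn_init_params <- function(arch) {
  P <- list()
  add_bn <- function(P, name, c) {
    P[[pn(name, "gamma")]] <- rep(1, c)
    P[[pn(name, "beta")]] <- rep(0, c)
    P
  }
  st <- arch$stem
  P[[pn("stem", "conv", "w")]] <- he_init(st$k, st$cin, st$cout)
  P <- add_bn(P, pn("stem", "bn"), st$cout)
  cin <- st$cout
  for (s in seq_along(arch$stages)) {
    stage <- arch$stages[[s]]
    for (b in seq_len(stage$blocks)) {
      pre <- pn("s", s, "b", b)
      stride <- if (b == 1) stage$stride else 1
      bin <- if (b == 1) cin else stage$cout
      P[[pn(pre, "conv1", "w")]] <- he_init(3, bin, stage$cout)
      P <- add_bn(P, pn(pre, "bn1"), stage$cout)
      P[[pn(pre, "conv2", "w")]] <- he_init(3, stage$cout, stage$cout)
      P <- add_bn(P, pn(pre, "bn2"), stage$cout)
      if (stride != 1 || bin != stage$cout) {
        P[[pn(pre, "down", "conv", "w")]] <- he_init(1, bin, stage$cout)
        P <- add_bn(P, pn(pre, "down", "bn"), stage$cout)
      }
    }
    cin <- stage$cout
  }
  P[[pn("fc", "w")]] <- matrix(rnorm(cin, 0, sqrt(1 / cin)), ncol = 1)
  P[[pn("fc", "b")]] <- 0
  P
}

nn_init_runstats <- function(P) {
  rs <- list()
  for (nm in names(P)) {
    if (grepl("\\.gamma$", nm)) {
      base <- sub("\\.gamma$", "", nm)
      rs[[pn(base, "rm")]] <- rep(0, length(P[[nm]]))
      rs[[pn(base, "rv")]] <- rep(1, length(P[[nm]]))
    }
  }
  rs
}

conv_bn_fw <- function(x, P, rs, conv_name, bn_name, stride, pad, training) {
  cv <- conv_fw(x, P[[pn(conv_name, "w")]], stride, pad)
  bn <- bn_fw(cv$y, P[[pn(bn_name, "gamma")]], P[[pn(bn_name, "beta")]],
              rs[[pn(bn_name, "rm")]], rs[[pn(bn_name, "rv")]], training)
  list(y = bn$y, conv = cv$cache, bn = bn$cache,
       rm = bn$rm, rv = bn$rv)
}

# Forward pass. Returns predictions, per-layer caches (training mode) and
# updated batch-norm running statistics.
nn_forward <- function(P, arch, rs, x, training = FALSE) {
  caches <- list()
  put_rs <- function(name, unit) {
    rs[[pn(name, "rm")]] <<- unit$rm
    rs[[pn(name, "rv")]] <<- unit$rv
  }
  st <- conv_bn_fw(x, P, rs, pn("stem", "conv"), pn("stem", "bn"),
                   arch$stem$stride, arch$stem$pad, training)
  put_rs(pn("stem", "bn"), st)
  r <- relu_fw(st$y)
  caches$stem <- list(conv = st$conv, bn = st$bn, relu = r$cache)
  h <- r$y
  if (arch$use_maxpool) {
    d <- dim(h)
    mp <- maxpool_fw(as.vector(h), d[1], d[2], d[3], d[4], 3L, 2L, 1L)
    caches$maxpool <- list(idx = mp$idx, dims = d)
    h <- mp$out
  }
  cin <- arch$stem$cout
  for (s in seq_along(arch$stages)) {
    stage <- arch$stages[[s]]
    for (b in seq_len(stage$blocks)) {
      pre <- pn("s", s, "b", b)
      stride <- if (b == 1) stage$stride else 1
      bin <- if (b == 1) cin else stage$cout
      identity_in <- h
      u1 <- conv_bn_fw(h, P, rs, pn(pre, "conv1"), pn(pre, "bn1"),
                       stride, 1, training)
      put_rs(pn(pre, "bn1"), u1)
      r1 <- relu_fw(u1$y)
      u2 <- conv_bn_fw(r1$y, P, rs, pn(pre, "conv2"), pn(pre, "bn2"),
                       1, 1, training)
      put_rs(pn(pre, "bn2"), u2)
      has_down <- stride != 1 || bin != stage$cout
      if (has_down) {
        dn <- conv_bn_fw(identity_in, P, rs, pn(pre, "down", "conv"),
                         pn(pre, "down", "bn"), stride, 0, training)
        put_rs(pn(pre, "down", "bn"), dn)
        shortcut <- dn$y
      } else {
        dn <- NULL
        shortcut <- identity_in
      }
      summ <- u2$y + shortcut
      r2 <- relu_fw(summ)
      caches[[pre]] <- list(u1 = u1, relu1 = r1$cache, u2 = u2, down = dn,
                            has_down = has_down, relu2 = r2$cache)
      h <- r2$y
    }
    cin <- stage$cout
  }
  g <- gap_fw(h)
  caches$gap <- g$cache
  z <- g$y                                   # C x N
  pred <- as.vector(crossprod(P[[pn("fc", "w")]], z)) + P[[pn("fc", "b")]]
  caches$fc_in <- z
  list(pred = pred, caches = caches, rs = rs)
}

conv_bn_bw <- function(dy, unit, conv_name, bn_name, G) {
  b <- bn_bw(dy, unit$bn)
  G[[pn(bn_name, "gamma")]] <- b$dgamma
  G[[pn(bn_name, "beta")]] <- b$dbeta
  cv <- conv_bw(b$dx, unit$conv)
  G[[pn(conv_name, "w")]] <- cv$dw
  list(dx = cv$dx, G = G)
}

nn_backward <- function(P, arch, caches, dpred) {
  G <- list()
  z <- caches$fc_in
  n <- length(dpred)
  G[[pn("fc", "w")]] <- z %*% matrix(dpred, ncol = 1)
  G[[pn("fc", "b")]] <- sum(dpred)
  dz <- P[[pn("fc", "w")]] %*% matrix(dpred, nrow = 1)   # C x N
  dh <- gap_bw(dz, caches$gap)
  cin_per_stage <- c(arch$stem$cout,
                     vapply(arch$stages, `[[`, 0, "cout"))
  for (s in rev(seq_along(arch$stages))) {
    stage <- arch$stages[[s]]
    for (b in rev(seq_len(stage$blocks))) {
      pre <- pn("s", s, "b", b)
      cc <- caches[[pre]]
      dsum <- relu_bw(dh, cc$relu2)
      u2b <- conv_bn_bw(dsum, cc$u2, pn(pre, "conv2"), pn(pre, "bn2"), G)
      G <- u2b$G
      dr1 <- relu_bw(u2b$dx, cc$relu1)
      u1b <- conv_bn_bw(dr1, cc$u1, pn(pre, "conv1"), pn(pre, "bn1"), G)
      G <- u1b$G
      if (cc$has_down) {
        dnb <- conv_bn_bw(dsum, cc$down, pn(pre, "down", "conv"),
                          pn(pre, "down", "bn"), G)
        G <- dnb$G
        dh <- u1b$dx + dnb$dx
      } else {
        dh <- u1b$dx + dsum
      }
    }
  }
  if (arch$use_maxpool) {
    d <- caches$maxpool$dims
    dh <- maxpool_bw(as.vector(dh), caches$maxpool$idx, d[1], d[2], d[3], d[4])
  }
  dstem <- relu_bw(dh, caches$stem$relu)
  bb <- bn_bw(dstem, caches$stem$bn)
  G[[pn("stem", "bn", "gamma")]] <- bb$dgamma
  G[[pn("stem", "bn", "beta")]] <- bb$dbeta
  cv <- conv_bw(bb$dx, caches$stem$conv)
  G[[pn("stem", "conv", "w")]] <- cv$dw
  G
}

# ---- optimizer ---------------------------------------------------------

adam_init <- function(P) {
  list(m = lapply(P, function(p) p * 0),
       v = lapply(P, function(p) p * 0), t = 0)
}

adam_step <- function(P, G, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, l2 = 0) {
  state$t <- state$t + 1
  for (nm in names(G)) {
    g <- G[[nm]]
    if (l2 > 0) g <- g + l2 * P[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    P[[nm]] <- P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(P = P, state = state)
}

nn_param_count <- function(P) sum(vapply(P, length, 0L))
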