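# A compact encoder-decoder convolutional network with skip connections
# (U-Net style, 3 resolution levels: s -> s/2 -> s/4), per-pixel sigmoid
# output, binary cross-entropy loss, Adam optimizer. Activations are arrays
# dim (H, W, C, N); convolutions run in compiled code (conv2d_fwd_cpp /
# conv2d_bwd_cpp), pooling/upsampling/ReLU are vectorized R.

.unet_layer_specs <- function(c0) {
  list(
    e1a = c(1, c0, 3), e1b = c(c0, c0, 3),
    e2a = c(c0, 2 * c0, 3), e2b = c(2 * c0, 2 * c0, 3),
    b1 = c(2 * c0, 4 * c0, 3), b2 = c(4 * c0, 4 * c0, 3),
    d2a = c(6 * c0, 2 * c0, 3), d2b = c(2 * c0, 2 * c0, 3),
    d1a = c(3 * c0, c0, 3), d1b = c(c0, c0, 3),
    out = c(c0, 1, 1))
}

unet_init <- function(patch_size, base_channels = 8L, seed = 1L) {
  if (patch_size %% 4 != 0) stop("patch_size must be divisible by 4")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  specs <- .unet_layer_specs(base_channels)
  params <- lapply(specs, function(s) {
    k <- s[3]
    w <- array(rnorm(k * k * s[1] * s[2]) * sqrt(2 / (k * k * s[1])),
               dim = c(k, k, s[1], s[2]))
    list(w = w, b = numeric(s[2]))
  })
  params
}

.conv_f <- function(x, layer) {
  d <- dim(x); wd <- dim(layer$w)
  array(conv2d_fwd_cpp(x, d, layer$w, wd, layer$b),
        dim = c(d[1], d[2], wd[4], d[4]))
}

.conv_b <- function(x, layer, dy) {
  g <- conv2d_bwd_cpp(x, dim(x), layer$w, dim(layer$w), dy)
  list(dx = array(g$dx, dim(x)),
       dw = array(g$dw, dim(layer$w)), db = g$db)
}

.relu <- function(x) { x[x < 0] <- 0; x }

.mp_f <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  p1 <- seq(1L, d[2], 2L); p2 <- seq(2L, d[2], 2L)
  a <- x[o1, p1, , , drop = FALSE]; b <- x[o2, p1, , , drop = FALSE]
  cc <- x[o1, p2, , , drop = FALSE]; e <- x[o2, p2, , , drop = FALSE]
  m <- pmax(a, b, cc, e)
  wa <- a == m; wb <- b == m & !wa; wc <- cc == m & !wa & !wb
  list(y = m, wa = wa, wb = wb, wc = wc, in_dim = d)
}

.mp_b <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  p1 <- seq(1L, d[2], 2L); p2 <- seq(2L, d[2], 2L)
  wd <- !(cache$wa | cache$wb | cache$wc)
  dx[o1, p1, , ] <- dy * cache$wa
  dx[o2, p1, , ] <- dy * cache$wb
  dx[o1, p2, , ] <- dy * cache$wc
  dx[o2, p2, , ] <- dy * wd
  dx
}

.up_f <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

.up_b <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  p1 <- seq(1L, d[2], 2L); p2 <- seq(2L, d[2], 2L)
  dy[o1, p1, , , drop = FALSE] + dy[o2, p1, , , drop = FALSE] +
    dy[o1, p2, , , drop = FALSE] + dy[o2, p2, , , drop = FALSE]
}

.cat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

unet_forward <- function(params, x, cache = FALSE) {
  cc <- list(x0 = x)
  a1a <- .relu(.conv_f(x, params$e1a))
  a1 <- .relu(.conv_f(a1a, params$e1b))
  p1 <- .mp_f(a1)
  a2a <- .relu(.conv_f(p1$y, params$e2a))
  a2 <- .relu(.conv_f(a2a, params$e2b))
  p2 <- .mp_f(a2)
  a3a <- .relu(.conv_f(p2$y, params$b1))
  a3 <- .relu(.conv_f(a3a, params$b2))
  c2 <- .cat_c(.up_f(a3), a2)
  a4a <- .relu(.conv_f(c2, params$d2a))
  a4 <- .relu(.conv_f(a4a, params$d2b))
  c1 <- .cat_c(.up_f(a4), a1)
  a5a <- .relu(.conv_f(c1, params$d1a))
  a5 <- .relu(.conv_f(a5a, params$d1b))
  zo <- .conv_f(a5, params$out)
  p <- 1 / (1 + exp(-zo))
  if (!cache) return(p)
  list(p = p, cache = list(x0 = x, a1a = a1a, a1 = a1, p1 = p1, a2a = a2a,
                           a2 = a2, p2 = p2, a3a = a3a, a3 = a3, c2 = c2,
                           a4a = a4a, a4 = a4, c1 = c1, a5a = a5a, a5 = a5))
}

# dzo is the gradient at the pre-sigmoid output; returns gradients named
# like params
unet_backward <- function(params, cache, dzo) {
  gr <- list()
  g <- .conv_b(cache$a5, params$out, dzo)
  gr$out <- g[c("dw", "db")]
  dz <- g$dx * (cache$a5 > 0)
  g <- .conv_b(cache$a5a, params$d1b, dz)
  gr$d1b <- g[c("dw", "db")]
  dz <- g$dx * (cache$a5a > 0)
  g <- .conv_b(cache$c1, params$d1a, dz)
  gr$d1a <- g[c("dw", "db")]
  cu <- dim(cache$c1)[3] - dim(cache$a1)[3]
  da4 <- .up_b(g$dx[, , seq_len(cu), , drop = FALSE])
  da1_skip <- g$dx[, , cu + seq_len(dim(cache$a1)[3]), , drop = FALSE]

  dz <- da4 * (cache$a4 > 0)
  g <- .conv_b(cache$a4a, params$d2b, dz)
  gr$d2b <- g[c("dw", "db")]
  dz <- g$dx * (cache$a4a > 0)
  g <- .conv_b(cache$c2, params$d2a, dz)
  gr$d2a <- g[c("dw", "db")]
  cu <- dim(cache$c2)[3] - dim(cache$a2)[3]
  da3 <- .up_b(g$dx[, , seq_len(cu), , drop = FALSE])
  da2_skip <- g$dx[, , cu + seq_len(dim(cache$a2)[3]), , drop = FALSE]

  dz <- da3 * (cache$a3 > 0)
  g <- .conv_b(cache$a3a, params$b2, dz)
  gr$b2 <- g[c("dw", "db")]
  dz <- g$dx * (cache$a3a > 0)
  g <- .conv_b(cache$p2$y, params$b1, dz)
  gr$b1 <- g[c("dw", "db")]
  da2 <- .mp_b(g$dx, cache$p2) + da2_skip

  dz <- da2 * (cache$a2 > 0)
  g <- .conv_b(cache$a2a, params$e2b, dz)
  gr$e2b <- g[c("dw", "db")]
  dz <- g$dx * (cache$a2a > 0)
  g <- .conv_b(cache$p1$y, params$e2a, dz)
  gr$e2a <- g[c("dw", "db")]
  da1 <- .mp_b(g$dx, cache$p1) + da1_skip

  dz <- da1 * (cache$a1 > 0)
  g <- .conv_b(cache$a1a, params$e1b, dz)
  gr$e1b <- g[c("dw", "db")]
  dz <- g$dx * (cache$a1a > 0)
  g <- .conv_b(cache$x0, params$e1a, dz)
  gr$e1a <- g[c("dw", "db")]
  gr
}

unet_bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  lapply(params, function(l) list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
                                  mb = numeric(length(l$b)),
                                  vb = numeric(length(l$b))))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$dw
    s$vw <- beta2 * s$vw + (1 - beta2) * g$dw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    params[[nm]]$w <- params[[nm]]$w - lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}
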