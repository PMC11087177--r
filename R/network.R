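#' Model configuration for the segmentation network family
#'
#' One factory configuration covers the whole ladder of architectures:
#' `"unet3d"` (standard isotropic 3D U-Net reference), `"scsp"`
#' (single-channel single-path variant with the anisotropic downsampling
#' schedule, channel attention, and deep supervision), `"mcsp"`
#' (multi-channel single-path: aCT1, aCTV1, CT2 stacked as channels), and
#' `"mcmp"` (multi-channel multi-path: one independent encoder path per
#' input channel, no cross-path mixing before the decoder).
#'
#' Every conv module is a 3x3x3 convolution + instance normalization +
#' LReLU. Downsampling is a stride-2 convolution that doubles the channel
#' count; in the anisotropic schedule the first and last downsampling
#' steps leave the axial dimension unchanged. The decoder upsamples by
#' transposed convolution, concatenates the skip tensors of every path
#' (re-weighted by a squeeze-excitation channel-attention gate), and the
#' deep-supervision heads are 1x1x1 convolutions whose logits are
#' upsampled trilinearly and summed with the final head before softmax.
#'
#' @param variant One of `"unet3d"`, `"scsp"`, `"mcsp"`, `"mcmp"`.
#' @param in_channels 1 or 3; forced to 1 for unet3d/scsp and 3 for mcmp.
#' @param n_classes Number of classes K (background + CTV by default).
#' @param base_filters Filters at the first level; doubled per level.
#' @param n_levels Resolution levels (downsampling steps = n_levels - 1).
#' @param lrelu_alpha LReLU negative slope.
#' @param use_channel_attention Gate the concatenated skip tensors.
#' @param ca_reduction Squeeze-excitation bottleneck reduction ratio.
#' @param deep_supervision_heads Number of auxiliary coarse heads.
#' @return A list of class `model_config`.
#' @export
model_config <- function(variant = c("mcmp", "mcsp", "scsp", "unet3d"),
                         in_channels = NULL, n_classes = 2L,
                         base_filters = 16L, n_levels = 5L,
                         lrelu_alpha = 0.2,
                         use_channel_attention = NULL,
                         ca_reduction = 8L,
                         deep_supervision_heads = 3L) {
  variant <- match.arg(variant)
  default_in <- switch(variant, mcmp = 3L, mcsp = 3L, scsp = 1L,
                       unet3d = 1L)
  in_channels <- as.integer(in_channels %||% default_in)
  if (variant == "mcmp" && in_channels != 3L)
    stop("variant 'mcmp' requires in_channels = 3")
  if (variant %in% c("scsp", "unet3d") && in_channels != 1L)
    stop("variant '", variant, "' requires in_channels = 1")
  if (is.null(use_channel_attention))
    use_channel_attention <- variant != "unet3d"
  if (variant == "unet3d") {
    use_channel_attention <- FALSE
    deep_supervision_heads <- 0L
  }
  structure(list(variant = variant, in_channels = in_channels,
                 n_classes = as.integer(n_classes),
                 base_filters = as.integer(base_filters),
                 n_levels = as.integer(n_levels),
                 lrelu_alpha = lrelu_alpha,
                 use_channel_attention = use_channel_attention,
                 ca_reduction = as.integer(ca_reduction),
                 deep_supervision_heads =
                   as.integer(deep_supervision_heads)),
            class = "model_config")
}

# Stride of downsampling step l (1-based, of n_levels - 1 steps).
step_stride <- function(cfg, l) {
  if (cfg$variant == "unet3d") return(c(2L, 2L, 2L))
  if (l == 1L || l == cfg$n_levels - 1L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
}

he_normal <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a segmentation network
#'
#' Instantiates parameters for the configured architecture with
#' "he_normal" initialization; two builds from the same `(config, seed)`
#' are identical.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the initialization.
#' @return A list of class `rg_network` with elements `cfg`, `arch`, and
#'   the flat parameter list `params`.
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  L <- cfg$n_levels
  P <- if (cfg$variant == "mcmp") 3L else 1L
  path_in <- if (cfg$variant == "mcmp") 1L else cfg$in_channels
  ch <- cfg$base_filters * 2L^(seq_len(L) - 1L)
  K <- cfg$n_classes
  n_dec <- L - 1L
  ds_levels <- if (cfg$deep_supervision_heads > 0L)
    seq(n_dec, by = -1L, length.out = min(cfg$deep_supervision_heads,
                                          max(n_dec - 1L, 0L)))
  else integer(0)
  # channel-attention feasibility on the concatenated skip tensors
  if (cfg$use_channel_attention) {
    for (d in seq_len(n_dec)) {
      S <- P * ch[d]
      if (cfg$ca_reduction > S)
        stop("ca_reduction (", cfg$ca_reduction,
             ") exceeds the skip channel count (", S, ") at depth ", d)
      if (S %% cfg$ca_reduction != 0L)
        stop("skip channel count (", S, ") at depth ", d,
             " is not divisible by ca_reduction (", cfg$ca_reduction, ")")
    }
  }
  params <- list()
  with_seed(seed, {
    add_cm <- function(pfx, cin, cout, k = c(3L, 3L, 3L)) {
      params[[paste0(pfx, ".W")]] <<- he_normal(c(k, cin, cout),
                                                prod(k) * cin)
      params[[paste0(pfx, ".b")]] <<- numeric(cout)
      params[[paste0(pfx, ".g")]] <<- rep(1, cout)
      params[[paste0(pfx, ".be")]] <<- numeric(cout)
    }
    for (p in seq_len(P)) {
      for (l in seq_len(L)) {
        cin <- if (l == 1L) path_in else ch[l]
        add_cm(sprintf("enc%d.l%d.c1", p, l), cin, ch[l])
        add_cm(sprintf("enc%d.l%d.c2", p, l), ch[l], ch[l])
        if (l < L) {
          # stride-2 downsampling conv, doubling channels
          add_cm(sprintf("enc%d.d%d", p, l), ch[l], ch[l + 1L])
        }
      }
    }
    for (d in seq(n_dec, 1L)) {
      cin_up <- if (d == n_dec) P * ch[L] else ch[d + 1L]
      s <- step_stride(cfg, d)
      params[[sprintf("dec.l%d.up.W", d)]] <-
        he_normal(c(s, cin_up, ch[d]), cin_up)
      params[[sprintf("dec.l%d.up.b", d)]] <- numeric(ch[d])
      params[[sprintf("dec.l%d.up.g", d)]] <- rep(1, ch[d])
      params[[sprintf("dec.l%d.up.be", d)]] <- numeric(ch[d])
      if (cfg$use_channel_attention) {
        S <- P * ch[d]
        H <- S %/% cfg$ca_reduction
        params[[sprintf("dec.l%d.ca.W1", d)]] <-
          matrix(rnorm(H * S, 0, sqrt(2 / S)), H, S)
        params[[sprintf("dec.l%d.ca.b1", d)]] <- numeric(H)
        # zero-initialized excitation: gates start neutral at 0.5
        params[[sprintf("dec.l%d.ca.W2", d)]] <- matrix(0, S, H)
        params[[sprintf("dec.l%d.ca.b2", d)]] <- numeric(S)
      }
      add_cm(sprintf("dec.l%d.c1", d), P * ch[d] + ch[d], ch[d])
      add_cm(sprintf("dec.l%d.c2", d), ch[d], ch[d])
    }
    for (d in unique(c(1L, ds_levels))) {
      params[[sprintf("head.l%d.W", d)]] <-
        he_normal(c(1L, 1L, 1L, ch[d], K), ch[d])
      params[[sprintf("head.l%d.b", d)]] <- numeric(K)
    }
  })
  structure(list(cfg = cfg, params = params,
                 arch = list(P = P, L = L, channels = ch, K = K,
                             path_in = path_in, n_dec = n_dec,
                             ds_levels = ds_levels,
                             strides = lapply(seq_len(L - 1L),
                                              function(l)
                                                step_stride(cfg, l)),
                             seed = seed)),
            class = "rg_network")
}

#' @export
print.rg_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<rg_network> variant %s, %d path(s), %d levels, %s params\n",
              x$cfg$variant, x$arch$P, x$arch$L, format(np, big.mark = ",")))
  invisible(x)
}

# ---- primitive layers (forward + backward) --------------------------------

# conv module: conv(k=3, given stride) + instance norm + LReLU
cm_fw <- function(x, W, b, g, be, stride, alpha) {
  kd <- dim(W)
  y <- cpp_conv3d_fw(x, dim(x), W, kd, b, as.integer(stride))
  inr <- cpp_instnorm_fw(y, dim(y), g, be, 1e-5)
  act <- cpp_lrelu_fw(inr$y, alpha)
  list(y = act, cache = list(x = x, xd = dim(x), kd = kd, yd = dim(y),
                             xhat = inr$xhat, istd = inr$istd, act = act,
                             stride = as.integer(stride)))
}

cm_bw <- function(dy, cache, W, g, alpha) {
  d1 <- cpp_lrelu_bw(dy, cache$act, alpha)
  d2 <- cpp_instnorm_bw(d1, cache$xhat, cache$istd, g, cache$yd)
  d3 <- cpp_conv3d_bw(cache$x, cache$xd, W, cache$kd, d2$dx, cache$stride)
  list(dx = d3$dx, dW = d3$dw, db = d3$db, dg = d2$dg, dbe = d2$dbe)
}

# transposed-conv module (kernel == stride) + instance norm + LReLU
up_fw <- function(x, W, b, g, be, stride, alpha) {
  cout <- dim(W)[5]
  y <- cpp_convT3d_fw(x, dim(x), W, as.integer(stride), b, cout)
  inr <- cpp_instnorm_fw(y, dim(y), g, be, 1e-5)
  act <- cpp_lrelu_fw(inr$y, alpha)
  list(y = act, cache = list(x = x, xd = dim(x), cout = cout, yd = dim(y),
                             xhat = inr$xhat, istd = inr$istd, act = act,
                             stride = as.integer(stride)))
}

up_bw <- function(dy, cache, W, g, alpha) {
  d1 <- cpp_lrelu_bw(dy, cache$act, alpha)
  d2 <- cpp_instnorm_bw(d1, cache$xhat, cache$istd, g, cache$yd)
  d3 <- cpp_convT3d_bw(cache$x, cache$xd, W, cache$stride, cache$cout,
                       d2$dx)
  list(dx = d3$dx, dW = d3$dw, db = d3$db, dg = d2$dg, dbe = d2$dbe)
}

ca_fw <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  C <- d[4]
  n <- prod(d[1:3])
  xm <- matrix(x, n, C)
  s <- colMeans(xm)
  z1 <- as.numeric(W1 %*% s + b1)
  a1 <- pmax(z1, 0)
  z2 <- as.numeric(W2 %*% a1 + b2)
  gate <- 1 / (1 + exp(-z2))
  y <- sweep(xm, 2, gate, "*")
  list(y = array(y, d), cache = list(xm = xm, s = s, z1 = z1, a1 = a1,
                                     gate = gate, d = d))
}

ca_bw <- function(dy, cache, W1, W2) {
  d <- cache$d
  C <- d[4]
  n <- prod(d[1:3])
  dym <- matrix(dy, n, C)
  dgate <- colSums(dym * cache$xm)
  dxm <- sweep(dym, 2, cache$gate, "*")
  dz2 <- dgate * cache$gate * (1 - cache$gate)
  dW2 <- dz2 %o% cache$a1
  db2 <- dz2
  da1 <- as.numeric(t(W2) %*% dz2)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- dz1 %o% cache$s
  db1 <- dz1
  ds <- as.numeric(t(W1) %*% dz1)
  dxm <- dxm + matrix(ds / n, n, C, byrow = TRUE)
  list(dx = array(dxm, d), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Squeeze-excitation channel attention
#'
#' Global-average-pools the feature map per channel, passes the squeeze
#' vector through a reduction bottleneck, and rescales each channel by a
#' sigmoid gate in (0, 1). With the default neutral excitation weights
#' (zero-initialized, as in the network) every gate is 0.5.
#'
#' @param features 4D feature array `[x, y, z, channels]`.
#' @param reduction Bottleneck reduction; must divide the channel count
#'   and not exceed it.
#' @param params Optional list with `W1`, `b1`, `W2`, `b2`; defaults to a
#'   seeded he_normal squeeze and zero excitation.
#' @return A list with the gated `features` and the per-channel `gates`.
#' @export
channel_attention <- function(features, reduction, params = NULL) {
  d <- dim(features)
  if (length(d) != 4L) stop("features must be a 4D array")
  C <- d[4]
  if (reduction > C)
    stop("reduction (", reduction, ") exceeds the channel count (", C, ")")
  if (C %% reduction != 0L)
    stop("channel count (", C, ") must be divisible by the reduction (",
         reduction, ")")
  if (is.null(params)) {
    H <- C %/% reduction
    params <- with_seed(0L, list(W1 = matrix(rnorm(H * C, 0,
                                                   sqrt(2 / C)), H, C),
                                 b1 = numeric(H),
                                 W2 = matrix(0, C, H), b2 = numeric(C)))
  }
  r <- ca_fw(features, params$W1, params$b1, params$W2, params$b2)
  list(features = r$y, gates = r$cache$gate)
}

softmax_classes <- function(logits) {
  d <- dim(logits)
  K <- d[4]
  m <- matrix(logits, ncol = K)
  mx <- m[, 1]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, m[, k])
  e <- exp(m - mx)
  array(e / rowSums(e), d)
}

concat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:3]
  cs <- vapply(xs, function(a) dim(a)[4], integer(1))
  out <- array(0, c(d, sum(cs)))
  at <- 0L
  for (a in xs) {
    out[, , , at + seq_len(dim(a)[4])] <- a
    at <- at + dim(a)[4]
  }
  out
}

check_input_shape <- function(net, d) {
  ax_names <- c("x (lateral)", "y (lateral)", "z (axial)")
  cur <- d[1:3]
  for (l in seq_len(net$arch$L - 1L)) {
    s <- net$arch$strides[[l]]
    for (ax in 1:3) {
      if (cur[ax] %% s[ax] != 0L)
        stop("input axis ", ax_names[ax], " has extent ", cur[ax],
             " which is not divisible by stride ", s[ax],
             " at downsampling step ", l)
    }
    cur <- cur %/% s
  }
  invisible(NULL)
}

as_input_array <- function(net, x) {
  if (is.list(x) && !is.null(x$ct2)) {
    chans <- if (net$cfg$in_channels == 3L)
      list(x$act1, x$actv1, x$ct2) else list(x$ct2)
    chans <- lapply(chans, function(v)
      if (inherits(v, "rg_volume")) v$data else v)
    d <- dim(chans[[1]])
    arr <- array(0, c(d, length(chans)))
    for (i in seq_along(chans)) arr[, , , i] <- chans[[i]]
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  stop("input must be a 4D array, a 3D array, or an aligned-inputs list")
}

# Full forward pass. Returns probs, the combined logits, and (optionally)
# every intermediate cache needed for backprop.
net_forward <- function(net, x, want_cache = FALSE) {
  a <- net$arch
  cfg <- net$cfg
  x <- as_input_array(net, x)
  d <- dim(x)
  if (d[4] != cfg$in_channels)
    stop("input has ", d[4], " channels; expected ", cfg$in_channels)
  check_input_shape(net, d)
  pr <- net$params
  alpha <- cfg$lrelu_alpha
  caches <- if (want_cache) list(enc = vector("list", a$P),
                                 dec = list(), heads = list()) else NULL
  skips <- vector("list", a$P)
  bots <- vector("list", a$P)
  for (p in seq_len(a$P)) {
    h <- if (a$P == 3L) x[, , , p, drop = FALSE] else x
    skips[[p]] <- vector("list", a$n_dec)
    if (want_cache) caches$enc[[p]] <- list()
    for (l in seq_len(a$L)) {
      for (j in 1:2) {
        pfx <- sprintf("enc%d.l%d.c%d", p, l, j)
        r <- cm_fw(h, pr[[paste0(pfx, ".W")]], pr[[paste0(pfx, ".b")]],
                   pr[[paste0(pfx, ".g")]], pr[[paste0(pfx, ".be")]],
                   c(1L, 1L, 1L), alpha)
        h <- r$y
        if (want_cache) caches$enc[[p]][[pfx]] <- r$cache
      }
      if (l < a$L) {
        skips[[p]][[l]] <- h
        pfx <- sprintf("enc%d.d%d", p, l)
        r <- cm_fw(h, pr[[paste0(pfx, ".W")]], pr[[paste0(pfx, ".b")]],
                   pr[[paste0(pfx, ".g")]], pr[[paste0(pfx, ".be")]],
                   a$strides[[l]], alpha)
        h <- r$y
        if (want_cache) caches$enc[[p]][[pfx]] <- r$cache
      }
    }
    bots[[p]] <- h
  }
  dec <- do.call(concat_channels, bots)
  logits_at <- list()
  for (dlev in seq(a$n_dec, 1L)) {
    pfx <- sprintf("dec.l%d", dlev)
    r <- up_fw(dec, pr[[paste0(pfx, ".up.W")]], pr[[paste0(pfx, ".up.b")]],
               pr[[paste0(pfx, ".up.g")]], pr[[paste0(pfx, ".up.be")]],
               a$strides[[dlev]], alpha)
    if (want_cache) caches$dec[[paste0(pfx, ".up")]] <- r$cache
    up <- r$y
    skipcat <- do.call(concat_channels,
                       lapply(seq_len(a$P), function(p)
                         skips[[p]][[dlev]]))
    if (cfg$use_channel_attention) {
      rca <- ca_fw(skipcat, pr[[paste0(pfx, ".ca.W1")]],
                   pr[[paste0(pfx, ".ca.b1")]],
                   pr[[paste0(pfx, ".ca.W2")]],
                   pr[[paste0(pfx, ".ca.b2")]])
      skipcat <- rca$y
      if (want_cache) caches$dec[[paste0(pfx, ".ca")]] <- rca$cache
    }
    h <- concat_channels(skipcat, up)
    for (j in 1:2) {
      cp <- sprintf("%s.c%d", pfx, j)
      r <- cm_fw(h, pr[[paste0(cp, ".W")]], pr[[paste0(cp, ".b")]],
                 pr[[paste0(cp, ".g")]], pr[[paste0(cp, ".be")]],
                 c(1L, 1L, 1L), alpha)
      h <- r$y
      if (want_cache) caches$dec[[cp]] <- r$cache
    }
    dec <- h
    if (dlev == 1L || dlev %in% a$ds_levels) {
      hp <- sprintf("head.l%d", dlev)
      kd <- dim(pr[[paste0(hp, ".W")]])
      lg <- cpp_conv3d_fw(dec, dim(dec), pr[[paste0(hp, ".W")]], kd,
                          pr[[paste0(hp, ".b")]], c(1L, 1L, 1L))
      logits_at[[as.character(dlev)]] <- lg
      if (want_cache)
        caches$heads[[hp]] <- list(x = dec, xd = dim(dec), kd = kd)
    }
  }
  full_d <- dim(logits_at[["1"]])[1:3]
  combined <- logits_at[["1"]]
  for (dlev in a$ds_levels) {
    lg <- logits_at[[as.character(dlev)]]
    f <- as.integer(full_d / dim(lg)[1:3])
    combined <- combined + cpp_upsample3_fw(lg, dim(lg), f)
  }
  probs <- softmax_classes(combined)
  list(probs = probs, logits = combined, logits_at = logits_at,
       caches = caches, skips_dims = lapply(skips[[1]], dim))
}

#' Forward pass: per-voxel class probabilities
#'
#' Runs the network on normalized aligned inputs and returns a valid
#' probability map (K channels summing to 1 per voxel) at the input
#' resolution, combining the deep-supervision heads by trilinear
#' upsampling before the softmax. Evaluation is deterministic.
#'
#' @param net An [build_model()] network.
#' @param x A 4D array `[x, y, z, channels]`, a 3D single-channel array,
#'   or a list with `act1`, `actv1`, `ct2` volumes.
#' @return 4D array of class probabilities.
#' @export
forward <- function(net, x) {
  net_forward(net, x, want_cache = FALSE)$probs
}

#' Predicted binary mask for one input
#'
#' @inheritParams forward
#' @return 3D integer array, 1 where the CTV class has the highest
#'   probability.
#' @export
predict_mask <- function(net, x) {
  p <- forward(net, x)
  d <- dim(p)
  array(as.integer(p[, , , 2] >= p[, , , 1]), d[1:3])
}

# Full backward pass. dlogits: gradient wrt the combined logits.
# Returns the flat gradient list (same names as params).
net_backward <- function(net, fwd, dlogits) {
  a <- net$arch
  cfg <- net$cfg
  pr <- net$params
  alpha <- cfg$lrelu_alpha
  caches <- fwd$caches
  grads <- new.env(parent = emptyenv())
  acc <- function(name, val) {
    cur <- grads[[name]]
    grads[[name]] <- if (is.null(cur)) val else cur + val
  }
  # distribute the combined-logit gradient to the heads
  dlog_at <- list()
  dlog_at[["1"]] <- dlogits
  for (dlev in a$ds_levels) {
    lg <- fwd$logits_at[[as.character(dlev)]]
    f <- as.integer(dim(dlogits)[1:3] / dim(lg)[1:3])
    dlog_at[[as.character(dlev)]] <- cpp_upsample3_adj(dlogits, dim(lg), f)
  }
  dskip <- vector("list", a$P)  # per path, per level
  for (p in seq_len(a$P)) dskip[[p]] <- vector("list", a$n_dec)
  ddec <- NULL  # gradient wrt decoder output at the current level
  for (dlev in seq_len(a$n_dec)) {  # walk from full-res back to coarse
    pfx <- sprintf("dec.l%d", dlev)
    dh <- if (is.null(ddec)) NULL else ddec
    dl <- dlog_at[[as.character(dlev)]]
    if (!is.null(dl)) {
      hp <- sprintf("head.l%d", dlev)
      hc <- caches$heads[[hp]]
      hb <- cpp_conv3d_bw(hc$x, hc$xd, pr[[paste0(hp, ".W")]], hc$kd, dl,
                          c(1L, 1L, 1L))
      acc(paste0(hp, ".W"), hb$dw)
      acc(paste0(hp, ".b"), hb$db)
      dh <- if (is.null(dh)) hb$dx else dh + hb$dx
    }
    for (j in 2:1) {
      cp <- sprintf("%s.c%d", pfx, j)
      r <- cm_bw(dh, caches$dec[[cp]], pr[[paste0(cp, ".W")]],
                 pr[[paste0(cp, ".g")]], alpha)
      acc(paste0(cp, ".W"), r$dW)
      acc(paste0(cp, ".b"), r$db)
      acc(paste0(cp, ".g"), r$dg)
      acc(paste0(cp, ".be"), r$dbe)
      dh <- r$dx
    }
    # split into skip-concat part and upsampled part
    S <- a$P * a$channels[dlev]
    dskipcat <- dh[, , , seq_len(S), drop = FALSE]
    dup <- dh[, , , S + seq_len(a$channels[dlev]), drop = FALSE]
    if (cfg$use_channel_attention) {
      r <- ca_bw(dskipcat, caches$dec[[paste0(pfx, ".ca")]],
                 pr[[paste0(pfx, ".ca.W1")]], pr[[paste0(pfx, ".ca.W2")]])
      acc(paste0(pfx, ".ca.W1"), r$dW1)
      acc(paste0(pfx, ".ca.b1"), r$db1)
      acc(paste0(pfx, ".ca.W2"), r$dW2)
      acc(paste0(pfx, ".ca.b2"), r$db2)
      dskipcat <- r$dx
    }
    for (p in seq_len(a$P)) {
      C <- a$channels[dlev]
      dskip[[p]][[dlev]] <- dskipcat[, , , (p - 1L) * C + seq_len(C),
                                     drop = FALSE]
    }
    r <- up_bw(dup, caches$dec[[paste0(pfx, ".up")]],
               pr[[paste0(pfx, ".up.W")]], pr[[paste0(pfx, ".up.g")]],
               alpha)
    acc(paste0(pfx, ".up.W"), r$dW)
    acc(paste0(pfx, ".up.b"), r$db)
    acc(paste0(pfx, ".up.g"), r$dg)
    acc(paste0(pfx, ".up.be"), r$dbe)
    ddec <- r$dx
  }
  # ddec now holds the gradient wrt the concatenated bottleneck
  CL <- a$channels[a$L]
  for (p in seq_len(a$P)) {
    dh <- ddec[, , , (p - 1L) * CL + seq_len(CL), drop = FALSE]
    for (l in seq(a$L, 1L)) {
      if (l < a$L) {
        pfx <- sprintf("enc%d.d%d", p, l)
        r <- cm_bw(dh, caches$enc[[p]][[pfx]], pr[[paste0(pfx, ".W")]],
                   pr[[paste0(pfx, ".g")]], alpha)
        acc(paste0(pfx, ".W"), r$dW)
        acc(paste0(pfx, ".b"), r$db)
        acc(paste0(pfx, ".g"), r$dg)
        acc(paste0(pfx, ".be"), r$dbe)
        dh <- r$dx + dskip[[p]][[l]]
      }
      for (j in 2:1) {
        pfx <- sprintf("enc%d.l%d.c%d", p, l, j)
        r <- cm_bw(dh, caches$enc[[p]][[pfx]], pr[[paste0(pfx, ".W")]],
                   pr[[paste0(pfx, ".g")]], alpha)
        acc(paste0(pfx, ".W"), r$dW)
        acc(paste0(pfx, ".b"), r$db)
        acc(paste0(pfx, ".g"), r$dg)
        acc(paste0(pfx, ".be"), r$dbe)
        dh <- r$dx
      }
    }
  }
  as.list(grads)
}

#' Architecture audit: shapes and parameter counts
#'
#' Computes, without running a forward pass, the spatial feature shapes
#' along the encoder for a given input shape, and splits the trainable
#' parameter count into encoder paths, decoder, and heads.
#'
#' @param net An `rg_network`.
#' @param input_shape Spatial voxel triple.
#' @return A list with `encoder_shapes` (matrix, levels x 3),
#'   `parameters` (named totals), and `encoder_path_parameters` (one
#'   count per path).
#' @export
model_audit <- function(net, input_shape = c(192, 160, 48)) {
  a <- net$arch
  shapes <- matrix(0L, a$L, 3)
  cur <- as.integer(input_shape)
  shapes[1, ] <- cur
  for (l in seq_len(a$L - 1L)) {
    cur <- cur %/% a$strides[[l]]
    shapes[l + 1L, ] <- cur
  }
  colnames(shapes) <- c("x", "y", "z")
  nm <- names(net$params)
  count <- function(pat) sum(vapply(net$params[grepl(pat, nm)], length,
                                    integer(1)))
  path_counts <- vapply(seq_len(a$P), function(p)
    count(sprintf("^enc%d\\.", p)), numeric(1))
  list(encoder_shapes = shapes,
       parameters = c(encoder = count("^enc"), decoder = count("^dec"),
                      heads = count("^head"),
                      total = count(".")),
       encoder_path_parameters = path_counts)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameters with the embedded model
#' configuration.
#'
#' @param net An `rg_network`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the restored network (load).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = unclass(net$cfg), params = net$params,
               arch = net$arch), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(cfg = structure(obj$cfg, class = "model_config"),
                 params = obj$params, arch = obj$arch),
            class = "rg_network")
}
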