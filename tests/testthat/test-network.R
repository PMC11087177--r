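test_that("the encoder follows the anisotropic downsampling schedule", {
  net <- build_model(model_config("mcmp"), seed = 0)
  aud <- model_audit(net, c(192, 160, 48))
  expect_equal(aud$encoder_shapes[, "z"], c(48, 48, 24, 12, 12))
  expect_equal(aud$encoder_shapes[, "x"], c(192, 96, 48, 24, 12))
  expect_equal(aud$encoder_shapes[, "y"], c(160, 80, 40, 20, 10))
})

test_that("the multi-path encoder has three equal, independent paths", {
  net <- build_model(model_config("mcmp", base_filters = 16), seed = 0)
  nets <- build_model(model_config("scsp", base_filters = 16), seed = 0)
  a <- model_audit(net)
  s <- model_audit(nets)
  expect_length(a$encoder_path_parameters, 3)
  expect_true(all(a$encoder_path_parameters ==
                    a$encoder_path_parameters[1]))
  # single-channel paths: the mcmp encoder is exactly 3x the scsp encoder
  expect_equal(unname(a$parameters["encoder"]),
               3 * unname(s$parameters["encoder"]))
})

test_that("encoder paths are cross-talk free before the decoder", {
  cfg <- model_config("mcmp", base_filters = 2, n_levels = 3,
                      ca_reduction = 2)
  net <- build_model(cfg, seed = 1)
  set.seed(2)
  x <- array(runif(16 * 16 * 8 * 3), c(16, 16, 8, 3))
  x2 <- x
  x2[, , , 2] <- runif(16 * 16 * 8)  # perturb only channel 2
  f1 <- rgmcmp:::net_forward(net, x, want_cache = TRUE)
  f2 <- rgmcmp:::net_forward(net, x2, want_cache = TRUE)
  # encoder activations of paths 1 and 3 are untouched by channel 2
  for (p in c(1, 3)) {
    for (nm in names(f1$caches$enc[[p]])) {
      expect_identical(f1$caches$enc[[p]][[nm]]$x,
                       f2$caches$enc[[p]][[nm]]$x)
    }
  }
  # ... while the combined output is not (channel 2 is live)
  expect_false(identical(f1$probs, f2$probs))
})

test_that("forward produces a valid, deterministic probability map", {
  cfg <- model_config("mcmp", base_filters = 2, n_levels = 3,
                      ca_reduction = 2)
  net <- build_model(cfg, seed = 3)
  set.seed(4)
  x <- array(runif(16 * 16 * 8 * 3), c(16, 16, 8, 3))
  p <- forward(net, x)
  expect_equal(dim(p), c(16, 16, 8, 2))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-5)
  expect_identical(p, forward(net, x))
  expect_error(forward(net, array(0, c(15, 16, 8, 3))), "not divisible")
  expect_error(forward(net, array(0, c(16, 16, 8, 2))), "channels")
})

test_that("two builds from the same configuration and seed are identical", {
  cfg <- model_config("scsp", base_filters = 4, n_levels = 3,
                      ca_reduction = 4)
  expect_identical(build_model(cfg, seed = 9), build_model(cfg, seed = 9))
  expect_false(identical(build_model(cfg, seed = 9)$params,
                         build_model(cfg, seed = 10)$params))
})

test_that("unet3d and scsp differ but accept the same input", {
  u <- build_model(model_config("unet3d", base_filters = 2, n_levels = 3),
                   seed = 0)
  s <- build_model(model_config("scsp", base_filters = 2, n_levels = 3,
                                ca_reduction = 2), seed = 0)
  expect_false(u$cfg$use_channel_attention)
  expect_equal(u$cfg$deep_supervision_heads, 0L)
  expect_true(s$cfg$use_channel_attention)
  # unet3d downsampling is isotropic, scsp preserves the axial dimension
  expect_equal(model_audit(u, c(16, 16, 8))$encoder_shapes[, "z"],
               c(8, 4, 2))
  expect_equal(model_audit(s, c(16, 16, 8))$encoder_shapes[, "z"],
               c(8, 8, 8))
  x <- array(runif(16 * 16 * 8), c(16, 16, 8, 1))
  expect_equal(dim(forward(u, x)), dim(forward(s, x)))
})

test_that("configuration constraints are enforced", {
  expect_error(model_config("mcmp", in_channels = 1), "in_channels = 3")
  expect_error(model_config("scsp", in_channels = 3), "in_channels = 1")
  expect_error(build_model(model_config("scsp", base_filters = 4,
                                        n_levels = 3, ca_reduction = 64)),
               "exceeds")
  expect_error(build_model(model_config("scsp", base_filters = 6,
                                        n_levels = 3, ca_reduction = 4)),
               "divisible")
})

test_that("channel attention gates are shape-preserving channel scalings", {
  set.seed(5)
  x <- array(rnorm(6 * 6 * 4 * 8), c(6, 6, 4, 8))
  r <- channel_attention(x, reduction = 4)
  expect_equal(dim(r$features), dim(x))
  expect_true(all(r$gates > 0 & r$gates < 1))
  # per-channel output/input ratio is constant across voxels
  for (c in 1:8) {
    ratio <- r$features[, , , c] / x[, , , c]
    expect_lt(diff(range(ratio)), 1e-12)
    expect_equal(ratio[1], r$gates[c], tolerance = 1e-12)
  }
  # identical channels receive equal gates under the neutral excitation
  xi <- array(rep(rnorm(6 * 6 * 4), 8), c(6, 6, 4, 8))
  ri <- channel_attention(xi, reduction = 4)
  expect_lt(diff(range(ri$gates)), 1e-12)
  # zero input stays zero
  r0 <- channel_attention(array(0, c(4, 4, 2, 4)), reduction = 2)
  expect_true(all(r0$features == 0))
  expect_error(channel_attention(x, reduction = 16), "exceeds")
  expect_error(channel_attention(array(0, c(4, 4, 2, 6)), reduction = 4),
               "divisible")
})

test_that("backpropagation matches finite differences through the full
           architecture", {
  cfg <- model_config("mcmp", base_filters = 2, n_levels = 3,
                      ca_reduction = 2)
  net <- build_model(cfg, seed = 3)
  set.seed(6)
  x <- array(runif(16 * 16 * 8 * 3), c(16, 16, 8, 3))
  y <- rgmcmp:::one_hot(random_mask(c(16, 16, 8), 0.3))
  lc <- loss_config()
  fwd <- rgmcmp:::net_forward(net, x, want_cache = TRUE)
  g <- rgmcmp:::net_backward(net, fwd,
                             rgmcmp:::loss_grad_logits(fwd$probs, y, lc))
  f <- function(params) {
    n2 <- net
    n2$params <- params
    total_loss(rgmcmp:::net_forward(n2, x, FALSE)$probs, y, lc)
  }
  eps <- 1e-5
  for (nm in sample(names(g), 8)) {
    i <- sample(length(net$params[[nm]]), 1)
    pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (f(pp) - f(pm)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip parameters and configuration", {
  net <- build_model(tiny_model("mcsp"), seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, net$params)
  expect_equal(unclass(back$cfg), unclass(net$cfg))
  set.seed(1)
  x <- array(runif(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  expect_identical(forward(back, x), forward(net, x))
})
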