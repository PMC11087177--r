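toy_sample <- function(seed, dims = c(8, 8, 4)) {
  set.seed(seed)
  x <- array(runif(prod(dims)), c(dims, 1))
  m <- array(0L, dims)
  m[3:6, 3:6, 2:3] <- 1L
  x[, , , 1] <- x[, , , 1] + 0.5 * m
  list(x = x, y = rgmcmp:::one_hot(m))
}

test_that("training configuration constraints hold", {
  expect_error(train_config(lr_factor = 1.2), "lr_factor")
  expect_error(train_config(lr_patience = 30, stop_patience = 10),
               "stop_patience")
  expect_error(train(build_model(tiny_model("scsp")), list(),
                     list(toy_sample(1))), "nonempty")
})

test_that("training is reproducible from the seed", {
  s1 <- toy_sample(1)
  s2 <- toy_sample(2)
  net <- build_model(tiny_model("scsp"), seed = 4)
  cfg <- train_config(initial_lr = 1e-3, max_epochs = 6, seed = 11)
  f1 <- train(net, list(s1, s2), list(s1), cfg = cfg)
  f2 <- train(net, list(s1, s2), list(s1), cfg = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
})

test_that("the plateau schedule drops the learning rate after 30 stalled
           epochs and stops after 50", {
  # a vanishing learning rate freezes the model, so the validation loss
  # plateaus at epoch 1 by construction
  s <- toy_sample(3)
  net <- build_model(tiny_model("scsp"), seed = 1)
  cfg <- train_config(initial_lr = 1e-30, max_epochs = 200, seed = 2)
  fit <- train(net, list(s), list(s), cfg = cfg)
  h <- fit$history
  expect_equal(fit$best_epoch, 1L)
  expect_equal(nrow(h), 51L)               # stops at best + 50
  expect_equal(h$lr[2:31], rep(1e-30, 30)) # unchanged through the stall
  expect_equal(h$lr[32:51] / h$lr[2:21], rep(0.2, 20),
               tolerance = 1e-12)          # one 0.2x drop at best + 30
  # frozen model: returned parameters are the initialization
  expect_equal(fit$net$params, net$params, tolerance = 1e-20)
})

test_that("the returned checkpoint attains the minimum validation loss", {
  s1 <- toy_sample(5)
  s2 <- toy_sample(6)
  net <- build_model(tiny_model("scsp"), seed = 2)
  cfg <- train_config(initial_lr = 5e-3, max_epochs = 12, seed = 3)
  fit <- train(net, list(s1), list(s2), cfg = cfg)
  got <- rgmcmp:::sample_loss(fit$net, s2, loss_config())
  expect_equal(got, min(fit$history$val_loss), tolerance = 1e-10)
  expect_equal(fit$history$val_loss[fit$best_epoch],
               min(fit$history$val_loss))
})

test_that("a small multi-path model overfits a phantom cohort", {
  p <- tiny_phantom(grid_shape = c(24, 24, 16),
                    target_radii_mm = c(10, 8, 7), ctv_margin_mm = 5,
                    rigid_offset_mm = c(3, 2, 1),
                    deform_amplitude_mm = 4)
  cohort <- generate_cohort(5, p, seed = 1)
  pre <- preprocess_config(slab_slices = 12, target_shape = c(16, 16, 12))
  samples <- lapply(cohort, function(case) {
    # guidance from the stored ground-truth transform: the trainer is
    # under test here, not the registration stage
    act1 <- propagate(case$ct1, case$true_transform, grid_of(case$ct2))
    actv1 <- propagate(case$ctv1, case$true_transform, grid_of(case$ct2))
    u <- rg_mask(array(as.integer(actv1$data | case$ctv2$data),
                       vol_dims(actv1)), actv1$spacing, actv1$origin)
    slab <- extract_slab(case$ct2, u, pre)
    zr <- slab$slab
    d <- vol_dims(case$ct2)
    sub <- function(v) rgmcmp:::crop_volume(v, c(1L, d[1]), c(1L, d[2]),
                                            zr)
    rs2 <- resample_to_grid(sub(case$ct2), sub(case$ctv2), pre)
    rs1 <- resample_to_grid(sub(act1), sub(actv1), pre)
    x <- array(0, c(16, 16, 12, 3))
    x[, , , 1] <- normalize_hu(rs1$vol, pre)$data
    x[, , , 2] <- rs1$mask$data
    x[, , , 3] <- normalize_hu(rs2$vol, pre)$data
    list(x = x, y = rgmcmp:::one_hot(rs2$mask$data))
  })
  net <- build_model(model_config("mcmp", base_filters = 2, n_levels = 2,
                                  ca_reduction = 2), seed = 7)
  fit <- train(net, samples, samples[1],
               cfg = train_config(initial_lr = 5e-3, max_epochs = 100,
                                  seed = 7))
  expect_lt(min(fit$history$train_loss), 0.1)
  # the guidance channel is live: zeroing it changes the output
  x <- samples[[1]]$x
  x0 <- x
  x0[, , , 2] <- 0
  expect_false(identical(forward(fit$net, x), forward(fit$net, x0)))
})
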