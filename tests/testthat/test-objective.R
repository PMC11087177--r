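uniform_case <- function(p_true, dims = c(4, 4, 2)) {
  y <- rgmcmp:::one_hot(random_mask(dims, 0.4))
  p <- array(0, dim(y))
  p[, , , 1] <- ifelse(y[, , , 1] == 1, p_true, 1 - p_true)
  p[, , , 2] <- 1 - p[, , , 1]
  list(p = p, y = y)
}

test_that("cross-entropy matches its closed forms", {
  set.seed(1)
  cfg <- loss_config()
  u <- uniform_case(0.5)
  expect_equal(cross_entropy_loss(u$p, u$y, cfg), -log(0.5),
               tolerance = 1e-12)
  u2 <- uniform_case(0.25)
  expect_equal(cross_entropy_loss(u2$p, u2$y, cfg), -log(0.25),
               tolerance = 1e-12)
  # perfect prediction is (numerically) zero
  expect_lt(cross_entropy_loss(u$y, u$y, cfg), 1e-6)
  expect_error(cross_entropy_loss(u$p, u$y[, , 1:1, ]), "dimensions")
})

test_that("Dice loss matches its closed forms and epsilon rescues empties", {
  set.seed(2)
  cfg <- loss_config()
  y <- rgmcmp:::one_hot(random_mask(c(5, 4, 3), 0.3))
  expect_equal(dice_loss(y, y, cfg), 0, tolerance = 1e-12)
  # both prediction and truth empty for the foreground class:
  # the epsilon = 1 ratio is (0 + 1)/(0 + 0 + 1) = 1, so no penalty
  y0 <- rgmcmp:::one_hot(array(0L, c(4, 4, 2)))
  expect_equal(dice_loss(y0, y0, cfg), 0, tolerance = 1e-12)
  # K = 1, N = 8, S = 4 positives, p = 0.5: 1 - 5/9
  p1 <- array(0.5, c(2, 2, 2, 1))
  y1 <- array(c(rep(1, 4), rep(0, 4)), c(2, 2, 2, 1))
  expect_equal(dice_loss(p1, y1, cfg), 1 - 5 / 9, tolerance = 1e-12)
})

test_that("total loss is the stated weighted combination", {
  set.seed(3)
  cfg <- loss_config()
  u <- uniform_case(0.5)
  expect_equal(total_loss(u$p, u$y, cfg),
               0.5 * (-log(0.5)) + 0.5 * dice_loss(u$p, u$y, cfg),
               tolerance = 1e-12)
  cfg_ce <- loss_config(weights = c(1, 0))
  expect_equal(total_loss(u$p, u$y, cfg_ce),
               cross_entropy_loss(u$p, u$y, cfg_ce), tolerance = 1e-12)
  expect_lt(total_loss(u$y, u$y, cfg), 1e-6)
})

test_that("losses are invariant under voxel permutation", {
  set.seed(4)
  dims <- c(4, 3, 2)
  y <- rgmcmp:::one_hot(random_mask(dims, 0.4))
  p <- array(runif(prod(dims) * 2), c(dims, 2))
  p <- p / array(rep(p[, , , 1] + p[, , , 2], 2), dim(p))
  perm <- sample(prod(dims))
  pm <- matrix(p, ncol = 2)[perm, ]
  ym <- matrix(y, ncol = 2)[perm, ]
  pp <- array(pm, dim(p))
  yp <- array(ym, dim(y))
  cfg <- loss_config()
  expect_equal(cross_entropy_loss(p, y, cfg),
               cross_entropy_loss(pp, yp, cfg), tolerance = 1e-12)
  expect_equal(dice_loss(p, y, cfg), dice_loss(pp, yp, cfg),
               tolerance = 1e-12)
})

test_that("Dice loss decreases as true-positive probability rises", {
  set.seed(5)
  cfg <- loss_config()
  for (i in 1:20) {
    dims <- c(4, 4, 2)
    y <- rgmcmp:::one_hot(random_mask(dims, 0.5))
    p <- array(runif(prod(dims) * 2, 0.05, 0.95), c(dims, 2))
    p[, , , 2] <- 1 - p[, , , 1]
    # raise p on one true-foreground voxel, renormalized
    fg <- which(y[, , , 2] == 1)
    if (length(fg) == 0) next
    i0 <- sample(fg, 1)
    p2 <- p
    m <- matrix(p2, ncol = 2)
    m[i0, 2] <- m[i0, 2] + 0.8 * (1 - m[i0, 2])
    m[i0, 1] <- 1 - m[i0, 2]
    p2 <- array(m, dim(p))
    expect_lt(dice_loss(p2, y, cfg), dice_loss(p, y, cfg))
  }
})

test_that("the analytic logit gradient matches finite differences", {
  set.seed(6)
  dims <- c(3, 3, 2)
  y <- rgmcmp:::one_hot(random_mask(dims, 0.4))
  logits <- array(rnorm(prod(dims) * 2), c(dims, 2))
  cfg <- loss_config()
  softmax <- rgmcmp:::softmax_classes
  g <- rgmcmp:::loss_grad_logits(softmax(logits), y, cfg)
  eps <- 1e-6
  for (i in sample(length(logits), 10)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (total_loss(softmax(lp), y, cfg) -
              total_loss(softmax(lm), y, cfg)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("one optimizer step on a toy problem reduces the total loss", {
  set.seed(7)
  net <- build_model(tiny_model("scsp"), seed = 1)
  x <- array(runif(4 * 4 * 4), c(4, 4, 4, 1))
  y <- rgmcmp:::one_hot(random_mask(c(4, 4, 4), 0.3))
  cfg <- loss_config()
  fwd <- rgmcmp:::net_forward(net, x, want_cache = TRUE)
  l0 <- total_loss(fwd$probs, y, cfg)
  g <- rgmcmp:::net_backward(net, fwd,
                             rgmcmp:::loss_grad_logits(fwd$probs, y, cfg))
  st <- rgmcmp:::adam_init(net$params)
  net$params <- rgmcmp:::adam_step(net$params, g, st, 1e-3)$params
  l1 <- total_loss(forward(net, x), y, cfg)
  expect_lt(l1, l0)
})
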