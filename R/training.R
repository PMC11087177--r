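#' Training configuration
#'
#' The protocol applied identically to every network variant: "he_normal"
#' initialization, Adam with initial learning rate 2e-4 and batch size 1,
#' validation loss computed once per epoch, learning rate multiplied by
#' 0.2 after 30 consecutive epochs without a new best validation loss,
#' early stopping after 50, and the parameters at the minimum validation
#' loss returned.
#'
#' @param initial_lr Initial learning rate.
#' @param batch_size Mini-batch size (1, as in the protocol).
#' @param lr_patience Epochs without improvement before an LR drop.
#' @param lr_factor Multiplicative LR drop factor.
#' @param stop_patience Epochs without improvement before stopping.
#' @param max_epochs Hard epoch cap (early stopping normally fires
#'   first).
#' @param seed Seed controlling the per-epoch data order.
#' @param optimizer Only `"adam"`.
#' @param init_scheme Only `"he_normal"`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(initial_lr = 2e-4, batch_size = 1L,
                         lr_patience = 30L, lr_factor = 0.2,
                         stop_patience = 50L, max_epochs = 1000L,
                         seed = 0L, optimizer = "adam",
                         init_scheme = "he_normal") {
  if (lr_factor <= 0 || lr_factor >= 1)
    stop("lr_factor must lie in (0, 1)")
  if (stop_patience < lr_patience)
    stop("stop_patience must be >= lr_patience")
  structure(list(initial_lr = initial_lr, batch_size = as.integer(
    batch_size), lr_patience = as.integer(lr_patience),
    lr_factor = lr_factor, stop_patience = as.integer(stop_patience),
    max_epochs = as.integer(max_epochs), seed = as.integer(seed),
    optimizer = optimizer, init_scheme = init_scheme),
    class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params,
                                                         function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sample_loss <- function(net, sample, loss_cfg) {
  fwd <- net_forward(net, sample$x, want_cache = FALSE)
  total_loss(fwd$probs, sample$y, loss_cfg)
}

#' Train a segmentation network
#'
#' Runs the shared training protocol on in-memory datasets. A training
#' sample is a list with `x` (input array or aligned-inputs list) and `y`
#' (one-hot label array). Data order is reshuffled every epoch from the
#' run seed, the validation loss is evaluated once per epoch, and the
#' returned model carries the parameters of the epoch with the smallest
#' validation loss.
#'
#' @param net A freshly built [build_model()] network.
#' @param train_set,val_set Nonempty lists of samples.
#' @param loss_cfg A [loss_config()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A list with `net` (best model), `history` (data frame with
#'   epoch, train_loss, val_loss, lr), and `best_epoch`.
#' @export
train <- function(net, train_set, val_set, loss_cfg = loss_config(),
                  cfg = train_config(), verbose = FALSE) {
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("training and validation sets must be nonempty")
  state <- adam_init(net$params)
  lr <- cfg$initial_lr
  best_val <- Inf
  best_params <- net$params
  best_epoch <- 0L
  last_drop_ref <- 0L
  hist <- list()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(train_set))
      tl <- 0
      for (i in ord) {
        s <- train_set[[i]]
        fwd <- net_forward(net, s$x, want_cache = TRUE)
        l <- total_loss(fwd$probs, s$y, loss_cfg)
        if (!is.finite(l))
          stop("non-finite training loss at epoch ", epoch,
               "; aborting (check inputs and learning rate)")
        tl <- tl + l
        dlog <- loss_grad_logits(fwd$probs, s$y, loss_cfg)
        grads <- net_backward(net, fwd, dlog)
        upd <- adam_step(net$params, grads, state, lr)
        net$params <- upd$params
        state <- upd$state
      }
      tl <- tl / length(train_set)
      vl <- mean(vapply(val_set, function(s)
        sample_loss(net, s, loss_cfg), numeric(1)))
      if (!is.finite(vl))
        stop("non-finite validation loss at epoch ", epoch)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl,
                                  val_loss = vl, lr = lr)
      if (verbose)
        message(sprintf("epoch %d train %.4f val %.4f lr %g", epoch, tl,
                        vl, lr))
      if (vl < best_val) {
        best_val <- vl
        best_params <- net$params
        best_epoch <- epoch
        last_drop_ref <- epoch
      } else {
        if (epoch - best_epoch >= cfg$stop_patience) break
        if (epoch - last_drop_ref >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          last_drop_ref <- epoch
        }
      }
    }
  })
  net$params <- best_params
  list(net = net, history = do.call(rbind, hist), best_epoch = best_epoch,
       best_val_loss = best_val)
}
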