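#' Table of available methods
#'
#' The method ladder of the comparison experiment: standalone rigid (rb)
#' and deformable (dir) contour propagation, the unguided deep-learning
#' models (unet3d, scsp), and the registration-guided multi-channel
#' single-path / multi-path models under either guidance.
#'
#' @return A data frame with `method_id`, `type`, `guidance`, `variant`.
#' @export
method_table <- function() {
  data.frame(
    method_id = c("rb", "dir", "unet3d", "scsp", "rb_mcsp", "dir_mcsp",
                  "rb_mcmp", "dir_mcmp"),
    type = c("reg", "reg", "dl", "dl", "dl", "dl", "dl", "dl"),
    guidance = c("rb", "dir", "none", "none", "rb", "dir", "rb", "dir"),
    variant = c(NA, NA, "unet3d", "scsp", "mcsp", "mcsp", "mcmp", "mcmp"),
    stringsAsFactors = FALSE)
}

#' Two-sided paired t-test p-value
#'
#' @param a,b Equal-length paired numeric vectors (length >= 3).
#' @return The two-sided p-value.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("paired samples must have equal length >= 3")
  d <- a - b
  if (sd(d) == 0)
    stop("degenerate paired t-test: zero-variance differences")
  t.test(a, b, paired = TRUE)$p.value
}

# Split n cases into train/val/test mirroring the 60/15/15 layout.
split_cohort <- function(n, fractions = c(4, 1, 1) / 6) {
  n_val <- max(1L, round(n * fractions[2]))
  n_test <- max(1L, round(n * fractions[3]))
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("cohort too small to split")
  list(train = seq_len(n_train), val = n_train + seq_len(n_val),
       test = n_train + n_val + seq_len(n_test))
}

# Register (if guided), propagate, and preprocess one case; returns the
# network input channels, the processed ground truth, and the propagated
# contour.
prepare_case <- function(case, guidance, reg_cfg, pre_cfg) {
  if (guidance == "none") {
    slab <- extract_slab(case$ct2, case$ctv2, pre_cfg)
    cr <- crop_to_union(slab$ct, slab$ct, masks = list(slab$mask),
                        cfg = pre_cfg)
    rs <- resample_to_grid(cr$ct2, cr$masks[[1]], pre_cfg)
    return(list(x = list(ct2 = normalize_hu(rs$vol, pre_cfg)),
                y_mask = rs$mask, actv1 = NULL))
  }
  t <- if (guidance == "rb") register_rigid(case$ct2, case$ct1, reg_cfg)
  else register_bspline(case$ct2, case$ct1, reg_cfg)
  act1 <- propagate(case$ct1, t, grid_of(case$ct2))
  actv1 <- propagate(case$ctv1, t, grid_of(case$ct2))
  # slab must contain both the propagated and the ground-truth contour
  u <- rg_mask(array(as.integer(actv1$data | case$ctv2$data),
                     vol_dims(actv1)), actv1$spacing, actv1$origin)
  slab <- extract_slab(case$ct2, u, pre_cfg)
  zr <- slab$slab
  d <- vol_dims(case$ct2)
  sub <- function(v) crop_volume(v, c(1L, d[1]), c(1L, d[2]), zr)
  cr <- crop_to_union(sub(case$ct2), sub(act1),
                      masks = list(sub(actv1), sub(case$ctv2)),
                      cfg = pre_cfg)
  rs2 <- resample_to_grid(cr$ct2, cr$masks[[2]], pre_cfg)
  rs1 <- resample_to_grid(cr$act1, cr$masks[[1]], pre_cfg)
  list(x = list(act1 = normalize_hu(rs1$vol, pre_cfg),
                actv1 = rs1$mask,
                ct2 = normalize_hu(rs2$vol, pre_cfg)),
       y_mask = rs2$mask, actv1 = rs1$mask, transform = t)
}

prepared_sample <- function(prep, n_classes = 2L) {
  chans <- prep$x
  arrs <- lapply(chans, function(v) v$data)
  d <- dim(arrs[[1]])
  x <- array(0, c(d, length(arrs)))
  for (i in seq_along(arrs)) x[, , , i] <- arrs[[i]]
  list(x = x, y = one_hot(prep$y_mask$data, n_classes))
}

#' Run the full method-comparison experiment on a cohort
#'
#' Prepares every case once per required guidance (registration +
#' propagation + preprocessing), trains each deep-learning method with
#' the shared training configuration, scores every method on the
#' identical test partition, and collects per-case metrics, per-method
#' means, paired t-tests on DSC, and the correlation between the
#' registration and guided-model per-case DSC deltas.
#'
#' @param cohort List of `rg_case` objects (see [generate_cohort()]).
#' @param methods Character vector of method ids from [method_table()].
#' @param train_cfg,loss_cfg,reg_cfg,pre_cfg Stage configurations shared
#'   by every method.
#' @param model_args Extra arguments passed to [model_config()] for every
#'   DL method (e.g. `base_filters`, `n_levels`) so the experiment scale
#'   is configurable.
#' @param seed Base seed for model initialization.
#' @param verbose Print progress.
#' @return A list of class `rg_comparison` with `per_case`, `summary`,
#'   `pvalues`, `delta_correlation`, and `provenance`.
#' @export
run_experiment <- function(cohort, methods,
                           train_cfg = train_config(),
                           loss_cfg = loss_config(),
                           reg_cfg = registration_config(),
                           pre_cfg = preprocess_config(),
                           model_args = list(), seed = 0L,
                           verbose = FALSE) {
  mt <- method_table()
  if (anyDuplicated(methods)) {
    warning("duplicate method entries removed")
    methods <- unique(methods)
  }
  bad <- setdiff(methods, mt$method_id)
  if (length(bad) > 0)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  mt <- mt[mt$method_id %in% methods, , drop = FALSE]
  split <- split_cohort(length(cohort))
  guidances <- unique(mt$guidance)
  prepped <- list()
  for (g in guidances) {
    if (verbose) message("preparing guidance '", g, "'")
    prepped[[g]] <- lapply(cohort, prepare_case, guidance = g,
                           reg_cfg = reg_cfg, pre_cfg = pre_cfg)
  }
  rows <- list()
  add_row <- function(case_id, method_id, m) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(case_id = case_id, method_id = method_id,
                 stringsAsFactors = FALSE), m)
  }
  trained <- list()
  for (mi in seq_len(nrow(mt))) {
    spec <- mt[mi, ]
    pc <- prepped[[spec$guidance]]
    if (spec$type == "reg") {
      for (ci in split$test) {
        prep <- pc[[ci]]
        m <- segmentation_metrics(prep$actv1, prep$y_mask)
        add_row(cohort[[ci]]$case_id, spec$method_id, m)
      }
    } else {
      if (verbose) message("training ", spec$method_id)
      in_ch <- if (spec$guidance == "none") 1L else 3L
      mc <- do.call(model_config,
                    c(list(variant = spec$variant, in_channels = in_ch),
                      model_args))
      net <- build_model(mc, seed = seed + mi)
      mk <- function(idx) lapply(pc[idx], prepared_sample,
                                 n_classes = mc$n_classes)
      fit <- train(net, mk(split$train), mk(split$val), loss_cfg,
                   train_cfg, verbose = verbose)
      trained[[spec$method_id]] <- fit
      for (ci in split$test) {
        prep <- pc[[ci]]
        s <- prepared_sample(prep, mc$n_classes)
        pred <- predict_mask(fit$net, s$x)
        pm <- rg_mask(pred, prep$y_mask$spacing, prep$y_mask$origin)
        m <- if (sum(pred) == 0)
          data.frame(dsc = dsc(pm, prep$y_mask), hd95_mm = NA_real_,
                     asd_mm = NA_real_)
        else segmentation_metrics(pm, prep$y_mask)
        add_row(cohort[[ci]]$case_id, spec$method_id, m)
      }
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- aggregate(cbind(dsc, hd95_mm, asd_mm) ~ method_id,
                       data = per_case, FUN = mean, na.action = NULL)
  ids <- mt$method_id
  pvalues <- list()
  if (length(split$test) >= 3) {
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      a <- per_case$dsc[per_case$method_id == ids[i]]
      b <- per_case$dsc[per_case$method_id == ids[j]]
      pvalues[[paste0(ids[i], "_vs_", ids[j])]] <-
        tryCatch(paired_ttest(a, b), error = function(e) NA_real_)
    }
  }
  res <- structure(list(per_case = per_case, summary = summary,
                        pvalues = pvalues,
                        delta_correlation = NA_real_,
                        history = lapply(trained, `[[`, "history"),
                        provenance = list(seed = seed, split = split,
                                          methods = methods,
                                          train_cfg = unclass(train_cfg),
                                          reg_cfg = unclass(reg_cfg),
                                          pre_cfg = unclass(pre_cfg),
                                          model_args = model_args)),
                   class = "rg_comparison")
  if (all(c("rb", "dir", "rb_mcmp", "dir_mcmp") %in% ids))
    res$delta_correlation <- tryCatch(delta_correlation(res),
                                      error = function(e) NA_real_)
  res
}

#' Correlation between registration and guided-model accuracy deltas
#'
#' Pearson correlation between the per-case DSC difference of the two
#' registration methods (dir - rb) and the per-case DSC difference of
#' the two guided multi-path models (dir_mcmp - rb_mcmp).
#'
#' @param result An `rg_comparison` with all four methods present.
#' @return The Pearson correlation coefficient.
#' @export
delta_correlation <- function(result) {
  pc <- result$per_case
  get <- function(id) {
    v <- pc[pc$method_id == id, c("case_id", "dsc")]
    setNames(v$dsc, v$case_id)
  }
  rb <- get("rb")
  ids <- names(rb)
  if (length(ids) < 3)
    stop("delta correlation needs >= 3 test cases")
  dreg <- get("dir")[ids] - rb
  dmcmp <- get("dir_mcmp")[ids] - get("rb_mcmp")[ids]
  if (sd(dreg) == 0 || sd(dmcmp) == 0)
    stop("degenerate delta correlation: zero variance in a delta vector")
  cor(dreg, dmcmp)
}

#' @export
print.rg_comparison <- function(x, ...) {
  cat("<rg_comparison>\n")
  print(x$summary, row.names = FALSE)
  if (is.finite(x$delta_correlation))
    cat(sprintf("delta correlation R = %.3f\n", x$delta_correlation))
  cat("note: p-values are two-sided paired t-tests on DSC,",
      "uncorrected for multiple testing\n")
  invisible(x)
}

#' Box plots of the per-case metrics by method
#'
#' @param result An `rg_comparison`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_comparison <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_comparison requires the ggplot2 package")
  pc <- result$per_case
  long <- do.call(rbind, lapply(c("dsc", "hd95_mm", "asd_mm"),
                                function(m)
                                  data.frame(method = pc$method_id,
                                             metric = m,
                                             value = pc[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = method, y = value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_bw()
}
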