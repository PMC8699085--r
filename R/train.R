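#' Training configuration
#'
#' Collects the training hyper-parameters of the MSI model. The batch size of
#' the full-scale protocol is 512 images; the desk-scale default here is 128.
#' The optimizer (Adam) and the learning rate are deliberate package choices
#' exposed here, as is the adversarial weight `lambda`.
#'
#' @param net_px Network input resolution: tiles are area-averaged to
#'   `net_px` x `net_px` before flattening.
#' @param feature_dim,fe_hidden,head_hidden Widths of the feature extractor
#'   and heads; see [network_spec()].
#' @param biases Character vector of manifest columns treated as protected
#'   variables (each gets an adversarial head when `ablate = TRUE`).
#' @param rho Conditioning class on which the bias heads are trained (and the
#'   feature extractor fooled): `"MSS"` by default.
#' @param lambda Adversarial weight (>= 0) scaling the bias-fooling gradient.
#' @param lr Adam learning rate for all parameter groups.
#' @param batch_size Images per training batch.
#' @param epochs Training epochs (cap; default 3).
#' @param min_bias_batch Minimal rho-conditioned sub-batch size; below it the
#'   adversarial sub-steps are skipped for that iteration.
#' @param be_lr_mult Learning-rate multiplier for the bias heads (the
#'   adversary must track the moving feature extractor; a faster adversary
#'   keeps the fooling gradient informative).
#' @param be_steps Inner bias-head updates per iteration (step 2 repeated).
#' @param monitor Extra manifest columns whose per-batch dc with the features
#'   is logged (the target and the biases are always monitored).
#' @param seed Master seed: initialisation, batch order and monitoring
#'   subsampling derive disjoint streams from it.
#' @return A `train_config` list.
#' @export
train_config <- function(net_px = 16, feature_dim = 128, fe_hidden = 128,
                         head_hidden = 128,
                         biases = c("project", "patient", "glass"),
                         rho = "MSS", lambda = 1, lr = 1e-3,
                         batch_size = 128, epochs = 3, min_bias_batch = 8,
                         be_lr_mult = 5, be_steps = 1,
                         monitor = character(), seed = 1L) {
  assert_that(lambda >= 0, "lambda must be >= 0")
  assert_that(rho %in% c("MSS", "MSI-H"), "rho must be 'MSS' or 'MSI-H'")
  assert_that(be_steps >= 1, "be_steps must be >= 1")
  structure(list(net_px = as.integer(net_px),
    feature_dim = as.integer(feature_dim), fe_hidden = as.integer(fe_hidden),
    head_hidden = as.integer(head_hidden), biases = biases, rho = rho,
    lambda = lambda, lr = lr, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), min_bias_batch = as.integer(min_bias_batch),
    be_lr_mult = be_lr_mult, be_steps = as.integer(be_steps),
    monitor = monitor, seed = as.integer(seed)), class = "train_config")
}

#' Initialise a training state
#'
#' Bundles the network, per-parameter-group Adam states and the encoded bias
#' targets for the training cohort. Parameter collections (FE, MSI head, BE
#' heads) are disjoint and separately optimised.
#'
#' @param manifest Training-cohort manifest (one row per tile) with
#'   `msi_label` and the bias columns named in the config.
#' @param x Row-aligned input matrix (see [as_input_matrix()]).
#' @param config A [train_config()].
#' @param ablate Attach adversarial bias heads?
#' @return A `train_state`.
#' @export
train_state <- function(manifest, x, config, ablate = TRUE) {
  assert_that(inherits(config, "train_config"), "config must be a train_config")
  x <- as.matrix(x)
  assert_that(nrow(x) == nrow(manifest), "x and manifest rows must align")
  assert_that(any(manifest$msi_label == "MSI-H"),
    "no MSI-H patients in the training cohort")
  assert_that(any(manifest$msi_label == "MSS"),
    "no MSS patients in the training cohort")
  spec <- network_spec(ncol(x), feature_dim = config$feature_dim,
    fe_hidden = config$fe_hidden, head_hidden = config$head_hidden)
  bias_specs <- list()
  if (ablate) {
    bias_specs <- lapply(config$biases, function(v) {
      bias_spec(v, unique(as.character(manifest[[v]])), rho = config$rho)
    })
  }
  network <- init_network(spec, bias_specs, seed = config$seed)
  # fixed-width encoded targets for the whole training cohort
  enc <- lapply(bias_specs, function(bs) {
    encode_bias(as.character(manifest[[bs$name]]), bs, drop_absent = FALSE)
  })
  names(enc) <- vapply(bias_specs, `[[`, "", "name")
  y <- cbind(`MSI-H` = as.numeric(manifest$msi_label == "MSI-H"),
             MSS = as.numeric(manifest$msi_label == "MSS"))
  monitors <- unique(c("msi_label", config$biases, config$monitor))
  # standardize the input on training-cohort statistics (conditioning)
  x_center <- colMeans(x)
  x_scale <- pmax(apply(x, 2, stats::sd), 1e-3)
  x <- sweep(sweep(x, 2, x_center), 2, x_scale, `/`)
  structure(list(
    network = network, config = config, ablate = isTRUE(ablate),
    x = x, y = y, manifest = manifest, enc = enc,
    x_center = x_center, x_scale = x_scale,
    monitors = monitors,
    opt_fe = adam_state(network$fe), opt_msi = adam_state(network$msi),
    opt_be = lapply(network$be, adam_state),
    iter = 0L, skipped_bias_steps = 0L, trace = list()
  ), class = "train_state")
}

#' One three-step adversarial training iteration
#'
#' Executes, in order: (1) back-propagate the cross-entropy MSI loss to update
#' the feature extractor and the MSI head; (2) for each bias consecutively,
#' with the feature extractor fixed, minimise the bias loss to update that
#' bias head; (3) with the bias heads fixed, maximise the bias losses (scaled
#' by `lambda`) to update the feature extractor, distilling the biases out of
#' the representation. Steps 2–3 operate only on the rho-conditioned
#' sub-batch and are skipped (and counted) when it is smaller than
#' `min_bias_batch`; they are also skipped entirely when the state has no
#' bias heads or `lambda` related machinery is disabled (baseline training).
#'
#' @param state A [train_state()].
#' @param batch_idx Integer row indices of the batch within the training
#'   cohort.
#' @return The updated `train_state` (with one appended trace row).
#' @export
adversarial_iteration <- function(state, batch_idx) {
  cfg <- state$config
  xb <- state$x[batch_idx, , drop = FALSE]
  yb <- state$y[batch_idx, , drop = FALSE]
  nb <- length(batch_idx)

  # -- step 1: classification update (theta_fe, theta_msi)
  fw_fe <- stack_forward(state$network$fe, xb)
  fw_msi <- stack_forward(state$network$msi, fw_fe$out)
  p <- softmax(fw_msi$out)
  loss <- msi_loss(yb, p)
  dlogits <- (p - yb) / nb
  bk_msi <- stack_backward(state$network$msi, fw_msi, dlogits)
  bk_fe <- stack_backward(state$network$fe, fw_fe, bk_msi$dinput)
  up <- adam_step(state$network$msi, bk_msi$grads, state$opt_msi, cfg$lr)
  state$network$msi <- up$stack; state$opt_msi <- up$opt
  up <- adam_step(state$network$fe, bk_fe$grads, state$opt_fe, cfg$lr)
  state$network$fe <- up$stack; state$opt_fe <- up$opt

  # -- monitoring: batch-level dc between features and each variable
  feats <- fw_fe$out
  dc_row <- list()
  for (v in state$monitors) {
    vals <- as.character(state$manifest[[v]][batch_idx])
    if (length(unique(vals)) < 2) {
      dc_row[[paste0("dc_", v)]] <- NA_real_
      next
    }
    sp <- bias_spec(v, unique(vals))
    dc_row[[paste0("dc_", v)]] <-
      squared_distance_correlation(feats, encode_bias(vals, sp))
  }

  # -- steps 2-3: adversarial sub-steps on the rho-conditioned sub-batch
  bias_active <- state$ablate && length(state$network$be) > 0 && cfg$lambda > 0
  if (bias_active) {
    rho_rows <- which(as.character(state$manifest$msi_label[batch_idx]) == cfg$rho)
    if (length(rho_rows) < cfg$min_bias_batch) {
      state$skipped_bias_steps <- state$skipped_bias_steps + 1L
    } else {
      x_rho <- xb[rho_rows, , drop = FALSE]
      idx_rho <- batch_idx[rho_rows]
      n_rho <- length(rho_rows)
      for (bs in state$network$bias_specs) {
        nm <- bs$name
        b <- state$enc[[nm]][idx_rho, , drop = FALSE]
        # step 2: fix theta_fe, minimise L_be (= -sum corr^2) w.r.t. the head
        fw_f <- stack_forward(state$network$fe, x_rho)
        for (s2 in seq_len(cfg$be_steps)) {
          fw_b <- stack_forward(state$network$be[[nm]], fw_f$out)
          cs <- corr2_sum(b, fw_b$out)
          bk <- stack_backward(state$network$be[[nm]], fw_b, -cs$grad / n_rho)
          up <- adam_step(state$network$be[[nm]], bk$grads,
            state$opt_be[[nm]], cfg$lr * cfg$be_lr_mult)
          state$network$be[[nm]] <- up$stack; state$opt_be[[nm]] <- up$opt
        }
        # step 3: fix theta_be, maximise L_be w.r.t. theta_fe (scaled by lambda)
        fw_b2 <- stack_forward(state$network$be[[nm]], fw_f$out)
        cs2 <- corr2_sum(b, fw_b2$out)
        bk_head <- stack_backward(state$network$be[[nm]], fw_b2,
          cfg$lambda * cs2$grad / n_rho)
        bk_fe2 <- stack_backward(state$network$fe, fw_f, bk_head$dinput)
        up <- adam_step(state$network$fe, bk_fe2$grads, state$opt_fe, cfg$lr)
        state$network$fe <- up$stack; state$opt_fe <- up$opt
      }
    }
  }

  state$iter <- state$iter + 1L
  state$trace[[state$iter]] <- tibble::tibble(
    iteration = state$iter, loss_msi = loss / nb, !!!dc_row
  )
  state
}

#' Train the MSI model (baseline or bias-ablated)
#'
#' Trains the feature extractor and MSI head with composite patient/class
#' balanced sampling; with `ablate = TRUE` one adversarial head per protected
#' variable is attached and the three-step min-max schedule of
#' [adversarial_iteration()] is applied. The squared distance correlation
#' between the batch features and the target plus each bias is logged every
#' iteration.
#'
#' With `lambda = 0` (or `ablate = FALSE`) the feature-extractor and MSI-head
#' trajectories are bit-identical to a baseline run under the same seed: all
#' parameter groups draw initialisation from disjoint seed streams and the
#' batch stream does not depend on the presence of bias heads.
#'
#' @param manifest Full tile manifest.
#' @param x Row-aligned input matrix.
#' @param config A [train_config()].
#' @param ablate Attach and train adversarial bias heads?
#' @param fold_plan Optional [grouped_kfold_split()] plan.
#' @param fold Validation fold number (used when `fold_plan` is given).
#' @return An `msi_model`: the trained network plus the per-iteration trace,
#'   the fold row indices and the configuration.
#' @export
train_model <- function(manifest, x, config = train_config(),
                        ablate = TRUE, fold_plan = NULL, fold = 1L) {
  x <- as.matrix(x)
  idx <- if (is.null(fold_plan)) {
    list(train = seq_len(nrow(manifest)), val = integer())
  } else {
    fold_indices(manifest, fold_plan, fold)
  }
  man_tr <- manifest[idx$train, , drop = FALSE]
  state <- train_state(man_tr, x[idx$train, , drop = FALSE], config, ablate)
  w <- composite_weights(man_tr)
  n_tr <- nrow(man_tr)
  iters_per_epoch <- max(1L, n_tr %/% config$batch_size)
  sampling_seed <- derive_seeds(config$seed, 1, salt = 29L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(sampling_seed)
  for (ep in seq_len(config$epochs)) {
    for (it in seq_len(iters_per_epoch)) {
      batch_idx <- sample.int(n_tr, config$batch_size, replace = TRUE, prob = w)
      state <- adversarial_iteration(state, batch_idx)
    }
  }
  trace <- dplyr::bind_rows(state$trace)
  trace$epoch <- rep(seq_len(config$epochs), each = iters_per_epoch)
  structure(list(
    network = state$network, config = config, ablate = isTRUE(ablate),
    trace = trace, train_idx = idx$train, val_idx = idx$val,
    skipped_bias_steps = state$skipped_bias_steps,
    x_center = state$x_center, x_scale = state$x_scale,
    n_train = n_tr
  ), class = "msi_model")
}

#' @export
print.msi_model <- function(x, ...) {
  cat("<msi_model> ", if (x$ablate) "bias-ablated" else "baseline",
    "; ", nrow(x$trace), " iterations on ", x$n_train, " tiles",
    if (length(x$network$be) > 0) paste0("; bias heads: ",
      paste(names(x$network$be), collapse = ", ")) else "",
    "\n", sep = "")
  invisible(x)
}

#' Predict from a trained MSI model
#'
#' @param object An `msi_model`.
#' @param x Input matrix (same preprocessing as in training).
#' @param type `"prob"` for a tibble of class probabilities plus the hard
#'   label at the 0.5 threshold, `"features"` for the extracted feature
#'   matrix.
#' @param ... Unused.
#' @return A tibble (`type = "prob"`) or a matrix (`type = "features"`).
#' @export
predict.msi_model <- function(object, x, type = c("prob", "features"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  x <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, `/`)
  fw <- network_forward(object$network, x)
  if (type == "features") return(fw$features)
  tibble::tibble(
    prob_msi = fw$prob[, "MSI-H"],
    prob_mss = fw$prob[, "MSS"],
    pred_label = ifelse(fw$prob[, "MSI-H"] >= 0.5, "MSI-H", "MSS")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-iteration training trace of an MSI model
#'
#' @param x An `msi_model`.
#' @param ... Unused.
#' @return Long tibble with columns `iteration, epoch, metric, value`
#'   covering the MSI loss and every monitored dc series.
#' @method tidy msi_model
#' @export
tidy.msi_model <- function(x, ...) {
  tidyr::pivot_longer(x$trace, cols = -c("iteration", "epoch"),
    names_to = "metric", values_to = "value")
}

#' One-row summary of a trained MSI model
#'
#' @param x An `msi_model`.
#' @param ... Unused.
#' @return Tibble with the model kind, iteration count, final MSI loss and
#'   the mean of each dc series over the last epoch.
#' @method glance msi_model
#' @export
glance.msi_model <- function(x, ...) {
  last <- dplyr::filter(x$trace, .data$epoch == max(.data$epoch))
  dc_cols <- grep("^dc_", names(last), value = TRUE)
  out <- tibble::tibble(
    model = if (x$ablate) "bias-ablated" else "baseline",
    iterations = nrow(x$trace),
    final_loss_msi = last$loss_msi[nrow(last)],
    skipped_bias_steps = x$skipped_bias_steps
  )
  for (cc in dc_cols) out[[paste0("mean_", cc)]] <- mean(last[[cc]], na.rm = TRUE)
  out
}
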