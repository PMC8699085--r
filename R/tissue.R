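#' Train the nine-class tissue classifier
#'
#' Trains a softmax classifier over the nine colorectal tissue classes on
#' labelled tiles. Its trunk has exactly the feature-extractor shape of the
#' MSI network ([network_spec()]), so a trained tissue classifier's trunk is
#' reusable as the feature extractor of the end-to-end system; its head has
#' two hidden ReLU layers and nine outputs.
#'
#' @param dataset A `synth_dataset` (or any list with `manifest$tissue` and
#'   `pixels`) of labelled tiles.
#' @param net_px Input resolution (tiles are area-averaged to this size).
#' @param feature_dim,fe_hidden,head_hidden Network widths, as in
#'   [network_spec()].
#' @param lr,batch_size,epochs Adam learning rate, batch size, epochs.
#' @param classes Class set that must all be present in the training data.
#' @param seed Integer seed.
#' @return A `tissue_classifier`.
#' @export
train_tissue_classifier <- function(dataset, net_px = 16, feature_dim = 128,
                                    fe_hidden = 128, head_hidden = 128,
                                    lr = 1e-3, batch_size = 64, epochs = 10,
                                    classes = tissue_classes(), seed = 1L) {
  labels <- as.character(dataset$manifest$tissue)
  absent <- setdiff(classes, unique(labels))
  if (length(absent) > 0) {
    stop("missing tissue class(es) in training data: ",
      paste(sort(absent), collapse = ", "), call. = FALSE)
  }
  classes <- sort(classes)
  x <- as_input_matrix(dataset, net_px)
  x_center <- colMeans(x)
  x_scale <- pmax(apply(x, 2, stats::sd), 1e-3)
  x <- sweep(sweep(x, 2, x_center), 2, x_scale, `/`)
  y <- matrix(0, nrow(x), length(classes))
  y[cbind(seq_len(nrow(x)), match(labels, classes))] <- 1

  spec <- network_spec(ncol(x), feature_dim = feature_dim,
    fe_hidden = fe_hidden, head_hidden = head_hidden,
    msi_out = length(classes))
  seeds <- derive_seeds(seed, 3, salt = 41L)
  fe <- init_stack(c(spec$input_dim, spec$fe_hidden, spec$feature_dim),
    seeds[1], final_relu = TRUE)
  head <- init_stack(c(spec$feature_dim, spec$head_hidden, spec$head_hidden,
    length(classes)), seeds[2])
  opt_fe <- adam_state(fe)
  opt_head <- adam_state(head)
  n <- nrow(x)
  losses <- numeric(0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seeds[3])
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      if (length(idx) < 2) next
      fw_fe <- stack_forward(fe, x[idx, , drop = FALSE])
      fw_h <- stack_forward(head, fw_fe$out)
      p <- softmax(fw_h$out)
      losses <- c(losses, msi_loss(y[idx, , drop = FALSE], p) / length(idx))
      dlogits <- (p - y[idx, , drop = FALSE]) / length(idx)
      bk_h <- stack_backward(head, fw_h, dlogits)
      bk_fe <- stack_backward(fe, fw_fe, bk_h$dinput)
      up <- adam_step(head, bk_h$grads, opt_head, lr)
      head <- up$stack; opt_head <- up$opt
      up <- adam_step(fe, bk_fe$grads, opt_fe, lr)
      fe <- up$stack; opt_fe <- up$opt
    }
  }
  structure(list(fe = fe, head = head, classes = classes, net_px = net_px,
    x_center = x_center, x_scale = x_scale,
    spec = spec, loss_trace = losses), class = "tissue_classifier")
}

#' Predict tissue classes for tiles
#'
#' @param object A [train_tissue_classifier()] model.
#' @param tiles A `synth_dataset`, a list of RGB arrays, or an input matrix
#'   already at the classifier's resolution.
#' @param ... Unused.
#' @return Tibble with one probability column per class and the argmax class
#'   in `tissue`.
#' @export
predict.tissue_classifier <- function(object, tiles, ...) {
  x <- if (is.matrix(tiles)) tiles else as_input_matrix(tiles, object$net_px)
  x <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, `/`)
  f <- stack_forward(object$fe, x)$out
  p <- softmax(stack_forward(object$head, f)$out)
  colnames(p) <- object$classes
  out <- tibble::as_tibble(p)
  out$tissue <- object$classes[max.col(p, ties.method = "first")]
  out
}

#' Extract the trained trunk as an MSI-network feature extractor
#'
#' @param classifier A `tissue_classifier`.
#' @return An `mlp_stack` usable as the `fe` component of an [init_network()]
#'   model with a matching [network_spec()].
#' @export
tissue_trunk <- function(classifier) {
  assert_that(inherits(classifier, "tissue_classifier"),
    "classifier must be a tissue_classifier")
  classifier$fe
}
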