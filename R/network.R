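# Dense network machinery: the feature extractor (FE), the MSI head and the
# adversarial bias (BE) heads are stacks of fully connected layers with ReLU
# activations, trained by hand-written backpropagation and Adam. The
# bias-ablation mechanism is backbone-agnostic; a dense trunk on
# area-averaged tile input keeps desk-scale training tractable on one CPU.

#' Network architecture specification
#'
#' The feature extractor maps the flattened tile input through `fe_hidden`
#' ReLU layers to `feature_dim` features; the MSI head and every bias head
#' have two hidden ReLU layers of width `head_hidden`. The MSI head emits two
#' logits (MSI-H vs MSS, softmax); each bias head emits one output per
#' encoded level of its protected variable.
#'
#' @param input_dim Flattened input width (`net_px^2 * 3`).
#' @param feature_dim Width D of the extracted feature vector.
#' @param fe_hidden Integer vector of FE hidden-layer widths.
#' @param head_hidden Hidden width of the MSI and bias heads.
#' @param msi_out Number of target classes (2).
#' @return A `network_spec` list.
#' @export
network_spec <- function(input_dim, feature_dim = 128,
                         fe_hidden = 128, head_hidden = 128, msi_out = 2) {
  assert_that(feature_dim > 0, "feature_dim must be positive")
  structure(list(input_dim = as.integer(input_dim),
    feature_dim = as.integer(feature_dim),
    fe_hidden = as.integer(fe_hidden),
    head_hidden = as.integer(head_hidden),
    msi_out = as.integer(msi_out)), class = "network_spec")
}

# ---- stack primitives -------------------------------------------------------

# He-normal initialisation of a dense stack with given layer widths.
# final_relu: whether the last layer is followed by ReLU (TRUE for the FE so
# features are non-negative activations; FALSE for head outputs).
init_stack <- function(dims, seed, final_relu = FALSE) {
  layers <- vector("list", length(dims) - 1)
  with_seed(seed, {
    for (i in seq_along(layers)) {
      fan_in <- dims[i]
      layers[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * dims[i + 1], 0, sqrt(2 / fan_in)),
          fan_in, dims[i + 1]),
        b = rep(0, dims[i + 1])
      )
    }
  })
  structure(list(layers = layers, final_relu = final_relu), class = "mlp_stack")
}

# Forward pass; returns output and the per-layer inputs needed for backprop.
stack_forward <- function(stack, x) {
  cache <- vector("list", length(stack$layers))
  a <- x
  for (i in seq_along(stack$layers)) {
    cache[[i]] <- a
    z <- a %*% stack$layers[[i]]$W
    z <- sweep(z, 2, stack$layers[[i]]$b, `+`)
    a <- if (i < length(stack$layers) || stack$final_relu) pmax(z, 0) else z
  }
  list(out = a, cache = cache)
}

# Backward pass given d(loss)/d(output); returns parameter gradients and
# d(loss)/d(input).
stack_backward <- function(stack, fw, dout) {
  n_layers <- length(stack$layers)
  grads <- vector("list", n_layers)
  da <- dout
  for (i in rev(seq_len(n_layers))) {
    a_in <- fw$cache[[i]]
    relu_here <- i < n_layers || stack$final_relu
    if (relu_here) {
      # recompute this layer's post-activation mask
      z <- sweep(a_in %*% stack$layers[[i]]$W, 2, stack$layers[[i]]$b, `+`)
      da <- da * (z > 0)
    }
    grads[[i]] <- list(W = crossprod(a_in, da), b = colSums(da))
    da <- tcrossprod(da, stack$layers[[i]]$W)
  }
  list(grads = grads, dinput = da)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_state <- function(stack) {
  list(t = 0L, m = lapply(stack$layers, function(l)
    list(W = l$W * 0, b = l$b * 0)),
    v = lapply(stack$layers, function(l) list(W = l$W * 0, b = l$b * 0)))
}

adam_step <- function(stack, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(stack$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      opt$m[[i]][[p]] <- beta1 * opt$m[[i]][[p]] + (1 - beta1) * g
      opt$v[[i]][[p]] <- beta2 * opt$v[[i]][[p]] + (1 - beta2) * g^2
      step <- lr * (opt$m[[i]][[p]] / bc1) /
        (sqrt(opt$v[[i]][[p]] / bc2) + eps)
      stack$layers[[i]][[p]] <- stack$layers[[i]][[p]] - step
    }
  }
  list(stack = stack, opt = opt)
}

# ---- model ------------------------------------------------------------------

#' Initialise the FE / MSI / BE network
#'
#' Parameter groups are disjoint and each is initialised from its own seed
#' stream derived from `seed`, so that attaching bias heads does not perturb
#' the initialisation of the feature extractor or the MSI head.
#'
#' @param spec A [network_spec()].
#' @param bias_specs List of [bias_spec()]; one adversarial head is created
#'   per entry, with output width equal to the number of declared levels.
#' @param seed Integer master seed.
#' @return An `msi_network` with elements `fe`, `msi`, `be` (named list) and
#'   bookkeeping.
#' @export
init_network <- function(spec, bias_specs = list(), seed = 1L) {
  assert_that(inherits(spec, "network_spec"), "spec must be a network_spec")
  seeds <- derive_seeds(seed, 2 + length(bias_specs), salt = 17L)
  fe <- init_stack(c(spec$input_dim, spec$fe_hidden, spec$feature_dim),
    seeds[1], final_relu = TRUE)
  msi <- init_stack(c(spec$feature_dim, spec$head_hidden, spec$head_hidden,
    spec$msi_out), seeds[2])
  be <- list()
  if (length(bias_specs) > 0) {
    for (i in seq_along(bias_specs)) {
      bs <- bias_specs[[i]]
      assert_that(inherits(bs, "bias_spec"),
        "bias_specs must be a list of bias_spec objects")
      be[[bs$name]] <- init_stack(c(spec$feature_dim, spec$head_hidden,
        spec$head_hidden, length(bs$levels)), seeds[2 + i])
    }
  }
  structure(list(spec = spec, fe = fe, msi = msi, be = be,
    bias_specs = bias_specs, seed = as.integer(seed)),
    class = "msi_network")
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through the full network
#'
#' @param model An [init_network()] model.
#' @param x N x input_dim matrix of flattened, preprocessed tiles.
#' @return List with `features` (N x D), `prob` (N x 2 softmax rows summing
#'   to 1, columns `MSI-H`, `MSS`) and `bias_pred` (named list of N x K
#'   matrices, one per bias head).
#' @export
network_forward <- function(model, x) {
  assert_that(inherits(model, "msi_network"), "model must be an msi_network")
  x <- as.matrix(x)
  assert_that(ncol(x) == model$spec$input_dim,
    paste0("input width ", ncol(x), " does not match network input_dim ",
      model$spec$input_dim))
  f <- stack_forward(model$fe, x)$out
  p <- softmax(stack_forward(model$msi, f)$out)
  colnames(p) <- c("MSI-H", "MSS")
  bp <- lapply(model$be, function(h) stack_forward(h, f)$out)
  list(features = f, prob = p, bias_pred = bp)
}

# ---- losses -----------------------------------------------------------------

#' Cross-entropy MSI classification loss
#'
#' The summed cross-entropy over the batch between indicator targets and
#' predicted class probabilities; non-negative, and zero only for perfect,
#' fully confident predictions.
#'
#' @param y N x M indicator matrix (one 1 per row) or a vector of class
#'   indices in `1..M`.
#' @param y_hat N x M matrix of predicted probabilities (rows sum to 1).
#' @param eps Clamping floor for the probabilities.
#' @return Scalar loss (sum over the batch).
#' @export
msi_loss <- function(y, y_hat, eps = 1e-12) {
  y_hat <- as.matrix(y_hat)
  if (is.vector(y) || ncol(as.matrix(y)) == 1) {
    yi <- as.integer(y)
    y <- matrix(0, length(yi), ncol(y_hat))
    y[cbind(seq_along(yi), yi)] <- 1
  }
  y <- as.matrix(y)
  assert_that(all(dim(y) == dim(y_hat)), "y and y_hat shapes differ")
  if (any(y_hat < 0 | y_hat > 1 + 1e-9)) {
    stop("y_hat must contain probabilities in [0, 1]", call. = FALSE)
  }
  -sum(y * log(pmax(y_hat, eps)))
}

#' Adversarial bias loss (negative summed squared Pearson correlation)
#'
#' For each of the K encoded bias columns, the squared Pearson correlation
#' between the bias indicator and the head's prediction is computed; the loss
#' is minus their sum, so it lies in `[-K, 0]`. Columns with zero variance in
#' either vector contribute 0. Computed on the rho-conditioned sub-batch only
#' (the caller selects the rows).
#'
#' @param b N x K encoded bias matrix.
#' @param b_hat N x K predictions from the bias head.
#' @return Scalar loss in `[-K, 0]`.
#' @export
bias_loss <- function(b, b_hat) {
  -corr2_sum(as.matrix(b), as.matrix(b_hat))$value
}

# Sum over columns of squared Pearson correlation, plus its gradient with
# respect to b_hat. Zero-variance columns (in either argument) contribute
# nothing. Epsilon-guarded denominators.
corr2_sum <- function(b, b_hat, eps = 1e-8) {
  assert_that(nrow(b) == nrow(b_hat) && ncol(b) == ncol(b_hat),
    "b and b_hat must have identical shapes")
  n <- nrow(b)
  assert_that(n >= 2, "at least 2 rows are required for a correlation")
  grad <- b_hat * 0
  total <- 0
  for (k in seq_len(ncol(b))) {
    u <- b[, k] - mean(b[, k])
    v <- b_hat[, k] - mean(b_hat[, k])
    suu <- sum(u^2)
    svv <- sum(v^2)
    if (suu < eps || svv < eps) next
    suv <- sum(u * v)
    r <- suv / sqrt(suu * svv)
    total <- total + r^2
    # d r / d v, then centre (account for the mean subtraction)
    dr_dv <- u / sqrt(suu * svv) - (suv / (sqrt(suu) * svv^1.5)) * v
    g <- 2 * r * dr_dv
    grad[, k] <- g - mean(g)
  }
  list(value = total, grad = grad)
}
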