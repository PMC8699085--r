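# Small shared training fixture: confounded dataset at toy scale.
local_train_fixture <- function(seed = 21) {
  ds <- synthesize_dataset(synth_config(
    n_patients = 24, tiles_per_patient_range = c(6, 10),
    msi_prevalence = 0.35, project_confound = 0.8,
    stain_shift_magnitude = 0.12, glass_tint_magnitude = 0.1,
    patient_texture_sd = 0.06, signal_strength = 0.8,
    tile_px = 32, seed = seed), net_px = 8)
  list(man = ds$manifest, x = as_input_matrix(ds, 8))
}

test_that("lambda = 0 reduces the ablated trainer to the baseline bit for bit", {
  fx <- local_train_fixture()
  cfg <- train_config(net_px = 8, feature_dim = 16, fe_hidden = 16,
    head_hidden = 16, batch_size = 32, epochs = 2, lambda = 0, seed = 5)
  m_abl <- train_model(fx$man, fx$x, cfg, ablate = TRUE)
  m_base <- train_model(fx$man, fx$x, cfg, ablate = FALSE)
  expect_identical(m_abl$network$fe, m_base$network$fe)
  expect_identical(m_abl$network$msi, m_base$network$msi)
  expect_identical(m_abl$trace$loss_msi, m_base$trace$loss_msi)
  # the ablated variant still owns (untrained-by-step-3) bias heads
  expect_identical(sort(names(m_abl$network$be)),
    c("glass", "patient", "project"))
  expect_length(m_base$network$be, 0)
})

test_that("training states and iterations respect the declared contracts", {
  fx <- local_train_fixture(22)
  cfg <- train_config(net_px = 8, feature_dim = 16, fe_hidden = 16,
    head_hidden = 16, batch_size = 32, epochs = 1, lambda = 1, seed = 6)
  st <- train_state(fx$man, fx$x, cfg, ablate = TRUE)
  expect_s3_class(st, "train_state")
  st2 <- adversarial_iteration(st, 1:32)
  expect_identical(st2$iter, 1L)
  expect_identical(nrow(st2$trace[[1]]), 1L)
  expect_true(all(c("dc_msi_label", "dc_project") %in% names(st2$trace[[1]])))
  # rho sub-batch below the minimum skips the adversarial sub-steps
  msi_rows <- which(fx$man$msi_label == "MSI-H")[1:32]
  st3 <- adversarial_iteration(st, msi_rows)
  expect_identical(st3$skipped_bias_steps, 1L)
  # single-class cohort is rejected
  mss_only <- fx$man$msi_label == "MSS"
  expect_error(train_state(fx$man[mss_only, ], fx$x[mss_only, ], cfg),
    "no MSI-H patients")
})

test_that("repeated adversary updates on a frozen extractor increase corr^2", {
  fx <- local_train_fixture(23)
  cfg <- train_config(net_px = 8, feature_dim = 16, fe_hidden = 16,
    head_hidden = 16, batch_size = 64, epochs = 1, seed = 7)
  st <- train_state(fx$man, fx$x, cfg, ablate = TRUE)
  set.seed(3)
  rows <- sample(which(fx$man$msi_label == "MSS"), 64)
  # glass is unconfounded, so the fixed batch carries several levels
  expect_gt(dplyr::n_distinct(fx$man$glass[rows]), 1)
  b <- st$enc[["glass"]][rows, , drop = FALSE]
  feats <- msidistill:::stack_forward(st$network$fe, st$x[rows, ])$out
  head_stack <- st$network$be[["glass"]]
  opt <- msidistill:::adam_state(head_stack)
  vals <- numeric(50)
  for (i in 1:50) {
    fw <- msidistill:::stack_forward(head_stack, feats)
    cs <- msidistill:::corr2_sum(b, fw$out)
    vals[i] <- cs$value
    bk <- msidistill:::stack_backward(head_stack, fw, -cs$grad / nrow(b))
    up <- msidistill:::adam_step(head_stack, bk$grads, opt, 1e-3)
    head_stack <- up$stack; opt <- up$opt
  }
  # running mean of corr^2 is higher over the last 10 than the first 10
  expect_gt(mean(vals[41:50]), mean(vals[1:10]))
  expect_gt(vals[50], vals[1])
})

test_that("ablation removes a linearly encoded bias while keeping the signal", {
  # toy inputs: one coordinate carries the class, another the bias
  set.seed(40)
  n <- 1200
  y <- rep(c("MSI-H", "MSS"), each = n / 2)
  bias <- sample(c("L1", "L2"), n, replace = TRUE)
  x <- cbind(
    (y == "MSI-H") + rnorm(n, 0, 0.3),
    (bias == "L1") + rnorm(n, 0, 0.3),
    matrix(rnorm(2 * n, 0, 0.3), n)
  )
  man <- tibble::tibble(patient = sprintf("p%03d", rep(1:120, each = 10)),
    msi_label = y, lab = bias)
  cfg <- train_config(net_px = 2, feature_dim = 8, fe_hidden = 8,
    head_hidden = 8, biases = "lab", lambda = 20, lr = 1e-2,
    batch_size = 64, epochs = 12, seed = 8)
  hold <- man$patient %in% sprintf("p%03d", 91:120)
  m_abl <- train_model(man[!hold, ], x[!hold, ], cfg, ablate = TRUE)
  m_base <- train_model(man[!hold, ], x[!hold, ], cfg, ablate = FALSE)
  # probe: refit a linear read-out of the bias on half the held-out MSS
  # features and score its out-of-sample corr^2 on the other half
  probe_corr2 <- function(m) {
    idx <- which(hold & y == "MSS")
    f <- predict(m, x[idx, ], type = "features")
    b <- as.numeric(bias[idx] == "L1")
    tr <- seq_len(length(idx) %/% 2)
    te <- setdiff(seq_along(idx), tr)
    fit <- stats::lm(b[tr] ~ f[tr, , drop = FALSE])
    pred <- cbind(1, f[te, ]) %*% ifelse(is.na(coef(fit)), 0, coef(fit))
    stats::cor(b[te], pred)^2
  }
  expect_lt(probe_corr2(m_abl), 0.2)
  expect_gt(probe_corr2(m_base), 0.2)
  pr <- predict(m_abl, x[hold, ])
  expect_gt(mean(pr$pred_label == y[hold]), 0.9)
})

test_that("dc trace, tidy and glance expose the monitored series", {
  fx <- local_train_fixture(25)
  cfg <- train_config(net_px = 8, feature_dim = 16, fe_hidden = 16,
    head_hidden = 16, batch_size = 32, epochs = 2, seed = 9)
  m <- train_model(fx$man, fx$x, cfg, ablate = TRUE)
  expect_true(all(c("iteration", "epoch", "loss_msi", "dc_msi_label",
    "dc_project", "dc_patient", "dc_glass") %in% names(m$trace)))
  td <- tidy(m)
  expect_setequal(unique(td$metric),
    c("loss_msi", "dc_msi_label", "dc_project", "dc_patient", "dc_glass"))
  gl <- glance(m)
  expect_identical(gl$model, "bias-ablated")
  expect_identical(gl$iterations, nrow(m$trace))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("patient-grouped training split never leaks and predicts tibbles", {
  fx <- local_train_fixture(26)
  plan <- grouped_kfold_split(fx$man, k = 4, seed = 2)
  cfg <- train_config(net_px = 8, feature_dim = 16, fe_hidden = 16,
    head_hidden = 16, batch_size = 32, epochs = 1, seed = 10)
  m <- train_model(fx$man, fx$x, cfg, ablate = FALSE, fold_plan = plan,
    fold = 2)
  expect_length(intersect(fx$man$patient[m$train_idx],
    fx$man$patient[m$val_idx]), 0)
  pr <- predict(m, fx$x[m$val_idx, , drop = FALSE])
  expect_s3_class(pr, "tbl_df")
  expect_identical(nrow(pr), length(m$val_idx))
  expect_true(all(abs(pr$prob_msi + pr$prob_mss - 1) < 1e-9))
  f <- predict(m, fx$x[1:3, , drop = FALSE], type = "features")
  expect_identical(dim(f), c(3L, 16L))
})
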