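#' Removable-confound synthetic benchmark
#'
#' Builds the paired train / bias-flipped-test datasets used to demonstrate
#' bias distillation: the training cohort carries a strong but removable
#' project-label confound (both classes occur in every project), glass tints
#' and patient signatures; the test cohort is drawn with the project-class
#' association reversed, so a model that exploits the project stain shift
#' collapses on it while a model that relies on morphology does not.
#'
#' Scale and conditions: about 200 patients with about 40 tiles each at 64-px
#' resolution, MSI-H patient prevalence 15% (the assumed real-population
#' screening prevalence), project confound 0.7 — strong but removable: both
#' classes stay represented in both projects, the regime in which adversarial
#' ablation is effective — and mixed glasses (`glass_class_purity = 0`).
#' `degenerate_glass = TRUE` switches to the single-class-glass configuration
#' (`glass_class_purity = 1`, two glasses) in which the glass and the label
#' are unequivocally associated and decoupling is infeasible.
#'
#' @param seed Integer seed (the test cohort uses a derived seed).
#' @param n_patients Patients in the training cohort.
#' @param net_px Stored pixel resolution (network input side).
#' @param degenerate_glass Use single-class glasses?
#' @return List with `train` and `test` (both `synth_dataset`, pixels stored
#'   at `net_px`) and the shared `config`.
#' @export
confound_benchmark <- function(seed = 1L, n_patients = 200, net_px = 16,
                               degenerate_glass = FALSE) {
  cfg <- synth_config(
    n_patients = n_patients,
    tiles_per_patient_range = c(30, 50),
    msi_prevalence = 0.15,
    n_projects = 2,
    n_glasses = if (degenerate_glass) 2 else 8,
    glass_class_purity = if (degenerate_glass) 1 else 0,
    project_confound = 0.7,
    stain_shift_magnitude = 0.12,
    glass_tint_magnitude = 0.15,
    patient_texture_sd = 0.12,
    signal_strength = 0.8,
    magnifications = "x40",
    tile_px = 64,
    seed = seed
  )
  test_cfg <- cfg
  test_cfg$n_patients <- max(40L, as.integer(n_patients / 4))
  test_cfg$confound_flip <- TRUE
  test_cfg$seed <- derive_seeds(seed, 1, salt = 97L)
  list(
    train = synthesize_dataset(cfg, net_px = net_px),
    test = synthesize_dataset(test_cfg, net_px = net_px),
    config = cfg
  )
}

#' Train paired baseline and bias-ablated models on a benchmark
#'
#' Trains both regimes under the same seed and data order, audits the
#' MSS-conditioned dependence of the learned features on each protected
#' variable, and evaluates tile-level AUC on the bias-flipped test cohort.
#'
#' @param bench A [confound_benchmark()].
#' @param config A [train_config()]; its seed governs both runs.
#' @return List with `baseline` and `ablated` (each: `model`, `audit`,
#'   `auc_flipped`) and the benchmark.
#' @export
run_ablation_benchmark <- function(bench, config = train_config()) {
  x_train <- as_input_matrix(bench$train, config$net_px)
  x_test <- as_input_matrix(bench$test, config$net_px)
  man <- bench$train$manifest
  one <- function(ablate) {
    model <- train_model(man, x_train, config, ablate = ablate)
    mss <- man$msi_label == config$rho
    feats <- predict(model, x_train[mss, , drop = FALSE], type = "features")
    audit <- bias_audit(man[mss, , drop = FALSE], feats,
      variables = config$biases, max_n = 2048, seed = config$seed)
    pred <- predict(model, x_test)
    list(model = model, audit = audit,
      auc_flipped = auc_rank(pred$prob_msi, bench$test$manifest$msi_label))
  }
  list(baseline = one(FALSE), ablated = one(TRUE), bench = bench)
}
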