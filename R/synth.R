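#' Configuration for the synthetic TMA tile generator
#'
#' Defines the generative factors of a synthetic tissue-microarray dataset:
#' a class-dependent morphology signal (the only "biological" information),
#' plus three protected-variable overlays that emulate the batch effects of
#' multi-centre TMA studies — a per-project stain shift that may be
#' correlated with the MSI label, a per-glass hue tint (optionally with
#' single-class glasses), and a per-patient colour/texture signature.
#'
#' @param n_patients Number of patients.
#' @param tiles_per_patient_range Integer `c(min, max)`: tiles drawn uniformly
#'   per patient.
#' @param msi_prevalence Fraction of MSI-H patients in `[0,1]`. Default 0.074,
#'   the population-based prevalence of mismatch-repair deficiency in the
#'   cohorts the generator emulates.
#' @param n_projects Number of contributing projects (sources).
#' @param n_glasses Number of TMA glasses.
#' @param glass_class_purity Fraction in `[0,1]`; probability that a patient is
#'   placed on a glass holding only its own MSI class. `1.0` makes every glass
#'   single-class (the degenerate configuration in which the glass and the
#'   label are unequivocally confounded).
#' @param project_confound Strength in `[0,1]`: probability that a patient's
#'   project follows its MSI class (MSI-H to project 1, MSS to the others)
#'   rather than being drawn uniformly.
#' @param confound_flip If `TRUE`, the project–class association is reversed
#'   (MSS to project 1). Used to build bias-flipped evaluation splits.
#' @param stain_shift_magnitude RGB offset scale of the per-project stain shift.
#' @param glass_tint_magnitude Hue offset scale of the per-glass tint
#'   (fraction of the hue circle).
#' @param patient_texture_sd Standard deviation of the per-patient colour
#'   offset and amplitude of the per-patient low-frequency texture signature.
#' @param signal_strength Separation of the class-dependent morphology in
#'   `[0,1]`: scales the excess density of dark tumour nuclei and the
#'   mucin-like pale regions of MSI-H tiles.
#' @param magnifications Character vector, subset of
#'   `c("x40","x20","x10","x5","x0")`; one is sampled per tile. `"x0"` denotes
#'   a whole-spot thumbnail view, emulated at the strongest blur level.
#' @param tissue_probs Named numeric vector of sampling probabilities over the
#'   nine tissue classes; defaults to the post-filtering mix of tumour
#'   epithelium, lymphocytes and mucin.
#' @param tile_px Tile side in pixels.
#' @param seed Integer seed; identical seed and configuration give a
#'   byte-identical dataset.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 200,
                         tiles_per_patient_range = c(20, 60),
                         msi_prevalence = 0.074,
                         n_projects = 2,
                         n_glasses = 8,
                         glass_class_purity = 0,
                         project_confound = 0,
                         confound_flip = FALSE,
                         stain_shift_magnitude = 0.10,
                         glass_tint_magnitude = 0.05,
                         patient_texture_sd = 0.03,
                         signal_strength = 0.7,
                         magnifications = "x40",
                         tissue_probs = c(TUM = 0.7, LYM = 0.15, MUC = 0.15),
                         tile_px = 64,
                         seed = 1L) {
  fr <- c(msi_prevalence = msi_prevalence,
          glass_class_purity = glass_class_purity,
          project_confound = project_confound,
          signal_strength = signal_strength)
  for (nm in names(fr)) {
    assert_that(is.numeric(fr[[nm]]) && fr[[nm]] >= 0 && fr[[nm]] <= 1,
      paste0(nm, " must lie in [0, 1]"))
  }
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  assert_that(length(tiles_per_patient_range) == 2 &&
    tiles_per_patient_range[1] >= 1 &&
    tiles_per_patient_range[1] <= tiles_per_patient_range[2],
    "tiles_per_patient_range must be c(min, max) with 1 <= min <= max")
  assert_that(n_projects >= 1 && n_glasses >= 1,
    "n_projects and n_glasses must be >= 1")
  assert_that(all(magnifications %in% names(mag_factors())),
    paste0("magnifications must be a subset of ",
      paste(names(mag_factors()), collapse = ", ")))
  bad <- setdiff(names(tissue_probs), tissue_classes())
  assert_that(length(bad) == 0,
    paste0("unknown tissue class(es): ", paste(bad, collapse = ", ")))
  assert_that(tile_px >= 16, "tile_px must be >= 16")
  if (glass_class_purity == 1 && msi_prevalence > 0 && msi_prevalence < 1 &&
      n_glasses < 2) {
    stop("configuration error: glass_class_purity = 1 with both classes ",
      "requires n_glasses >= 2", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      tiles_per_patient_range = as.integer(tiles_per_patient_range),
      msi_prevalence = msi_prevalence,
      n_projects = as.integer(n_projects),
      n_glasses = as.integer(n_glasses),
      glass_class_purity = glass_class_purity,
      project_confound = project_confound,
      confound_flip = isTRUE(confound_flip),
      stain_shift_magnitude = stain_shift_magnitude,
      glass_tint_magnitude = glass_tint_magnitude,
      patient_texture_sd = patient_texture_sd,
      signal_strength = signal_strength,
      magnifications = magnifications,
      tissue_probs = tissue_probs / sum(tissue_probs),
      tile_px = as.integer(tile_px),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' The nine colorectal tissue classes
#'
#' Adipose (ADI), background (BACK), debris (DEB), lymphocytes (LYM), mucus
#' (MUC), smooth muscle (MUS), normal epithelium (NORM), cancer-associated
#' stroma (STR) and tumour epithelium (TUM).
#'
#' @return Character vector of the nine class codes.
#' @export
tissue_classes <- function() {
  c("ADI", "BACK", "DEB", "LYM", "MUC", "MUS", "NORM", "STR", "TUM")
}

# Linear downsampling factor per magnification relative to native x40.
mag_factors <- function() {
  c(x40 = 1L, x20 = 2L, x10 = 4L, x5 = 8L, x0 = 16L)
}

# ---- painters ---------------------------------------------------------------
# All painters consume the current RNG stream; callers control reproducibility.

# Per-tissue texture parameters: base colour and structural elements.
tissue_palette <- function() {
  list(
    TUM  = list(base = c(0.85, 0.70, 0.82), n_nuclei = 9,  nuc_r = c(2.0, 4.0),
                stripes = 0,    dots = 0,  signal = 1.0),
    LYM  = list(base = c(0.80, 0.72, 0.88), n_nuclei = 0,  nuc_r = c(1.0, 1.8),
                stripes = 0,    dots = 45, signal = 0.55),
    MUC  = list(base = c(0.89, 0.87, 0.94), n_nuclei = 3,  nuc_r = c(1.5, 2.5),
                stripes = 0.04, dots = 0,  signal = 0.55),
    STR  = list(base = c(0.90, 0.76, 0.86), n_nuclei = 4,  nuc_r = c(1.5, 3.0),
                stripes = 0.08, dots = 0,  signal = 0),
    NORM = list(base = c(0.87, 0.72, 0.83), n_nuclei = 6,  nuc_r = c(1.8, 3.0),
                stripes = 0,    dots = 0,  signal = 0, rings = 3),
    MUS  = list(base = c(0.86, 0.62, 0.76), n_nuclei = 2,  nuc_r = c(1.2, 2.2),
                stripes = 0.16, dots = 0,  signal = 0),
    ADI  = list(base = c(0.95, 0.92, 0.95), n_nuclei = 0,  nuc_r = c(1.0, 1.5),
                stripes = 0,    dots = 0,  signal = 0, rings = 5),
    DEB  = list(base = c(0.76, 0.68, 0.70), n_nuclei = 0,  nuc_r = c(1.0, 2.0),
                stripes = 0,    dots = 0,  signal = 0, grain = 0.10),
    BACK = list(base = c(0.97, 0.96, 0.97), n_nuclei = 0,  nuc_r = c(1.0, 1.0),
                stripes = 0,    dots = 0,  signal = 0, flat = TRUE)
  )
}

# Paint elliptical dark blobs ("nuclei") onto an image; soft-edged alpha
# blend. Work is confined to each blob's bounding box.
paint_nuclei <- function(img, n, r_range, colour = c(0.28, 0.16, 0.46),
                         elongation = 1) {
  if (n <= 0) return(img)
  px <- dim(img)[1]
  cx <- runif(n, 1, px); cy <- runif(n, 1, px)
  rx <- runif(n, r_range[1], r_range[2]) * elongation
  ry <- runif(n, r_range[1], r_range[2])
  th <- runif(n, 0, pi)
  shade <- runif(n, 0.85, 1.15)
  for (i in seq_len(n)) {
    rmax <- max(rx[i], ry[i])
    rows <- max(1, floor(cy[i] - rmax)):min(px, ceiling(cy[i] + rmax))
    cols <- max(1, floor(cx[i] - rmax)):min(px, ceiling(cx[i] + rmax))
    dx <- outer(rep(1, length(rows)), cols - cx[i])
    dy <- outer(rows - cy[i], rep(1, length(cols)))
    u <- (dx * cos(th[i]) + dy * sin(th[i])) / rx[i]
    v <- (-dx * sin(th[i]) + dy * cos(th[i])) / ry[i]
    alpha <- pmin(pmax(1.6 * (1 - (u^2 + v^2)), 0), 0.92)
    if (!any(alpha > 0)) next
    for (ch in 1:3) {
      img[rows, cols, ch] <- img[rows, cols, ch] * (1 - alpha) +
        colour[ch] * shade[i] * alpha
    }
  }
  img
}

# Paint pale round regions (mucin pools / fat vacuoles).
paint_pale_blobs <- function(img, n, r_range, colour = c(0.93, 0.91, 0.96),
                             alpha_max = 0.65) {
  if (n <= 0) return(img)
  px <- dim(img)[1]
  cx <- runif(n, 1, px); cy <- runif(n, 1, px)
  r <- runif(n, r_range[1], r_range[2])
  for (i in seq_len(n)) {
    rows <- max(1, floor(cy[i] - r[i])):min(px, ceiling(cy[i] + r[i]))
    cols <- max(1, floor(cx[i] - r[i])):min(px, ceiling(cx[i] + r[i]))
    dx <- outer(rep(1, length(rows)), cols - cx[i])
    dy <- outer(rows - cy[i], rep(1, length(cols)))
    d2 <- (dx^2 + dy^2) / r[i]^2
    alpha <- pmin(pmax(1.3 * (1 - d2), 0), alpha_max)
    if (!any(alpha > 0)) next
    for (ch in 1:3) {
      img[rows, cols, ch] <- img[rows, cols, ch] * (1 - alpha) +
        colour[ch] * alpha
    }
  }
  img
}

# Paint one tile of a given tissue class; msi and signal_strength control the
# class-dependent morphology (denser, larger nuclei and mucin-like pale
# regions in MSI-H tumour epithelium; attenuated in LYM/MUC).
paint_tile <- function(tile_px, tissue, msi, signal_strength) {
  pal <- tissue_palette()[[tissue]]
  img <- array(rep(pal$base, each = tile_px * tile_px), c(tile_px, tile_px, 3))
  g <- pixel_grids(tile_px)
  xs <- g$xs / tile_px
  ys <- g$ys / tile_px

  if (!isTRUE(pal$flat)) {
    # low-frequency background mottle
    ph <- runif(4, 0, 2 * pi)
    mottle <- 0.025 * (sin(2 * pi * (1.7 * xs + 0.9 * ys) + ph[1]) +
                       sin(2 * pi * (0.8 * xs - 1.9 * ys) + ph[2]))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + mottle
  }
  if (pal$stripes > 0) {
    ang <- runif(1, 0, pi)
    freq <- runif(1, 4, 7)
    stripe <- pal$stripes * sin(2 * pi * freq * (cos(ang) * xs + sin(ang) * ys) +
      runif(1, 0, 2 * pi))
    img[, , 1] <- img[, , 1] - stripe
    img[, , 2] <- img[, , 2] - 1.4 * stripe
    img[, , 3] <- img[, , 3] - 0.6 * stripe
  }
  if (!is.null(pal$grain)) {
    g <- matrix(runif(tile_px^2, -pal$grain, pal$grain), tile_px)
    g <- (g + rbind(g[-1, ], g[1, ]) + cbind(g[, -1], g[, 1])) / 3
    for (ch in 1:3) img[, , ch] <- img[, , ch] + g
  }
  if (!is.null(pal$rings)) {
    # ring structures: glands (NORM) or fat vacuole borders (ADI)
    n <- rpois(1, pal$rings)
    if (n > 0) {
      pxs <- g$xs
      pys <- g$ys
      for (i in seq_len(n)) {
        cx <- runif(1, 1, tile_px); cy <- runif(1, 1, tile_px)
        r <- runif(1, tile_px / 10, tile_px / 5)
        d <- sqrt((pxs - cx)^2 + (pys - cy)^2)
        ring <- pmax(0, 1 - abs(d - r) / 1.5) * 0.35
        for (ch in 1:3) img[, , ch] <- img[, , ch] - ring * c(0.4, 0.5, 0.2)[ch]
      }
    }
  }
  if (pal$dots > 0) {
    n <- rpois(1, pal$dots * (1 + 1.2 * pal$signal * signal_strength * msi))
    img <- paint_nuclei(img, n, pal$nuc_r, colour = c(0.30, 0.20, 0.52))
  }
  if (pal$n_nuclei > 0) {
    boost <- 1 + 2.5 * pal$signal * signal_strength * msi
    n <- rpois(1, pal$n_nuclei * boost)
    elong <- if (tissue %in% c("STR", "MUS")) 2.2 else 1
    # MSI-H tumour nuclei drawn larger (enlarged, irregular nuclei)
    rr <- pal$nuc_r * (1 + 0.4 * pal$signal * signal_strength * msi)
    img <- paint_nuclei(img, n, rr, elongation = elong)
  }
  if (msi == 1 && pal$signal > 0) {
    n_muc <- rpois(1, 2.5 * pal$signal * signal_strength)
    img <- paint_pale_blobs(img, n_muc, c(tile_px / 10, tile_px / 5))
  }
  # re-centre each channel to the tissue base colour so the class morphology
  # carries spatial structure (texture, granularity) rather than a mean colour
  # shift; mean-colour axes are reserved for the batch-effect overlays
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] - mean(img[, , ch]) + pal$base[ch]
  }
  clamp01(img)
}

# Fixed per-project stain-shift directions (unit RGB vectors, recycled).
project_directions <- function(n) {
  base <- rbind(
    c(1, -0.4, -0.2),
    c(-0.8, 0.3, 0.9),
    c(0.2, 1, -0.7),
    c(-0.5, -0.6, 0.6)
  )
  base <- base / sqrt(rowSums(base^2))
  base[((seq_len(n) - 1) %% nrow(base)) + 1, , drop = FALSE]
}

# Deterministic per-glass hue offsets in [-1, 1], golden-ratio spaced.
glass_hue_units <- function(n) {
  ((seq_len(n) * 0.6180339887) %% 1) * 2 - 1
}

# Apply the batch-effect overlays to a painted tile.
apply_batch_effects <- function(img, config, project, glass,
                                patient_offset, patient_phase) {
  px <- dim(img)[1]
  # project stain shift
  if (config$stain_shift_magnitude > 0) {
    d <- project_directions(config$n_projects)[project, ]
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] + config$stain_shift_magnitude * d[ch]
    }
  }
  # glass tint (hue rotation)
  if (config$glass_tint_magnitude > 0) {
    delta <- config$glass_tint_magnitude * glass_hue_units(config$n_glasses)[glass]
    img <- shift_hue(clamp01(img), delta)
  }
  # patient signature: colour offset + a patient-specific mixture of
  # low-frequency textured fields (distinct frequencies, phases and channel
  # weights per patient), giving each patient a high-dimensional stain/texture
  # fingerprint as tiles of one patient share lab and slicing conditions
  if (config$patient_texture_sd > 0) {
    g <- pixel_grids(px)
    xs <- g$xs / px
    ys <- g$ys / px
    fields <- lapply(1:3, function(k) {
      p <- patient_phase[(k - 1) * 6 + 1:6]
      sin(2 * pi * (p[1] * xs + p[2] * ys) + p[3])
    })
    for (ch in 1:3) {
      tex <- 0
      for (k in 1:3) {
        w <- patient_phase[(k - 1) * 6 + 3 + ch]
        tex <- tex + w * fields[[k]]
      }
      img[, , ch] <- img[, , ch] + patient_offset[ch] +
        config$patient_texture_sd * tex
    }
  }
  # sensor noise
  img <- img + array(rnorm(length(img), 0, 0.015), dim(img))
  clamp01(img)
}

# Emulate a magnification level: box-filter downsample by the magnification
# factor, then nearest-neighbour upsample back to the native tile size, so all
# magnifications share the tile raster while carrying coarser detail.
emulate_magnification <- function(img, magnification) {
  f <- mag_factors()[[magnification]]
  if (f == 1L) return(img)
  upsample_nn(block_mean(img, f), f)
}

# ---- dataset synthesis ------------------------------------------------------

#' Synthesize a TMA-like tile dataset with controllable batch effects
#'
#' Draws patients with MSI labels, assigns them to projects and TMA glasses
#' (optionally confounded with the label), paints per-tile morphology whose
#' class signal is the only biological information, overlays project /
#' glass / patient colour effects, and emulates the requested magnifications.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory: when given, tiles are written as PNG files
#'   under one sub-directory per magnification, together with `manifest.csv`
#'   and `config.yaml`, and the manifest gains a `path` column.
#' @param net_px Optional integer: when given, stored pixel arrays are
#'   area-averaged down to `net_px` x `net_px` (the network input resolution),
#'   which keeps large benchmark datasets memory-light. PNG output (via `dir`)
#'   is always written at full tile resolution.
#'
#' @return A `synth_dataset`: list with `manifest` (tibble with columns
#'   `tile_id, spot_id, patient, project, glass, magnification, tissue,
#'   msi_label`), `pixels` (list of RGB arrays aligned with the manifest) and
#'   `config`.
#' @export
#' @examples
#' ds <- synthesize_dataset(synth_config(n_patients = 4,
#'   tiles_per_patient_range = c(2, 3), tile_px = 32, seed = 7))
#' ds$manifest
synthesize_dataset <- function(config, dir = NULL, net_px = NULL) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  seeds <- derive_seeds(config$seed, 2)
  pts <- with_seed(seeds[1], draw_patients(config))
  n_tiles_per <- with_seed((seeds[1] + 1L) %% .Machine$integer.max,
    sample(seq(config$tiles_per_patient_range[1],
      config$tiles_per_patient_range[2]), config$n_patients, replace = TRUE))

  manifests <- vector("list", config$n_patients)
  pixel_sets <- vector("list", config$n_patients)
  tissue_names <- names(config$tissue_probs)
  for (i in seq_len(config$n_patients)) {
    nt <- n_tiles_per[i]
    res <- with_seed((seeds[2] + i) %% .Machine$integer.max, {
      mags <- sample(config$magnifications, nt, replace = TRUE)
      tissues <- sample(tissue_names, nt, replace = TRUE,
        prob = config$tissue_probs)
      spots <- sample(1:2, nt, replace = TRUE)
      tiles <- vector("list", nt)
      for (j in seq_len(nt)) {
        img <- paint_tile(config$tile_px, tissues[j], pts$msi[i],
          config$signal_strength)
        img <- apply_batch_effects(img, config, pts$project[i], pts$glass[i],
          pts$offset[i, ], pts$phase[i, ])
        img <- emulate_magnification(img, mags[j])
        if (!is.null(net_px)) img <- resize_rgb(img, as.integer(net_px))
        tiles[[j]] <- img
      }
      list(mags = mags, tissues = tissues, spots = spots, tiles = tiles)
    })
    manifests[[i]] <- tibble::tibble(
      patient = pts$id[i],
      spot_id = paste0(pts$id[i], "_s", res$spots),
      project = paste0("P", pts$project[i]),
      glass = paste0("G", pts$glass[i]),
      magnification = res$mags,
      tissue = res$tissues,
      msi_label = if (pts$msi[i] == 1) "MSI-H" else "MSS"
    )
    pixel_sets[[i]] <- res$tiles
  }
  manifest <- dplyr::bind_rows(manifests)
  manifest$tile_id <- sprintf("t%06d", seq_len(nrow(manifest)))
  manifest <- manifest[, c("tile_id", "spot_id", "patient", "project", "glass",
    "magnification", "tissue", "msi_label")]
  pixels <- unlist(pixel_sets, recursive = FALSE)

  out <- structure(list(manifest = manifest, pixels = pixels, config = config),
    class = "synth_dataset")
  if (!is.null(dir)) {
    write_synth_dataset(out, dir)
    out$manifest$path <- file.path(dir, out$manifest$magnification,
      paste0(out$manifest$tile_id, ".png"))
  }
  out
}

# Patient-level draws: MSI label, project, glass, colour signature.
draw_patients <- function(config) {
  n <- config$n_patients
  msi <- as.integer(runif(n) < config$msi_prevalence)
  # project assignment, optionally confounded with the label
  msi_proj <- if (config$confound_flip) 1 - msi else msi
  project <- integer(n)
  for (i in seq_len(n)) {
    if (config$n_projects == 1) {
      project[i] <- 1L
    } else if (runif(1) < config$project_confound) {
      pool <- seq(2L, config$n_projects)
      project[i] <- if (msi_proj[i] == 1) 1L else
        pool[sample.int(length(pool), 1)]
    } else {
      project[i] <- sample.int(config$n_projects, 1)
    }
  }
  # glass assignment with optional single-class glasses
  glass_class <- rep_len(c(0L, 1L), config$n_glasses)  # designated class per glass
  glass <- integer(n)
  for (i in seq_len(n)) {
    if (runif(1) < config$glass_class_purity) {
      pool <- which(glass_class == msi[i])
      if (length(pool) == 0) {
        stop("configuration error: no glass available for class ",
          c("MSS", "MSI-H")[msi[i] + 1], " at glass_class_purity = 1",
          call. = FALSE)
      }
      glass[i] <- pool[sample.int(length(pool), 1)]
    } else {
      glass[i] <- sample.int(config$n_glasses, 1)
    }
  }
  offset <- matrix(rnorm(3 * n, 0, config$patient_texture_sd), n, 3)
  # per patient: 3 texture components x (freq_x, freq_y, phase, 3 channel
  # weights); frequencies low so the fields survive area-averaging
  phase <- matrix(0, n, 18)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      phase[i, (k - 1) * 6 + 1:6] <- c(runif(2, 0.5, 2.5), runif(1, 0, 2 * pi),
        rnorm(3, 0, 0.7))
    }
  }
  list(id = sprintf("pt%04d", seq_len(n)), msi = msi, project = project,
    glass = glass, offset = offset, phase = phase)
}

# Write tiles as PNG plus manifest.csv and config.yaml.
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in unique(dataset$manifest$magnification)) {
    dir.create(file.path(dir, m), showWarnings = FALSE)
  }
  for (i in seq_len(nrow(dataset$manifest))) {
    png::writePNG(dataset$pixels[[i]],
      file.path(dir, dataset$manifest$magnification[i],
        paste0(dataset$manifest$tile_id[i], ".png")))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
    row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$tissue_probs <- as.list(cfg$tissue_probs)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset> ", nrow(x$manifest), " tiles, ",
    length(unique(x$manifest$patient)), " patients, ",
    sum(x$manifest$msi_label == "MSI-H"), " MSI-H tiles\n", sep = "")
  invisible(x)
}

#' Synthesize a whole TMA spot image
#'
#' Paints a single spot raster (one patient's tissue core) with the same
#' texture model as [synthesize_dataset()], for exercising the tiling
#' pipeline. The raster need not be square.
#'
#' @param width,height Raster size in pixels at native resolution.
#' @param tissue Tissue class painted across the spot.
#' @param msi 0/1 morphology signal flag.
#' @param signal_strength Morphology separation in `[0,1]`.
#' @param mpp Microns per pixel at native resolution.
#' @param spot_id,patient,project,glass Identifiers carried on the object.
#' @param seed Integer seed.
#' @return A `spot_image`: list with `pixels`, `mpp` and the identifiers.
#' @export
synthesize_spot <- function(width = 1200, height = 800, tissue = "TUM",
                            msi = 0, signal_strength = 0.7, mpp = 0.25,
                            spot_id = "spot1", patient = "pt0001",
                            project = "P1", glass = "G1", seed = 1L) {
  px <- max(width, height)
  img <- with_seed(seed, {
    base <- paint_tile(px, tissue, msi, signal_strength)
    base[seq_len(height), seq_len(width), , drop = FALSE]
  })
  spot_image(img, mpp = mpp, spot_id = spot_id, patient = patient,
    project = project, glass = glass)
}

#' Construct a spot image object
#'
#' @param pixels RGB array (rows x cols x 3, values in `[0,1]`).
#' @param mpp Microns per pixel at native resolution (must be > 0).
#' @param spot_id,patient,project,glass Identifiers.
#' @return A `spot_image` object.
#' @export
spot_image <- function(pixels, mpp = 0.25, spot_id = "spot1",
                       patient = "pt0001", project = "P1", glass = "G1") {
  assert_that(is_rgb_array(pixels), "pixels must be an RGB array (h x w x 3)")
  assert_that(length(pixels) > 0, "raster must be non-empty")
  assert_that(is.numeric(mpp) && mpp > 0, "mpp must be > 0")
  structure(list(pixels = pixels, mpp = mpp, spot_id = spot_id,
    patient = patient, project = project, glass = glass),
    class = "spot_image")
}

#' Synthesize a labelled nine-tissue-class dataset
#'
#' Emits tiles of all nine colorectal tissue classes as distinct procedural
#' textures (no batch-effect overlays), for training and testing the tissue
#' classifier.
#'
#' @param n_per_class Tiles per tissue class.
#' @param tile_px Tile side in pixels.
#' @param classes Character vector of classes to emit (default all nine).
#' @param seed Integer seed.
#' @return A `synth_dataset` with a `tissue` column and no MSI structure.
#' @export
synthesize_tissue_dataset <- function(n_per_class = 60, tile_px = 32,
                                      classes = tissue_classes(), seed = 1L) {
  bad <- setdiff(classes, tissue_classes())
  assert_that(length(bad) == 0,
    paste0("unknown tissue class(es): ", paste(bad, collapse = ", ")))
  grid <- expand.grid(tissue = classes, rep = seq_len(n_per_class),
    stringsAsFactors = FALSE)
  pixels <- vector("list", nrow(grid))
  with_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      img <- paint_tile(tile_px, grid$tissue[i], msi = 0, signal_strength = 0)
      img <- img + array(rnorm(length(img), 0, 0.015), dim(img))
      pixels[[i]] <- clamp01(img)
    }
  })
  manifest <- tibble::tibble(
    tile_id = sprintf("t%06d", seq_len(nrow(grid))),
    spot_id = NA_character_, patient = NA_character_,
    project = NA_character_, glass = NA_character_,
    magnification = "x40", tissue = grid$tissue, msi_label = NA_character_
  )
  structure(list(manifest = manifest, pixels = pixels, config = NULL),
    class = "synth_dataset")
}

#' Flatten a dataset's tiles into a network input matrix
#'
#' Area-averages every tile to `net_px` pixels, optionally appends local
#' gradient-magnitude maps (absolute horizontal and vertical neighbour
#' differences per channel — a fixed edge/texture front end for the dense
#' trunk), and flattens everything to a row of a numeric matrix (row order
#' matches the manifest).
#'
#' @param dataset A `synth_dataset`, or a list of RGB arrays.
#' @param net_px Network input resolution (side in pixels).
#' @param gradients Append gradient-magnitude maps? (default `TRUE`).
#' @return N x p numeric matrix; `p = net_px^2 * 3` plus
#'   `2 * (net_px - 1) * net_px * 3` when `gradients = TRUE`.
#' @export
as_input_matrix <- function(dataset, net_px = 16L, gradients = TRUE) {
  pixels <- if (inherits(dataset, "synth_dataset")) dataset$pixels else dataset
  do.call(rbind, lapply(pixels, function(img) {
    tile_input_features(resize_rgb(img, as.integer(net_px)), gradients)
  }))
}

# One tile's flattened network input: pixels (+ gradient magnitudes).
tile_input_features <- function(img, gradients = TRUE) {
  if (!gradients) return(as.vector(img))
  d <- dim(img)
  dv <- abs(img[-1, , , drop = FALSE] - img[-d[1], , , drop = FALSE])
  dh <- abs(img[, -1, , drop = FALSE] - img[, -d[2], , drop = FALSE])
  c(as.vector(img), as.vector(dv), as.vector(dh))
}
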