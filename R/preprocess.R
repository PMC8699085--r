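#' Extract non-overlapping tiles from a TMA spot at multiple magnifications
#'
#' For each requested magnification the native raster (assumed scanned at
#' x40, 0.25 microns per pixel) is area-averaged down by the magnification
#' factor (x20 halves the linear resolution, and so on), then cut into a
#' non-overlapping `tile_px` grid anchored at the top-left corner, row-major;
#' partial border tiles are discarded. `"x0"` denotes a whole-spot thumbnail:
#' the full raster resized to one `tile_px` tile. Background-only tiles
#' (more than `background_max_frac` of pixels with HSV saturation below
#' `background_sat`) are dropped before tissue classification.
#'
#' @param spot A [spot_image()].
#' @param magnifications Character vector, subset of
#'   `c("x40","x20","x10","x5","x0")`.
#' @param tile_px Tile side in pixels (default 400, the native tiling size).
#' @param background_sat,background_max_frac Saturation threshold and maximal
#'   background fraction of the pre-filter; set `background_max_frac = 1` to
#'   disable it (background can then still be rejected later through the
#'   tissue classifier's BACK class).
#'
#' @return A tibble with one row per retained tile: `tile_id, spot_id,
#'   patient, project, glass, magnification, row, col` and a `pixels`
#'   list-column of `tile_px` RGB arrays.
#' @export
extract_tiles <- function(spot, magnifications = "x40", tile_px = 400,
                          background_sat = 0.05, background_max_frac = 0.8) {
  assert_that(inherits(spot, "spot_image"), "spot must be a spot_image")
  fac <- mag_factors()
  bad <- setdiff(magnifications, names(fac))
  if (length(bad) > 0) {
    stop("unsupported magnification(s): ", paste(bad, collapse = ", "),
      call. = FALSE)
  }
  d <- dim(spot$pixels)
  rows <- list()
  for (m in magnifications) {
    if (m == "x0") {
      img <- resize_rgb(square_crop(spot$pixels), tile_px)
      grid <- data.frame(row = 1L, col = 1L)
      tiles <- list(img)
    } else {
      f <- fac[[m]]
      if (d[1] %/% f < 1 || d[2] %/% f < 1) {
        stop("unsupported magnification ", m, " for raster of size ",
          d[1], "x", d[2], call. = FALSE)
      }
      img <- block_mean(spot$pixels, f)
      nr <- dim(img)[1] %/% tile_px
      nc <- dim(img)[2] %/% tile_px
      if (nr < 1 || nc < 1) next
      grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, c("row", "col")]
      tiles <- lapply(seq_len(nrow(grid)), function(i) {
        r0 <- (grid$row[i] - 1) * tile_px
        c0 <- (grid$col[i] - 1) * tile_px
        img[r0 + seq_len(tile_px), c0 + seq_len(tile_px), , drop = FALSE]
      })
    }
    keep <- !vapply(tiles, is_background_tile, logical(1),
      sat = background_sat, max_frac = background_max_frac)
    if (!any(keep)) next
    rows[[m]] <- tibble::tibble(
      spot_id = spot$spot_id, patient = spot$patient,
      project = spot$project, glass = spot$glass,
      magnification = m, row = grid$row[keep], col = grid$col[keep],
      pixels = tiles[keep]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(tile_id = character(), spot_id = character(),
      patient = character(), project = character(), glass = character(),
      magnification = character(), row = integer(), col = integer(),
      pixels = list()))
  }
  out$tile_id <- sprintf("%s_%s_r%02dc%02d", out$spot_id, out$magnification,
    out$row, out$col)
  out[, c("tile_id", "spot_id", "patient", "project", "glass",
    "magnification", "row", "col", "pixels")]
}

square_crop <- function(img) {
  d <- dim(img)
  s <- min(d[1], d[2])
  img[seq_len(s), seq_len(s), , drop = FALSE]
}

is_background_tile <- function(tile, sat = 0.05, max_frac = 0.8) {
  if (max_frac >= 1) return(FALSE)
  mx <- pmax(tile[, , 1], tile[, , 2], tile[, , 3])
  mn <- pmin(tile[, , 1], tile[, , 2], tile[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  mean(s < sat) > max_frac
}

# ---- Macenko stain normalization -------------------------------------------

#' Estimate Macenko stain statistics from a reference tile
#'
#' Computes the optical-density (OD) stain matrix by the Macenko plane-fit
#' construction — singular vectors of the above-threshold OD cloud, extreme
#' angular directions at the `alpha` percentiles — plus the `beta_pct`
#' percentile of the stain concentrations, to serve as the normalization
#' target.
#'
#' @param tile RGB array in `[0,1]`.
#' @param od_threshold OD below which pixels are treated as background.
#' @param alpha Percentile (in percent) for the extreme angle selection.
#' @param beta_pct Percentile (in percent) of concentrations used as the
#'   robust maximum.
#' @return A `macenko_reference`: list with `stain_matrix` (3 x 2, unit
#'   columns: haematoxylin then eosin) and `max_conc` (length 2).
#' @export
macenko_reference <- function(tile, od_threshold = 0.15, alpha = 1,
                              beta_pct = 99) {
  fit <- macenko_fit(tile, od_threshold, alpha)
  if (is.null(fit)) {
    stop("tile has no above-threshold optical-density pixels; cannot serve ",
      "as a stain reference", call. = FALSE)
  }
  structure(list(stain_matrix = fit$stain_matrix,
    max_conc = fit$max_conc, od_threshold = od_threshold, alpha = alpha,
    beta_pct = beta_pct), class = "macenko_reference")
}

# Core Macenko estimation; returns NULL for blank tiles.
macenko_fit <- function(tile, od_threshold = 0.15, alpha = 1, beta_pct = 99) {
  od <- od_from_rgb(tile)
  odm <- matrix(od, ncol = 3)
  # drop transparent (background) pixels: mean OD below threshold
  keep <- rowMeans(odm) > od_threshold
  if (sum(keep) < 10) return(NULL)
  ods <- odm[keep, , drop = FALSE]
  # plane spanned by the two leading principal directions of the OD cloud
  sv <- svd(ods, nu = 0, nv = 3)
  v <- sv$v[, 1:2, drop = FALSE]
  # orient plane axes so projections are positive
  proj <- ods %*% v
  if (stats::median(proj[, 1]) < 0) v[, 1] <- -v[, 1]
  if (stats::median(proj[, 2]) < 0) v[, 2] <- -v[, 2]
  proj <- ods %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- stats::quantile(phi, alpha / 100, names = FALSE)
  hi <- stats::quantile(phi, 1 - alpha / 100, names = FALSE)
  s1 <- v %*% c(cos(lo), sin(lo))
  s2 <- v %*% c(cos(hi), sin(hi))
  s1 <- s1 / sqrt(sum(s1^2))
  s2 <- s2 / sqrt(sum(s2^2))
  # haematoxylin is the more blue-absorbing vector (larger first/red OD)
  stains <- if (s1[1] >= s2[1]) cbind(s1, s2) else cbind(s2, s1)
  colnames(stains) <- c("H", "E")
  conc <- stain_concentrations(odm, stains)
  max_conc <- apply(conc, 2, stats::quantile, probs = beta_pct / 100,
    names = FALSE)
  list(stain_matrix = stains, max_conc = pmax(max_conc, 1e-6))
}

od_from_rgb <- function(tile, eps = 1 / 255) {
  -log(pmax(tile, eps))
}

rgb_from_od <- function(od) {
  clamp01(exp(-od))
}

# Least-squares concentrations (pixels x 2) given a 3 x 2 stain matrix.
stain_concentrations <- function(odm, stains) {
  pmax(odm %*% stains %*% solve(crossprod(stains)), 0)
}

#' Macenko stain normalization of a tile
#'
#' Estimates the tile's own stain vectors from its optical densities, maps
#' its stain concentrations onto the reference percentile scale, and
#' reconstructs the tile in the reference stain basis. Blank tiles (no
#' above-threshold OD pixels) are returned unchanged with attribute
#' `blank = TRUE` and a warning.
#'
#' @param tile RGB array in `[0,1]`.
#' @param reference A [macenko_reference()].
#' @return Normalized RGB array (same shape); attribute `blank` is `TRUE`
#'   when the tile was left untouched.
#' @export
macenko_normalize <- function(tile, reference) {
  assert_that(inherits(reference, "macenko_reference"),
    "reference must be a macenko_reference")
  assert_that(is_rgb_array(tile), "tile must be an RGB array")
  fit <- macenko_fit(tile, reference$od_threshold, reference$alpha,
    reference$beta_pct)
  if (is.null(fit)) {
    warning("blank tile: no above-threshold optical-density pixels; ",
      "returned unchanged")
    attr(tile, "blank") <- TRUE
    return(tile)
  }
  od <- matrix(od_from_rgb(tile), ncol = 3)
  conc <- stain_concentrations(od, fit$stain_matrix)
  conc <- sweep(conc, 2, reference$max_conc / fit$max_conc, `*`)
  od_new <- conc %*% t(reference$stain_matrix)
  out <- array(rgb_from_od(od_new), dim(tile))
  attr(out, "blank") <- FALSE
  out
}

#' Channel-statistics color normalization
#'
#' Standardizes each RGB channel to the supplied dataset statistics:
#' subtracts the tile mean, divides by the tile standard deviation, then
#' rescales to the target mean/sd and clamps to `[0,1]`. A disabled flag
#' makes it the identity, mirroring runs with and without this extra
#' normalization step.
#'
#' @param tile RGB array.
#' @param channel_stats List with numeric length-3 `mean` and `sd` (target
#'   statistics computed from the training image dataset).
#' @param enabled If `FALSE`, return the tile unchanged.
#' @return Normalized RGB array.
#' @export
dataset_stats_normalize <- function(tile, channel_stats, enabled = TRUE) {
  if (!enabled) return(tile)
  assert_that(is_rgb_array(tile), "tile must be an RGB array")
  assert_that(all(c("mean", "sd") %in% names(channel_stats)),
    "channel_stats must have elements mean and sd")
  assert_that(all(channel_stats$sd > 0), "zero sd channel in channel_stats")
  out <- tile
  for (ch in 1:3) {
    m <- mean(tile[, , ch])
    s <- stats::sd(as.vector(tile[, , ch]))
    assert_that(s > 0, paste0("zero sd in tile channel ", ch))
    out[, , ch] <- (tile[, , ch] - m) / s * channel_stats$sd[ch] +
      channel_stats$mean[ch]
  }
  clamp01(out)
}

# ---- augmentation -----------------------------------------------------------

#' Training-time augmentation policy
#'
#' Random rotations up to `max_rotate` degrees, dihedral flips with
#' probability `flip_prob`, perspective warping of maximal magnitude
#' `max_warp`, and hue variations of maximal magnitude `max_hue`.
#'
#' @param max_rotate Maximal rotation in degrees.
#' @param flip_prob Probability of each dihedral flip (horizontal, vertical).
#' @param max_warp Maximal relative corner displacement of the perspective
#'   warp.
#' @param max_hue Maximal hue shift (fraction of the hue circle).
#' @param enabled If `FALSE`, [augment_tile()] is the identity.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(max_rotate = 90, flip_prob = 0.5, max_warp = 0.2,
                           max_hue = 0.15, enabled = TRUE) {
  structure(list(max_rotate = max_rotate, flip_prob = flip_prob,
    max_warp = max_warp, max_hue = max_hue, enabled = isTRUE(enabled)),
    class = "augment_policy")
}

#' Apply a random augmentation to a tile
#'
#' Shape-preserving and deterministic under a fixed seed: the same seed and
#' policy give identical output.
#'
#' @param tile RGB array.
#' @param policy An [augment_policy()].
#' @param seed Integer seed for the random draws.
#' @return Augmented RGB array of the same shape.
#' @export
augment_tile <- function(tile, policy = augment_policy(), seed = 1L) {
  assert_that(inherits(policy, "augment_policy"),
    "policy must be an augment_policy")
  if (!policy$enabled) return(tile)
  with_seed(seed, {
    out <- tile
    ang <- stats::runif(1, -policy$max_rotate, policy$max_rotate)
    if (policy$max_rotate > 0) out <- rotate_tile(out, ang)
    if (stats::runif(1) < policy$flip_prob) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    if (stats::runif(1) < policy$flip_prob) out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
    if (policy$max_warp > 0) {
      w <- stats::runif(8, -policy$max_warp, policy$max_warp)
      out <- perspective_warp(out, w)
    }
    if (policy$max_hue > 0) {
      out <- shift_hue(out, stats::runif(1, -policy$max_hue, policy$max_hue))
    }
    out
  })
}

# Rotate about the centre by `degrees`; bilinear, border-clamped. Multiples of
# 90 degrees resolve to exact index permutations.
rotate_tile <- function(img, degrees) {
  deg <- degrees %% 360
  if (abs(deg) < 1e-9) return(img)
  if (abs(deg - 90) < 1e-9) return(aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , , drop = FALSE])
  if (abs(deg - 180) < 1e-9) return(img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), , drop = FALSE])
  if (abs(deg - 270) < 1e-9) return(aperm(img, c(2, 1, 3))[, rev(seq_len(dim(img)[1])), , drop = FALSE])
  d <- dim(img)
  th <- degrees * pi / 180
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  rr0 <- matrix(rep(seq_len(d[1]), times = d[2]), d[1]) - cy
  cc0 <- matrix(rep(seq_len(d[2]), each = d[1]), d[1]) - cx
  rr <- cos(th) * rr0 - sin(th) * cc0 + cy
  cc <- sin(th) * rr0 + cos(th) * cc0 + cx
  interp_grid(img, rr, cc)
}

# Projective warp driven by 8 relative corner displacements in [-w, w].
perspective_warp <- function(img, w) {
  d <- dim(img)
  h <- d[1]; wd <- d[2]
  src <- rbind(c(1, 1), c(1, wd), c(h, 1), c(h, wd))
  dst <- src + cbind(w[1:4] * h, w[5:8] * wd)
  H <- solve_homography(dst, src)  # inverse map: output coord -> input coord
  rr0 <- matrix(rep(seq_len(h), times = wd), h)
  cc0 <- matrix(rep(seq_len(wd), each = h), h)
  den <- H[3, 1] * rr0 + H[3, 2] * cc0 + H[3, 3]
  rr <- (H[1, 1] * rr0 + H[1, 2] * cc0 + H[1, 3]) / den
  cc <- (H[2, 1] * rr0 + H[2, 2] * cc0 + H[2, 3]) / den
  interp_grid(img, rr, cc)
}

# Homography mapping four (row, col) points `from` onto `to`.
solve_homography <- function(from, to) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- from[i, 1]; y <- from[i, 2]
    u <- to[i, 1]; v <- to[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# ---- ROI filtering ----------------------------------------------------------

#' Filter tiles to regions of interest and exclude spots without tumour
#'
#' Retains only tiles whose (predicted) tissue class is in `keep`, then drops
#' every spot that retains no tumour-epithelium (TUM) tile — spots without
#' remaining tumour epithelium are excluded entirely.
#'
#' @param tiles Tibble with columns `spot_id` and `tissue` (argmax tissue
#'   class per tile, predicted or known).
#' @param keep Tissue classes to retain.
#' @param require_tum If `TRUE` (default), spots lacking TUM tiles after
#'   filtering are removed with all their tiles.
#' @return The filtered tibble (possibly zero rows).
#' @export
filter_rois <- function(tiles, keep = c("TUM", "LYM", "MUC"),
                        require_tum = TRUE) {
  assert_that(all(c("spot_id", "tissue") %in% names(tiles)),
    "tiles must have columns spot_id and tissue")
  out <- dplyr::filter(tiles, .data$tissue %in% keep)
  if (require_tum && nrow(out) > 0) {
    tum_spots <- unique(out$spot_id[out$tissue == "TUM"])
    out <- dplyr::filter(out, .data$spot_id %in% tum_spots)
  }
  out
}
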