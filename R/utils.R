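# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Derive a stream of independent 32-bit sub-seeds from a master seed.
# Used so that e.g. network initialisation and batch sampling draw from
# disjoint, reproducible streams (a trainer with extra heads must not
# perturb the data-order stream of a trainer without them).
derive_seeds <- function(seed, n, salt = 0L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed((as.integer(seed) + 1000003L * as.integer(salt)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run code under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# Cached per-size pixel coordinate grids (column and row index matrices),
# reused across painted tiles.
.grid_cache <- new.env(parent = emptyenv())
pixel_grids <- function(px) {
  key <- as.character(px)
  if (is.null(.grid_cache[[key]])) {
    .grid_cache[[key]] <- list(
      xs = matrix(rep(seq_len(px), each = px), px),  # column index
      ys = matrix(rep(seq_len(px), times = px), px)  # row index
    )
  }
  .grid_cache[[key]]
}

# ---- raster helpers ---------------------------------------------------------
# Tiles are numeric arrays h x w x 3 with values in [0, 1].

is_rgb_array <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

# Area-average (block mean) downsampling by an integer factor. Acts as a
# box anti-alias filter, which is what downscanning a slide effectively does.
block_mean <- function(img, factor) {
  if (factor == 1L) return(img)
  d <- dim(img)
  h <- (d[1] %/% factor) * factor
  w <- (d[2] %/% factor) * factor
  img <- img[seq_len(h), seq_len(w), , drop = FALSE]
  out <- array(0, c(h %/% factor, w %/% factor, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    # average rows in blocks, then columns
    m <- rowsum(m, rep(seq_len(h %/% factor), each = factor)) / factor
    m <- t(rowsum(t(m), rep(seq_len(w %/% factor), each = factor)) / factor)
    out[, , ch] <- m
  }
  out
}

# Nearest-neighbour upsampling by an integer factor.
upsample_nn <- function(img, factor) {
  if (factor == 1L) return(img)
  d <- dim(img)
  img[rep(seq_len(d[1]), each = factor), rep(seq_len(d[2]), each = factor), , drop = FALSE]
}

# Resize to a square target via block mean (downscale) and/or nearest
# neighbour (upscale); general sizes handled by bilinear sampling.
resize_rgb <- function(img, px) {
  d <- dim(img)
  if (d[1] == px && d[2] == px) return(img)
  if (d[1] == d[2] && d[1] %% px == 0L) return(block_mean(img, d[1] %/% px))
  if (d[1] == d[2] && px %% d[1] == 0L) return(upsample_nn(img, px %/% d[1]))
  bilinear_sample(img, px, px)
}

# Bilinear resampling of an RGB array to nrow_out x ncol_out.
bilinear_sample <- function(img, nrow_out, ncol_out) {
  d <- dim(img)
  ys <- (seq_len(nrow_out) - 0.5) * d[1] / nrow_out + 0.5
  xs <- (seq_len(ncol_out) - 0.5) * d[2] / ncol_out + 0.5
  interp_grid(img, outer(ys, rep(1, ncol_out)), outer(rep(1, nrow_out), xs))
}

# Bilinear interpolation of img at (row, col) coordinate matrices.
# Coordinates outside the raster are clamped to the border.
interp_grid <- function(img, rr, cc) {
  d <- dim(img)
  rr <- pmin(pmax(rr, 1), d[1])
  cc <- pmin(pmax(cc, 1), d[2])
  r0 <- pmin(floor(rr), d[1] - 1L)
  c0 <- pmin(floor(cc), d[2] - 1L)
  fr <- rr - r0
  fc <- cc - c0
  out <- array(0, c(nrow(rr), ncol(rr), d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    i00 <- m[cbind(as.vector(r0), as.vector(c0))]
    i01 <- m[cbind(as.vector(r0), as.vector(c0 + 1L))]
    i10 <- m[cbind(as.vector(r0 + 1L), as.vector(c0))]
    i11 <- m[cbind(as.vector(r0 + 1L), as.vector(c0 + 1L))]
    v <- i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
      i10 * fr * (1 - fc) + i11 * fr * fc
    out[, , ch] <- v
  }
  out
}

# ---- colour helpers ---------------------------------------------------------

# Vectorised RGB -> HSV on an h x w x 3 array; returns same shape with
# channels hue (in [0,1)), saturation, value.
rgb_to_hsv_array <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  ir <- nz & mx == r
  ig <- nz & mx == g & !ir
  ib <- nz & !ir & !ig
  h[ir] <- ((g[ir] - b[ir]) / delta[ir]) %% 6
  h[ig] <- (b[ig] - r[ig]) / delta[ig] + 2
  h[ib] <- (r[ib] - g[ib]) / delta[ib] + 4
  h <- h / 6
  s <- ifelse(mx > 0, delta / mx, 0)
  out <- array(0, dim(img))
  out[, , 1] <- h; out[, , 2] <- s; out[, , 3] <- mx
  out
}

hsv_to_rgb_array <- function(hsv) {
  h <- (hsv[, , 1] %% 1) * 6
  s <- hsv[, , 2]; v <- hsv[, , 3]
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  for (k in 0:5) {
    m <- i == k
    if (!any(m)) next
    vals <- switch(as.character(k),
      "0" = list(v, t, p), "1" = list(q, v, p), "2" = list(p, v, t),
      "3" = list(p, q, v), "4" = list(t, p, v), "5" = list(v, p, q)
    )
    r[m] <- vals[[1]][m]; g[m] <- vals[[2]][m]; b[m] <- vals[[3]][m]
  }
  out <- array(0, dim(hsv))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

# Shift hue of an RGB array by `delta` (fraction of the full hue circle).
shift_hue <- function(img, delta) {
  hsv <- rgb_to_hsv_array(img)
  hsv[, , 1] <- (hsv[, , 1] + delta) %% 1
  hsv_to_rgb_array(hsv)
}

# Flatten a list of equally sized RGB arrays into an N x (h*w*3) matrix.
flatten_tiles <- function(tiles) {
  do.call(rbind, lapply(tiles, function(t) as.vector(t)))
}
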