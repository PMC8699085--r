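#' Squared distance correlation (V-statistic)
#'
#' Szekely's distance-correlation dependence measure between two row-aligned
#' samples: pairwise Euclidean distance matrices are double-centred (row,
#' column and grand means removed); the squared distance covariance is the
#' mean elementwise product, and the statistic is
#' `dCov2 / sqrt(dVarX * dVarY)`. It lies in `[0, 1]` and is zero (in the
#' population) only under statistical independence. When either distance
#' variance is zero (a constant sample) the statistic is 0 by convention.
#'
#' @param x,y Numeric matrices (or vectors) with N aligned rows, N >= 2.
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100), 50)
#' squared_distance_correlation(x, x) # 1
#' squared_distance_correlation(x, matrix(rnorm(100), 50)) # near 0
squared_distance_correlation <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  assert_that(nrow(x) == nrow(y), "x and y must have the same number of rows")
  assert_that(nrow(x) >= 2, "at least 2 observations are required")
  assert_that(!anyNA(x) && !anyNA(y), "NaN/NA input is not allowed")
  A <- dcenter(as.matrix(stats::dist(x)))
  B <- dcenter(as.matrix(stats::dist(y)))
  dvar_x <- mean(A * A)
  dvar_y <- mean(B * B)
  if (dvar_x <= .Machine$double.eps || dvar_y <= .Machine$double.eps) {
    return(0)
  }
  dcov2 <- mean(A * B)
  min(max(dcov2 / sqrt(dvar_x * dvar_y), 0), 1)
}

# Double-centre a distance matrix: remove row means, column means, add grand
# mean.
dcenter <- function(d) {
  rm <- rowMeans(d)
  gm <- mean(d)
  sweep(sweep(d, 1, rm), 2, rm) + gm
}

#' Protected-variable specification
#'
#' Declares one protected (bias) variable: its name, categorical levels, and
#' the target class of the y-conditioned cohort on which its adversarial head
#' is trained (the conditioning group rho, MSS by default, so that features
#' become conditionally independent of the bias given the label).
#'
#' @param name Variable name (e.g. `"project"`, `"patient"`, `"glass"`).
#' @param levels Character vector of category levels (non-empty).
#' @param rho Conditioning class, `"MSS"` or `"MSI-H"`.
#' @return A `bias_spec` object.
#' @export
bias_spec <- function(name, levels, rho = "MSS") {
  assert_that(is.character(name) && length(name) == 1, "name must be a string")
  levels <- as.character(levels)
  assert_that(length(levels) > 0, "levels must be non-empty")
  assert_that(rho %in% c("MSS", "MSI-H"), "rho must be 'MSS' or 'MSI-H'")
  structure(list(name = name, levels = sort(unique(levels)), rho = rho),
    class = "bias_spec")
}

#' Indicator encoding of a categorical bias variable
#'
#' One column per level, deterministic (sorted) column order. By default only
#' levels present in the supplied values are encoded (the batch-restricted
#' encoding used for audits); with `drop_absent = FALSE` all declared levels
#' are encoded, giving the fixed-width target used by the adversarial heads
#' (absent levels yield constant zero columns, which contribute zero
#' correlation downstream).
#'
#' @param values Character vector of N categorical labels.
#' @param spec A [bias_spec()] whose levels cover `values`.
#' @param drop_absent Drop declared levels not present in `values`?
#' @return N x K indicator matrix with level names as columns.
#' @export
encode_bias <- function(values, spec, drop_absent = TRUE) {
  assert_that(inherits(spec, "bias_spec"), "spec must be a bias_spec")
  values <- as.character(values)
  unseen <- setdiff(unique(values), spec$levels)
  if (length(unseen) > 0) {
    stop("unseen level(s) not declared in bias spec '", spec$name, "': ",
      paste(unseen, collapse = ", "), call. = FALSE)
  }
  lev <- if (drop_absent) sort(unique(values)) else spec$levels
  m <- matrix(0, length(values), length(lev), dimnames = list(NULL, lev))
  m[cbind(seq_along(values), match(values, lev))] <- 1
  m
}

#' Audit learned features against protected variables
#'
#' Computes the squared distance correlation between a feature matrix and the
#' indicator encoding of each protected variable — globally, and within each
#' level of each grouping variable in `subset_by` (backward-selection subgroup
#' analysis). A subgroup entry is flagged as a hidden interaction when its
#' dc exceeds the variable's global dc by at least `flag_threshold`.
#'
#' For large cohorts the N x N distance matrices become costly; when N exceeds
#' `max_n`, a seeded random subsample of `max_n` rows is used per entry.
#'
#' @param data Tibble with one row per example carrying the variable columns.
#' @param features Numeric matrix of learned features, row-aligned with
#'   `data`.
#' @param variables Character vector of columns of `data` to audit (the
#'   target label may be included).
#' @param subset_by Character vector of grouping columns for the subgroup
#'   analysis (default none).
#' @param flag_threshold Subgroup excess over global dc that raises an
#'   interaction flag.
#' @param max_n Maximal rows per dc evaluation before subsampling.
#' @param seed Seed for the subsampling.
#' @return A tibble of class `bias_audit` with columns `subset, variable, dc,
#'   n, interaction_flag`.
#' @export
bias_audit <- function(data, features, variables,
                       subset_by = character(), flag_threshold = 0.10,
                       max_n = 2048, seed = 1L) {
  features <- as.matrix(features)
  assert_that(nrow(features) == nrow(data),
    "features and data must have the same number of rows")
  missing_cols <- setdiff(c(variables, subset_by), names(data))
  assert_that(length(missing_cols) == 0,
    paste0("missing columns: ", paste(missing_cols, collapse = ", ")))

  dc_entry <- function(idx, variable, subset_label) {
    if (length(idx) < 2) {
      warning("subgroup '", subset_label, "' has fewer than 2 rows; skipped")
      return(NULL)
    }
    if (length(idx) > max_n) {
      idx <- with_seed(seed, sample(idx, max_n))
    }
    vals <- as.character(data[[variable]][idx])
    if (length(unique(vals)) < 1) return(NULL)
    spec <- bias_spec(variable, unique(vals))
    enc <- encode_bias(vals, spec)
    tibble::tibble(subset = subset_label, variable = variable,
      dc = squared_distance_correlation(features[idx, , drop = FALSE], enc),
      n = length(idx))
  }

  entries <- list()
  for (v in variables) {
    entries[[length(entries) + 1]] <- dc_entry(seq_len(nrow(data)), v, "all")
  }
  for (g in subset_by) {
    for (lv in sort(unique(as.character(data[[g]])))) {
      idx <- which(as.character(data[[g]]) == lv)
      for (v in setdiff(variables, g)) {
        entries[[length(entries) + 1]] <-
          dc_entry(idx, v, paste0(g, "=", lv))
      }
    }
  }
  out <- dplyr::bind_rows(entries)
  glob <- stats::setNames(out$dc[out$subset == "all"],
    out$variable[out$subset == "all"])
  out$interaction_flag <- out$subset != "all" &
    out$dc - glob[out$variable] >= flag_threshold
  class(out) <- c("bias_audit", class(out))
  out
}

#' Two-dimensional PCA projection of learned features
#'
#' Projects features onto the first two principal components to visualise how
#' the representation space is organised by a protected variable.
#'
#' @param features N x D numeric matrix, N >= 3.
#' @param color_variable Optional vector of N labels attached to the scores
#'   for plotting.
#' @return A tibble of class `pca_projection` with columns `PC1, PC2` (and
#'   `color`), plus attribute `explained` (proportion of variance per
#'   component, non-increasing).
#' @export
pca_projection <- function(features, color_variable = NULL) {
  features <- as.matrix(features)
  assert_that(nrow(features) >= 3, "at least 3 rows are required")
  vars <- apply(features, 2, stats::var)
  assert_that(any(vars > 0), "rank-0 input: all feature columns are constant")
  p <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(p$x))
  scores <- tibble::as_tibble(p$x[, seq_len(k), drop = FALSE])
  if (k == 1) scores$PC2 <- 0
  if (!is.null(color_variable)) scores$color <- as.character(color_variable)
  explained <- p$sdev^2 / sum(p$sdev^2)
  attr(scores, "explained") <- explained
  class(scores) <- c("pca_projection", class(scores))
  scores
}
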