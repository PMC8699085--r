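# Small fixtures shared across tests; everything is generated in code.

tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_patients = 12, tiles_per_patient_range = c(4, 8),
    msi_prevalence = 0.4, n_projects = 2, n_glasses = 4,
    tile_px = 32, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# Checkerboard-ish asymmetric test pattern (h x w x 3) for geometry oracles.
test_pattern <- function(h = 8, w = 8) {
  a <- array(0, c(h, w, 3))
  a[, , 1] <- matrix(seq_len(h * w) / (h * w), h, w)
  a[, , 2] <- outer(seq_len(h), seq_len(w), function(i, j) (i %% 2) * 0.5)
  a[, , 3] <- outer(seq_len(h), seq_len(w), function(i, j) (j > w / 2) * 0.8)
  a
}

# Direct-summation (S1 + S2 - 2 S3) brute-force oracle for the squared
# distance correlation; an independent algebraic route from the
# double-centering implementation.
dcor2_bruteforce <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  a <- as.matrix(dist(x))
  b <- as.matrix(dist(y))
  term <- function(a, b) {
    s1 <- mean(a * b)
    s2 <- mean(a) * mean(b)
    s3 <- mean(rowMeans(a) * rowMeans(b))
    s1 + s2 - 2 * s3
  }
  dcov2 <- term(a, b)
  dvarx <- term(a, a)
  dvary <- term(b, b)
  if (dvarx <= .Machine$double.eps || dvary <= .Machine$double.eps) return(0)
  dcov2 / sqrt(dvarx * dvary)
}

# Exhaustive truth-table oracle for the MSI labeling rule, written as a
# direct transcription of the screening algorithm.
msi_label_oracle <- function(loss, pcr, braf) {
  if ("MSH2" %in% loss) return("MSI-H")
  if ("MSH6" %in% loss) return("MSI-H")
  if ("PMS2" %in% loss && !("MLH1" %in% loss)) return("MSI-H")
  if ("MLH1" %in% loss || pcr) {
    if (is.na(braf)) return("error")
    return(if (braf) "MSS" else "MSI-H")
  }
  "MSS"
}
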