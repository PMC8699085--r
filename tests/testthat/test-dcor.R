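test_that("squared distance correlation matches the direct-summation oracle", {
  set.seed(404)
  worst <- 0
  for (i in 1:100) {
    n <- sample(4:64, 1)
    p <- sample(1:8, 1)
    q <- sample(1:8, 1)
    x <- matrix(rnorm(n * p), n)
    y <- if (i %% 3 == 0) x[, 1] + matrix(rnorm(n * q, sd = 0.3), n)[, 1]
      else matrix(rnorm(n * q), n)
    got <- squared_distance_correlation(x, y)
    want <- dcor2_bruteforce(x, y)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-10)
})

test_that("self-dependence, constants and conventions", {
  set.seed(1)
  x <- matrix(rnorm(80), 40)
  expect_equal(squared_distance_correlation(x, x), 1, tolerance = 1e-12)
  # constant sample: zero distance variance -> 0 by convention
  expect_identical(squared_distance_correlation(matrix(1, 40, 2), x), 0)
  # hand-checkable 4-point instance against the oracle
  xv <- matrix(c(0, 1, 2, 3), 4)
  yv <- matrix(c(0, 1, 0, 1), 4)
  expect_equal(squared_distance_correlation(xv, yv),
    dcor2_bruteforce(xv, yv), tolerance = 1e-12)
  expect_error(squared_distance_correlation(matrix(1, 1, 1), matrix(1, 1, 1)),
    "at least 2")
  expect_error(squared_distance_correlation(matrix(c(1, NA), 2), matrix(1:2, 2)),
    "NaN/NA")
  expect_error(squared_distance_correlation(matrix(1:4, 2), matrix(1:6, 3)),
    "same number of rows")
})

test_that("dc is symmetric and invariant to rotation, translation and scale", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    x <- matrix(rnorm(n * 3), n)
    y <- matrix(rnorm(n * 2), n)
    d0 <- squared_distance_correlation(x, y)
    expect_equal(squared_distance_correlation(y, x), d0, tolerance = 1e-12)
    # translation
    expect_equal(squared_distance_correlation(x + 5, y), d0, tolerance = 1e-12)
    # rotation of x
    qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(squared_distance_correlation(x %*% qr_r, y), d0,
      tolerance = 1e-10)
    # non-zero rescale of either argument
    expect_equal(squared_distance_correlation(3.7 * x, y), d0,
      tolerance = 1e-10)
    expect_equal(squared_distance_correlation(x, -0.2 * y), d0,
      tolerance = 1e-10)
  }
})

test_that("independent permuted pairs stay within the small-sample envelope", {
  # the V-statistic has an O(1/N) positive bias under independence (about
  # 3.2/N for 1-dim normal pairs); the permutation-null mean must sit inside
  # a c/N envelope and shrink with N
  set.seed(11)
  null_mean <- function(n) {
    x <- matrix(rnorm(n), n)
    y <- matrix(rnorm(n), n)
    mean(replicate(40,
      squared_distance_correlation(x, y[sample(n), , drop = FALSE])))
  }
  m128 <- null_mean(128)
  m512 <- null_mean(512)
  expect_lt(m128, 5 / 128)
  expect_lt(m512, 5 / 512)
  expect_lt(m512, 0.5 * m128)
})

test_that("encode_bias produces deterministic indicator matrices", {
  spec <- bias_spec("glass", c("G2", "G1", "G3"))
  expect_identical(spec$levels, c("G1", "G2", "G3"))
  m <- encode_bias(c("G2", "G1", "G2", "G2"), spec)
  expect_identical(colnames(m), c("G1", "G2"))  # absent level dropped
  expect_identical(rowSums(m), rep(1, 4))
  m_full <- encode_bias(c("G2", "G1", "G2", "G2"), spec, drop_absent = FALSE)
  expect_identical(colnames(m_full), c("G1", "G2", "G3"))
  expect_identical(sum(m_full[, "G3"]), 0)
  # single-level batch: one constant column
  m1 <- encode_bias(rep("G1", 3), spec)
  expect_identical(dim(m1), c(3L, 1L))
  expect_error(encode_bias(c("G1", "G9"), spec), "G9")
})

test_that("bias_audit flags constructed subgroup interactions", {
  set.seed(21)
  n <- 400
  project <- rep(c("P1", "P2"), each = n / 2)
  glass <- sample(c("G1", "G2"), n, replace = TRUE)
  f <- matrix(rnorm(n * 6), n)
  # glass tint present only inside project P2 (hidden interaction)
  f[project == "P2" & glass == "G2", 1] <-
    f[project == "P2" & glass == "G2", 1] + 4
  data <- tibble::tibble(project = project, glass = glass)
  rep_audit <- bias_audit(data, f, variables = c("project", "glass"),
    subset_by = "project")
  expect_s3_class(rep_audit, "bias_audit")
  expect_true(all(rep_audit$dc >= 0 & rep_audit$dc <= 1))
  g_all <- rep_audit$dc[rep_audit$subset == "all" & rep_audit$variable == "glass"]
  g_p2 <- rep_audit$dc[rep_audit$subset == "project=P2" &
    rep_audit$variable == "glass"]
  expect_gte(g_p2, g_all + 0.10)
  expect_true(rep_audit$interaction_flag[rep_audit$subset == "project=P2" &
    rep_audit$variable == "glass"])
  # independent features: all dc small, no flags
  f0 <- matrix(rnorm(n * 6), n)
  rep0 <- bias_audit(data, f0, variables = c("project", "glass"),
    subset_by = "project")
  expect_true(all(rep0$dc < 0.05))
  expect_false(any(rep0$interaction_flag))
})

test_that("bias_audit warns and skips undersized subgroups", {
  data <- tibble::tibble(project = c("P1", "P1", "P1", "P2"),
    glass = c("G1", "G2", "G1", "G2"))
  f <- matrix(rnorm(8), 4)
  expect_warning(
    rep_audit <- bias_audit(data, f, variables = "glass", subset_by = "project"),
    "fewer than 2")
  expect_false(any(rep_audit$subset == "project=P2"))
})

test_that("pca projection orders variance and handles degenerate input", {
  set.seed(5)
  # rank-1 data: PC1 explains everything
  v <- rnorm(30)
  f1 <- cbind(v, 2 * v, -v)
  p1 <- pca_projection(f1)
  expect_gt(attr(p1, "explained")[1], 0.999)
  # isotropic: roughly equal split, non-increasing order
  f2 <- matrix(rnorm(2000), 1000, 2)
  p2 <- pca_projection(f2, color_variable = rep(c("a", "b"), 500))
  expl <- attr(p2, "explained")
  expect_true(all(diff(expl) <= 1e-12))
  expect_lt(expl[1] - expl[2], 0.15)
  expect_true("color" %in% names(p2))
  expect_error(pca_projection(matrix(1, 5, 3)), "rank-0")
  expect_error(pca_projection(matrix(rnorm(4), 2)), "at least 3")
})
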