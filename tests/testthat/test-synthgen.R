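test_that("identical seed and config give a byte-identical dataset", {
  a <- synthesize_dataset(tiny_config(seed = 9))
  b <- synthesize_dataset(tiny_config(seed = 9))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$pixels, b$pixels)
  c <- synthesize_dataset(tiny_config(seed = 10))
  expect_false(identical(a$manifest, c$manifest))
})

test_that("every tile carries exactly one value of each factor", {
  ds <- synthesize_dataset(tiny_config(seed = 2,
    magnifications = c("x40", "x20", "x0")))
  m <- ds$manifest
  expect_false(anyNA(m))
  expect_true(all(m$msi_label %in% c("MSI-H", "MSS")))
  expect_true(all(m$magnification %in% c("x40", "x20", "x0")))
  expect_true(all(m$tissue %in% tissue_classes()))
  # one patient per spot, one project/glass per patient
  per_pat <- dplyr::summarise(dplyr::group_by(m, patient),
    np = dplyr::n_distinct(project), ng = dplyr::n_distinct(glass),
    nl = dplyr::n_distinct(msi_label))
  expect_true(all(per_pat$np == 1 & per_pat$ng == 1 & per_pat$nl == 1))
  expect_identical(length(ds$pixels), nrow(m))
  expect_true(all(vapply(ds$pixels, function(p)
    all(dim(p) == c(32, 32, 3)) && min(p) >= 0 && max(p) <= 1, logical(1))))
})

test_that("pure glasses hold a single MSI class", {
  ds <- synthesize_dataset(tiny_config(seed = 3, glass_class_purity = 1,
    msi_prevalence = 0.5, n_glasses = 4))
  per_glass <- dplyr::summarise(dplyr::group_by(ds$manifest, glass),
    k = dplyr::n_distinct(msi_label))
  expect_true(all(per_glass$k == 1))
  expect_error(synth_config(glass_class_purity = 1, n_glasses = 1,
    msi_prevalence = 0.5), "configuration error")
})

test_that("MSI-H patient fraction falls in the exact binomial 99% interval", {
  cfg <- synth_config(n_patients = 500, tiles_per_patient_range = c(1, 2),
    msi_prevalence = 0.074, tile_px = 16, seed = 77)
  ds <- synthesize_dataset(cfg, net_px = 16)
  n_msi <- dplyr::n_distinct(
    ds$manifest$patient[ds$manifest$msi_label == "MSI-H"])
  bounds <- qbinom(c(0.005, 0.995), 500, 0.074)
  expect_gte(n_msi, bounds[1])
  expect_lte(n_msi, bounds[2])
})

test_that("unconfounded projects are independent of the label", {
  ds <- synthesize_dataset(synth_config(n_patients = 300,
    tiles_per_patient_range = c(1, 1), msi_prevalence = 0.5,
    project_confound = 0, glass_class_purity = 0.5, tile_px = 16, seed = 31),
    net_px = 16)
  m <- ds$manifest
  proj <- encode_bias(m$project, bias_spec("project", unique(m$project)))
  lab <- encode_bias(m$msi_label, bias_spec("msi_label", unique(m$msi_label)))
  expect_lt(squared_distance_correlation(proj, lab), 0.03)
})

test_that("confounded projects track the label (and flip reverses it)", {
  cfg <- synth_config(n_patients = 200, tiles_per_patient_range = c(1, 1),
    msi_prevalence = 0.5, project_confound = 1, tile_px = 16, seed = 13)
  ds <- synthesize_dataset(cfg, net_px = 16)
  m <- ds$manifest
  expect_true(all(m$project[m$msi_label == "MSI-H"] == "P1"))
  expect_true(all(m$project[m$msi_label == "MSS"] != "P1"))
  cfg$confound_flip <- TRUE
  dsf <- synthesize_dataset(cfg, net_px = 16)
  mf <- dsf$manifest
  expect_true(all(mf$project[mf$msi_label == "MSS"] == "P1"))
})

test_that("lower magnifications are coarser versions of the field", {
  set.seed(4)
  img <- msidistill:::paint_tile(32, "TUM", 1, 0.8)
  x40 <- msidistill:::emulate_magnification(img, "x40")
  x10 <- msidistill:::emulate_magnification(img, "x10")
  expect_identical(x40, img)
  expect_identical(dim(x10), dim(img))
  # coarser view has less high-frequency energy
  hf <- function(a) mean(abs(diff(a[, , 1])))
  expect_lt(hf(x10), hf(x40))
  # x10 is piecewise constant on 4x4 blocks
  expect_identical(x10[1, 1, 1], x10[4, 4, 1])
})

test_that("datasets round-trip through PNG + CSV on disk", {
  dir <- withr::local_tempdir()
  ds <- synthesize_dataset(tiny_config(seed = 6,
    magnifications = c("x40", "x5")), dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(all(file.exists(ds$manifest$path)))
  back <- png::readPNG(ds$manifest$path[1])
  expect_equal(back, ds$pixels[[1]], tolerance = 1 / 255)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), nrow(ds$manifest))
})

test_that("tissue dataset emits all nine classes as separable textures", {
  ds <- synthesize_tissue_dataset(n_per_class = 3, tile_px = 24, seed = 1)
  expect_identical(sort(unique(ds$manifest$tissue)), tissue_classes())
  expect_identical(nrow(ds$manifest), 27L)
  expect_error(synthesize_tissue_dataset(classes = "XXX"), "unknown tissue")
})

test_that("input matrix has the documented width", {
  ds <- synthesize_tissue_dataset(n_per_class = 2, tile_px = 24, seed = 2)
  x <- as_input_matrix(ds, net_px = 8)
  expect_identical(ncol(x), 8L * 8L * 3L + 2L * 7L * 8L * 3L)
  x0 <- as_input_matrix(ds, net_px = 8, gradients = FALSE)
  expect_identical(ncol(x0), 192L)
})
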