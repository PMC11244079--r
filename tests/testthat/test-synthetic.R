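small_specs <- function(n1 = 10, n2 = 20, length_px = 70) {
  tf <- pip_template_features(demo_config())
  list(
    shape_class_spec("wild", tf$wild, 0.02, n1, length_px = length_px),
    shape_class_spec("domestic", tf$domestic, 0.02, n2,
                     length_px = length_px, status = "domestic",
                     cultivar_id = "cv001")
  )
}

test_that("population bookkeeping matches the requested sample counts", {
  pop <- generate_population(small_specs(10, 20), image_size = 160, seed = 1)
  expect_length(pop$images, 30L)
  expect_identical(nrow(pop$truth), 30L)
  expect_identical(sum(pop$truth$class == "wild"), 10L)
  expect_identical(sum(pop$truth$class == "domestic"), 20L)
  expect_identical(unique(pop$truth$cultivar_id[pop$truth$class == "domestic"]),
                   "cv001")
  expect_identical(anyDuplicated(pop$truth$sample_id), 0L)
})

test_that("the same seed reproduces the dataset exactly", {
  p1 <- generate_population(small_specs(4, 4), image_size = 160, seed = 99)
  p2 <- generate_population(small_specs(4, 4), image_size = 160, seed = 99)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$images, p2$images)
  p3 <- generate_population(small_specs(4, 4), image_size = 160, seed = 100)
  expect_false(identical(p3$truth, p1$truth))
})

test_that("invalid class specifications are rejected", {
  tf <- pip_template_features(demo_config())
  bad_cov <- diag(24); bad_cov[1, 1] <- -1
  expect_error(shape_class_spec("x", tf$wild, bad_cov, 5),
               "positive semi-definite")
  expect_error(shape_class_spec("x", tf$wild[1:10], 0.1, 5), "24")
  expect_error(shape_class_spec("x", tf$wild, 0.1, 0), "n_samples")
  ## canvas too small for the seed length
  expect_error(generate_population(small_specs(2, 2, length_px = 200),
                                   image_size = 128, seed = 1), "margin")
})

test_that("generation fails loudly when outlines cannot be made simple", {
  tf <- pip_template_features(demo_config())
  wild <- shape_class_spec("hopeless", tf$wild, rep(2, 24), 2,
                           length_px = 60)
  expect_error(generate_population(list(wild), image_size = 160, seed = 1),
               "hopeless")
})

test_that("rasterised outlines have the right area and extent", {
  disk <- rasterize_outline(circle_outline(360), image_size = 140,
                            length_px = 100)
  expect_lt(abs(sum(disk) / (pi * 50^2) - 1), 0.02)
  sq <- rasterize_outline(square_outline(), image_size = 160, length_px = 100)
  ## a unit square scaled to Feret diameter 100 px has side 100/sqrt(2)
  expect_lt(abs(sum(sq) / (100 / sqrt(2))^2 - 1), 0.02)
  expect_error(rasterize_outline(circle_outline(360), image_size = 64,
                                 length_px = 100), "canvas")
  bow <- tibble::tibble(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(rasterize_outline(bow, 64, 30), "self-intersect")
})

test_that("image extraction recovers the generating features", {
  set.seed(31)
  cfg <- default_config()
  specs <- pip_class_specs(15, 15, delta = 3.4, config = cfg)
  pop <- generate_population(specs, image_size = 512, seed = 7)
  feat <- extract_features(pop)
  truth <- pop$truth[match(feat$sample_id, pop$truth$sample_id), ]
  fn <- grep("^[abcd][1-6]$", names(feat), value = TRUE)
  err <- abs(as.matrix(feat[fn]) - as.matrix(truth[fn]))
  ## typical per-coefficient recovery well inside 0.02 at 142 px seed length
  expect_lt(stats::median(apply(err, 1, max)), 0.02)
  expect_lt(mean(apply(err, 1, max) > 0.05), 0.1)
})

test_that("cultivar metadata sampling respects weights and seed", {
  meta <- generate_cultivar_metadata(331, seed = 3)
  expect_identical(nrow(meta), 331L)
  expect_identical(anyDuplicated(meta$cultivar_id), 0L)
  counts <- table(factor(meta$colour, levels = c("white", "red", "pink")))
  expected <- 331 * c(145, 183, 3) / 331
  ## within ~4 sd of the multinomial
  sds <- sqrt(expected * (1 - c(145, 183, 3) / 331))
  expect_true(all(abs(counts - expected) < 4 * sds + 1))

  single <- generate_cultivar_metadata(20, region_weights = c(Sardinia = 1),
                                       seed = 4)
  expect_true(all(single$origin_region == "Sardinia"))
  expect_identical(generate_cultivar_metadata(50, seed = 11),
                   generate_cultivar_metadata(50, seed = 11))
  expect_error(generate_cultivar_metadata(0), "n_cultivars")
  expect_error(generate_cultivar_metadata(5, colour_weights = c(white = 0)),
               "not all zero")
})

test_that("the packaged assignment-count table matches the printed values", {
  t1 <- table1_fixture()
  expect_identical(nrow(t1), 29L)
  cann <- t1[t1$cultivar == "Cannonanu (Garnacha tinta)", ]
  expect_identical(c(cann$well_n, cann$well_kk, cann$nora, cann$total),
                   c(81L, 29L, 51L, 161L))
  musc <- t1[t1$cultivar == "Moscato bianco (Muscat à petits grains blancs)", ]
  expect_identical(c(musc$well_n, musc$well_kk, musc$nora, musc$total),
                   c(232L, 11L, 2L, 245L))
  expect_identical(t1$total, t1$well_n + t1$well_kk + t1$nora)
  expect_true(all(t1$total >= 10L))
  expect_true(all(t1$colour %in% c("white", "red")))
})

test_that("class separation is calibrated in extracted-feature space", {
  cfg <- default_config()
  specs <- pip_class_specs(200, 200, delta = 2, config = cfg)
  pop <- generate_population(specs, image_size = 512, seed = 5)
  feat <- extract_features(pop)
  feat$status <- pop$truth$class[match(feat$sample_id, pop$truth$sample_id)]
  fn <- grep("^[abcd][1-6]$", names(feat), value = TRUE)
  X <- as.matrix(feat[fn]); y <- factor(feat$status)
  mu <- rowsum(X, y) / as.vector(table(y))
  Xc <- X - mu[as.integer(y), ]
  S <- crossprod(Xc) / (nrow(X) - 2)
  dmu <- mu[1, ] - mu[2, ]
  d_emp <- sqrt(drop(crossprod(dmu, solve(S, dmu))))
  expect_lt(abs(d_emp - 2) / 2, 0.15)
})

test_that("identical class specs give chance-level discrimination", {
  cfg <- demo_config()
  tf <- pip_template_features(cfg)
  sds <- rep(0.03, 24)
  specs <- list(
    shape_class_spec("wild", tf$wild, sds, 40, length_px = 70),
    shape_class_spec("domestic", tf$wild, sds, 40, length_px = 70,
                     status = "domestic")
  )
  pop <- generate_population(specs, image_size = 192, seed = 12)
  feat <- extract_features(pop)
  feat$status <- pop$truth$class[match(feat$sample_id, pop$truth$sample_id)]
  fn <- grep("^[abcd][1-6]$", names(feat), value = TRUE)
  cv <- loocv(feat, "status", fn)
  ## binomial chance band around 0.5 at n = 80 (plus estimation noise)
  expect_lt(abs(cv$accuracy - 0.5), 0.2)
})
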