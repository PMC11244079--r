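test_that("normalisation removes scale, start index and rotation", {
  set.seed(21)
  for (i in 1:6) {
    o <- random_smooth_outline()
    n0 <- normalize_outline(o)
    n_scaled <- normalize_outline(dplyr::mutate(o, x = 3 * x, y = 3 * y))
    expect_lt(max(abs(as.matrix(n_scaled) - as.matrix(n0))), 1e-9)
    n_shift <- normalize_outline(o[c(91:360, 1:90), ])
    expect_lt(max(abs(as.matrix(n_shift) - as.matrix(n0))), 1e-9)
    th <- runif(1, 0.1, 2 * pi)
    rot <- tibble::tibble(x = cos(th) * o$x - sin(th) * o$y,
                          y = sin(th) * o$x + cos(th) * o$y)
    expect_lt(max(abs(as.matrix(normalize_outline(rot)) - as.matrix(n0))),
              1e-6)
  }
})

test_that("normalised outlines are centred, unit-size and start on +x", {
  o <- normalize_outline(random_smooth_outline())
  expect_lt(abs(o$y[1]), 1e-6)
  expect_gt(o$x[1], 0)
  expect_error(normalize_outline(tibble::tibble(x = rep(2, 5), y = rep(3, 5))),
               "degenerate")
})

test_that("closed-form coefficients are exact for a circle", {
  e <- efd(circle_outline(360), 6)
  expect_equal(unname(e$coefficients[1, "a"]), 1, tolerance = 1e-3)
  expect_equal(unname(e$coefficients[1, "d"]), 1, tolerance = 1e-3)
  expect_lt(abs(e$coefficients[1, "b"]), 1e-3)
  expect_lt(abs(e$coefficients[1, "c"]), 1e-3)
  expect_lt(max(abs(e$coefficients[2:6, ])), 1e-3)
  expect_equal(e$perimeter, 2 * pi, tolerance = 1e-3)
})

test_that("ellipse coefficients follow the arc-length parameterisation", {
  ## under the chord-length (arc-length) parameterisation the first
  ## harmonic of an angle-sampled 2:1 ellipse is not (2, 1): the outline
  ## spends more arc length near the flat ends. Values frozen from the
  ## independent trapezoidal oracle.
  o <- ellipse_outline(2, 1, 720)
  e <- efd(o, 3)
  oracle <- efd_trapezoid_oracle(o, 3)
  expect_lt(max(abs(e$coefficients - oracle)), 1e-6)
  expect_equal(unname(e$coefficients[1, "a"]), 1.82839, tolerance = 1e-4)
  expect_equal(unname(e$coefficients[1, "d"]), 1.07301, tolerance = 1e-4)
  expect_lt(abs(e$coefficients[1, "b"]), 1e-6)
  expect_lt(abs(e$coefficients[1, "c"]), 1e-6)
})

test_that("closed form agrees with trapezoidal Fourier integration", {
  set.seed(33)
  for (i in 1:5) {
    o <- random_smooth_outline(n_points = 400)
    e <- efd(o, 8)
    oracle <- efd_trapezoid_oracle(o, 8)
    expect_lt(max(abs(e$coefficients - oracle)), 1e-6)
  }
})

test_that("efd rejects repeated consecutive points", {
  o <- circle_outline(100)
  o <- o[c(1:50, 50, 51:100), ]
  expect_error(efd(o, 4), "repeated consecutive points")
})

test_that("feature vectors are invariant to similarity transforms", {
  set.seed(55)
  for (i in 1:4) {
    o <- random_smooth_outline()
    f0 <- unlist(outline_features(o))
    expect_length(f0, 24L)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.2, 5)
    congruent <- tibble::tibble(
      x = 10 + s * (cos(th) * o$x - sin(th) * o$y),
      y = -4 + s * (sin(th) * o$x + cos(th) * o$y)
    )[c(200:360, 1:199), ]
    expect_lt(max(abs(unlist(outline_features(congruent)) - f0)), 1e-6)
  }
  fc <- unlist(outline_features(circle_outline(360, r = 2, cx = 3)))
  expect_equal(fc[["a1"]], fc[["d1"]], tolerance = 1e-3)
  expect_lt(max(abs(fc[c("b1", "c1")])), 1e-3)
  expect_lt(max(abs(fc[5:24])), 1e-3)
})

test_that("reconstruction inverts the descriptor set", {
  e1 <- matrix(c(1, 0, 0, 1), 1, dimnames = list(NULL, c("a", "b", "c", "d")))
  o <- efd_reconstruct(e1, 360)
  expect_lt(max(abs(sqrt(o$x^2 + o$y^2) - 1)), 1e-9)

  z <- efd_reconstruct(matrix(0, 2, 4), 10)
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_true(all(z$x == 0) && all(z$y == 0))
})

test_that("template shapes are fixed points of reconstruct-then-extract", {
  tf <- pip_template_features()
  for (v in tf) {
    m <- matrix(v, ncol = 4, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c", "d")))
    back <- unlist(outline_features(efd_reconstruct(m, 360)))
    expect_lt(max(abs(back - v)), 2e-3)
  }
})

test_that("harmonic power spectrum and cumulative fractions are correct", {
  ## a circle is arc-length parameterised, so all power sits in harmonic 1;
  ## an ellipse read by arc length keeps a little in the odd harmonics
  hp_circ <- harmonic_power(efd(circle_outline(720), 6))
  expect_gt(hp_circ$proportion[1], 1 - 1e-6)
  e <- efd(ellipse_outline(2, 1, 720), 6)
  hp <- harmonic_power(e)
  expect_gt(hp$proportion[1], 0.99)
  expect_equal(hp$cumulative[6], 1, tolerance = 1e-12)

  fake <- structure(
    list(coefficients = matrix(c(sqrt(2), 0, 0, 2, 0, 0, sqrt(2), 0),
                               2, 4, byrow = TRUE,
                               dimnames = list(NULL, c("a", "b", "c", "d"))),
         n_harmonics = 2L, centroid = c(x = 0, y = 0), centroid_size = 1,
         perimeter = 1, n_points = 8L),
    class = "pip_efd")
  hp2 <- harmonic_power(fake)
  expect_equal(hp2$power, c(3, 1))
  expect_equal(hp2$cumulative, c(0.75, 1))

  fake$coefficients[] <- 0
  expect_error(harmonic_power(fake), "degenerate")
})

test_that("reconstruction error decreases as harmonics are added", {
  set.seed(77)
  for (i in 1:3) {
    o <- resample_outline(random_smooth_outline(n_harmonics = 10), 360)
    e <- efd(dplyr::mutate(o, x = x - mean(x), y = y - mean(y)), 10)
    errs <- vapply(1:10, function(h) {
      eh <- e
      eh$coefficients <- eh$coefficients[seq_len(h), , drop = FALSE]
      r <- efd_reconstruct(eh, 360)
      mean(sqrt((r$x - (o$x - mean(o$x)))^2 + (r$y - (o$y - mean(o$y)))^2))
    }, numeric(1))
    expect_true(all(diff(errs) < 1e-9))
  }
})

test_that("tidy and glance summarise descriptor sets", {
  e <- efd(circle_outline(360), 4)
  td <- tidy(e)
  expect_identical(names(td), c("harmonic", "a", "b", "c", "d"))
  expect_identical(nrow(td), 4L)
  gl <- glance(e)
  expect_identical(gl$n_harmonics, 4L)
  expect_equal(gl$perimeter, 2 * pi, tolerance = 1e-3)
})
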