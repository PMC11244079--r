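#' Normalise an outline for size, position and starting point
#'
#' Applies the normalisation used before computing Fourier descriptors:
#' the outline is translated so its centroid sits at the origin, scaled by
#' centroid size (the RMS distance of the points from the centroid),
#' re-indexed cyclically so the first point is the point farthest from the
#' centroid (ties broken by the lowest original index), and rigidly rotated
#' so that this first point lies on the positive x axis. Orientation stays
#' counter-clockwise; reflection is deliberately not normalised, since
#' dorsal-view scans have a fixed handedness.
#'
#' @param outline data frame with `x`, `y` columns.
#' @return A tibble with columns `x`, `y`; attributes `centroid` and
#'   `centroid_size` record the removed translation and scale.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 121)[-121]
#' o <- tibble::tibble(x = 3 + 2 * cos(th), y = -1 + sin(th))
#' n <- normalize_outline(o)
#' colMeans(n)
#' @export
normalize_outline <- function(outline) {
  o <- as_outline(outline)
  cx <- mean(o$x); cy <- mean(o$y)
  x <- o$x - cx; y <- o$y - cy
  r2 <- x^2 + y^2
  size <- sqrt(mean(r2))
  if (size <= .Machine$double.eps) {
    abort("degenerate outline: all points coincide with the centroid")
  }
  x <- x / size; y <- y / size
  start <- which.max(r2)           # ties: which.max takes the lowest index
  ## a sampled outline locates the true farthest point only to +/- half a
  ## sample; that quantisation would jitter both the rotation and the
  ## Fourier phase origin between re-digitisations of the same shape. The
  ## sub-sample position of the radius maximum is estimated by a quadratic
  ## fit and the interpolated tip is inserted as the new first vertex (it
  ## lies on the polygon, so the curve itself is unchanged).
  n <- length(x)
  w <- min(5L, (n - 1L) %/% 4L)
  delta <- 0
  if (w >= 1L) {
    j <- -w:w
    rw <- sqrt(r2[((start - 1L + j) %% n) + 1L])
    fit <- stats::lm.fit(cbind(1, j, j^2), rw)$coefficients
    if (is.finite(fit[3L]) && fit[3L] < 0) {
      delta <- min(max(-fit[2L] / (2 * fit[3L]), -w), w)
    }
  }
  if (abs(delta) < 1e-9) {
    idx <- c(start:n, seq_len(start - 1L))
    x <- x[idx]; y <- y[idx]
  } else {
    ## fractional index start + delta: insert the interpolated tip (a point
    ## on the polygon, so the curve is unchanged) as the new first vertex
    base <- ((start - 1L + floor(delta)) %% n) + 1L
    frac <- delta - floor(delta)
    nb <- (base %% n) + 1L
    tip <- c((1 - frac) * x[base] + frac * x[nb],
             (1 - frac) * y[base] + frac * y[nb])
    first <- if (frac > 1e-9) nb else base
    idx <- c(first:n, seq_len(first - 1L))
    keep <- !(sqrt((x[idx] - tip[1L])^2 + (y[idx] - tip[2L])^2) < 1e-12)
    x <- c(tip[1L], x[idx][keep]); y <- c(tip[2L], y[idx][keep])
  }
  phi <- atan2(y[1L], x[1L])
  cs <- cos(-phi); sn <- sin(-phi)
  xr <- cs * x - sn * y
  yr <- sn * x + cs * y
  out <- tibble(x = xr, y = yr)
  attr(out, "centroid") <- c(x = cx, y = cy)
  attr(out, "centroid_size") <- size
  out
}

#' Elliptic Fourier descriptors of a closed outline
#'
#' Computes per-harmonic coefficient quadruples `(a_n, b_n, c_n, d_n)` of
#' the closed polygon by the exact closed-form sums over polygon segments
#' (Kuhl & Giardina), with the chord-length parameterisation
#' `t_p = cumulative arc length` and period `T = perimeter`:
#' \deqn{a_n = \frac{T}{2 n^2 \pi^2} \sum_p \frac{\Delta x_p}{\Delta t_p}
#'   \left[\cos\frac{2\pi n t_p}{T} - \cos\frac{2\pi n t_{p-1}}{T}\right]}
#' and analogously `b_n` with sines, `c_n`, `d_n` with `\Delta y_p`. The
#' constant (DC) terms are not carried; the outline centroid is recorded
#' instead, and is ~0 for centred outlines.
#'
#' @param outline data frame with `x`, `y` columns (closed, first point not
#'   repeated, at least 3 points, no repeated consecutive points).
#' @param n_harmonics number of harmonics to compute.
#' @return An object of class `pip_efd`: a list with `coefficients`
#'   (`n_harmonics` x 4 matrix, columns `a`, `b`, `c`, `d`), `n_harmonics`,
#'   `centroid`, `centroid_size`, `perimeter` and `n_points`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' e <- efd(tibble::tibble(x = cos(th), y = sin(th)), 4)
#' round(e$coefficients, 3)
#' @export
efd <- function(outline, n_harmonics = 6L) {
  o <- as_outline(outline)
  n_harmonics <- assert_scalar_count(n_harmonics, "n_harmonics")
  x <- c(o$x, o$x[1L]); y <- c(o$y, o$y[1L])
  dx <- diff(x); dy <- diff(y)
  dt <- sqrt(dx^2 + dy^2)
  zero <- which(dt == 0)
  if (length(zero) > 0L) {
    abort(sprintf("repeated consecutive points at indices: %s",
                  paste(head(zero, 10L), collapse = ", ")))
  }
  tp <- cumsum(dt)
  T_ <- tp[length(tp)]
  t0 <- c(0, tp[-length(tp)])
  n <- seq_len(n_harmonics)
  ang1 <- outer(tp, n) * (2 * pi / T_)   # K x N
  ang0 <- outer(t0, n) * (2 * pi / T_)
  dcos <- cos(ang1) - cos(ang0)
  dsin <- sin(ang1) - sin(ang0)
  scale <- T_ / (2 * pi^2 * n^2)
  coef <- cbind(
    a = scale * colSums((dx / dt) * dcos),
    b = scale * colSums((dx / dt) * dsin),
    c = scale * colSums((dy / dt) * dcos),
    d = scale * colSums((dy / dt) * dsin)
  )
  structure(
    list(coefficients = coef, n_harmonics = n_harmonics,
         centroid = c(x = mean(o$x), y = mean(o$y)),
         centroid_size = sqrt(mean((o$x - mean(o$x))^2 + (o$y - mean(o$y))^2)),
         perimeter = T_, n_points = nrow(o)),
    class = "pip_efd"
  )
}

#' @export
print.pip_efd <- function(x, ...) {
  cat(sprintf("<pip_efd> %d harmonics over %d points, perimeter %.4g\n",
              x$n_harmonics, x$n_points, x$perimeter))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname efd
#' @param x a `pip_efd` object.
#' @param ... unused.
#' @export
tidy.pip_efd <- function(x, ...) {
  tibble(harmonic = seq_len(x$n_harmonics),
         a = x$coefficients[, "a"], b = x$coefficients[, "b"],
         c = x$coefficients[, "c"], d = x$coefficients[, "d"])
}

#' @rdname efd
#' @export
glance.pip_efd <- function(x, ...) {
  tibble(n_harmonics = x$n_harmonics, n_points = x$n_points,
         perimeter = x$perimeter, centroid_size = x$centroid_size,
         centroid_x = unname(x$centroid["x"]),
         centroid_y = unname(x$centroid["y"]))
}

#' Reconstruct an outline from elliptic Fourier descriptors
#'
#' Evaluates the truncated Fourier series
#' `x(t) = centroid_x + sum_n a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)`
#' (and analogously `y(t)` with `c_n`, `d_n`) at `n_points` equal steps of
#' `t` over one period.
#'
#' @param e a `pip_efd` object, or a plain `n x 4` coefficient matrix with
#'   columns `a`, `b`, `c`, `d`.
#' @param n_points number of points to evaluate.
#' @return A tibble with columns `x`, `y`. If all coefficients are zero the
#'   points collapse onto the centroid and an attribute `degenerate = TRUE`
#'   is set.
#' @examples
#' e <- matrix(c(1, 0, 0, 1), 1, dimnames = list(NULL, c("a", "b", "c", "d")))
#' head(efd_reconstruct(e, 8))
#' @export
efd_reconstruct <- function(e, n_points = 360L) {
  n_points <- assert_scalar_count(n_points, "n_points", min = 3L)
  if (inherits(e, "pip_efd")) {
    coef <- e$coefficients
    centroid <- e$centroid
  } else {
    coef <- as.matrix(e)
    if (ncol(coef) != 4L) abort("coefficient matrix must have 4 columns")
    colnames(coef) <- c("a", "b", "c", "d")
    centroid <- c(x = 0, y = 0)
  }
  nh <- nrow(coef)
  t_ <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  ang <- outer(t_, seq_len(nh))
  cs <- cos(ang); sn <- sin(ang)
  out <- tibble(
    x = centroid["x"] + as.vector(cs %*% coef[, "a"] + sn %*% coef[, "b"]),
    y = centroid["y"] + as.vector(cs %*% coef[, "c"] + sn %*% coef[, "d"])
  )
  if (all(coef == 0)) attr(out, "degenerate") <- TRUE
  out
}

#' Harmonic power spectrum of an EFD set
#'
#' The power of harmonic `n` is `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`; the
#' cumulative proportion measures how much of the total shape variation the
#' first harmonics capture. The total is taken over the harmonics present in
#' `e`, so compute `e` to the reference harmonic count (30 by default in the
#' pipeline) before reading off the proportion captured by the first six.
#'
#' @param e a `pip_efd` object.
#' @return A tibble with columns `harmonic`, `power`, `proportion`,
#'   `cumulative`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' e <- efd(tibble::tibble(x = 2 * cos(th), y = sin(th)), 5)
#' harmonic_power(e)
#' @export
harmonic_power <- function(e) {
  if (!inherits(e, "pip_efd")) abort("`e` must be a `pip_efd` object")
  p <- rowSums(e$coefficients^2) / 2
  if (sum(p) <= 0) abort("degenerate outline: all coefficients are zero")
  tibble(harmonic = seq_along(p), power = p,
         proportion = p / sum(p), cumulative = cumsum(p) / sum(p))
}

#' 24-coefficient shape features of an outline
#'
#' Composes [normalize_outline()] and [efd()] with six harmonics and
#' flattens the result to the fixed harmonic-major order
#' `a1, b1, c1, d1, ..., a6, b6, c6, d6`. These features are invariant to
#' translation, uniform scaling, rotation and the starting index of the
#' outline, and are the variables used in all discriminant analyses.
#'
#' @param outline data frame with `x`, `y` columns.
#' @param n_harmonics number of harmonics retained (default 6, i.e. 24
#'   coefficients).
#' @return A one-row tibble with `4 * n_harmonics` named columns.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' outline_features(tibble::tibble(x = 2 * cos(th), y = sin(th)))
#' @export
outline_features <- function(outline, n_harmonics = 6L) {
  nrm <- normalize_outline(outline)
  e <- efd(nrm, n_harmonics = n_harmonics)
  v <- as.vector(t(e$coefficients))
  as_tibble(as.list(setNames(v, feature_names(e$n_harmonics))))
}

#' Extract shape features from a set of silhouettes
#'
#' Runs trace -> resample -> normalise -> EFD for every silhouette and
#' returns one feature row per sample. This is the bulk version of
#' [outline_features()] used by the classification pipeline.
#'
#' @param x a `pip_population` (see [generate_population()]) or a named list
#'   of logical matrices.
#' @param n_points number of equally spaced outline points (default 360).
#' @param n_harmonics harmonics retained (default 6).
#' @param min_size minimum component size passed to [trace_outline()].
#' @return A tibble with a `sample_id` column followed by the coefficient
#'   columns.
#' @export
extract_features <- function(x, n_points = 360L, n_harmonics = 6L,
                             min_size = 32L) {
  images <- if (inherits(x, "pip_population")) x$images else x
  if (!is.list(images) || length(images) == 0L) {
    abort("`x` must be a `pip_population` or a non-empty list of silhouettes")
  }
  ids <- names(images) %||% as.character(seq_along(images))
  rows <- purrr::map(images, function(img) {
    o <- trace_outline(img, min_size = min_size)
    outline_features(resample_outline(o, n_points), n_harmonics = n_harmonics)
  })
  dplyr::bind_cols(tibble(sample_id = ids), dplyr::bind_rows(rows))
}
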