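#' Threshold a greyscale image into a seed silhouette
#'
#' Converts a greyscale raster into a binary silhouette with the seed as
#' foreground. Images are matrices in raster orientation (row 1 at the top),
#' with intensities in `[0, 1]`; logical matrices pass through unchanged.
#'
#' @param image numeric or logical matrix. Multichannel arrays are averaged
#'   to grey first.
#' @param threshold either a numeric cutoff in `[0, 1]` or `"otsu"` (default)
#'   for Otsu's between-class variance criterion.
#' @param foreground `"light"` (default) when the seed is brighter than the
#'   background, `"dark"` otherwise.
#' @return A logical matrix of class `pip_silhouette` with attributes
#'   `threshold` (the cutoff used) and `threshold_method`.
#' @examples
#' img <- matrix(0, 32, 32)
#' img[10:22, 10:22] <- 0.8
#' sil <- binarize(img)
#' sum(sil)
#' @export
binarize <- function(image, threshold = "otsu", foreground = c("light", "dark")) {
  foreground <- match.arg(foreground)
  if (length(dim(image)) == 3L) image <- apply(image, c(1L, 2L), mean)
  if (!is.matrix(image) || length(image) == 0L) {
    abort("`image` must be a non-empty matrix")
  }
  if (is.logical(image)) {
    sil <- image
    thr <- NA_real_
    method <- "binary"
  } else {
    if (identical(threshold, "otsu")) {
      thr <- otsu_threshold(image)
      method <- "otsu"
    } else {
      if (!is.numeric(threshold) || length(threshold) != 1L) {
        abort("`threshold` must be a single number or \"otsu\"")
      }
      thr <- threshold
      method <- "fixed"
    }
    sil <- if (foreground == "light") image > thr else image < thr
  }
  if (!any(sil)) abort("no object: thresholding produced an empty foreground")
  structure(sil, class = c("pip_silhouette", class(sil)),
            threshold = thr, threshold_method = method)
}

## Otsu's threshold: maximise between-class variance on a 256-bin histogram
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

## label 8-connected foreground components by breadth-first frontier
## expansion; returns an integer matrix of labels (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  npr <- nr + 2L
  offs <- c(-1L, 1L, -npr, npr, -npr - 1L, -npr + 1L, npr - 1L, npr + 1L)
  labels <- integer(length(pad))
  todo <- which(pad)
  lab <- 0L
  while (length(todo) > 0L) {
    lab <- lab + 1L
    frontier <- todo[1L]
    labels[frontier] <- lab
    while (length(frontier) > 0L) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[pad[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
    todo <- todo[labels[todo] == 0L]
  }
  matrix(labels, npr)[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

## Moore-neighbour boundary following with Jacob's stopping criterion on a
## single-component mask; returns boundary pixel (row, col) pairs in order
moore_boundary <- function(mask) {
  nr <- nrow(mask)
  pad <- matrix(FALSE, nr + 2L, ncol(mask) + 2L)
  pad[2:(nr + 1L), 2:(ncol(mask) + 1L)] <- mask
  npr <- nrow(pad)
  s <- which(pad)[1L]
  sr <- ((s - 1L) %% npr) + 1L
  sc <- ((s - 1L) %/% npr) + 1L
  ## clockwise neighbour order in raster axes: W, NW, N, NE, E, SE, S, SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dirmat <- matrix(0L, 3L, 3L)
  for (d in 1:8) dirmat[dr[d] + 2L, dc[d] + 2L] <- d
  cr <- sr; cc <- sc
  pr <- sr; pc <- sc - 1L   # scan order guarantees the W neighbour is background
  path_r <- integer(1024L); path_c <- integer(1024L); np <- 0L
  first_move <- NULL
  budget <- 8L * sum(mask) + 16L
  repeat {
    np <- np + 1L
    if (np > length(path_r)) {
      path_r <- c(path_r, integer(length(path_r)))
      path_c <- c(path_c, integer(length(path_c)))
    }
    path_r[np] <- cr; path_c[np] <- cc
    bd <- dirmat[pr - cr + 2L, pc - cc + 2L]
    nxr <- 0L
    for (k in 1:8) {
      d <- ((bd - 1L + k) %% 8L) + 1L
      rr <- cr + dr[d]; cc2 <- cc + dc[d]
      if (pad[rr, cc2]) { nxr <- rr; nxc <- cc2; break }
    }
    if (nxr == 0L) break   # isolated pixel
    if (is.null(first_move)) {
      first_move <- c(cr, cc, nxr, nxc)
    } else if (cr == first_move[1L] && cc == first_move[2L] &&
               nxr == first_move[3L] && nxc == first_move[4L]) {
      np <- np - 1L
      break
    }
    pr <- cr; pc <- cc
    cr <- nxr; cc <- nxc
    if (np > budget) abort("boundary tracing failed to terminate")
  }
  cbind(row = path_r[seq_len(np)] - 1L, col = path_c[seq_len(np)] - 1L)
}

## circular moving average of polygon vertices (digitisation smoothing)
smooth_closed <- function(xy, window) {
  n <- nrow(xy)
  if (window <= 1L || n <= window) return(xy)
  k <- (window - 1L) %/% 2L
  out <- xy
  for (j in c(-(k:1), 1:k)) {
    out <- out + xy[((seq_len(n) + j - 1L) %% n) + 1L, , drop = FALSE]
  }
  out / window
}

## push vertices outward along the local normal (counter-clockwise, y-up);
## compensates the half-pixel bias of tracing through pixel centres
offset_outward <- function(xy, d) {
  n <- nrow(xy)
  nxt <- xy[c(2:n, 1L), , drop = FALSE]
  prv <- xy[c(n, 1:(n - 1L)), , drop = FALSE]
  tg <- nxt - prv
  len <- sqrt(rowSums(tg^2))
  len[len == 0] <- 1
  xy + d * cbind(tg[, 2L], -tg[, 1L]) / len
}

#' Trace the outer contour of a silhouette
#'
#' Extracts the boundary of the largest 8-connected foreground component by
#' Moore-neighbour boundary following. Raster row/column coordinates are
#' converted to mathematical x/y axes (y up), the polygon is oriented
#' counter-clockwise, lightly smoothed to remove pixel staircase artefacts,
#' and offset outward by half a pixel so that enclosed area and perimeter
#' track the underlying silhouette. Interior holes are ignored.
#'
#' @param silhouette logical matrix (or [binarize()] output).
#' @param min_size minimum pixel count of the traced component; smaller
#'   objects raise an error (guards against noise specks).
#' @param smooth_window width of the circular moving-average filter applied
#'   to boundary vertices; 1 disables smoothing.
#' @return A tibble with columns `x`, `y`: one closed counter-clockwise
#'   outline (first point not repeated).
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:44, 16:48] <- 1
#' o <- trace_outline(binarize(img, 0.5))
#' nrow(o)
#' @export
trace_outline <- function(silhouette, min_size = 32L, smooth_window = 5L) {
  mask <- unclass(silhouette)
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`silhouette` must be a logical matrix")
  }
  if (!any(mask)) abort("no object: silhouette is empty")
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  largest <- which.max(sizes)
  if (sizes[largest] < min_size) {
    abort(sprintf("object too small: largest component has %d px (< %d)",
                  sizes[largest], as.integer(min_size)))
  }
  comp <- labels == largest
  b <- moore_boundary(comp)
  ## raster (row, col) -> mathematical (x, y), y up
  xy <- cbind(x = as.numeric(b[, "col"]), y = nrow(mask) - as.numeric(b[, "row"]) + 1)
  ## drop consecutive duplicates created by spur backtracking
  nxt <- c(2:nrow(xy), 1L)
  dup <- xy[, 1L] == xy[nxt, 1L] & xy[, 2L] == xy[nxt, 2L]
  if (any(dup)) xy <- xy[!dup, , drop = FALSE]
  if (nrow(xy) >= 3L && signed_area(xy[, 1L], xy[, 2L]) < 0) {
    xy <- xy[nrow(xy):1L, , drop = FALSE]
  }
  if (nrow(xy) >= 3L) {
    xy <- smooth_closed(xy, as.integer(smooth_window))
    xy <- offset_outward(xy, 0.5)
  }
  tibble(x = xy[, 1L], y = xy[, 2L])
}

#' Resample an outline at equal arc-length spacing
#'
#' Places `n_points` points at equal arc-length intervals along the closed
#' polygon, by linear interpolation on the segments, starting at the
#' outline's first point. Total perimeter is preserved to well within 0.5%.
#'
#' @param outline data frame with `x`, `y` columns (closed polygon, first
#'   point not repeated).
#' @param n_points number of points to return (default 360).
#' @return A tibble with `n_points` rows and columns `x`, `y`.
#' @examples
#' sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' resample_outline(sq, 8)
#' @export
resample_outline <- function(outline, n_points = 360L) {
  o <- as_outline(outline)
  n_points <- assert_scalar_count(n_points, "n_points", min = 3L)
  x <- c(o$x, o$x[1L]); y <- c(o$y, o$y[1L])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  t_cum <- c(0, cumsum(seg))
  total <- t_cum[length(t_cum)]
  if (total <= 0) abort("outline has zero-length perimeter")
  ti <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  tibble(
    x = approx(t_cum, x, xout = ti, ties = "ordered")$y,
    y = approx(t_cum, y, xout = ti, ties = "ordered")$y
  )
}
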