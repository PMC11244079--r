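#' Define a shape class for the synthetic silhouette generator
#'
#' A shape class is a Gaussian in the 24-dimensional normalised EFD feature
#' space: samples are coefficient vectors drawn from
#' `N(mean_coefficients, covariance)`, reconstructed into outlines by the
#' inverse elliptic Fourier transform and rasterised into silhouettes.
#'
#' @param label class name (e.g. `"wild"`, `"domestic"`, or a cultivar id).
#' @param mean_coefficients numeric vector of length 24: the class mean in
#'   harmonic-major `a1, b1, c1, d1, ...` order.
#' @param covariance 24 x 24 positive semi-definite matrix, or a vector of
#'   24 standard deviations (expanded to a diagonal covariance), or a single
#'   standard deviation.
#' @param n_samples number of silhouettes to generate for this class.
#' @param length_px nominal seed length in pixels applied at rasterisation
#'   (142 px, about 6 mm at 600 dpi, by default).
#' @param status morphotype the class belongs to (defaults to `label`);
#'   carried into the truth table so cultivar classes can be marked
#'   `"domestic"`.
#' @param cultivar_id optional cultivar identifier for per-cultivar classes.
#' @return An object of class `shape_class_spec`.
#' @export
shape_class_spec <- function(label, mean_coefficients, covariance, n_samples,
                             length_px = 142, status = label,
                             cultivar_id = NA_character_) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort("`label` must be a non-empty string")
  }
  mu <- as.numeric(mean_coefficients)
  if (length(mu) != 24L || any(!is.finite(mu))) {
    abort("`mean_coefficients` must be 24 finite values")
  }
  if (is.matrix(covariance)) {
    sigma <- covariance
  } else if (length(covariance) %in% c(1L, 24L)) {
    sigma <- diag(rep(as.numeric(covariance)^2, length.out = 24L), 24L)
  } else {
    abort("`covariance` must be a 24 x 24 matrix, 24 sds, or a single sd")
  }
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8))) {
    abort(sprintf("covariance for class '%s' is not symmetric", label))
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort(sprintf("covariance for class '%s' is not positive semi-definite",
                  label))
  }
  n_samples <- assert_scalar_count(n_samples, "n_samples")
  if (!is.numeric(length_px) || length_px <= 0) {
    abort("`length_px` must be positive")
  }
  structure(
    list(label = label, mean_coefficients = mu, covariance = sigma,
         n_samples = n_samples, length_px = as.numeric(length_px),
         status = status, cultivar_id = cultivar_id),
    class = "shape_class_spec"
  )
}

#' Rasterise an outline into a binary silhouette
#'
#' Scales the (simple, closed) polygon so that its maximum Feret diameter
#' equals `length_px`, centres it on the canvas and fills it by scan-line
#' polygon filling over pixel centres: foreground is white-on-black, one
#' seed per image.
#'
#' @param outline data frame with `x`, `y` columns.
#' @param image_size canvas side length in pixels (square canvas).
#' @param length_px target major-axis extent in pixels.
#' @return A logical `image_size` x `image_size` matrix (raster orientation,
#'   row 1 at top).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 181)[-181]
#' m <- rasterize_outline(tibble::tibble(x = cos(th), y = sin(th)), 128, 100)
#' sum(m) / (pi * 50^2)
#' @export
rasterize_outline <- function(outline, image_size = 512L, length_px = 142) {
  o <- as_outline(outline)
  image_size <- assert_scalar_count(image_size, "image_size", min = 8L)
  if (!is_simple_polygon(o$x, o$y)) {
    abort("outline is self-intersecting and cannot be rasterised")
  }
  hull <- grDevices::chull(o$x, o$y)
  hx <- o$x[hull]; hy <- o$y[hull]
  feret <- sqrt(max(outer(hx, hx, `-`)^2 + outer(hy, hy, `-`)^2))
  if (feret <= 0) abort("degenerate outline: zero extent")
  s <- length_px / feret
  x <- (o$x - mean(range(o$x))) * s + (image_size + 1) / 2
  y <- (o$y - mean(range(o$y))) * s + (image_size + 1) / 2
  if (min(x) < 1 || max(x) > image_size || min(y) < 1 || max(y) > image_size) {
    abort("outline exceeds the canvas; increase `image_size`")
  }
  mask <- matrix(FALSE, image_size, image_size)
  nxt <- c(2:length(x), 1L)
  x1 <- x; y1 <- y; x2 <- x[nxt]; y2 <- y[nxt]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  ## half-open scan-line rule: edge crosses integer scanline y0 when
  ## min(y) <= y0 < max(y), which counts shared vertices exactly once
  lo <- ceiling(pmin(y1, y2))
  hi <- ceiling(pmax(y1, y2)) - 1L
  cnt <- pmax(hi - lo + 1L, 0L)
  e <- rep.int(seq_along(x1), cnt)
  y0 <- sequence(cnt) - 1L + rep.int(lo, cnt)
  xc <- x1[e] + (y0 - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
  ord <- order(y0, xc)
  y0 <- y0[ord]; xc <- xc[ord]
  odd <- seq_along(xc) %% 2L == 1L
  xl <- xc[odd]; xr <- xc[!odd]; yl <- y0[odd]
  cl <- ceiling(xl - 1e-9); cr <- floor(xr + 1e-9)
  ncols <- pmax(cr - cl + 1L, 0L)
  cols <- sequence(ncols) - 1L + rep.int(cl, ncols)
  rows <- rep.int(image_size - yl + 1L, ncols)
  mask[cbind(rows, cols)] <- TRUE
  mask
}

## draw one simple outline from a class Gaussian; rejection sampling with a
## bounded retry budget keeps outlines valid polygons
draw_class_outline <- function(spec, n_points, check_points = 180L,
                               max_retries = 100L) {
  for (i in seq_len(max_retries)) {
    v <- MASS::mvrnorm(1L, spec$mean_coefficients, spec$covariance)
    coef <- matrix(v, ncol = 4L, byrow = TRUE,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
    probe <- efd_reconstruct(coef, check_points)
    if (is_simple_polygon(probe$x, probe$y)) {
      return(list(coefficients = v, outline = efd_reconstruct(coef, n_points)))
    }
  }
  abort(sprintf(
    "generation failed for class '%s': outlines still self-intersecting after %d retries",
    spec$label, max_retries))
}

#' Generate a synthetic silhouette population
#'
#' Draws coefficient vectors from each class Gaussian, reconstructs each
#' outline by the inverse elliptic Fourier transform, rejects and redraws
#' self-intersecting outlines (bounded retries), and rasterises each outline
#' into a binary silhouette. The truth table records the generating
#' coefficients for every sample, so downstream feature extraction can be
#' validated by parameter recovery.
#'
#' @param specs list of [shape_class_spec()] objects.
#' @param image_size canvas side length in pixels.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param n_points outline points used at rasterisation.
#' @param metadata optional cultivar metadata table to attach.
#' @return An object of class `pip_population`: a list with `images` (named
#'   list of logical matrices), `truth` (tibble: `sample_id`, `class`,
#'   `cultivar_id`, `label`, and the 24 true coefficients), `metadata`,
#'   `image_size` and `seed`.
#' @examples
#' spec <- shape_class_spec("demo", pip_template_features()$wild, 0.02, 3,
#'                          length_px = 60)
#' pop <- generate_population(list(spec), image_size = 128, seed = 1)
#' pop$truth$sample_id
#' @export
generate_population <- function(specs, image_size = 512L, seed = 1L,
                                n_points = 360L, metadata = NULL) {
  if (inherits(specs, "shape_class_spec")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "shape_class_spec"))) {
    abort("`specs` must be a non-empty list of `shape_class_spec` objects")
  }
  image_size <- assert_scalar_count(image_size, "image_size", min = 8L)
  for (sp in specs) {
    if (sp$length_px > image_size - 8L) {
      abort(sprintf("class '%s': length_px %g leaves no margin on a %d px canvas",
                    sp$label, sp$length_px, image_size))
    }
  }
  set.seed(as.integer(seed))
  images <- list()
  truth <- vector("list", length(specs))
  k <- 0L
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    coefs <- matrix(NA_real_, sp$n_samples, 24L)
    ids <- character(sp$n_samples)
    for (i in seq_len(sp$n_samples)) {
      k <- k + 1L
      d <- draw_class_outline(sp, n_points)
      id <- sprintf("pip%05d", k)
      images[[id]] <- rasterize_outline(d$outline, image_size, sp$length_px)
      ## truth = normalized features of the ideal (pre-raster) outline, the
      ## quantity image extraction is meant to recover
      coefs[i, ] <- unlist(outline_features(d$outline))
      ids[i] <- id
    }
    colnames(coefs) <- feature_names()
    truth[[si]] <- dplyr::bind_cols(
      tibble(sample_id = ids, class = sp$status,
             cultivar_id = sp$cultivar_id, label = sp$label),
      as_tibble(coefs)
    )
  }
  structure(
    list(images = images, truth = dplyr::bind_rows(truth),
         metadata = metadata, image_size = image_size,
         seed = as.integer(seed)),
    class = "pip_population"
  )
}

#' @export
print.pip_population <- function(x, ...) {
  cat(sprintf("<pip_population> %d silhouettes (%d x %d px), %d classes, seed %d\n",
              length(x$images), x$image_size, x$image_size,
              length(unique(x$truth$label)), x$seed))
  invisible(x)
}

#' Generate a cultivar metadata table
#'
#' Samples berry colour, geographic origin region and use class for
#' `n_cultivars` cultivars from the given weights. The default colour
#' weights mirror a reference collection of 145 white, 183 red and 3 pink
#' cultivars.
#'
#' @param n_cultivars number of cultivars.
#' @param colour_weights named non-negative weights over
#'   `white`/`red`/`pink`.
#' @param region_weights named non-negative weights over origin regions.
#' @param use_weights named non-negative weights over use classes `W`
#'   (wine), `T` (table), `W/T`, `ND`.
#' @param seed integer seed.
#' @return A tibble with columns `cultivar_id`, `name`, `colour`,
#'   `origin_region`, `use`.
#' @examples
#' generate_cultivar_metadata(5, seed = 1)
#' @export
generate_cultivar_metadata <- function(n_cultivars,
                                       colour_weights = c(white = 145, red = 183, pink = 3),
                                       region_weights = c("Sardinia" = 30,
                                                          "Italian peninsula" = 30,
                                                          "Balkans" = 20,
                                                          "Caucasus" = 12,
                                                          "central western Europe" = 8),
                                       use_weights = c("W" = 24, "T" = 2,
                                                       "W/T" = 5, "ND" = 1),
                                       seed = 1L) {
  n_cultivars <- assert_scalar_count(n_cultivars, "n_cultivars")
  check_w <- function(w, name, vocab = NULL) {
    if (any(w < 0) || sum(w) <= 0) {
      abort(sprintf("`%s` must be non-negative and not all zero", name))
    }
    if (!is.null(vocab) && !all(names(w) %in% vocab)) {
      abort(sprintf("`%s` names must be in: %s", name,
                    paste(vocab, collapse = ", ")))
    }
  }
  check_w(colour_weights, "colour_weights", c("white", "red", "pink"))
  check_w(region_weights, "region_weights")
  check_w(use_weights, "use_weights", c("W", "T", "W/T", "ND"))
  set.seed(as.integer(seed))
  tibble(
    cultivar_id = sprintf("cv%03d", seq_len(n_cultivars)),
    name = sprintf("Cultivar %03d", seq_len(n_cultivars)),
    colour = sample(names(colour_weights), n_cultivars, replace = TRUE,
                    prob = colour_weights / sum(colour_weights)),
    origin_region = sample(names(region_weights), n_cultivars, replace = TRUE,
                           prob = region_weights / sum(region_weights)),
    use = sample(names(use_weights), n_cultivars, replace = TRUE,
                 prob = use_weights / sum(use_weights))
  )
}
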