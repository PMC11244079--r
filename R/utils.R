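## internal helpers shared across modules

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves moved away from zero,
#' the convention used for all reported allocation percentages. Base
#' `round()` rounds half to even, which cannot reproduce e.g. 7.5% -> 8%.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_away(c(7.5, 92.467, -2.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## column names of the 24-coefficient feature block, harmonic-major
feature_names <- function(n_harmonics = 6L) {
  as.vector(t(outer(seq_len(n_harmonics), c("a", "b", "c", "d"),
                    function(n, l) paste0(l, n))))
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

## closed-polygon signed area (shoelace); positive for counter-clockwise
signed_area <- function(x, y) {
  nxt <- c(2:length(x), 1L)
  sum(x * y[nxt] - x[nxt] * y) / 2
}

polygon_perimeter <- function(x, y) {
  nxt <- c(2:length(x), 1L)
  sum(sqrt((x[nxt] - x)^2 + (y[nxt] - y)^2))
}

## coerce a data frame with x/y columns to a validated outline tibble
as_outline <- function(o, arg = "outline") {
  if (!is.data.frame(o) || !all(c("x", "y") %in% names(o))) {
    abort(sprintf("`%s` must be a data frame with `x` and `y` columns", arg))
  }
  if (nrow(o) < 3L) abort(sprintf("`%s` must have at least 3 points", arg))
  if (any(!is.finite(o$x)) || any(!is.finite(o$y))) {
    abort(sprintf("`%s` contains non-finite coordinates", arg))
  }
  tibble(x = as.numeric(o$x), y = as.numeric(o$y))
}

## TRUE when no two non-adjacent edges of the closed polygon intersect
is_simple_polygon <- function(x, y) {
  n <- length(x)
  nxt <- c(2:n, 1L)
  x1 <- x; y1 <- y; x2 <- x[nxt]; y2 <- y[nxt]
  ## orientation of point (px,py) wrt each segment, vectorised over pairs
  i <- rep(seq_len(n), each = n); j <- rep(seq_len(n), times = n)
  keep <- i < j & (j - i) > 1L & !(i == 1L & j == n)
  i <- i[keep]; j <- j[keep]
  d1 <- (x2[i] - x1[i]) * (y1[j] - y1[i]) - (y2[i] - y1[i]) * (x1[j] - x1[i])
  d2 <- (x2[i] - x1[i]) * (y2[j] - y1[i]) - (y2[i] - y1[i]) * (x2[j] - x1[i])
  d3 <- (x2[j] - x1[j]) * (y1[i] - y1[j]) - (y2[j] - y1[j]) * (x1[i] - x1[j])
  d4 <- (x2[j] - x1[j]) * (y2[i] - y1[j]) - (y2[j] - y1[j]) * (x2[i] - x1[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}
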