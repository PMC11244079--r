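## geometric fixtures and independent oracles used across test files

circle_outline <- function(n = 360L, r = 1, cx = 0, cy = 0, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  tibble::tibble(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_outline <- function(a = 2, b = 1, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  tibble::tibble(x = a * cos(th), y = b * sin(th))
}

square_outline <- function(side = 1) {
  tibble::tibble(x = c(0, side, side, 0), y = c(0, 0, side, side))
}

## random smooth closed curve from low-harmonic coefficients; always simple
## for the magnitudes used here
random_smooth_outline <- function(n_points = 360L, n_harmonics = 6L,
                                  base = c(1, 0.6), decay = 2.5) {
  coef <- matrix(rnorm(4L * n_harmonics, sd = 0.25 / (1:n_harmonics)^decay),
                 n_harmonics, 4L)
  coef[1L, 1L] <- base[1L]
  coef[1L, 4L] <- base[2L]
  colnames(coef) <- c("a", "b", "c", "d")
  efd_reconstruct(coef, n_points)
}

rasterize_disk <- function(r, size = 2L * r + 21L) {
  ctr <- (size + 1) / 2
  col <- matrix(rep(seq_len(size), each = size), size, size)
  row <- matrix(rep(seq_len(size), times = size), size, size)
  (col - ctr)^2 + (row - ctr)^2 <= r^2
}

shoelace_area <- function(o) {
  nxt <- c(2:nrow(o), 1L)
  abs(sum(o$x * o$y[nxt] - o$x[nxt] * o$y)) / 2
}

## area (shoelace) centroid of a closed polygon: invariant to how the
## boundary is sampled, unlike the plain vertex mean
polygon_centroid <- function(o) {
  nxt <- c(2:nrow(o), 1L)
  cr <- o$x * o$y[nxt] - o$x[nxt] * o$y
  a <- sum(cr) / 2
  c(sum((o$x + o$x[nxt]) * cr) / (6 * a),
    sum((o$y + o$y[nxt]) * cr) / (6 * a))
}

perimeter_of <- function(o) {
  nxt <- c(2:nrow(o), 1L)
  sum(sqrt((o$x[nxt] - o$x)^2 + (o$y[nxt] - o$y)^2))
}

## independent EFD oracle: a_n etc. are the Fourier coefficients of the
## piecewise-linear x(t), y(t) in the cumulative chord parameterisation;
## computed here by dense trapezoidal integration, not by the closed form
efd_trapezoid_oracle <- function(outline, n_harmonics, subdiv = 100L) {
  x <- c(outline$x, outline$x[1L]); y <- c(outline$y, outline$y[1L])
  dt <- sqrt(diff(x)^2 + diff(y)^2)
  tp <- c(0, cumsum(dt))
  T_ <- tp[length(tp)]
  ## fine grid: subdiv points per segment (x, y linear within a segment)
  fr <- seq(0, 1, length.out = subdiv + 1L)[-(subdiv + 1L)]
  tfine <- as.vector(vapply(seq_along(dt), function(p)
    tp[p] + fr * dt[p], numeric(subdiv)))
  tfine <- c(tfine, T_)
  xf <- stats::approx(tp, x, xout = tfine)$y
  yf <- stats::approx(tp, y, xout = tfine)$y
  trapz <- function(f) sum((f[-1] + f[-length(f)]) / 2 * diff(tfine))
  coef <- vapply(seq_len(n_harmonics), function(n) {
    w <- 2 * pi * n * tfine / T_
    c(a = (2 / T_) * trapz(xf * cos(w)), b = (2 / T_) * trapz(xf * sin(w)),
      c = (2 / T_) * trapz(yf * cos(w)), d = (2 / T_) * trapz(yf * sin(w)))
  }, numeric(4))
  t(coef)
}

## independent Wilks' lambda via one-way MANOVA (eigenvalue route); falls
## back to explicit sums of squares for a single response
wilks_manova_oracle <- function(data, group, features) {
  X <- as.matrix(data[features])
  g <- factor(data[[group]])
  if (ncol(X) == 1L) {
    ssw <- sum(tapply(X[, 1L], g, function(v) sum((v - mean(v))^2)))
    sst <- sum((X[, 1L] - mean(X[, 1L]))^2)
    return(ssw / sst)
  }
  fit <- stats::manova(X ~ g)
  unname(summary(fit, test = "Wilks")$stats[1L, "Wilks"])
}

## literal leave-one-out loop: refit means/covariance from scratch per case
naive_loocv <- function(data, group, features, priors = "equal") {
  n <- nrow(data)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_lda(data[-i, , drop = FALSE], group, features, priors = priors)
    pred[i] <- as.character(classify(fit, data[i, , drop = FALSE])$.class)
  }
  pred
}

## brute-force equal-prior classifier: nearest group mean in Mahalanobis
## distance under the pooled within-class covariance
mahalanobis_classifier <- function(train, group, features, newdata) {
  X <- as.matrix(train[features])
  y <- factor(train[[group]])
  means <- rowsum(X, y) / as.vector(table(y))
  Xc <- X - means[as.integer(y), , drop = FALSE]
  pooled <- crossprod(Xc) / (nrow(X) - nlevels(y))
  Xn <- as.matrix(newdata[features])
  d2 <- sapply(seq_len(nrow(means)), function(j)
    stats::mahalanobis(Xn, means[j, ], pooled))
  levels(y)[max.col(-d2, ties.method = "first")]
}

## two-class Gaussian feature table with a given Mahalanobis separation
## spread over the first k coordinates (p total), unit sds
gaussian_two_class <- function(n_per_class, delta, p = 6L, k = 3L) {
  shift <- rep(0, p)
  shift[seq_len(k)] <- delta / sqrt(k)
  X <- rbind(
    matrix(rnorm(n_per_class * p), n_per_class),
    matrix(rnorm(n_per_class * p), n_per_class) +
      matrix(shift, n_per_class, p, byrow = TRUE)
  )
  colnames(X) <- paste0("x", seq_len(p))
  out <- tibble::as_tibble(as.data.frame(X))
  out$g <- rep(c("A", "B"), each = n_per_class)
  out$sample_id <- as.character(seq_len(2L * n_per_class))
  out
}
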