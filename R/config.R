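#' Read a pipeline configuration file
#'
#' Configurations are plain YAML lists covering the generator (class
#' templates, coefficient spreads, class separation), imaging (canvas size,
#' seed length), outline extraction, discriminant-analysis thresholds,
#' reference and site sample sizes, and reporting options. See
#' `system.file("extdata", "default_config.yaml", package = "pipmorph")` for
#' the annotated default.
#'
#' @param path path to a YAML file.
#' @return A named list.
#' @export
read_pip_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_pip_config
#' @details `default_config()` returns the packaged configuration that
#'   mirrors the scale of the study design this package models: a balanced
#'   reference of 1319 wild and 1319 domestic pips drawn from 330 cultivars
#'   and 22 wild accessions, and three unknown assemblages of 1686, 301 and
#'   241 pips. `demo_config()` is a scaled-down variant for examples and
#'   quick checks.
#' @export
default_config <- function() {
  read_pip_config(system.file("extdata", "default_config.yaml",
                              package = "pipmorph", mustWork = TRUE))
}

#' @rdname read_pip_config
#' @export
demo_config <- function() {
  read_pip_config(system.file("extdata", "demo_config.yaml",
                              package = "pipmorph", mustWork = TRUE))
}

#' Morphotype outline templates
#'
#' `pip_templates()` returns the raw low-harmonic template curves of the two
#' morphotypes: a rounder, low-eccentricity "wild" form and an elongated,
#' beak-bearing "domestic" form built from harmonics 1-3. They are
#' illustrative defaults, read from the packaged configuration.
#' `pip_template_features()` converts each template into its 24-coefficient
#' normalised feature vector (reconstruct, normalise, re-extract), which is
#' the fixed point of the feature extractor that the generator uses as the
#' class mean.
#'
#' @param config a configuration list with a `generator$templates` entry.
#' @return `pip_templates()`: a named list of `n x 4` coefficient matrices.
#'   `pip_template_features()`: a named list of length-24 feature vectors.
#' @export
pip_templates <- function(config = default_config()) {
  purrr::map(config$generator$templates, function(tm) {
    coef <- cbind(a = as.numeric(tm$a), b = as.numeric(tm$b),
                  c = as.numeric(tm$c), d = as.numeric(tm$d))
    coef
  })
}

#' @rdname pip_templates
#' @details Because elliptic Fourier extraction reads the outline in its
#'   arc-length parameterisation, a raw coefficient vector is not exactly
#'   reproduced by reconstruct-then-extract; `pip_template_features()`
#'   iterates that map a few times so the stored class means are numerical
#'   fixed points of the feature extractor.
#' @export
pip_template_features <- function(config = default_config()) {
  purrr::map(pip_templates(config), function(coef) {
    v <- unlist(outline_features(efd_reconstruct(coef, 360L)))
    for (i in 1:5) {
      m <- matrix(v, ncol = 4L, byrow = TRUE,
                  dimnames = list(NULL, c("a", "b", "c", "d")))
      v <- unlist(outline_features(efd_reconstruct(m, 360L)))
    }
    v
  })
}

## per-coefficient generator standard deviations: shape variation decays
## with harmonic rank but is floored so no coordinate degenerates
coefficient_sds <- function(config = default_config()) {
  g <- config$generator
  sds <- pmax(g$base_sd / rep(1:6, each = 4L), g$floor_sd)
  setNames(sds, feature_names())
}

## drawn coefficient vector -> normalized features of the ideal outline
## (the quantity image extraction recovers)
coef_to_features <- function(v, n_points = 360L) {
  m <- matrix(v, ncol = 4L, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  unlist(outline_features(efd_reconstruct(m, n_points)))
}

## unscented-transform estimate of the feature-space mean and covariance of
## a class Gaussian pushed through coef_to_features
ut_feature_moments <- function(mu, sds) {
  n <- length(mu)
  steps <- sqrt(n) * sds
  pts <- rbind(
    matrix(mu, 2L * n, n, byrow = TRUE) +
      rbind(diag(steps, n), -diag(steps, n))
  )
  G <- t(apply(pts, 1L, coef_to_features))
  m <- colMeans(G)
  Gc <- sweep(G, 2L, m)
  list(mean = m, cov = crossprod(Gc) / (2L * n))
}

#' Build wild/domestic class specs at a given separation
#'
#' Places the two class means symmetrically about the midpoint of the wild
#' and domestic template feature vectors, scaled so that the Mahalanobis
#' distance between the classes *as seen by the feature extractor* equals
#' `delta`. Because outline reconstruction followed by normalised re-
#' extraction is mildly non-linear, a naive drawn-space separation shrinks
#' by ~10% in feature space; the constructor therefore calibrates the
#' separation with a deterministic unscented propagation of each class
#' Gaussian through the reconstruct-extract map and solves for the scale
#' that achieves the requested feature-space distance. With equal priors
#' and a shared covariance the Bayes accuracy of the two-class problem is
#' then `pnorm(delta / 2)`, which makes the generator's separation directly
#' testable.
#'
#' @param n_wild,n_domestic samples per class.
#' @param delta target Mahalanobis distance between the class means in
#'   extracted-feature space.
#' @param config configuration list.
#' @return A list of two [shape_class_spec()] objects named `wild` and
#'   `domestic`.
#' @export
pip_class_specs <- function(n_wild, n_domestic, delta = NULL,
                            config = default_config()) {
  delta <- delta %||% config$generator$delta
  tf <- pip_template_features(config)
  sds <- coefficient_sds(config)
  mid <- (tf$wild + tf$domestic) / 2
  dir <- tf$domestic - tf$wild
  delta0 <- sqrt(sum((dir / sds)^2))
  sc <- delta / delta0
  if (delta > 0) {
    for (it in 1:3) {
      a <- ut_feature_moments(mid - sc / 2 * dir, sds)
      b <- ut_feature_moments(mid + sc / 2 * dir, sds)
      pool <- (a$cov + b$cov) / 2
      d <- b$mean - a$mean
      delta_g <- sqrt(drop(crossprod(d, solve(pool, d))))
      if (abs(delta_g - delta) < 0.005 * delta) break
      sc <- sc * delta / delta_g
    }
  }
  lp <- config$image$length_px
  list(
    wild = shape_class_spec("wild", mid - sc / 2 * dir, sds, n_wild,
                            length_px = lp * config$generator$wild_length_ratio),
    domestic = shape_class_spec("domestic", mid + sc / 2 * dir, sds,
                                n_domestic, length_px = lp)
  )
}

#' Assignment counts of archaeological pips to modern cultivars
#'
#' Returns the packaged 29-row worked-example table of per-cultivar
#' assignment counts across the three archaeological assemblages (wells N
#' and KK of Sa Osa, and Nora), restricted to cultivars represented by at
#' least 10 pips. Used for reporting-arithmetic checks and as a demo input
#' to the aggregation helpers.
#'
#' @return A tibble with columns `cultivar`, `origin`, `use`, `colour`,
#'   `well_n`, `well_kk`, `nora`, `total`.
#' @examples
#' table1_fixture()
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "cultivar_assignment_counts.csv",
                      package = "pipmorph", mustWork = TRUE)
  as_tibble(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
}
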