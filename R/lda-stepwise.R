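## ---- labelled-feature bookkeeping ------------------------------------

## validate and unpack a labelled feature table; `features` default: all
## numeric columns except the group column and sample_id
unpack_labelled <- function(data, group, features = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  if (!is.character(group) || length(group) != 1L || !group %in% names(data)) {
    abort("`group` must name a column of `data`")
  }
  if (is.null(features)) {
    num <- vapply(data, is.numeric, logical(1))
    features <- setdiff(names(data)[num], c(group, "sample_id"))
  }
  missing_f <- setdiff(features, names(data))
  if (length(missing_f) > 0L) {
    abort(sprintf("features not in `data`: %s", paste(missing_f, collapse = ", ")))
  }
  X <- as.matrix(data[features])
  if (!is.numeric(X)) abort("feature columns must be numeric")
  y <- data[[group]]
  y <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(sort(y)))
  n <- nrow(X); g <- nlevels(y)
  if (g < 2L) abort("need at least two groups")
  if (n <= g) abort("need more samples than groups")
  counts <- table(y)
  if (any(counts < 2L)) {
    abort(sprintf("every group needs >= 2 members; too small: %s",
                  paste(names(counts)[counts < 2L], collapse = ", ")))
  }
  list(X = X, y = y, features = features, n = n, g = g, counts = c(counts))
}

## within-group and total SSCP matrices over all features at once
sscp_matrices <- function(X, y) {
  means <- rowsum(X, y) / as.vector(table(y))
  Xc <- X - means[as.integer(y), , drop = FALSE]
  W <- crossprod(Xc)
  Tc <- sweep(X, 2L, colMeans(X))
  list(W = W, T = crossprod(Tc), means = means)
}

lambda_from_sscp <- function(W, T_, subset) {
  dW <- det(W[subset, subset, drop = FALSE])
  dT <- det(T_[subset, subset, drop = FALSE])
  if (!is.finite(dT) || dT <= .Machine$double.eps^2) {
    abort("total SSCP matrix is singular on the requested subset")
  }
  dW / dT
}

#' Wilks' lambda of a feature subset
#'
#' `Lambda = det(W) / det(T)`, the ratio of the within-group to the total
#' sum-of-squares-and-cross-products determinant on the chosen features.
#' Values near 0 indicate strong group separation; 1 means none.
#'
#' @param data data frame of features plus a group column.
#' @param group name of the grouping column.
#' @param features character vector of feature columns (default: all numeric
#'   columns except `group` and `sample_id`).
#' @return A single number in `(0, 1]`.
#' @examples
#' d <- data.frame(g = rep(c("A", "B"), each = 2), x = c(0, 1, 10, 11))
#' wilks_lambda(d, "g")  # 1 / 101
#' @export
wilks_lambda <- function(data, group, features = NULL) {
  u <- unpack_labelled(data, group, features)
  s <- sscp_matrices(u$X, u$y)
  lambda_from_sscp(s$W, s$T, u$features)
}

## partial F for adding `candidate` to `in_model` (Lambda_0 = 1)
f_enter_stat <- function(W, T_, n, g, in_model, candidate) {
  p <- length(in_model)
  if (n - g - p <= 0L) {
    abort("insufficient residual degrees of freedom to test entry")
  }
  l_p <- if (p == 0L) 1 else lambda_from_sscp(W, T_, in_model)
  l_p1 <- lambda_from_sscp(W, T_, c(in_model, candidate))
  ((n - g - p) / (g - 1)) * (l_p / l_p1 - 1)
}

## partial F for removing `variable` from `in_model`
f_remove_stat <- function(W, T_, n, g, in_model, variable) {
  rest <- setdiff(in_model, variable)
  p <- length(rest)
  l_rest <- if (p == 0L) 1 else lambda_from_sscp(W, T_, rest)
  l_full <- lambda_from_sscp(W, T_, in_model)
  ((n - g - p) / (g - 1)) * (l_rest / l_full - 1)
}

## tolerance = 1 - R^2 of the candidate's within-group regression on the
## in-model variables (pooled within-group SSCP); collinearity guard
tolerance_stat <- function(W, in_model, candidate) {
  wcc <- W[candidate, candidate]
  if (wcc <= 0) return(0)
  if (length(in_model) == 0L) return(1)
  wmm <- W[in_model, in_model, drop = FALSE]
  wmc <- W[in_model, candidate]
  fit <- tryCatch(solve(wmm, wmc), error = function(e) NULL)
  if (is.null(fit)) return(0)
  max(0, (wcc - sum(wmc * fit)) / wcc)
}

#' F-to-enter of a candidate feature
#'
#' The partial F statistic for adding `candidate` to the variables already
#' in the model:
#' `F = ((n - g - p) / (g - 1)) * (Lambda_p / Lambda_{p+1} - 1)`,
#' where `p` is the current model size and `Lambda_0 = 1`. With an empty
#' model and one candidate this reduces to the one-way ANOVA F.
#'
#' @inheritParams wilks_lambda
#' @param in_model character vector of features already in the model (may be
#'   empty).
#' @param candidate single feature name not in `in_model`.
#' @return A single non-negative number.
#' @examples
#' d <- data.frame(g = rep(c("A", "B"), each = 2), x = c(0, 1, 10, 11))
#' f_to_enter(d, "g", character(), "x")  # 200
#' @export
f_to_enter <- function(data, group, in_model, candidate) {
  if (candidate %in% in_model) abort("`candidate` is already in the model")
  u <- unpack_labelled(data, group, unique(c(in_model, candidate)))
  s <- sscp_matrices(u$X, u$y)
  f_enter_stat(s$W, s$T, u$n, u$g, in_model, candidate)
}

#' Stepwise feature selection for discriminant analysis
#'
#' Forward-stepwise selection with Wilks'-lambda partial F criteria, as in
#' classic stepwise discriminant analysis. At each step the in-model
#' variable with the smallest F-to-remove is removed if that F falls below
#' `f_remove`; otherwise, among candidates whose tolerance (1 - within-group
#' R^2 on the in-model variables) is at least `tolerance_min`, the variable
#' with the largest F-to-enter is entered if that F strictly exceeds
#' `f_enter`. Selection stops when neither rule applies (or after
#' `max_steps`); a revisited model state stops selection with a warning
#' event in the trace.
#'
#' @inheritParams wilks_lambda
#' @param f_enter entry threshold (default 3.84, the 5% chi-square/F
#'   criterion used by classic stepwise discriminant software).
#' @param f_remove removal threshold (default 2.71).
#' @param tolerance_min minimum tolerance for a candidate (default 0.001).
#' @param max_steps step budget (default `4 * p`).
#' @return An object of class `stepwise_lda`: list with `selected` (ordered
#'   feature names) and `trace`, a tibble with one row per event (`step`,
#'   `action`, `variable`, `statistic`, `lambda`, `tolerance`).
#' @examples
#' set.seed(1)
#' d <- data.frame(g = rep(c("w", "d"), each = 40),
#'                 x1 = rnorm(80, rep(c(0, 3), each = 40)),
#'                 x2 = rnorm(80))
#' stepwise_select(d, "g")$selected
#' @export
stepwise_select <- function(data, group, features = NULL, f_enter = 3.84,
                            f_remove = 2.71, tolerance_min = 0.001,
                            max_steps = NULL) {
  u <- unpack_labelled(data, group, features)
  s <- sscp_matrices(u$X, u$y)
  W <- s$W; T_ <- s$T; n <- u$n; g <- u$g
  p_all <- length(u$features)
  max_steps <- max_steps %||% (4L * p_all)
  selected <- character()
  trace <- list()
  seen <- character()
  step <- 0L
  repeat {
    if (step >= max_steps) break
    state <- paste(sort(selected), collapse = "|")
    if (state %in% seen) {
      warn("stepwise selection revisited a model state; stopping")
      trace[[length(trace) + 1L]] <- tibble(
        step = step, action = "warning", variable = NA_character_,
        statistic = NA_real_, lambda = NA_real_, tolerance = NA_real_)
      break
    }
    seen <- c(seen, state)
    step <- step + 1L
    ## (a) removal first
    if (length(selected) > 0L) {
      f_rem <- vapply(selected, function(v)
        f_remove_stat(W, T_, n, g, selected, v), numeric(1))
      worst <- which.min(f_rem)
      if (f_rem[worst] < f_remove) {
        victim <- selected[worst]
        selected <- setdiff(selected, victim)
        trace[[length(trace) + 1L]] <- tibble(
          step = step, action = "remove", variable = victim,
          statistic = f_rem[worst],
          lambda = if (length(selected) == 0L) 1
                   else lambda_from_sscp(W, T_, selected),
          tolerance = NA_real_)
        next
      }
    }
    ## (b) entry
    candidates <- setdiff(u$features, selected)
    if (length(candidates) == 0L || n - g - length(selected) <= 0L) break
    tol <- vapply(candidates, function(v)
      tolerance_stat(W, selected, v), numeric(1))
    ok <- tol >= tolerance_min
    if (!any(ok)) break
    fe <- rep(-Inf, length(candidates))
    fe[ok] <- vapply(candidates[ok], function(v)
      f_enter_stat(W, T_, n, g, selected, v), numeric(1))
    best <- which.max(fe)
    if (!(fe[best] > f_enter)) break
    entered <- candidates[best]
    selected <- c(selected, entered)
    trace[[length(trace) + 1L]] <- tibble(
      step = step, action = "enter", variable = entered,
      statistic = fe[best], lambda = lambda_from_sscp(W, T_, selected),
      tolerance = tol[best])
  }
  structure(list(selected = selected,
                 trace = if (length(trace) > 0L) dplyr::bind_rows(trace)
                         else tibble(step = integer(), action = character(),
                                     variable = character(),
                                     statistic = numeric(), lambda = numeric(),
                                     tolerance = numeric()),
                 f_enter = f_enter, f_remove = f_remove,
                 tolerance_min = tolerance_min),
            class = "stepwise_lda")
}

#' @export
print.stepwise_lda <- function(x, ...) {
  cat(sprintf("<stepwise_lda> %d features selected (F-enter > %g, F-remove < %g)\n",
              length(x$selected), x$f_enter, x$f_remove))
  if (length(x$selected) > 0L) {
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname stepwise_select
#' @param x a `stepwise_lda` object.
#' @param ... unused.
#' @export
tidy.stepwise_lda <- function(x, ...) x$trace

#' @rdname stepwise_select
#' @export
glance.stepwise_lda <- function(x, ...) {
  tibble(n_selected = length(x$selected),
         n_steps = if (nrow(x$trace) > 0L) max(x$trace$step) else 0L,
         final_lambda = if (nrow(x$trace) > 0L)
           x$trace$lambda[max(which(!is.na(x$trace$lambda)))] else NA_real_)
}
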