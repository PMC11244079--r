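resolve_priors <- function(priors, counts, g, groups) {
  if (identical(priors, "equal")) return(rep(1 / g, g))
  if (identical(priors, "proportional")) return(counts / sum(counts))
  if (is.numeric(priors) && length(priors) == g) {
    if (any(priors <= 0)) abort("priors must be positive")
    return(priors / sum(priors))
  }
  abort("`priors` must be \"equal\", \"proportional\", or one value per group")
}

#' Fit linear discriminant classification functions
#'
#' Estimates group means and the pooled within-class covariance `W` on the
#' selected features and derives one linear classification function per
#' group:
#' `C_j(x) = mu_j' W^-1 x - 1/2 mu_j' W^-1 mu_j + log pi_j`.
#' A sample is assigned to the group with the largest `C_j`. This is the
#' Gaussian equal-covariance discriminant rule; with equal priors it is the
#' minimum-Mahalanobis-distance classifier.
#'
#' @inheritParams wilks_lambda
#' @param priors `"equal"` (default), `"proportional"` to group sizes, or a
#'   numeric vector of prior probabilities (one per group, normalised).
#' @return An object of class `pip_lda`: list with `features`, `groups`,
#'   `counts`, `means`, `pooled_cov`, `priors`, `coef` (features x groups)
#'   and `const`.
#' @examples
#' d <- data.frame(g = rep(c("A", "B"), each = 10),
#'                 x = c(rnorm(10, -2), rnorm(10, 2)))
#' fit <- fit_lda(d, "g")
#' classify(fit, data.frame(x = c(-1.5, 1.5)))$.class
#' @export
fit_lda <- function(data, group, features = NULL, priors = "equal") {
  u <- unpack_labelled(data, group, features)
  s <- sscp_matrices(u$X, u$y)
  pooled <- s$W / (u$n - u$g)
  ## condition assessed on the correlation matrix so that per-feature
  ## rescaling (which must not change the classifier) cannot trip the check
  kap <- kappa(stats::cov2cor(pooled), exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    abort(paste("pooled within-class covariance is numerically singular;",
                "use fewer features or more samples per group"))
  }
  pr <- resolve_priors(priors, u$counts, u$g, levels(u$y))
  winv <- solve(pooled)
  coef <- winv %*% t(s$means)                    # p x g
  const <- -0.5 * colSums(t(s$means) * coef) + log(pr)
  structure(
    list(features = u$features, groups = levels(u$y), counts = u$counts,
         means = s$means, pooled_cov = pooled, priors = pr,
         coef = coef, const = const, n = u$n),
    class = "pip_lda"
  )
}

#' @export
print.pip_lda <- function(x, ...) {
  cat(sprintf("<pip_lda> %d groups, %d features, n = %d\n",
              length(x$groups), length(x$features), x$n))
  invisible(x)
}

#' @rdname fit_lda
#' @param x a `pip_lda` object.
#' @param ... unused.
#' @export
tidy.pip_lda <- function(x, ...) {
  co <- rbind(x$coef, constant = x$const)
  as_tibble(co, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "group", values_to = "estimate")
}

#' @rdname fit_lda
#' @export
glance.pip_lda <- function(x, ...) {
  tibble(n = x$n, n_groups = length(x$groups),
         n_features = length(x$features))
}

#' Classify samples with a fitted discriminant model
#'
#' Evaluates the classification functions on new samples and assigns each to
#' the group with the largest score, with ties broken deterministically in
#' favour of the lowest group index. Posterior probabilities are the
#' softmax of the classification-function scores, which equals the Bayes
#' posterior under the shared-covariance Gaussian model. Samples with
#' missing or non-finite feature values are not classified; they are
#' returned with `.class = NA` and an `.error` message, and a warning
#' reports how many were excluded.
#'
#' @param model a `pip_lda` object.
#' @param newdata data frame containing the model's feature columns.
#' @param keep_scores if `TRUE`, append per-group score and posterior
#'   columns.
#' @return A tibble with one row per sample: `sample_id` (if present in
#'   `newdata`), `.class`, `.posterior` (posterior of the assigned class)
#'   and `.error`.
#' @export
classify <- function(model, newdata, keep_scores = FALSE) {
  if (!inherits(model, "pip_lda")) abort("`model` must be a `pip_lda` object")
  missing_f <- setdiff(model$features, names(newdata))
  if (length(missing_f) > 0L) {
    abort(sprintf("newdata lacks model features: %s",
                  paste(missing_f, collapse = ", ")))
  }
  X <- as.matrix(newdata[model$features])
  ok <- apply(is.finite(X), 1L, all)
  n <- nrow(X); g <- length(model$groups)
  scores <- matrix(NA_real_, n, g, dimnames = list(NULL, model$groups))
  if (any(ok)) {
    scores[ok, ] <- sweep(X[ok, , drop = FALSE] %*% model$coef, 2L,
                          model$const, `+`)
  }
  cls <- rep(NA_character_, n)
  postmax <- rep(NA_real_, n)
  post <- matrix(NA_real_, n, g, dimnames = list(NULL, model$groups))
  if (any(ok)) {
    idx <- max.col(scores[ok, , drop = FALSE], ties.method = "first")
    cls[ok] <- model$groups[idx]
    sh <- scores[ok, , drop = FALSE]
    sh <- exp(sh - apply(sh, 1L, max))
    post[ok, ] <- sh / rowSums(sh)
    postmax[ok] <- post[ok, , drop = FALSE][cbind(seq_len(sum(ok)), idx)]
  }
  if (any(!ok)) {
    warn(sprintf("%d sample(s) with non-finite features were not classified",
                 sum(!ok)))
  }
  out <- tibble(
    .class = factor(cls, levels = model$groups),
    .posterior = postmax,
    .error = ifelse(ok, NA_character_, "non-finite feature values")
  )
  if ("sample_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble(sample_id = newdata$sample_id), out)
  }
  if (keep_scores) {
    colnames(scores) <- paste0("score_", model$groups)
    colnames(post) <- paste0("posterior_", model$groups)
    out <- dplyr::bind_cols(out, as_tibble(scores), as_tibble(post))
  }
  out
}

#' Leave-one-out cross-validation of a discriminant model
#'
#' Classifies every case with classification functions recomputed from all
#' data except that case: group means and the pooled within-class covariance
#' are downdated per case (a rank-one Sherman-Morrison update of the inverse
#' scatter, exactly equivalent to refitting from scratch), while the feature
#' set is held fixed. Reports overall accuracy and the true-by-assigned
#' confusion matrix.
#'
#' @inheritParams fit_lda
#' @return An object of class `pip_loocv`: list with `accuracy`,
#'   `confusion` (tibble of `true`, `assigned`, `n`) and `predictions`.
#' @examples
#' d <- data.frame(g = rep(c("A", "B"), each = 20),
#'                 x = c(rnorm(20, -3), rnorm(20, 3)))
#' loocv(d, "g")$accuracy
#' @export
loocv <- function(data, group, features = NULL, priors = "equal") {
  u <- unpack_labelled(data, group, features)
  if (any(u$counts < 3L)) {
    abort(sprintf("every group needs >= 3 members so each retains 2 after deletion; too small: %s",
                  paste(names(u$counts)[u$counts < 3L], collapse = ", ")))
  }
  s <- sscp_matrices(u$X, u$y)
  X <- u$X; y <- u$y; n <- u$n; g <- u$g
  counts <- u$counts
  A <- tryCatch(solve(s$W), error = function(e)
    abort("pooled within-group scatter is singular; use fewer features"))
  logpr_equal <- identical(priors, "equal")
  base_pr <- resolve_priors(priors, counts, g, levels(y))
  yi <- as.integer(y)
  Xc <- X - s$means[yi, , drop = FALSE]
  pred <- character(n)
  for (i in seq_len(n)) {
    gi <- yi[i]
    ng <- counts[gi]
    cc <- ng / (ng - 1)
    ui <- Xc[i, ]
    v <- A %*% ui
    denom <- 1 - cc * sum(ui * v)
    if (denom <= 1e-12) {
      abort(sprintf("deleting case %d ('%s') makes the pooled scatter singular",
                    i, if (!is.null(rownames(X))) rownames(X)[i] else as.character(i)))
    }
    Ai <- A + (cc / denom) * tcrossprod(v)
    siginv <- (n - 1 - g) * Ai
    M <- s$means
    M[gi, ] <- (ng * M[gi, ] - X[i, ]) / (ng - 1)
    pr <- if (logpr_equal) base_pr else {
      cts <- counts; cts[gi] <- cts[gi] - 1L
      resolve_priors(priors, cts, g, levels(y))
    }
    B <- M %*% siginv                       # g x p
    sc <- B %*% X[i, ] - 0.5 * rowSums(B * M) + log(pr)
    pred[i] <- levels(y)[which.max(sc)]
  }
  predictions <- tibble(
    sample_id = if ("sample_id" %in% names(data)) data$sample_id
                else as.character(seq_len(n)),
    true = as.character(y),
    assigned = pred
  )
  confusion <- dplyr::count(predictions, .data$true, .data$assigned, name = "n")
  structure(
    list(accuracy = mean(pred == as.character(y)),
         confusion = confusion, predictions = predictions,
         n = n, groups = levels(y)),
    class = "pip_loocv"
  )
}

#' @export
print.pip_loocv <- function(x, ...) {
  cat(sprintf("<pip_loocv> accuracy %.3f over %d cases, %d groups\n",
              x$accuracy, x$n, length(x$groups)))
  invisible(x)
}

#' @rdname loocv
#' @param x a `pip_loocv` object.
#' @param ... unused.
#' @export
tidy.pip_loocv <- function(x, ...) x$confusion

#' @rdname loocv
#' @export
glance.pip_loocv <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n, n_groups = length(x$groups))
}
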