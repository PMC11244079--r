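test_that("wilks_lambda matches hand arithmetic and the MANOVA oracle", {
  d <- data.frame(g = rep(c("A", "B"), each = 2), x = c(0, 1, 10, 11))
  expect_equal(wilks_lambda(d, "g"), 1 / 101, tolerance = 1e-12)

  ## equal group means -> W = T -> lambda 1
  d2 <- data.frame(g = rep(c("A", "B"), each = 3), x = c(1, 2, 3, 3, 2, 1))
  expect_equal(wilks_lambda(d2, "g"), 1, tolerance = 1e-12)

  set.seed(5)
  d3 <- data.frame(g = sample(c("A", "B", "C"), 45, replace = TRUE),
                   x1 = rnorm(45), x2 = rnorm(45), x3 = rnorm(45))
  d3$x1 <- d3$x1 + 2 * (d3$g == "B")
  for (sub in list("x1", c("x1", "x2"), c("x1", "x2", "x3"))) {
    expect_equal(wilks_lambda(d3, "g", sub),
                 wilks_manova_oracle(d3, "g", sub), tolerance = 1e-10)
  }
})

test_that("F-to-enter reduces to the one-way ANOVA F for a first variable", {
  d <- data.frame(g = rep(c("A", "B"), each = 2), x = c(0, 1, 10, 11))
  expect_equal(f_to_enter(d, "g", character(), "x"), 200, tolerance = 1e-10)
  set.seed(9)
  d2 <- data.frame(g = rep(c("A", "B", "C"), each = 10), x = rnorm(30))
  f_aov <- summary(stats::aov(x ~ g, data = d2))[[1]]$`F value`[1]
  expect_equal(f_to_enter(d2, "g", character(), "x"), f_aov,
               tolerance = 1e-10)
  expect_error(f_to_enter(d, "g", "x", "x"), "already in the model")
})

test_that("null-simulation entry rate matches the F(1, n-2) tail", {
  set.seed(123)
  n1 <- 50; n2 <- 50; reps <- 2000
  X <- matrix(rnorm((n1 + n2) * reps), n1 + n2, reps)
  m1 <- colMeans(X[1:n1, ]); m2 <- colMeans(X[(n1 + 1):(n1 + n2), ])
  ss <- colSums((X[1:n1, ] - rep(m1, each = n1))^2) +
    colSums((X[(n1 + 1):(n1 + n2), ] - rep(m2, each = n2))^2)
  f <- (m1 - m2)^2 / ((ss / (n1 + n2 - 2)) * (1 / n1 + 1 / n2))
  expect_lt(abs(mean(f > 3.84) - (1 - pf(3.84, 1, n1 + n2 - 2))), 0.01)
  ## spot-check the package statistic against the same formula
  d <- data.frame(g = rep(c("A", "B"), c(n1, n2)), x = X[, 1])
  expect_equal(f_to_enter(d, "g", character(), "x"), f[1], tolerance = 1e-10)
})

test_that("stepwise selection enters the discriminating variable first", {
  set.seed(2)
  n <- 100
  d <- data.frame(g = rep(c("w", "d"), each = n),
                  x1 = rnorm(2 * n, rep(c(0, 5), each = n)),
                  x2 = rnorm(2 * n), x3 = rnorm(2 * n),
                  x4 = rnorm(2 * n), x5 = rnorm(2 * n))
  sel <- stepwise_select(d, "g")
  expect_identical(sel$trace$variable[1], "x1")
  expect_identical(sel$trace$action[1], "enter")
  expect_true(all(diff(c(1, sel$trace$lambda[sel$trace$action == "enter"])) <= 1e-12))
})

test_that("nothing is selected when no variable can pass the entry bar", {
  set.seed(3)
  d <- data.frame(g = rep(c("A", "B"), each = 20),
                  x1 = rnorm(40), x2 = rnorm(40))
  sel <- stepwise_select(d, "g", f_enter = Inf)
  expect_length(sel$selected, 0L)
  expect_identical(nrow(sel$trace), 0L)
})

test_that("a perfectly collinear candidate is excluded by the tolerance rule", {
  set.seed(4)
  d <- data.frame(g = rep(c("A", "B"), each = 25),
                  x1 = rnorm(50, rep(c(0, 3), each = 25)))
  d$x2 <- 2 * d$x1
  sel <- stepwise_select(d, "g")
  expect_length(sel$selected, 1L)
})

test_that("every stepwise entry is the argmax of exhaustively recomputed F values", {
  set.seed(6)
  for (rep in 1:3) {
    g <- sample(c("A", "B", "C"), 60, replace = TRUE)
    X <- matrix(rnorm(60 * 6), 60)
    X[, 1] <- X[, 1] + 1.5 * (g == "B")
    X[, 3] <- X[, 3] + 1.2 * (g == "C")
    d <- as.data.frame(X); names(d) <- paste0("x", 1:6); d$g <- g
    sel <- stepwise_select(d, "g")
    in_model <- character()
    for (i in seq_len(nrow(sel$trace))) {
      ev <- sel$trace[i, ]
      if (ev$action == "enter") {
        cand <- setdiff(paste0("x", 1:6), in_model)
        fs <- vapply(cand, function(v) f_to_enter(d, "g", in_model, v),
                     numeric(1))
        expect_identical(ev$variable, cand[which.max(fs)])
        expect_equal(ev$statistic, max(fs), tolerance = 1e-10)
        expect_gt(ev$statistic, 3.84)
        in_model <- c(in_model, ev$variable)
      } else if (ev$action == "remove") {
        in_model <- setdiff(in_model, ev$variable)
      }
    }
    expect_setequal(sel$selected, in_model)
  }
})

test_that("classification functions implement the Gaussian Bayes rule", {
  set.seed(8)
  d <- gaussian_two_class(40, 3)
  fit <- fit_lda(d, "g")
  ## posterior equals a direct pooled-covariance Gaussian-density Bayes rule
  X <- as.matrix(d[fit$features])
  y <- factor(d$g)
  means <- rowsum(X, y) / as.vector(table(y))
  Xc <- X - means[as.integer(y), ]
  pooled <- crossprod(Xc) / (nrow(X) - 2)
  pred <- classify(fit, d, keep_scores = TRUE)
  dens <- sapply(1:2, function(j)
    -0.5 * stats::mahalanobis(X, means[j, ], pooled))
  post_direct <- exp(dens) / rowSums(exp(dens))
  expect_lt(max(abs(pred$posterior_A - post_direct[, 1])), 1e-10)
  ## group means classify to their own group
  centers <- as.data.frame(means)
  expect_identical(as.character(classify(fit, centers)$.class), c("A", "B"))
})

test_that("the 1-D decision boundary sits at zero for symmetric classes", {
  d <- data.frame(g = rep(c("A", "B"), each = 4),
                  x = c(-1, -2, -3, -4, 1, 2, 3, 4))
  fit <- fit_lda(d, "g")
  eps <- 1e-6
  expect_identical(as.character(classify(fit, data.frame(x = -eps))$.class), "A")
  expect_identical(as.character(classify(fit, data.frame(x = eps))$.class), "B")
  ## exact tie goes to the lowest group index
  expect_identical(as.character(classify(fit, data.frame(x = 0))$.class), "A")
})

test_that("classification agrees with brute-force Mahalanobis assignment", {
  set.seed(10)
  train <- gaussian_two_class(60, 2.5)
  fit <- fit_lda(train, "g")
  new <- gaussian_two_class(100, 2.5)
  expect_identical(as.character(classify(fit, new)$.class),
                   mahalanobis_classifier(train, "g",
                                          paste0("x", 1:6), new))
})

test_that("classification agrees with an independent reference implementation", {
  set.seed(12)
  d <- gaussian_two_class(50, 2)
  fit <- fit_lda(d, "g")
  ref <- MASS::lda(as.matrix(d[paste0("x", 1:6)]), grouping = d$g,
                   prior = c(0.5, 0.5))
  ref_pred <- stats::predict(ref, as.matrix(d[paste0("x", 1:6)]))
  mine <- classify(fit, d, keep_scores = TRUE)
  expect_identical(as.character(mine$.class), as.character(ref_pred$class))
  expect_lt(max(abs(mine$posterior_A - ref_pred$posterior[, "A"])), 1e-8)
})

test_that("samples with non-finite features are excluded with a record", {
  set.seed(14)
  d <- gaussian_two_class(30, 3)
  fit <- fit_lda(d, "g")
  bad <- d[1:3, ]; bad$x1[2] <- NA
  expect_warning(out <- classify(fit, bad), "non-finite")
  expect_true(is.na(out$.class[2]))
  expect_identical(out$.error[2], "non-finite feature values")
  expect_false(anyNA(out$.class[c(1, 3)]))
})

test_that("fast LOOCV equals a naive from-scratch refit loop", {
  set.seed(16)
  d <- gaussian_two_class(30, 1.5, p = 4, k = 2)  # n = 60
  cv <- loocv(d, "g")
  expect_identical(cv$predictions$assigned, naive_loocv(d, "g", paste0("x", 1:4)))
  expect_equal(cv$accuracy, mean(cv$predictions$assigned == d$g))
  ## three-group case too
  set.seed(17)
  d3 <- data.frame(g = rep(c("A", "B", "C"), each = 20),
                   x1 = rnorm(60, rep(c(0, 2, 4), each = 20)),
                   x2 = rnorm(60))
  cv3 <- loocv(d3, "g")
  expect_identical(cv3$predictions$assigned,
                   naive_loocv(d3, "g", c("x1", "x2")))
})

test_that("LOOCV is perfect for well-separated classes and near Bayes otherwise", {
  set.seed(18)
  far <- gaussian_two_class(20, 100)
  expect_equal(loocv(far, "g")$accuracy, 1)
  mid <- gaussian_two_class(400, 2)
  expect_equal(loocv(mid, "g")$accuracy, pnorm(1), tolerance = 0.03)
})

test_that("rescaling a feature changes neither F statistics nor assignments", {
  set.seed(20)
  d <- gaussian_two_class(40, 2)
  sel1 <- stepwise_select(d, "g")
  d2 <- dplyr::mutate(d, x1 = 1000 * x1, x3 = 1e-4 * x3)
  sel2 <- stepwise_select(d2, "g")
  expect_identical(sel1$trace$variable, sel2$trace$variable)
  expect_equal(sel1$trace$statistic, sel2$trace$statistic, tolerance = 1e-8)
  fit1 <- fit_lda(d, "g", sel1$selected)
  fit2 <- fit_lda(d2, "g", sel2$selected)
  expect_identical(as.character(classify(fit1, d)$.class),
                   as.character(classify(fit2, d2)$.class))
})

test_that("LOOCV accuracy does not beat resubstitution on average", {
  set.seed(22)
  diff_acc <- replicate(50, {
    d <- gaussian_two_class(20, 1.5, p = 4, k = 2)
    fit <- fit_lda(d, "g")
    resub <- mean(as.character(classify(fit, d)$.class) == d$g)
    resub - loocv(d, "g")$accuracy
  })
  expect_gte(mean(diff_acc), 0)
})

test_that("degenerate fits are rejected with informative errors", {
  d <- data.frame(g = rep(c("A", "B"), each = 3), x1 = rnorm(6))
  d$x2 <- d$x1  # singular pooled covariance
  expect_error(fit_lda(d, "g"), "singular")
  expect_error(loocv(data.frame(g = rep(c("A", "B"), c(2, 10)),
                                x = rnorm(12)), "g"), ">= 3 members")
})
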