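# two columns with an exactly controlled sample correlation
corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  u <- rnorm(n); v <- rnorm(n)
  u <- as.numeric(scale(u))
  v <- resid(lm(v ~ u))
  v <- as.numeric(scale(v))
  tibble::tibble(a = u, b = r * u + sqrt(1 - r^2) * v)
}

test_that("correlation filter removes exactly the later column above 0.85", {
  d90 <- corr_pair(200, 0.90)
  expect_equal(unname(abs(cor(d90$a, d90$b))), 0.90, tolerance = 1e-10)
  p90 <- preprocess(d90)
  expect_identical(names(p90), "a")
  expect_identical(attr(p90, "dropped"), "b")

  d80 <- corr_pair(200, 0.80)
  p80 <- preprocess(d80)
  expect_identical(names(p80), c("a", "b"))
})

test_that("preprocessing standardizes, is idempotent, and flags degeneracy", {
  d <- tibble::tibble(x = rnorm(50, 100, 20), y = runif(50))
  p <- preprocess(d)
  expect_equal(unname(colMeans(as.matrix(p))), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(p), 2, sd)), c(1, 1), tolerance = 1e-12)
  p2 <- preprocess(tibble::as_tibble(as.data.frame(p)))
  expect_equal(as.matrix(p2), as.matrix(p), tolerance = 1e-9)

  expect_warning(preprocess(tibble::tibble(x = rnorm(20), z = rep(3, 20))),
                 "zero-variance")
  expect_error(preprocess(d[1, ]), "at least 2")
  # missing values imputed with the column maximum
  d$x[3] <- NA
  pim <- preprocess(d)
  expect_no_na(as.matrix(pim))
})

test_that("LOO-CV separates a separable cohort and not a permuted one", {
  set.seed(11)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- tibble::tibble(
    f1 = rnorm(n, mean = 3 * y), f2 = rnorm(n, mean = -2.5 * y),
    f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n)
  )
  for (sel in c("univariate", "l1", "rfe")) {
    cv <- suppressWarnings(loo_cv(x, y, selector = sel, n_select = 3))
    expect_gte(cv$auc, 0.95)
    expect_equal(nrow(cv$scores), n)
  }
  y_perm <- sample(y)
  cv0 <- suppressWarnings(loo_cv(x, y_perm, n_select = 3))
  expect_gt(cv0$auc, 0.35)
  expect_lt(cv0$auc, 0.65)
  expect_error(loo_cv(x, rep(1, n)), "single class")
})

test_that("held-out scores are honest and scale invariant", {
  set.seed(12)
  n <- 40
  y <- rbinom(n, 1, 0.5)
  x <- tibble::tibble(f1 = rnorm(n, y), f2 = rnorm(n), f3 = rnorm(n))
  cv <- suppressWarnings(loo_cv(x, y, n_select = 2))
  # corrupting the held-out label never changes its own score
  y2 <- y; y2[7] <- 1 - y2[7]
  cv2 <- suppressWarnings(loo_cv(x, y2, n_select = 2))
  expect_equal(cv$scores$score[7], cv2$scores$score[7], tolerance = 1e-12)
  # rescaling a raw column is absorbed by normalization
  x3 <- x; x3$f1 <- x$f1 * 1000
  cv3 <- suppressWarnings(loo_cv(x3, y, n_select = 2))
  expect_equal(cv$scores$score, cv3$scores$score, tolerance = 1e-8)
})

test_that("final model recovers generating coefficients within 3 SE", {
  set.seed(21)
  n <- 500
  beta <- c(f1 = 0.8, f2 = -0.6, f3 = 0.4, f4 = 0, f5 = -0.3, f6 = 0.5,
            f7 = -0.2)
  X <- matrix(rnorm(n * 7), n, dimnames = list(NULL, names(beta)))
  y <- rbinom(n, 1, plogis(X %*% beta))
  d <- tibble::as_tibble(X)
  model <- train_final(d, y, features = names(beta))
  expect_length(model$coefficients, 7)
  # SEs from the same maximum-likelihood fit
  g <- glm(y ~ ., data = cbind(as.data.frame(scale(X)), y = y),
           family = binomial())
  se <- summary(g)$coefficients[names(beta), "Std. Error"]
  expect_true(all(abs(model$coefficients - beta) <= 3 * se))
  # duplicating every row leaves the MLE unchanged
  model2 <- train_final(dplyr::bind_rows(d, d), c(y, y), features = names(beta))
  expect_equal(model2$coefficients, model$coefficients, tolerance = 1e-3)
  expect_error(train_final(d, y, features = c("f1", "nope")), "nope")
})

test_that("consistency: coefficient bias shrinks as the cohort grows", {
  beta <- c(lvef = -0.4, bmi = -0.3, edd = -0.4, scar_lvps = 0.6,
            tat95_lbbb = 0.5, ad_rvlv_lbbb = 0.7, ad_rvlv_biv = -0.6)
  bias_at <- function(n) {
    reps <- vapply(1:3, function(r) {
      co <- sample_cohort(cohort_spec(n = n, seed = 100 * r))
      ds <- make_dataset(co)
      m <- suppressWarnings(train_final(ds$features, ds$labels))
      mean(abs(m$coefficients - beta))
    }, numeric(1))
    mean(reps)
  }
  b <- vapply(c(100, 300, 1000), bias_at, numeric(1))
  expect_lt(b[3], b[1])
})

test_that("ML-score is a calibrated monotone logistic probability", {
  set.seed(5)
  d <- tibble::tibble(f1 = rnorm(60), f2 = rnorm(60))
  y <- rbinom(60, 1, plogis(d$f1))
  model <- suppressWarnings(train_final(d, y, features = c("f1", "f2")))
  # record at the training means has linear predictor = intercept
  rec <- list(f1 = model$center[["f1"]], f2 = model$center[["f2"]])
  expect_equal(ml_score(model, rec), plogis(model$intercept), tolerance = 1e-12)
  zero_model <- model; zero_model$intercept <- 0
  zero_model$coefficients[] <- 0
  expect_equal(ml_score(zero_model, rec), 0.5)
  # monotone in a positively weighted feature
  stopifnot(model$coefficients[["f1"]] > 0)
  s1 <- ml_score(model, list(f1 = 0, f2 = 0))
  s2 <- ml_score(model, list(f1 = 1, f2 = 0))
  expect_gt(s2, s1)
  expect_error(ml_score(model, list(f1 = 1)), "f2")
  # cutoff classification
  expect_equal(model$cutoff, 0.51)
  nd <- tibble::tibble(f1 = c(-10, 10), f2 = 0)
  cls <- predict(model, nd, type = "class")
  expect_identical(cls, c(0L, 1L))
})

test_that("ROC AUC follows the Mann-Whitney convention and matches pROC", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), y), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), y), 0)
  expect_equal(roc_auc(rep(0.5, 4), y), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(9)
  s <- runif(100); yy <- rbinom(100, 1, 0.4)
  ref <- as.numeric(suppressMessages(pROC::auc(yy, s, direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(s, yy), ref, tolerance = 1e-12)
})
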