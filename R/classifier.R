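#' Preprocess a hybrid clinical + simulated feature table
#'
#' Standard preprocessing for the response classifier: missing values are
#' imputed with the column maximum (the farthest-from-scar convention for the
#' scar-distance feature, never a silent zero), zero-variance columns are
#' dropped with a warning, one member of every highly correlated pair
#' (|Pearson r| above the threshold) is removed — deterministically the
#' later-listed column — and non-categorical columns are centered and scaled
#' to unit variance.
#'
#' @param x data frame / tibble of features (rows = patients).
#' @param cor_threshold absolute-correlation removal threshold (default 0.85;
#'   pairs strictly above it lose their later column).
#' @param categorical character vector of columns excluded from scaling.
#' @return standardized tibble of class `crt_features`; attributes `center`,
#'   `scale`, `impute`, `dropped` record the fitted transform.
#' @export
preprocess <- function(x, cor_threshold = 0.85, categorical = character()) {
  x <- tibble::as_tibble(x)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  num_cols <- setdiff(names(x), categorical)

  impute <- vapply(x[num_cols], function(col) {
    if (anyNA(col)) max(col, na.rm = TRUE) else NA_real_
  }, numeric(1))
  for (cn in num_cols[!is.na(impute)]) {
    x[[cn]][is.na(x[[cn]])] <- impute[[cn]]
  }

  sds <- vapply(x[num_cols], sd, numeric(1))
  zv <- num_cols[sds < 1e-12 | !is.finite(sds)]
  if (length(zv)) {
    warning("removing zero-variance columns: ", paste(zv, collapse = ", "),
            call. = FALSE)
    x <- x[setdiff(names(x), zv)]
    num_cols <- setdiff(num_cols, zv)
  }

  dropped <- character()
  retained <- character()
  for (cn in num_cols) {
    r <- if (length(retained)) {
      suppressWarnings(abs(cor(x[[cn]], as.matrix(x[retained]))))
    } else numeric()
    if (length(r) && any(r > cor_threshold, na.rm = TRUE)) {
      dropped <- c(dropped, cn)
    } else {
      retained <- c(retained, cn)
    }
  }
  x <- x[setdiff(names(x), dropped)]
  num_cols <- retained
  if (!length(names(x))) stop("all columns removed by preprocessing", call. = FALSE)

  center <- vapply(x[num_cols], mean, numeric(1))
  scale_ <- vapply(x[num_cols], sd, numeric(1))
  for (cn in num_cols) x[[cn]] <- (x[[cn]] - center[[cn]]) / scale_[[cn]]

  structure(x, class = c("crt_features", class(x)),
            center = center, scale = scale_, impute = impute,
            dropped = c(zv, dropped), categorical = categorical)
}

apply_preprocess <- function(fitted, newdata) {
  center <- attr(fitted, "center"); scale_ <- attr(fitted, "scale")
  impute <- attr(fitted, "impute")
  out <- tibble::as_tibble(newdata)[names(fitted)]
  for (cn in names(center)) {
    v <- out[[cn]]
    if (anyNA(v) && !is.na(impute[[cn]])) v[is.na(v)] <- impute[[cn]]
    out[[cn]] <- (v - center[[cn]]) / scale_[[cn]]
  }
  out
}

fit_logistic <- function(X, y, ridge_fallback = TRUE) {
  df <- as.data.frame(X)
  df$.y <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- coef(fit)
  if (ridge_fallback && (sep || any(abs(co[-1]) > 20, na.rm = TRUE))) {
    warning("perfect separation detected; refitting with weak ridge penalty",
            call. = FALSE)
    co_ridge <- if (ncol(X) >= 2 && min(table(y)) >= 2) {
      tryCatch({
        g <- glmnet::glmnet(as.matrix(X), y, family = "binomial", alpha = 0,
                            lambda = 0.05, standardize = FALSE)
        cg <- c(as.numeric(g$a0), as.numeric(g$beta))
        names(cg) <- c("(Intercept)", colnames(X))
        cg
      }, error = function(e) NULL)
    } else NULL
    # degenerate designs (tiny n, one class nearly absent): bound the drift
    co <- if (is.null(co_ridge)) pmin(pmax(co, -20), 20) else co_ridge
  }
  co[is.na(co)] <- 0
  co
}

select_univariate <- function(X, y, n_select) {
  stat <- vapply(as.data.frame(X), function(col) {
    s <- tryCatch(abs(stats::t.test(col[y == 1], col[y == 0])$statistic),
                  error = function(e) 0)
    as.numeric(s)
  }, numeric(1))
  names(sort(stat, decreasing = TRUE))[seq_len(min(n_select, ncol(X)))]
}

select_l1 <- function(X, y, n_select) {
  g <- glmnet::glmnet(as.matrix(X), y, family = "binomial", alpha = 1,
                      standardize = FALSE, nlambda = 100)
  entry <- apply(as.matrix(g$beta) != 0, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else Inf
  })
  ord <- names(sort(entry))
  picked <- ord[seq_len(min(n_select, sum(is.finite(entry))))]
  if (length(picked) < n_select) {
    extra <- setdiff(select_univariate(X, y, ncol(X)), picked)
    picked <- c(picked, extra[seq_len(n_select - length(picked))])
  }
  picked
}

select_rfe <- function(X, y, n_select) {
  keep <- colnames(X)
  while (length(keep) > n_select) {
    co <- fit_logistic(X[, keep, drop = FALSE], y, ridge_fallback = TRUE)
    co <- co[setdiff(names(co), "(Intercept)")]
    keep <- setdiff(keep, names(which.min(abs(co))))
  }
  keep
}

#' Leave-one-out cross-validated response classifier
#'
#' For every patient, preprocessing statistics, feature selection and the
#' logistic fit are recomputed on the remaining patients only; the held-out
#' patient is then scored with the frozen transform, so no information leaks
#' from the held-out row. Feature selection runs inside the loop with one of
#' three selectors: univariate ranking, the L1-regularization entry order, or
#' recursive elimination of the weakest coefficient.
#'
#' @param x raw feature table (rows = patients).
#' @param labels binary response labels (0/1 or logical).
#' @param selector feature-selection method.
#' @param n_select number of features selected per fold (default 7).
#' @param cutoff classification cutoff on the ML-score (default 0.51).
#' @param cor_threshold passed to [preprocess()].
#' @return object of class `crt_cv`: held-out `scores` tibble, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `selection_freq`.
#' @export
loo_cv <- function(x, labels, selector = c("univariate", "l1", "rfe"),
                   n_select = 7, cutoff = 0.51, cor_threshold = 0.85) {
  selector <- match.arg(selector)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class", call. = FALSE)
  x <- tibble::as_tibble(x)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  sel_fun <- switch(selector, univariate = select_univariate,
                    l1 = select_l1, rfe = select_rfe)
  scores <- numeric(n)
  sel_count <- integer(0)
  for (i in seq_len(n)) {
    tr <- suppressWarnings(preprocess(x[-i, ], cor_threshold = cor_threshold))
    ytr <- labels[-i]
    Xtr <- as.matrix(tr)
    feats <- sel_fun(Xtr, ytr, n_select)
    co <- suppressWarnings(fit_logistic(Xtr[, feats, drop = FALSE], ytr))
    te <- apply_preprocess(tr, x[i, ])
    eta <- co[["(Intercept)"]] +
      sum(co[feats] * as.numeric(te[1, feats]), na.rm = TRUE)
    scores[i] <- plogis(eta)
    for (f in feats) sel_count[f] <- (if (is.na(sel_count[f])) 0L else sel_count[f]) + 1L
  }
  pred <- as.integer(scores > cutoff)
  structure(list(
    scores = tibble::tibble(patient = seq_len(n), score = scores,
                            label = labels, predicted = pred),
    auc = roc_auc(scores, labels),
    accuracy = mean(pred == labels),
    sensitivity = mean(pred[labels == 1] == 1),
    specificity = mean(pred[labels == 0] == 0),
    selection_freq = tibble::tibble(
      feature = names(sel_count),
      frequency = as.integer(sel_count) / n
    ),
    cutoff = cutoff, selector = selector, n_select = n_select
  ), class = "crt_cv")
}

#' Train the final logistic response classifier
#'
#' Maximum-likelihood logistic regression on the full cohort restricted to a
#' fixed feature list (by default the seven-feature set: LVEF, BMI, EDD, the
#' scar distance, baseline TAT95, and the inter-ventricular delays at
#' baseline and under pacing). Falls back to a weak ridge penalty, with a
#' warning, only under perfect separation.
#'
#' @param x raw feature table.
#' @param labels binary response labels.
#' @param features character vector of feature names to use.
#' @param cutoff ML-score classification cutoff (default 0.51).
#' @return object of class `crt_lr`.
#' @export
train_final <- function(x, labels,
                        features = c("lvef", "bmi", "edd", "scar_lvps",
                                     "tat95_lbbb", "ad_rvlv_lbbb",
                                     "ad_rvlv_biv"),
                        cutoff = 0.51) {
  labels <- as.integer(labels)
  x <- tibble::as_tibble(x)
  missing_f <- setdiff(features, names(x))
  if (length(missing_f)) {
    stop("features not present: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0,1)", call. = FALSE)
  sub <- x[features]
  pre <- suppressWarnings(preprocess(sub, cor_threshold = Inf))
  co <- fit_logistic(as.matrix(pre), labels)
  structure(list(
    features = features,
    coefficients = co[features],
    intercept = co[["(Intercept)"]],
    center = attr(pre, "center"),
    scale = attr(pre, "scale"),
    impute = attr(pre, "impute"),
    cutoff = cutoff,
    n = nrow(x)
  ), class = "crt_lr")
}

#' ML-score of a patient record
#'
#' Probability of a positive CRT response under the fitted logistic model:
#' the record is standardized with the training statistics and passed through
#' the logistic link. Classification is positive when the score exceeds the
#' model cutoff.
#'
#' @param model a `crt_lr`.
#' @param record named list / one-row data frame with all model features
#'   (raw scale).
#' @return numeric probability in (0, 1).
#' @export
ml_score <- function(model, record) {
  record <- as.list(record)
  miss <- model$features[!model$features %in% names(record)]
  if (length(miss)) {
    stop("missing feature: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  eta <- model$intercept
  for (f in model$features) {
    v <- as.numeric(record[[f]])
    if (is.na(v)) {
      v <- model$impute[[f]]
      if (is.na(v)) v <- model$center[[f]]
    }
    eta <- eta + model$coefficients[[f]] * (v - model$center[[f]]) / model$scale[[f]]
  }
  unname(plogis(eta))
}

#' @export
predict.crt_lr <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)
  s <- vapply(seq_len(nrow(newdata)),
              function(i) ml_score(object, newdata[i, ]), numeric(1))
  if (type == "score") s else as.integer(s > object$cutoff)
}

#' Area under the ROC curve
#'
#' Mann-Whitney U formulation: the probability that a random positive scores
#' above a random negative, ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.crt_lr <- function(x, ...) {
  cat("<crt_lr>", length(x$features), "features, cutoff", x$cutoff, "\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @export
print.crt_cv <- function(x, ...) {
  cat(sprintf("<crt_cv> %s selector, n_select %d: AUC %.3f, acc %.2f, sens %.2f, spec %.2f\n",
              x$selector, x$n_select, x$auc, x$accuracy, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Tidiers for crtsim result objects
#'
#' `tidy()` returns the per-term, per-patient or per-iteration table of a
#' fitted object; `glance()` returns its one-row summary.
#'
#' @param x a `crt_lr`, `crt_cv` or `crt_opt` object.
#' @param ... unused.
#' @name crtsim-tidiers
NULL

#' @rdname crtsim-tidiers
#' @export
tidy.crt_lr <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$features),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname crtsim-tidiers
#' @export
glance.crt_lr <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$features), cutoff = x$cutoff)
}

#' @rdname crtsim-tidiers
#' @export
tidy.crt_cv <- function(x, ...) x$scores

#' @rdname crtsim-tidiers
#' @export
glance.crt_cv <- function(x, ...) {
  tibble::tibble(auc = x$auc, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 cutoff = x$cutoff, selector = x$selector)
}
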