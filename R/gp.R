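#' Fit a Gaussian-process surrogate over pacing-site coordinates
#'
#' Zero-mean (after centering) GP regression with a squared-exponential
#' kernel on 3D Euclidean site coordinates. The length scale is chosen by
#' maximizing the log marginal likelihood within bounds; the signal variance
#' is profiled in closed form; the noise variance is kept at a small floor so
#' the posterior mean interpolates the training scores.
#'
#' @param X n x 3 matrix of site coordinates (mm).
#' @param y numeric scores at the sites.
#' @param lengthscale_bounds admissible kernel length scales (mm).
#' @param noise noise-variance floor.
#' @param lengthscale optional fixed length scale (mm); skips the marginal-
#'   likelihood optimization when supplied.
#' @return object of class `crt_gp`.
#' @export
gp_fit <- function(X, y, lengthscale_bounds = c(5, 100), noise = 1e-10,
                   lengthscale = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training points", call. = FALSE)
  stopifnot(length(y) == nrow(X))
  dup <- duplicated(X)
  if (any(dup)) {
    key <- apply(X, 1, paste, collapse = ",")
    spread <- tapply(y, key, function(v) diff(range(v)))
    if (any(spread > 1e-9)) {
      message("duplicate inputs with conflicting targets; absorbed by the noise floor")
    }
  }
  mu0 <- mean(y)
  yc <- y - mu0
  D2 <- as.matrix(dist(X))^2
  n <- nrow(X)
  nll <- function(log_ell) {
    ell <- exp(log_ell)
    R <- exp(-0.5 * D2 / ell^2) + diag(noise, n)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    s2 <- max(sum(yc * alpha) / n, 1e-12)
    0.5 * n * log(s2) + sum(log(diag(ch))) + 0.5 * n
  }
  ell <- if (is.null(lengthscale)) {
    exp(optimize(nll, interval = log(lengthscale_bounds))$minimum)
  } else lengthscale
  # escalate the jitter only as far as the factorization requires
  ch <- NULL
  for (i in 0:6) {
    R <- exp(-0.5 * D2 / ell^2) + diag(noise * 10^i, n)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (!is.null(ch)) { noise <- noise * 10^i; break }
  }
  if (is.null(ch)) stop("kernel matrix is not positive definite", call. = FALSE)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  s2 <- max(sum(yc * alpha) / n, 1e-12)
  structure(list(X = X, y = y, mean = mu0, lengthscale = ell,
                 signal_var = s2, noise = noise,
                 chol = ch, alpha = alpha),
            class = "crt_gp")
}

#' Posterior mean and standard deviation of a GP surrogate
#'
#' @param surrogate a fitted surrogate (e.g. `crt_gp`).
#' @param Xnew matrix of query coordinates (rows) or a length-3 vector.
#' @param ... passed to methods.
#' @return tibble with columns `mean` and `sd`.
#' @export
gp_predict <- function(surrogate, Xnew, ...) UseMethod("gp_predict")

#' @export
gp_predict.crt_gp <- function(surrogate, Xnew, ...) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, ncol = 3)
  Xnew <- as.matrix(Xnew)
  g <- surrogate
  # cross-covariance (scaled): exp(-0.5 d^2 / ell^2)
  d2 <- outer(rowSums(Xnew^2), rowSums(g$X^2), "+") - 2 * Xnew %*% t(g$X)
  d2[d2 < 0] <- 0
  Ks <- exp(-0.5 * d2 / g$lengthscale^2)
  mu <- g$mean + Ks %*% g$alpha
  # correlation-scale solves: R^{ -1 } ks'
  v <- forwardsolve(t(g$chol), t(Ks))
  var_rel <- pmax(1 + g$noise - colSums(v^2), 0)
  tibble::tibble(mean = as.numeric(mu), sd = sqrt(g$signal_var * var_rel))
}

#' Upper-confidence-bound acquisition
#'
#' The Bayesian-optimization acquisition rule `L(mu, sigma) = mu + 2 sigma`
#' (or `mu - 2 sigma` when minimizing): the GP posterior mean plus twice the
#' posterior standard deviation.
#'
#' @param surrogate fitted surrogate accepted by [gp_predict()].
#' @param Xnew query coordinates (rows, mm).
#' @param minimize lower instead of upper confidence bound.
#' @param beta uncertainty weight (default 2).
#' @return numeric acquisition values.
#' @export
acquisition <- function(surrogate, Xnew, minimize = FALSE, beta = 2) {
  p <- gp_predict(surrogate, Xnew)
  if (minimize) p$mean - beta * p$sd else p$mean + beta * p$sd
}

#' @export
print.crt_gp <- function(x, ...) {
  cat(sprintf("<crt_gp> %d points, lengthscale %.1f mm, signal sd %.3f\n",
              nrow(x$X), x$lengthscale, sqrt(x$signal_var)))
  invisible(x)
}
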