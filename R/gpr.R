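#' Gaussian-process regression with a squared-exponential kernel
#'
#' Minimal exact GP regressor used for the per-region age models. The
#' covariance is an isotropic squared-exponential over z-scored features
#' plus white noise:
#'
#'   k(x, x') = sf2 * exp(-||x - x'||^2 / (2 l^2)) + sn2 * 1(x == x')
#'
#' Hyperparameters are chosen by maximising the log marginal likelihood.
#' The signal variance has a closed-form optimum given the length-scale `l`
#' and the noise-to-signal ratio `g = sn2 / sf2`, so the search runs over
#' (log l, log g) only, with analytic gradients and several restarts.
#' Features are z-scored per column with training statistics (stored in the
#' fit); the target is centred.
#'
#' @param X subjects x features numeric matrix.
#' @param y numeric response (years).
#' @param n_restarts optimiser restarts (default 3).
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return object of class `gpr_fit`.
#' @export
gpr_fit <- function(X, y, n_restarts = 3L, maxit = 60L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n < 3L) stop("need at least 3 training points", call. = FALSE)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[x_sd == 0 | !is.finite(x_sd)] <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  D2 <- sq_dist(Xs, Xs)
  med <- stats::median(sqrt(D2[upper.tri(D2)]))
  if (!is.finite(med) || med <= 0) med <- 1

  # optim calls fn and gr at the same point in sequence; memoise the last one
  last <- list(theta = NULL, res = NULL)
  nll_grad <- function(theta) {
    if (!is.null(last$theta) && identical(theta, last$theta)) return(last$res)
    l <- exp(theta[1]); g <- exp(theta[2])
    C <- exp(-D2 / (2 * l^2))
    M <- C
    diag(M) <- diag(M) + g
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      res <- list(value = 1e10, grad = c(0, 0))
      last <<- list(theta = theta, res = res)
      return(res)
    }
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    q <- sum(yc * alpha)
    if (q <= 0) {
      res <- list(value = 1e10, grad = c(0, 0))
      last <<- list(theta = theta, res = res)
      return(res)
    }
    logdet <- 2 * sum(log(diag(ch)))
    value <- 0.5 * n * log(q) + 0.5 * logdet
    Minv <- chol2inv(ch)
    dM_l <- C * D2 / l^2            # dM/d(log l)
    g1 <- 0.5 * sum(Minv * dM_l) -
      0.5 * n * as.numeric(t(alpha) %*% dM_l %*% alpha) / q
    g2 <- 0.5 * g * sum(diag(Minv)) - 0.5 * n * g * sum(alpha^2) / q
    res <- list(value = value, grad = c(g1, g2))
    last <<- list(theta = theta, res = res)
    res
  }

  starts <- list(c(log(med), log(0.1)),
                 c(log(med / 3), log(1)),
                 c(log(3 * med), log(0.01)))
  starts <- starts[seq_len(min(n_restarts, length(starts)))]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s,
                   fn = function(th) nll_grad(th)$value,
                   gr = function(th) nll_grad(th)$grad,
                   method = "L-BFGS-B",
                   lower = c(log(med) - 6, log(1e-8)),
                   upper = c(log(med) + 6, log(1e3)),
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("GP hyperparameter optimisation failed (degenerate kernel fit); ",
         "n = ", n, ", features = ", ncol(X), call. = FALSE)
  }
  l <- exp(best$par[1]); g <- exp(best$par[2])
  M <- exp(-D2 / (2 * l^2))
  diag(M) <- diag(M) + g
  ch <- chol(M)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  sf2 <- sum(yc * alpha) / n
  structure(
    list(x_mean = x_mean, x_sd = x_sd, Xs = Xs, y_mean = y_mean,
         length_scale = l, noise_ratio = g, signal_var = sf2,
         alpha = alpha, nll = best$value),
    class = "gpr_fit"
  )
}

#' Predict from a fitted GP regressor
#'
#' Posterior mean at new inputs: `k(X*, X) (K + sn2 I)^{-1} y` (the signal
#' variance cancels in the mean, so only the correlation kernel is needed).
#'
#' @param object a `gpr_fit`.
#' @param newdata new subjects x features matrix (same columns as training).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gpr_fit <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$x_mean), call. = FALSE)
  }
  Zs <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_sd, "/")
  D2 <- sq_dist(Zs, object$Xs)
  Kstar <- exp(-D2 / (2 * object$length_scale^2))
  as.numeric(Kstar %*% object$alpha) + object$y_mean
}

# squared euclidean distances between rows of A and rows of B
sq_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * A %*% t(B)
  d[d < 0] <- 0
  d
}
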