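#' Gaussian-process regression fit
#'
#' Squared-exponential (ARD) kernel with additive Gaussian noise on
#' standardized features and target. Hyperparameters (per-feature length
#' scales, signal variance, noise variance) are set by maximizing the log
#' marginal likelihood with analytic gradients and seeded multi-start
#' L-BFGS-B. Training sets larger than `max_train` are subsampled (seeded)
#' for tractability.
#'
#' @param X numeric matrix or data.frame of features (no NA).
#' @param y numeric target.
#' @param seed RNG seed (restarts and subsampling).
#' @param n_restarts optimizer restarts beyond the default start.
#' @param max_train training-row cap (subsampled above, <= 3000 advised).
#' @param maxit optimizer iteration cap per start.
#' @return object of class `gpr_model`.
#' @export
gpr_fit <- function(X, y, seed = 1L, n_restarts = 2, max_train = 1000,
                    maxit = 80) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("gpr_fit: non-finite features")
  if (any(!is.finite(y))) stop("gpr_fit: non-finite target")
  n <- nrow(X)
  if (n < 20) stop("gpr_fit: need >= 20 samples")
  set.seed(seed)
  if (n > max_train) {
    keep <- sort(sample.int(n, max_train))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    n <- max_train
  }
  d <- ncol(X)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  # squared distances per feature
  D2 <- vector("list", d)
  for (k in seq_len(d)) D2[[k]] <- outer(Xs[, k], Xs[, k], "-")^2

  nll_grad <- function(theta) {
    ll <- exp(theta[seq_len(d)])
    sf2 <- exp(2 * theta[d + 1])
    sn2 <- exp(2 * theta[d + 2])
    Q <- matrix(0, n, n)
    for (k in seq_len(d)) Q <- Q + D2[[k]] / ll[k]^2
    E <- exp(-0.5 * Q)
    K <- sf2 * E + diag(sn2, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    jit <- 1e-8
    while (is.null(L) && jit < 1) {
      L <- tryCatch(chol(K + diag(jit * sf2, n)), error = function(e) NULL)
      jit <- jit * 10
    }
    if (is.null(L)) return(list(value = 1e10, grad = rep(0, d + 2)))
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    nll <- 0.5 * sum(ys * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
    Kinv <- chol2inv(L)
    W <- Kinv - tcrossprod(alpha)          # note: grad = +0.5 sum(W * dK)
    g <- numeric(d + 2)
    SE <- sf2 * E
    for (k in seq_len(d)) g[k] <- 0.5 * sum(W * (SE * D2[[k]] / ll[k]^2))
    g[d + 1] <- 0.5 * sum(W * (2 * SE))
    g[d + 2] <- 0.5 * sum(diag(W)) * 2 * sn2
    list(value = nll, grad = g)
  }

  starts <- list(c(rep(0, d), 0, log(0.3)))
  for (r in seq_len(n_restarts))
    starts[[r + 1]] <- starts[[1]] + stats::rnorm(d + 2, 0, 0.7)
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, fn = function(th) nll_grad(th)$value,
                   gr = function(th) nll_grad(th)$grad,
                   method = "L-BFGS-B", lower = rep(-5, d + 2),
                   upper = rep(5, d + 2), control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("gpr_fit: optimization failed")
  theta <- best$par
  ll <- exp(theta[seq_len(d)])
  sf2 <- exp(2 * theta[d + 1])
  sn2 <- exp(2 * theta[d + 2])
  Q <- matrix(0, n, n)
  for (k in seq_len(d)) Q <- Q + D2[[k]] / ll[k]^2
  K <- sf2 * exp(-0.5 * Q) + diag(sn2, n)
  L <- NULL; jit <- 0
  while (is.null(L)) {
    L <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
    if (is.null(L)) {
      jit <- if (jit == 0) 1e-8 * sf2 else jit * 10
      if (jit > sf2) stop("gpr_fit: singular kernel matrix")
    }
  }
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(Xs = Xs, alpha = alpha, L = L, lengthscales = ll,
                 sf2 = sf2, sn2 = sn2, x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, y_sd = y_sd, nll = best$value,
                 feature_names = colnames(X), seed = seed),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf("<gpr_model> n=%d, d=%d, noise sd (std units) %.3f, NLL %.1f\n",
              nrow(x$Xs), ncol(x$Xs), sqrt(x$sn2), x$nll))
  invisible(x)
}

#' Predict from a Gaussian-process model
#'
#' @param model a [gpr_fit()] result.
#' @param Xnew feature matrix/data.frame with the training columns.
#' @param se return predictive standard deviations as well.
#' @return numeric predictions, or a list `mean`/`sd` when `se = TRUE`.
#' @export
gpr_predict <- function(model, Xnew, se = FALSE) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(model$Xs)) stop("gpr_predict: feature mismatch")
  if (any(!is.finite(Xnew))) stop("gpr_predict: non-finite features")
  Xn <- sweep(sweep(Xnew, 2, model$x_mean), 2, model$x_sd, "/")
  d <- ncol(Xn)
  Q <- matrix(0, nrow(Xn), nrow(model$Xs))
  for (k in seq_len(d))
    Q <- Q + outer(Xn[, k], model$Xs[, k], "-")^2 / model$lengthscales[k]^2
  Ks <- model$sf2 * exp(-0.5 * Q)
  mu <- model$y_mean + model$y_sd * as.numeric(Ks %*% model$alpha)
  if (!se) return(mu)
  V <- forwardsolve(t(model$L), t(Ks))
  var_s <- pmax(model$sf2 + model$sn2 - colSums(V^2), 0)
  list(mean = mu, sd = model$y_sd * sqrt(var_s))
}
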