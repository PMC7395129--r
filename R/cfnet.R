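## ---------------------------------------------------------------------------
## Cascade-forward neural network: two sigmoidal hidden layers with direct
## connections from the input to every successive layer and a linear
## output, trained by Levenberg-Marquardt least squares (analytic
## Jacobian, light weight decay for conditioning).
## ---------------------------------------------------------------------------

#' Cascade-forward network specification
#'
#' @param hidden_sizes sizes of the two hidden layers, default `c(10, 8)`.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param weight_decay ridge penalty on the weights added to the
#'   least-squares objective; keeps the normal equations well conditioned
#'   when the net has more weights than training rows.
#' @param init_sd standard deviation of the random weight initialisation.
#' @param seed integer seed for the initial weights.
#' @return a `cf_net_spec`.
#' @export
cf_net_spec <- function(hidden_sizes = c(10, 8), max_iter = 50,
                        weight_decay = 1e-3, init_sd = 0.3, seed = 1L) {
  if (length(hidden_sizes) != 2 || any(hidden_sizes < 1))
    stopf("exactly two hidden layers with >= 1 unit each")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 max_iter = max_iter, weight_decay = weight_decay,
                 init_sd = init_sd, seed = seed),
            class = "cf_net_spec")
}

cf_n_par <- function(p, h1, h2) h1 * (p + 1) + h2 * (p + h1 + 1) + (p + h1 + h2 + 1)

cf_unpack <- function(par, p, h1, h2) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(h1 * (p + 1))], h1); i <- i + h1 * (p + 1)
  W2 <- matrix(par[i + seq_len(h2 * (p + h1 + 1))], h2); i <- i + h2 * (p + h1 + 1)
  list(W1 = W1, W2 = W2, w3 = par[i + seq_len(p + h1 + h2 + 1)])
}

cf_forward <- function(par, X, p, h1, h2) {
  w <- cf_unpack(par, p, h1, h2)
  sig <- function(z) 1 / (1 + exp(-z))
  A1 <- cbind(X, 1); H1 <- sig(tcrossprod(A1, w$W1))
  A2 <- cbind(X, H1, 1); H2 <- sig(tcrossprod(A2, w$W2))
  A3 <- cbind(X, H1, H2, 1)
  list(yhat = as.numeric(A3 %*% w$w3),
       A1 = A1, A2 = A2, A3 = A3, H1 = H1, H2 = H2, w = w)
}

## analytic Jacobian of the outputs w.r.t. the packed weights;
## column order matches R's column-major matrix packing
cf_jacobian <- function(par, X, p, h1, h2) {
  f <- cf_forward(par, X, p, h1, h2)
  n <- nrow(X); w <- f$w
  d1 <- f$H1 * (1 - f$H1); d2 <- f$H2 * (1 - f$H2)
  w3h1 <- w$w3[p + seq_len(h1)]; w3h2 <- w$w3[p + h1 + seq_len(h2)]
  G2 <- sweep(d2, 2, w3h2, "*")
  D1 <- matrix(w3h1, n, h1, byrow = TRUE) +
    G2 %*% w$W2[, p + seq_len(h1), drop = FALSE]
  G1 <- D1 * d1
  J1 <- do.call(cbind, lapply(seq_len(p + 1), function(k) f$A1[, k] * G1))
  J2 <- do.call(cbind, lapply(seq_len(p + h1 + 1), function(k) f$A2[, k] * G2))
  cbind(J1, J2, f$A3)
}

## per-column [-1, 1] range scaling fitted on training data
range_scaler <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- hi - lo; span[span == 0] <- 1
  list(lo = lo, span = span)
}
range_apply <- function(X, sc) sweep(sweep(X, 2, sc$lo), 2, sc$span, "/") * 2 - 1

#' Train a cascade-forward network
#'
#' Inputs and target are range-scaled to \[-1, 1\] using training
#' statistics; the mean squared error (plus a light ridge penalty on the
#' weights) is minimised by Levenberg-Marquardt with an analytic Jacobian.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cf_net_spec()].
#' @param X numeric matrix of predictors (rows = observations).
#' @param y numeric target vector.
#' @return a `cf_net` model with a [predict][predict.cf_net] method.
#' @export
train_cf_net <- function(spec, X, y) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stopf("non-finite inputs")
  if (nrow(X) != length(y)) stopf("X and y sizes disagree")
  p <- ncol(X); h1 <- spec$hidden_sizes[1]; h2 <- spec$hidden_sizes[2]
  sx <- range_scaler(X); sy <- range_scaler(matrix(y))
  Xs <- range_apply(X, sx)
  ys <- as.numeric(range_apply(matrix(y), sy))
  np <- cf_n_par(p, h1, h2)
  sl <- sqrt(spec$weight_decay)
  par0 <- with_seed_if(spec$seed, rnorm(np, 0, spec$init_sd))
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par0,
    fn = function(pp) c(cf_forward(pp, Xs, p, h1, h2)$yhat - ys, sl * pp),
    jac = function(pp) rbind(cf_jacobian(pp, Xs, p, h1, h2), diag(sl, np)),
    control = minpack.lm::nls.lm.control(maxiter = spec$max_iter,
                                         ptol = 1e-8, ftol = 1e-10)
  ))
  structure(list(par = fit$par, p = p, h1 = h1, h2 = h2,
                 scaler_x = sx, scaler_y = sy, spec = spec,
                 niter = fit$niter,
                 train_mse = mean((cf_forward(fit$par, Xs, p, h1, h2)$yhat - ys)^2)),
            class = "cf_net")
}

#' Predict from a trained cascade-forward network
#'
#' @param object a `cf_net` from [train_cf_net()].
#' @param newdata matrix of predictors.
#' @param ... unused.
#' @return numeric predictions on the original target scale.
#' @export
predict.cf_net <- function(object, newdata, ...) {
  Xs <- range_apply(as.matrix(newdata), object$scaler_x)
  ys <- cf_forward(object$par, Xs, object$p, object$h1, object$h2)$yhat
  sy <- object$scaler_y
  (ys + 1) / 2 * sy$span + sy$lo
}

#' @export
print.cf_net <- function(x, ...) {
  cat(sprintf("<cf_net> %d-%d-%d-1 cascade-forward, %d weights, train MSE %.3g (%d LM iterations)\n",
              x$p, x$h1, x$h2, cf_n_par(x$p, x$h1, x$h2), x$train_mse, x$niter))
  invisible(x)
}
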