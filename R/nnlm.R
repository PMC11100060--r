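## Feed-forward network regression trained by Levenberg-Marquardt (damped
## Gauss-Newton on the sum of squared errors) or Bayesian regularization
## (LM on beta*SSE + alpha*||w||^2 with evidence-approximation updates of
## alpha and beta each epoch).
##
## Architecture: one hidden layer (tanh by default, switchable to linear for
## testing against closed-form least squares) and a single output neuron,
## linear-rectified (ReLU) or plain linear.

.actFun <- function(kind) switch(kind,
  tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2),
  linear = list(f = identity, df = function(z) rep(1, length(z))),
  relu = list(f = function(z) pmax(z, 0), df = function(z) as.numeric(z > 0)))

.nnUnpack <- function(w, d, h) {
  i <- 0
  W1 <- matrix(w[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- w[i + seq_len(h)]; i <- i + h
  w2 <- w[i + seq_len(h)]; i <- i + h
  b2 <- w[i + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

.nnInit <- function(d, h, y, seed) {
  withSeed(seed, {
    w <- c(stats::rnorm(d * h, 0, 1 / sqrt(d)), rep(0, h),
           stats::rnorm(h, 0, 1 / sqrt(h)), mean(y))
  })
}

## Forward pass + per-sample Jacobian of the network output wrt the weights.
.nnForwardJac <- function(w, X, d, h, hAct, oAct, jacobian = TRUE) {
  p <- .nnUnpack(w, d, h)
  fh <- .actFun(hAct); fo <- .actFun(oAct)
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")      # N x h
  A1 <- fh$f(Z1)
  z2 <- drop(A1 %*% p$w2) + p$b2             # N
  yhat <- fo$f(z2)
  if (!jacobian) return(list(yhat = yhat))
  g <- fo$df(z2)                             # N
  S <- (g * matrix(p$w2, nrow(X), h, byrow = TRUE)) * fh$df(Z1)  # N x h
  JW1 <- X[, rep(seq_len(d), h), drop = FALSE] *
    S[, rep(seq_len(h), each = d), drop = FALSE]
  J <- cbind(JW1, S, A1 * g, g)
  list(yhat = yhat, J = J)
}

#' Train a feed-forward regression network by Levenberg-Marquardt
#'
#' Damped Gauss-Newton on the sum of squared errors: the damping factor is
#' increased when a step fails to reduce the loss and decreased when a step
#' is accepted, so the loss over accepted steps is non-increasing.  Singular
#' normal equations only escalate the damping; they never abort.
#'
#' @param X numeric input matrix (typically z-scored features).
#' @param y numeric targets.
#' @param hidden hidden-layer width.
#' @param epochs maximum LM epochs (0 returns the initial network).
#' @param hiddenActivation "tanh" or "linear".
#' @param outputActivation "relu" (linear-rectified) or "linear".
#' @param gradTol stop when the gradient infinity-norm falls below this.
#' @param seed RNG seed for the weight initialization.
#' @return list of class "sqFfnn" with weights, architecture and the
#'   accepted-step loss trajectory.
#' @export
trainFfnn <- function(X, y, hidden = 50L, epochs = 1000L,
                      hiddenActivation = "tanh", outputActivation = "relu",
                      gradTol = 1e-10, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), all(is.finite(y)), epochs >= 0)
  d <- ncol(X); h <- as.integer(hidden)
  w <- .nnInit(d, h, y, seed)
  mu <- 1e-2
  fw <- .nnForwardJac(w, X, d, h, hiddenActivation, outputActivation)
  r <- y - fw$yhat
  sse <- sum(r^2)
  loss <- sse
  for (ep in seq_len(epochs)) {
    J <- fw$J
    g <- crossprod(J, r)
    if (max(abs(g)) < gradTol) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (tries in 1:30) {
      H <- JtJ + diag(mu, ncol(J))
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (!is.null(step)) {
        wNew <- w + drop(step)
        fwNew <- .nnForwardJac(wNew, X, d, h, hiddenActivation,
                               outputActivation)
        sseNew <- sum((y - fwNew$yhat)^2)
        if (is.finite(sseNew) && sseNew <= sse) {
          w <- wNew; fw <- fwNew; r <- y - fw$yhat; sse <- sseNew
          mu <- max(mu / 9, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- min(mu * 11, 1e12)
    }
    loss <- c(loss, sse)
    if (!accepted) break
  }
  structure(list(weights = w, d = d, h = h,
                 hiddenActivation = hiddenActivation,
                 outputActivation = outputActivation,
                 loss = loss, trainer = "LM"),
            class = "sqFfnn")
}

#' Train a feed-forward regression network with Bayesian regularization
#'
#' LM inner loop on the regularized objective beta*SSE + alpha*||w||^2; after
#' every epoch alpha and beta are re-estimated by the evidence approximation
#' via the effective number of parameters
#' gamma = n_w - alpha * tr(H^-1), alpha = gamma / (2 ||w||^2),
#' beta = (N - gamma) / (2 SSE).
#'
#' @inheritParams trainFfnn
#' @param alpha0,beta0 initial regularization hyperparameters.
#' @param updateHyper re-estimate alpha/beta each epoch; with FALSE and
#'   alpha0 = 0 the trainer reduces exactly to Levenberg-Marquardt.
#' @return list of class "sqFfnn" with the evidence diagnostics (alpha,
#'   beta, gamma).
#' @export
trainFfnnBr <- function(X, y, hidden = 50L, epochs = 1000L,
                        hiddenActivation = "tanh", outputActivation = "relu",
                        gradTol = 1e-10, seed = 1L,
                        alpha0 = 0.01, beta0 = 1, updateHyper = TRUE) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), all(is.finite(y)), epochs >= 0)
  d <- ncol(X); h <- as.integer(hidden)
  N <- nrow(X)
  w <- .nnInit(d, h, y, seed)
  nw <- length(w)
  alpha <- alpha0; beta <- beta0
  mu <- 1e-2
  fw <- .nnForwardJac(w, X, d, h, hiddenActivation, outputActivation)
  r <- y - fw$yhat
  sse <- sum(r^2)
  obj <- beta * sse + alpha * sum(w^2)
  loss <- sse
  gamma <- NA_real_
  for (ep in seq_len(epochs)) {
    J <- fw$J
    g <- beta * crossprod(J, r) - alpha * w
    if (max(abs(g)) < gradTol) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (tries in 1:30) {
      H <- beta * JtJ + diag(alpha + mu, nw)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (!is.null(step)) {
        wNew <- w + drop(step)
        fwNew <- .nnForwardJac(wNew, X, d, h, hiddenActivation,
                               outputActivation)
        sseNew <- sum((y - fwNew$yhat)^2)
        objNew <- beta * sseNew + alpha * sum(wNew^2)
        if (is.finite(objNew) && objNew <= obj) {
          w <- wNew; fw <- fwNew; r <- y - fw$yhat
          sse <- sseNew; obj <- objNew
          mu <- max(mu / 9, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- min(mu * 11, 1e12)
    }
    loss <- c(loss, sse)
    if (!updateHyper) {
      if (!accepted && mu >= 1e12) break
      next
    }
    ## evidence-approximation hyperparameter updates
    Hreg <- beta * JtJ + diag(alpha, nw)
    trInv <- tryCatch(sum(diag(chol2inv(chol(Hreg)))), error = function(e) NA)
    if (is.finite(trInv)) {
      gamma <- nw - alpha * trInv
      alpha <- max(gamma, 1e-6) / max(2 * sum(w^2), 1e-12)
      beta <- max(N - gamma, 1e-6) / max(2 * sse, 1e-12)
      obj <- beta * sse + alpha * sum(w^2)
    }
    if (!accepted && mu >= 1e12) break
  }
  structure(list(weights = w, d = d, h = h,
                 hiddenActivation = hiddenActivation,
                 outputActivation = outputActivation,
                 loss = loss, trainer = "BR",
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "sqFfnn")
}

#' @rdname trainFfnn
#' @param object a fitted "sqFfnn".
#' @param newdata input matrix on the training scale.
#' @export
predictFfnn <- function(object, newdata) {
  .nnForwardJac(object$weights, as.matrix(newdata), object$d, object$h,
                object$hiddenActivation, object$outputActivation,
                jacobian = FALSE)$yhat
}
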