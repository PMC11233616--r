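#' Multilayer perceptron with identity activations
#'
#' A three-hidden-layer perceptron whose hidden units use the identity
#' activation function, trained with full-batch gradient descent under an
#' adaptive learning rate (halved whenever the penalised log-loss stops
#' improving) and a sigmoid output for binary classification.  With
#' identity activations the network composes to a single linear map, so
#' its connection-weight product is an exact signed attribution of each
#' input feature.
#'
#' @param x numeric matrix of standardized features (n x p).
#' @param y 0/1 labels.
#' @param hidden integer vector of the three hidden-layer widths.
#' @param lr initial learning rate.
#' @param epochs number of full-batch epochs.
#' @param l2 ridge penalty on all weights.
#' @param seed integer seed for the weight initialisation.
#' @return An object of class `linear_mlp`.
#' @export
fit_linear_mlp <- function(x, y, hidden = c(16L, 8L, 4L), lr = 0.05,
                           epochs = 400L, l2 = 1e-4, seed = 1L) {
  stopifnot(length(hidden) == 3L)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dims <- c(p, hidden, 1L)
  W <- lapply(seq_len(4L), function(l)
    matrix(stats::rnorm(dims[l] * dims[l + 1L], 0, sqrt(1 / dims[l])),
           dims[l], dims[l + 1L]))
  rownames(W[[1]]) <- colnames(x)
  b <- lapply(seq_len(4L), function(l) numeric(dims[l + 1L]))
  vel_W <- lapply(W, function(w) w * 0)
  vel_b <- lapply(b, function(v) v * 0)
  mom <- 0.9
  forward <- function() {
    H <- vector("list", 4L)
    a <- x
    for (l in 1:4) {
      a <- sweep(a %*% W[[l]], 2, b[[l]], "+")
      H[[l]] <- a
    }
    H
  }
  loss_of <- function(H) {
    eta <- H[[4]][, 1]
    -mean(y * eta - log1p(exp(eta))) +
      l2 / 2 * sum(vapply(W, function(w) sum(w^2), numeric(1)))
  }
  prev <- Inf
  for (ep in seq_len(epochs)) {
    H <- forward()
    cur <- loss_of(H)
    if (cur > prev - 1e-12) lr <- lr / 2
    if (lr < 1e-8) break
    prev <- cur
    prob <- stats::plogis(H[[4]][, 1])
    delta <- matrix((prob - y) / n, ncol = 1L)
    for (l in 4:1) {
      inp <- if (l == 1L) x else H[[l - 1L]]
      gW <- crossprod(inp, delta) + l2 * W[[l]]
      gb <- colSums(delta)
      if (l > 1L) delta <- delta %*% t(W[[l]])
      vel_W[[l]] <- mom * vel_W[[l]] - lr * gW
      vel_b[[l]] <- mom * vel_b[[l]] - lr * gb
      W[[l]] <- W[[l]] + vel_W[[l]]
      b[[l]] <- b[[l]] + vel_b[[l]]
    }
  }
  structure(list(W = W, b = b, hidden = hidden, final_loss = prev),
            class = "linear_mlp")
}

#' @rdname fit_linear_mlp
#' @param object a fitted `linear_mlp`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return `predict()`: vector of rupture probabilities.
#' @export
predict.linear_mlp <- function(object, newdata, ...) {
  a <- as.matrix(newdata)
  for (l in 1:4) a <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
  stats::plogis(a[, 1])
}

#' Composed linear coefficients of an identity-activation MLP
#'
#' The product of the connection-weight matrices across all layers, i.e.
#' the coefficient vector of the single linear map the network computes on
#' the logit scale.  Valid as a signed feature attribution because every
#' hidden activation is the identity.
#'
#' @param object a fitted `linear_mlp`.
#' @return Named numeric vector of per-feature signed weights.
#' @export
mlp_coefficients <- function(object) {
  w <- object$W[[1]] %*% object$W[[2]] %*% object$W[[3]] %*% object$W[[4]]
  stats::setNames(w[, 1], rownames(object$W[[1]]))
}
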