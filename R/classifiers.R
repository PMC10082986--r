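#' Classifier contracts
#'
#' Classifiers are used only through a minimal contract: a list with
#' `fit(X, y) -> model` and `predict_prob(model, X) -> n x C` probability
#' matrix (columns ordered by class `1..C`, rows summing to 1). This keeps
#' the selection framework classifier-agnostic.
#'
#' `classifier_svm()` wraps a radial-basis-function support-vector machine
#' (libsvm via e1071) with sigmoid-calibrated probabilities. When `sigma` is
#' `NULL` the kernel width is set at fit time by the median-distance
#' heuristic: `gamma = 1 / (2 * median(pairwise distance)^2)`.
#'
#' @param sigma RBF kernel coefficient (`gamma` in `exp(-gamma * |x-y|^2)`),
#'   or `NULL` for the median heuristic.
#' @param cost Soft-margin cost parameter.
#' @return A classifier contract list with elements `fit`, `predict_prob`,
#'   and `label`.
#' @export
classifier_svm <- function(sigma = NULL, cost = 1) {
  list(
    label = sprintf("rbf_svm(sigma=%s, cost=%g)",
                    if (is.null(sigma)) "median" else format(sigma), cost),
    fit = function(X, y) {
      C <- max(y)
      g <- sigma
      if (is.null(g)) {
        med <- stats::median(dist(X))
        if (!is.finite(med) || med <= 0) med <- 1
        g <- 1 / (2 * med^2)
      }
      fit <- e1071::svm(x = X, y = factor(y, levels = seq_len(C)),
                        kernel = "radial", gamma = g, cost = cost,
                        probability = TRUE)
      list(fit = fit, C = C)
    },
    predict_prob = function(model, X) {
      pr <- predict(model$fit, X, probability = TRUE)
      prob <- attr(pr, "probabilities")
      out <- matrix(0, nrow(X), model$C)
      if (is.null(prob)) {          # degenerate probability model: one-hot
        out[cbind(seq_len(nrow(X)), as.integer(as.character(pr)))] <- 1
      } else {
        out[, as.integer(colnames(prob))] <- prob
      }
      out
    }
  )
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Rprop+ (resilient backpropagation with weight backtracking) on a
# two-hidden-layer tanh network with softmax/cross-entropy output.
# Full-batch: sign-based per-weight step sizes, so no learning rate to tune.
train_mlp_rprop <- function(X, y, hn1, hn2, epochs = 300, seed_weights = TRUE,
                            eta_plus = 1.2, eta_minus = 0.5,
                            delta0 = 0.1, delta_max = 50, delta_min = 1e-6) {
  n <- nrow(X); p <- ncol(X); C <- max(y)
  Yind <- matrix(0, n, C); Yind[cbind(seq_len(n), y)] <- 1
  init <- function(r, c) matrix(rnorm(r * c, sd = 1 / sqrt(r)), r, c)
  W <- list(init(p, hn1), init(hn1, hn2), init(hn2, C))
  b <- list(numeric(hn1), numeric(hn2), numeric(C))
  forward <- function(W, b) {
    A1 <- tanh(sweep(X %*% W[[1]], 2, b[[1]], "+"))
    A2 <- tanh(sweep(A1 %*% W[[2]], 2, b[[2]], "+"))
    P <- softmax_rows(sweep(A2 %*% W[[3]], 2, b[[3]], "+"))
    list(A1 = A1, A2 = A2, P = P)
  }
  grads <- function(fw) {
    d3 <- (fw$P - Yind) / n
    gW3 <- t(fw$A2) %*% d3; gb3 <- colSums(d3)
    d2 <- (d3 %*% t(W[[3]])) * (1 - fw$A2^2)
    gW2 <- t(fw$A1) %*% d2; gb2 <- colSums(d2)
    d1 <- (d2 %*% t(W[[2]])) * (1 - fw$A1^2)
    gW1 <- t(X) %*% d1; gb1 <- colSums(d1)
    list(W = list(gW1, gW2, gW3), b = list(gb1, gb2, gb3))
  }
  loss <- function(P) -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  delta_W <- lapply(W, function(w) array(delta0, dim(w)))
  delta_b <- lapply(b, function(v) rep(delta0, length(v)))
  prevg_W <- lapply(W, function(w) array(0, dim(w)))
  prevg_b <- lapply(b, function(v) numeric(length(v)))
  prevstep_W <- lapply(W, function(w) array(0, dim(w)))
  prevstep_b <- lapply(b, function(v) numeric(length(v)))
  prev_loss <- Inf
  rprop_step <- function(g, prevg, delta, prevstep, cur_worse) {
    s <- sign(g) * sign(prevg)
    delta <- ifelse(s > 0, pmin(delta * eta_plus, delta_max),
             ifelse(s < 0, pmax(delta * eta_minus, delta_min), delta))
    step <- -sign(g) * delta
    # weight backtracking: on a sign change while the loss rose, undo the
    # previous step and do not move this epoch
    if (cur_worse) step[s < 0] <- -prevstep[s < 0]
    g[s < 0] <- 0
    list(step = step, delta = delta, g = g)
  }
  for (ep in seq_len(epochs)) {
    fw <- forward(W, b)
    cur <- loss(fw$P)
    gr <- grads(fw)
    worse <- cur > prev_loss
    for (l in 1:3) {
      up <- rprop_step(gr$W[[l]], prevg_W[[l]], delta_W[[l]], prevstep_W[[l]], worse)
      W[[l]] <- W[[l]] + up$step
      delta_W[[l]] <- up$delta; prevg_W[[l]] <- up$g; prevstep_W[[l]] <- up$step
      upb <- rprop_step(gr$b[[l]], prevg_b[[l]], delta_b[[l]], prevstep_b[[l]], worse)
      b[[l]] <- b[[l]] + upb$step
      delta_b[[l]] <- upb$delta; prevg_b[[l]] <- upb$g; prevstep_b[[l]] <- upb$step
    }
    prev_loss <- cur
  }
  list(W = W, b = b, C = C)
}

#' @rdname classifier_svm
#' @param hn1,hn2 Node counts of the first and second hidden layers of the
#'   Rprop-trained neural network.
#' @param epochs Training epochs for the neural network.
#' @export
classifier_mlp <- function(hn1 = 10, hn2 = 4, epochs = 300) {
  list(
    label = sprintf("rprop_mlp(hn1=%d, hn2=%d)", hn1, hn2),
    fit = function(X, y) train_mlp_rprop(as.matrix(X), y, hn1, hn2, epochs),
    predict_prob = function(model, X) {
      X <- as.matrix(X)
      A1 <- tanh(sweep(X %*% model$W[[1]], 2, model$b[[1]], "+"))
      A2 <- tanh(sweep(A1 %*% model$W[[2]], 2, model$b[[2]], "+"))
      softmax_rows(sweep(A2 %*% model$W[[3]], 2, model$b[[3]], "+"))
    }
  )
}

# hard class predictions from a contract classifier
predict_class <- function(clf, model, X) {
  apply(clf$predict_prob(model, X), 1, which.max)
}
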