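# Penalized single-hidden-layer network for two task conditions.
#
# Hidden units z_m = logistic(alpha_m0 + sum_j alpha_jm x_j); a single
# logistic output gives f_NoGo = logistic(beta_0 + sum_m beta_m z_m) and
# f_Go = 1 - f_NoGo (this 2-class form has M(p+2)+1 weights; the weight-
# decay penalty lambda is the final tunable). Loss is the cross-entropy
# plus lambda * (sum alpha_jm^2 + sum beta_m^2); biases are excluded from
# the penalty by default (`penalize_bias = TRUE` gives the common
# alternative). Training is BFGS with analytic gradients from random
# uniform [-0.5, 0.5] initial weights.

logistic <- function(x) 1 / (1 + exp(-x))

n_weights <- function(M, p) M * (p + 1) + (M + 1)

unpack_theta <- function(theta, M, p) {
  na <- M * (p + 1)
  alpha <- matrix(theta[seq_len(na)], M, p + 1)   # col 1 = bias
  beta <- theta[na + seq_len(M + 1)]              # [1] = bias
  list(alpha = alpha, beta = beta)
}

#' Construct a network model object
#'
#' @param theta Weight vector (length `M (p+1) + M + 1`).
#' @param M Hidden-unit count.
#' @param p Feature length.
#' @param lambda L2 penalty weight.
#' @param penalize_bias Whether biases entered the penalty.
#' @param index_map Optional feature index map.
#' @param meta Optional training metadata list.
#' @return An `nn_model`.
#' @export
nn_model <- function(theta, M, p, lambda, penalize_bias = FALSE,
                     index_map = NULL, meta = list()) {
  stopifnot(length(theta) == n_weights(M, p), all(is.finite(theta)))
  structure(c(unpack_theta(theta, M, p),
              list(theta = theta, M = M, p = p, lambda = lambda,
                   penalize_bias = penalize_bias, index_map = index_map,
                   meta = meta)),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> M = %d hidden units, p = %d features, lambda = %g (%d weights)\n",
              x$M, x$p, x$lambda, length(x$theta)))
  invisible(x)
}

#' Forward pass: condition probabilities
#'
#' @param model An `nn_model`.
#' @param X Feature matrix (n x p) or a single length-p vector.
#' @return Data frame with `f_go`, `f_nogo`, `chat` (predicted class) and
#'   `margin_ratio` (winning over losing probability).
#' @export
nn_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$p) {
    stop(errorCondition("feature dimension does not match the model",
                        class = c("ersplearn_dim_mismatch", "error")))
  }
  Z <- logistic(cbind(1, X) %*% t(model$alpha))   # n x M
  f_nogo <- as.numeric(logistic(cbind(1, Z) %*% model$beta))
  f_go <- 1 - f_nogo
  chat <- factor(ifelse(f_nogo > 0.5, "NoGo", "Go"), levels = c("Go", "NoGo"))
  data.frame(f_go = f_go, f_nogo = f_nogo, chat = chat,
             margin_ratio = pmax(f_go, f_nogo) / pmin(f_go, f_nogo))
}

hidden_activations <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  logistic(cbind(1, X) %*% t(model$alpha))
}

#' Penalized cross-entropy loss (and gradient)
#'
#' @param theta Weight vector.
#' @param X n x p features.
#' @param y01 0/1 labels (1 = NoGo).
#' @param M,lambda Architecture and penalty.
#' @param penalize_bias Include bias weights in the penalty.
#' @return `nn_loss` returns a list with `ce`, `penalty`, `total`;
#'   `nn_grad` the gradient of the total loss.
#' @export
nn_loss <- function(theta, X, y01, M, lambda, penalize_bias = FALSE) {
  p <- ncol(X)
  th <- unpack_theta(theta, M, p)
  Z <- logistic(cbind(1, X) %*% t(th$alpha))
  f <- as.numeric(logistic(cbind(1, Z) %*% th$beta))
  f <- pmin(1 - 1e-12, pmax(1e-12, f))
  ce <- -sum(y01 * log(f) + (1 - y01) * log(1 - f))
  pen_a <- if (penalize_bias) sum(th$alpha^2) else sum(th$alpha[, -1]^2)
  pen_b <- if (penalize_bias) sum(th$beta^2) else sum(th$beta[-1]^2)
  pen <- pen_a + pen_b
  list(ce = ce, penalty = pen, total = ce + lambda * pen)
}

#' @rdname nn_loss
#' @export
nn_grad <- function(theta, X, y01, M, lambda, penalize_bias = FALSE) {
  p <- ncol(X)
  th <- unpack_theta(theta, M, p)
  X1 <- cbind(1, X)
  Z <- logistic(X1 %*% t(th$alpha))                # n x M
  Z1 <- cbind(1, Z)
  f <- as.numeric(logistic(Z1 %*% th$beta))
  du <- f - y01                                    # d CE / d output-logit
  g_beta <- as.numeric(t(Z1) %*% du)
  dz <- outer(du, th$beta[-1]) * Z * (1 - Z)       # n x M
  g_alpha <- t(dz) %*% X1                          # M x (p+1)
  pen_a <- 2 * th$alpha; pen_b <- 2 * th$beta
  if (!penalize_bias) { pen_a[, 1] <- 0; pen_b[1] <- 0 }
  c(as.numeric(g_alpha + lambda * pen_a), g_beta + lambda * pen_b)
}

#' Train the network
#'
#' Quasi-Newton (BFGS) minimization of the penalized cross-entropy from
#' uniform random initial weights in [-0.5, 0.5]; with several restarts the
#' fit with the lowest training loss is returned. Deterministic given
#' `seed`.
#'
#' @param X n x p feature matrix.
#' @param y Factor with levels Go/NoGo, or 0/1 vector (1 = NoGo).
#' @param M Hidden units (>= 1).
#' @param lambda Penalty weight (>= 0).
#' @param seed Integer seed for the initialization.
#' @param restarts Number of random restarts.
#' @param maxit BFGS iteration cap.
#' @param penalize_bias Include biases in the penalty.
#' @param index_map Optional feature index map stored on the model.
#' @return An `nn_model` with training metadata (`loss`, `ce`, `penalty`,
#'   `iterations`, `restart_losses`, `init_theta`).
#' @export
nn_train <- function(X, y, M = 4, lambda = 0.005, seed = 1L, restarts = 1L,
                     maxit = 500L, penalize_bias = FALSE, index_map = NULL) {
  stopifnot(M >= 1, lambda >= 0)
  y01 <- if (is.factor(y)) as.integer(y == "NoGo") else as.integer(y)
  p <- ncol(X)
  nw <- n_weights(M, p)
  best <- NULL
  losses <- numeric(0)
  for (r in seq_len(restarts)) {
    attempt <- 0L
    repeat {
      init <- with_seed(seed_stream(seed, 11L, r, attempt),
                        stats::runif(nw, -0.5, 0.5))
      o <- stats::optim(init, fn = function(th) nn_loss(th, X, y01, M, lambda,
                                                        penalize_bias)$total,
                        gr = function(th) nn_grad(th, X, y01, M, lambda,
                                                  penalize_bias),
                        method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-8))
      if (is.finite(o$value) && all(is.finite(o$par))) break
      attempt <- attempt + 1L
      if (attempt > 5L) stop("training produced non-finite loss repeatedly",
                             call. = FALSE)
    }
    losses[r] <- o$value
    if (is.null(best) || o$value < best$value) {
      best <- o; best$init <- init
    }
  }
  lv <- nn_loss(best$par, X, y01, M, lambda, penalize_bias)
  nn_model(best$par, M, p, lambda, penalize_bias, index_map,
           meta = list(loss = lv$total, ce = lv$ce, penalty = lv$penalty,
                       iterations = best$counts[["function"]],
                       restart_losses = losses, seed = seed,
                       init_loss = nn_loss(best$init, X, y01, M, lambda,
                                           penalize_bias)$total))
}
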