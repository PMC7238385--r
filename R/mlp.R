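# 10-10-1 multilayer perceptron trained by Levenberg-Marquardt on MSE loss.

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Training control parameters
#'
#' The "initial learning rate" of 0.01 is realized as the initial
#' Levenberg-Marquardt damping parameter mu (the damped Gauss-Newton update
#' has no classical learning rate); mu is multiplied by \code{mu_factor} on a
#' rejected step and divided by it on an accepted one.
#'
#' @param mu_init initial damping (default 0.01).
#' @param max_iter maximum iterations (default 1000).
#' @param goal_mse stopping mean squared error (default 1e-6).
#' @param mu_factor damping adaptation factor (default 10).
#' @param mu_max damping ceiling; exceeding it stops training with status
#'   \code{"mu_overflow"}.
#' @param seed RNG seed for weight initialization.
#' @return a list of class \code{"mlp_control"}.
#' @export
mlp_control <- function(mu_init = 0.01, max_iter = 1000L, goal_mse = 1e-6,
                        mu_factor = 10, mu_max = 1e10, seed = 1L) {
  stopifnot(mu_init > 0, max_iter >= 1, goal_mse > 0, mu_factor > 1, mu_max > 0)
  structure(list(mu_init = mu_init, max_iter = as.integer(max_iter),
                 goal_mse = goal_mse, mu_factor = mu_factor, mu_max = mu_max,
                 seed = as.integer(seed)),
            class = "mlp_control")
}

#' Initialize network weights
#'
#' Seeded uniform weights in [-0.5, 0.5] for the fixed n_in-hidden-1
#' architecture (hyperbolic tangent hidden layer, linear output).
#'
#' @param seed integer seed; equal seeds give identical weights.
#' @param n_in number of inputs (default 10).
#' @param hidden hidden-layer size (default 10).
#' @return list with \code{W1} (hidden x n_in), \code{Bias1} (hidden),
#'   \code{W2} (1 x hidden), \code{Bias2} (scalar).
#' @export
init_mlp <- function(seed, n_in = 10L, hidden = 10L) {
  .with_seed(seed, {
    list(W1 = matrix(stats::runif(hidden * n_in, -0.5, 0.5), hidden, n_in),
         Bias1 = stats::runif(hidden, -0.5, 0.5),
         W2 = matrix(stats::runif(hidden, -0.5, 0.5), 1L, hidden),
         Bias2 = stats::runif(1L, -0.5, 0.5))
  })
}

# pack/unpack the 121-parameter vector (column-major W1, Bias1, W2, Bias2)
.mlp_pack <- function(w) c(as.numeric(w$W1), w$Bias1, as.numeric(w$W2), w$Bias2)
.mlp_unpack <- function(theta, n_in, hidden) {
  i1 <- hidden * n_in
  list(W1 = matrix(theta[seq_len(i1)], hidden, n_in),
       Bias1 = theta[i1 + seq_len(hidden)],
       W2 = matrix(theta[i1 + hidden + seq_len(hidden)], 1L, hidden),
       Bias2 = theta[i1 + 2L * hidden + 1L])
}

# forward pass; returns scores (n) and hidden activations (n x hidden)
.mlp_forward <- function(w, X) {
  H <- tanh(sweep(X %*% t(w$W1), 2L, w$Bias1, `+`))
  list(y = as.numeric(H %*% t(w$W2)) + w$Bias2, H = H)
}

# Jacobian of the network output wrt all parameters, n x p
.mlp_jacobian <- function(w, X, H) {
  n <- nrow(X); hidden <- ncol(H); n_in <- ncol(X)
  G <- (1 - H^2) * matrix(w$W2, n, hidden, byrow = TRUE)   # dy/d(pre-act)
  J_W1 <- X[, rep(seq_len(n_in), each = hidden), drop = FALSE] *
    G[, rep(seq_len(hidden), times = n_in), drop = FALSE]
  cbind(J_W1, G, H, rep(1, n))
}

#' Fit a murmur-classifier neural network
#'
#' Trains a single-hidden-layer perceptron (tanh hidden units, linear output)
#' on 0/1 class targets by Levenberg-Marquardt: each iteration solves the
#' damped normal equations \eqn{(J'J + \mu I)\delta = J'r} of the mean
#' squared error and accepts the step only if the error decreases, adapting
#' the damping \eqn{\mu} up on rejection and down on acceptance. Features are
#' min-max scaled to \eqn{\pm 1} (fitted on the training rows) before they
#' reach the network.
#'
#' @param x numeric matrix (n x 10 by default) of features, or a data frame.
#' @param y numeric vector of 0/1 targets.
#' @param hidden hidden-layer size (default 10).
#' @param control a [mlp_control()] list.
#' @param scale logical; fit a \eqn{\pm 1} feature scaler on \code{x}
#'   (default TRUE). Disable when the caller scales externally.
#' @return an object of class \code{"pcg_mlp"} with components
#'   \code{weights}, \code{scaler}, \code{trace} (per-iteration MSE),
#'   \code{mse}, \code{iterations}, \code{status}
#'   (\code{"goal"}, \code{"max_iter"} or \code{"mu_overflow"}), and the
#'   training data dimensions.
#' @seealso [predict.pcg_mlp()], [pcg_jackknife()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 10), 40)
#' y <- as.numeric(x[, 1] + x[, 2] > 0)
#' fit <- pcg_mlp(x, y, control = mlp_control(max_iter = 50, seed = 3))
#' summary(fit)
#' @export
pcg_mlp <- function(x, y, hidden = 10L, control = mlp_control(), scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 training samples", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)))
    stop("non-finite values in training data", call. = FALSE)
  scaler <- NULL
  if (scale) {
    scaler <- fit_feature_scaler(x)
    x <- apply_feature_scaler(scaler, x)
  }
  w <- init_mlp(control$seed, n_in = ncol(x), hidden = hidden)
  theta <- .mlp_pack(w)
  mu <- control$mu_init
  fwd <- .mlp_forward(w, x)
  r <- fwd$y - y
  sse <- sum(r^2)
  n <- length(y)
  trace <- numeric(0)
  status <- "max_iter"
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    J <- .mlp_jacobian(w, x, fwd$H)
    g <- crossprod(J, r)
    A <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(solve(A + diag(mu, ncol(A)), g), error = function(e) NULL)
      if (!is.null(delta)) {
        theta_new <- theta - as.numeric(delta)
        w_new <- .mlp_unpack(theta_new, ncol(x), hidden)
        fwd_new <- .mlp_forward(w_new, x)
        r_new <- fwd_new$y - y
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new; w <- w_new; fwd <- fwd_new; r <- r_new
          sse <- sse_new
          mu <- mu / control$mu_factor
          accepted <- TRUE
        }
      }
      if (!accepted) {
        mu <- mu * control$mu_factor
        if (mu > control$mu_max) break
      }
    }
    trace <- c(trace, sse / n)
    if (!accepted) { status <- "mu_overflow"; break }
    if (sse / n <= control$goal_mse) { status <- "goal"; break }
  }
  structure(list(weights = w, scaler = scaler, trace = trace, mse = sse / n,
                 iterations = iter, status = status, hidden = hidden,
                 n_in = ncol(x), n_train = n, control = control,
                 fitted_scores = fwd$y, y = y),
            class = "pcg_mlp")
}

#' Predict murmur scores or labels
#'
#' The raw network output is a real score; labels apply the fixed decision
#' threshold: class 1 (murmur) when the score exceeds 0.5, class 0 (normal)
#' otherwise (a score of exactly 0.5 maps to 0).
#'
#' @param object a fitted [pcg_mlp()].
#' @param newdata matrix or data frame with the same columns as the training
#'   features (unscaled; the stored scaler is applied).
#' @param type \code{"label"} (default) or \code{"score"}.
#' @param ... unused.
#' @return numeric vector of scores or 0/1 labels.
#' @export
predict.pcg_mlp <- function(object, newdata, type = c("label", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (ncol(X) != object$n_in)
    stop("expected ", object$n_in, " feature columns, got ", ncol(X), call. = FALSE)
  if (!is.null(object$scaler)) X <- apply_feature_scaler(object$scaler, X)
  score <- .mlp_forward(object$weights, X)$y
  if (type == "score") score else as.numeric(score > 0.5)
}

#' @export
print.pcg_mlp <- function(x, ...) {
  cat(sprintf("Murmur classifier: %d-%d-1 perceptron (tanh/linear), Levenberg-Marquardt\n",
              x$n_in, x$hidden))
  cat(sprintf("  trained on %d samples; %d iterations, MSE %.3g (%s)\n",
              x$n_train, x$iterations, x$mse, x$status))
  invisible(x)
}

#' @export
summary.pcg_mlp <- function(object, ...) {
  lab <- as.numeric(object$fitted_scores > 0.5)
  structure(list(model = object,
                 train_accuracy = 100 * mean(lab == object$y)),
            class = "summary.pcg_mlp")
}

#' @export
print.summary.pcg_mlp <- function(x, ...) {
  print(x$model)
  cat(sprintf("  apparent (training) accuracy: %.1f%%\n", x$train_accuracy))
  invisible(x)
}

#' @export
coef.pcg_mlp <- function(object, ...) object$weights

#' @export
residuals.pcg_mlp <- function(object, ...) object$y - object$fitted_scores

#' @export
fitted.pcg_mlp <- function(object, ...) object$fitted_scores

#' @export
plot.pcg_mlp <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", log = "y",
       xlab = "iteration", ylab = "MSE", ...)
  graphics::abline(h = x$control$goal_mse, lty = 2)
  invisible(x)
}

#' Fit a per-feature min-max scaler to \eqn{\pm 1}
#'
#' @param x numeric training matrix.
#' @return list of class \code{"feature_scaler"} with per-column center and
#'   half-range. Constant columns map to 0 (with a warning on application).
#' @export
fit_feature_scaler <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  structure(list(center = (lo + hi) / 2, half = (hi - lo) / 2),
            class = "feature_scaler")
}

#' Apply a fitted feature scaler
#'
#' Values outside the training range extrapolate beyond \eqn{\pm 1} linearly.
#'
#' @param scaler a [fit_feature_scaler()] result.
#' @param x matrix to transform.
#' @return scaled matrix.
#' @export
apply_feature_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  const <- scaler$half == 0
  if (any(const)) warning("constant feature column(s) mapped to 0", call. = FALSE)
  half <- ifelse(const, 1, scaler$half)
  out <- sweep(sweep(x, 2L, scaler$center, `-`), 2L, half, `/`)
  out[, const] <- 0
  out
}
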