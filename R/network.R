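# The feed-forward regressor: a small multilayer perceptron (default
# 5-12-10-8-4, tanh hidden layers, identity output) whose parameters are fit
# by the Levenberg-Marquardt trainer in lm.R. Everything here is written
# from scratch: the damped Gauss-Newton update on the residual Jacobian is
# the method this package exists to provide.

#' Training configuration
#'
#' Defaults are the tuned operating point of the prescription model:
#' eta/beta drive only the plain gradient-descent fallback (`method = "gd"`
#' in [train_network()]); the LM update has no learning rate or momentum.
#'
#' @param eta learning rate (gradient-descent fallback only).
#' @param beta momentum factor (gradient-descent fallback only).
#' @param alpha L2 regularization coefficient on weights (biases excluded
#'   unless `penalize_bias`).
#' @param lambda0 initial LM damping factor.
#' @param fd_step finite-difference Jacobian step.
#' @param error_precision training-MSE goal; training stops when reached.
#' @param patience early-stopping epochs without validation improvement.
#' @param max_epochs epoch cap.
#' @param display_interval logging cadence in epochs.
#' @param jacobian `"analytic"` (reverse accumulation) or `"fd"`.
#' @param penalize_bias include biases in the L2 penalty (off by default;
#'   penalizing output offsets is rarely wanted).
#' @param lambda_min,lambda_max damping bounds.
#' @return a `train_config` list.
#' @export
train_config <- function(eta = 0.01, beta = 0.9, alpha = 0.001,
                         lambda0 = 0.01, fd_step = 1e-5,
                         error_precision = 1e-7, patience = 10,
                         max_epochs = 1000, display_interval = 25,
                         jacobian = c("analytic", "fd"),
                         penalize_bias = FALSE,
                         lambda_min = 1e-12, lambda_max = 1e12) {
  jacobian <- match.arg(jacobian)
  stopifnot(eta > 0, beta > 0, alpha >= 0, lambda0 > 0, fd_step > 0,
            error_precision > 0, patience >= 1, max_epochs >= 1)
  structure(list(eta = eta, beta = beta, alpha = alpha, lambda0 = lambda0,
                 fd_step = fd_step, error_precision = error_precision,
                 patience = patience, max_epochs = max_epochs,
                 display_interval = display_interval, jacobian = jacobian,
                 penalize_bias = penalize_bias,
                 lambda_min = lambda_min, lambda_max = lambda_max),
            class = "train_config")
}

#' Candidate hidden-layer widths from the empirical sizing rule
#'
#' The classical rule n1 = round(sqrt(n + m)) + a for a small integer
#' offset a: with 5 inputs and 4 outputs and a in 1..10 this yields widths
#' 4 through 13.
#'
#' @param n_inputs,n_outputs input/output dimensions.
#' @param a_range integer offsets, a subset of 1..10.
#' @return integer vector of candidate widths, increasing in `a`.
#' @export
hidden_neuron_range <- function(n_inputs = 5, n_outputs = 4, a_range = 1:10) {
  stopifnot(all(a_range == as.integer(a_range)),
            all(a_range >= 1), all(a_range <= 10))
  as.integer(round(sqrt(n_inputs + n_outputs)) + a_range)
}

#' Initialize a feed-forward network
#'
#' Weights are symmetric-uniform with fan-in scaling (a Nguyen-Widrow-like
#' range), biases zero. Hidden activation is tanh by default; the output
#' layer is linear.
#'
#' @param sizes layer widths, input first, output last (default the
#'   5-12-10-8-4 prescription architecture).
#' @param seed integer seed for the weight draw.
#' @param activation hidden activation, `"tanh"` or `"identity"`.
#' @param init_scale multiplier on the fan-in-scaled init range.
#' @return a `fitt_network`.
#' @export
init_network <- function(sizes = c(5, 12, 10, 8, 4), seed = 1,
                         activation = c("tanh", "identity"),
                         init_scale = 1) {
  activation <- match.arg(activation)
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- init_scale * 0.7 * sqrt(3 / sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(sizes = sizes, W = W, b = b, activation = activation,
                 input_scale = NULL, seed = seed),
            class = "fitt_network")
}

#' @export
print.fitt_network <- function(x, ...) {
  cat(sprintf("Feed-forward network %s (%d parameters, %s hidden units%s)\n",
              paste(x$sizes, collapse = "-"), n_params(x), x$activation,
              if (is.null(x$input_scale)) "" else ", min-max input scaling"))
  invisible(x)
}

#' Attach min-max input scaling to a network
#'
#' Optional preprocessing (off by default: the coding layer is otherwise the
#' only input scaling). When attached, inputs are mapped feature-wise to
#' `[-1, 1]` using the ranges of the supplied training matrix before every
#' forward pass; the mapping travels with the network, so prediction and
#' prescription use the training ranges.
#'
#' @param net a `fitt_network`.
#' @param x training input matrix whose column ranges define the map.
#' @return the network with scaling attached.
#' @export
attach_input_scaling <- function(net, x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant feature maps to -1, harmless
  net$input_scale <- list(lo = lo, span = span)
  net
}

scale_input <- function(net, x) {
  if (is.null(net$input_scale)) return(x)
  s <- net$input_scale
  sweep(sweep(x, 2, s$lo), 2, s$span, "/") * 2 - 1
}

# total parameter count: sum over layers of (fan_in + 1) * fan_out
n_params <- function(net) {
  sum(vapply(seq_along(net$W),
             function(l) length(net$W[[l]]) + length(net$b[[l]]), numeric(1)))
}

# flatten parameters layer by layer: vec(W_l) then b_l
flatten_params <- function(net) {
  unlist(lapply(seq_along(net$W),
                function(l) c(as.vector(net$W[[l]]), net$b[[l]])),
         use.names = FALSE)
}

# inverse of flatten_params
set_params <- function(net, w) {
  pos <- 0
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]] <- matrix(w[pos + seq_len(nw)], nrow(net$W[[l]]),
                         ncol(net$W[[l]]))
    pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]] <- w[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}

# logical mask over the flattened vector: TRUE for weights, FALSE for biases
weight_mask <- function(net) {
  unlist(lapply(seq_along(net$W), function(l) {
    c(rep(TRUE, length(net$W[[l]])), rep(FALSE, length(net$b[[l]])))
  }), use.names = FALSE)
}

act_fun <- function(net) {
  if (net$activation == "tanh") tanh else identity
}

act_deriv <- function(net, a) {
  if (net$activation == "tanh") 1 - a^2 else matrix(1, nrow(a), ncol(a))
}

# full forward pass keeping layer activations (for backprop); x is n x p
forward_pass <- function(net, x) {
  a <- list(scale_input(net, x))
  L <- length(net$W)
  f <- act_fun(net)
  for (l in seq_len(L)) {
    z <- a[[l]] %*% net$W[[l]] +
      matrix(net$b[[l]], nrow(a[[l]]), length(net$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l < L) f(z) else z  # identity output layer
  }
  a
}

#' Evaluate the network
#'
#' @param net a `fitt_network`.
#' @param x input matrix (n x p) or a single input vector.
#' @return prediction matrix (n x m), or a vector for vector input.
#' @export
forward <- function(net, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  if (any(!is.finite(x))) stop("network input must be finite")
  if (ncol(x) != net$sizes[1]) {
    stop("input has ", ncol(x), " columns; network expects ", net$sizes[1])
  }
  out <- forward_pass(net, x)[[length(net$W) + 1]]
  if (vec) drop(out) else out
}

#' Regularized network loss
#'
#' The training objective: mean squared error over all samples and output
#' dimensions jointly, plus `alpha` times the sum of squared weights
#' (biases excluded by default).
#'
#' @param net a `fitt_network`.
#' @param x,y input and target matrices.
#' @param alpha L2 coefficient.
#' @param penalize_bias include biases in the penalty.
#' @return list with `mse`, `penalty`, `total = mse + penalty`.
#' @export
network_loss <- function(net, x, y, alpha = 0, penalize_bias = FALSE) {
  if (length(y) == 0) stop("empty data")
  pred <- forward(net, x)
  mse <- mean((pred - y)^2)
  w <- flatten_params(net)
  if (!penalize_bias) w <- w[weight_mask(net)]
  penalty <- alpha * sum(w^2)
  structure(list(mse = mse, penalty = penalty, total = mse + penalty),
            class = "loss_parts")
}

#' Jacobian of the residual vector with respect to the parameters
#'
#' Residuals are `e[(i-1)*m + o] = pred[i, o] - y[i, o]` (sample-major, one
#' row per sample-output pair). The analytic mode runs one reverse
#' accumulation per output dimension, vectorized over samples; the
#' finite-difference mode perturbs each parameter by `fd_step` (forward
#' differences).
#'
#' @param net a `fitt_network`.
#' @param x,y input and target matrices.
#' @param mode `"analytic"` or `"fd"`.
#' @param fd_step finite-difference step.
#' @return list with `J` (n*m x n_params) and residual vector `e`.
#' @export
network_jacobian <- function(net, x, y, mode = c("analytic", "fd"),
                             fd_step = 1e-5) {
  mode <- match.arg(mode)
  n <- nrow(x); m <- net$sizes[length(net$sizes)]
  if (mode == "fd") {
    w0 <- flatten_params(net)
    e0 <- as.vector(t(forward(net, x) - y))
    J <- matrix(0, n * m, length(w0))
    for (k in seq_along(w0)) {
      wk <- w0
      wk[k] <- wk[k] + fd_step
      ek <- as.vector(t(forward(set_params(net, wk), x) - y))
      J[, k] <- (ek - e0) / fd_step
    }
    return(list(J = J, e = e0))
  }
  a <- forward_pass(net, x)
  L <- length(net$W)
  pred <- a[[L + 1]]
  e <- as.vector(t(pred - y))
  J <- matrix(0, n * m, n_params(net))
  for (o in seq_len(m)) {
    rows <- (seq_len(n) - 1) * m + o
    # delta at the (linear) output layer: basis vector for output o
    delta <- matrix(0, n, m)
    delta[, o] <- 1
    deltas <- vector("list", L)
    deltas[[L]] <- delta
    for (l in rev(seq_len(L - 1))) {
      deltas[[l]] <- (deltas[[l + 1]] %*% t(net$W[[l + 1]])) *
        act_deriv(net, a[[l + 1]])
    }
    pos <- 0
    for (l in seq_len(L)) {
      fin <- nrow(net$W[[l]]); fout <- ncol(net$W[[l]])
      # dE/dW_l[i, j] per sample = a_{l-1}[, i] * delta_l[, j], laid out
      # column-major to match flatten_params
      Jw <- a[[l]][, rep(seq_len(fin), times = fout), drop = FALSE] *
        deltas[[l]][, rep(seq_len(fout), each = fin), drop = FALSE]
      J[rows, pos + seq_len(fin * fout)] <- Jw
      pos <- pos + fin * fout
      J[rows, pos + seq_len(fout)] <- deltas[[l]]
      pos <- pos + fout
    }
  }
  list(J = J, e = e)
}

#' Save / load a network checkpoint as JSON
#'
#' Stores layer sizes, flattened parameters, activation, input scaling and
#' the training seed; text-only and round-trip exact at full double
#' precision.
#'
#' @param net a `fitt_network` (or a `fitt_fit`, whose network is saved).
#' @param path JSON file path.
#' @param extra optional named list merged into the checkpoint (e.g. seed,
#'   config hash).
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` the
#'   network.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  if (inherits(net, "fitt_fit")) net <- net$network
  payload <- c(list(
    sizes = net$sizes, activation = net$activation,
    params = flatten_params(net),
    input_scale = net$input_scale, seed = net$seed
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- init_network(p$sizes, seed = if (is.null(p$seed)) 1 else p$seed,
                      activation = p$activation)
  net <- set_params(net, p$params)
  if (!is.null(p$input_scale)) {
    net$input_scale <- list(lo = as.numeric(p$input_scale$lo),
                            span = as.numeric(p$input_scale$span))
  }
  net
}
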