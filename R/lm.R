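# Levenberg-Marquardt trainer: damped Gauss-Newton steps
#   delta_w = (J'J + lambda I)^-1 J'e
# on the residual Jacobian, with the L2 penalty folded into the normal
# equations exactly (Gauss-Newton treatment of L = MSE + alpha * sum w^2),
# adaptive damping (decrease on acceptance, increase on rejection), and
# validation-based early stopping. A plain gradient-descent trainer with
# momentum is kept as the traditional back-propagation baseline; it is the
# only consumer of eta and beta.

#' One Levenberg-Marquardt update
#'
#' Forms the damped regularized normal equations from the residual Jacobian
#' and proposes `w - delta_w`. If the candidate lowers the regularized loss
#' the step is accepted and the damping factor shrinks (x0.1); otherwise the
#' damping grows (x10) and the solve is retried, up to the damping ceiling.
#' Accepted steps therefore never increase the loss; a singular system at
#' small damping is handled by the damping increase, never by failure.
#'
#' @param net a `fitt_network`.
#' @param x,y training matrices.
#' @param config a [train_config()].
#' @param lambda current damping factor.
#' @return list with `network`, `lambda`, `accepted`, `loss`
#'   (a `loss_parts` for the returned network) and `n_tries`.
#' @export
lm_step <- function(net, x, y, config = train_config(),
                    lambda = config$lambda0) {
  stopifnot(lambda > 0)
  nm <- length(y)
  jac <- network_jacobian(net, x, y, mode = config$jacobian,
                          fd_step = config$fd_step)
  w <- flatten_params(net)
  mask <- if (config$penalize_bias) rep(TRUE, length(w)) else weight_mask(net)
  # scale so that r'r = MSE; penalty enters as alpha * D with D = diag(mask)
  Jr <- jac$J / sqrt(nm)
  r <- jac$e / sqrt(nm)
  A0 <- crossprod(Jr)
  diag(A0) <- diag(A0) + config$alpha * mask
  g <- crossprod(Jr, r) + config$alpha * (mask * w)
  loss0 <- network_loss(net, x, y, config$alpha, config$penalize_bias)
  n_tries <- 0L
  repeat {
    n_tries <- n_tries + 1L
    A <- A0
    diag(A) <- diag(A) + lambda
    delta <- tryCatch(solve(A, g), error = function(e) NULL)
    if (!is.null(delta) && all(is.finite(delta))) {
      cand <- set_params(net, w - as.vector(delta))
      loss1 <- network_loss(cand, x, y, config$alpha, config$penalize_bias)
      if (is.finite(loss1$total) && loss1$total <= loss0$total) {
        return(list(network = cand,
                    lambda = max(lambda * 0.1, config$lambda_min),
                    accepted = TRUE, loss = loss1, n_tries = n_tries))
      }
    }
    lambda <- lambda * 10
    if (lambda > config$lambda_max) {
      return(list(network = net, lambda = config$lambda_max,
                  accepted = FALSE, loss = loss0, n_tries = n_tries))
    }
  }
}

#' Train a network
#'
#' Full-batch training with the Levenberg-Marquardt update (default) or the
#' plain gradient-descent-with-momentum baseline. One epoch is one accepted
#' (or retry-exhausted) full-batch update. Training stops at the epoch cap,
#' when training MSE reaches `error_precision`, or when the validation loss
#' has not improved for `patience` consecutive epochs; the returned network
#' is the best-validation snapshot.
#'
#' @param net an initialized `fitt_network`.
#' @param x,y training matrices (disjoint from validation).
#' @param x_val,y_val optional validation matrices for early stopping.
#' @param config a [train_config()].
#' @param method `"lm"` or `"gd"`.
#' @param verbose print the training trace every `display_interval` epochs.
#' @return a `fitt_fit`: `network` (best snapshot), `final_network`,
#'   `history` data frame (epoch, train_mse, val_mse, lambda), `stopped`
#'   reason, `epochs`, `config`, `method`.
#' @export
train_network <- function(net, x, y, x_val = NULL, y_val = NULL,
                          config = train_config(),
                          method = c("lm", "gd"), verbose = FALSE) {
  method <- match.arg(method)
  has_val <- !is.null(x_val)
  lambda <- config$lambda0
  velocity <- numeric(n_params(net))
  best_net <- net
  best_val <- Inf
  since_improve <- 0L
  hist <- vector("list", config$max_epochs)
  stopped <- "max_epochs"
  epoch <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    if (method == "lm") {
      st <- lm_step(net, x, y, config, lambda)
      net <- st$network
      lambda <- st$lambda
      train_mse <- st$loss$mse
      if (!st$accepted) {
        stopped <- "plateau"
      }
    } else {
      jac <- network_jacobian(net, x, y, mode = config$jacobian,
                              fd_step = config$fd_step)
      w <- flatten_params(net)
      mask <- if (config$penalize_bias) rep(TRUE, length(w)) else weight_mask(net)
      grad <- 2 * crossprod(jac$J, jac$e) / length(y) +
        2 * config$alpha * (mask * w)
      velocity <- config$beta * velocity - config$eta * as.vector(grad)
      net <- set_params(net, w + velocity)
      train_mse <- network_loss(net, x, y)$mse
    }
    if (!is.finite(train_mse)) {
      stop("training diverged at epoch ", epoch, " (non-finite loss)")
    }
    val_mse <- if (has_val) network_loss(net, x_val, y_val)$mse else train_mse
    hist[[epoch]] <- c(epoch = epoch, train_mse = train_mse,
                       val_mse = val_mse, lambda = lambda)
    if (verbose && epoch %% config$display_interval == 0) {
      message(sprintf("epoch %4d  train MSE %.3e  val MSE %.3e  lambda %.1e",
                      epoch, train_mse, val_mse, lambda))
    }
    if (val_mse < best_val) {
      best_val <- val_mse
      best_net <- net
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    if (train_mse <= config$error_precision) {
      stopped <- "goal"
      break
    }
    if (since_improve >= config$patience) {
      stopped <- "patience"
      break
    }
    if (stopped == "plateau") break
  }
  history <- as.data.frame(do.call(rbind, hist[seq_len(epoch)]))
  structure(list(network = best_net, final_network = net, history = history,
                 stopped = stopped, epochs = epoch, best_val_mse = best_val,
                 config = config, method = method),
            class = "fitt_fit")
}

#' @export
print.fitt_fit <- function(x, ...) {
  cat(sprintf(
    "Trained network %s (%s): %d epochs, stopped on %s, best val MSE %.4g\n",
    paste(x$network$sizes, collapse = "-"), x$method, x$epochs, x$stopped,
    x$best_val_mse))
  invisible(x)
}
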