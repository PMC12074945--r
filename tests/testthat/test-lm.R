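test_that("one LM step with small damping solves the linear least-squares problem", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 5), n)
  Y <- X %*% matrix(rnorm(20), 5, 4) + rnorm(n * 4, 0, 0.3)
  net <- init_network(c(5, 4), seed = 2, activation = "identity")
  st <- lm_step(net, X, Y, train_config(alpha = 0, lambda0 = 1e-10))
  expect_true(st$accepted)
  # closed-form normal-equation oracle on the bias-augmented design
  Xa <- cbind(X, 1)
  A <- solve(crossprod(Xa), crossprod(Xa, Y))
  fitted <- rbind(st$network$W[[1]], st$network$b[[1]])
  expect_lt(max(abs(fitted - A)), 1e-8)
})

test_that("trained linear model matches penalty-matched ridge closed form", {
  set.seed(6)
  n <- 50
  X <- matrix(rnorm(n * 5), n)
  Y <- X %*% matrix(rnorm(20), 5, 4) + rnorm(n * 4, 0, 0.2)
  alpha <- 0.01
  net <- init_network(c(5, 4), seed = 3, activation = "identity")
  fit <- train_network(net, X, Y,
                       config = train_config(alpha = alpha, max_epochs = 100,
                                             patience = 100,
                                             error_precision = 1e-12))
  # ridge oracle: (Xa'Xa/(nm) + alpha D) A = Xa'Y/(nm), biases unpenalized
  Xa <- cbind(X, 1)
  D <- diag(c(rep(1, 5), 0))
  A <- solve(crossprod(Xa) / (n * 4) + alpha * D, crossprod(Xa, Y) / (n * 4))
  fitted <- rbind(fit$final_network$W[[1]], fit$final_network$b[[1]])
  expect_lt(max(abs(fitted - A)), 1e-6)
})

test_that("very large damping degenerates to a scaled gradient step", {
  net <- init_network(c(3, 5, 2), seed = 4)
  x <- matrix(rnorm(30), 10, 3)
  y <- matrix(rnorm(20), 10, 2)
  cfg <- train_config(alpha = 0, lambda_max = 1e30)
  lambda <- 1e12
  jac <- network_jacobian(net, x, y, "analytic")
  g <- crossprod(jac$J / sqrt(length(y)), jac$e / sqrt(length(y)))
  st <- lm_step(net, x, y, cfg, lambda = lambda)
  delta <- fittnet:::flatten_params(net) -
    fittnet:::flatten_params(st$network)
  # direction matches J'e; magnitude ~ |g|/lambda
  cosine <- sum(delta * g) / sqrt(sum(delta^2) * sum(g^2))
  expect_gt(cosine, 1 - 1e-6)
  expect_equal(sqrt(sum(delta^2)), sqrt(sum(g^2)) / lambda, tolerance = 1e-3)
})

test_that("accepted LM steps never increase the regularized loss", {
  surf <- synth_response_surface(80, seed = 31, noise_sd = 0.3)
  net <- init_network(seed = 17)
  net <- attach_input_scaling(net, surf$x)
  cfg <- train_config(alpha = 0.001, max_epochs = 40, patience = 40)
  lambda <- cfg$lambda0
  prev <- network_loss(net, surf$x, surf$y, cfg$alpha)$total
  for (i in 1:15) {
    st <- lm_step(net, surf$x, surf$y, cfg, lambda)
    if (!st$accepted) break
    total <- st$loss$total + 0  # regularized loss of the accepted candidate
    expect_lte(total, prev)
    expect_gt(st$lambda, 0)
    expect_lte(st$lambda, cfg$lambda_max)
    prev <- total
    net <- st$network
    lambda <- st$lambda
  }
})

test_that("rank-deficient problems are handled by damping, never a crash", {
  # duplicated feature makes J'J singular at lambda -> 0
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  X <- cbind(X, X[, 1])
  Y <- matrix(X[, 1] + X[, 2], 10, 1)
  net <- init_network(c(3, 1), seed = 1, activation = "identity")
  st <- lm_step(net, X, Y, train_config(alpha = 0, lambda0 = 1e-12))
  expect_true(st$accepted)
  expect_true(all(is.finite(fittnet:::flatten_params(st$network))))
})

test_that("training on a noise-free realizable surface reaches tiny MSE", {
  surf <- teacher_surface()
  net <- init_network(seed = 11)
  net <- attach_input_scaling(net, surf$x)
  cfg <- train_config(alpha = 0, max_epochs = 200, patience = 200,
                      error_precision = 1e-8)
  fit <- train_network(net, surf$x, surf$y, config = cfg)
  expect_lt(tail(fit$history$train_mse, 1), 1e-6)
  expect_true(all(diff(fit$history$train_mse) <= 1e-12))
  expect_equal(fit$stopped, "goal")
})

test_that("training is deterministic under fixed seeds", {
  surf <- synth_response_surface(60, seed = 3, noise_sd = 0.2)
  run <- function() {
    net <- init_network(seed = 5)
    net <- attach_input_scaling(net, surf$x)
    train_network(net, surf$x, surf$y,
                  config = train_config(max_epochs = 15, patience = 15))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(fittnet:::flatten_params(f1$network),
                   fittnet:::flatten_params(f2$network))
})

test_that("early stopping halts after patience epochs without improvement", {
  surf <- synth_response_surface(60, seed = 9, noise_sd = 0.5)
  net <- init_network(seed = 2)
  net <- attach_input_scaling(net, surf$x)
  # validation = training: stops only when training loss itself plateaus
  fit <- train_network(net, surf$x, surf$y, surf$x, surf$y,
                       config = train_config(patience = 1, max_epochs = 300))
  expect_true(fit$stopped %in% c("patience", "plateau", "goal"))
  # best snapshot has the minimal validation MSE seen
  expect_equal(fit$best_val_mse, min(fit$history$val_mse))
  # held-out validation with small patience stops early
  idx <- 1:40
  fit2 <- train_network(net, surf$x[idx, ], surf$y[idx, ],
                        surf$x[-idx, ], surf$y[-idx, ],
                        config = train_config(patience = 3, max_epochs = 300))
  expect_lt(fit2$epochs, 300)
})

test_that("the gradient-descent fallback uses eta/beta and descends", {
  set.seed(10)
  X <- matrix(rnorm(80), 40, 2)
  Y <- matrix(tanh(X[, 1]) - 0.5 * X[, 2], 40, 1)
  net <- init_network(c(2, 4, 1), seed = 3)
  cfg <- train_config(eta = 0.05, beta = 0.9, alpha = 0,
                      max_epochs = 200, patience = 200)
  fit <- train_network(net, X, Y, config = cfg, method = "gd")
  expect_lt(tail(fit$history$train_mse, 1), fit$history$train_mse[1])
  # eta matters for gd (unlike lm): different eta, different trajectory
  cfg2 <- cfg
  cfg2$eta <- 0.01
  fit2 <- train_network(init_network(c(2, 4, 1), seed = 3), X, Y,
                        config = cfg2, method = "gd")
  expect_false(identical(fit$history$train_mse, fit2$history$train_mse))
})
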