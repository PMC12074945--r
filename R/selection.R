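# Dataset partitioning, hyperparameter grid search and the nested 10x10
# cross-validation harness with per-fold weight reinitialization.

#' Printed-convention split sizes
#'
#' The 80/10/10 partition by floor division, the arithmetic that reproduces
#' the published counts (e.g. 1,594 -> 1,275 / 159 / 159, which drops one
#' sample). The operational splitter [make_splits()] keeps every sample;
#' this function exists to state the printed convention.
#'
#' @param n_total total sample count, at least 10.
#' @return named integer vector `(train, validation, test)`.
#' @export
published_split_sizes <- function(n_total) {
  if (n_total < 10) stop("need at least 10 samples for an 80/10/10 split")
  c(train = floor(0.8 * n_total),
    validation = floor(0.1 * n_total),
    test = floor(0.1 * n_total))
}

#' Partition samples into k balanced segments
#'
#' Seeded shuffle followed by contiguous segmentation; segment sizes differ
#' by at most one and no sample is dropped (remainders land in the earliest
#' segments, which the role assignment gives to training).
#'
#' @param n number of samples (or a `fitt_corpus`).
#' @param seed integer seed.
#' @param k number of segments (default 10).
#' @return a `split_plan`: list with `fold` (segment id per sample, in
#'   original sample order), `k`, `seed`.
#' @export
make_splits <- function(n, seed, k = 10) {
  if (inherits(n, "fitt_corpus")) n <- nrow(n$x)
  stopifnot(n >= k, k >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, "splits"))
  ord <- sample.int(n)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k), times = sizes)
  structure(list(fold = fold, k = k, seed = seed), class = "split_plan")
}

#' Segment roles for one round: 8 train, 1 validation, 1 test
#'
#' @param plan a [make_splits()] plan.
#' @param test_fold segment held out for testing.
#' @param val_fold segment used for early stopping (defaults to the segment
#'   after `test_fold`, cyclically).
#' @return list of index vectors `train`, `validation`, `test`.
#' @export
split_roles <- function(plan, test_fold = plan$k,
                        val_fold = test_fold %% plan$k + 1) {
  stopifnot(test_fold != val_fold)
  list(train = which(!plan$fold %in% c(test_fold, val_fold)),
       validation = which(plan$fold == val_fold),
       test = which(plan$fold == test_fold))
}

#' Hyperparameter grid
#'
#' Defaults are the candidate sets tuned over: learning rate
#' {0.001, 0.01, 0.1}, momentum {0.5, 0.7, 0.9}, L2 coefficient
#' {0, 0.001, 0.01}.
#'
#' @param eta,beta,alpha candidate vectors.
#' @return a `grid_spec` data frame of all combinations, ordered by alpha
#'   then eta then beta (the tie-break order).
#' @export
grid_spec <- function(eta = c(0.001, 0.01, 0.1),
                      beta = c(0.5, 0.7, 0.9),
                      alpha = c(0, 0.001, 0.01)) {
  stopifnot(length(eta) > 0, length(beta) > 0, length(alpha) > 0)
  g <- expand.grid(eta = eta, beta = beta, alpha = alpha,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$alpha, g$eta, g$beta), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("grid_spec", "data.frame")
  g
}

#' Grid search by inner-validation RMSE
#'
#' Trains every grid configuration on each inner train/validation split and
#' returns the configuration with the smallest mean validation RMSE. Exact
#' ties go to the smaller alpha, then the smaller eta (the grid is already
#' ordered that way, so the first minimum wins). A grid of size one is
#' returned without training.
#'
#' @param x,y data matrices (the outer-training portion only).
#' @param grid a [grid_spec()].
#' @param inner_plan a [make_splits()] plan over `nrow(x)`.
#' @param base_config [train_config()] whose eta/beta/alpha are overridden
#'   per grid row (use a reduced `max_epochs` here to keep search cheap).
#' @param sizes network architecture.
#' @param seed seed for per-evaluation weight initialization.
#' @param n_inner_rounds how many of the inner folds to actually rotate
#'   through (defaults to all; fewer keeps the search cheap).
#' @param method training method passed to [train_network()].
#' @return list with `best` (one grid row), `config` (base config with the
#'   winners filled in), `results` (per-configuration mean RMSE).
#' @export
grid_search <- function(x, y, grid, inner_plan, base_config = train_config(),
                        sizes = c(5, 12, 10, 8, 4), seed = 1,
                        n_inner_rounds = inner_plan$k, method = "lm") {
  stopifnot(nrow(grid) >= 1)
  if (nrow(grid) == 1) {
    cfg <- override_config(base_config, grid[1, ])
    return(list(best = grid[1, ], config = cfg,
                results = cbind(grid, mean_rmse = NA_real_)))
  }
  rounds <- seq_len(n_inner_rounds)
  scores <- matrix(NA_real_, nrow(grid), length(rounds))
  for (g in seq_len(nrow(grid))) {
    cfg <- override_config(base_config, grid[g, ])
    for (r in rounds) {
      roles <- split_roles(inner_plan, test_fold = r)
      # inner criterion is validation RMSE, so train on the train segments
      # and score the held-out validation segment
      # one init per inner round, shared across configurations, so grid
      # comparisons differ only in the hyperparameters
      net <- init_network(sizes, seed = child_seed(seed, r))
      if (!is.null(attr(x, "input_scaling")) &&
          identical(attr(x, "input_scaling"), "minmax")) {
        net <- attach_input_scaling(net, x[roles$train, , drop = FALSE])
      }
      fit <- train_network(net, x[roles$train, , drop = FALSE],
                           y[roles$train, , drop = FALSE],
                           x[roles$validation, , drop = FALSE],
                           y[roles$validation, , drop = FALSE],
                           config = cfg, method = method)
      pred <- forward(fit$network, x[roles$validation, , drop = FALSE])
      scores[g, r] <- sqrt(mean((pred - y[roles$validation, , drop = FALSE])^2))
    }
  }
  mean_rmse <- rowMeans(scores)
  if (all(!is.finite(mean_rmse))) {
    stop("grid search failed: every configuration diverged")
  }
  best_i <- which.min(mean_rmse)  # grid pre-ordered by alpha, eta, beta
  list(best = grid[best_i, ],
       config = override_config(base_config, grid[best_i, ]),
       results = cbind(grid, mean_rmse = mean_rmse))
}

override_config <- function(config, row) {
  config$eta <- row$eta
  config$beta <- row$beta
  config$alpha <- row$alpha
  config
}

#' Nested cross-validation
#'
#' Outer loop: `k_outer` folds for train/test splits; inner loop:
#' `k_inner` folds over each outer-training portion for hyperparameter
#' selection by grid search. For each outer fold the weights are
#' reinitialized from a fresh child seed (never carried over), the
#' inner-loop winner is retrained on the outer-training portion (with one
#' inner segment as the early-stopping validation set), and the held-out
#' fold is predicted. Per-round RMSE, MAE and R-squared are computed on
#' the encoded 4-dimensional outputs jointly (all residuals pooled).
#'
#' @param x,y full data matrices.
#' @param grid a [grid_spec()].
#' @param seed root seed (splits and weight draws flow from it).
#' @param k_outer,k_inner fold counts (default 10 and 10).
#' @param base_config [train_config()] for the final per-fold training.
#' @param inner_config [train_config()] for inner-loop training (defaults
#'   to `base_config` with a quarter of the epoch budget).
#' @param sizes network architecture.
#' @param n_inner_rounds inner folds actually rotated in the grid search.
#' @param method training method.
#' @param input_scaling `"none"` or `"minmax"` (fit on each training
#'   portion only).
#' @return a `cv_result`: `rounds` data frame (round, rmse, mae, r2,
#'   eta, beta, alpha), `mean` and `best` summary rows (best = minimum
#'   RMSE round), and the seed.
#' @export
nested_cv <- function(x, y, grid = grid_spec(), seed = 1,
                      k_outer = 10, k_inner = 10,
                      base_config = train_config(),
                      inner_config = NULL,
                      sizes = c(5, 12, 10, 8, 4),
                      n_inner_rounds = 2, method = "lm",
                      input_scaling = c("none", "minmax")) {
  input_scaling <- match.arg(input_scaling)
  n <- nrow(x)
  if (n < 10 * k_outer) stop("corpus too small for ", k_outer, "-fold nested CV")
  if (is.null(inner_config)) {
    inner_config <- base_config
    inner_config$max_epochs <- max(5, base_config$max_epochs %/% 4)
  }
  outer <- make_splits(n, child_seed(seed, "outer"), k = k_outer)
  rounds <- vector("list", k_outer)
  for (fold in seq_len(k_outer)) {
    test_idx <- which(outer$fold == fold)
    rest_idx <- which(outer$fold != fold)
    # structural no-leakage guarantee: the held-out fold never reaches the
    # inner loop
    stopifnot(length(intersect(test_idx, rest_idx)) == 0)
    xr <- x[rest_idx, , drop = FALSE]
    yr <- y[rest_idx, , drop = FALSE]
    attr(xr, "input_scaling") <- input_scaling
    inner <- make_splits(length(rest_idx),
                         child_seed(seed, paste0("inner-", fold)),
                         k = k_inner)
    gs <- grid_search(xr, yr, grid, inner, inner_config, sizes,
                      seed = child_seed(seed, paste0("gs-", fold)),
                      n_inner_rounds = n_inner_rounds, method = method)
    # final training on the outer-training portion: last inner segment
    # serves as the early-stopping validation set
    roles <- split_roles(inner, test_fold = k_inner,
                         val_fold = k_inner - 1)
    tr <- c(roles$train, roles$test)
    cfg <- gs$config
    cfg$max_epochs <- base_config$max_epochs
    net <- init_network(sizes, seed = child_seed(seed, paste0("init-", fold)))
    if (input_scaling == "minmax") {
      net <- attach_input_scaling(net, xr[tr, , drop = FALSE])
    }
    fit <- train_network(net, xr[tr, , drop = FALSE], yr[tr, , drop = FALSE],
                         xr[roles$validation, , drop = FALSE],
                         yr[roles$validation, , drop = FALSE],
                         config = cfg, method = method)
    pred <- forward(fit$network, x[test_idx, , drop = FALSE])
    ms <- metric_set(pred, y[test_idx, , drop = FALSE])
    rounds[[fold]] <- data.frame(round = fold, rmse = ms$rmse, mae = ms$mae,
                                 r2 = ms$r2, eta = gs$best$eta,
                                 beta = gs$best$beta, alpha = gs$best$alpha)
  }
  rounds <- do.call(rbind, rounds)
  best_i <- which.min(rounds$rmse)
  structure(list(
    rounds = rounds,
    mean = c(rmse = mean(rounds$rmse), mae = mean(rounds$mae),
             r2 = mean(rounds$r2)),
    best = c(round = rounds$round[best_i], rmse = rounds$rmse[best_i],
             mae = rounds$mae[best_i], r2 = rounds$r2[best_i]),
    seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-round nested cross-validation (seed %d)\n",
              nrow(x$rounds), x$seed))
  print(round(x$rounds[, c("round", "rmse", "mae", "r2")], 4),
        row.names = FALSE)
  cat(sprintf("Mean  RMSE %.4f  MAE %.4f  R2 %.4f\n",
              x$mean["rmse"], x$mean["mae"], x$mean["r2"]))
  cat(sprintf("Best  round %d: RMSE %.4f\n", x$best["round"], x$best["rmse"]))
  invisible(x)
}
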