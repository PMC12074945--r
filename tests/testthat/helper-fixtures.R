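# Shared fixtures, built in code. Heavier objects (teacher surface, trained
# nets) are cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

# a small valid study record
tiny_record <- function(n_subjects = 5, sds = c(4.2, 3.4, 2.2),
                        prop_male = 0, id = "S1") {
  study_record(id, n_subjects,
               age_mean = 68.5, age_sd = sds[1],
               bmi_mean = 24.6, bmi_sd = sds[2],
               vo2_mean = 11.9, vo2_sd = sds[3],
               prop_male = prop_male, improvement = 0.10,
               prescription = prescription(2, 60, 48, 12))
}

# noise-free teacher surface shared by the recovery tests
teacher_surface <- function() {
  cached("teacher300", function() {
    synth_response_surface(300, seed = 7, noise_sd = 0, mode = "teacher")
  })
}

# a quick well-trained fit on the smooth surface (used by prescription tests)
smooth_fit <- function() {
  cached("smooth_fit", function() {
    surf <- synth_response_surface(200, seed = 21, noise_sd = 0,
                                   mode = "smooth")
    net <- init_network(seed = 9)
    net <- attach_input_scaling(net, surf$x)
    cfg <- train_config(alpha = 0, max_epochs = 150, patience = 150,
                        error_precision = 1e-8)
    list(surf = surf,
         fit = train_network(net, surf$x, surf$y, config = cfg))
  })
}

# independent naive forward evaluation: explicit loops, no matrix algebra
naive_forward <- function(net, xrow) {
  a <- xrow
  if (!is.null(net$input_scale)) {
    a <- (a - net$input_scale$lo) / net$input_scale$span * 2 - 1
  }
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- numeric(ncol(net$W[[l]]))
    for (j in seq_along(z)) {
      acc <- net$b[[l]][j]
      for (i in seq_along(a)) acc <- acc + a[i] * net$W[[l]][i, j]
      z[j] <- acc
    }
    a <- if (l < L && net$activation == "tanh") tanh(z) else z
  }
  a
}
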