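test_that("degenerate zero-SD augmentation yields identical mean samples", {
  rec <- tiny_record(n_subjects = 5, sds = c(0, 0, 0))
  out <- augment_study(rec, seed = 1)
  expect_equal(nrow(out$x), 5)
  for (i in 1:5) {
    expect_equal(unname(out$x[i, ]), c(68.5, 0, 24.6, 11.9, 0.10))
    expect_equal(unname(out$y[i, ]), c(2, 0.1, 48, 12))
  }
})

test_that("augmented moments recover the study's mean and SD", {
  n <- 10000
  rec <- tiny_record(n_subjects = n)
  out <- augment_study(rec, seed = 99)
  # CLT bound on the mean, 3 standard errors
  expect_lt(abs(mean(out$x[, "age"]) - 68.5), 3 * 4.2 / sqrt(n))
  expect_lt(abs(mean(out$x[, "bmi"]) - 24.6), 3 * 3.4 / sqrt(n))
  expect_lt(abs(mean(out$x[, "vo2_pre"]) - 11.9), 3 * 2.2 / sqrt(n))
  # SD recovery, 3 standard errors of the SD (~ sd / sqrt(2n))
  expect_lt(abs(sd(out$x[, "age"]) - 4.2), 3 * 4.2 / sqrt(2 * n))
  expect_lt(abs(sd(out$x[, "vo2_pre"]) - 2.2), 3 * 2.2 / sqrt(2 * n))
  # positivity is enforced by redraw, never by clipping
  expect_true(all(out$x[, c("age", "bmi", "vo2_pre")] > 0))
})

test_that("sex and improvement are held fixed; mixed sex follows prop_male", {
  out0 <- augment_study(tiny_record(50, prop_male = 0), seed = 3)
  expect_true(all(out0$x[, "sex"] == 0))
  expect_true(all(out0$x[, "improvement"] == 0.10))
  out1 <- augment_study(tiny_record(50, prop_male = 1), seed = 3)
  expect_true(all(out1$x[, "sex"] == 1))
  outm <- augment_study(tiny_record(2000, prop_male = 0.6), seed = 3)
  expect_lt(abs(mean(outm$x[, "sex"]) - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
})

test_that("augmentation is deterministic under its seed", {
  rec <- tiny_record(20)
  expect_identical(augment_study(rec, 7), augment_study(rec, 7))
  expect_false(identical(augment_study(rec, 7), augment_study(rec, 8)))
})

test_that("corpus size equals the sum of subject counts, always", {
  table <- list(tiny_record(3, id = "s1"), tiny_record(3, id = "s2"))
  corpus <- build_corpus(table, seed = 1)
  expect_equal(nrow(corpus$x), 6)
  expect_equal(corpus$provenance, c("s1", "s1", "s1", "s2", "s2", "s2"))
  set.seed(11)
  sizes <- sample(5:30, 7)
  tab <- lapply(seq_along(sizes), function(i)
    tiny_record(sizes[i], id = paste0("x", i)))
  expect_equal(nrow(build_corpus(tab, seed = 2)$x), sum(sizes))
  expect_error(build_corpus(list(), seed = 1), "empty")
})

test_that("permuting table rows permutes provenance but not per-study draws", {
  tab <- lapply(1:4, function(i) tiny_record(6, id = paste0("s", i),
                                             sds = c(4, 3, 2)))
  fwd <- build_corpus(tab, seed = 5)
  rev_ <- build_corpus(rev(tab), seed = 5)
  for (id in paste0("s", 1:4)) {
    expect_equal(fwd$x[fwd$provenance == id, ],
                 rev_$x[rev_$provenance == id, ])
  }
})

test_that("synthetic study tables respect stated ranges and forced totals", {
  tab <- synth_study_table(68, seed = 10, n_total = 1594)
  expect_length(tab, 68)
  expect_equal(sum(vapply(tab, `[[`, integer(1), "n_subjects")), 1594L)
  for (r in tab) {
    expect_true(r$age_mean >= 60 && r$age_mean <= 80)
    expect_true(r$bmi_mean >= 21 && r$bmi_mean <= 30)
    expect_true(r$vo2_mean >= 10 && r$vo2_mean <= 35)
    expect_true(r$improvement >= 0.05 && r$improvement <= 0.20)
    expect_true(r$prescription$frequency %in% 2:5)
    expect_true(r$prescription$intensity >= 50 && r$prescription$intensity <= 80)
    expect_true(r$prescription$time_min >= 20 && r$prescription$time_min <= 60)
    expect_true(r$prescription$volume_wk >= 8 && r$prescription$volume_wk <= 24)
  }
  expect_length(synth_study_table(1, seed = 1), 1)
})

test_that("study tables and corpora round-trip through CSV byte-identically", {
  tab <- synth_study_table(5, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_study_table(tab, p1)
  write_study_table(synth_study_table(5, seed = 3), p2)
  expect_identical(readLines(p1), readLines(p2))
  tab2 <- read_study_table(p1)
  expect_equal(tab2[[2]]$age_mean, tab[[2]]$age_mean)
  expect_equal(tab2[[3]]$prescription$intensity, tab[[3]]$prescription$intensity)

  corpus <- build_corpus(tab, seed = 3)
  pc <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, pc)
  back <- read_corpus(pc)
  expect_equal(back$x, corpus$x, ignore_attr = TRUE)
  expect_equal(back$y, corpus$y, ignore_attr = TRUE)
  expect_equal(back$provenance, corpus$provenance)
  expect_equal(back$seed, corpus$seed)
})

test_that("response surfaces are seeded, labelled and noise-controlled", {
  s1 <- synth_response_surface(100, seed = 4)
  s2 <- synth_response_surface(100, seed = 4)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$y, s2$y)
  # noise-free surface: targets equal the generating function exactly
  expect_equal(s1$y, s1$f(s1$x))
  sn <- synth_response_surface(5000, seed = 4, noise_sd = 0.5)
  resid <- sn$y - sn$f(sn$x)
  expect_lt(abs(sd(as.numeric(resid)) - 0.5), 0.02)
  # smooth mode: coded intensity decreases in BMI and age, time rises with
  # the improvement target
  base <- matrix(c(70, 0, 25, 20, 0.10), 1)
  hi_bmi <- base; hi_bmi[3] <- 29
  hi_imp <- base; hi_imp[5] <- 0.18
  expect_lt(s1$f(hi_bmi)[1, 2], s1$f(base)[1, 2])
  expect_gt(s1$f(hi_imp)[1, 3], s1$f(base)[1, 3])
  st <- synth_response_surface(50, seed = 4, mode = "teacher")
  expect_s3_class(st$teacher, "fitt_network")
  expect_equal(st$y, forward(st$teacher, st$x))
})
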