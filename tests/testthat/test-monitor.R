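test_that("reference_range trims by one-pass z-score and keeps min/max", {
  vals <- c(rep(2, 29), 8)
  z8 <- abs(8 - mean(vals)) / sd(vals)
  rng <- reference_range(vals, z_max = 3)
  if (z8 > 3) {
    expect_equal(c(rng$lower, rng$upper), c(2, 2))
    expect_equal(rng$n_trimmed, 1)
  } else {
    expect_equal(c(rng$lower, rng$upper), c(2, 8))
  }
  # explicit arithmetic on a small set: 10 is outside 3 sd of the others
  v2 <- c(1.0, 1.1, 0.9, 1.05, 0.95, 10)
  keep <- abs(v2 - mean(v2)) / sd(v2) <= 1
  rng2 <- reference_range(v2, z_max = 1)
  expect_equal(c(rng2$lower, rng2$upper), range(v2[keep]))
  expect_error(reference_range(c(1, 2)), "at least 3")
})

test_that("relative_error: closed forms and scale invariance", {
  expect_equal(relative_error(110, 100), 0.1)
  expect_equal(relative_error(100, 100), 0)
  expect_equal(relative_error(50, 200), 0.75)
  expect_equal(relative_error(7 * 110, 7 * 100), relative_error(110, 100))
  expect_error(relative_error(1, 0), "undefined")
})

test_that("compute_indices: constructions with known values", {
  g <- wl_grid(c(254, 310, 320), seq(300, 480, by = 5))
  z <- matrix(0, 3, length(g$em))
  # HIX numerator zero: energy only in the 300-345 band at ex 254
  z[1, g$em >= 300 & g$em <= 345] <- 4
  # BIX ratio 2:1 at ex 310
  z[2, which.min(abs(g$em - 380))] <- 2
  z[2, which.min(abs(g$em - 430))] <- 1
  z[3, ] <- 1
  pair <- sample_pair("idx", eem(g, z), eem(g, z), 0,
                      absorbance = abs_spectrum(c(200, 600), c(0.5, 0.5)))
  s <- compute_indices(pair)
  expect_equal(s$hix, 0)
  expect_equal(s$bix, 2)
  expect_equal(s$aqy_254, sum(z[1, ]) / 0.5)
  expect_equal(attr(s, "ex_used")[["hix"]], 254)

  # perfectly reconstructable EEM -> zero reconstruction error
  m <- fit_parafac_hals(list(a = pure_pair()$original, b = pure_pair()$quenched),
                        1, n_restarts = 1, seed = 1)
  perfect <- reconstruct_eem(m, 2.0)
  ppair <- sample_pair("perfect", perfect, perfect, 0)
  s2 <- suppressMessages(compute_indices(ppair, model = m))
  expect_lt(s2$reconstruction_error, 1e-8)
  expect_lt(s2$relative_reconstruction_error, 1e-10)
  expect_true(is.na(s2$aqy_254)) # no absorbance attached
})

test_that("train_monitor recovers a constructed linear truth exactly", {
  g <- small_grid()
  cp <- model_compounds()
  pairs <- lapply(1:8, function(i) {
    concs <- c(0.7, 1.67) * (0.4 + 0.15 * i)
    p <- generate_pair(cp, concs, Q_e = 2.5, grid = g, seed = i,
                       sample_id = sprintf("t%d", i))
    # target defined as exactly 2 x the pair's own peak intensity (= Fmax of
    # the single shared-spectrum component), so slope 2 / intercept 0 / r2 1
    p$targets <- c(Y = 2 * max(p$original$intensity))
    p
  })
  b <- train_monitor(eem_dataset(pairs), target_names = "Y", R = 1, seed = 1)
  cal <- b$calibrations$Y
  expect_equal(cal$component, 1)
  expect_equal(cal$slope, 2, tolerance = 1e-4)
  expect_equal(cal$intercept, 0, tolerance = 1e-3)
  expect_equal(cal$r_squared, 1, tolerance = 1e-6)
  expect_error(train_monitor(eem_dataset(pairs), target_names = "missing", R = 1),
               "missing")
  constant <- lapply(pairs, function(p) { p$targets <- c(Y = 5); p })
  expect_error(train_monitor(eem_dataset(constant), target_names = "Y", R = 1),
               "constant")
})

test_that("predict_sample: replay, planted shift, and the F0/F = 1 boundary", {
  g <- small_grid()
  sc <- monitoring_scenario(n_train = 16, n_test = 4, grid = g, seed = 6,
                            noise_sigma = 0.02)
  b <- suppressWarnings(train_monitor(sc$train, target_names = "TCC", R = 3, seed = 1))

  # replayed training sample: prediction within the OLS residual spread, no flags
  p1 <- sc$train$pairs[[1]]
  v1 <- predict_sample(b, p1)
  expect_false(any(v1$f0f_outlier_flags))
  resid_scale <- stats::sd(vapply(sc$train$pairs, function(p) p$targets[["TCC"]],
                                  numeric(1)))
  expect_lt(abs(v1$predictions[["TCC"]] - p1$targets[["TCC"]]), 2 * resid_scale)

  # composition shift doubling the strong-quencher share flags the sample
  drift <- monitoring_scenario(n_train = 4, n_test = 4, share_shift = 0.6,
                               grid = g, seed = 6, noise_sigma = 0.02)
  v2 <- predict_sample(b, drift$test$pairs[[1]])
  expect_true(any(v2$f0f_outlier_flags))

  # quenched replaced by original -> F0/F = 1, flagged iff 1 outside range
  p3 <- sc$train$pairs[[2]]
  same <- sample_pair("same", p3$original, p3$original, 0,
                      absorbance = p3$absorbance)
  v3 <- predict_sample(b, same)
  expect_equal(unname(v3$apparent_f0f), rep(1, 3), tolerance = 1e-9)
  for (r in 1:3) {
    outside <- 1 < b$f0f_ranges[[r]]$lower || 1 > b$f0f_ranges[[r]]$upper
    expect_equal(v3$f0f_outlier_flags[r], outside)
  }
})

test_that("outlier_rate counts the selected flag", {
  mk <- function(flags, any_flag = any(flags)) {
    structure(list(sample_id = "x", predictions = c(TCC = 1),
                   apparent_f0f = rep(1, length(flags)),
                   f0f_outlier_flags = flags,
                   index_values = NULL,
                   index_outlier_flags = list(hix = flags[1]),
                   any_f0f_outlier = any_flag), class = "monitor_verdict")
  }
  vs <- c(lapply(1:3, function(i) mk(c(TRUE, FALSE))),
          lapply(1:7, function(i) mk(c(FALSE, FALSE))))
  expect_equal(outlier_rate(vs, 1), 0.3)
  expect_equal(outlier_rate(vs, 2), 0)
  expect_equal(outlier_rate(vs, "any"), 0.3)
  expect_equal(outlier_rate(vs, "hix"), 0.3)
  expect_equal(outlier_rate(lapply(1:4, function(i) mk(TRUE)), 1), 1)
  expect_error(outlier_rate(list()), "empty")
})

test_that("zero-drift false positives are rare; verdicts serialize", {
  g <- small_grid()
  # scaled-down version of the stationarity property (2 replicates here;
  # the acceptance suite runs the full 20-replicate protocol)
  rates <- vapply(1:2, function(rep) {
    sc <- monitoring_scenario(n_train = 24, n_test = 12, grid = g,
                              seed = 20 + rep, noise_sigma = 0.02)
    b <- suppressWarnings(train_monitor(sc$train, target_names = "TCC", R = 3,
                                        seed = 1))
    v <- predict_dataset(b, sc$test)
    mean(vapply(1:3, function(r) outlier_rate(v, r), numeric(1)))
  }, numeric(1))
  expect_lt(mean(rates), 0.15)

  sc <- monitoring_scenario(n_train = 8, n_test = 4, grid = g, seed = 33)
  b <- suppressWarnings(train_monitor(sc$train, target_names = "TCC", R = 2, seed = 1))
  v <- predict_dataset(b, sc$test)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_verdicts(v, path)
  expect_true(file.exists(path))
  expect_equal(nrow(df), 4)
  expect_true(all(c("pred_TCC", "f0f_C1", "flag_C1", "flag_any_f0f") %in% names(df)))
})
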