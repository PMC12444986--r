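test_that("stern_volmer_ratio covers the independent and shielded regimes", {
  m <- quench_model(K_e = 1)
  r <- stern_volmer_ratio(m, quench_scenario(Q_e = 2.5))
  expect_equal(r$pre_dose_factor, 1)
  expect_equal(r$true_f0f, 3.5)

  # alpha = 0: post/pre is 1 + K_e Q_e for every intrinsic level
  m2 <- quench_model(K_e = 0.4, K_s = 0.2, alpha = 0)
  f <- vapply(c(0, 5, 20), function(qi)
    stern_volmer_ratio(m2, quench_scenario(2.5, qi))$true_f0f, numeric(1))
  expect_equal(f, rep(1 + 0.4 * 2.5, 3))

  # alpha > 0: strictly decreasing in Q_i
  m3 <- quench_model(K_e = 0.4, K_s = 0.2, alpha = 0.1)
  f3 <- vapply(seq(0, 20, by = 2), function(qi)
    stern_volmer_ratio(m3, quench_scenario(2.5, qi))$true_f0f, numeric(1))
  expect_true(all(diff(f3) < 0))
  expect_error(quench_model(-1), ">= 0")
  expect_error(quench_scenario(-0.1), ">= 0")
})

test_that("apparent_f0f is the paired Fmax ratio and refuses bad quenched values", {
  expect_equal(apparent_f0f(100, 50), 2)
  expect_equal(apparent_f0f(c(3, 7), c(3, 7)), c(1, 1))
  expect_error(apparent_f0f(1, 0), "component\\(s\\) 1")
})

test_that("mixture_f0f_oracle: closed form, degeneracy, bounds, monotonicity", {
  expect_equal(mixture_f0f_oracle(c(1, 1), c(2, 4)), 2 / (0.5 + 0.25))
  expect_equal(mixture_f0f_oracle(5, 3.2), 3.2)
  set.seed(3)
  for (i in 1:20) {
    F0 <- runif(4, 0.1, 5)
    fac <- runif(4, 1, 6)
    v <- mixture_f0f_oracle(F0, fac)
    expect_gte(v, min(fac))
    expect_lte(v, max(fac))
  }
  # raising the share of the strong quencher raises the aggregate ratio
  shares <- seq(0, 1, by = 0.1)
  vals <- vapply(shares, function(s) mixture_f0f_oracle(c(1 - s, s), c(1.2, 3)),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(mixture_f0f_oracle(numeric(0), numeric(0)), "empty")
})

test_that("pure compound through the full pipeline reproduces 1 + K_e Q_e", {
  pair <- pure_pair(K_e = 0.4, Q_e = 2.5)
  m <- fit_parafac_hals(list(pure__original = pair$original,
                             pure__quenched = pair$quenched), 1,
                        n_restarts = 2, seed = 1)
  ds <- eem_dataset(list(pair))
  tab <- dataset_f0f(m, ds)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$apparent_f0f, 2, tolerance = 1e-3)
})

test_that("dataset_f0f pairs by id, projects unseen EEMs, flags undefined ratios", {
  g <- small_grid()
  pairs <- lapply(1:3, function(i) pure_pair(grid = g, id = sprintf("s%d", i)))
  ds <- eem_dataset(pairs)
  m <- fit_parafac_hals(ds, 1, n_restarts = 2, seed = 1)
  tab <- dataset_f0f(m, ds)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$apparent_f0f, rep(2, 3), tolerance = 1e-3)

  # identical original/quenched EEMs give ratio 1 via projection
  x <- pairs[[1]]$original
  same <- sample_pair("same", x, x, 0)
  tab2 <- dataset_f0f(m, eem_dataset(list(same)))
  expect_equal(tab2$apparent_f0f, 1, tolerance = 1e-9)

  # an all-zero quenched EEM is flagged, not imputed
  zero <- eem(g, matrix(0, length(g$ex), length(g$em)))
  bad <- sample_pair("bad", x, zero, 2.5)
  tab3 <- dataset_f0f(m, eem_dataset(list(bad)))
  expect_false(tab3$ok)
  expect_true(is.na(tab3$apparent_f0f))
})

test_that("simulated mixture series follows the harmonic-mean oracle direction", {
  g <- small_grid()
  ds <- mixture_series(Q_e_levels = 2.5, grid = g, seed = 1)
  m <- fit_parafac_hals(ds, 1, n_restarts = 2, seed = 1)
  tab <- dataset_f0f(m, ds)
  # ratios are ordered pure-protein ... pure-bacteria along the design
  ratios <- vapply(ds$pairs, function(p) p$labels[["ratio"]], character(1))
  f0f <- tab$apparent_f0f[match(c("0:1", "1:3", "1:1", "3:1", "1:0"), ratios)]
  expect_true(all(diff(f0f) < 0)) # more bacteria -> weaker quenching
  mc <- model_compounds()
  expect_equal(f0f[1], 1 + mc$protein_like$quench$K_e * 2.5, tolerance = 1e-3)
  expect_equal(f0f[5], 1 + mc$bacteria_like$quench$K_e * 2.5, tolerance = 1e-3)
})

test_that("peak-picked F0/F matches PARAFAC for a pure compound and not for mixtures", {
  pair <- pure_pair(K_e = 0.4, Q_e = 2.5)
  expect_equal(peak_picked_f0f(pair, c(270, 290), c(330, 350)), 2, tolerance = 0.01)

  x <- pair$original
  same <- sample_pair("same", x, x, 0)
  expect_equal(peak_picked_f0f(same, c(270, 290), c(330, 350)), 1)

  # overlapping two-compound case: window average disagrees with the
  # component-resolved value once a second fluorophore leaks into the window
  g <- small_grid()
  cps <- list(
    a = compound_spec("a", 280, 12, 340, 25, brightness = 100,
                      quench = quench_model(0.4)),
    b = compound_spec("b", 300, 14, 390, 22, brightness = 100,
                      quench = quench_model(0.04)))
  mixpair <- generate_pair(cps, c(1, 1.5), Q_e = 2.5, grid = g, sample_id = "mix")
  m <- fit_parafac_hals(list(mix__original = mixpair$original,
                             mix__quenched = mixpair$quenched), 2,
                        n_restarts = 3, seed = 1)
  tab <- dataset_f0f(m, eem_dataset(list(mixpair)))
  comp_a <- which.max(vapply(1:2, function(r)
    tucker_congruence(m$ex_loadings[, r], gauss_profile(g$ex, 280, 12)), numeric(1)))
  parafac_val <- tab$apparent_f0f[tab$component == comp_a]
  peak_val <- peak_picked_f0f(mixpair, c(274, 310), c(320, 400))
  expect_gt(abs(peak_val - parafac_val) / parafac_val, 0.05)
  expect_error(peak_picked_f0f(mixpair, c(100, 110), c(320, 400)), "window")
})
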