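# Ground-truth loading profiles for the simulator's compound groups.
true_loadings <- function(grid, groups) {
  list(ex = vapply(groups, function(g)
         gauss_profile(grid$ex, g$A$ex_center, g$A$ex_sigma),
         numeric(length(grid$ex))),
       em = vapply(groups, function(g)
         gauss_profile(grid$em, g$A$em_center, g$A$em_sigma),
         numeric(length(grid$em))))
}

test_that("rank-1 noiseless tensor is fitted exactly", {
  pair <- pure_pair()
  m <- fit_parafac_hals(list(a = pair$original, b = pair$quenched), 1,
                        n_restarts = 2, seed = 1)
  expect_lt(m$rel_error, 1e-6)
  # unit-max normalization: score == Fmax == peak intensity
  expect_equal(max(m$ex_loadings), 1)
  expect_equal(max(m$em_loadings), 1)
  expect_equal(compute_fmax(m, 1), max(pair$original$intensity), tolerance = 1e-6)
  expect_error(fit_parafac_hals(list(a = pair$original, b = pair$quenched), 0),
               "positive")
})

test_that("3-component recovery against the simulator's known loadings", {
  g <- small_grid()
  groups <- monitoring_compounds()
  sc <- monitoring_scenario(n_train = 20, n_test = 4, noise_sigma = 0,
                            grid = g, seed = 3)
  m <- fit_parafac_hals(sc$train, 3, n_restarts = 3, seed = 1)
  expect_lt(m$rel_error, 1e-4)
  truth <- true_loadings(g, groups)
  # every true profile is matched by some component at >= 0.99 in both modes
  for (k in 1:3) {
    cong <- vapply(1:3, function(r)
      min(tucker_congruence(m$ex_loadings[, r], truth$ex[, k]),
          tucker_congruence(m$em_loadings[, r], truth$em[, k])), numeric(1))
    expect_gte(max(cong), 0.99)
  }
})

test_that("restarts with different seeds agree on component-matched Fmax", {
  g <- small_grid()
  sc <- monitoring_scenario(n_train = 12, n_test = 4, noise_sigma = 0,
                            grid = g, seed = 5)
  m1 <- fit_parafac_hals(sc$train, 3, n_restarts = 2, seed = 1)
  m2 <- fit_parafac_hals(sc$train, 3, n_restarts = 2, seed = 99)
  perm <- match_components(m1, m2)
  f1 <- compute_fmax(m1, 3)
  f2 <- compute_fmax(m2, 3)[perm]
  expect_lt(max(abs(f1 - f2) / pmax(f1, 1e-9)), 1e-4)
})

test_that("HALS objective is non-increasing and order-invariant", {
  g <- small_grid()
  noisy <- monitoring_scenario(n_train = 10, n_test = 4, noise_sigma = 0.02,
                               grid = g, seed = 7)
  mn <- fit_parafac_hals(noisy$train, 2, n_restarts = 1, seed = 1)
  expect_true(all(diff(mn$obj_trace) <= 1e-10))

  # order invariance needs a well-posed problem: noiseless data at true rank
  sc <- monitoring_scenario(n_train = 10, n_test = 4, noise_sigma = 0,
                            grid = g, seed = 7)
  m <- fit_parafac_hals(sc$train, 3, n_restarts = 2, seed = 1)
  rev_ds <- eem_dataset(rev(sc$train$pairs))
  m_rev <- fit_parafac_hals(rev_ds, 3, n_restarts = 2, seed = 1)
  perm <- match_components(m, m_rev)
  for (id in m$eem_ids) {
    f1 <- compute_fmax(m, id)
    f2 <- compute_fmax(m_rev, id)[perm]
    expect_lt(max(abs(f1 - f2) / pmax(f1, 1e-9)), 1e-3)
  }
})

test_that("project_eem is self-consistent and exact on constructions", {
  g <- small_grid()
  sc <- monitoring_scenario(n_train = 10, n_test = 4, noise_sigma = 0,
                            grid = g, seed = 2)
  m <- fit_parafac_hals(sc$train, 3, n_restarts = 2, seed = 1)
  # training EEM projects back to its training scores
  pr <- project_eem(m, sc$train$pairs[[1]]$original)
  expect_lt(max(abs(pr$scores - m$scores[1, ]) / pmax(m$scores[1, ], 1e-9)), 1e-5)

  zero <- eem(g, matrix(0, length(g$ex), length(g$em)))
  expect_equal(project_eem(m, zero)$scores, rep(0, 3))

  # EEM = 3 x (component 1 pattern) -> scores (3, 0, 0)
  patt <- eem(g, 3 * outer(m$ex_loadings[, 1], m$em_loadings[, 1]))
  expect_equal(project_eem(m, patt)$scores, c(3, 0, 0), tolerance = 1e-8)
  expect_error(project_eem(m, eem(wl_grid(c(300, 310), c(320, 330)),
                                  matrix(0, 2, 2))), "grid")
})

test_that("tucker_congruence: identity, orthogonality, scale invariance", {
  expect_equal(tucker_congruence(c(1, 2, 2), c(1, 2, 2)), 1)
  expect_equal(tucker_congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(tucker_congruence(c(1, 2, 2), c(2, 4, 4)), 1)
  expect_error(tucker_congruence(c(0, 0), c(1, 1)), "zero")
  expect_error(tucker_congruence(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("match_components equals brute force and handles swaps", {
  g <- small_grid()
  sc <- monitoring_scenario(n_train = 10, n_test = 4, noise_sigma = 0,
                            grid = g, seed = 4)
  m <- fit_parafac_hals(sc$train, 3, n_restarts = 2, seed = 1)
  expect_equal(as.integer(match_components(m, m)), 1:3)

  swap <- m
  p0 <- c(2L, 3L, 1L)
  swap$ex_loadings <- m$ex_loadings[, p0]
  swap$em_loadings <- m$em_loadings[, p0]
  swap$scores <- m$scores[, p0]
  expect_equal(as.integer(match_components(m, swap)), order(p0))

  # exhaustive oracle over all 6 permutations of a noisy copy
  noisy <- m
  set.seed(8)
  noisy$ex_loadings <- pmax(m$ex_loadings[, p0] + matrix(rnorm(length(m$ex_loadings), 0, 0.02),
                                                         nrow(m$ex_loadings)), 0)
  noisy$em_loadings <- pmax(m$em_loadings[, p0] + matrix(rnorm(length(m$em_loadings), 0, 0.02),
                                                         nrow(m$em_loadings)), 0)
  score_perm <- function(p) sum(vapply(1:3, function(r)
    tucker_congruence(m$ex_loadings[, r], noisy$ex_loadings[, p[r]]) +
      tucker_congruence(m$em_loadings[, r], noisy$em_loadings[, p[r]]), numeric(1)))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- perms[[which.max(vapply(perms, score_perm, numeric(1)))]]
  expect_equal(as.integer(match_components(m, noisy)), as.integer(best))
})

test_that("split-half similarity: determinism and identical-loading ceiling", {
  g <- small_grid()
  # all pairs from one 2-group composition -> halves share the loadings
  groups <- monitoring_compounds()[1:2]
  pairs <- lapply(1:8, function(i)
    generate_pair(unlist(groups, recursive = FALSE), c(0.35, 0.8, 3, 2),
                  Q_e = 2.5, grid = g, sample_id = sprintf("p%d", i)))
  ds <- eem_dataset(pairs)
  r1 <- split_half_similarity(ds, 2, N = 1, seed = 5)
  expect_gt(r1$mean_similarity, 0.999)
  r2 <- split_half_similarity(ds, 2, N = 1, seed = 5)
  expect_identical(r1$per_split, r2$per_split)
  expect_error(split_half_similarity(ds, 5, N = 1), "too small")
})

test_that("select_n_components finds the true rank and warns at the boundary", {
  g <- small_grid()
  cp <- model_compounds()
  one <- eem_dataset(lapply(1:8, function(i)
    generate_pair(cp, c(0.7, 1.67) * (0.5 + 0.1 * i), Q_e = 2.5, grid = g,
                  noise_sigma = 0.01, seed = i, sample_id = sprintf("o%d", i))))
  res <- select_n_components(one, R_range = 1:2, N = 3, seed = 2)
  expect_equal(res$recommended_R, 1)
  expect_warning(select_n_components(one, R_range = 1, N = 1, seed = 2,
                                     threshold = 1.01), "argmax")
})

test_that("model serialization round-trips through CSV/JSON", {
  m <- fit_parafac_hals(list(a = pure_pair()$original, b = pure_pair()$quenched),
                        1, n_restarts = 1, seed = 1)
  dir <- withr::local_tempdir()
  write_parafac(m, dir)
  back <- read_parafac(dir)
  expect_equal(back$R, m$R)
  expect_lt(max(abs(back$scores - m$scores)), 1e-9)
  expect_lt(max(abs(back$ex_loadings - m$ex_loadings)), 1e-9)
  expect_true(grid_equal(back$grid, m$grid))
})
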