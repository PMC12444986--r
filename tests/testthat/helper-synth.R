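# Shared fixtures: a coarsened instrument grid keeps the suite fast while
# preserving the spectral ranges; all fixtures are generated in code.

small_grid <- function() default_grid(ex_step = 6, em_step = 6)

tiny_eem <- function(values = matrix(1:4, 2, 2), ex = c(274, 276),
                     em = c(310, 311)) {
  eem(wl_grid(ex, em), values)
}

# Pure single-compound pair: true F0/F is exactly 1 + K_e * Q_e (alpha = 0).
pure_pair <- function(K_e = 0.4, Q_e = 2.5, Q_i = 0, K_s = 0, alpha = 0,
                      conc = 1, noise_sigma = 0, seed = NULL,
                      grid = small_grid(), id = "pure") {
  cp <- compound_spec("pure", 280, 12, 340, 25, brightness = 100,
                      quench = quench_model(K_e, K_s, alpha))
  generate_pair(list(cp), conc, Q_e = Q_e, Q_i = Q_i, grid = grid,
                noise_sigma = noise_sigma, seed = seed, sample_id = id)
}

# Two planted populations sharing one spectrum, quench factors 1.5 vs 3.0
# at the 2.5 g/L dose (K_e = 0.2 vs 0.8).
planted_two_pop <- function(n_per = 20, noise_sigma = 0.02, seed = 1,
                            grid = small_grid()) {
  make_pop <- function(K_e, seed0, tag) {
    cp <- compound_spec(tag, 280, 12, 340, 25, brightness = 100,
                        quench = quench_model(K_e))
    lapply(seq_len(n_per), function(i) {
      conc <- exp(stats::rnorm(1, 0, 0.2))
      generate_pair(list(cp), conc, Q_e = 2.5, grid = grid,
                    noise_sigma = noise_sigma, seed = seed0 + i,
                    sample_id = sprintf("%s_%02d", tag, i))
    })
  }
  pairs <- withr::with_seed(seed, c(make_pop(0.2, seed * 1000L, "lo"),
                                    make_pop(0.8, seed * 1000L + 500L, "hi")))
  list(dataset = eem_dataset(pairs), truth = rep(1:2, each = n_per))
}
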