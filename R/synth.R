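#' Specification of a synthetic fluorescent compound
#'
#' The simulator's ground truth: a Gaussian excitation profile times a
#' Gaussian emission profile (unit peak each), a brightness (fluorescence
#' units per concentration unit), and a [quench_model()] describing how the
#' compound responds to the intrinsic and extrinsic quenchers. Compounds
#' sharing the same spectral centers/sigmas are spectrally indistinguishable
#' and collapse into one PARAFAC component — the mechanism the apparent
#' F0/F indicator exploits.
#'
#' @param name Compound name.
#' @param ex_center,ex_sigma Excitation Gaussian center and sd (nm).
#' @param em_center,em_sigma Emission Gaussian center and sd (nm).
#' @param brightness Peak fluorescence per concentration unit, >= 0.
#' @param conc_unit Text unit (e.g. "million cells/mL", "mg/L").
#' @param quench A `quench_model`.
#' @param absorptivity Absorbance at 254 nm per concentration unit
#'   (used when synthesizing absorbance spectra); default 0.
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(name, ex_center, ex_sigma, em_center, em_sigma,
                          brightness, conc_unit = "mg/L",
                          quench = quench_model(0), absorptivity = 0) {
  if (ex_sigma <= 0 || em_sigma <= 0) stop("spectral sigmas must be > 0")
  if (em_center <= ex_center) stop("emission center must exceed excitation center (Stokes shift)")
  if (brightness < 0) stop("brightness must be >= 0")
  stopifnot(inherits(quench, "quench_model"))
  structure(list(name = name, ex_center = ex_center, ex_sigma = ex_sigma,
                 em_center = em_center, em_sigma = em_sigma,
                 brightness = brightness, conc_unit = conc_unit,
                 quench = quench, absorptivity = absorptivity),
            class = "compound_spec")
}

#' Built-in model compounds for the two-compound mixture design
#'
#' Two compounds sharing one tryptophan-like spectral signature
#' (excitation 280/12 nm, emission 340/25 nm) but with very different
#' quenching behaviour:
#' \describe{
#'   \item{bacteria_like}{weak extrinsic quenching (cellular structures
#'     shield the fluorophores), nearly insensitive to the intrinsic
#'     quencher; brightness scaled so the baseline 0.7 million cells/mL has
#'     peak intensity 100.}
#'   \item{protein_like}{strong extrinsic quenching, strong static binding
#'     by the intrinsic humic-like quencher, and shielding (`alpha > 0`):
#'     rising intrinsic quencher attenuates the extrinsic effect;
#'     brightness scaled so the baseline 1.67 mg/L has peak intensity 100.}
#' }
#' Quenching magnitudes are declared simulator constants chosen to give
#' roughly 2x quenching of the protein at a 2.5 g/L dose versus 1.2x for
#' the bacteria; they are not measured values.
#'
#' @return Named list of two `compound_spec`s.
#' @export
model_compounds <- function() {
  list(
    bacteria_like = compound_spec(
      "bacteria_like", ex_center = 280, ex_sigma = 12,
      em_center = 340, em_sigma = 25, brightness = 100 / 0.7,
      conc_unit = "million cells/mL",
      quench = quench_model(K_e = 0.08, K_s = 0.01, alpha = 0)),
    protein_like = compound_spec(
      "protein_like", ex_center = 280, ex_sigma = 12,
      em_center = 340, em_sigma = 25, brightness = 100 / 1.67,
      conc_unit = "mg/L",
      quench = quench_model(K_e = 0.4, K_s = 0.15, alpha = 0.1),
      absorptivity = 0.005)
  )
}

#' Unit-peak Gaussian spectral profile
#'
#' The simulator's excitation/emission band shape; exposed so tests and
#' reports can build ground-truth loadings for recovery checks.
#'
#' @param wl Wavelengths (nm).
#' @param center,sigma Gaussian center and sd (nm).
#' @return Numeric vector in (0, 1].
#' @export
gauss_profile <- function(wl, center, sigma) exp(-((wl - center)^2) / (2 * sigma^2))

#' Generate one synthetic EEM under a quenching scenario
#'
#' The pristine (quencher-free) signal is the sum over compounds of
#' concentration x brightness x excitation Gaussian (x) emission Gaussian.
#' Each compound's contribution is divided by its own attenuation factor
#' under (`Q_e`, `Q_i`) from [stern_volmer_ratio()]. Optional additive
#' Gaussian noise has sd `noise_sigma` times the peak of the noiseless
#' signal; optional scatter bands (for preprocessing tests) add ridge
#' signal along the Rayleigh diagonals and the water Raman line.
#'
#' @param compounds List of `compound_spec`s.
#' @param concs Numeric concentrations, one per compound.
#' @param Q_e,Q_i Extrinsic (g/L) and intrinsic (mg/L) quencher levels.
#' @param grid A `wl_grid`.
#' @param noise_sigma Noise level as a fraction of peak intensity.
#' @param seed Optional integer; when given, noise is drawn from a private
#'   seeded stream.
#' @param include_scatter Add synthetic Rayleigh/Raman ridges.
#' @return List with `eem` (observed, possibly noisy) and `pristine`
#'   (noiseless, quencher-free twin).
#' @export
generate_eem <- function(compounds, concs, Q_e = 0, Q_i = 0,
                         grid = default_grid(), noise_sigma = 0, seed = NULL,
                         include_scatter = FALSE) {
  if (length(compounds) != length(concs)) stop("one concentration per compound")
  if (any(concs < 0)) stop("concentrations must be >= 0")
  z_pristine <- matrix(0, length(grid$ex), length(grid$em))
  z <- z_pristine
  sc <- quench_scenario(Q_e, Q_i)
  for (c in seq_along(compounds)) {
    cp <- compounds[[c]]
    patt <- concs[c] * cp$brightness *
      outer(gauss_profile(grid$ex, cp$ex_center, cp$ex_sigma),
            gauss_profile(grid$em, cp$em_center, cp$em_sigma))
    z_pristine <- z_pristine + patt
    z <- z + patt / stern_volmer_ratio(cp$quench, sc)$post_dose_factor
  }
  if (include_scatter) {
    # triangular ridges narrower than the default removal bands
    peak <- max(z_pristine)
    for (i in seq_along(grid$ex)) {
      centers <- c(grid$ex[i], 2 * grid$ex[i], raman_emission(grid$ex[i], 3400))
      support <- c(8, 8, 4)
      for (b in 1:3) {
        w <- abs(grid$em - centers[b])
        z[i, ] <- z[i, ] + 2 * peak * pmax(1 - w / support[b], 0)
      }
    }
  }
  if (noise_sigma > 0) {
    sdv <- noise_sigma * max(z)
    noise_draw <- function() matrix(stats::rnorm(length(z), 0, sdv), nrow(z), ncol(z))
    z <- z + if (is.null(seed)) noise_draw() else with_seed(seed, noise_draw())
  }
  list(eem = eem(grid, z), pristine = eem(grid, z_pristine))
}

#' Generate a paired original/quenched synthetic sample
#'
#' The original EEM is measured at extrinsic dose zero (the intrinsic
#' quencher, if present, still acts); the quenched EEM at dose `Q_e`.
#' The two measurements receive independent noise draws from one seeded
#' stream.
#'
#' @inheritParams generate_eem
#' @param sample_id Sample id for the resulting pair.
#' @param targets,labels Passed to [sample_pair()].
#' @param absorbance Optional `abs_spectrum` attached to the pair.
#' @return A `sample_pair`.
#' @export
generate_pair <- function(compounds, concs, Q_e, Q_i = 0,
                          grid = default_grid(), noise_sigma = 0, seed = NULL,
                          sample_id = "synthetic", targets = NULL,
                          labels = NULL, absorbance = NULL,
                          include_scatter = FALSE) {
  make <- function() {
    orig <- generate_eem(compounds, concs, Q_e = 0, Q_i = Q_i, grid = grid,
                         noise_sigma = noise_sigma,
                         include_scatter = include_scatter)$eem
    quen <- generate_eem(compounds, concs, Q_e = Q_e, Q_i = Q_i, grid = grid,
                         noise_sigma = noise_sigma,
                         include_scatter = include_scatter)$eem
    sample_pair(sample_id, orig, quen, Q_e, absorbance = absorbance,
                targets = targets, labels = labels)
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Full-factorial two-compound mixture dataset
#'
#' Replays the model-compound design: baseline solutions of the
#' bacteria-like compound (0.7 million cells/mL) and the protein-like
#' compound (1.67 mg/L) mixed at volume ratios 0:1, 1:3, 1:1, 3:1, 1:0,
#' crossed with extrinsic quencher doses (default 0, 1.25, 2.5, 3.75,
#' 5 g/L) and intrinsic quencher levels (default 0). Both compounds share
#' one spectral signature so a one-component PARAFAC generalizes them.
#'
#' @param ratios List of length-2 numeric vectors `c(parts_A, parts_B)`.
#' @param Q_e_levels,Q_i_levels Numeric dose grids.
#' @param compounds Named list of two `compound_spec`s
#'   (default [model_compounds()]); first is "A" (bacteria-like).
#' @param baselines Baseline concentrations of the two pure solutions.
#' @param grid,noise_sigma,seed As in [generate_eem()].
#' @return An `eem_dataset`; each pair carries targets `TCC` (cells/mL,
#'   from compound A) and `DOC` (mg/L, compound B) plus labels
#'   `ratio`, `Q_e`, `Q_i`.
#' @export
mixture_series <- function(ratios = list(c(0, 1), c(1, 3), c(1, 1), c(3, 1), c(1, 0)),
                           Q_e_levels = c(0, 1.25, 2.5, 3.75, 5),
                           Q_i_levels = 0,
                           compounds = model_compounds(),
                           baselines = c(0.7, 1.67),
                           grid = default_grid(), noise_sigma = 0, seed = 1) {
  if (length(ratios) == 0) stop("ratios must be nonempty")
  if (length(compounds) != 2) stop("mixture_series uses exactly two compounds")
  pairs <- list()
  n <- 0L
  for (ri in seq_along(ratios)) {
    rt <- ratios[[ri]]
    fr <- rt / sum(rt)
    concs <- baselines * fr
    for (qe in Q_e_levels) {
      for (qi in Q_i_levels) {
        n <- n + 1L
        id <- sprintf("mix_r%d_qe%g_qi%g", ri, qe, qi)
        pairs[[n]] <- generate_pair(
          compounds, concs, Q_e = qe, Q_i = qi, grid = grid,
          noise_sigma = noise_sigma, seed = seed + n,
          sample_id = id,
          targets = c(TCC = concs[1] * 1e6, DOC = concs[2]),
          labels = c(ratio = paste(rt, collapse = ":"),
                     Q_e = as.character(qe), Q_i = as.character(qi)))
      }
    }
  }
  eem_dataset(pairs, provenance = "synthetic two-compound mixture series")
}

#' Built-in compound groups for the monitoring scenario
#'
#' Three spectrally distinct fluorophore groups, each a two-compound
#' mixture with contrasting extrinsic quenching constants, so every
#' PARAFAC component aggregates compounds with different true F0/F:
#' a tryptophan-like group (bacteria-like vs protein-like, from
#' [model_compounds()]), a humic-like group, and a fulvic-like group.
#'
#' @param alpha_zero If `TRUE`, set every shielding coefficient to zero
#'   (the fully multiplicative two-quencher regime in which apparent F0/F
#'   is blind to intrinsic-quencher changes).
#' @param uniform_K_s If `TRUE`, replace each group's static binding
#'   constants by their group mean. Together with `alpha_zero = TRUE` this
#'   is the regime in which a mixture's apparent F0/F is exactly blind to
#'   intrinsic-quencher changes: equal static quenching leaves the
#'   compounds' intensity weights untouched while `alpha = 0` leaves each
#'   compound's own ratio at `1 + K_e Q_e`.
#' @param n_groups 3 (default) or 4; the optional fourth group is a
#'   spectrally distinct tyrosine-like pair for higher-rank recovery tests.
#' @return List of groups; each group is a list of two `compound_spec`s.
#' @export
monitoring_compounds <- function(alpha_zero = FALSE, uniform_K_s = FALSE,
                                 n_groups = 3) {
  mc <- model_compounds()
  groups <- list(
    tryptophan = list(A = mc$bacteria_like, B = mc$protein_like),
    humic = list(
      A = compound_spec("humic_terrestrial", 330, 20, 430, 30, brightness = 40,
                        quench = quench_model(K_e = 0.1, K_s = 0.02, alpha = 0),
                        absorptivity = 0.02),
      B = compound_spec("humic_microbial", 330, 20, 430, 30, brightness = 40,
                        quench = quench_model(K_e = 0.32, K_s = 0.05, alpha = 0.05),
                        absorptivity = 0.02)),
    fulvic = list(
      A = compound_spec("fulvic_slow", 366, 18, 470, 25, brightness = 30,
                        quench = quench_model(K_e = 0.12, K_s = 0.02, alpha = 0),
                        absorptivity = 0.01),
      B = compound_spec("fulvic_fast", 366, 18, 470, 25, brightness = 30,
                        quench = quench_model(K_e = 0.36, K_s = 0.04, alpha = 0.05),
                        absorptivity = 0.01))
  )
  if (n_groups >= 4) {
    groups$tyrosine <- list(
      A = compound_spec("tyrosine_bound", 300, 10, 386, 16, brightness = 60,
                        quench = quench_model(K_e = 0.06, K_s = 0.01, alpha = 0)),
      B = compound_spec("tyrosine_free", 300, 10, 386, 16, brightness = 60,
                        quench = quench_model(K_e = 0.5, K_s = 0.1, alpha = 0.08)))
  }
  if (alpha_zero) {
    for (g in seq_along(groups)) {
      for (c in seq_along(groups[[g]])) groups[[g]][[c]]$quench$alpha <- 0
    }
  }
  if (uniform_K_s) {
    for (g in seq_along(groups)) {
      ks <- mean(vapply(groups[[g]], function(cp) cp$quench$K_s, numeric(1)))
      for (c in seq_along(groups[[g]])) groups[[g]][[c]]$quench$K_s <- ks
    }
  }
  groups
}

# Draw one sample's compound concentrations from the scenario regime.
draw_sample_concs <- function(groups, share_shift, conc_sd = 0.25, share_sd = 0.06,
                              base_share = 0.35) {
  lapply(groups, function(g) {
    total <- exp(stats::rnorm(1, 0, conc_sd))
    share_B <- min(max(stats::rnorm(1, base_share + share_shift, share_sd), 0), 1)
    # scaled so that a unit total roughly matches the baseline intensities
    c(A = total * (1 - share_B), B = total * share_B)
  })
}

#' Simulated monitoring campaign: training and test datasets
#'
#' Training pairs are drawn from a baseline regime: per-group total
#' concentration lognormal around a fixed baseline, the second (strongly
#' quenched) compound holding a share of about 0.35 of each group's total,
#' intrinsic quencher lognormal around `Q_i_base`, and the extrinsic dose
#' fixed at 2.5 g/L for every sample. Test pairs come from the same regime
#' shifted by `share_shift` (added to the strongly quenched compound's
#' share — a composition drift that moves the true mixture F0/F) and
#' `Q_i_shift` (added to the intrinsic quencher level). Nonzero drift
#' samples carry the label `anomaly = "yes"`.
#'
#' Targets: `TCC` (cells/mL) is proportional to the bacteria-like
#' compound's concentration; `DOC` (mg/L) to the summed organic
#' concentrations. A synthetic absorbance spectrum proportional to DOC is
#' attached to every pair so quantum-yield indices can be computed.
#'
#' @param n_train,n_test Number of pairs in each phase (>= 4).
#' @param share_shift,Q_i_shift Drift applied to the test phase only.
#' @param groups Compound groups (default [monitoring_compounds()]).
#' @param Q_e Extrinsic dose for every pair (g/L, default 2.5).
#' @param Q_i_base Baseline intrinsic quencher level (mg/L, default 2).
#' @param grid A `wl_grid`.
#' @param noise_sigma Noise level (default 0.02).
#' @param seed Integer seed; the whole campaign is reproducible from it.
#' @return List with `train` and `test` (`eem_dataset`s).
#' @export
monitoring_scenario <- function(n_train = 40, n_test = 20, share_shift = 0,
                                Q_i_shift = 0, groups = monitoring_compounds(),
                                Q_e = 2.5, Q_i_base = 2,
                                grid = default_grid(), noise_sigma = 0.02,
                                seed = 1) {
  if (n_train < 4 || n_test < 4) stop("need at least 4 pairs per phase")
  compounds <- unlist(groups, recursive = FALSE)
  base_conc <- c(0.7, 1.67, 6, 6, 4, 4) # per-compound scale of one regime unit
  if (length(compounds) != length(base_conc)) {
    base_conc <- rep(1, length(compounds))
  }
  make_phase <- function(n, phase, shift, qi_shift, seed0) {
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      pairs[[i]] <- with_seed(seed0 + i, {
        cs <- draw_sample_concs(groups, shift)
        concs <- unlist(cs) * base_conc
        q_i <- Q_i_base * exp(stats::rnorm(1, 0, 0.2)) + qi_shift
        tcc <- unname(concs[1]) * 1e6   # bacteria-like compound drives TCC
        doc <- sum(concs[-1])           # organics drive DOC
        a254 <- sum(concs * vapply(compounds, function(cp) cp$absorptivity,
                                   numeric(1))) + 0.002 * q_i
        absorb <- abs_spectrum(seq(250, 600, by = 10),
                               a254 * exp(-0.012 * (seq(250, 600, by = 10) - 254)))
        anomaly <- if (shift != 0 || qi_shift != 0) "yes" else "no"
        generate_pair(compounds, concs, Q_e = Q_e, Q_i = q_i, grid = grid,
                      noise_sigma = noise_sigma,
                      sample_id = sprintf("%s_%03d", phase, i),
                      targets = c(TCC = tcc, DOC = doc),
                      labels = c(phase = phase, anomaly = anomaly),
                      absorbance = absorb)
      })
    }
    eem_dataset(pairs, provenance = sprintf("synthetic monitoring %s phase", phase))
  }
  # fold so derived seeds stay inside R's 32-bit integer range
  base <- (as.numeric(seed) %% 200000) * 10000
  list(train = make_phase(n_train, "train", 0, 0, base),
       test = make_phase(n_test, "test", share_shift, Q_i_shift,
                         base + 5000))
}
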