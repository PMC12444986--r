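#' Quenching model of a fluorescent compound
#'
#' Stern-Volmer behaviour toward an extrinsic dosed quencher (constant
#' `K_e`, L/g) combined with static quenching by an intrinsic quencher
#' already present in the sample (constant `K_s`, L/mg). The intrinsic
#' quencher may additionally shield the compound from the extrinsic one:
#' the effective extrinsic constant is `K_e / (1 + alpha * Q_i)`. With
#' `alpha = 0` the two quenchers act independently (fully multiplicative
#' regime) and the apparent F0/F reduces to `1 + K_e * Q_e`, independent
#' of the intrinsic quencher.
#'
#' @param K_e Extrinsic Stern-Volmer constant (L/g), >= 0.
#' @param K_s Intrinsic static binding constant (L/mg), >= 0.
#' @param alpha Shielding coefficient (L/mg), >= 0.
#' @return An object of class `quench_model`.
#' @export
quench_model <- function(K_e, K_s = 0, alpha = 0) {
  if (any(c(K_e, K_s, alpha) < 0)) stop("quenching constants must be >= 0")
  structure(list(K_e = K_e, K_s = K_s, alpha = alpha), class = "quench_model")
}

#' Quenching scenario: doses of the two quenchers
#' @param Q_e Extrinsic quencher concentration (g/L), >= 0.
#' @param Q_i Intrinsic quencher concentration (mg/L), >= 0.
#' @return An object of class `quench_scenario`.
#' @export
quench_scenario <- function(Q_e, Q_i = 0) {
  if (Q_e < 0 || Q_i < 0) stop("quencher concentrations must be >= 0")
  structure(list(Q_e = Q_e, Q_i = Q_i), class = "quench_scenario")
}

#' Stern-Volmer attenuation factors before and after dosing
#'
#' `pre_dose_factor` is the ratio of the pristine (quencher-free)
#' fluorescence to the fluorescence with only the intrinsic quencher
#' present: `1 + K_s * Q_i`. `post_dose_factor` additionally applies the
#' (possibly shielded) extrinsic quencher:
#' `(1 + K_s * Q_i) * (1 + K_e' * Q_e)` with `K_e' = K_e / (1 + alpha * Q_i)`.
#' Observed fluorescence is pristine intensity divided by the factor; the
#' compound's true F0/F under the dose is `post / pre`.
#'
#' @param model A `quench_model`.
#' @param scenario A `quench_scenario`.
#' @return List with `pre_dose_factor`, `post_dose_factor`, and their ratio
#'   `true_f0f`.
#' @export
stern_volmer_ratio <- function(model, scenario) {
  stopifnot(inherits(model, "quench_model"), inherits(scenario, "quench_scenario"))
  pre <- 1 + model$K_s * scenario$Q_i
  ke_eff <- model$K_e / (1 + model$alpha * scenario$Q_i)
  post <- pre * (1 + ke_eff * scenario$Q_e)
  list(pre_dose_factor = pre, post_dose_factor = post, true_f0f = post / pre)
}

#' Apparent F0/F of a component from a paired Fmax record
#'
#' The ratio of a PARAFAC component's Fmax in the original sample to its
#' Fmax in the quencher-dosed sample. A nonpositive quenched Fmax makes
#' the ratio undefined and raises an error rather than returning a value.
#'
#' @param fmax_original,fmax_quenched Numeric vectors (per component).
#' @return Numeric vector of apparent F0/F values.
#' @export
apparent_f0f <- function(fmax_original, fmax_quenched) {
  if (length(fmax_original) != length(fmax_quenched)) stop("length mismatch")
  bad <- which(fmax_quenched <= 0)
  if (length(bad)) {
    stop(sprintf("apparent F0/F undefined: quenched Fmax <= 0 for component(s) %s",
                 paste(bad, collapse = ", ")))
  }
  fmax_original / fmax_quenched
}

#' Closed-form apparent F0/F of a mixture of same-spectrum compounds
#'
#' Compounds sharing one spectral signature contribute additively to a
#' single component; each is quenched by its own factor. The aggregate
#' ratio is total pre-dose fluorescence over total post-dose fluorescence:
#' `sum(F0_i) / sum(F0_i / factor_i)` — an intensity-weighted harmonic
#' mean of the individual factors. This is the independent oracle against
#' which the simulate-and-decompose pipeline is checked.
#'
#' @param F0 Pre-dose fluorescence contributions, >= 0 with positive sum.
#' @param factor Individual quenching factors, >= 1.
#' @return Scalar apparent F0/F, within `[min(factor), max(factor)]`.
#' @export
mixture_f0f_oracle <- function(F0, factor) {
  if (length(F0) == 0) stop("empty mixture")
  if (length(F0) != length(factor)) stop("length mismatch")
  if (any(F0 < 0) || sum(F0) <= 0) stop("contributions must be >= 0 with positive total")
  if (any(factor <= 0)) stop("quench factors must be positive")
  sum(F0) / sum(F0 / factor)
}

#' Apparent F0/F table for every sample pair in a dataset
#'
#' Pairs each sample's original and quenched EEM through the PARAFAC model.
#' EEMs present in the model are read off its score matrix; others are
#' projected with [project_eem()]. Nonpositive quenched Fmax values yield
#' `NA` with `ok = FALSE` (flagged, never imputed).
#'
#' @param model A `parafac_model` (fitted on or projectable onto the data).
#' @param dataset An `eem_dataset`.
#' @return Tidy data frame: sample_id, component, fmax_original,
#'   fmax_quenched, apparent_f0f, ok.
#' @export
dataset_f0f <- function(model, dataset) {
  stopifnot(inherits(model, "parafac_model"), inherits(dataset, "eem_dataset"))
  get_fmax <- function(id, role, x) {
    key <- paste0(id, "__", role)
    i <- match(key, model$eem_ids)
    if (!is.na(i)) compute_fmax(model, i) else project_eem(model, x)$fmax
  }
  rows <- lapply(dataset$pairs, function(p) {
    fo <- get_fmax(p$sample_id, "original", p$original)
    fq <- get_fmax(p$sample_id, "quenched", p$quenched)
    ok <- fq > 0
    data.frame(sample_id = p$sample_id, component = seq_len(model$R),
               fmax_original = fo, fmax_quenched = fq,
               apparent_f0f = ifelse(ok, fo / fq, NA_real_), ok = ok,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apparent F0/F vector (one value per component) of a single pair
#' @param model A `parafac_model`.
#' @param pair A `sample_pair`.
#' @return Numeric length-R vector (NA where undefined).
#' @export
pair_f0f <- function(model, pair) {
  fo <- project_eem(model, pair$original)$fmax
  fq <- project_eem(model, pair$quenched)$fmax
  ifelse(fq > 0, fo / fq, NA_real_)
}

#' Peak-picked apparent F0/F over a wavelength window
#'
#' Ratio of the mean intensity of the original EEM over the mean intensity
#' of the quenched EEM within an excitation x emission window — the
#' decomposition-free alternative to the PARAFAC-derived indicator. For a
#' single pure compound the two agree; with spectral overlap of compounds
#' they generally differ.
#'
#' @param pair A `sample_pair`.
#' @param ex_window,em_window Length-2 numeric ranges (nm).
#' @return Scalar ratio.
#' @export
peak_picked_f0f <- function(pair, ex_window, em_window) {
  stopifnot(inherits(pair, "sample_pair"))
  g <- pair$original$grid
  ri <- which(g$ex >= ex_window[1] & g$ex <= ex_window[2])
  ci <- which(g$em >= em_window[1] & g$em <= em_window[2])
  if (length(ri) == 0 || length(ci) == 0) {
    stop("peak-picking window contains no grid points")
  }
  num <- mean(pair$original$intensity[ri, ci])
  den <- mean(pair$quenched$intensity[ri, ci])
  if (den <= 0) stop("peak-picked F0/F undefined: quenched window mean <= 0")
  num / den
}
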