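#' Inner filter effect correction (absorbance-based, ABA)
#'
#' Multiplies every cell by `10^((A(ex) + A(em))/2 * pathlength)`, the
#' standard absorbance-based correction for primary plus secondary inner
#' filtering in a 1 cm cuvette. Correction factors are always >= 1, so
#' corrected intensities never decrease.
#'
#' @param x An `eem`.
#' @param absorbance An `abs_spectrum` covering both wavelength axes.
#' @param pathlength Cuvette pathlength in cm (default 1).
#' @return Corrected `eem`.
#' @export
ife_correct <- function(x, absorbance, pathlength = 1) {
  stopifnot(inherits(x, "eem"), inherits(absorbance, "abs_spectrum"))
  a_ex <- abs_at(absorbance, x$grid$ex)
  a_em <- abs_at(absorbance, x$grid$em)
  factor <- 10^(outer(a_ex, a_em, `+`) / 2 * pathlength)
  eem(x$grid, x$intensity * factor, x$mask)
}

# Fill masked entries of one emission row: linear interpolation between the
# flanking unmasked points; bands touching an axis edge are extrapolated
# linearly from the two nearest interior points (clamped at 0) — constant
# extension would overshoot on a rising spectral flank.
fill_run <- function(em, v, nas) {
  good <- which(!nas)
  out <- stats::approx(em[good], v[good], xout = em, rule = 2)$y
  if (good[1] > 1 && length(good) >= 2) {
    g1 <- good[1]; g2 <- good[2]
    slope <- (v[g2] - v[g1]) / (em[g2] - em[g1])
    lead <- seq_len(g1 - 1)
    out[lead] <- pmax(v[g1] + slope * (em[lead] - em[g1]), 0)
  }
  gl <- length(good)
  if (good[gl] < length(em) && gl >= 2) {
    g1 <- good[gl]; g2 <- good[gl - 1]
    slope <- (v[g1] - v[g2]) / (em[g1] - em[g2])
    trail <- (good[gl] + 1):length(em)
    out[trail] <- pmax(v[g1] + slope * (em[trail] - em[g1]), 0)
  }
  out
}

# Raman line: emission wavelength excited at ex with a solvent Raman shift
# (cm^-1); 1e7 converts nm <-> cm^-1.
raman_emission <- function(ex_nm, raman_shift_cm1) {
  1 / (1 / ex_nm - raman_shift_cm1 * 1e-7)
}

#' Remove Rayleigh and Raman scatter bands and interpolate
#'
#' Masks cells within the stated half-widths of the first-order Rayleigh
#' diagonal (em = ex), second-order Rayleigh (em = 2 ex), and the solvent
#' Raman line, then fills masked cells by linear interpolation along the
#' emission axis within each excitation row. Rows left fully masked are
#' zero-filled with a warning. Pre-existing masked cells are interpolated
#' too, so the operation is idempotent.
#'
#' @param x An `eem`.
#' @param widths Named list/vector of half-widths in nm:
#'   `rayleigh1`, `rayleigh2`, `raman` (defaults 15, 15, 5).
#' @param raman_shift Solvent Raman shift in cm^-1 (default 3400, water).
#' @return An `eem` with no masked cells.
#' @export
remove_scatter <- function(x, widths = c(rayleigh1 = 15, rayleigh2 = 15, raman = 5),
                           raman_shift = 3400) {
  stopifnot(inherits(x, "eem"))
  w <- c(rayleigh1 = 15, rayleigh2 = 15, raman = 5)
  w[names(widths)] <- unlist(widths)
  if (any(w < 0)) stop("scatter band widths must be >= 0")
  ex <- x$grid$ex
  em <- x$grid$em
  mask <- x$mask
  for (i in seq_along(ex)) {
    centers <- c(ex[i], 2 * ex[i], raman_emission(ex[i], raman_shift))
    half <- c(w[["rayleigh1"]], w[["rayleigh2"]], w[["raman"]])
    inband <- rep(FALSE, length(em))
    for (b in 1:3) inband <- inband | abs(em - centers[b]) <= half[b]
    mask[i, ] <- mask[i, ] | inband
  }
  z <- x$intensity
  z[mask] <- NA_real_
  dead_rows <- numeric(0)
  for (i in seq_len(nrow(z))) {
    nas <- is.na(z[i, ])
    if (!any(nas)) next
    if (all(nas)) {
      dead_rows <- c(dead_rows, ex[i])
      z[i, ] <- 0
      next
    }
    z[i, ] <- fill_run(em, z[i, ], nas)
  }
  if (length(dead_rows)) {
    warning(sprintf("scatter bands cover the whole emission row at ex = %s nm; zero-filled",
                    paste(format(dead_rows), collapse = ", ")))
  }
  eem(x$grid, z)
}

#' 2-D median filter with edge replication
#'
#' @param x An `eem` (no masked cells).
#' @param kernel Odd window size; `kernel = 1` is the identity.
#' @return Filtered `eem`.
#' @export
median_filter_eem <- function(x, kernel = 3) {
  stopifnot(inherits(x, "eem"))
  if (kernel %% 2 != 1 || kernel < 1) stop("median filter kernel must be odd and >= 1")
  if (kernel == 1) return(x)
  if (any(x$mask)) stop("median_filter_eem expects an EEM without masked cells")
  h <- (kernel - 1) / 2
  z <- x$intensity
  n <- nrow(z); m <- ncol(z)
  # edge replication via index clamping
  ridx <- pmin(pmax(seq(1 - h, n + h), 1L), n)
  cidx <- pmin(pmax(seq(1 - h, m + h), 1L), m)
  zp <- z[ridx, cidx, drop = FALSE]
  out <- z
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- stats::median(zp[i:(i + 2 * h), j:(j + 2 * h)])
    }
  }
  eem(x$grid, out, x$mask)
}

#' Default preprocessing configuration
#'
#' @return Named list of stage settings understood by
#'   [preprocess_pipeline()]: `ife` (enabled, pathlength_cm), `scatter`
#'   (enabled, widths_nm, raman_shift_cm1), `median` (enabled, kernel).
#' @export
preprocess_config <- function() {
  list(
    ife = list(enabled = TRUE, pathlength_cm = 1),
    scatter = list(enabled = TRUE,
                   widths_nm = c(rayleigh1 = 15, rayleigh2 = 15, raman = 5),
                   raman_shift_cm1 = 3400),
    median = list(enabled = TRUE, kernel = 3)
  )
}

#' Run the standard preprocessing chain on a sample pair
#'
#' Stage order is fixed: inner-filter correction, then scatter removal with
#' interpolation, then median filtering — applied identically to the
#' original and the quenched EEM.
#'
#' @param pair A `sample_pair`.
#' @param config Configuration list as produced by [preprocess_config()];
#'   disable stages by setting `enabled = FALSE`.
#' @return The preprocessed `sample_pair`.
#' @export
preprocess_pipeline <- function(pair, config = preprocess_config()) {
  stopifnot(inherits(pair, "sample_pair"))
  cfg <- utils::modifyList(preprocess_config(), config)
  step <- function(x) {
    if (isTRUE(cfg$ife$enabled)) {
      if (is.null(pair$absorbance)) {
        stop(sprintf("sample '%s': IFE correction enabled but no absorbance spectrum attached",
                     pair$sample_id))
      }
      x <- ife_correct(x, pair$absorbance, cfg$ife$pathlength_cm)
    }
    if (isTRUE(cfg$scatter$enabled)) {
      x <- remove_scatter(x, cfg$scatter$widths_nm, cfg$scatter$raman_shift_cm1)
    }
    if (isTRUE(cfg$median$enabled)) {
      x <- median_filter_eem(x, cfg$median$kernel)
    }
    x
  }
  pair$original <- step(pair$original)
  pair$quenched <- step(pair$quenched)
  pair
}

#' Preprocess every pair of a dataset
#' @param dataset An `eem_dataset`.
#' @param config See [preprocess_pipeline()].
#' @return The preprocessed dataset.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  dataset$pairs <- lapply(dataset$pairs, preprocess_pipeline, config = config)
  dataset
}
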