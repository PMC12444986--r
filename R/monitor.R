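#' Reference range from training values after z-score trimming
#'
#' Values with `|z| > z_max` under the training sample mean and standard
#' deviation (computed once, no iterative re-trimming) are removed; the
#' range is the min/max of survivors (`mode = "minmax"`, the default,
#' matching the "fell outside the historical range" rule) or their 1st/99th
#' percentiles (`mode = "percentile"`).
#'
#' @param values Numeric training values (NA dropped).
#' @param z_max Trimming threshold (default 3).
#' @param mode "minmax" or "percentile".
#' @return List: `lower`, `upper`, `n_used`, `n_trimmed`.
#' @export
reference_range <- function(values, z_max = 3, mode = c("minmax", "percentile")) {
  mode <- match.arg(mode)
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("reference range needs at least 3 finite values")
  s <- stats::sd(values)
  keep <- if (s > 0) abs(values - mean(values)) / s <= z_max else rep(TRUE, length(values))
  kept <- values[keep]
  bounds <- if (mode == "minmax") range(kept) else
    stats::quantile(kept, c(0.01, 0.99), names = FALSE)
  list(lower = bounds[1], upper = bounds[2],
       n_used = length(kept), n_trimmed = sum(!keep))
}

in_range <- function(x, rng) is.finite(x) & x >= rng$lower & x <= rng$upper

target_of <- function(pair, name) {
  v <- pair$targets
  if (is.null(v) || !(name %in% names(v))) NA_real_ else as.numeric(v[[name]])
}

#' Classical fluorescence indices and reconstruction error for one pair
#'
#' Computed on the original (undosed) EEM:
#' \describe{
#'   \item{hix}{humification index — emission sum over 435-480 nm divided by
#'     the sum over 300-345 nm at the excitation column nearest 254 nm
#'     available on the grid (an instrument starting at 274 nm uses its
#'     first column; the column used is recorded).}
#'   \item{bix}{biological index — intensity at emission 380 nm over
#'     430 nm at the excitation column nearest 310 nm.}
#'   \item{aqy_254, aqy_320}{apparent quantum yield — integrated emission at
#'     the excitation column nearest 254/320 nm divided by the absorbance at
#'     that wavelength; `NA` with a notice when no absorbance is attached.}
#'   \item{reconstruction_error}{Frobenius norm of (EEM - PARAFAC
#'     reconstruction) after projecting the EEM onto `model`; `NA` without
#'     a model.}
#'   \item{relative_reconstruction_error}{the norm above divided by the
#'     EEM's Frobenius norm.}
#' }
#'
#' @param pair A `sample_pair`.
#' @param model Optional `parafac_model` for the reconstruction errors.
#' @param windows Optional overrides: list with `hix_num`, `hix_den`
#'   (emission nm ranges), `hix_ex`, `bix_ex`, `bix_em` (length 2),
#'   `aqy_ex` (length 2).
#' @return Named list of class `index_set`; attribute `ex_used` records the
#'   excitation column actually used for each index.
#' @export
compute_indices <- function(pair, model = NULL, windows = list()) {
  stopifnot(inherits(pair, "sample_pair"))
  w <- utils::modifyList(list(hix_num = c(435, 480), hix_den = c(300, 345),
                              hix_ex = 254, bix_ex = 310, bix_em = c(380, 430),
                              aqy_ex = c(254, 320)), windows)
  x <- pair$original
  g <- x$grid
  nearest_ex <- function(target) which.min(abs(g$ex - target))
  em_sum <- function(row, rng) {
    j <- which(g$em >= rng[1] & g$em <= rng[2])
    if (length(j) == 0) stop(sprintf("emission window %.0f-%.0f nm is off-grid", rng[1], rng[2]))
    sum(x$intensity[row, j])
  }
  ex_used <- c()

  i_hix <- nearest_ex(w$hix_ex)
  ex_used["hix"] <- g$ex[i_hix]
  den <- em_sum(i_hix, w$hix_den)
  hix <- if (den > 0) em_sum(i_hix, w$hix_num) / den else {
    num <- em_sum(i_hix, w$hix_num)
    if (num == 0) 0 else Inf
  }

  i_bix <- nearest_ex(w$bix_ex)
  ex_used["bix"] <- g$ex[i_bix]
  near_em <- function(target) which.min(abs(g$em - target))
  b_den <- x$intensity[i_bix, near_em(w$bix_em[2])]
  bix <- if (b_den > 0) x$intensity[i_bix, near_em(w$bix_em[1])] / b_den else NA_real_

  aqy <- stats::setNames(rep(NA_real_, length(w$aqy_ex)),
                         paste0("aqy_", round(w$aqy_ex)))
  if (!is.null(pair$absorbance)) {
    for (q in seq_along(w$aqy_ex)) {
      i_q <- nearest_ex(w$aqy_ex[q])
      ex_used[names(aqy)[q]] <- g$ex[i_q]
      a <- abs_at(pair$absorbance, w$aqy_ex[q])
      if (a > 0) aqy[q] <- sum(x$intensity[i_q, ]) / a
    }
  } else {
    message(sprintf("sample '%s': no absorbance spectrum; AQY omitted", pair$sample_id))
  }

  re <- NA_real_; rre <- NA_real_
  if (!is.null(model)) {
    pr <- project_eem(model, x)
    re <- pr$residual_norm
    rre <- pr$relative_residual
  }
  structure(list(hix = hix, bix = bix, aqy_254 = aqy[[1]],
                 aqy_320 = if (length(aqy) > 1) aqy[[2]] else NA_real_,
                 reconstruction_error = re,
                 relative_reconstruction_error = rre),
            ex_used = ex_used, class = "index_set")
}

#' Train the real-time monitoring bundle
#'
#' Fits a PARAFAC model on all training EEMs (original + quenched),
#' computes per-pair Fmax and apparent F0/F, selects for each requested
#' target the component with the highest absolute Pearson correlation
#' between original-sample Fmax and the target (overridable), fits an
#' ordinary least-squares calibration line, and builds z-trimmed reference
#' ranges for every component's apparent F0/F and for every comparison
#' indicator (HIX, BIX, AQY, reconstruction errors).
#'
#' @param train An `eem_dataset` whose pairs carry the target(s).
#' @param target_names Character vector, e.g. `c("TCC", "DOC")`.
#' @param R Number of PARAFAC components.
#' @param component Optional named integer vector forcing the calibration
#'   component per target.
#' @param z_max z-score trimming threshold (default 3).
#' @param range_mode "minmax" (default) or "percentile".
#' @param seed,n_restarts Passed to [fit_parafac_hals()].
#' @return An object of class `monitor_bundle`: `model`, `calibrations`
#'   (per target: component, slope, intercept, pearson_r, r_squared),
#'   `f0f_ranges` (per component), `index_ranges` (per indicator),
#'   `train_f0f` (matrix), `z_max`, `range_mode`.
#' @export
train_monitor <- function(train, target_names = "TCC", R = 3, component = NULL,
                          z_max = 3, range_mode = "minmax", seed = 1,
                          n_restarts = 3) {
  stopifnot(inherits(train, "eem_dataset"))
  n <- length(train$pairs)
  if (n < max(3, 2 * R)) stop("too few training pairs")
  model <- fit_parafac_hals(train, R, seed = seed, n_restarts = n_restarts)
  tab <- dataset_f0f(model, train)
  ids <- dataset_ids(train)
  fmax_o <- matrix(tab$fmax_original, nrow = n, ncol = R, byrow = TRUE)
  f0f <- matrix(tab$apparent_f0f, nrow = n, ncol = R, byrow = TRUE)
  rownames(fmax_o) <- rownames(f0f) <- ids

  calibrations <- list()
  for (t in target_names) {
    y <- vapply(train$pairs, target_of, numeric(1), name = t)
    if (all(is.na(y))) stop(sprintf("no training pair carries target '%s'", t))
    if (stats::sd(y, na.rm = TRUE) == 0) {
      stop(sprintf("target '%s' is constant in training; correlation undefined", t))
    }
    cors <- vapply(seq_len(R), function(r) {
      if (stats::sd(fmax_o[, r]) == 0) return(0)
      stats::cor(fmax_o[, r], y, use = "complete.obs")
    }, numeric(1))
    comp <- if (!is.null(component) && !is.null(component[[t]])) {
      as.integer(component[[t]])
    } else {
      which.max(abs(cors)) # ties broken toward the lower index by which.max
    }
    fit <- stats::lm(y ~ fmax_o[, comp])
    # synthetic calibrations can be exact; the perfect-fit warning is noise
    r2 <- suppressWarnings(summary(fit)$r.squared)
    calibrations[[t]] <- list(component = comp,
                              slope = unname(stats::coef(fit)[2]),
                              intercept = unname(stats::coef(fit)[1]),
                              pearson_r = cors[comp],
                              r_squared = r2,
                              target_name = t)
  }

  f0f_ranges <- lapply(seq_len(R), function(r)
    reference_range(f0f[, r], z_max = z_max, mode = range_mode))

  idx <- lapply(train$pairs, compute_indices, model = model)
  index_names <- c("hix", "bix", "aqy_254", "aqy_320",
                   "reconstruction_error", "relative_reconstruction_error")
  index_ranges <- list()
  for (nm in index_names) {
    vals <- vapply(idx, function(s) s[[nm]], numeric(1))
    if (sum(is.finite(vals)) >= 3) {
      index_ranges[[nm]] <- reference_range(vals, z_max = z_max, mode = range_mode)
    }
  }

  structure(list(model = model, calibrations = calibrations,
                 f0f_ranges = f0f_ranges, index_ranges = index_ranges,
                 train_f0f = f0f, z_max = z_max, range_mode = range_mode),
            class = "monitor_bundle")
}

#' Predict targets for a new sample and flag reliability outliers
#'
#' Projects the pair's original and quenched EEMs onto the trained PARAFAC
#' components, predicts each calibrated target from the original-sample
#' Fmax via the training regression line, and flags the sample per
#' component when its apparent F0/F falls outside the historical reference
#' range (and per indicator by the same protocol). Predictions are never
#' suppressed for flagged samples — flags are advisory; negative
#' predictions are returned as-is with a warning.
#'
#' @param bundle A `monitor_bundle` from [train_monitor()].
#' @param pair A `sample_pair` on the model grid.
#' @return An object of class `monitor_verdict`: `sample_id`,
#'   `predictions` (named numeric), `apparent_f0f` (per component),
#'   `f0f_outlier_flags` (per component), `index_values`,
#'   `index_outlier_flags`, `any_f0f_outlier`.
#' @export
predict_sample <- function(bundle, pair) {
  stopifnot(inherits(bundle, "monitor_bundle"), inherits(pair, "sample_pair"))
  model <- bundle$model
  fo <- project_eem(model, pair$original)$fmax
  fq <- project_eem(model, pair$quenched)$fmax
  f0f <- ifelse(fq > 0, fo / fq, NA_real_)

  predictions <- vapply(bundle$calibrations, function(cl)
    cl$intercept + cl$slope * fo[cl$component], numeric(1))
  if (any(predictions < 0, na.rm = TRUE)) {
    warning(sprintf("sample '%s': negative prediction reported as-is", pair$sample_id))
  }

  f0f_flags <- vapply(seq_along(bundle$f0f_ranges), function(r)
    !in_range(f0f[r], bundle$f0f_ranges[[r]]), logical(1))

  idx <- suppressMessages(compute_indices(pair, model = model))
  index_flags <- vapply(names(bundle$index_ranges), function(nm)
    !in_range(idx[[nm]], bundle$index_ranges[[nm]]), logical(1))

  structure(list(sample_id = pair$sample_id, predictions = predictions,
                 apparent_f0f = f0f, f0f_outlier_flags = f0f_flags,
                 index_values = idx, index_outlier_flags = index_flags,
                 any_f0f_outlier = any(f0f_flags)),
            class = "monitor_verdict")
}

#' Predict a whole dataset
#' @param bundle A `monitor_bundle`.
#' @param dataset An `eem_dataset`.
#' @return List of `monitor_verdict` objects (named by sample id).
#' @export
predict_dataset <- function(bundle, dataset) {
  out <- lapply(dataset$pairs, function(p) predict_sample(bundle, p))
  stats::setNames(out, dataset_ids(dataset))
}

#' Relative prediction error
#'
#' The ratio of the absolute error to the true value,
#' `|predicted - actual| / |actual|`; scale-invariant.
#'
#' @param predicted,actual Numeric (vectorized); `actual` must be nonzero.
#' @return Numeric.
#' @export
relative_error <- function(predicted, actual) {
  if (any(actual == 0)) stop("relative error undefined for actual = 0")
  abs(predicted - actual) / abs(actual)
}

#' Fraction of verdicts flagged by a selected indicator
#'
#' @param verdicts List of `monitor_verdict` objects.
#' @param flag_selector Either an integer (component index: uses the
#'   per-component F0/F flag), the string "any" (any-component F0/F flag),
#'   or an indicator name from the index ranges (e.g. "hix").
#' @return Proportion in [0, 1].
#' @export
outlier_rate <- function(verdicts, flag_selector = "any") {
  if (length(verdicts) == 0) stop("empty verdict list")
  flags <- vapply(verdicts, function(v) {
    if (is.numeric(flag_selector)) v$f0f_outlier_flags[flag_selector]
    else if (identical(flag_selector, "any")) v$any_f0f_outlier
    else v$index_outlier_flags[[flag_selector]] %||% NA
  }, logical(1))
  mean(flags, na.rm = TRUE)
}

#' Write monitoring verdicts to a tidy CSV
#' @param verdicts List of `monitor_verdict`s.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_verdicts <- function(verdicts, path) {
  rows <- lapply(verdicts, function(v) {
    row <- data.frame(sample_id = v$sample_id, stringsAsFactors = FALSE)
    for (t in names(v$predictions)) row[[paste0("pred_", t)]] <- v$predictions[[t]]
    for (r in seq_along(v$apparent_f0f)) {
      row[[sprintf("f0f_C%d", r)]] <- v$apparent_f0f[r]
      row[[sprintf("flag_C%d", r)]] <- v$f0f_outlier_flags[r]
    }
    for (nm in names(v$index_outlier_flags)) row[[paste0("flag_", nm)]] <- v$index_outlier_flags[[nm]]
    row$flag_any_f0f <- v$any_f0f_outlier
    row
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
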