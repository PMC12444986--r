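#' Wavelength grid for excitation-emission matrices
#'
#' A grid is the pair of wavelength axes on which an EEM is measured.
#' Axes are stored strictly ascending; downstream math relies on this.
#'
#' @param excitation Numeric vector of excitation wavelengths (nm).
#' @param emission Numeric vector of emission wavelengths (nm).
#' @return An object of class `wl_grid` with elements `ex` and `em`.
#' @examples
#' g <- wl_grid(seq(274, 400, by = 2), seq(309.6, 500.4, by = 1.19))
#' @export
wl_grid <- function(excitation, emission) {
  excitation <- as.numeric(excitation)
  emission <- as.numeric(emission)
  for (ax in list(excitation = excitation, emission = emission)) {
    if (length(ax) < 2L) stop("wavelength axes need at least 2 points")
    if (any(!is.finite(ax)) || any(ax <= 0)) {
      stop("wavelengths must be finite and positive")
    }
    if (any(diff(ax) <= 0)) stop("wavelength axes must be strictly increasing")
  }
  structure(list(ex = excitation, em = emission), class = "wl_grid")
}

#' Default instrument wavelength grid
#'
#' Excitation 274-400 nm in 2 nm steps; emission 309.6-500.4 nm in 1.19 nm
#' steps (a common bench spectrometer configuration for protein-like and
#' humic-like fluorescence).
#'
#' @param ex_step,em_step Optional coarser steps for faster simulation;
#'   the ranges stay fixed.
#' @return A `wl_grid`.
#' @export
default_grid <- function(ex_step = 2, em_step = 1.19) {
  wl_grid(seq(274, 400, by = ex_step), seq(309.6, 500.4, by = em_step))
}

#' Test two grids for equality within a wavelength tolerance
#' @param a,b `wl_grid` objects.
#' @param tol Tolerance in nm (default 1e-6).
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-6) {
  length(a$ex) == length(b$ex) && length(a$em) == length(b$em) &&
    max(abs(a$ex - b$ex)) <= tol && max(abs(a$em - b$em)) <= tol
}

#' Construct an excitation-emission matrix (EEM)
#'
#' @param grid A `wl_grid`.
#' @param intensity Numeric matrix, `length(grid$ex)` rows (excitation) by
#'   `length(grid$em)` columns (emission), arbitrary fluorescence units.
#' @param mask Optional logical matrix of the same shape; `TRUE` marks cells
#'   removed/invalid (e.g. scatter) awaiting interpolation.
#' @return An object of class `eem`.
#' @export
eem <- function(grid, intensity, mask = NULL) {
  stopifnot(inherits(grid, "wl_grid"))
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(grid$ex) || ncol(intensity) != length(grid$em)) {
    stop(sprintf("intensity is %d x %d but grid is %d ex x %d em",
                 nrow(intensity), ncol(intensity),
                 length(grid$ex), length(grid$em)))
  }
  if (is.null(mask)) {
    mask <- is.na(intensity)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(intensity))) stop("mask shape mismatch")
    mask <- mask | is.na(intensity)
  }
  if (any(!is.finite(intensity[!mask]))) stop("unmasked intensities must be finite")
  structure(list(grid = grid, intensity = intensity, mask = mask), class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d ex (%.1f-%.1f nm) x %d em (%.1f-%.1f nm), %d masked cells\n",
              length(x$grid$ex), min(x$grid$ex), max(x$grid$ex),
              length(x$grid$em), min(x$grid$em), max(x$grid$em),
              sum(x$mask)))
  invisible(x)
}

#' Construct an absorbance spectrum
#'
#' @param wavelengths Numeric, nm, strictly increasing.
#' @param absorbance Numeric, dimensionless (per cm pathlength), >= 0.
#' @return An object of class `abs_spectrum`.
#' @export
abs_spectrum <- function(wavelengths, absorbance) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance)) stop("length mismatch")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(!is.finite(absorbance)) || any(absorbance < 0)) {
    stop("absorbance must be finite and >= 0")
  }
  structure(list(wl = wavelengths, a = absorbance), class = "abs_spectrum")
}

#' Evaluate an absorbance spectrum at arbitrary wavelengths
#' @param spec An `abs_spectrum`.
#' @param wl Wavelengths (nm); must lie inside the spectrum's range.
#' @return Numeric vector of absorbance values.
#' @export
abs_at <- function(spec, wl) {
  if (min(wl) < min(spec$wl) - 1e-9 || max(wl) > max(spec$wl) + 1e-9) {
    stop(sprintf("absorbance spectrum covers %.1f-%.1f nm; %.1f-%.1f requested",
                 min(spec$wl), max(spec$wl), min(wl), max(wl)))
  }
  stats::approx(spec$wl, spec$a, xout = wl, rule = 2)$y
}

#' Construct a paired original/quenched sample
#'
#' One physical sample measured twice: once untouched (`original`) and once
#' after dosing an extrinsic quencher such as iodide (`quenched`). The pair is
#' the unit on which the apparent F0/F indicator is defined.
#'
#' @param sample_id Character id, unique within a dataset.
#' @param original,quenched `eem` objects on a common grid.
#' @param quencher_conc Quencher dose Q_e in g/L (>= 0).
#' @param absorbance Optional `abs_spectrum` for inner-filter correction.
#' @param targets Optional named numeric vector of reference measurements
#'   (e.g. `c(TCC = 1e5, DOC = 3.2)`).
#' @param labels Optional named character vector of condition/location tags.
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(sample_id, original, quenched, quencher_conc,
                        absorbance = NULL, targets = NULL, labels = NULL) {
  stopifnot(inherits(original, "eem"), inherits(quenched, "eem"))
  if (!grid_equal(original$grid, quenched$grid)) {
    stop(sprintf("sample '%s': original and quenched EEMs are on different grids",
                 sample_id))
  }
  if (!is.numeric(quencher_conc) || quencher_conc < 0) {
    stop("quencher_conc must be >= 0")
  }
  structure(list(sample_id = as.character(sample_id), original = original,
                 quenched = quenched, quencher_conc = quencher_conc,
                 absorbance = absorbance, targets = targets, labels = labels),
            class = "sample_pair")
}

#' Construct a dataset of sample pairs
#'
#' @param pairs List of `sample_pair` objects with unique ids on one grid.
#' @param provenance Free-text metadata.
#' @return An object of class `eem_dataset`.
#' @export
eem_dataset <- function(pairs, provenance = "") {
  if (length(pairs) == 0L) stop("dataset must contain at least one pair")
  ids <- vapply(pairs, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  g <- pairs[[1]]$original$grid
  for (p in pairs) {
    if (!grid_equal(p$original$grid, g)) {
      stop(sprintf("sample '%s' is not on the common grid", p$sample_id))
    }
  }
  structure(list(pairs = pairs, provenance = provenance), class = "eem_dataset")
}

#' @export
print.eem_dataset <- function(x, ...) {
  cat(sprintf("<eem_dataset> %d sample pairs on a %d x %d grid\n",
              length(x$pairs), length(x$pairs[[1]]$original$grid$ex),
              length(x$pairs[[1]]$original$grid$em)))
  invisible(x)
}

#' Sample ids of a dataset
#' @param dataset An `eem_dataset`.
#' @return Character vector.
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset$pairs, function(p) p$sample_id, character(1))
}

#' Flatten a dataset to an interleaved list of EEMs
#'
#' Returns the original and quenched EEM of every pair (both enter PARAFAC
#' model establishment), with names `<id>__original` / `<id>__quenched`.
#'
#' @param dataset An `eem_dataset`.
#' @return Named list of `eem` objects.
#' @export
dataset_eems <- function(dataset) {
  out <- list()
  for (p in dataset$pairs) {
    out[[paste0(p$sample_id, "__original")]] <- p$original
    out[[paste0(p$sample_id, "__quenched")]] <- p$quenched
  }
  out
}

# ---- file I/O ---------------------------------------------------------------

#' Read an EEM from a wide CSV file
#'
#' Dialect: first row holds emission wavelengths, first column excitation
#' wavelengths, numeric body; the top-left cell is ignored. Axes are sorted
#' ascending on read (rows/columns reordered accordingly). `nan` tokens are
#' read back as masked cells.
#'
#' @param path File path.
#' @return An `eem`.
#' @export
read_eem <- function(path) {
  if (!file.exists(path)) stop(sprintf("EEM file not found: %s", path))
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(raw) < 3L || ncol(raw) < 3L) {
    stop(sprintf("%s: EEM file needs at least 2 excitation rows and 2 emission columns", path))
  }
  em <- suppressWarnings(as.numeric(raw[1, -1]))
  if (any(is.na(em))) {
    stop(sprintf("%s: malformed header row: non-numeric emission wavelength in column %d",
                 path, which(is.na(em))[1] + 1L))
  }
  ex <- suppressWarnings(as.numeric(raw[-1, 1]))
  if (any(is.na(ex))) {
    stop(sprintf("%s: malformed header column: non-numeric excitation wavelength in row %d",
                 path, which(is.na(ex))[1] + 1L))
  }
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  mask <- toupper(trimws(body)) %in% c("NAN", "NA", "")
  dim(mask) <- dim(body)
  num <- suppressWarnings(as.numeric(body))
  dim(num) <- dim(body)
  bad <- which(is.na(num) & !mask, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("%s: non-numeric cell at excitation row %d, emission column %d",
                 path, bad[1, 1] + 1L, bad[1, 2] + 1L))
  }
  num[mask] <- NA_real_
  oex <- order(ex)
  oem <- order(em)
  eem(wl_grid(ex[oex], em[oem]), num[oex, oem, drop = FALSE],
      mask[oex, oem, drop = FALSE])
}

#' Write an EEM to a wide CSV file
#'
#' Inverse of [read_eem()]; masked cells are written as `nan` tokens,
#' never as sentinel numbers.
#'
#' @param x An `eem`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  body <- format(x$intensity, digits = 17, trim = TRUE, scientific = TRUE)
  body[x$mask] <- "nan"
  header <- c("ex_nm\\em_nm", format(x$grid$em, digits = 17, trim = TRUE))
  rows <- cbind(format(x$grid$ex, digits = 17, trim = TRUE), body)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(rows, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a two-column absorbance CSV (wavelength_nm, absorbance)
#' @param path File path.
#' @return An `abs_spectrum`.
#' @export
read_absorbance <- function(path) {
  if (!file.exists(path)) stop(sprintf("absorbance file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop(sprintf("%s: expected two columns", path))
  o <- order(d[[1]])
  abs_spectrum(d[[1]][o], d[[2]][o])
}

#' Bilinearly regrid an EEM onto a target wavelength grid
#'
#' Interpolation only; requesting wavelengths outside the source axes is an
#' error. Masked source cells propagate to every target cell whose bilinear
#' stencil touches them.
#'
#' @param x An `eem`.
#' @param target A `wl_grid` inside the source ranges.
#' @return An `eem` on `target`.
#' @export
regrid <- function(x, target) {
  stopifnot(inherits(x, "eem"), inherits(target, "wl_grid"))
  if (grid_equal(x$grid, target)) return(x)
  if (min(target$ex) < min(x$grid$ex) - 1e-9 ||
      max(target$ex) > max(x$grid$ex) + 1e-9 ||
      min(target$em) < min(x$grid$em) - 1e-9 ||
      max(target$em) > max(x$grid$em) + 1e-9) {
    stop("regrid target extends beyond source grid (extrapolation not supported)")
  }
  # clamp to avoid findInterval edge fall-off from float round-off
  tx <- pmin(pmax(target$ex, min(x$grid$ex)), max(x$grid$ex))
  tm <- pmin(pmax(target$em, min(x$grid$em)), max(x$grid$em))
  ix <- pmin(findInterval(tx, x$grid$ex), length(x$grid$ex) - 1L)
  im <- pmin(findInterval(tm, x$grid$em), length(x$grid$em) - 1L)
  wx <- (tx - x$grid$ex[ix]) / (x$grid$ex[ix + 1L] - x$grid$ex[ix])
  wm <- (tm - x$grid$em[im]) / (x$grid$em[im + 1L] - x$grid$em[im])
  z <- x$intensity
  z[x$mask] <- NA_real_
  out <- outer(1 - wx, 1 - wm) * z[ix, im, drop = FALSE] +
    outer(wx, 1 - wm) * z[ix + 1L, im, drop = FALSE] +
    outer(1 - wx, wm) * z[ix, im + 1L, drop = FALSE] +
    outer(wx, wm) * z[ix + 1L, im + 1L, drop = FALSE]
  eem(wl_grid(target$ex, target$em), out)
}

#' Intersection grid of a list of grids
#'
#' The densest common representation: the union of axis points restricted to
#' the overlapping wavelength range, deduplicated at 1e-6 nm.
#'
#' @param grids List of `wl_grid` objects.
#' @return A `wl_grid`.
#' @export
common_grid <- function(grids) {
  lo_ex <- max(vapply(grids, function(g) min(g$ex), numeric(1)))
  hi_ex <- min(vapply(grids, function(g) max(g$ex), numeric(1)))
  lo_em <- max(vapply(grids, function(g) min(g$em), numeric(1)))
  hi_em <- min(vapply(grids, function(g) max(g$em), numeric(1)))
  if (lo_ex >= hi_ex || lo_em >= hi_em) stop("grids do not overlap")
  dedup <- function(v) v[c(TRUE, diff(v) > 1e-6)]
  ex <- dedup(sort(unlist(lapply(grids, function(g) g$ex))))
  em <- dedup(sort(unlist(lapply(grids, function(g) g$em))))
  wl_grid(ex[ex >= lo_ex - 1e-9 & ex <= hi_ex + 1e-9],
          em[em >= lo_em - 1e-9 & em <= hi_em + 1e-9])
}

#' Read a sample manifest CSV into an EEM dataset
#'
#' Manifest columns: `sample_id`, `eem_original`, `eem_quenched`,
#' `quencher_conc`; optional `absorbance` (path), `TCC`, `DOC` (numeric
#' targets), and any further columns kept as labels. Relative paths are
#' resolved against the manifest's directory. Pairs measured on slightly
#' different grids are regridded onto the common intersection grid.
#'
#' @param path Manifest CSV path.
#' @return An `eem_dataset`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "eem_original", "eem_quenched", "quencher_conc")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop(sprintf("manifest missing columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$sample_id)) {
    stop(sprintf("manifest has duplicate sample_id: %s",
                 paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  target_cols <- intersect(c("TCC", "DOC"), names(d))
  label_cols <- setdiff(names(d), c(req, "absorbance", target_cols))
  pairs <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    id <- d$sample_id[i]
    for (col in c("eem_original", "eem_quenched")) {
      f <- resolve(d[[col]][i])
      if (!file.exists(f)) {
        stop(sprintf("manifest row for sample '%s': file not found: %s", id, d[[col]][i]))
      }
    }
    absorb <- NULL
    if ("absorbance" %in% names(d) && nzchar(d$absorbance[i] %||% "")) {
      f <- resolve(d$absorbance[i])
      if (!file.exists(f)) {
        stop(sprintf("manifest row for sample '%s': absorbance file not found: %s",
                     id, d$absorbance[i]))
      }
      absorb <- read_absorbance(f)
    }
    targets <- NULL
    if (length(target_cols)) {
      vals <- vapply(target_cols, function(cl) as.numeric(d[[cl]][i]), numeric(1))
      vals <- vals[!is.na(vals)]
      if (length(vals)) targets <- vals
    }
    labels <- NULL
    if (length(label_cols)) {
      lv <- vapply(label_cols, function(cl) as.character(d[[cl]][i]), character(1))
      labels <- lv
    }
    pairs[[i]] <- sample_pair(id,
                              read_eem(resolve(d$eem_original[i])),
                              read_eem(resolve(d$eem_quenched[i])),
                              d$quencher_conc[i],
                              absorbance = absorb, targets = targets,
                              labels = labels)
  }
  grids <- unlist(lapply(pairs, function(p) list(p$original$grid, p$quenched$grid)),
                  recursive = FALSE)
  same <- all(vapply(grids, grid_equal, logical(1), b = grids[[1]]))
  if (!same) {
    g <- common_grid(grids)
    pairs <- lapply(pairs, function(p) {
      p$original <- regrid(p$original, g)
      p$quenched <- regrid(p$quenched, g)
      p
    })
  }
  eem_dataset(pairs, provenance = sprintf("manifest: %s", path))
}

#' Write a dataset to disk as EEM CSVs plus a manifest
#'
#' @param dataset An `eem_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- dataset_ids(dataset)
  rows <- lapply(dataset$pairs, function(p) {
    fo <- paste0(p$sample_id, "_original.csv")
    fq <- paste0(p$sample_id, "_quenched.csv")
    write_eem(p$original, file.path(dir, fo))
    write_eem(p$quenched, file.path(dir, fq))
    row <- data.frame(sample_id = p$sample_id, eem_original = fo,
                      eem_quenched = fq, quencher_conc = p$quencher_conc,
                      stringsAsFactors = FALSE)
    for (t in names(p$targets)) row[[t]] <- p$targets[[t]]
    for (l in names(p$labels)) row[[l]] <- p$labels[[l]]
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA
    r[all_cols]
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
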