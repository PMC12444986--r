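#' @title Nonnegative PARAFAC for EEM stacks
#' @description
#' A stack of EEMs sharing one wavelength grid forms a three-way array
#' (sample x excitation x emission). PARAFAC expresses it as a sum of R
#' trilinear components, each an excitation profile (x) emission profile
#' scaled per sample. All three modes are constrained nonnegative, the
#' standard physical constraint for fluorescence. Loadings are normalized
#' to unit maximum so that a sample's score on a component directly equals
#' that component's Fmax (its peak intensity contribution) in the sample.
#' @name parafac
NULL

# Evaluate code with a private, restored RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Khatri-Rao product of columns: column r = vec(outer(a_r, b_r)).
khatri_rao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- as.vector(outer(A[, r], B[, r]))
  out
}

# Stack a list of EEMs into the three mode unfoldings used by HALS.
# X1: samples x (ex*em); X2: ex x (samples*em); X3: em x (samples*ex).
stack_eems <- function(eems) {
  g <- eems[[1]]$grid
  J <- length(g$ex); K <- length(g$em); I <- length(eems)
  X1 <- matrix(0, I, J * K)
  for (i in seq_len(I)) {
    e <- eems[[i]]
    if (!grid_equal(e$grid, g)) stop("all EEMs must share one grid")
    if (any(e$mask)) stop("EEMs entering PARAFAC must have no masked cells (preprocess first)")
    X1[i, ] <- as.vector(e$intensity)
  }
  arr <- array(t(X1), dim = c(J, K, I))          # j,k,i
  X2 <- matrix(aperm(arr, c(1, 3, 2)), J, I * K) # index i + (k-1)I
  X3 <- matrix(aperm(arr, c(2, 3, 1)), K, I * J) # index i + (j-1)I
  list(X1 = X1, X2 = X2, X3 = X3, I = I, J = J, K = K, grid = g)
}

# One HALS sweep for a factor: F (n x R), P = Xunf %*% G, Q = gram product.
hals_update <- function(Fm, P, Q) {
  for (r in seq_len(ncol(Fm))) {
    v <- Fm[, r] + (P[, r] - Fm %*% Q[, r]) / Q[r, r]
    Fm[, r] <- pmax(v, 0)
  }
  Fm
}

# Revive all-zero columns with a tiny deterministic draw so HALS can't stall.
revive_zero <- function(Fm, scale) {
  dead <- colSums(Fm) <= 0
  if (any(dead)) {
    Fm[, dead] <- matrix(stats::runif(nrow(Fm) * sum(dead), 0, 1e-8 * scale),
                         nrow(Fm), sum(dead))
  }
  Fm
}

parafac_single_fit <- function(st, R, max_iter, tol) {
  I <- st$I; J <- st$J; K <- st$K
  scale <- sqrt(mean(st$X1^2)) + 1e-300
  S <- matrix(stats::runif(I * R), I, R) * scale
  A <- matrix(stats::runif(J * R), J, R)
  B <- matrix(stats::runif(K * R), K, R)
  ssq_x <- sum(st$X1^2)
  err_prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # excitation loadings
    G <- khatri_rao(S, B)                         # (I*K) x R, index i+(k-1)I
    Q <- crossprod(S) * crossprod(B)
    A <- revive_zero(hals_update(A, st$X2 %*% G, Q), 1)
    # emission loadings
    G <- khatri_rao(S, A)                         # (I*J) x R
    Q <- crossprod(S) * crossprod(A)
    B <- revive_zero(hals_update(B, st$X3 %*% G, Q), 1)
    # scores
    G <- khatri_rao(A, B)                         # (J*K) x R
    Q <- crossprod(A) * crossprod(B)
    P <- st$X1 %*% G
    S <- revive_zero(hals_update(S, P, Q), scale)
    ssq_res <- max(ssq_x - 2 * sum(P * S) + sum(crossprod(S) * Q), 0)
    err <- sqrt(ssq_res / ssq_x)
    trace <- c(trace, err)
    if (!is.finite(err)) stop("PARAFAC diverged (non-finite reconstruction error)")
    if (abs(err_prev - err) < tol) break
    err_prev <- err
  }
  list(S = S, A = A, B = B, err = err, trace = trace, iters = it)
}

# Push loading scales into the scores so both loadings have unit maximum.
normalize_unit_max <- function(S, A, B) {
  ma <- apply(A, 2, max)
  mb <- apply(B, 2, max)
  ma[ma <= 0] <- 1
  mb[mb <= 0] <- 1
  list(S = S * rep(ma * mb, each = nrow(S)),
       A = sweep(A, 2, ma, "/"),
       B = sweep(B, 2, mb, "/"))
}

#' Fit a nonnegative PARAFAC model by hierarchical alternating least squares
#'
#' Multiplicative-free HALS: each factor column is updated in turn by a
#' nonnegatively-clipped exact coordinate step, which makes the squared
#' reconstruction error non-increasing. The best of `n_restarts` random
#' nonnegative initializations (seed-controlled, reproducible) is kept.
#' Components are returned in decreasing order of total score and with
#' excitation/emission loadings normalized to unit maximum, so
#' `scores[i, r]` is component r's Fmax in EEM i.
#'
#' @param eems A list of `eem` objects on one grid, or an `eem_dataset`
#'   (whose original and quenched EEMs all enter the fit).
#' @param R Number of components (>= 1).
#' @param max_iter Maximum HALS sweeps per restart (default 500).
#' @param tol Convergence threshold on the change of relative reconstruction
#'   error between sweeps (default 1e-8).
#' @param n_restarts Random restarts (default 5).
#' @param seed Integer seed controlling all restarts.
#' @return An object of class `parafac_model`: `ex_loadings` (n_ex x R),
#'   `em_loadings` (n_em x R), `scores` (n_eems x R), `grid`, `eem_ids`,
#'   `R`, `rel_error`, `obj_trace` (per-iteration relative error of the
#'   winning restart).
#' @export
fit_parafac_hals <- function(eems, R, max_iter = 500, tol = 1e-8,
                             n_restarts = 5, seed = 1) {
  if (inherits(eems, "eem_dataset")) eems <- dataset_eems(eems)
  if (!is.numeric(R) || R < 1) stop("R must be a positive integer")
  R <- as.integer(R)
  if (length(eems) < 2L) stop("need at least 2 EEMs")
  ids <- names(eems)
  if (is.null(ids)) ids <- sprintf("eem_%03d", seq_along(eems))
  st <- stack_eems(eems)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    fit <- with_seed(seed + k - 1L,
                     parafac_single_fit(st, R, max_iter, tol))
    if (is.null(best) || fit$err < best$err) best <- fit
  }
  nz <- normalize_unit_max(best$S, best$A, best$B)
  ord <- order(colSums(nz$S), decreasing = TRUE)
  structure(list(ex_loadings = nz$A[, ord, drop = FALSE],
                 em_loadings = nz$B[, ord, drop = FALSE],
                 scores = nz$S[, ord, drop = FALSE],
                 grid = st$grid, eem_ids = ids, R = R,
                 rel_error = best$err, obj_trace = best$trace,
                 opts = list(max_iter = max_iter, tol = tol,
                             n_restarts = n_restarts, seed = seed)),
            class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("<parafac_model> R = %d, %d EEMs, relative error %.3g\n",
              x$R, nrow(x$scores), x$rel_error))
  invisible(x)
}

#' Fmax of every component in one modeled EEM
#'
#' Fmax is a component's score multiplied by the maxima of its excitation and
#' emission loadings — the component's peak intensity contribution. With the
#' unit-maximum loading convention used here it equals the score, but the
#' product form is computed so the value is invariant to renormalization.
#'
#' @param model A `parafac_model`.
#' @param eem_index Row index or EEM id.
#' @return Numeric vector of length R.
#' @export
compute_fmax <- function(model, eem_index) {
  if (is.character(eem_index)) {
    i <- match(eem_index, model$eem_ids)
    if (is.na(i)) stop(sprintf("unknown EEM id '%s'", eem_index))
  } else {
    i <- as.integer(eem_index)
    if (i < 1 || i > nrow(model$scores)) stop("EEM index out of bounds")
  }
  model$scores[i, ] * apply(model$ex_loadings, 2, max) *
    apply(model$em_loadings, 2, max)
}

# JK x R matrix whose columns are the vectorized component patterns.
component_basis <- function(model) {
  khatri_rao(model$ex_loadings, model$em_loadings)
}

# Exact small-scale nonnegative least squares by enumerating active sets.
nnls_exact <- function(AtA, Atb) {
  R <- length(Atb)
  if (R > 12) stop("nnls_exact supports up to 12 components")
  best_x <- rep(0, R)
  best_obj <- 0 # objective relative to x = 0: x'AtA x - 2 x'Atb
  for (code in seq_len(2^R) - 1L) {
    s <- which(bitwAnd(code, 2^(seq_len(R) - 1L)) > 0)
    if (length(s) == 0) next
    x_s <- tryCatch(solve(AtA[s, s, drop = FALSE], Atb[s]),
                    error = function(e) NULL)
    if (is.null(x_s) || any(!is.finite(x_s)) || any(x_s < 0)) next
    obj <- sum(x_s * (AtA[s, s, drop = FALSE] %*% x_s)) - 2 * sum(x_s * Atb[s])
    if (obj < best_obj - 1e-12 * max(abs(best_obj), 1)) {
      best_obj <- obj
      best_x <- rep(0, R)
      best_x[s] <- x_s
    }
  }
  best_x
}

#' Project a new EEM onto fixed PARAFAC components
#'
#' Solves a nonnegative least-squares fit of the model's fixed
#' excitation (x) emission component patterns to the new EEM, yielding the
#' new sample's scores (= Fmax under the unit-maximum convention) without
#' refitting the model.
#'
#' @param model A `parafac_model`.
#' @param x An `eem` on the model grid.
#' @return List with `scores` (length R), `fmax` (identical scale),
#'   `residual_norm` (Frobenius norm of the misfit), and
#'   `relative_residual`.
#' @export
project_eem <- function(model, x) {
  stopifnot(inherits(model, "parafac_model"), inherits(x, "eem"))
  if (!grid_equal(model$grid, x$grid)) stop("EEM is not on the model grid")
  if (any(x$mask)) stop("EEM has masked cells; preprocess first")
  Phi <- component_basis(model)
  y <- as.vector(x$intensity)
  s <- nnls_exact(crossprod(Phi), crossprod(Phi, y))
  resid <- y - Phi %*% s
  rn <- sqrt(sum(resid^2))
  yn <- sqrt(sum(y^2))
  list(scores = as.numeric(s),
       fmax = as.numeric(s) * apply(model$ex_loadings, 2, max) *
         apply(model$em_loadings, 2, max),
       residual_norm = rn,
       relative_residual = if (yn > 0) rn / yn else 0)
}

#' Reconstruct the model's fitted EEM for one sample
#' @param model A `parafac_model`.
#' @param scores Length-R score vector (e.g. from [project_eem()]).
#' @return An `eem` on the model grid.
#' @export
reconstruct_eem <- function(model, scores) {
  z <- matrix(0, length(model$grid$ex), length(model$grid$em))
  for (r in seq_len(model$R)) {
    z <- z + scores[r] * outer(model$ex_loadings[, r], model$em_loadings[, r])
  }
  eem(model$grid, z)
}

#' Tucker congruence coefficient of two loading vectors
#'
#' The cosine similarity `a.b / (|a| |b|)`; 1 for proportional vectors,
#' 0 for orthogonal ones. The standard statistic for matching PARAFAC
#' components across models (as used by spectral libraries).
#'
#' @param a,b Numeric vectors of equal length with nonzero norm.
#' @return Scalar in [-1, 1].
#' @export
tucker_congruence <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("tucker_congruence undefined for zero vectors")
  sum(a * b) / (na * nb)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Match components of one PARAFAC model to another
#'
#' Finds the permutation of model `b`'s components maximizing the summed
#' excitation-plus-emission Tucker congruence with model `a`'s components,
#' by exhaustive search over permutations (exact optimal assignment; ties
#' broken toward the lexicographically smallest permutation).
#'
#' @param a,b `parafac_model` objects with equal R on one grid.
#' @return Integer vector `perm`: `b`'s component `perm[r]` matches `a`'s
#'   component `r`. Attribute `congruence` holds the per-pair mean
#'   excitation/emission congruence.
#' @export
match_components <- function(a, b) {
  if (a$R != b$R) stop("models have different numbers of components")
  R <- a$R
  if (R > 8) stop("exhaustive matching supports up to 8 components")
  C <- matrix(0, R, R)
  for (r in seq_len(R)) {
    for (s in seq_len(R)) {
      C[r, s] <- tucker_congruence(a$ex_loadings[, r], b$ex_loadings[, s]) +
        tucker_congruence(a$em_loadings[, r], b$em_loadings[, s])
    }
  }
  perms <- all_permutations(R)
  # all_permutations emits lexicographic order for the tie-break
  perms <- perms[order(vapply(perms, function(p) paste(sprintf("%02d", p), collapse = ""), character(1)))]
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    v <- sum(C[cbind(seq_len(R), p)])
    if (v > best_val + 1e-12) {
      best_val <- v
      best <- p
    }
  }
  structure(as.integer(best),
            congruence = C[cbind(seq_len(R), best)] / 2)
}

#' Split-half similarity of PARAFAC loadings at a candidate component count
#'
#' For each of N random halvings of the sample pairs (a pair's original and
#' quenched EEMs always fall in the same half), a model is fitted on each
#' half, components are matched by Tucker congruence, and the Pearson
#' correlations of matched excitation and emission loadings are recorded.
#' The summary statistic is the mean over splits and components of
#' `(sim_ex + sim_em)/2`.
#'
#' @param dataset An `eem_dataset` with at least 4 pairs.
#' @param R Candidate component count.
#' @param N Number of split-half repetitions (default 100).
#' @param seed Integer seed.
#' @param n_restarts Restarts per half-fit (default 2; halves are refit many
#'   times so this trades robustness for time).
#' @param max_iter,tol Passed to [fit_parafac_hals()].
#' @return List of class `split_half_result`: `R`, `mean_similarity`,
#'   `per_split` (data frame with split, component, sim_ex, sim_em), `N`.
#' @export
split_half_similarity <- function(dataset, R, N = 100, seed = 1,
                                  n_restarts = 2, max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(dataset, "eem_dataset"))
  n <- length(dataset$pairs)
  if (n < 4) stop("split-half validation needs at least 4 sample pairs")
  if (N < 1) stop("N must be >= 1")
  if (floor(n / 2) * 2 < 2 * R) {
    stop(sprintf("halves of %d pairs are too small to fit R = %d", n, R))
  }
  rows <- vector("list", N)
  split_base <- (as.numeric(seed) %% 2000000) * 1000
  for (s in seq_len(N)) {
    idx <- with_seed(split_base + s, sample.int(n))
    h1 <- idx[seq_len(floor(n / 2))]
    h2 <- idx[(floor(n / 2) + 1L):n]
    m1 <- fit_parafac_hals(eem_dataset(dataset$pairs[h1]), R,
                           max_iter = max_iter, tol = tol,
                           n_restarts = n_restarts, seed = seed + 7L * s)
    m2 <- fit_parafac_hals(eem_dataset(dataset$pairs[h2]), R,
                           max_iter = max_iter, tol = tol,
                           n_restarts = n_restarts, seed = seed + 7L * s + 3L)
    perm <- match_components(m1, m2)
    rows[[s]] <- data.frame(
      split = s, component = seq_len(R),
      sim_ex = vapply(seq_len(R), function(r)
        stats::cor(m1$ex_loadings[, r], m2$ex_loadings[, perm[r]]), numeric(1)),
      sim_em = vapply(seq_len(R), function(r)
        stats::cor(m1$em_loadings[, r], m2$em_loadings[, perm[r]]), numeric(1)))
  }
  per_split <- do.call(rbind, rows)
  structure(list(R = R,
                 mean_similarity = mean((per_split$sim_ex + per_split$sim_em) / 2),
                 per_split = per_split, N = N),
            class = "split_half_result")
}

#' Does a fitted model duplicate a component?
#'
#' Near-identical components (both-mode Tucker congruence above the cutoff
#' between two components of one model) are the classic sign of
#' overfactoring: the solver split one chemical signature in two. Such
#' models can look deceptively stable under split-half validation because
#' the duplicated loadings correlate perfectly across halves.
#'
#' @param model A `parafac_model`.
#' @param cutoff Congruence cutoff (default 0.98).
#' @return Logical scalar.
#' @export
has_duplicate_components <- function(model, cutoff = 0.98) {
  R <- model$R
  if (R < 2) return(FALSE)
  for (r in seq_len(R - 1)) {
    for (s in (r + 1):R) {
      if (tucker_congruence(model$ex_loadings[, r], model$ex_loadings[, s]) > cutoff &&
          tucker_congruence(model$em_loadings[, r], model$em_loadings[, s]) > cutoff) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Choose the number of PARAFAC components by split-half similarity
#'
#' Computes the split-half similarity curve over a range of candidate R and
#' recommends the largest R whose mean similarity reaches the threshold
#' (stable loadings) and whose full-data fit does not duplicate a
#' component (see [has_duplicate_components()]); if no candidate qualifies,
#' the similarity argmax is returned with a warning.
#'
#' @param dataset An `eem_dataset`.
#' @param R_range Candidate component counts (default 2:6).
#' @param N Split repetitions per candidate.
#' @param seed Integer seed.
#' @param threshold Similarity cutoff (default 0.95).
#' @param ... Passed to [split_half_similarity()].
#' @return List with `recommended_R` and `curve` (data frame R,
#'   mean_similarity).
#' @export
select_n_components <- function(dataset, R_range = 2:6, N = 100, seed = 1,
                                threshold = 0.95, ...) {
  if (length(R_range) == 0) stop("R_range must be nonempty")
  sims <- vapply(R_range, function(R)
    split_half_similarity(dataset, R, N = N, seed = seed, ...)$mean_similarity,
    numeric(1))
  dup <- vapply(R_range, function(R)
    has_duplicate_components(fit_parafac_hals(dataset, R, seed = seed,
                                              n_restarts = 2)),
    logical(1))
  curve <- data.frame(R = R_range, mean_similarity = sims, duplicated = dup)
  pass <- R_range[sims >= threshold & !dup]
  if (length(pass) > 0) {
    rec <- max(pass)
  } else {
    rec <- R_range[which.max(sims)]
    warning(sprintf("no candidate reached split-half similarity %.3f; returning argmax R = %d",
                    threshold, rec))
  }
  list(recommended_R = rec, curve = curve)
}

#' Write a PARAFAC model to a directory of CSV/JSON files
#' @param model A `parafac_model`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_parafac <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(ex_nm = model$grid$ex, model$ex_loadings),
                   file.path(dir, "ex_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(em_nm = model$grid$em, model$em_loadings),
                   file.path(dir, "em_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(eem_id = model$eem_ids, model$scores),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(list(R = model$R, rel_error = model$rel_error,
                            opts = model$opts),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a PARAFAC model written by [write_parafac()]
#' @param dir Model directory.
#' @return A `parafac_model`.
#' @export
read_parafac <- function(dir) {
  exd <- utils::read.csv(file.path(dir, "ex_loadings.csv"))
  emd <- utils::read.csv(file.path(dir, "em_loadings.csv"))
  sc <- utils::read.csv(file.path(dir, "scores.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(ex_loadings = as.matrix(exd[, -1, drop = FALSE]),
                 em_loadings = as.matrix(emd[, -1, drop = FALSE]),
                 scores = as.matrix(sc[, -1, drop = FALSE]),
                 grid = wl_grid(exd[[1]], emd[[1]]),
                 eem_ids = as.character(sc[[1]]),
                 R = as.integer(meta$R), rel_error = meta$rel_error,
                 obj_trace = numeric(0), opts = meta$opts),
            class = "parafac_model")
}
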