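#' Cluster sample pairs by apparent F0/F with per-cluster PARAFAC models
#'
#' A k-means-style alternation in the space of apparent-F0/F vectors.
#' Initialization: a global PARAFAC model at `R` is fitted on all EEMs, each
#' pair's per-component apparent F0/F vector is computed under it, and the
#' vectors are k-means-partitioned into `K` groups. Iteration: a PARAFAC
#' model is refitted on each cluster's member EEMs (original + quenched),
#' its components are matched to the global model by Tucker congruence so
#' F0/F vectors stay comparable across clusters, every pair is projected
#' under every cluster model, and each pair is reassigned to the cluster
#' whose centroid F0/F vector (mean over current members under that
#' cluster's own model) is nearest in squared distance. The objective is
#' the sum of squared distances of pairs to their assigned centroids; an
#' iteration is accepted only if it does not increase the objective, so the
#' recorded trace is non-increasing. Pairs move atomically (original and
#' quenched EEMs are always co-clustered).
#'
#' Clusters shrinking below `min_size` are refilled with the nearest
#' surplus pairs from the largest cluster (deterministic: by distance,
#' ties by sample id).
#'
#' @param dataset An `eem_dataset` with at least `K * min_size` pairs.
#' @param K Number of clusters (>= 1).
#' @param R Components per PARAFAC model.
#' @param max_iter Maximum alternation steps (default 20).
#' @param min_size Minimum cluster size (default `2 * R` pairs).
#' @param seed Integer seed (k-means init and PARAFAC restarts).
#' @param n_restarts Restarts for the per-cluster fits (default 2).
#' @return An object of class `f0f_clustering`: `labels` (named integer
#'   vector, sample_id -> cluster), `models` (per-cluster `parafac_model`),
#'   `global_model`, `f0f_centroids` (K x R matrix), `objective_trace`,
#'   `f0f` (pair x component matrix under the assigned cluster's model).
#' @export
f0f_kparafacs <- function(dataset, K, R, max_iter = 20, min_size = 2 * R,
                          seed = 1, n_restarts = 2) {
  stopifnot(inherits(dataset, "eem_dataset"))
  if (K < 1) stop("K must be >= 1")
  n <- length(dataset$pairs)
  if (n < K * min_size) {
    stop(sprintf("%d pairs cannot sustain %d clusters of at least %d", n, K, min_size))
  }
  ids <- dataset_ids(dataset)

  # vapply collapses to a plain vector at R = 1; force a pairs x R matrix
  f0f_matrix <- function(pairs, model) {
    v <- vapply(pairs, function(p) pair_f0f(model, p), numeric(R))
    if (R == 1) matrix(v, ncol = 1) else t(v)
  }

  global <- fit_parafac_hals(dataset, R, seed = seed, n_restarts = n_restarts)
  f0f_global <- f0f_matrix(dataset$pairs, global)

  if (K == 1L) {
    labels <- stats::setNames(rep(1L, n), ids)
    centroid <- matrix(colMeans(f0f_global, na.rm = TRUE), 1, R)
    obj <- sum((sweep(f0f_global, 2, centroid[1, ]))^2, na.rm = TRUE)
    return(structure(list(labels = labels, models = list(global),
                          global_model = global, f0f_centroids = centroid,
                          objective_trace = obj, f0f = f0f_global),
                     class = "f0f_clustering"))
  }

  seed_v <- f0f_global
  seed_v[!is.finite(seed_v)] <- mean(seed_v[is.finite(seed_v)])
  km <- with_seed(seed, stats::kmeans(seed_v, centers = K, nstart = 10))
  labels <- km$cluster

  enforce_min_size <- function(labels, dist_mat) {
    repeat {
      sizes <- tabulate(labels, K)
      small <- which(sizes < min_size)
      if (length(small) == 0) return(labels)
      k <- small[1]
      donor <- which.max(sizes)
      cand <- which(labels == donor)
      ord <- cand[order(dist_mat[cand, k], ids[cand])]
      take <- ord[seq_len(min(min_size - sizes[k], length(ord) - min_size))]
      if (length(take) == 0) return(labels)
      labels[take] <- k
    }
  }

  models <- vector("list", K)
  centroids <- matrix(NA_real_, K, R)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  f0f_assigned <- f0f_global

  for (iter in seq_len(max_iter)) {
    f0f_by_model <- vector("list", K)
    for (k in seq_len(K)) {
      members <- which(labels == k)
      mdl <- fit_parafac_hals(eem_dataset(dataset$pairs[members]), R,
                              seed = seed + 31L * iter + k,
                              n_restarts = n_restarts)
      perm <- match_components(global, mdl)
      mdl$ex_loadings <- mdl$ex_loadings[, perm, drop = FALSE]
      mdl$em_loadings <- mdl$em_loadings[, perm, drop = FALSE]
      mdl$scores <- mdl$scores[, perm, drop = FALSE]
      models[[k]] <- mdl
      f0f_by_model[[k]] <- f0f_matrix(dataset$pairs, mdl)
      centroids[k, ] <- colMeans(f0f_by_model[[k]][members, , drop = FALSE],
                                 na.rm = TRUE)
    }
    dist_mat <- matrix(Inf, n, K)
    for (k in seq_len(K)) {
      d <- sweep(f0f_by_model[[k]], 2, centroids[k, ])^2
      dist_mat[, k] <- rowSums(d, na.rm = TRUE) +
        ifelse(rowSums(is.finite(d)) == 0, Inf, 0)
    }
    new_labels <- max.col(-dist_mat, ties.method = "first")
    new_labels <- enforce_min_size(new_labels, dist_mat)
    obj <- sum(dist_mat[cbind(seq_len(n), new_labels)])
    if (obj > obj_prev + 1e-12) break  # reject non-improving move, keep previous state
    obj_trace <- c(obj_trace, obj)
    converged <- identical(new_labels, labels) && iter > 1
    labels <- new_labels
    obj_prev <- obj
    for (i in seq_len(n)) f0f_assigned[i, ] <- f0f_by_model[[labels[i]]][i, ]
    if (converged) break
  }

  structure(list(labels = stats::setNames(as.integer(labels), ids),
                 models = models, global_model = global,
                 f0f_centroids = centroids, objective_trace = obj_trace,
                 f0f = f0f_assigned),
            class = "f0f_clustering")
}

#' @export
print.f0f_clustering <- function(x, ...) {
  cat(sprintf("<f0f_clustering> K = %d clusters, sizes: %s; final objective %.4g\n",
              nrow(x$f0f_centroids),
              paste(tabulate(x$labels, nrow(x$f0f_centroids)), collapse = ", "),
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Per-cluster summary of apparent F0/F and target-to-Fmax ratios
#'
#' For every cluster x component: mean and sd of apparent F0/F under the
#' cluster's own model, and — where pairs carry targets — mean and sd of
#' target / Fmax(original) ratios (the amount of target concentration one
#' unit of Fmax corresponds to, e.g. `TCC_per_fmax`).
#'
#' @param result An `f0f_clustering`.
#' @param dataset The clustered `eem_dataset`.
#' @return Data frame: cluster, component, n, f0f_mean, f0f_sd, and
#'   `<target>_per_fmax_mean`/`_sd` columns per available target.
#' @export
cluster_summary <- function(result, dataset) {
  stopifnot(inherits(result, "f0f_clustering"))
  ids <- dataset_ids(dataset)
  K <- nrow(result$f0f_centroids)
  R <- ncol(result$f0f_centroids)
  target_names <- unique(unlist(lapply(dataset$pairs, function(p) names(p$targets))))
  rows <- list()
  for (k in seq_len(K)) {
    members <- which(result$labels[ids] == k)
    if (length(members) == 0) next
    mdl <- result$models[[k]]
    fm <- vapply(dataset$pairs[members],
                 function(p) project_eem(mdl, p$original)$fmax, numeric(R))
    fmax_orig <- if (R == 1) matrix(fm, ncol = 1) else t(fm)
    for (r in seq_len(R)) {
      row <- data.frame(cluster = k, component = r, n = length(members),
                        f0f_mean = mean(result$f0f[members, r], na.rm = TRUE),
                        f0f_sd = stats::sd(result$f0f[members, r]))
      for (t in target_names) {
        tv <- vapply(dataset$pairs[members], target_of, numeric(1), name = t)
        ratio <- tv / fmax_orig[, r]
        ratio[!is.finite(ratio)] <- NA
        row[[paste0(t, "_per_fmax_mean")]] <- mean(ratio, na.rm = TRUE)
        row[[paste0(t, "_per_fmax_sd")]] <- stats::sd(ratio[is.finite(ratio)])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and a reference
#' partition: 1 for identical partitions (up to label renaming), about 0
#' for random agreement.
#'
#' @param a,b Integer/factor vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
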