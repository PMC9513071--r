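#' Align RF centres within a field
#'
#' Individual RFs are noisy, so centres are found on pre-cluster averages:
#' RFs are hierarchically pre-clustered (correlation distance, average
#' linkage) and cut at a fixed distance criterion (default 0.05); within
#' each pre-cluster the centre is the spatial bin of the extremum of the
#' pre-cluster mean RF (maximum for On, minimum for Off groups), and every
#' member is shifted by whole bins so that centre lands on the common
#' reference bin (the middle of the grid). Vacated bins are zero-filled.
#'
#' @param rfs list of [spacetime_rf] on a common grid.
#' @param link_threshold distance criterion for cutting the dendrogram.
#' @return list of aligned [spacetime_rf] with an attribute
#'   `precluster` giving the pre-cluster index per RF.
#' @export
align_centers <- function(rfs, link_threshold = 0.05) {
  if (length(rfs) == 0L) stop("need at least one RF", call. = FALSE)
  nx <- nrow(rfs[[1]]$weights)
  V <- t(vapply(rfs, function(r) as.numeric(r$weights),
                numeric(length(rfs[[1]]$weights))))
  if (length(rfs) == 1L) {
    groups <- 1L
  } else {
    cc <- suppressWarnings(stats::cor(t(V)))
    cc[!is.finite(cc)] <- 0
    d <- stats::as.dist(1 - cc)
    hc <- stats::hclust(d, method = "average")
    groups <- stats::cutree(hc, h = link_threshold)
  }
  ref_bin <- (nx + 1L) %/% 2L
  out <- rfs
  max_lag <- nx %/% 3L
  for (g in unique(groups)) {
    idx <- which(groups == g)
    avg <- Reduce(`+`, lapply(out[idx], `[[`, "weights")) / length(idx)
    prof_max <- max(avg); prof_min <- min(avg)
    cbin <- if (abs(prof_max) >= abs(prof_min))
      which(avg == prof_max, arr.ind = TRUE)[1, 1]
    else which(avg == prof_min, arr.ind = TRUE)[1, 1]
    for (i in idx) {
      # residual offset of this member relative to the pre-cluster mean,
      # found by spatial cross-correlation over whole-bin lags
      lags <- -max_lag:max_lag
      score <- vapply(lags, function(l)
        sum(shift_rows(out[[i]]$weights, l) * avg), numeric(1))
      l_best <- lags[which.max(score)]
      shift <- l_best + (ref_bin - cbin)
      out[[i]]$weights <- shift_rows(out[[i]]$weights, shift)
      out[[i]]$center_um <- out[[i]]$origin_um + (ref_bin - 1L) * out[[i]]$dx
    }
  }
  attr(out, "precluster") <- unname(groups)
  out
}

# shift matrix rows by k (positive = toward larger index), zero-filling
shift_rows <- function(m, k) {
  if (k == 0L) return(m)
  out <- matrix(0, nrow(m), ncol(m))
  if (k > 0) out[(k + 1):nrow(m), ] <- m[1:(nrow(m) - k), , drop = FALSE]
  else out[1:(nrow(m) + k), ] <- m[(1 - k):nrow(m), , drop = FALSE]
  out
}

#' Flatten one spatial half of an aligned RF
#'
#' Clustering is performed on half of the RF (the half available for all
#' ROIs when the stimulus may be off-centre): the rows from the centre bin
#' to the grid edge, over the full lag span, flattened to a vector
#' (lag-major per spatial bin).
#'
#' @param rf an aligned [spacetime_rf].
#' @param side `"right"` (centre to max x) or `"left"` (reflected).
#' @return numeric vector of length `(half bins) * (lag bins)`.
#' @export
crop_half <- function(rf, side = c("right", "left")) {
  side <- match.arg(side)
  xs <- stim_space(rf)
  cbin <- which.min(abs(xs - rf$center_um))
  if (abs(xs[cbin] - rf$center_um) > rf$dx / 2 + 1e-9)
    stop("RF centre lies outside the spatial extent", call. = FALSE)
  rows <- if (side == "right") cbin:nrow(rf$weights) else cbin:1
  as.numeric(t(rf$weights[rows, , drop = FALSE]))
}

#' Mirror a half RF into a full symmetric RF
#'
#' Reflects the centre-to-edge half about the centre column to build a
#' spatially symmetric RF (used to condition RFs for the dendrite model and
#' as the inverse of [crop_half] for symmetric RFs).
#'
#' @param rf a [spacetime_rf]; the half from its centre bin rightward is used.
#' @return a symmetric [spacetime_rf] centred at `center_um`.
#' @export
mirror_rf <- function(rf) {
  xs <- stim_space(rf)
  cbin <- which.min(abs(xs - rf$center_um))
  half <- rf$weights[cbin:nrow(rf$weights), , drop = FALSE]
  full <- rbind(half[rev(seq_len(nrow(half))[-1]), , drop = FALSE], half)
  spacetime_rf(full, dx = rf$dx, dt = rf$dt,
               origin_um = xs[cbin] - (nrow(half) - 1L) * rf$dx,
               center_um = xs[cbin], polarity = rf$polarity,
               ipl_depth = rf$ipl_depth, label = paste(rf$label, "(mirrored)"))
}

# rank-1 penalised matrix decomposition with L1 soft-thresholded loadings,
# deflated for k components; penalty 0 reduces to plain SVD
sparse_pca <- function(X, k = 4, penalty = 0.1, max_iter = 100, tol = 1e-7) {
  Xc <- sweep(X, 2L, colMeans(X))
  R <- Xc
  load <- matrix(0, ncol(X), k)
  soft <- function(a, l) sign(a) * pmax(abs(a) - l, 0)
  for (comp in seq_len(k)) {
    sv <- svd(R, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    if (sv$d[1] < 1e-12) break
    for (it in seq_len(max_iter)) {
      v_old <- v
      a <- drop(crossprod(R, u))
      lam <- penalty * max(abs(a))
      v <- soft(a, lam)
      nv <- sqrt(sum(v^2))
      if (nv == 0) { v <- v_old; break }
      v <- v / nv
      u <- drop(R %*% v)
      nu <- sqrt(sum(u^2))
      if (nu == 0) break
      u <- u / nu
      if (sum((v - v_old)^2) < tol) break
    }
    d <- drop(crossprod(u, R %*% v))
    load[, comp] <- v
    R <- R - d * tcrossprod(u, v)
  }
  list(loadings = load, center = colMeans(X))
}

# least-squares projection of rows of X onto sparse loadings
spca_scores <- function(X, pca) {
  Xc <- sweep(X, 2L, pca$center)
  L <- pca$loadings
  Xc %*% L %*% solve(crossprod(L) + 1e-10 * diag(ncol(L)))
}

#' Fit the RF cluster model: sparse PCA + Gaussian mixture with BIC
#'
#' Flattened half-RF vectors are reduced to `n_components` sparse principal
#' components; the component scores (optionally together with standardised
#' IPL depth) form the feature set for Gaussian-mixture clustering. One
#' mixture is fitted per candidate cluster count in `k_range` and the count
#' minimising the Bayesian information criterion is selected.
#'
#' @param vectors numeric matrix, one row per ROI (e.g. from [crop_half]).
#' @param depths optional IPL depths in \[0, 1\] appended as a feature.
#' @param n_components number of sparse PCs.
#' @param k_range candidate cluster counts (paper default 3..19).
#' @param sparsity L1 penalty of the sparse PCA (0 = plain PCA).
#' @param seed integer seed (mixture initialisation is deterministic given
#'   the data; the seed also covers any stochastic fallback).
#' @return An object of class `cluster_model` with elements `pca`,
#'   `mixture`, `k_selected`, `bic_curve` (minimise convention),
#'   `assignments`, `depth_included`, `feature_scale`.
#' @importFrom mclust Mclust mclustBIC predict.Mclust
#' @export
fit_cluster_model <- function(vectors, depths = NULL, n_components = 4,
                              k_range = 3:19, sparsity = 0.1, seed = 1) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < max(k_range)) {
    drop_k <- k_range[k_range > n]
    if (length(drop_k))
      warning("skipping k > number of samples: ", paste(drop_k, collapse = ", "))
    k_range <- k_range[k_range <= n]
    if (length(k_range) == 0L) stop("fewer samples than every candidate k", call. = FALSE)
  }
  pca <- local_seed(seed, sparse_pca(vectors, k = n_components, penalty = sparsity))
  feats <- spca_scores(vectors, pca)
  depth_included <- !is.null(depths)
  if (depth_included) feats <- cbind(feats, depths)
  sds <- apply(feats, 2L, stats::sd)
  degenerate <- all(sds < 1e-12)
  if (!degenerate) {
    sds[sds < 1e-12] <- 1
    feats <- sweep(feats, 2L, colMeans(feats))
    feats <- sweep(feats, 2L, sds, "/")
  }
  if (degenerate) {
    # all samples identical: a single cluster explains the data
    k_sel <- min(k_range)
    bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
    bic[1] <- 0
    model <- list(mean = colMeans(feats))
    out <- structure(list(pca = pca, mixture = NULL, k_selected = k_sel,
                          bic_curve = bic,
                          assignments = rep(1L, n), depth_included = depth_included,
                          feature_scale = sds, degenerate = TRUE),
                     class = "cluster_model")
    return(out)
  }
  fit <- local_seed(seed, mclust::Mclust(feats, G = k_range, verbose = FALSE))
  if (is.null(fit)) stop("mixture fitting failed for every k", call. = FALSE)
  # classical BIC (-2 loglik + p log n): mclust maximises the opposite sign
  bic_max <- apply(fit$BIC, 1L, function(r) suppressWarnings(max(r, na.rm = TRUE)))
  bic_max[!is.finite(bic_max)] <- NA_real_
  bic <- stats::setNames(-bic_max, rownames(fit$BIC))
  if (any(is.na(bic)))
    warning("mixture fit unavailable for k = ",
            paste(names(bic)[is.na(bic)], collapse = ", "))
  structure(list(pca = pca, mixture = fit, k_selected = fit$G,
                 bic_curve = bic, assignments = fit$classification,
                 depth_included = depth_included,
                 feature_scale = sds, degenerate = FALSE,
                 feats_center = colMeans(spca_raw_feats(vectors, depths, pca))),
            class = "cluster_model")
}

# raw (unscaled) feature matrix for a data set under a fitted pca
spca_raw_feats <- function(vectors, depths, pca) {
  feats <- spca_scores(as.matrix(vectors), pca)
  if (!is.null(depths)) feats <- cbind(feats, depths)
  feats
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d clusters (of candidates %s)%s\n",
              x$k_selected, paste(range(as.integer(names(x$bic_curve))), collapse = ".."),
              if (x$depth_included) ", depth included" else ""))
  invisible(x)
}

#' Predict cluster membership for new RF vectors
#'
#' Projects new half-RF vectors onto the fitted sparse-PCA basis, applies
#' the model's feature scaling, and assigns the maximum-posterior mixture
#' component (used e.g. to carry control-condition cluster labels onto drug
#' conditions).
#'
#' @param model a fitted [fit_cluster_model].
#' @param vectors matrix of new flattened half-RFs (same length as training).
#' @param depths depths, required iff the model used them.
#' @return list with `cluster` (integer) and `posterior` (matrix, rows sum 1).
#' @export
predict_cluster <- function(model, vectors, depths = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (!is.matrix(vectors))
    vectors <- matrix(as.numeric(vectors), nrow = 1L)
  if (ncol(vectors) != length(model$pca$center))
    stop("feature mismatch: vector length differs from training", call. = FALSE)
  if (model$depth_included && is.null(depths))
    stop("model was fitted with depths; supply them", call. = FALSE)
  if (isTRUE(model$degenerate)) {
    return(list(cluster = rep(1L, nrow(vectors)),
                posterior = matrix(1, nrow(vectors), 1L)))
  }
  feats <- spca_raw_feats(vectors, depths, model$pca)
  feats <- sweep(feats, 2L, model$feats_center)
  feats <- sweep(feats, 2L, model$feature_scale, "/")
  pr <- mclust::predict.Mclust(model$mixture, newdata = feats)
  list(cluster = as.integer(pr$classification), posterior = pr$z)
}

#' Stratification profile: kernel density of IPL depths
#'
#' Gaussian kernel density estimate of the IPL depths of a set of ROIs,
#' evaluated on a common depth grid and normalised to integrate to one.
#'
#' @param depths IPL depths in \[0, 1\].
#' @param grid depth grid (default 101 points on \[0, 1\]).
#' @param bw kernel bandwidth (default `stats::bw.nrd0`).
#' @return An object of class `strat_profile`: list with `depth`, `density`.
#' @export
stratification_profile <- function(depths, grid = seq(0, 1, length.out = 101),
                                   bw = NULL) {
  if (length(depths) < 1L) stop("need at least one depth", call. = FALSE)
  if (is.null(bw)) bw <- max(stats::bw.nrd0(depths), 0.01)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, depths, bw)), numeric(1))
  dens <- dens / (sum(dens) * mean(diff(grid)))
  structure(list(depth = grid, density = dens), class = "strat_profile")
}

#' Correlate cluster stratification with reference profiles
#'
#' Pearson correlation between each cluster's depth-density profile and each
#' reference (e.g. EM-reconstructed bipolar-cell type) profile on a shared
#' depth grid. Pairs exceeding `match_threshold` (paper used 0.7) are
#' reported as matches.
#'
#' @param cluster_profiles,reference_profiles named lists of `strat_profile`
#'   (or numeric vectors on the same grid).
#' @param match_threshold correlation threshold for a match.
#' @return correlation matrix (clusters x references) with a `matches`
#'   attribute (logical matrix).
#' @export
stratification_correlation <- function(cluster_profiles, reference_profiles,
                                       match_threshold = 0.7) {
  getd <- function(p) if (inherits(p, "strat_profile")) p$density else as.numeric(p)
  cl <- lapply(cluster_profiles, getd)
  rf <- lapply(reference_profiles, getd)
  if (length(unique(vapply(c(cl, rf), length, integer(1)))) != 1L)
    stop("profiles must share a common depth grid", call. = FALSE)
  if (any(vapply(c(cl, rf), stats::sd, numeric(1)) == 0))
    stop("correlation undefined: zero-variance profile", call. = FALSE)
  M <- matrix(NA_real_, length(cl), length(rf),
              dimnames = list(names(cl), names(rf)))
  for (i in seq_along(cl)) for (j in seq_along(rf))
    M[i, j] <- stats::cor(cl[[i]], rf[[j]])
  attr(M, "matches") <- M >= match_threshold
  M
}
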