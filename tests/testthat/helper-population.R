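# small planted population on a coarse grid for clustering tests
planted_vectors <- function(n_per = 20, seed = 1, types = NULL, jitter = 0.02) {
  if (is.null(types))
    types <- list(list(surround_strength = 0.1, surround_latency_s = 0.04,
                       center_tau_s = 0.05),
                  list(surround_strength = 0.8, surround_latency_s = 0.08,
                       center_tau_s = 0.09))
  rfs <- list(); labels <- integer(0); depths <- numeric(0)
  k <- 0L
  local_seed_vals <- function(i) seed * 1000 + i
  for (ty in seq_along(types)) {
    for (r in seq_len(n_per)) {
      k <- k + 1L
      p <- do.call(syn_rf_params, types[[ty]])
      rf <- make_rf(p, dx = 20, dt = 0.02, lag_span_s = 0.4,
                    extent_um = c(-200, 200))
      set.seed(local_seed_vals(k))
      rf$weights <- rf$weights * (1 + rnorm(1, 0, jitter)) +
        matrix(rnorm(length(rf$weights), 0, jitter), nrow(rf$weights))
      rfs[[k]] <- rf
      labels[k] <- ty
      depths[k] <- 0.3 + 0.4 * (ty - 1) + rnorm(1, 0, 0.02)
    }
  }
  vecs <- t(vapply(rfs, crop_half, numeric(length(crop_half(rfs[[1]])))))
  list(vectors = vecs, labels = labels, depths = pmin(pmax(depths, 0), 1),
       rfs = rfs)
}

# same planted construction with an explicit type list (acceptance suite)
planted_vectors_acc <- function(types, n_per = 15, seed = 1)
  planted_vectors(n_per = n_per, seed = seed, types = types)
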