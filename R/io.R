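#' Write / read a space-time RF as CSV + JSON sidecar
#'
#' The shared array schema of the package: the weight matrix as a plain CSV
#' (rows = space bins) and a `<path>.json` sidecar holding the physical
#' attributes (`dx`, `dt`, `origin_um`, `center_um`, `polarity`,
#' `ipl_depth`, `label`). Round trips are lossless to full double precision.
#'
#' @param rf a [spacetime_rf].
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_rf <- function(rf, path) {
  stopifnot(inherits(rf, "spacetime_rf"))
  utils::write.table(format(rf$weights, digits = 17, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- rf[c("dx", "dt", "origin_um", "center_um", "polarity",
               "ipl_depth", "label")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_rf
#' @param path CSV path written by [write_rf].
#' @return a [spacetime_rf].
#' @export
read_rf <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("validation error: missing sidecar ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("dx", "dt", "origin_um", "polarity")
  missing_f <- setdiff(required, names(meta))
  if (length(missing_f))
    stop("validation error: sidecar missing attribute(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  w <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(w) <- NULL
  spacetime_rf(w, dx = meta$dx, dt = meta$dt, origin_um = meta$origin_um,
               center_um = meta$center_um %||% 0, polarity = meta$polarity,
               ipl_depth = meta$ipl_depth %||% NA_real_,
               label = meta$label %||% "")
}

#' Write / read a stimulus as CSV + JSON sidecar
#' @param stim a [spacetime_stim]; `path` the CSV path.
#' @return `path` invisibly; `read_stimulus` returns the [spacetime_stim].
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "spacetime_stim"))
  utils::write.table(format(stim$values, digits = 17, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- stim[c("dx", "dt", "origin_um", "label")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("validation error: missing sidecar ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  missing_f <- setdiff(c("dx", "dt"), names(meta))
  if (length(missing_f))
    stop("validation error: sidecar missing attribute(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  spacetime_stim(v, dx = meta$dx, dt = meta$dt,
                 origin_um = meta$origin_um %||% 0, label = meta$label %||% "")
}

# default stage parameters of the demo pipeline
default_pipeline_config <- function() {
  list(
    seed = 1,
    synth = list(n_types = 3, rois_per_type = 12, dx = 10, dt = 0.01),
    noise = list(duration_s = 120, n_bars = 20, bar_w_um = 20, rate_hz = 20,
                 noise_sd = 0.3),
    estimate = list(lag_span_s = 0.4, basis_space = 12, basis_lag = 10),
    cluster = list(n_components = 4, k_min = 2, k_max = 6, use_depth = TRUE),
    motion = list(velocities = c(250, 500, 1000)),
    sac = list(velocities = c(500, 1000), path_variant = "single_dendrite",
               wiring_mode = "original", surround_factor = 1)
  )
}

validate_config <- function(config, template = default_pipeline_config()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(config)) {
    if (is.list(template[[k]])) {
      bad <- setdiff(names(config[[k]]), names(template[[k]]))
      if (length(bad))
        stop("unknown config key(s) in '", k, "': ", paste(bad, collapse = ", "),
             call. = FALSE)
      template[[k]] <- utils::modifyList(template[[k]], config[[k]])
    } else template[[k]] <- config[[k]]
  }
  template
}

#' Run the full analysis pipeline
#'
#' Demo pipeline tying the stages together on synthetic data: generate an RF
#' population, simulate its responses to a 1-D noise stimulus, estimate RFs
#' back, extract features, align/crop/cluster, compute motion-model tuning
#' per cluster, and run the SAC dendrite protocol. All randomness flows from
#' the single config seed. Writes CSV artifacts and a JSON manifest
#' (package version, config, file checksums) into `out_dir`.
#'
#' @param config named list (or YAML path) overriding
#'   `default_pipeline_config()`; unknown keys raise an error naming them.
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("rdsbc_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  pop <- make_population(cfg$synth$n_types, cfg$synth$rois_per_type,
                         seed = seed, dx = cfg$synth$dx, dt = cfg$synth$dt)
  stim <- make_1d_noise(cfg$noise$n_bars, cfg$noise$bar_w_um,
                        cfg$noise$rate_hz, cfg$noise$duration_s,
                        seed = seed + 1, dx = cfg$synth$dx, dt = cfg$synth$dt,
                        origin_um = -(cfg$noise$n_bars * cfg$noise$bar_w_um) / 2)
  est <- vector("list", length(pop$rfs))
  feats <- vector("list", length(pop$rfs))
  for (i in seq_along(pop$rfs)) {
    tr <- simulate_response(pop$rfs[[i]], stim, noise_sd = cfg$noise$noise_sd,
                            seed = seed + 100 + i)
    est[[i]] <- estimate_rf(stim, tr, lag_span_s = cfg$estimate$lag_span_s,
                            basis_dim = c(cfg$estimate$basis_space,
                                          cfg$estimate$basis_lag),
                            ipl_depth = pop$params$ipl_depth[i])
    feats[[i]] <- as.data.frame(extract_features(est[[i]]))
  }
  feat_tab <- cbind(pop$params[, c("roi", "type")], do.call(rbind, feats))
  utils::write.csv(feat_tab, file.path(out_dir, "rf_features.csv"),
                   row.names = FALSE)

  aligned <- align_centers(est)
  vecs <- t(vapply(aligned, crop_half, numeric(length(crop_half(aligned[[1]])))))
  depths <- if (cfg$cluster$use_depth) pop$params$ipl_depth else NULL
  cm <- fit_cluster_model(vecs, depths, n_components = cfg$cluster$n_components,
                          k_range = cfg$cluster$k_min:cfg$cluster$k_max,
                          seed = seed)
  utils::write.csv(data.frame(roi = pop$params$roi, true_type = pop$params$type,
                              cluster = cm$assignments),
                   file.path(out_dir, "cluster_assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(k = as.integer(names(cm$bic_curve)),
                              bic = unname(cm$bic_curve)),
                   file.path(out_dir, "bic_curve.csv"), row.names = FALSE)

  tun <- lapply(seq_along(pop$rfs), function(i)
    cbind(roi = i, rds_tuning(pop$rfs[[i]], cfg$motion$velocities)))
  utils::write.csv(do.call(rbind, tun), file.path(out_dir, "rds_tuning.csv"),
                   row.names = FALSE)

  sac <- run_protocol(sac_config(), velocities = cfg$sac$velocities,
                      path_variant = cfg$sac$path_variant,
                      wiring_mode = cfg$sac$wiring_mode,
                      surround_factor = cfg$sac$surround_factor)
  utils::write.csv(sac, file.path(out_dir, "sac_dsi.csv"), row.names = FALSE)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "rdsbc",
    version = as.character(utils::packageVersion("rdsbc")),
    seed = seed,
    config = cfg,
    checksums = as.list(tools::md5sum(sort(files))))
  names(manifest$checksums) <- basename(sort(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
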