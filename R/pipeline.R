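# Orchestration of the factorial simulation experiment:
# arrays x noise conditions x cleaning methods -> localization error and
# moment-magnitude distributions with median/IQR summaries.

#' Experiment configuration
#'
#' @param arrays array kinds to simulate
#' @param noise one of "sensor" (white sensor noise only), "brain"
#'   (sensor + distributed brain noise), "movement" (sensor + brain +
#'   movement through the non-uniform ambient field), "movement_uniform"
#'   (idem with the uniform-field variant)
#' @param cleaning subset of "baseline", "hfc1", "hfc3", "dssp", "tsss1",
#'   "tsss3", "amm", "lcmv"
#' @param n_locations number of dipole locations to draw (without
#'   replacement) from the 10 mm signal grid; `NULL` uses all of them
#' @param n_segments segments per recording (default 45)
#' @param segment_stride keep every k-th segment (default 1 = all); a
#'   stride spreads a reduced segment count over the whole recording
#' @param sigma_sensor white sensor-noise SD (T); 2 pT default
#' @param amplitude simulated dipole amplitude (A*m); 10 nAm default
#' @param seed master seed; all per-recording noise seeds derive from it
#' @param n_samples samples per recording (default 6000)
#' @param signal_spacing,signal_z_min signal-grid lattice parameters (m)
#' @param brain_spacing brain-noise grid spacing (m)
#' @param field_summary targets for the synthetic ambient field
#'   (mean |B|, first-, second-order gradient; T, T/m, T/m^2)
#' @param motion_pars translation SD (m), rotation SD (deg), smoothness (s)
#' @return list of class `opm_experiment_config`
#' @export
experiment_config <- function(arrays = c("monoaxial", "biaxial", "triaxial"),
                              noise = "sensor",
                              cleaning = "baseline",
                              n_locations = NULL,
                              n_segments = 45,
                              segment_stride = 1,
                              sigma_sensor = 2e-12,
                              amplitude = 10e-9,
                              seed = 1,
                              n_samples = 6000,
                              signal_spacing = 0.010,
                              signal_z_min = 0.020,
                              brain_spacing = 6.3e-3,
                              field_summary = c(50.1e-9, 6.7e-9, 35.6e-9),
                              motion_pars = c(5e-3, 1, 2)) {
  noise <- match.arg(noise, c("sensor", "brain", "movement",
                              "movement_uniform"))
  methods <- c("baseline", "hfc1", "hfc3", "dssp", "tsss1", "tsss3",
               "amm", "lcmv")
  cleaning <- match.arg(cleaning, methods, several.ok = TRUE)
  structure(
    list(arrays = arrays, noise = noise, cleaning = cleaning,
         n_locations = n_locations, n_segments = n_segments,
         segment_stride = segment_stride,
         sigma_sensor = sigma_sensor, amplitude = amplitude, seed = seed,
         n_samples = n_samples, signal_spacing = signal_spacing,
         signal_z_min = signal_z_min, brain_spacing = brain_spacing,
         field_summary = field_summary, motion_pars = motion_pars),
    class = "opm_experiment_config"
  )
}

#' Run the factorial simulation experiment
#'
#' For each array kind and each selected dipole location/orientation:
#' simulate a 6,000-sample recording (signal in even columns, the selected
#' noise mixture everywhere), cut it into overlapping segments, clean each
#' segment with every requested method, fit a dipole per segment starting
#' from the true location (LCMV localizes by its own scan instead) and
#' collect localization errors (mm) and moment magnitudes (nAm).
#' Fully deterministic given the configuration.
#'
#' @param cfg an [experiment_config()]
#' @param verbose print progress lines
#' @return object of class `opm_experiment`: nested list
#'   `results[[array]][[method]]` with `errors`, `moments` and a
#'   [summarize_metrics()] summary; plus the per-array location sets and
#'   excluded-fit counts
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "opm_experiment_config"))
  signal_grid <- make_source_grid(cfg$signal_spacing, brain_ellipsoid(),
                                  cfg$signal_z_min)
  all_pos <- signal_grid$positions
  loc_idx <- if (is.null(cfg$n_locations) ||
                 cfg$n_locations >= nrow(all_pos)) {
    seq_len(nrow(all_pos))
  } else {
    local_seed(derive_seed(cfg$seed, 7),
               sort(sample.int(nrow(all_pos), cfg$n_locations)))
  }
  positions <- all_pos[loc_idx, , drop = FALSE]
  movement <- cfg$noise %in% c("movement", "movement_uniform")
  with_brain <- cfg$noise %in% c("brain", "movement", "movement_uniform")

  fmap <- motion <- NULL
  if (movement) {
    fmap <- synth_field_map(cfg$field_summary[1], cfg$field_summary[2],
                            cfg$field_summary[3],
                            seed = derive_seed(cfg$seed, 97))
    if (cfg$noise == "movement_uniform") fmap <- uniform_variant(fmap)
    motion <- synth_motion(n_samples = cfg$n_samples,
                           translation_sd = cfg$motion_pars[1],
                           rotation_sd = cfg$motion_pars[2],
                           smoothness = cfg$motion_pars[3],
                           seed = derive_seed(cfg$seed, 98))
  }

  results <- list()
  excluded <- list()
  for (ai in seq_along(cfg$arrays)) {
    kind <- cfg$arrays[ai]
    array <- build_array(kind)
    assets <- prepare_cleaning_assets(cfg, array, signal_grid)
    ambient <- if (movement) project_ambient(array, motion, fmap) else NULL
    bfac <- if (with_brain) {
      brain_noise_factor(array, cfg$brain_spacing)
    } else NULL

    metrics <- lapply(cfg$cleaning, function(m) {
      list(errors = numeric(0), moments = numeric(0))
    })
    names(metrics) <- cfg$cleaning
    n_excl <- 0L

    for (li in seq_len(nrow(positions))) {
      pos <- positions[li, ]
      for (ori in 1:2) {
        noise <- white_sensor_noise(
          nrow(array$channels), cfg$n_samples, cfg$sigma_sensor,
          seed = derive_seed(cfg$seed, ai, loc_idx[li], ori, 1))
        if (with_brain) {
          noise <- noise + brain_noise(
            array, cfg$n_samples, factor = bfac,
            seed = derive_seed(cfg$seed, ai, loc_idx[li], ori, 2))
        }
        if (movement) noise <- noise + ambient
        rec <- simulate_dipole_recording(array, pos, ori, noise,
                                         cfg$amplitude)
        segs <- segment_recording(rec, n_segments = cfg$n_segments)
        if (cfg$segment_stride > 1) {
          segs <- segs[seq(1, length(segs), by = cfg$segment_stride)]
        }
        for (m in cfg$cleaning) {
          r <- tryCatch(
            eval_method(m, segs, array, pos, assets),
            error = function(e) {
              warning(sprintf("fit excluded (%s, loc %d, ori %d): %s",
                              m, loc_idx[li], ori, conditionMessage(e)))
              NULL
            })
          if (is.null(r)) {
            n_excl <- n_excl + 1L
          } else {
            metrics[[m]]$errors <- c(metrics[[m]]$errors, r$errors)
            metrics[[m]]$moments <- c(metrics[[m]]$moments, r$moments)
          }
        }
      }
      if (verbose && li %% 10 == 0) {
        message(sprintf("[%s] %d/%d locations", kind, li, nrow(positions)))
      }
    }
    results[[kind]] <- lapply(metrics, function(m) {
      c(m, list(summary = summarize_metrics(m$errors, m$moments)))
    })
    excluded[[kind]] <- n_excl
  }
  structure(list(results = results, config = cfg, positions = positions,
                 location_index = loc_idx, excluded = excluded,
                 n_grid_locations = nrow(all_pos)),
            class = "opm_experiment")
}

#' @noRd
prepare_cleaning_assets <- function(cfg, array, signal_grid) {
  a <- list()
  cl <- cfg$cleaning
  if ("hfc1" %in% cl) a$hfc1 <- hfc_projector(array, 1)
  if ("hfc3" %in% cl) a$hfc3 <- hfc_projector(array, 3)
  if (any(c("tsss1", "tsss3", "amm") %in% cl)) {
    if ("tsss1" %in% cl) a$sss1 <- sss_basis(array, 8, 1)
    if ("tsss3" %in% cl) a$sss3 <- sss_basis(array, 8, 3)
    if ("amm" %in% cl) a$amm <- a$sss1 %||% sss_basis(array, 8, 1)
  }
  if ("dssp" %in% cl) a$dssp <- dssp_subspace(array, signal_grid)
  if ("lcmv" %in% cl) a$lcmv_lf <- grid_leadfield(array, signal_grid)
  a
}

#' @noRd
eval_method <- function(method, segs, array, truth_pos, assets) {
  if (method == "lcmv") {
    loc <- lcmv_localize(segs, array, NULL, leadfield = assets$lcmv_lf)
    errs <- apply(loc$peaks, 1, localization_error, truth_pos = truth_pos)
    return(list(errors = as.numeric(errs),
                moments = rep(NA_real_, length(errs))))
  }
  topo_fun <- switch(method,
    baseline = function(s) clean_baseline(s),
    hfc1 = function(s) clean_hfc(s, array, 1, projector = assets$hfc1),
    hfc3 = function(s) clean_hfc(s, array, 3, projector = assets$hfc3),
    tsss1 = function(s) clean_tsss(s, array, L_out = 1, basis = assets$sss1),
    tsss3 = function(s) clean_tsss(s, array, L_out = 3, basis = assets$sss3),
    amm = function(s) clean_amm(s, array, basis = assets$amm),
    dssp = function(s) clean_dssp(s, array, subspace = assets$dssp),
    stopf("unknown cleaning method '%s'", method)
  )
  errs <- numeric(length(segs)); moms <- numeric(length(segs))
  for (i in seq_along(segs)) {
    topo <- topo_fun(segs[[i]])
    fit <- fit_dipole(topo, array, truth_pos)
    errs[i] <- localization_error(fit, truth_pos)
    moms[i] <- moment_magnitude(fit)
  }
  list(errors = errs, moments = moms)
}

#' Median and interquartile summaries of error/moment distributions
#'
#' Quantiles use the linear-interpolation definition
#' (`stats::quantile` type 7).
#'
#' @param errors localization errors (mm)
#' @param moments moment magnitudes (nAm); may contain NA (e.g. LCMV)
#' @return list with `n` and median/q25/q75 of both metrics
#' @export
summarize_metrics <- function(errors, moments = NULL) {
  if (length(errors) == 0) stopf("empty metric vector")
  qs <- stats::quantile(errors, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- list(n = length(errors),
              error_median = qs[2], error_q25 = qs[1], error_q75 = qs[3])
  if (!is.null(moments) && any(is.finite(moments))) {
    mq <- stats::quantile(moments, c(0.25, 0.5, 0.75), names = FALSE,
                          type = 7, na.rm = TRUE)
    out <- c(out, list(moment_median = mq[2], moment_q25 = mq[1],
                       moment_q75 = mq[3]))
  } else {
    out <- c(out, list(moment_median = NA_real_, moment_q25 = NA_real_,
                       moment_q75 = NA_real_))
  }
  out
}

#' Summary tables of an experiment
#'
#' One row per array kind, one column per cleaning method; the first table
#' holds the median localization error (mm), the second the moment IQR
#' (nAm) formatted as "q25 - q75".
#'
#' @param experiment an `opm_experiment` (or its `results` component)
#' @return list with data frames `localization` and `moment_iqr`
#' @export
render_tables <- function(experiment) {
  results <- if (inherits(experiment, "opm_experiment")) {
    experiment$results
  } else experiment
  arrays <- names(results)
  if (length(arrays) == 0) {
    return(list(localization = data.frame(array = character(0)),
                moment_iqr = data.frame(array = character(0))))
  }
  methods <- unique(unlist(lapply(results, names)))
  loc <- data.frame(array = arrays, stringsAsFactors = FALSE)
  iqr <- data.frame(array = arrays, stringsAsFactors = FALSE)
  for (m in methods) {
    loc[[m]] <- sapply(arrays, function(a) {
      s <- results[[a]][[m]]
      if (is.null(s)) NA_real_ else round(s$summary$error_median, 1)
    })
    iqr[[m]] <- sapply(arrays, function(a) {
      s <- results[[a]][[m]]
      if (is.null(s) || !is.finite(s$summary$moment_q25)) NA else {
        sprintf("%.1f - %.1f", s$summary$moment_q25, s$summary$moment_q75)
      }
    })
  }
  list(localization = loc, moment_iqr = iqr)
}

#' Write experiment tables as CSV and markdown
#' @param tables output of [render_tables()]
#' @param dir output directory
#' @param prefix file-name prefix
#' @export
write_tables <- function(tables, dir, prefix = "summary") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]],
                       file.path(dir, sprintf("%s_%s.csv", prefix, nm)),
                       sep = ",", quote = FALSE, row.names = FALSE)
    md <- file.path(dir, sprintf("%s_%s.md", prefix, nm))
    tb <- tables[[nm]]
    lines <- c(paste0("| ", paste(names(tb), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(tb)), collapse = "|"), "|"),
               apply(tb, 1, function(r) {
                 paste0("| ", paste(r, collapse = " | "), " |")
               }))
    writeLines(lines, md)
  }
  invisible(dir)
}

#' @export
print.opm_experiment <- function(x, ...) {
  cat(sprintf("<opm_experiment> noise=%s, %d locations x 2 orientations\n",
              x$config$noise, nrow(x$positions)))
  print(render_tables(x)$localization)
  invisible(x)
}
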