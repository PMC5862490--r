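# End-to-end orchestration: synthetic study -> preprocessing -> calibrated
# phasors -> separability -> classification, plus run configs, fixtures and
# manifests.

#' Analyze a synthetic (or assembled) study into a measurement table
#'
#' For every paired acquisition: median filter, vessel masking, 3x3 binning
#' with the photon floor, per-harmonic phasor images of both acquisitions,
#' optional calibration against a simulated measurement of the reference
#' standard (acquired with the study's instrument settings), and unweighted
#' pixel-mean aggregation. Each pair contributes two rows: the treated
#' measurement under its condition label (with its \eqn{\Delta I}) and the
#' pre-treatment measurement under `baseline_label` (with \eqn{\Delta I = 0}).
#'
#' @param study A [make_study()] result.
#' @param harmonics Integer vector of harmonics to compute.
#' @param calibrate_phasors Calibrate against `reference_model`?
#' @param reference_model [lifetime_mixture()] of the calibration standard.
#' @param ref_photons Photon budget of the simulated standard measurement.
#' @param kernel,bin_window,min_photons Preprocessing parameters.
#' @param median_target `"counts"` filters the count planes before phasor
#'   computation (default); `"phasor"` computes phasors from raw counts and
#'   median-filters the resulting g/s planes instead.
#' @param baseline_label Label given to pre-treatment rows.
#' @param verbose Log per-stage counts to stderr.
#' @return Measurement data.frame (see [measurement_table()]).
#' @export
analyze_study <- function(study, harmonics = c(1L, 2L),
                          calibrate_phasors = TRUE,
                          reference_model = nadh_reference_model(),
                          ref_photons = 2e6,
                          kernel = 3L, bin_window = 3L, min_photons = 5000,
                          median_target = c("counts", "phasor"),
                          baseline_label = "baseline", verbose = FALSE) {
  stopifnot(inherits(study, "flim_study"))
  median_target <- match.arg(median_target)
  meta <- study$params$meta
  transforms <- NULL
  if (calibrate_phasors) {
    set.seed(study$params$seed + 777L)
    ref <- generate_decay(reference_model, ref_photons, meta,
                          irf = study$params$irf, mode = "sampled")
    ref <- apply_tac_truncation(ref, study$params$tac_truncated_bins)
    transforms <- lapply(harmonics, function(k)
      calibrate(pixel_phasor(ref, k), reference_model, meta, k))
    names(transforms) <- as.character(harmonics)
  }
  points <- list()
  for (rec in study$measurements) {
    pp <- preprocess_pair(rec$scene$baseline, rec$scene$treated,
                          vessel_mask = rec$scene$masks$vessel,
                          kernel = if (median_target == "counts") kernel else 1L,
                          bin_window = bin_window, min_photons = min_photons)
    ims_t <- list(); ims_b <- list()
    for (k in harmonics) {
      pt <- phasor_image(pp$treated, pp$valid, k)
      pb <- phasor_image(pp$baseline, pp$valid, k)
      if (median_target == "phasor") {
        pt$g <- .median_filter_plane(pt$g, kernel)
        pt$s <- .median_filter_plane(pt$s, kernel)
        pb$g <- .median_filter_plane(pb$g, kernel)
        pb$s <- .median_filter_plane(pb$s, kernel)
      }
      if (!is.null(transforms)) {
        pt <- apply_calibration(pt, transforms[[as.character(k)]])
        pb <- apply_calibration(pb, transforms[[as.character(k)]])
      }
      ims_t[[as.character(k)]] <- pt
      ims_b[[as.character(k)]] <- pb
    }
    points[[length(points) + 1L]] <- aggregate_measurement(
      ims_t, pp$delta_I, rec$condition, rec$animal_id, rec$location_id)
    points[[length(points) + 1L]] <- aggregate_measurement(
      ims_b, 0, baseline_label, rec$animal_id, rec$location_id)
    if (verbose)
      message(sprintf("  %s / %s / %s: %d valid pixels, dI = %+.3f",
                      rec$condition, rec$animal_id, rec$location_id,
                      sum(pp$valid$include), pp$delta_I))
  }
  measurement_table(points)
}

#' Default run configuration
#'
#' A single list covering the simulation, preprocessing, phasor, statistics
#' and classification blocks; one such config (echoed into the run manifest)
#' reproduces a whole study.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Named list of parameters accepted by [run_full_analysis()].
#' @export
default_run_config <- function(seed = 1L, out_dir = "flimphasor_run") {
  list(
    seed = as.integer(seed), out_dir = out_dir,
    conditions = c("glycolysis_inhibition", "tca_inhibition",
                   "etc_inhibition", "oxphos_uncoupling"),
    test_condition = "seizure_like",
    n_animals = 3L, n_locations = 3L,
    height = 16L, width = 16L, brightness = 1000, vessel_frac = 0.06,
    dispersion_animal = 0.02, dispersion_location = 0.05,
    intensity_jitter = 0.03,
    irf = c(fwhm = 0.2, offset = 0.5), tac_truncated_bins = 5L,
    harmonics = c(1L, 2L), calibrate = TRUE,
    kernel = 3L, bin_window = 3L, min_photons = 5000,
    alpha = 0.05, algorithms = c("lda", "knn", "nb"),
    kfolds = 5L, knn_k = 3L, make_plots = TRUE
  )
}

#' Run the complete analysis pipeline
#'
#' Simulates the configured study, analyzes it into a measurement table,
#' writes the separability report for every configured harmonic, trains the
#' configured classifiers on the mitochondrial classes, reports K-fold
#' cross-validation error and the class fractions predicted for the held-out
#' seizure-like test measurements, and writes a manifest echoing every
#' parameter. Deterministic given `config$seed`: repeated runs produce
#' byte-identical tables and reports.
#'
#' @param config List as from [default_run_config()], or a path to a JSON
#'   file holding one (missing entries take defaults).
#' @return Invisibly, a results bundle: `measurements`, `separability`,
#'   `classification`, `paths`.
#' @export
run_full_analysis <- function(config = default_run_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  base <- default_run_config()
  config <- utils::modifyList(base, config)
  if (!is.null(config$irf)) config$irf <- stats::setNames(
    as.numeric(config$irf), c("fwhm", "offset"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)
  message(sprintf("[run] simulating %d condition(s) x %d animals x %d locations",
                  length(config$conditions), config$n_animals, config$n_locations))
  study <- make_study(
    config$conditions, config$n_animals, config$n_locations,
    height = config$height, width = config$width,
    brightness = config$brightness, vessel_frac = config$vessel_frac,
    dispersion_animal = config$dispersion_animal,
    dispersion_location = config$dispersion_location,
    intensity_jitter = config$intensity_jitter,
    irf = config$irf, tac_truncated_bins = config$tac_truncated_bins,
    seed = config$seed)
  meas <- analyze_study(
    study, harmonics = config$harmonics,
    calibrate_phasors = isTRUE(config$calibrate),
    kernel = config$kernel, bin_window = config$bin_window,
    min_photons = config$min_photons)
  message(sprintf("[run] %d measurements", nrow(meas)))
  write_measurement_table(meas, pth("measurements.csv"))

  sep <- separability_report(meas, "baseline", config$harmonics, config$alpha)
  sep_out <- sep
  num <- vapply(sep_out, is.numeric, logical(1))
  sep_out[num] <- lapply(sep_out[num], function(x) signif(x, 15))
  utils::write.csv(sep_out, pth("separability.csv"), row.names = FALSE, quote = FALSE)
  message(sprintf("[run] separability: %d/%d condition x harmonic rows significant",
                  sum(sep$significant), nrow(sep)))

  test_study <- make_study(
    config$test_condition, config$n_animals, config$n_locations,
    height = config$height, width = config$width,
    brightness = config$brightness, vessel_frac = config$vessel_frac,
    dispersion_animal = config$dispersion_animal,
    dispersion_location = config$dispersion_location,
    intensity_jitter = config$intensity_jitter,
    irf = config$irf, tac_truncated_bins = config$tac_truncated_bins,
    seed = config$seed + 104729L)
  test_meas <- analyze_study(
    test_study, harmonics = config$harmonics,
    calibrate_phasors = isTRUE(config$calibrate),
    kernel = config$kernel, bin_window = config$bin_window,
    min_photons = config$min_photons)
  test_meas <- test_meas[test_meas$condition == config$test_condition, ,
                         drop = FALSE]

  classification <- list()
  for (k in config$harmonics) {
    feats <- suppressMessages(build_feature_table(meas, k))
    write_measurement_table(
      cbind(feats, harmonic = attr(feats, "harmonic")),
      pth(sprintf("features_h%d.csv", k)))
    test_feats <- build_feature_table(test_meas, k, class_map = NULL)
    per_algo <- list()
    for (algo in config$algorithms) {
      err <- kfold_cv_error(feats, algo, K = config$kfolds,
                            seed = config$seed, knn_k = config$knn_k)
      model <- train_classifier(feats, algo, knn_k = config$knn_k)
      pred <- stats::predict(model, test_feats)
      per_algo[[algo]] <- list(
        cv_error = as.numeric(err), cv_accuracy = 1 - as.numeric(err),
        kfolds = config$kfolds,
        test_fractions = as.list(pred$fractions),
        test_labels = pred$labels)
      message(sprintf(
        "[run] harmonic %d %s: CV error %.3f, test ETC fraction %.2f",
        k, toupper(algo), as.numeric(err), pred$fractions[["ETC"]]))
    }
    classification[[paste0("harmonic_", k)]] <- per_algo
  }
  jsonlite::write_json(classification, pth("classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(config$make_plots)) {
    for (k in config$harmonics)
      try(plot_phasor(meas, k, file = pth(sprintf("phasor_h%d.png", k)),
                      csv = pth(sprintf("phasor_h%d.csv", k))), silent = TRUE)
  }

  manifest <- list(
    package = "flimphasor",
    version = as.character(utils::packageVersion("flimphasor")),
    config = config,
    n_measurements = nrow(meas),
    n_test_measurements = nrow(test_meas),
    outputs = c("measurements.csv", "separability.csv", "classification.json"))
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(measurements = meas, separability = sep,
                 classification = classification,
                 paths = list(out_dir = config$out_dir)))
}

#' Write a deterministic fixture set
#'
#' One small paired baseline/treated scene per condition preset (written via
#' the TIFF stack interface, with vessel masks as CSV), a sampled
#' reference-standard decay as CSV, and a manifest listing every file with
#' its MD5 checksum. Regeneration with the same seed is byte-idempotent.
#'
#' @param out_dir Writable output directory.
#' @param seed Integer seed.
#' @param height,width Scene dimensions.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(out_dir, seed = 1L, height = 16L, width = 16L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- default_presets()
  files <- character(0)
  for (nm in names(presets)) {
    spec <- default_scene_spec(presets[[nm]], height = height, width = width,
                               seed = seed + match(nm, names(presets)))
    sc <- generate_scene(spec)
    fb <- file.path(out_dir, sprintf("%s_baseline.tif", nm))
    ft <- file.path(out_dir, sprintf("%s_treated.tif", nm))
    write_tcspc_stack(sc$baseline, fb)
    write_tcspc_stack(sc$treated, ft)
    fm <- file.path(out_dir, sprintf("%s_vessel.csv", nm))
    utils::write.csv(sc$masks$vessel$include * 1L, fm, row.names = FALSE)
    files <- c(files, fb, .sidecar_path(fb), ft, .sidecar_path(ft), fm)
  }
  set.seed(seed)
  ref <- generate_decay(nadh_reference_model(), 2e6, mode = "sampled",
                        irf = c(fwhm = 0.2, offset = 0.5))
  ref <- apply_tac_truncation(ref, 5L)
  fr <- file.path(out_dir, "reference_standard.csv")
  utils::write.csv(data.frame(bin = seq_along(ref$counts) - 1L,
                              counts = ref$counts), fr, row.names = FALSE)
  files <- c(files, fr)
  manifest <- list(seed = as.integer(seed), height = height, width = width,
                   files = lapply(files, function(f)
                     list(name = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "fixtures_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
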