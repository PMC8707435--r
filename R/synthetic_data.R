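#' Phenotype profile for the synthetic cohort generator
#'
#' A profile plants class-specific marker m/z values (per omics layer) on
#' top of background peaks shared by all classes. Inter-class similarity is
#' controlled by how many marker m/z values two profiles share: phenotypes
#' sharing more markers produce more similar files and end up closer in the
#' learned distance matrix.
#'
#' @param label One of CNT, OVC, RNC, PRC.
#' @param marker_mz Named list (proteomic, metabolomic) of marker m/z
#'   vectors, in Thomson, inside the layer's m/z range.
#' @param marker_intensity_scale Multiplier on marker intensity relative to
#'   the unit-median background.
#' @param shared_background Named list of background m/z common to all
#'   classes.
#' @return A list of class `phenotype_profile`.
#' @export
phenotype_profile <- function(label, marker_mz, marker_intensity_scale = 5,
                              shared_background = NULL) {
  stopifnot(label %in% PHENOTYPE_LEVELS)
  structure(list(label = label, marker_mz = marker_mz,
                 marker_intensity_scale = marker_intensity_scale,
                 shared_background = shared_background),
            class = "phenotype_profile")
}

#' Default phenotype profiles with controlled marker overlap
#'
#' The default geometry mirrors the qualitative structure the classifiers
#' are expected to recover: the three cancer classes share a pool of
#' "cancer-common" markers absent from the control, kidney (RNC) and
#' ovarian (OVC) cancer share the most pairwise markers, ovarian and
#' prostate (PRC) the fewest, and the control carries only its own
#' markers. So by construction the control is the most distant phenotype
#' and the RNC/OVC pair the closest.
#'
#' @param marker_intensity_scale Marker intensity multiplier (default 5).
#' @return Named list of four [phenotype_profile()]s.
#' @export
default_phenotype_profiles <- function(marker_intensity_scale = 5) {
  # deterministic, well-separated marker positions per layer
  prot <- function(i) 150 + 37 * i       # 100-2000 Th range
  met <- function(i) 60 + 17 * i         # 50-1000 Th range
  sets <- function(idx) list(proteomic = prot(idx), metabolomic = met(idx))
  cancer_common <- 1:6
  rnc_ovc <- 7:10          # 4 shared markers: closest pair
  rnc_prc <- 11:12         # 2 shared
  ovc_prc <- 13L           # 1 shared: most distant cancer pair
  uniq <- list(CNT = 14:21, OVC = 22:29, RNC = 30:37, PRC = 38:45)
  background <- sets(46:49)
  mk <- function(idx) sets(sort(idx))
  list(
    CNT = phenotype_profile("CNT", mk(uniq$CNT),
                            marker_intensity_scale, background),
    OVC = phenotype_profile("OVC", mk(c(cancer_common, rnc_ovc, ovc_prc,
                                        uniq$OVC)),
                            marker_intensity_scale, background),
    RNC = phenotype_profile("RNC", mk(c(cancer_common, rnc_ovc, rnc_prc,
                                        uniq$RNC)),
                            marker_intensity_scale, background),
    PRC = phenotype_profile("PRC", mk(c(cancer_common, rnc_prc, ovc_prc,
                                        uniq$PRC)),
                            marker_intensity_scale, background))
}

#' Generator configuration for synthetic cohorts
#'
#' Desk-scale defaults: 30 subjects per class, 200 spectra per file over a
#' 967 s run (ten image windows), around 30 background peaks per spectrum,
#' ppm-scale m/z jitter matched to instrument accuracy per layer (5 ppm
#' proteomic, 50 ppm metabolomic), log-normal intensity noise, and a 0.1
#' fraction of pure-noise spectra.
#'
#' @param n_files_per_class Subjects per phenotype class.
#' @param spectra_per_file Scans per file.
#' @param rt_span Chromatographic span in seconds.
#' @param peaks_per_spectrum Mean background (decoy) peaks per spectrum
#'   (Poisson).
#' @param mz_jitter_ppm Named vector of maximum m/z jitter per layer, ppm.
#' @param intensity_noise Log-normal sigma of intensity noise.
#' @param noise_spectrum_fraction Fraction of spectra carrying only decoys.
#' @param rt_drift_fraction Per-file chromatographic drift of marker
#'   elution centers, as a fraction of `rt_span` (default 0.02): elution
#'   times are analyte properties reproducible across runs up to a small
#'   run-to-run drift.
#' @param mz_range Named list of per-layer m/z ranges.
#' @param seed Master integer seed; per-file seeds are derived from it by a
#'   counter so cohorts are reproducible file by file.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_files_per_class = 30L, spectra_per_file = 200L,
                             rt_span = 967, peaks_per_spectrum = 30,
                             mz_jitter_ppm = c(proteomic = 5, metabolomic = 50),
                             intensity_noise = 0.3,
                             noise_spectrum_fraction = 0.1,
                             rt_drift_fraction = 0.02,
                             mz_range = list(proteomic = c(100, 2000),
                                             metabolomic = c(50, 1000)),
                             seed = 1L) {
  stopifnot(n_files_per_class >= 1, spectra_per_file >= 1, rt_span > 0,
            noise_spectrum_fraction >= 0, noise_spectrum_fraction <= 1)
  structure(list(n_files_per_class = as.integer(n_files_per_class),
                 spectra_per_file = as.integer(spectra_per_file),
                 rt_span = rt_span, peaks_per_spectrum = peaks_per_spectrum,
                 mz_jitter_ppm = mz_jitter_ppm,
                 intensity_noise = intensity_noise,
                 noise_spectrum_fraction = noise_spectrum_fraction,
                 rt_drift_fraction = rt_drift_fraction,
                 mz_range = mz_range, seed = as.integer(seed)),
            class = "generator_config")
}

derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1000003 + counter * 7919) %% 2147483629)
}

#' Generate one synthetic spectra file
#'
#' Spectra sit on an even RT grid across `rt_span`. Each marker elutes
#' with a Gaussian chromatographic envelope (random center and width per
#' file); background consists of the shared background m/z plus uniform
#' decoy peaks with log-normal intensities. A `noise_spectrum_fraction`
#' subset of spectra contains only decoys. Marker and background m/z are
#' jittered uniformly within the layer's ppm tolerance.
#'
#' @param profile A [phenotype_profile()].
#' @param layer `"proteomic"` or `"metabolomic"`.
#' @param cfg A [generator_config()].
#' @param file_seed Integer seed for this file.
#' @param file_id File identifier (default derived from label and seed).
#' @return A [spectra_file()] labeled with the profile's phenotype.
#' @export
generate_file <- function(profile, layer, cfg = generator_config(),
                          file_seed = 1L, file_id = NULL) {
  stopifnot(inherits(profile, "phenotype_profile"))
  layer <- match.arg(layer, OMICS_LAYERS)
  mzr <- cfg$mz_range[[layer]]
  markers <- profile$marker_mz[[layer]]
  if (any(markers < mzr[1] | markers > mzr[2]))
    stop("marker m/z outside the ", layer, " m/z range [",
         mzr[1], ", ", mzr[2], "]")
  if (is.null(file_id))
    file_id <- sprintf("%s_s%d_%s", profile$label, file_seed, layer)
  set.seed(as.integer(file_seed))
  n <- cfg$spectra_per_file
  rt <- seq(0, cfg$rt_span, length.out = n)
  is_noise <- runif(n) < cfg$noise_spectrum_fraction
  jit_max <- cfg$mz_jitter_ppm[[layer]] * 1e-6
  background <- profile$shared_background[[layer]]
  # Chromatography is reproducible across runs: each analyte elutes at a
  # time characteristic of the analyte, not of the run. Elution centers
  # and widths are therefore deterministic functions of the marker m/z
  # (so all files agree), with a small per-file drift.
  hash01 <- function(x, salt) {
    v <- sin(x * 12.9898 + salt) * 43758.5453
    v - floor(v)
  }
  centers <- (0.1 + 0.8 * hash01(markers, 1)) * cfg$rt_span +
    runif(length(markers), -1, 1) * cfg$rt_drift_fraction * cfg$rt_span
  widths <- (0.05 + 0.05 * hash01(markers, 2)) * cfg$rt_span
  scale <- profile$marker_intensity_scale
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    mz <- numeric(0); intensity <- numeric(0)
    if (!is_noise[i]) {
      env <- scale * exp(-(rt[i] - centers)^2 / (2 * widths^2))
      on <- env > 0.05 * scale
      if (any(on)) {
        m <- markers[on]
        jit <- if (jit_max > 0) runif(length(m), -jit_max, jit_max) else 0
        mz <- c(mz, m * (1 + jit))
        noise_mult <- if (cfg$intensity_noise > 0)
          rlnorm(length(m), 0, cfg$intensity_noise) else 1
        intensity <- c(intensity, env[on] * noise_mult)
      }
      if (length(background) > 0) {
        on_bg <- runif(length(background)) < 0.5
        if (any(on_bg)) {
          b <- background[on_bg]
          jit <- if (jit_max > 0) runif(length(b), -jit_max, jit_max) else 0
          mz <- c(mz, b * (1 + jit))
          intensity <- c(intensity, rlnorm(length(b), 0, cfg$intensity_noise))
        }
      }
    }
    n_decoy <- rpois(1, cfg$peaks_per_spectrum)
    if (n_decoy > 0) {
      mz <- c(mz, runif(n_decoy, mzr[1], mzr[2]))
      intensity <- c(intensity, rlnorm(n_decoy, 0, cfg$intensity_noise))
    }
    peaks <- if (length(mz) > 0) cbind(mz = mz, intensity = intensity)
      else empty_peaks()
    spectra[[i]] <- ms_spectrum(rt_seconds = rt[i],
                                precursor_mz = if (length(mz) > 0)
                                  max(mz) else mzr[2],
                                peaks = peaks,
                                title = sprintf("%s scan=%d RT=%g",
                                                file_id, i, rt[i]))
  }
  spectra_file(spectra, file_id = file_id, omics_layer = layer,
               class_label = profile$label)
}

#' Generate a labeled four-class cohort (both omics layers)
#'
#' One proteomic and one metabolomic file per subject, classes exactly
#' balanced. Ground-truth labels are returned separately from the catalog
#' so evaluation can be run blind.
#'
#' @param profiles Named list of 4 [phenotype_profile()]s with distinct
#'   labels (default [default_phenotype_profiles()]).
#' @param cfg A [generator_config()].
#' @return A list with `files` (named list of [spectra_file()]s),
#'   `catalog` (a [dataset_catalog()]) and `truth` (data frame subject,
#'   label).
#' @export
generate_cohort <- function(profiles = default_phenotype_profiles(),
                            cfg = generator_config()) {
  labels <- vapply(profiles, `[[`, character(1), "label")
  if (length(unique(labels)) != 4)
    stop("need 4 profiles with distinct labels")
  files <- list()
  rows <- list()
  truth <- list()
  counter <- 0L
  for (p in profiles) {
    for (i in seq_len(cfg$n_files_per_class)) {
      subject <- sprintf("%s%02d", p$label, i)
      for (layer in OMICS_LAYERS) {
        counter <- counter + 1L
        fid <- sprintf("%s_%s", subject, layer)
        files[[fid]] <- generate_file(p, layer, cfg,
                                      file_seed = derive_seed(cfg$seed, counter),
                                      file_id = fid)
        rows[[length(rows) + 1]] <- data.frame(
          file_id = fid, layer = layer, label = p$label, subject = subject,
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1]] <- data.frame(subject = subject,
                                               label = p$label,
                                               stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  catalog <- dataset_catalog(rows$file_id, rows$layer, rows$label,
                             subject = rows$subject)
  list(files = files, catalog = catalog, truth = do.call(rbind, truth))
}

#' Write a generated cohort to disk as mgf files plus catalog
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$catalog))
  for (i in seq_len(nrow(cohort$catalog))) {
    fid <- cohort$catalog$file_id[i]
    paths[i] <- file.path(dir, paste0(fid, ".mgf"))
    write_mgf(cohort$files[[fid]], paths[i])
  }
  cohort$catalog$path <- paths
  write_catalog(cohort$catalog, file.path(dir, "catalog.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
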