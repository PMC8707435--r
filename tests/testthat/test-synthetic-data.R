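small_cfg <- function(...) {
  args <- utils::modifyList(list(n_files_per_class = 2L,
                                 spectra_per_file = 40L, rt_span = 400,
                                 peaks_per_spectrum = 10, seed = 5L),
                            list(...))
  do.call(generator_config, args)
}

file_mz <- function(sf) unlist(lapply(sf$spectra, function(s) s$peaks[, "mz"]))

test_that("pure-noise files contain no marker m/z; zero jitter is exact", {
  prof <- default_phenotype_profiles()$OVC
  noisy <- generate_file(prof, "proteomic",
                         small_cfg(noise_spectrum_fraction = 1), 3)
  expect_false(any(file_mz(noisy) %in% prof$marker_mz$proteomic))
  clean <- generate_file(prof, "proteomic",
                         small_cfg(mz_jitter_ppm = c(proteomic = 0,
                                                     metabolomic = 0),
                                   intensity_noise = 0,
                                   noise_spectrum_fraction = 0,
                                   peaks_per_spectrum = 0), 3)
  mzs <- unique(file_mz(clean))
  expect_true(all(mzs %in% c(prof$marker_mz$proteomic,
                             prof$shared_background$proteomic)))
  expect_true(all(prof$marker_mz$proteomic %in% mzs))
})

test_that("marker m/z jitter stays within the configured ppm bound", {
  prof <- default_phenotype_profiles()$RNC
  cfg <- small_cfg(peaks_per_spectrum = 0, noise_spectrum_fraction = 0,
                   spectra_per_file = 200L)
  sf <- generate_file(prof, "metabolomic", cfg, 11)
  obs <- file_mz(sf)
  markers <- c(prof$marker_mz$metabolomic, prof$shared_background$metabolomic)
  nearest <- markers[vapply(obs, function(m) which.min(abs(markers - m)),
                            integer(1))]
  dev_ppm <- abs(obs - nearest) / nearest * 1e6
  expect_gt(length(obs), 1000)
  expect_true(all(dev_ppm <= 50 + 1e-9))
})

test_that("generation is deterministic in the file seed and errors out of range", {
  prof <- default_phenotype_profiles()$CNT
  a <- generate_file(prof, "proteomic", small_cfg(), 7)
  b <- generate_file(prof, "proteomic", small_cfg(), 7)
  expect_equal(file_mz(a), file_mz(b))
  c_ <- generate_file(prof, "proteomic", small_cfg(), 8)
  expect_false(identical(file_mz(a), file_mz(c_)))
  bad <- phenotype_profile("CNT", list(proteomic = 5000, metabolomic = 500))
  expect_error(generate_file(bad, "proteomic", small_cfg(), 1),
               "outside")
})

test_that("cohorts are paired, balanced, and labeled consistently", {
  cohort <- generate_cohort(default_phenotype_profiles(), small_cfg())
  expect_equal(nrow(cohort$truth), 8)          # 2 subjects x 4 classes
  expect_equal(nrow(cohort$catalog), 16)       # 2 omics layers each
  expect_equal(unname(table(cohort$truth$label)), rep(2L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(cohort$catalog$layer)), c(16L, 16L) / 2,
               ignore_attr = TRUE)
  for (i in seq_len(nrow(cohort$catalog))) {
    sf <- cohort$files[[cohort$catalog$file_id[i]]]
    expect_equal(sf$class_label, cohort$catalog$label[i])
    expect_equal(sf$omics_layer, cohort$catalog$layer[i])
  }
  # round trip through mgf on disk
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  expect_length(list.files(dir, pattern = "\\.mgf$"), 16)
  back <- read_mgf(file.path(dir, paste0(cohort$catalog$file_id[1], ".mgf")))
  expect_length(back$spectra, 40)
})

test_that("a nearest-centroid oracle on marker presence recovers all labels", {
  profiles <- disjoint_profiles()
  cfg <- small_cfg(n_files_per_class = 3L,
                   mz_jitter_ppm = c(proteomic = 0, metabolomic = 0),
                   intensity_noise = 0, noise_spectrum_fraction = 0,
                   peaks_per_spectrum = 2)
  cohort <- generate_cohort(profiles, cfg)
  markers <- all_marker_mz(profiles, "proteomic")
  presence <- function(sf) as.numeric(markers %in% round(file_mz(sf), 6))
  class_sets <- lapply(profiles, function(p)
    as.numeric(markers %in% p$marker_mz$proteomic))
  prot_ids <- cohort$catalog$file_id[cohort$catalog$layer == "proteomic"]
  pred <- vapply(prot_ids, function(id) {
    v <- presence(cohort$files[[id]])
    names(profiles)[which.max(vapply(class_sets, function(cs) sum(v * cs),
                                     numeric(1)))]
  }, character(1))
  truth <- cohort$catalog$label[match(prot_ids, cohort$catalog$file_id)]
  expect_equal(unname(pred), truth)
})

test_that("stronger planted markers never hurt downstream test accuracy", {
  # mean over two weight seeds: single runs on 16 test subjects carry a
  # couple-of-subjects training noise that would drown the effect
  accs <- vapply(c(0.3, 3, 10), function(scale) {
    cfg <- generator_config(n_files_per_class = 10L, spectra_per_file = 60L,
                            rt_span = 400, peaks_per_spectrum = 15, seed = 2L)
    cohort <- generate_cohort(default_phenotype_profiles(scale), cfg)
    catalog <- assign_splits(cohort$catalog, 0.6, seed = 1)
    pc <- preprocess_config(channel_length = 1024L)
    ds <- prepare_channel_dataset(cohort$files, catalog, pc, seed = 1)
    mean(vapply(c(4, 5), function(mseed) {
      m <- build_1d_model(model_1d_spec(channel_length = 1024L,
                                        stem_filters = 64L, stem_kernel = 1L,
                                        stem_stride = 2L,
                                        blocks = c(1L, 1L, 1L, 1L),
                                        filters = c(32L, 32L, 32L, 32L)),
                          seed = mseed)
      res <- train_model(m, ds$train, ds$test,
                         train_config(epochs = 12, batch_size = 8,
                                      plateau_patience = 3, seed = 6))
      evaluate_model(res$model, ds$test$x, ds$test$y)$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))
})
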