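# Fixtures are built in code; nothing is read from disk.

PHENO <- c("CNT", "OVC", "RNC", "PRC")

random_spectra_file <- function(n_spectra = 3, n_peaks = 5, seed = 1,
                                layer = "proteomic", label = "CNT",
                                rt_max = 100) {
  set.seed(seed)
  spectra <- lapply(seq_len(n_spectra), function(i) {
    k <- sample(0:n_peaks, 1)
    peaks <- if (k > 0) {
      cbind(mz = sort(runif(k, 100, 2000)), intensity = runif(k, 0.1, 1e4))
    } else matrix(numeric(0), ncol = 2)
    ms_spectrum(rt_seconds = runif(1, 0, rt_max),
                precursor_mz = runif(1, 200, 1500),
                peaks = peaks,
                title = sprintf("scan=%d", i),
                charge = sample(c(NA_integer_, 1L, 2L, 3L), 1))
  })
  spectra_file(spectra, sprintf("rand%d", seed), layer, label)
}

grid_spectra_file <- function(n_spectra, rt_max, peaks_fn,
                              layer = "proteomic", label = "CNT",
                              file_id = "grid") {
  rt <- seq(0, rt_max, length.out = n_spectra)
  spectra <- lapply(seq_len(n_spectra), function(i)
    ms_spectrum(rt_seconds = rt[i], precursor_mz = 500,
                peaks = peaks_fn(i), title = sprintf("scan=%d", i)))
  spectra_file(spectra, file_id, layer, label)
}

# balanced file catalog over the 4 phenotypes
balanced_catalog <- function(n_per_class, layer = "proteomic") {
  labels <- rep(PHENO, each = n_per_class)
  dataset_catalog(sprintf("%s%03d", labels, sequence(rep(n_per_class, 4))),
                  layer, labels)
}

# profiles with fully disjoint markers and no shared background: the
# maximally separable geometry used by oracle tests
disjoint_profiles <- function(scale = 5) {
  mk <- function(idx) list(proteomic = 150 + 40 * idx, metabolomic = 60 + 18 * idx)
  list(CNT = phenotype_profile("CNT", mk(1:6), scale),
       OVC = phenotype_profile("OVC", mk(7:12), scale),
       RNC = phenotype_profile("RNC", mk(13:18), scale),
       PRC = phenotype_profile("PRC", mk(19:24), scale))
}

all_marker_mz <- function(profiles, layer) {
  sort(unique(unlist(lapply(profiles, function(p) p$marker_mz[[layer]]))))
}

dense_frames <- function(n, size = 16, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(f)
    structure(list(frame_index = f,
                   pixels = matrix(runif(size * size, 0.05, 1), size, size),
                   rt_window = c(f - 1, f)),
              class = "spectrum_image"))
}

n_changed_frames <- function(before, after) {
  sum(vapply(seq_along(before),
             function(i) !identical(before[[i]]$pixels, after[[i]]$pixels),
             logical(1)))
}
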