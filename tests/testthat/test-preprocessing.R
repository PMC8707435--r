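test_that("feature extraction snaps RT to the grid and sorts by (rt, mz)", {
  sf <- spectra_file(list(
    ms_spectrum(1.04, 500, cbind(mz = c(100, 200), intensity = c(5, 7)))),
    "f", "proteomic")
  st <- extract_features(sf, preprocess_config(rt_step = 0.1))
  expect_equal(st$rt, c(1.0, 1.0))
  expect_equal(st$mz, c(100, 200))
  expect_equal(st$intensity, c(5, 7))

  empty <- spectra_file(list(), "e", "proteomic")
  st0 <- extract_features(empty)
  expect_equal(nrow(st0), 0)

  # brute-force sort oracle over 1000 random peaks
  sf2 <- random_spectra_file(n_spectra = 100, n_peaks = 19, seed = 42)
  st2 <- extract_features(sf2)
  n_exp <- sum(vapply(sf2$spectra, function(s) nrow(s$peaks), integer(1)))
  expect_equal(nrow(st2), n_exp)
  o <- order(st2$rt, st2$mz)
  expect_equal(o, seq_len(nrow(st2)))
})

test_that("ppm quantization bounds the relative error and is idempotent", {
  q <- quantize_mz(500.0, 10)
  expect_lt(abs(q$representative - 500), 0.0025 * (1 + 1e-9))
  # two values closer than half a bin share a bin
  q2 <- quantize_mz(c(500, 500 * (1 + 2e-6)), 10)
  expect_equal(q2$bin[1], q2$bin[2])
  # idempotence: quantizing the representative returns the same bin
  qq <- quantize_mz(q$representative, 10)
  expect_equal(qq$bin, q$bin)
  expect_error(quantize_mz(-1, 10), "> 0")

  set.seed(9)
  for (ppm in c(10, 100)) {
    mz <- runif(5000, 50, 2000)
    rep_ <- quantize_mz(mz, ppm)$representative
    expect_true(all(abs(rep_ - mz) / mz <= ppm * 1e-6))
  }
})

test_that("rare-feature filter keeps only bins present in > min_frequency files", {
  # bins occurring in 1, 2, 3 and 5 files
  mzs <- c(200, 300, 400, 500)
  streams <- lapply(1:5, function(i) {
    present <- mzs[c(i == 1, i <= 2, i <= 3, TRUE)]
    specphenonet:::feature_stream(rep(0, length(present)), present,
                                  rep(1, length(present)), "proteomic")
  })
  vocab <- build_feature_vocabulary(streams, 10)
  expect_equal(sort(vocab$count), c(1, 2, 3, 5))
  filt <- filter_rare_features(streams, vocab, 2)
  kept <- sort(unique(unlist(lapply(filt, `[[`, "mz"))))
  expect_equal(kept, c(400, 500))
  # idempotence
  vocab2 <- build_feature_vocabulary(filt, 10)
  filt2 <- filter_rare_features(filt, vocab2, 2)
  expect_equal(lapply(filt2, as.data.frame), lapply(filt, as.data.frame))
  # single-file dataset: every bin has frequency 1 -> everything removed
  solo <- filter_rare_features(streams[1], build_feature_vocabulary(streams[1], 10), 2)
  expect_equal(nrow(solo[[1]]), 0)
})

test_that("min-max scaling maps to [0, 1] with clipping and constant-to-zero", {
  st <- specphenonet:::feature_stream(c(0, 0, 0), c(100, 200, 300),
                                      c(10, 20, 30), "proteomic")
  stats <- fit_minmax_stats(list(st))
  sc <- minmax_scale(st, stats)
  expect_equal(sc$intensity, c(0, 0.5, 1))
  below <- specphenonet:::feature_stream(0, 50, 5, "proteomic")
  expect_equal(minmax_scale(below, stats)$intensity, 0)
  expect_equal(minmax_scale(below, stats)$mz, 0)
  const <- specphenonet:::feature_stream(c(0, 0), c(5, 5), c(7, 7), "proteomic")
  cs <- minmax_scale(const, fit_minmax_stats(list(const)))
  expect_equal(cs$intensity, c(0, 0))
  expect_error(fit_minmax_stats(list()), "empty")
  # property: scaled values always within [0, 1], lengths and RT untouched
  for (seed in 1:20) {
    set.seed(seed)
    r <- specphenonet:::feature_stream(sort(runif(50, 0, 10)),
                                       runif(50, 100, 2000),
                                       rlnorm(50, 0, 2), "proteomic")
    rs <- minmax_scale(r, stats)
    expect_true(all(rs$mz >= 0 & rs$mz <= 1))
    expect_true(all(rs$intensity >= 0 & rs$intensity <= 1))
    expect_equal(rs$rt, r$rt)
    expect_equal(nrow(rs), 50)
  }
})

test_that("elliptic envelope removes planted outliers, never more than the cut-off", {
  set.seed(4)
  n_in <- 980
  inlier <- cbind(rnorm(n_in, 0.5, 0.01), rnorm(n_in, 0.5, 0.01))
  outlier <- cbind(runif(20, 0.9, 1), runif(20, 0.9, 1))  # > 10 sigma away
  st <- specphenonet:::feature_stream(rep(0, 1000),
                                      c(inlier[, 1], outlier[, 1]),
                                      c(inlier[, 2], outlier[, 2]),
                                      "proteomic")
  f <- elliptic_envelope_filter(st, 0.2, seed = 1)
  removed <- 1000 - nrow(f)
  expect_lte(removed, 200)
  # all 20 planted extreme outliers are gone
  expect_false(any(f$mz >= 0.9))
})

test_that("elliptic envelope passes through short and degenerate streams", {
  short <- specphenonet:::feature_stream(rep(0, 10), runif(10), runif(10),
                                         "proteomic")
  expect_identical(elliptic_envelope_filter(short, 0.2), short)
  const <- specphenonet:::feature_stream(rep(0, 30), rep(0.5, 30),
                                         rep(0.5, 30), "proteomic")
  expect_warning(out <- elliptic_envelope_filter(const, 0.2), "degenerate")
  expect_equal(nrow(out), 30)
})

test_that("model channels subsample, pad, and preserve order", {
  cfg <- preprocess_config(channel_length = 16)
  mk <- function(n) specphenonet:::feature_stream(seq_len(n), seq_len(n) / n,
                                                  rev(seq_len(n)) / n,
                                                  "proteomic")
  exact <- to_model_channels(mk(16), mk(16), cfg)
  expect_equal(dim(exact), c(4, 16))
  expect_equal(unname(exact["prot_mz", ]), seq_len(16) / 16)
  # double length: every other element, order preserved
  dbl <- to_model_channels(mk(32), mk(16), cfg)
  expect_equal(unname(dbl["prot_mz", ]), (seq(1, 32, by = 2)) / 32)
  # short stream: zero right-padding
  short <- to_model_channels(mk(10), mk(16), cfg)
  expect_equal(unname(short["prot_mz", 11:16]), rep(0, 6))
  expect_equal(unname(short["prot_mz", 1:10]), seq_len(10) / 10)
  e <- specphenonet:::feature_stream(numeric(0), numeric(0), numeric(0),
                                     "proteomic")
  expect_error(to_model_channels(e, e, cfg), "empty")
})
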