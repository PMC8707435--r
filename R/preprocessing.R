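#' Preprocessing configuration
#'
#' Defaults follow the pipeline's noise-reduction scheme: features are
#' aligned on a 0.1 s retention-time grid, m/z is quantized to 10 ppm for
#' proteomic and 100 ppm for metabolomic data, features present in fewer
#' than three files are dropped (strict "frequency > 2"), intensities and
#' m/z are min-max scaled to [0, 1], and an elliptic-envelope step removes
#' at most a 0.2 fraction of outlying points.
#'
#' @param rt_step Retention-time grid step in seconds.
#' @param ppm_tolerance_proteomic,ppm_tolerance_metabolomic Quantization
#'   tolerances in parts per million.
#' @param min_feature_frequency Strict lower bound on the number of distinct
#'   files a quantized m/z bin must occur in to be kept (kept iff
#'   frequency > this value).
#' @param outlier_fraction Upper bound on the fraction of points removed by
#'   the elliptic envelope; must be in (0, 0.5).
#' @param channel_length Fixed length of each of the four 1D model channels.
#' @param minmax_source `"train_only"` fits scaling statistics on the
#'   training split only (leakage-safe default); `"per_dataset"` fits on
#'   whatever data is being scaled.
#' @param vocab_source `"train_only"` (default) counts feature frequencies
#'   on the training split and applies the resulting vocabulary to every
#'   split, so the filter treats all splits identically and leaks nothing;
#'   `"per_dataset"` counts within each split separately.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(rt_step = 0.1,
                              ppm_tolerance_proteomic = 10,
                              ppm_tolerance_metabolomic = 100,
                              min_feature_frequency = 2L,
                              outlier_fraction = 0.2,
                              channel_length = 2L^15L,
                              minmax_source = c("train_only", "per_dataset"),
                              vocab_source = c("train_only", "per_dataset")) {
  stopifnot(rt_step > 0, ppm_tolerance_proteomic > 0,
            ppm_tolerance_metabolomic > 0,
            outlier_fraction > 0, outlier_fraction < 0.5,
            channel_length >= 1)
  structure(list(rt_step = rt_step,
                 ppm_tolerance_proteomic = ppm_tolerance_proteomic,
                 ppm_tolerance_metabolomic = ppm_tolerance_metabolomic,
                 min_feature_frequency = as.integer(min_feature_frequency),
                 outlier_fraction = outlier_fraction,
                 channel_length = as.integer(channel_length),
                 minmax_source = match.arg(minmax_source),
                 vocab_source = match.arg(vocab_source)),
            class = "preprocess_config")
}

ppm_for_layer <- function(cfg, layer) {
  if (layer == "proteomic") cfg$ppm_tolerance_proteomic else cfg$ppm_tolerance_metabolomic
}

feature_stream <- function(rt, mz, intensity, layer) {
  stopifnot(length(rt) == length(mz), length(mz) == length(intensity))
  structure(data.frame(rt = as.numeric(rt), mz = as.numeric(mz),
                       intensity = as.numeric(intensity)),
            layer = layer, class = c("feature_stream", "data.frame"))
}

stream_layer <- function(stream) attr(stream, "layer")

#' Extract (rt, m/z, intensity) feature triples from a spectra file
#'
#' Step (a) of the noise-reduction scheme: every fragment peak of every
#' spectrum becomes one triple, with the retention time snapped to the
#' nearest multiple of `rt_step` and the triples ordered by (rt, m/z).
#'
#' @param sf A [spectra_file()].
#' @param cfg A [preprocess_config()].
#' @return A `feature_stream` data frame with columns rt, mz, intensity.
#' @export
extract_features <- function(sf, cfg = preprocess_config()) {
  stopifnot(inherits(sf, "spectra_file"))
  n_peaks <- vapply(sf$spectra, function(s) nrow(s$peaks), integer(1))
  if (length(n_peaks) == 0 || sum(n_peaks) == 0)
    return(feature_stream(numeric(0), numeric(0), numeric(0), sf$omics_layer))
  rt <- rep(round(rt_values(sf) / cfg$rt_step) * cfg$rt_step, n_peaks)
  mz <- unlist(lapply(sf$spectra, function(s) s$peaks[, 1]), use.names = FALSE)
  intensity <- unlist(lapply(sf$spectra, function(s) s$peaks[, 2]),
                      use.names = FALSE)
  o <- order(rt, mz)
  feature_stream(rt[o], mz[o], intensity[o], sf$omics_layer)
}

#' Quantize m/z values into multiplicative ppm bins
#'
#' Bins are log-spaced with ratio (1 + ppm * 1e-6), so the bin width is
#' proportional to mass everywhere -- the natural reading of a ppm
#' tolerance. The representative (bin center) deviates from any member by at
#' most half the tolerance: |rep - mz| / mz <= ppm * 1e-6 / 2 (+ float eps).
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param ppm Tolerance in parts per million.
#' @return A list with integer `bin` identifiers and numeric
#'   `representative` m/z, both parallel to `mz`.
#' @export
quantize_mz <- function(mz, ppm) {
  if (any(mz <= 0)) stop("m/z must be > 0")
  r <- log1p(ppm * 1e-6)
  bin <- as.integer(round(log(mz) / r))
  list(bin = bin, representative = exp(bin * r))
}

#' Count quantized feature occurrences across the files of a dataset
#'
#' Frequency of a bin = number of distinct files whose feature stream
#' contains that bin (not the within-file peak count).
#'
#' @param streams Named list of `feature_stream`s, one per file, all of the
#'   same omics layer.
#' @param ppm Quantization tolerance used for this layer.
#' @return A `feature_vocabulary`: data frame of (bin, count).
#' @export
build_feature_vocabulary <- function(streams, ppm) {
  per_file_bins <- lapply(streams, function(s) unique(quantize_mz(s$mz, ppm)$bin))
  tab <- table(unlist(per_file_bins, use.names = FALSE))
  structure(data.frame(bin = as.integer(names(tab)),
                       count = as.integer(tab)),
            ppm = ppm, files = names(streams),
            class = c("feature_vocabulary", "data.frame"))
}

#' Remove rare quantized features from feature streams
#'
#' Step (b): triples whose m/z bin occurs in `min_frequency` or fewer files
#' of the dataset are dropped; surviving bins all have frequency strictly
#' greater than `min_frequency` (the strict "exceeded 2" rule under the
#' default of 2). Applying the filter twice equals applying it once.
#'
#' @param streams List of `feature_stream`s (same layer as `vocab`).
#' @param vocab A [build_feature_vocabulary()] result from the same
#'   quantization tolerance.
#' @param min_frequency Strict threshold; bins kept iff count > this.
#' @param exclude_self If `TRUE`, a file that contributed to the
#'   vocabulary does not count its own presence: a bin survives in file f
#'   iff it occurs in more than `min_frequency` files *other than* f.
#'   Without this, files inside the counting set retain systematically
#'   more of their own background than files outside it (the vocabulary
#'   was selected by them), which skews any split the vocabulary was
#'   fitted on. The default `FALSE` keeps the plain dataset-wide rule.
#' @return The filtered list of streams (possibly with empty streams).
#' @export
filter_rare_features <- function(streams, vocab, min_frequency = 2L,
                                 exclude_self = FALSE) {
  ppm <- attr(vocab, "ppm")
  vocab_files <- attr(vocab, "files")
  out <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    if (nrow(s) == 0) return(s)
    thr <- min_frequency +
      (exclude_self && !is.null(vocab_files) &&
         !is.null(names(streams)) && names(streams)[i] %in% vocab_files)
    keep_bins <- vocab$bin[vocab$count > thr]
    bins <- quantize_mz(s$mz, ppm)$bin
    keep <- bins %in% keep_bins
    res <- s[keep, , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "layer") <- stream_layer(s)
    class(res) <- class(s)
    res
  })
  names(out) <- names(streams)
  out
}

#' Fit min-max scaling statistics over a set of feature streams
#'
#' @param streams List of `feature_stream`s (the designated statistics
#'   source, typically the training split).
#' @return A list with (min, max) per scaled channel (mz, intensity).
#' @export
fit_minmax_stats <- function(streams) {
  mz <- unlist(lapply(streams, `[[`, "mz"), use.names = FALSE)
  intensity <- unlist(lapply(streams, `[[`, "intensity"), use.names = FALSE)
  if (length(mz) == 0) stop("empty statistics source for min-max scaling")
  list(mz = range(mz), intensity = range(intensity))
}

#' Min-max scale the m/z and intensity channels of a feature stream
#'
#' Step (d): x -> (x - min) / (max - min), clipped to [0, 1] for values
#' outside the fitted range; a constant channel (max == min) maps to 0.
#' Array lengths and the RT grid are untouched.
#'
#' @param stream A `feature_stream`.
#' @param stats Result of [fit_minmax_stats()].
#' @return The scaled stream, with mz and intensity in [0, 1].
#' @export
minmax_scale <- function(stream, stats) {
  scale1 <- function(x, rng) {
    den <- rng[2] - rng[1]
    if (den <= 0) return(rep(0, length(x)))
    pmin(pmax((x - rng[1]) / den, 0), 1)
  }
  stream$mz <- scale1(stream$mz, stats$mz)
  stream$intensity <- scale1(stream$intensity, stats$intensity)
  stream
}

#' Elliptic-envelope outlier removal on (m/z, intensity) pairs
#'
#' Fits a robust location/scatter estimate (minimum covariance determinant)
#' to the (mz, intensity) point cloud of one file and removes the
#' `outlier_fraction` of points with the largest Mahalanobis distance. This
#' reflects the assumption that the weighted average error of the MS
#' measurements stays below the cut-off fraction. Streams shorter than
#' `min_points` pass through unfiltered; a degenerate (zero-variance) cloud
#' passes through with a warning.
#'
#' @param stream A `feature_stream`.
#' @param outlier_fraction Fraction of points to remove, in (0, 0.5).
#' @param seed Integer seed for the MCD subsampling.
#' @param min_points Minimum stream length for filtering (default 25).
#' @param max_fit_points Cap on the number of points used to fit the MCD
#'   estimate (default 2000); all points are still scored and filtered.
#' @return The filtered stream; the removed fraction never exceeds
#'   `outlier_fraction`.
#' @export
elliptic_envelope_filter <- function(stream, outlier_fraction = 0.2,
                                     seed = 1L, min_points = 25L,
                                     max_fit_points = 2000L) {
  stopifnot(outlier_fraction > 0, outlier_fraction < 0.5)
  n <- nrow(stream)
  if (n < min_points) return(stream)
  x <- cbind(stream$mz, stream$intensity)
  if (all(apply(x, 2, function(col) diff(range(col)) == 0))) {
    warning("degenerate (constant) point cloud; elliptic envelope skipped")
    return(stream)
  }
  set.seed(as.integer(seed))
  x_fit <- if (n > max_fit_points)
    x[sample.int(n, max_fit_points), , drop = FALSE] else x
  fit <- tryCatch(MASS::cov.rob(x_fit, method = "mcd"),
                  error = function(e) NULL)
  if (is.null(fit) || any(diag(fit$cov) <= 0) ||
      abs(det(fit$cov)) < .Machine$double.xmin) {
    warning("degenerate covariance; elliptic envelope skipped")
    return(stream)
  }
  d2 <- mahalanobis(x, fit$center, fit$cov)
  n_remove <- floor(outlier_fraction * n)
  if (n_remove == 0) return(stream)
  # ties at the cut distance: remove exactly n_remove points
  keep <- rank(-d2, ties.method = "first") > n_remove
  out <- stream[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "layer") <- stream_layer(stream)
  class(out) <- class(stream)
  out
}

#' Assemble the four fixed-length 1D model channels
#'
#' The 1D classifier consumes four parallel channels: proteomic m/z,
#' proteomic intensity, metabolomic m/z, metabolomic intensity. Streams
#' longer than `channel_length` are uniformly subsampled preserving RT
#' order; shorter streams are right-padded with zeros. Retention time
#' itself is not a channel: it orders the data but is not used at the
#' model input.
#'
#' @param proteomic,metabolomic Preprocessed, scaled `feature_stream`s.
#' @param cfg A [preprocess_config()].
#' @return A numeric matrix of dimension 4 x channel_length with rows
#'   (prot_mz, prot_intensity, met_mz, met_intensity).
#' @export
to_model_channels <- function(proteomic, metabolomic,
                              cfg = preprocess_config()) {
  if (nrow(proteomic) == 0 && nrow(metabolomic) == 0)
    stop("both feature streams are empty; no channels to build")
  L <- cfg$channel_length
  fit1 <- function(x) {
    n <- length(x)
    if (n == 0) return(numeric(L))
    if (n > L) {
      idx <- floor((seq_len(L) - 1) * n / L) + 1
      x[idx]
    } else c(x, numeric(L - n))
  }
  out <- rbind(prot_mz = fit1(proteomic$mz),
               prot_intensity = fit1(proteomic$intensity),
               met_mz = fit1(metabolomic$mz),
               met_intensity = fit1(metabolomic$intensity))
  out
}

#' Run the full noise-reduction pipeline over a catalogued cohort
#'
#' Applies, per omics layer, feature extraction (a), ppm quantization (c)
#' followed by the rare-feature frequency filter (b) on the quantized bins,
#' min-max scaling (d) and the elliptic-envelope step, then assembles the
#' four model channels per subject. Vocabulary and scaling statistics are
#' fitted per split ("each dataset") so no information crosses splits.
#'
#' @param files Named list of [spectra_file()]s (both layers; names are
#'   file_ids).
#' @param catalog A split-assigned [dataset_catalog()] covering the files.
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed (elliptic envelope subsampling).
#' @return A list with per-split elements, each containing `x` (array
#'   n x 4 x channel_length), `y` (factor of phenotype labels) and
#'   `subject` ids.
#' @export
prepare_channel_dataset <- function(files, catalog, cfg = preprocess_config(),
                                    seed = 1L) {
  stopifnot(all(catalog$file_id %in% names(files)))
  splits <- unique(catalog$split[catalog$split != "unassigned"])
  splits <- c(intersect(c("train", "validation", "test"), splits),
              setdiff(splits, c("train", "validation", "test")))
  has_train <- "train" %in% splits
  # vocabulary and scaling statistics fitted on the training split when
  # requested (and available), then applied unchanged to the other splits
  train_vocab <- list()
  train_stats <- NULL
  out <- list()
  for (split in splits) {
    sub <- catalog[catalog$split == split, , drop = FALSE]
    streams <- list()
    for (layer in OMICS_LAYERS) {
      ids <- sub$file_id[sub$layer == layer]
      raw <- lapply(setNames(ids, ids),
                    function(id) extract_features(files[[id]], cfg))
      ppm <- ppm_for_layer(cfg, layer)
      vocab <- if (cfg$vocab_source == "train_only" && has_train) {
        if (split == "train")
          train_vocab[[layer]] <- build_feature_vocabulary(raw, ppm)
        train_vocab[[layer]]
      } else build_feature_vocabulary(raw, ppm)
      filt <- filter_rare_features(raw, vocab, cfg$min_feature_frequency,
                                   exclude_self = TRUE)
      # replace m/z by its quantized representative (step c)
      filt <- lapply(filt, function(s) {
        if (nrow(s) > 0) s$mz <- quantize_mz(s$mz, ppm)$representative
        s
      })
      streams[[layer]] <- filt
    }
    stats_src <- if (cfg$minmax_source == "train_only" && has_train &&
                     split != "train") {
      train_stats
    } else NULL
    stats <- list()
    for (layer in OMICS_LAYERS) {
      stats[[layer]] <- if (is.null(stats_src)) {
        fit_minmax_stats(streams[[layer]])
      } else stats_src[[layer]]
      streams[[layer]] <- lapply(streams[[layer]], function(s) {
        s <- minmax_scale(s, stats[[layer]])
        elliptic_envelope_filter(s, cfg$outlier_fraction, seed = seed)
      })
    }
    if (split == "train") train_stats <- stats
    # pair the proteomic/metabolomic files of each subject
    subj_col <- if ("subject" %in% names(sub)) sub$subject else sub$file_id
    subj_ids <- unique(subj_col)
    x <- array(0, dim = c(length(subj_ids), 4, cfg$channel_length))
    y <- character(length(subj_ids))
    for (i in seq_along(subj_ids)) {
      sid <- subj_ids[i]
      pid <- sub$file_id[sub$layer == "proteomic" & subj_col == sid][1]
      mid <- sub$file_id[sub$layer == "metabolomic" & subj_col == sid][1]
      prot <- if (!is.na(pid)) streams[["proteomic"]][[pid]] else
        feature_stream(numeric(0), numeric(0), numeric(0), "proteomic")
      met <- if (!is.na(mid)) streams[["metabolomic"]][[mid]] else
        feature_stream(numeric(0), numeric(0), numeric(0), "metabolomic")
      x[i, , ] <- to_model_channels(prot, met, cfg)
      lab <- sub$label[match(c(pid, mid), sub$file_id)]
      y[i] <- lab[!is.na(lab)][1]
    }
    res <- list(x = x, y = factor(y, levels = PHENOTYPE_LEVELS),
                subject = subj_ids)
    attr(res, "minmax_stats") <- stats
    out[[split]] <- res
  }
  out
}
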