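#' @useDynLib specphenonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois rlnorm quantile sd mahalanobis setNames
#' @importFrom utils head tail write.csv read.csv
NULL

PHENOTYPE_LEVELS <- c("CNT", "OVC", "RNC", "PRC")
OMICS_LAYERS <- c("proteomic", "metabolomic")

#' Construct a single tandem mass spectrum
#'
#' A spectrum is one scan: a retention time, a precursor m/z, an optional
#' charge, and a fragment peak list. Peaks are kept sorted by ascending m/z.
#'
#' @param rt_seconds Retention time in seconds (must be >= 0).
#' @param precursor_mz Precursor mass-to-charge ratio in Thomson.
#' @param peaks Two-column numeric matrix (m/z, intensity); may have 0 rows.
#' @param title Free-text scan title.
#' @param charge Signed integer precursor charge, or `NA` when absent.
#' @return An object of class `spectrum`.
#' @export
ms_spectrum <- function(rt_seconds, precursor_mz, peaks = empty_peaks(),
                        title = "", charge = NA_integer_) {
  if (!is.matrix(peaks) || ncol(peaks) != 2)
    stop("peaks must be a two-column matrix (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0) {
    if (any(peaks[, 1] <= 0)) stop("peak m/z values must be > 0")
    if (any(peaks[, 2] < 0)) stop("peak intensities must be >= 0")
    if (is.unsorted(peaks[, 1])) peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  }
  if (!is.finite(rt_seconds) || rt_seconds < 0)
    stop("rt_seconds must be a finite non-negative number")
  structure(list(title = as.character(title),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = charge,
                 rt_seconds = as.numeric(rt_seconds),
                 peaks = peaks),
            class = "spectrum")
}

empty_peaks <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
}

#' Construct a spectra file (the in-memory form of one mgf file)
#'
#' @param spectra List of [ms_spectrum()] objects; re-ordered by retention time.
#' @param file_id Opaque identifier, unique per omics layer.
#' @param omics_layer `"proteomic"` or `"metabolomic"`.
#' @param class_label One of `CNT`, `OVC`, `RNC`, `PRC`, or `"unknown"`.
#' @return An object of class `spectra_file`.
#' @export
spectra_file <- function(spectra, file_id, omics_layer,
                         class_label = "unknown") {
  omics_layer <- match.arg(omics_layer, OMICS_LAYERS)
  if (!class_label %in% c(PHENOTYPE_LEVELS, "unknown"))
    stop("class_label must be one of ", paste(PHENOTYPE_LEVELS, collapse = ", "),
         " or 'unknown'")
  stopifnot(is.list(spectra))
  if (length(spectra) > 0) {
    rts <- vapply(spectra, function(s) s$rt_seconds, numeric(1))
    if (is.unsorted(rts)) spectra <- spectra[order(rts)]
  }
  structure(list(file_id = as.character(file_id),
                 omics_layer = omics_layer,
                 class_label = class_label,
                 spectra = spectra),
            class = "spectra_file")
}

#' @export
print.spectra_file <- function(x, ...) {
  cat(sprintf("<spectra_file> %s [%s, %s]: %d spectra\n",
              x$file_id, x$omics_layer, x$class_label, length(x$spectra)))
  invisible(x)
}

#' @export
length.spectra_file <- function(x) length(x$spectra)

rt_values <- function(sf) vapply(sf$spectra, function(s) s$rt_seconds, numeric(1))

parse_rt_from_title <- function(title) {
  m <- regmatches(title, regexpr("RT=[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?", title))
  if (length(m) == 0) return(NA_real_)
  as.numeric(sub("RT=", "", m))
}

#' Read a Mascot Generic Format peak-list file
#'
#' Parses BEGIN IONS/END IONS blocks with TITLE, PEPMASS, RTINSECONDS and
#' CHARGE headers and "mz intensity" peak lines. Retention time is taken from
#' RTINSECONDS, falling back to an `RT=<float>` token in the TITLE; a block
#' without any retention time is an error because the whole pipeline is
#' aligned on RT.
#'
#' @param path Path to an mgf file.
#' @param file_id Identifier to record; default the file name without extension.
#' @param omics_layer Omics layer of the file.
#' @param class_label Phenotype label, if known.
#' @param rt_units `"seconds"` (default) or `"minutes"`. Some mgf dialects
#'   store RT in minutes; with `rt_units = "minutes"` header values below 200
#'   are converted to seconds (values >= 200 are assumed to be seconds
#'   already).
#' @return A [spectra_file()].
#' @export
read_mgf <- function(path, file_id = NULL, omics_layer = "proteomic",
                     class_label = "unknown",
                     rt_units = c("seconds", "minutes")) {
  rt_units <- match.arg(rt_units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(file_id)) file_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  begin_idx <- which(lines == "BEGIN IONS")
  end_idx <- which(lines == "END IONS")
  if (length(begin_idx) != length(end_idx) ||
      (length(begin_idx) > 0 && any(end_idx < begin_idx)))
    stop(sprintf("malformed mgf '%s': BEGIN IONS at line %d without matching END IONS",
                 path, begin_idx[length(end_idx) + 1]))
  spectra <- vector("list", length(begin_idx))
  for (i in seq_along(begin_idx)) {
    block <- lines[(begin_idx[i] + 1):(end_idx[i] - 1)]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    keys <- sub("=.*$", "", headers)
    vals <- sub("^[A-Z]+=", "", headers)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else ""
    pepmass <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1]][1])
    } else NA_real_
    charge <- if ("CHARGE" %in% keys) {
      cv <- vals[match("CHARGE", keys)]
      sgn <- if (grepl("-", cv)) -1L else 1L
      sgn * as.integer(gsub("[^0-9]", "", cv))
    } else NA_integer_
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[match("RTINSECONDS", keys)])
    } else parse_rt_from_title(title)
    if (is.na(rt))
      stop(sprintf("spectrum %d (block starting line %d) of '%s' has no retention time (RTINSECONDS or RT= in TITLE)",
                   i, begin_idx[i], path))
    if (rt_units == "minutes" && rt < 200) rt <- rt * 60
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    peaks <- if (length(peak_lines) > 0) {
      fields <- strsplit(trimws(peak_lines), "[ \t]+")
      m <- matrix(as.numeric(unlist(lapply(fields, `[`, 1:2))),
                  ncol = 2, byrow = TRUE)
      m
    } else empty_peaks()
    spectra[[i]] <- ms_spectrum(rt_seconds = rt, precursor_mz = pepmass,
                                peaks = peaks, title = title, charge = charge)
  }
  spectra_file(spectra, file_id = file_id, omics_layer = omics_layer,
               class_label = class_label)
}

#' Write a spectra file as Mascot Generic Format text
#'
#' One BEGIN IONS/END IONS block per spectrum, fields in a fixed order
#' (TITLE, PEPMASS, RTINSECONDS, CHARGE), numbers printed with enough digits
#' that a read/write round trip is lossless well below 1e-6 relative error.
#'
#' @param sf A [spectra_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(sf, path) {
  stopifnot(inherits(sf, "spectra_file"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.12g", x)
  for (s in sf$spectra) {
    block <- c("BEGIN IONS",
               paste0("TITLE=", s$title),
               if (!is.na(s$precursor_mz)) paste0("PEPMASS=", fmt(s$precursor_mz)),
               paste0("RTINSECONDS=", fmt(s$rt_seconds)),
               if (!is.na(s$charge))
                 paste0("CHARGE=", abs(s$charge), if (s$charge < 0) "-" else "+"))
    writeLines(block, con)
    if (nrow(s$peaks) > 0)
      writeLines(paste(fmt(s$peaks[, 1]), fmt(s$peaks[, 2])), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Build a dataset catalog
#'
#' The catalog maps mgf files to omics layer, phenotype label, train/test/
#' validation split, and provenance (original vs augmented). It is the
#' file-system-backed replacement for a document store: a plain data frame
#' persisted as CSV.
#'
#' @param file_id Character vector of file identifiers.
#' @param layer Omics layer per file.
#' @param label Phenotype label per file.
#' @param split Split assignment (default `"unassigned"`).
#' @param provenance `"original"` or `"augmented"`.
#' @param source_file_id For augmented files, the originating file; `NA`
#'   otherwise.
#' @param subject Subject grouping: files of one subject (its omics layers)
#'   always share a split. Defaults to the file_id, i.e. no grouping.
#' @param path Optional on-disk location per file.
#' @return A `data.frame` with class `dataset_catalog`.
#' @export
dataset_catalog <- function(file_id, layer, label,
                            split = "unassigned", provenance = "original",
                            source_file_id = NA_character_,
                            subject = file_id, path = NA_character_) {
  cat_df <- data.frame(file_id = as.character(file_id),
                       layer = as.character(layer),
                       label = as.character(label),
                       split = as.character(split),
                       provenance = as.character(provenance),
                       source_file_id = as.character(source_file_id),
                       subject = as.character(subject),
                       path = as.character(path),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(cat_df[, c("file_id", "layer")]))
    stop("file_id must be unique within each omics layer")
  class(cat_df) <- c("dataset_catalog", "data.frame")
  cat_df
}

#' Persist a dataset catalog as CSV
#' @param catalog A [dataset_catalog()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset catalog from CSV
#' @param path CSV path written by [write_catalog()].
#' @return A [dataset_catalog()].
#' @export
read_catalog <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  do.call(dataset_catalog, df)
}

#' Stratified train/test/validation split of a dataset catalog
#'
#' Original files are assigned per phenotype class so that every split holds
#' the classes in (near) equal proportions; with 300 files and a 0.6 train
#' fraction this yields the canonical 180 train / 120 test partition.
#' Augmented files always inherit the split of their source file and are
#' never reassigned, which is what keeps augmentation leakage-free.
#'
#' @param catalog A [dataset_catalog()]; every original entry must carry a
#'   known class label.
#' @param train_fraction Fraction of original files per class for training.
#' @param validation_fraction Fraction per class for validation (default 0).
#' @param seed Integer seed; the assignment is deterministic given
#'   (catalog, seed).
#' @return The catalog with the `split` column filled in.
#' @export
assign_splits <- function(catalog, train_fraction = 0.6,
                          validation_fraction = 0, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            validation_fraction >= 0,
            train_fraction + validation_fraction <= 1)
  orig <- catalog$provenance == "original"
  if (any(is.na(catalog$label[orig]) | catalog$label[orig] == "unknown"))
    stop("every original catalog entry needs a class label before splitting")
  n_splits <- 2L + (validation_fraction > 0)
  counts <- table(catalog$label[orig][!duplicated(catalog$subject[orig])])
  too_small <- names(counts)[counts < n_splits]
  if (length(too_small) > 0)
    stop("class(es) with fewer files than splits: ",
         paste(too_small, collapse = ", "))
  set.seed(as.integer(seed))
  # stratify over subjects so that a subject's omics layers (and nothing
  # else) always travel together
  for (cl in sort(unique(catalog$label[orig]))) {
    subj <- sort(unique(catalog$subject[orig & catalog$label == cl]))
    subj <- subj[sample.int(length(subj))]
    n <- length(subj)
    n_train <- round(train_fraction * n)
    n_val <- round(validation_fraction * n)
    splits <- rep("test", n)
    splits[seq_len(n_train)] <- "train"
    if (n_val > 0) splits[n_train + seq_len(n_val)] <- "validation"
    catalog$split[orig & catalog$label == cl] <-
      splits[match(catalog$subject[orig & catalog$label == cl], subj)]
  }
  aug <- which(catalog$provenance == "augmented")
  if (length(aug) > 0) {
    key <- paste(catalog$file_id, catalog$layer)
    src_key <- paste(catalog$source_file_id[aug], catalog$layer[aug])
    m <- match(src_key, key)
    if (anyNA(m)) stop("augmented entries with unknown source_file_id")
    catalog$split[aug] <- catalog$split[m]
  }
  catalog
}
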