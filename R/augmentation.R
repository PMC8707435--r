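#' Extract edge spectra from a file into augmentation elements
#'
#' Up to 10 percent of a file's spectra -- the first `floor(head * N)` and
#' last `floor(tail * N)` scans in retention-time order -- are moved out of
#' the file and recorded as augmentation elements carrying their source file
#' and split. Original count = reduced count + extracted count, always.
#'
#' @param sf A [spectra_file()].
#' @param head,tail Fractions taken from the start and end of the file
#'   (defaults 0.05 each; head + tail < 1).
#' @param split Split of the source file, recorded immutably on every
#'   element.
#' @return A list with `reduced` (the trimmed [spectra_file()]) and
#'   `elements` (list of augmentation elements).
#' @export
extract_edge_elements <- function(sf, head = 0.05, tail = 0.05,
                                  split = "unassigned") {
  stopifnot(inherits(sf, "spectra_file"), head + tail < 1,
            head >= 0, tail >= 0)
  n <- length(sf$spectra)
  n_head <- floor(head * n)
  n_tail <- floor(tail * n)
  if (n == 0 || n_head + n_tail == 0)
    return(list(reduced = sf, elements = list()))
  take <- c(seq_len(n_head), n - n_tail + seq_len(n_tail))
  elements <- lapply(sf$spectra[take], function(s) {
    structure(list(source_file_id = sf$file_id, source_split = split,
                   layer = sf$omics_layer, original_rt = s$rt_seconds,
                   spectrum = s),
              class = "augmentation_element")
  })
  reduced <- sf
  reduced$spectra <- sf$spectra[-take]
  list(reduced = reduced, elements = elements)
}

#' Build an augmentation database from a catalogued cohort
#'
#' Runs [extract_edge_elements()] over every original file and pools the
#' elements, keyed by source split so that sampling never mixes splits.
#'
#' @param files Named list of [spectra_file()]s.
#' @param catalog A split-assigned [dataset_catalog()].
#' @param head_fraction,tail_fraction Edge fractions (defaults 0.05 each).
#' @return A list of class `augmentation_db` with `elements` and the
#'   reduced files, plus the edge fractions used.
#' @export
build_augmentation_db <- function(files, catalog,
                                  head_fraction = 0.05, tail_fraction = 0.05) {
  elements <- list()
  reduced <- files
  orig <- catalog[catalog$provenance == "original", , drop = FALSE]
  for (i in seq_len(nrow(orig))) {
    id <- orig$file_id[i]
    ex <- extract_edge_elements(files[[id]], head_fraction, tail_fraction,
                                split = orig$split[i])
    reduced[[id]] <- ex$reduced
    elements <- c(elements, ex$elements)
  }
  structure(list(elements = elements, reduced_files = reduced,
                 head_fraction = head_fraction, tail_fraction = tail_fraction),
            class = "augmentation_db")
}

db_elements_for_split <- function(db, split) {
  Filter(function(e) e$source_split == split, db$elements)
}

#' Synthesize augmented replicates of a spectra file
#'
#' Each replicate is the file with `round(insert_fraction * N)` elements,
#' drawn from the augmentation database restricted to the file's own split,
#' inserted at uniformly random retention times within the meaningful part
#' of the run (the middle 1 - head - tail span of the original RT range).
#' Inserted spectra are re-stamped with their new RT; replicates inherit the
#' source file's split and are marked as augmented provenance.
#'
#' @param sf A [spectra_file()] (typically the reduced file).
#' @param db An [build_augmentation_db()] result.
#' @param split Split of `sf`; only same-split elements are ever sampled.
#' @param n_replicates Number of replicates to synthesize.
#' @param insert_fraction Elements inserted per replicate as a fraction of
#'   the file's spectra count (default 0.10, mirroring the extracted
#'   fraction).
#' @param seed Integer seed; replicates differ through the seed stream.
#' @return A list of augmented [spectra_file()]s, each carrying attributes
#'   `provenance = "augmented"`, `split`, `source_file_id` and
#'   `inserted_sources` (data frame of the sampled elements' provenance).
#' @export
build_augmented_replicates <- function(sf, db, split, n_replicates,
                                       insert_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(sf, "spectra_file"), inherits(db, "augmentation_db"))
  if (n_replicates == 0) return(list())
  pool <- db_elements_for_split(db, split)
  if (length(pool) == 0)
    stop("augmentation database holds no elements for split '", split, "'")
  n <- length(sf$spectra)
  k <- round(insert_fraction * n)
  rts <- rt_values(sf)
  span <- range(rts)
  lo <- span[1] + db$head_fraction * diff(span)
  hi <- span[2] - db$tail_fraction * diff(span)
  set.seed(as.integer(seed))
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    picks <- sample.int(length(pool), k, replace = k > length(pool))
    new_rt <- runif(k, lo, hi)
    inserted <- lapply(seq_len(k), function(j) {
      s <- pool[[picks[j]]]$spectrum
      s$rt_seconds <- new_rt[j]
      s
    })
    rep_sf <- spectra_file(c(sf$spectra, inserted),
                           file_id = sprintf("%s_aug%d", sf$file_id, r),
                           omics_layer = sf$omics_layer,
                           class_label = sf$class_label)
    attr(rep_sf, "provenance") <- "augmented"
    attr(rep_sf, "split") <- split
    attr(rep_sf, "source_file_id") <- sf$file_id
    attr(rep_sf, "inserted_sources") <- data.frame(
      source_file_id = vapply(pool[picks], `[[`, character(1), "source_file_id"),
      source_split = vapply(pool[picks], `[[`, character(1), "source_split"),
      stringsAsFactors = FALSE)
    out[[r]] <- rep_sf
  }
  out
}

#' Enlarge the training split by edge-extraction augmentation
#'
#' Convenience wrapper for the full augmentation pathway: builds the
#' augmentation database over the whole catalog (every file loses its edge
#' scans to the database), then synthesizes `n_replicates` augmented
#' replicates for every training-split file from training-split elements
#' only. Test and validation files are left as their reduced versions and
#' are never augmented.
#'
#' @param files Named list of [spectra_file()]s.
#' @param catalog A split-assigned [dataset_catalog()].
#' @param n_replicates Replicates per training file.
#' @param insert_fraction Elements inserted per replicate as a fraction of
#'   the file's spectra count.
#' @param head_fraction,tail_fraction Edge fractions for the database.
#' @param seed Integer seed.
#' @return A list with the enlarged `files`, the extended `catalog`
#'   (augmented entries carry provenance `"augmented"` and their source
#'   subject), the `db`, and the list of `augmented` files for auditing.
#' @export
augment_training_split <- function(files, catalog, n_replicates = 3L,
                                   insert_fraction = 0.10,
                                   head_fraction = 0.05, tail_fraction = 0.05,
                                   seed = 1L) {
  db <- build_augmentation_db(files, catalog, head_fraction, tail_fraction)
  out_files <- db$reduced_files
  rows <- list()
  augmented <- list()
  train_idx <- which(catalog$split == "train" &
                       catalog$provenance == "original")
  for (i in train_idx) {
    id <- catalog$file_id[i]
    reps <- build_augmented_replicates(out_files[[id]], db, "train",
                                       n_replicates, insert_fraction,
                                       seed = derive_seed(seed, i))
    for (r in seq_along(reps)) {
      rid <- reps[[r]]$file_id
      out_files[[rid]] <- reps[[r]]
      augmented[[length(augmented) + 1]] <- reps[[r]]
      rows[[length(rows) + 1]] <- data.frame(
        file_id = rid, layer = catalog$layer[i], label = catalog$label[i],
        split = "train", provenance = "augmented", source_file_id = id,
        subject = sprintf("%s_aug%d", catalog$subject[i], r),
        path = NA_character_, stringsAsFactors = FALSE)
    }
  }
  new_catalog <- rbind(as.data.frame(catalog), do.call(rbind, rows))
  class(new_catalog) <- class(catalog)
  list(files = out_files, catalog = new_catalog, db = db,
       augmented = augmented)
}

#' Audit an augmented dataset for cross-split leakage
#'
#' Counts augmented files containing at least one element whose source split
#' differs from the file's own split. A correctly built dataset reports 0
#' violations.
#'
#' @param catalog A [dataset_catalog()] covering the augmented files.
#' @param augmented_files List of augmented [spectra_file()]s (as returned by
#'   [build_augmented_replicates()]).
#' @return A list with `n_violations` and a data frame of `violations`.
#' @export
audit_leakage <- function(catalog, augmented_files) {
  bad <- list()
  key <- paste(catalog$file_id, catalog$layer)
  for (sf in augmented_files) {
    own_split <- catalog$split[match(paste(sf$file_id, sf$omics_layer), key)]
    if (is.na(own_split)) own_split <- attr(sf, "split")
    src <- attr(sf, "inserted_sources")
    if (is.null(src) || nrow(src) == 0) next
    foreign <- src$source_split != own_split
    if (any(foreign))
      bad[[length(bad) + 1]] <- data.frame(
        file_id = sf$file_id, layer = sf$omics_layer, split = own_split,
        n_foreign_elements = sum(foreign), stringsAsFactors = FALSE)
  }
  violations <- if (length(bad) > 0) do.call(rbind, bad) else
    data.frame(file_id = character(0), layer = character(0),
               split = character(0), n_foreign_elements = integer(0))
  list(n_violations = nrow(violations), violations = violations)
}
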