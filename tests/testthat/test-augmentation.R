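edge_file <- function(n, seed = 1) {
  grid_spectra_file(n, rt_max = 1000, peaks_fn = function(i)
    cbind(mz = 100 + i, intensity = 1), file_id = sprintf("ef%d", seed))
}

test_that("edge extraction takes floor(head*N) + floor(tail*N) spectra", {
  ex <- extract_edge_elements(edge_file(100), 0.05, 0.05, split = "train")
  expect_length(ex$elements, 10)
  expect_length(ex$reduced$spectra, 90)
  # conservation and identity of the removed scans
  expect_equal(ex$elements[[1]]$spectrum$rt_seconds, 0)
  expect_equal(ex$elements[[10]]$spectrum$rt_seconds, 1000)
  expect_equal(vapply(ex$elements, `[[`, character(1), "source_split"),
               rep("train", 10))

  ex20 <- extract_edge_elements(edge_file(20), 0.05, 0.05)
  expect_length(ex20$elements, 2)

  ex0 <- extract_edge_elements(spectra_file(list(), "z", "proteomic"))
  expect_length(ex0$elements, 0)
  expect_length(ex0$reduced$spectra, 0)
})

test_that("conservation holds per file across the augmentation database", {
  catg <- balanced_catalog(2)
  catg <- assign_splits(catg, 0.6, seed = 1)
  files <- setNames(lapply(seq_len(nrow(catg)), function(i) {
    sf <- edge_file(40 + i, seed = i)
    sf$file_id <- catg$file_id[i]
    sf
  }), catg$file_id)
  db <- build_augmentation_db(files, catg)
  n_orig <- sum(vapply(files, length, integer(1)))
  n_red <- sum(vapply(db$reduced_files, length, integer(1)))
  expect_equal(n_red + length(db$elements), n_orig)
  # elements never co-mingle splits at sampling time
  for (sp in c("train", "test")) {
    pool <- specphenonet:::db_elements_for_split(db, sp)
    expect_true(all(vapply(pool, `[[`, character(1), "source_split") == sp))
  }
})

test_that("replicates add round(insert_fraction*N) spectra inside the meaningful RT span", {
  sf <- edge_file(100)
  ex <- extract_edge_elements(sf, 0.05, 0.05, split = "train")
  db <- structure(list(elements = ex$elements, reduced_files = list(),
                       head_fraction = 0.05, tail_fraction = 0.05),
                  class = "augmentation_db")
  expect_length(build_augmented_replicates(sf, db, "train", 0), 0)
  reps <- build_augmented_replicates(sf, db, "train", 3,
                                     insert_fraction = 0.1, seed = 5)
  expect_length(reps, 3)
  for (r in reps) {
    expect_length(r$spectra, 110)
    expect_equal(attr(r, "provenance"), "augmented")
    expect_equal(attr(r, "split"), "train")
    src <- attr(r, "inserted_sources")
    expect_equal(nrow(src), 10)
    # inserted RTs lie within the middle 90% of the original span
    ins <- setdiff(round(vapply(r$spectra, `[[`, numeric(1), "rt_seconds"), 9),
                   round(vapply(sf$spectra, `[[`, numeric(1), "rt_seconds"), 9))
    expect_true(all(ins >= 50 & ins <= 950))
  }
  # determinism given seed; different replicates differ
  reps2 <- build_augmented_replicates(sf, db, "train", 3,
                                      insert_fraction = 0.1, seed = 5)
  expect_identical(lapply(reps, rt_set <- function(r)
    vapply(r$spectra, `[[`, numeric(1), "rt_seconds")),
    lapply(reps2, rt_set))
  expect_false(identical(rt_set(reps[[1]]), rt_set(reps[[2]])))
  expect_error(build_augmented_replicates(sf, db, "test", 1), "no elements")
})

test_that("augment_training_split enlarges only the training split, leakage-free", {
  catg <- assign_splits(balanced_catalog(3), 0.6, seed = 4)
  files <- setNames(lapply(seq_len(nrow(catg)), function(i) {
    sf <- edge_file(60, seed = i); sf$file_id <- catg$file_id[i]; sf
  }), catg$file_id)
  aug <- augment_training_split(files, catg, n_replicates = 2L, seed = 9)
  n_train <- sum(catg$split == "train")
  expect_equal(nrow(aug$catalog), nrow(catg) + 2L * n_train)
  added <- aug$catalog[aug$catalog$provenance == "augmented", ]
  expect_true(all(added$split == "train"))
  # every file lost its edges to the database, replicates gained spectra
  expect_true(all(vapply(catg$file_id, function(id)
    length(aug$files[[id]]) < length(files[[id]]), logical(1))))
  expect_equal(audit_leakage(aug$catalog, aug$augmented)$n_violations, 0)
})

test_that("leakage audit reports zero on clean sets and flags planted violations", {
  catg <- assign_splits(balanced_catalog(3), 0.6, seed = 2)
  files <- setNames(lapply(seq_len(nrow(catg)), function(i) {
    sf <- edge_file(60, seed = i); sf$file_id <- catg$file_id[i]; sf
  }), catg$file_id)
  db <- build_augmentation_db(files, catg)
  aug <- unlist(lapply(seq_len(nrow(catg)), function(i)
    build_augmented_replicates(db$reduced_files[[catg$file_id[i]]], db,
                               catg$split[i], 2, seed = i)),
    recursive = FALSE)
  aug_cat <- dataset_catalog(
    vapply(aug, `[[`, character(1), "file_id"),
    vapply(aug, `[[`, character(1), "omics_layer"),
    vapply(aug, `[[`, character(1), "class_label"),
    split = vapply(aug, function(a) attr(a, "split"), character(1)),
    provenance = "augmented",
    source_file_id = vapply(aug, function(a) attr(a, "source_file_id"),
                            character(1)))
  expect_equal(audit_leakage(aug_cat, aug)$n_violations, 0)
  expect_equal(audit_leakage(aug_cat, list())$n_violations, 0)
  # plant one cross-split element
  corrupted <- aug
  src <- attr(corrupted[[1]], "inserted_sources")
  src$source_split[1] <- setdiff(c("train", "test"),
                                 attr(corrupted[[1]], "split"))[1]
  attr(corrupted[[1]], "inserted_sources") <- src
  res <- audit_leakage(aug_cat, corrupted)
  expect_equal(res$n_violations, 1)
  expect_equal(res$violations$file_id, corrupted[[1]]$file_id)
})
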