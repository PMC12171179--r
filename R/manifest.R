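## Cohort manifest: the on-disk contract tying together per-patient modality
## files, labels and splits.
##
## Layout: a CSV with columns patient_id, tongue_path, face_path, pulse_path,
## label, split (paths relative to the manifest's directory), plus a clinical
## table CSV whose first column is patient_id and whose remaining named
## columns are the clinical features.

MANIFEST_COLS <- c("patient_id", "tongue_path", "face_path", "pulse_path",
                   "label", "split")
SPLIT_LEVELS <- c("train", "internal", "external")

new_manifest <- function(records, clinical_table_path, features, root) {
  structure(list(records = records,
                 clinical_table_path = clinical_table_path,
                 features = features,
                 root = root),
            class = "cohort_manifest")
}

#' Read a cohort manifest
#'
#' @param path manifest CSV with columns
#'   `patient_id,tongue_path,face_path,pulse_path,label,split`.
#' @param clinical_path clinical table CSV; defaults to `clinical.csv` next
#'   to the manifest. First column must be `patient_id`.
#' @param check_paths validate that every referenced modality file exists.
#' @return A `cohort_manifest` object: `$records` (data.frame, row order as
#'   on disk), `$clinical_table_path`, `$features` (clinical feature names),
#'   `$root` (directory against which relative paths resolve).
#' @export
read_manifest <- function(path, clinical_path = NULL, check_paths = TRUE) {
  assert_that(file.exists(path), "manifest file not found: ", path)
  rec <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("patient_id", "tongue_path", "face_path", "pulse_path", "split"))))
  assert_that(identical(names(rec), MANIFEST_COLS),
              "manifest header must be: ", paste(MANIFEST_COLS, collapse = ","))
  root <- dirname(normalizePath(path))
  clinical_path <- clinical_path %||% file.path(root, "clinical.csv")
  m <- new_manifest(rec, clinical_path, features = character(0), root = root)
  if (nrow(rec)) {
    dup <- unique(rec$patient_id[duplicated(rec$patient_id)])
    assert_that(length(dup) == 0,
                "duplicated patient_id in manifest: ", paste(dup, collapse = ", "))
    assert_that(all(rec$label %in% c(0L, 1L)), "labels must be 0 or 1")
    assert_that(all(rec$split %in% SPLIT_LEVELS),
                "split must be one of: ", paste(SPLIT_LEVELS, collapse = ", "))
    if (check_paths) {
      paths <- c(file.path(root, rec$tongue_path), file.path(root, rec$face_path),
                 file.path(root, rec$pulse_path))
      missing <- paths[!file.exists(paths)]
      assert_that(length(missing) == 0,
                  "manifest references missing files: ",
                  paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  if (file.exists(clinical_path)) {
    hdr <- names(data.table::fread(clinical_path, nrows = 0))
    assert_that(hdr[1] == "patient_id", "clinical table must start with patient_id")
    m$features <- hdr[-1]
    if (nrow(rec)) {
      ids <- data.table::fread(clinical_path, select = "patient_id")$patient_id
      absent <- setdiff(rec$patient_id, as.character(ids))
      assert_that(length(absent) == 0, "patients absent from clinical table: ",
                  paste(utils::head(absent, 5), collapse = ", "))
    }
  }
  m
}

#' Write a cohort manifest CSV
#'
#' Inverse of [read_manifest()]: `read_manifest(write_manifest(m, p))` equals
#' `m` up to the resolved root directory.
#'
#' @param manifest a `cohort_manifest`.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  assert_that(inherits(manifest, "cohort_manifest"), "not a cohort_manifest")
  dir <- dirname(path)
  assert_that(dir.exists(dir), "target directory does not exist: ", dir)
  rec <- manifest$records
  if (nrow(rec) == 0) rec <- rec[, MANIFEST_COLS, drop = FALSE]
  data.table::fwrite(rec, path)
  invisible(path)
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat("Cohort manifest:", nrow(x$records), "patients\n")
  if (nrow(x$records)) {
    cat("  splits:", paste(sprintf("%s=%d", names(table(x$records$split)),
                                   table(x$records$split)), collapse = ", "), "\n")
    cat("  prevalence of label 1:",
        round(mean(x$records$label == 1), 3), "\n")
  }
  cat("  clinical features:", length(x$features), "\n")
  invisible(x)
}

read_clinical_table <- function(manifest) {
  assert_that(file.exists(manifest$clinical_table_path),
              "clinical table not found: ", manifest$clinical_table_path)
  tab <- as.data.frame(data.table::fread(manifest$clinical_table_path,
                                         colClasses = list(character = "patient_id")))
  rownames(tab) <- tab$patient_id
  tab <- tab[, -1, drop = FALSE]
  bad <- which(!stats::complete.cases(tab))
  if (length(bad)) {
    feat <- names(tab)[which(is.na(tab[bad[1], ]))[1]]
    stop_cadfuse("missing clinical value for patient ", rownames(tab)[bad[1]],
                 ", feature ", feat)
  }
  tab
}

#' Load one patient's multimodal record
#'
#' Decodes both images (resized to `image_size` with bilinear interpolation,
#' RGB, 0-255), parses the pulse CSV (`time_s,pressure`) into a
#' [pulse_recording()] and extracts the patient's clinical row in manifest
#' column order.
#'
#' @param manifest a `cohort_manifest`.
#' @param patient_id patient identifier present in the manifest.
#' @param image_size `c(H, W)` target raster size; both must be even.
#' @return A `sample_record` list: `patient_id`, `tongue_image`,
#'   `face_image`, `pulse`, `clinical` (named numeric vector), `label`,
#'   `split`.
#' @export
load_sample <- function(manifest, patient_id, image_size = c(64, 64)) {
  assert_that(inherits(manifest, "cohort_manifest"), "not a cohort_manifest")
  i <- match(patient_id, manifest$records$patient_id)
  assert_that(!is.na(i), "patient not in manifest: ", patient_id)
  assert_that(all(image_size %% 2 == 0), "image dimensions must be even")
  rec <- manifest$records[i, ]
  root <- manifest$root
  tongue <- read_image(file.path(root, rec$tongue_path), size = image_size)
  face <- read_image(file.path(root, rec$face_path), size = image_size)
  pulse <- read_pulse_csv(file.path(root, rec$pulse_path))
  clin <- numeric(0)
  if (length(manifest$features)) {
    tab <- read_clinical_table(manifest)
    clin <- as.numeric(tab[patient_id, manifest$features])
    names(clin) <- manifest$features
  }
  structure(list(patient_id = patient_id, tongue_image = tongue,
                 face_image = face, pulse = pulse, clinical = clin,
                 label = rec$label, split = rec$split),
            class = "sample_record")
}

#' Read a pulse pressure CSV (`time_s,pressure`)
#'
#' @param path CSV file with header `time_s,pressure`, `.` decimal separator.
#' @return a [pulse_recording()].
#' @export
read_pulse_csv <- function(path) {
  assert_that(file.exists(path), "pulse file not found: ", path)
  d <- data.table::fread(path)
  assert_that(identical(names(d), c("time_s", "pressure")),
              "pulse CSV header must be time_s,pressure")
  dt <- diff(d$time_s)
  assert_that(all(dt > 0), "pulse time column must be strictly increasing")
  assert_that(diff(range(dt)) < 1e-6, "pulse sampling must be uniform")
  pulse_recording(d$pressure, sampling_interval = dt[1])
}

write_pulse_csv <- function(rec, path) {
  t <- seq(0, by = rec$sampling_interval, length.out = length(rec$pressure))
  data.table::fwrite(data.frame(time_s = round(t, 6),
                                pressure = signif(rec$pressure, 8)), path)
  invisible(path)
}
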