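# File interfaces: NIfTI volumes, CSV tables for lesion features, tracks,
# design matrices and cohort manifests.

#' Write / read a patient scan as NIfTI volumes
#'
#' Writes three NIfTI files under `prefix`: `<prefix>_pet.nii.gz` (float32,
#' SUV), `<prefix>_lesions.nii.gz` and `<prefix>_organs.nii.gz` (int16
#' labels), all carrying the voxel spacing in their headers.
#'
#' @param scan A [patient_scan()].
#' @param prefix Output path prefix.
#' @return `write_scan`: the prefix, invisibly. `read_scan`: a
#'   `patient_scan`.
#' @export
write_scan <- function(scan, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input/output")
  }
  img <- function(a) {
    x <- RNifti::asNifti(a)
    RNifti::pixdim(x) <- scan$spacing
    x
  }
  RNifti::writeNifti(img(scan$pet), paste0(prefix, "_pet.nii.gz"),
                     datatype = "float")
  RNifti::writeNifti(img(scan$lesion_labels), paste0(prefix, "_lesions.nii.gz"),
                     datatype = "int16")
  RNifti::writeNifti(img(scan$organ_labels), paste0(prefix, "_organs.nii.gz"),
                     datatype = "int16")
  invisible(prefix)
}

#' @rdname write_scan
#' @param organ_codes Organ code mapping for the reconstructed scan.
#' @export
read_scan <- function(prefix, organ_codes = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input/output")
  }
  pet <- RNifti::readNifti(paste0(prefix, "_pet.nii.gz"))
  les <- RNifti::readNifti(paste0(prefix, "_lesions.nii.gz"))
  org <- RNifti::readNifti(paste0(prefix, "_organs.nii.gz"))
  spacing <- RNifti::pixdim(pet)[1:3]
  patient_scan(array(as.numeric(pet), dim = dim(pet)),
               array(as.integer(les), dim = dim(les)),
               array(as.integer(org), dim = dim(org)),
               spacing,
               organ_codes %||% organ_atlas(dim(pet), spacing)$codes)
}

#' Write cohort tables as CSV
#'
#' Writes, under `dir`: `manifest.csv` (patient id, lesion counts,
#' heterogeneity flag), `survival.csv`, `ground_truth.csv` (per-lesion
#' assigned categories), `assessments.csv` (criterion ordinals), and
#' per-patient lesion feature and track tables
#' (`patient<i>_{baseline,followup,tracks}.csv`).
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @param scans Also write every scan as NIfTI (`FALSE` by default).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, scans = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    patient = seq_len(cohort$n),
    n_lesions_baseline = vapply(cohort$patients, function(p) nrow(p$lesions_bl), integer(1)),
    n_lesions_followup = vapply(cohort$patients, function(p) nrow(p$lesions_fu), integer(1)),
    heterogeneous = vapply(cohort$patients, function(p) is_heterogeneous(p$tracks), logical(1)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"), row.names = FALSE)
  truth <- do.call(rbind, lapply(seq_len(cohort$n), function(i) {
    df <- cohort$patients[[i]]$truth$categories_df
    if (nrow(df)) cbind(patient = i, df) else NULL
  }))
  utils::write.csv(truth %||% data.frame(), file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(patient = seq_len(cohort$n), cohort$assessments),
                   file.path(dir, "assessments.csv"), row.names = FALSE)
  for (i in seq_len(cohort$n)) {
    p <- cohort$patients[[i]]
    utils::write.csv(p$lesions_bl, file.path(dir, sprintf("patient%03d_baseline.csv", i)),
                     row.names = FALSE)
    utils::write.csv(p$lesions_fu, file.path(dir, sprintf("patient%03d_followup.csv", i)),
                     row.names = FALSE)
    utils::write.csv(p$tracks, file.path(dir, sprintf("patient%03d_tracks.csv", i)),
                     row.names = FALSE)
    if (scans) {
      sc <- patient_scans(cohort, i)
      write_scan(sc$baseline, file.path(dir, sprintf("patient%03d_bl", i)))
      write_scan(sc$followup, file.path(dir, sprintf("patient%03d_fu", i)))
    }
  }
  invisible(dir)
}

#' Write a design matrix with its group-tag sidecar
#'
#' @param design Output of [assemble_design_matrix()].
#' @param path CSV path; a `.json` sidecar with per-column group tags is
#'   written next to it when jsonlite is available.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(as.list(attr(design, "groups")), side, auto_unbox = TRUE)
  }
  invisible(path)
}
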