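# NIfTI / CSV / JSON interchange. All units are fixed at module
# boundaries (cm/s, mm, ml/min, g, bpm); only readers/writers live here.

#' Write a phase-contrast phantom to disk
#'
#' One 4D-shaped NIfTI per vessel and map (magnitude, positive and
#' negative encodings, stored as `[nx, ny, n_phases]`), the ground-truth
#' ROI masks, a per-vessel metadata JSON (Venc, geometry), and the
#' phantom ground truth as JSON.
#'
#' @param phantom A `pcmri_phantom` from [synthesize_pcmri()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pcmri <- function(phantom, dir) {
  stopifnot(inherits(phantom, "pcmri_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pixdim <- c(phantom$pixel_spacing, 1)
  for (nm in names(phantom$datasets)) {
    ds <- phantom$datasets[[nm]]
    for (map in c("magnitude", "phase_pos", "phase_neg")) {
      img <- RNifti::asNifti(ds[[map]], pixdim = pixdim)
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", nm, map)),
                         datatype = "double")
    }
    roi <- RNifti::asNifti(array(as.integer(phantom$rois[[nm]]),
                                 dim = dim(phantom$rois[[nm]])),
                           pixdim = pixdim)
    RNifti::writeNifti(roi, file.path(dir, sprintf("%s_roi.nii.gz", nm)),
                       datatype = "uint8")
    meta <- list(vessel = nm, venc = ds$venc,
                 pixel_spacing = ds$pixel_spacing,
                 slice_thickness = ds$slice_thickness,
                 n_phases = ds$n_phases)
    jsonlite::write_json(meta, file.path(dir, sprintf("%s_meta.json", nm)),
                         auto_unbox = TRUE, digits = NA)
  }
  truth <- unclass(phantom$truth)
  truth$mean_flows <- as.list(truth$mean_flows)  # keep vessel names in JSON
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one vessel's phase-contrast dataset back from disk
#'
#' @param dir Directory written by [write_pcmri()].
#' @param vessel Vessel name (`"pv"`, `"infra_ivc"`, `"supra_ivc"`).
#' @return List with `dataset` (a [pcmri_dataset()]) and `roi` (logical
#'   matrix).
#' @export
read_pcmri <- function(dir, vessel) {
  meta_path <- file.path(dir, sprintf("%s_meta.json", vessel))
  if (!file.exists(meta_path)) {
    stop(sprintf("no metadata for vessel '%s' in %s", vessel, dir), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  grab <- function(map) {
    arr <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz", vessel, map)))
    array(as.numeric(arr), dim = dim(arr))
  }
  dataset <- pcmri_dataset(
    magnitude = grab("magnitude"), phase_pos = grab("phase_pos"),
    phase_neg = grab("phase_neg"), venc = meta$venc,
    pixel_spacing = meta$pixel_spacing,
    slice_thickness = meta$slice_thickness, vessel = meta$vessel)
  roi_arr <- RNifti::readNifti(file.path(dir, sprintf("%s_roi.nii.gz", vessel)))
  roi <- matrix(as.integer(roi_arr) > 0L, nrow = dim(roi_arr)[1])
  list(dataset = dataset, roi = roi)
}

#' Write / read a flow curve as CSV
#'
#' Columns `phase_index`, `flow_ml_min`.
#'
#' @param curve A [flow_curve()] (or numeric per-phase flow vector).
#' @param path CSV path.
#' @return `write_flow_curve()`: `path`, invisibly. `read_flow_curve()`:
#'   a `flow_curve`.
#' @export
write_flow_curve <- function(curve, path) {
  q <- as.numeric(curve)
  utils::write.csv(
    data.frame(phase_index = seq_along(q), flow_ml_min = q),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_curve
#' @param vessel Vessel name to attach on read.
#' @export
read_flow_curve <- function(path, vessel = "vessel") {
  df <- utils::read.csv(path)
  stopifnot(all(c("phase_index", "flow_ml_min") %in% names(df)))
  df <- df[order(df$phase_index), ]
  structure(df$flow_ml_min, class = "flow_curve", vessel = vessel,
            n_phases = nrow(df))
}

#' Write / read a long-format cohort table as CSV
#'
#' @param table A `cohort_table` (see [synthesize_cohort()]).
#' @param path CSV path.
#' @return `write_cohort_table()`: `path`, invisibly.
#'   `read_cohort_table()`: a validated `cohort_table`.
#' @export
write_cohort_table <- function(table, path) {
  check_cohort_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cohort_table(tbl)
  class(tbl) <- c("cohort_table", "data.frame")
  tbl
}
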