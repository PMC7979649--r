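#' Construct a short-axis cine study from segmentation masks
#'
#' Holds per-slice, per-phase endocardial and epicardial binary masks with
#' the geometry needed for disc-summation volumetry. Masks, not contours,
#' are the exchange format; partial-voxel effects are accepted as
#' discretisation error. The basal boundary is whatever slices are
#' provided (apex to mitral valve orifice); no basal-slice inclusion
#' heuristic is applied.
#'
#' @param endo,epi Logical (or 0/1) arrays `[nx, ny, n_slices, n_phases]`;
#'   the endocardial mask must be contained in the epicardial mask.
#' @param pixel_spacing In-plane pixel size, mm (length 1 or 2).
#' @param slice_thickness Slice thickness, mm.
#' @param heart_rate Heart rate, bpm.
#' @param body_weight Body weight, g.
#' @return A `cine_study` object.
#' @export
cine_study <- function(endo, epi, pixel_spacing, slice_thickness,
                       heart_rate, body_weight) {
  dims <- dim(endo)
  if (is.null(dims) || length(dims) != 4L) {
    stop("masks must be [nx, ny, n_slices, n_phases] arrays", call. = FALSE)
  }
  if (!identical(dim(epi), dims)) {
    stop("endocardial and epicardial masks must have identical dimensions",
         call. = FALSE)
  }
  endo <- array(as.logical(endo), dims)
  epi <- array(as.logical(epi), dims)
  if (anyNA(endo) || anyNA(epi)) {
    stop("masks contain missing values: a slice/phase is absent", call. = FALSE)
  }
  if (any(endo & !epi)) {
    stop("endocardial mask extends outside the epicardial mask", call. = FALSE)
  }
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stop("`pixel_spacing` must be > 0 mm", call. = FALSE)
  if (slice_thickness <= 0) stop("`slice_thickness` must be > 0 mm", call. = FALSE)
  if (heart_rate <= 0) stop("`heart_rate` must be > 0 bpm", call. = FALSE)
  if (body_weight <= 0) stop("`body_weight` must be > 0 g", call. = FALSE)
  structure(
    list(endo = endo, epi = epi, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, heart_rate = heart_rate,
         body_weight = body_weight,
         n_slices = dims[3], n_phases = dims[4]),
    class = "cine_study"
  )
}

#' @export
print.cine_study <- function(x, ...) {
  cat(sprintf(
    "<cine_study> %d slices x %d phases, %.3f x %.3f mm pixels, %g mm slices, HR %g bpm\n",
    x$n_slices, x$n_phases, x$pixel_spacing[1], x$pixel_spacing[2],
    x$slice_thickness, x$heart_rate))
  invisible(x)
}

#' Left-ventricular volume-time curve by the method of discs
#'
#' Per cardiac phase, sums the segmented area of every short-axis slice
#' times the slice thickness: `V = sum_slices area(cm^2) * thickness(cm)`,
#' in ml.
#'
#' @param study A [cine_study()].
#' @param surface `"endocardial"` (cavity) or `"epicardial"` (cavity +
#'   myocardium).
#' @return Numeric vector of per-phase volumes, ml.
#' @export
volume_curve <- function(study, surface = c("endocardial", "epicardial")) {
  stopifnot(inherits(study, "cine_study"))
  surface <- match.arg(surface)
  mask <- if (surface == "endocardial") study$endo else study$epi
  px_area_cm2 <- prod(study$pixel_spacing / 10)
  t_cm <- study$slice_thickness / 10
  vapply(seq_len(study$n_phases), function(ph) {
    sum(mask[, , , ph]) * px_area_cm2 * t_cm
  }, 0)
}

#' Left-ventricular systolic function parameters
#'
#' End-diastole and end-systole are the maximum and minimum of the
#' endocardial volume curve (not fixed phase indices). Stroke volume is
#' their difference, cardiac output SV x heart rate, ejection fraction
#' 100 SV / EDV, and LV mass the myocardial volume at the end-diastolic
#' phase (epicardial minus endocardial) times the myocardial density
#' 1.05 g/cm^3. Cardiac index and LV mass index divide by body weight in
#' kg.
#'
#' @param endo_curve,epi_curve Per-phase endocardial and epicardial
#'   volumes, ml (same length >= 2), e.g. from [volume_curve()].
#' @param heart_rate Heart rate, bpm.
#' @param body_weight Body weight, g (> 0).
#' @return One-row data frame (class `cardiac_function`) with `edv`, `esv`,
#'   `sv` (ml), `heart_rate` (bpm), `co` (ml/min), `ef` (%), `lv_mass` (g),
#'   `cardiac_index` (ml/min/kg), `lv_mass_index` (g/kg).
#' @examples
#' systolic_parameters(c(0.8, 0.4), c(1.6, 1.2), heart_rate = 300,
#'                     body_weight = 500)
#' @export
systolic_parameters <- function(endo_curve, epi_curve, heart_rate,
                                body_weight) {
  endo_curve <- as.numeric(endo_curve); epi_curve <- as.numeric(epi_curve)
  if (length(endo_curve) != length(epi_curve) || length(endo_curve) < 2L) {
    stop("volume curves must have the same length >= 2", call. = FALSE)
  }
  if (!all(is.finite(endo_curve)) || !all(is.finite(epi_curve))) {
    stop("volume curves must be finite", call. = FALSE)
  }
  stop_if_not_scalar_number(heart_rate, "heart_rate")
  stop_if_not_scalar_number(body_weight, "body_weight")
  if (body_weight <= 0) stop("`body_weight` must be > 0 g", call. = FALSE)

  ed_phase <- which.max(endo_curve)
  edv <- endo_curve[ed_phase]
  esv <- min(endo_curve)
  if (edv == 0) stop("EDV is zero: ejection fraction undefined", call. = FALSE)
  sv <- edv - esv
  co <- sv * heart_rate
  bw_kg <- body_weight / 1000
  lv_mass <- (epi_curve[ed_phase] - endo_curve[ed_phase]) * 1.05
  out <- data.frame(
    edv = edv, esv = esv, sv = sv, heart_rate = heart_rate, co = co,
    ef = 100 * sv / edv, lv_mass = lv_mass,
    cardiac_index = co / bw_kg, lv_mass_index = lv_mass / bw_kg,
    ed_phase = ed_phase
  )
  class(out) <- c("cardiac_function", "data.frame")
  out
}
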