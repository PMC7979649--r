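#' Specify a left-ventricular cine phantom
#'
#' Describes a truncated-ellipsoid left ventricle for the short-axis cine
#' phantom: a half-ellipsoid cavity whose disc-summed volume interpolates
#' between EDV (phase 0) and ESV (mid-cycle), wrapped in a myocardial
#' shell of constant volume.
#'
#' @param edv End-diastolic cavity volume, ml.
#' @param esv End-systolic cavity volume, ml; `0 < esv <= edv`
#'   (`esv == edv` gives a static heart with SV = EF = 0).
#' @param wall_volume Myocardial shell volume, ml. The default 0.857 ml
#'   corresponds to a 0.90 g LV at myocardial density 1.05 g/cm^3.
#' @param n_slices Number of contiguous short-axis slices covering apex to
#'   base.
#' @param slice_thickness Slice thickness, mm. Rodent protocol: 2 mm.
#' @param n_phases Cardiac phases (>= 2).
#' @param heart_rate Heart rate, bpm.
#' @param body_weight Body weight, g (for cardiac index and LV mass index).
#' @return An `lv_phantom_spec` object.
#' @export
lv_phantom_spec <- function(edv = 0.66, esv = 0.25, wall_volume = 0.857,
                            n_slices = 6L, slice_thickness = 2,
                            n_phases = 20L, heart_rate = 333,
                            body_weight = 470) {
  for (nm in c("edv", "esv", "wall_volume", "slice_thickness",
               "heart_rate", "body_weight")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (esv <= 0) stop("`esv` must be > 0 ml", call. = FALSE)
  if (esv > edv) stop("`esv` must be <= `edv`", call. = FALSE)
  if (wall_volume <= 0) stop("`wall_volume` must be > 0 ml", call. = FALSE)
  n_slices <- as.integer(n_slices); n_phases <- as.integer(n_phases)
  if (is.na(n_slices) || n_slices < 2L) stop("`n_slices` must be >= 2", call. = FALSE)
  if (is.na(n_phases) || n_phases < 2L) stop("`n_phases` must be >= 2", call. = FALSE)
  if (slice_thickness <= 0) stop("`slice_thickness` must be > 0 mm", call. = FALSE)
  if (heart_rate <= 0) stop("`heart_rate` must be > 0 bpm", call. = FALSE)
  if (body_weight <= 0) stop("`body_weight` must be > 0 g", call. = FALSE)
  structure(
    list(edv = edv, esv = esv, wall_volume = wall_volume,
         n_slices = n_slices, slice_thickness = slice_thickness,
         n_phases = n_phases, heart_rate = heart_rate,
         body_weight = body_weight),
    class = "lv_phantom_spec"
  )
}

# Squared in-plane cavity radius (mm^2) of a half-ellipsoid of volume V_ml
# and long axis L_mm at distance z_mm from the base:
# V = (2/3) pi R^2 L  =>  R^2 = 3 V / (2 pi L); r(z)^2 = R^2 (1 - (z/L)^2).
ellipsoid_r2 <- function(V_ml, L_mm, z_mm) {
  R2 <- 3 * (V_ml * 1000) / (2 * pi * L_mm)
  pmax(R2 * (1 - (z_mm / L_mm)^2), 0)
}

#' Analytic disc-summation reference volume of the cine phantom
#'
#' The volume the method of discs would report for the continuous
#' half-ellipsoid at the phantom's own slice sampling (slice centres,
#' exact circle areas): `sum_s pi r(z_s)^2 * t`. Pixelated mask volumes
#' converge to this reference as in-plane resolution increases; the
#' residual difference from the prescribed volume is the through-plane
#' discretisation bias.
#'
#' @param V_ml Cavity (or cavity + wall) volume, ml.
#' @param n_slices,slice_thickness Slice geometry (count, mm).
#' @return Disc-summed reference volume, ml.
#' @export
disc_reference_volume <- function(V_ml, n_slices, slice_thickness) {
  L <- n_slices * slice_thickness
  z <- (seq_len(n_slices) - 0.5) * slice_thickness
  sum(pi * ellipsoid_r2(V_ml, L, z)) * slice_thickness / 1000
}

#' Synthesize a short-axis cine study with known ground truth
#'
#' Builds per-slice, per-phase endocardial and epicardial binary masks of
#' a truncated-ellipsoid left ventricle. The cavity volume follows a
#' raised cosine from EDV at phase 0 to ESV at mid-cycle; the epicardial
#' surface encloses cavity + `wall_volume` at every phase, so the
#' myocardial shell volume is constant over the cycle. Pixels are in/out
#' by centre-point test. The stack spans apex to base:
#' `long axis = n_slices * slice_thickness`.
#'
#' @param spec An [lv_phantom_spec()].
#' @param pixel_spacing In-plane pixel size, mm (length 1 or 2). Rodent
#'   protocol: 0.313 x 0.625 mm.
#' @param matrix_size Image matrix (length 1 or 2); must contain the
#'   epicardial base.
#' @param seed Unused (the cine phantom is deterministic); accepted for
#'   interface symmetry with the other generators.
#' @return A list with `study` (a [cine_study()]) and `truth`
#'   (prescribed EDV/ESV/SV/EF, wall volume, per-phase cavity volumes, and
#'   the disc-summation reference volumes at this slice geometry).
#' @export
synthesize_cine <- function(spec, pixel_spacing = c(0.313, 0.625),
                            matrix_size = c(128, 64), seed = NULL) {
  stopifnot(inherits(spec, "lv_phantom_spec"))
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  matrix_size <- rep_len(as.integer(matrix_size), 2L)
  if (any(pixel_spacing <= 0)) stop("`pixel_spacing` must be > 0 mm", call. = FALSE)

  L <- spec$n_slices * spec$slice_thickness
  k <- seq_len(spec$n_phases) - 1L
  cavity <- spec$esv + (spec$edv - spec$esv) *
    (1 + cos(2 * pi * k / spec$n_phases)) / 2
  epi_vol <- cavity + spec$wall_volume

  # infeasible when the end-systolic basal radius is below one pixel
  r_es <- sqrt(ellipsoid_r2(spec$esv, L, 0))
  if (r_es < max(pixel_spacing)) {
    stop(sprintf(
      "geometry infeasible: end-systolic basal radius %.2f mm is below the %.2f mm pixel size",
      r_es, max(pixel_spacing)), call. = FALSE)
  }
  r_base_max <- sqrt(ellipsoid_r2(max(epi_vol), L, 0))
  half_x <- matrix_size[1] * pixel_spacing[1] / 2
  half_y <- matrix_size[2] * pixel_spacing[2] / 2
  if (r_base_max > half_x || r_base_max > half_y) {
    stop(sprintf("epicardial base (radius %.1f mm) exceeds the %g x %g mm field of view",
                 r_base_max, 2 * half_x, 2 * half_y), call. = FALSE)
  }

  nx <- matrix_size[1]; ny <- matrix_size[2]
  x_mm <- (seq_len(nx) - (nx + 1) / 2) * pixel_spacing[1]
  y_mm <- (seq_len(ny) - (ny + 1) / 2) * pixel_spacing[2]
  d2 <- outer(x_mm^2, y_mm^2, `+`)
  z <- (seq_len(spec$n_slices) - 0.5) * spec$slice_thickness  # base -> apex

  endo <- array(FALSE, dim = c(nx, ny, spec$n_slices, spec$n_phases))
  epi <- array(FALSE, dim = c(nx, ny, spec$n_slices, spec$n_phases))
  for (ph in seq_len(spec$n_phases)) {
    for (s in seq_len(spec$n_slices)) {
      endo[, , s, ph] <- d2 < ellipsoid_r2(cavity[ph], L, z[s])
      epi[, , s, ph] <- d2 < ellipsoid_r2(epi_vol[ph], L, z[s])
    }
  }

  study <- cine_study(endo = endo, epi = epi, pixel_spacing = pixel_spacing,
                      slice_thickness = spec$slice_thickness,
                      heart_rate = spec$heart_rate,
                      body_weight = spec$body_weight)
  truth <- list(
    edv = spec$edv, esv = spec$esv, sv = spec$edv - spec$esv,
    ef = 100 * (spec$edv - spec$esv) / spec$edv,
    wall_volume = spec$wall_volume,
    lv_mass = spec$wall_volume * 1.05,
    cavity_ml = cavity, epi_ml = epi_vol,
    endo_disc_ml = vapply(cavity, disc_reference_volume, 0,
                          n_slices = spec$n_slices,
                          slice_thickness = spec$slice_thickness),
    epi_disc_ml = vapply(epi_vol, disc_reference_volume, 0,
                         n_slices = spec$n_slices,
                         slice_thickness = spec$slice_thickness),
    heart_rate = spec$heart_rate, body_weight = spec$body_weight
  )
  list(study = study, truth = truth)
}
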