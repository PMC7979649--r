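#' Construct a phase-contrast MRI dataset for one vessel plane
#'
#' Bundles the per-cardiac-phase magnitude image and the pair of phase maps
#' acquired with opposite flow-encoding gradients, together with the
#' acquisition geometry needed to convert decoded velocities into bulk
#' flow. Phase values must already be in the principal interval
#' `(-pi, pi]` (see [wrap_phase()]).
#'
#' @param magnitude,phase_pos,phase_neg Numeric arrays `[nx, ny, n_phases]`;
#'   the two phase arrays hold the opposite-encoded phase maps in radians.
#' @param venc Velocity-encoding limit, cm/s.
#' @param pixel_spacing In-plane pixel size, mm (length 1 or 2).
#' @param slice_thickness Slice thickness, mm (metadata).
#' @param vessel Vessel name carried through to flow curves.
#' @return A `pcmri_dataset` object.
#' @export
pcmri_dataset <- function(magnitude, phase_pos, phase_neg, venc,
                          pixel_spacing, slice_thickness = 2,
                          vessel = "vessel") {
  dims <- dim(phase_pos)
  if (is.null(dims) || length(dims) != 3L) {
    stop("phase maps must be [nx, ny, n_phases] arrays", call. = FALSE)
  }
  if (!identical(dim(phase_neg), dims) || !identical(dim(magnitude), dims)) {
    stop("magnitude, phase_pos and phase_neg must have identical dimensions",
         call. = FALSE)
  }
  for (nm in c("phase_pos", "phase_neg")) {
    ph <- get(nm)
    if (any(ph <= -pi - 1e-9) || any(ph > pi + 1e-9)) {
      stop(sprintf("`%s` contains values outside (-pi, pi]; wrap_phase() first", nm),
           call. = FALSE)
    }
  }
  stop_if_not_scalar_number(venc, "venc")
  if (venc <= 0) stop("`venc` must be > 0 cm/s", call. = FALSE)
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stop("`pixel_spacing` must be > 0 mm", call. = FALSE)
  if (slice_thickness <= 0) stop("`slice_thickness` must be > 0 mm", call. = FALSE)
  structure(
    list(magnitude = magnitude, phase_pos = phase_pos, phase_neg = phase_neg,
         venc = venc, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, vessel = as.character(vessel),
         n_phases = dims[3]),
    class = "pcmri_dataset"
  )
}

#' @export
print.pcmri_dataset <- function(x, ...) {
  d <- dim(x$phase_pos)
  cat(sprintf(
    "<pcmri_dataset> vessel '%s': %d x %d pixels (%.3f x %.3f mm), %d cardiac phases, Venc %g cm/s\n",
    x$vessel, d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2],
    x$n_phases, x$venc))
  invisible(x)
}

#' Decode a through-plane velocity map from an opposite-encoded phase pair
#'
#' Subtracting the two encodings cancels any background phase common to
#' both (eddy currents, field inhomogeneity) and doubles the flow-encoded
#' phase. With the convention `phi = +/- pi v / venc` per encoding, the
#' half-difference wrapped into `(-pi, pi]` and scaled by `venc / pi`
#' recovers `v` exactly for `|v| < venc`; at the aliasing boundary
#' `|v| = venc` the sign is ambiguous and the map is flagged with a
#' warning (no unwrapping is attempted).
#'
#' @param dataset A [pcmri_dataset()].
#' @param phase_index Cardiac phase to decode (1-based).
#' @return Velocity map, cm/s, matrix `[nx, ny]`, with `|v| <= venc`.
#' @examples
#' # phase pair +pi/2 / -pi/2 at Venc 33 decodes to 16.5 cm/s
#' @export
decode_velocity <- function(dataset, phase_index) {
  stopifnot(inherits(dataset, "pcmri_dataset"))
  phase_index <- as.integer(phase_index)
  if (is.na(phase_index) || phase_index < 1L || phase_index > dataset$n_phases) {
    stop(sprintf("`phase_index` must be in 1..%d", dataset$n_phases), call. = FALSE)
  }
  half_diff <- wrap_phase(
    (dataset$phase_pos[, , phase_index] - dataset$phase_neg[, , phase_index]) / 2)
  v <- half_diff * dataset$venc / pi
  if (any(abs(abs(half_diff) - pi) < 1e-12)) {
    warning(sprintf(
      "vessel '%s', phase %d: velocity at the aliasing boundary (|v| = Venc); sign is ambiguous",
      dataset$vessel, phase_index), call. = FALSE)
  }
  v
}

#' Integrate ROI flow over the cardiac cycle
#'
#' For each cardiac phase, decodes the velocity map and sums
#' `v * pixel area` over the region of interest, converting to ml/min
#' (cm/s x cm^2 x 60). Positive flow is the through-plane direction of the
#' positive encoding; orient the ROI so physiological flow is positive.
#'
#' @param dataset A [pcmri_dataset()].
#' @param roi Logical matrix congruent with the image grid; `TRUE` marks
#'   vessel pixels. Must be non-empty; an ROI touching the image border
#'   triggers a warning (the vessel may be clipped).
#' @return A `flow_curve`: numeric vector of per-phase flow in ml/min with
#'   attributes `vessel` and `n_phases`.
#' @export
flow_curve <- function(dataset, roi) {
  stopifnot(inherits(dataset, "pcmri_dataset"))
  dims <- dim(dataset$phase_pos)
  if (is.logical(roi) && is.null(dim(roi))) roi <- matrix(roi, dims[1], dims[2])
  if (!is.logical(roi) || !identical(dim(roi), dims[1:2])) {
    stop("`roi` must be a logical matrix congruent with the image grid", call. = FALSE)
  }
  if (!any(roi)) stop("empty ROI: no pixels selected", call. = FALSE)
  if (any(roi[1, ]) || any(roi[dims[1], ]) || any(roi[, 1]) || any(roi[, dims[2]])) {
    warning("ROI touches the image border; the vessel may be clipped", call. = FALSE)
  }
  px_area_cm2 <- prod(dataset$pixel_spacing / 10)
  q <- vapply(seq_len(dataset$n_phases), function(k) {
    v <- decode_velocity(dataset, k)
    sum(v[roi]) * px_area_cm2 * 60
  }, 0)
  structure(q, class = "flow_curve", vessel = dataset$vessel,
            n_phases = dataset$n_phases)
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> vessel '%s', %d cardiac phases, mean %.2f ml/min\n",
              attr(x, "vessel"), attr(x, "n_phases"), mean(unclass(x))))
  print(round(as.numeric(x), 3))
  invisible(x)
}

#' Cycle-mean flow of a vessel
#'
#' Bulk vessel flow is taken as constant over the cardiac cycle for caval
#' subtraction: the unweighted arithmetic mean of the per-phase flow
#' samples (uniform prospective-gating sampling assumed).
#'
#' @param curve A [flow_curve()] or plain numeric vector of per-phase flow
#'   values, ml/min.
#' @return Mean flow, ml/min.
#' @export
mean_flow <- function(curve) {
  q <- as.numeric(curve)
  if (length(q) == 0L) stop("empty flow curve", call. = FALSE)
  if (!all(is.finite(q))) stop("flow curve contains non-finite values", call. = FALSE)
  mean(q)
}
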