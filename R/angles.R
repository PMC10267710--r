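# The bone-centered coordinate system and the two angle measurements.
#
# The frame is anchored at the distal tibial shaft center (DTC). Its third
# axis ez is the total tibial longitudinal axis DTC -> PTC; its second axis
# ey is the proximal caudal retrocondylar direction (medial -> lateral)
# orthogonalized against ez, so the dorsal plane keeps the retrocondylar
# orientation while the system stays orthogonal; ex = ey x ez completes a
# right-handed frame for both sides. The transverse plane has normal ez,
# the dorsal plane normal ex, the sagittal plane normal ey.
#
# Readout convention: 180 deg = neutral. Torsion readouts above 180 denote
# external rotation of the distal antecochlear axis, below 180 internal
# rotation; varus/valgus readouts above 180 denote valgus (lateral deviation
# of the distal longitudinal axis), below 180 varus. Side handling: the
# torsion sign flips with the bone side (an external twist is a mirrored
# rotation on the left), while the dorsal-plane normal ex flips orientation
# automatically under mirroring (a cross product is a pseudovector), so the
# valgus sign needs no explicit side term. Mirror consistency is covered by
# property tests.

.side_sign <- function(side) if (identical(side, "left")) -1 else 1

# Half the 0.1 deg table-reporting resolution: below this the direction
# label is "neutral".
.NEUTRAL_TOL <- 0.05

#' Build the bone-centered coordinate system from a landmark set
#'
#' @param lms A [tibia_landmarks()] set containing at least the six torsion
#'   landmarks.
#' @return A `bone_frame` object: `origin` (= DTC), unit axes `ex`, `ey`
#'   (medial to lateral), `ez` (distal to proximal), and `side`. The frame is
#'   right-handed for either side.
#' @examples
#' build_bone_frame(tibia_template())
#' @export
build_bone_frame <- function(lms) {
  stopifnot(inherits(lms, "tibia_landmarks"))
  .require_landmarks(lms, c("DTC", "PTC", "TRCAx_med", "TRCAx_lat"))
  dtc <- .lm(lms, "DTC")
  long_dir <- .lm(lms, "PTC") - dtc
  retro_dir <- .lm(lms, "TRCAx_lat") - .lm(lms, "TRCAx_med")
  fr <- orthonormal_frame(long_dir, retro_dir, "right")
  structure(list(origin = dtc, ex = fr$e1, ey = fr$e2, ez = fr$e3,
                 side = lms$side),
            class = "bone_frame")
}

#' @export
print.bone_frame <- function(x, ...) {
  cat(sprintf("Bone-centered frame (%s side), origin at DTC = (%.2f, %.2f, %.2f) mm\n",
              x$side, x$origin[1], x$origin[2], x$origin[3]))
  m <- rbind(ex = x$ex, ey = x$ey, ez = x$ez)
  colnames(m) <- c("x", "y", "z")
  print(round(m, 6))
  invisible(x)
}

.angle_measurement <- function(angle_type, signed_deviation) {
  direction <- if (abs(signed_deviation) < .NEUTRAL_TOL) {
    "neutral"
  } else if (angle_type == "TTA") {
    if (signed_deviation > 0) "external" else "internal"
  } else {
    if (signed_deviation > 0) "valgus" else "varus"
  }
  structure(list(angle_type = angle_type,
                 readout = 180 + signed_deviation,
                 signed_deviation = signed_deviation,
                 direction = direction),
            class = "angle_measurement")
}

#' @export
print.angle_measurement <- function(x, ...) {
  cat(sprintf("%s: %.1f deg (%+.1f deg, %s)\n", x$angle_type, x$readout,
              x$signed_deviation, x$direction))
  invisible(x)
}

#' Tibial torsion angle (TTA)
#'
#' Projects the proximal caudal retrocondylar axis and the distal cranial
#' antecochlear axis (both stored medial to lateral) into the transverse
#' plane and measures the signed angle between the projections about the
#' longitudinal axis. The readout is 180 deg plus the signed deviation, with
#' external rotation of the distal axis positive for either side.
#'
#' @param lms A [tibia_landmarks()] set.
#' @return An `angle_measurement` with `readout`, `signed_deviation` and a
#'   direction label (`"internal"`, `"external"` or `"neutral"`).
#' @examples
#' tibial_torsion_angle(apply_torsion(tibia_template(), 25))
#' @export
tibial_torsion_angle <- function(lms) {
  frame <- build_bone_frame(lms)
  prox <- .lm(lms, "TRCAx_lat") - .lm(lms, "TRCAx_med")
  dist <- .lm(lms, "TACAx_lat") - .lm(lms, "TACAx_med")
  raw <- signed_angle_in_plane(prox, dist, frame$ez,
                               names = c("retrocondylar axis", "antecochlear axis"))
  .angle_measurement("TTA", .side_sign(lms$side) * raw)
}

#' Tibial varus/valgus angle (TVA)
#'
#' Projects the proximal (MTCC to LTCC) and distal (MTCGC to LTCGC)
#' mediolateral joint surface axes into the dorsal plane. The angle between
#' the in-plane perpendiculars to these projections (the proximal and distal
#' tibial longitudinal axes) equals the signed angle between the projections
#' themselves, which is what is computed. Lateral deviation of the distal
#' longitudinal axis (valgus) is positive; the readout is 180 plus the
#' signed deviation.
#'
#' @inheritParams tibial_torsion_angle
#' @return An `angle_measurement` with direction `"varus"`, `"valgus"` or
#'   `"neutral"`.
#' @examples
#' tibial_varus_valgus_angle(apply_frontal_angulation(tibia_template(), 3.9))
#' @export
tibial_varus_valgus_angle <- function(lms) {
  stopifnot(inherits(lms, "tibia_landmarks"))
  .require_landmarks(lms, .LANDMARKS_TVA_EXTRA)
  frame <- build_bone_frame(lms)
  prox <- .lm(lms, "LTCC") - .lm(lms, "MTCC")
  dist <- .lm(lms, "LTCGC") - .lm(lms, "MTCGC")
  signed <- signed_angle_in_plane(prox, dist, frame$ex,
                                  names = c("proximal joint surface axis",
                                            "distal joint surface axis"))
  .angle_measurement("TVA", signed)
}

#' Measure torsion and varus/valgus angles of one tibia
#'
#' Bundles [tibial_torsion_angle()] and [tibial_varus_valgus_angle()] with
#' the underlying [build_bone_frame()]; requires the full ten-landmark set.
#'
#' @inheritParams tibial_torsion_angle
#' @return A `tibia_angles` object with elements `bone_id`, `TTA`, `TVA`
#'   and `frame`.
#' @examples
#' measure_tibia(tibia_template())
#' @export
measure_tibia <- function(lms) {
  stopifnot(inherits(lms, "tibia_landmarks"))
  .require_landmarks(lms, .LANDMARKS_ALL)
  structure(list(bone_id = lms$bone_id,
                 TTA = tibial_torsion_angle(lms),
                 TVA = tibial_varus_valgus_angle(lms),
                 frame = build_bone_frame(lms)),
            class = "tibia_angles")
}

#' @export
print.tibia_angles <- function(x, ...) {
  cat(sprintf("Tibia '%s' (%s side)\n", x$bone_id, x$frame$side))
  print(x$TTA)
  print(x$TVA)
  invisible(x)
}
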