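# Parametric synthetic tibia: a landmark template in canonical pose plus the
# experimental manipulations used for validation — a mid-diaphyseal torsion
# hinge, frontal-plane angulation, rigid double-oblique repositioning, and
# Gaussian landmark placement noise.
#
# Template pose (right side): the long axis lies on +z (distal at z = 0,
# proximal at z = bone length), +y is caudal, +x is lateral; a left template
# is the exact mirror image (x negated) with unchanged landmark names. All
# mediolateral axes are parallel in the template, so it measures exactly
# 180/180. The dimensions default to a plausible medium-dog tibia, but the
# angle measurements are provably independent of them (size-invariance is a
# tested property), so no anatomical fidelity is claimed.

# Landmarks distal to the mid-diaphyseal cut; DTC lies on the torsion axis
# and is numerically unchanged by a pure torsion.
.DISTAL_LANDMARKS <- c("TACAx_med", "TACAx_lat", "LTCGC", "MTCGC", "DTC")

#' Synthetic neutral tibia landmark template
#'
#' @param bone_length Total bone length, mm.
#' @param proximal_condylar_width Mediolateral width spanned by the
#'   retrocondylar axis endpoints, mm.
#' @param distal_cochlear_width Mediolateral width spanned by the
#'   antecochlear axis endpoints, mm.
#' @param retrocondylar_offset Caudal offset of the retrocondylar axis from
#'   the shaft axis, mm.
#' @param antecochlear_offset Cranial offset of the antecochlear axis, mm.
#' @param shaft_center_levels Fractions of bone length locating DTC and PTC
#'   (must satisfy 0 < DTC level < PTC level < 1).
#' @param side `"right"` or `"left"`; the left template is the mirror image.
#' @param bone_id Identifier stored in the set.
#' @return A [tibia_landmarks()] set measuring exactly 180/180.
#' @examples
#' measure_tibia(tibia_template())
#' @export
tibia_template <- function(bone_length = 180,
                           proximal_condylar_width = 32,
                           distal_cochlear_width = 20,
                           retrocondylar_offset = 12,
                           antecochlear_offset = 8,
                           shaft_center_levels = c(0.25, 0.75),
                           side = c("right", "left"),
                           bone_id = NULL) {
  side <- match.arg(side)
  lens <- c(bone_length, proximal_condylar_width, distal_cochlear_width,
            retrocondylar_offset, antecochlear_offset)
  if (!all(is.finite(lens)) || any(lens <= 0)) {
    .stop_validation("all template dimensions must be positive and finite")
  }
  lv <- shaft_center_levels
  if (length(lv) != 2L || !(0 < lv[1L] && lv[1L] < lv[2L] && lv[2L] < 1)) {
    .stop_validation("shaft_center_levels must satisfy 0 < DTC level < PTC level < 1")
  }
  L <- bone_length
  wp <- proximal_condylar_width / 2
  wd <- distal_cochlear_width / 2
  lat <- if (side == "right") 1 else -1  # +x is lateral on the right template
  lms <- list(
    TRCAx_med = c(-lat * wp, retrocondylar_offset, 0.95 * L),
    TRCAx_lat = c(lat * wp, retrocondylar_offset, 0.95 * L),
    TACAx_med = c(-lat * wd, -antecochlear_offset, 0.03 * L),
    TACAx_lat = c(lat * wd, -antecochlear_offset, 0.03 * L),
    DTC = c(0, 0, lv[1L] * L),
    PTC = c(0, 0, lv[2L] * L),
    LTCC = c(lat * 0.8 * wp, 0, L),
    MTCC = c(-lat * 0.8 * wp, 0, L),
    LTCGC = c(lat * 0.8 * wd, 0, 0),
    MTCGC = c(-lat * 0.8 * wd, 0, 0)
  )
  tibia_landmarks(lms, side = side,
                  bone_id = if (is.null(bone_id)) paste0("template_", side) else bone_id,
                  coordinate_frame = "LPS")
}

.replace_landmarks <- function(lms, new_coords) {
  out <- lms
  out$landmarks <- new_coords
  out
}

.check_hinge <- function(hinge_level) {
  if (!is.numeric(hinge_level) || length(hinge_level) != 1L ||
      !is.finite(hinge_level) || hinge_level <= 0 || hinge_level >= 1) {
    .stop_validation("hinge_level must lie strictly between 0 (DTC) and 1 (PTC)")
  }
  hinge_level
}

#' Apply a diaphyseal torsion to a landmark set
#'
#' Rotates every landmark distal to the mid-diaphyseal hinge (the
#' antecochlear axis endpoints, the cochlear groove centers, and DTC, which
#' lies on the axis and is unchanged) about the DTC-to-PTC line. Positive
#' `theta_deg` produces external torsion for the set's side.
#'
#' @param lms A [tibia_landmarks()] set.
#' @param theta_deg Torsion angle in degrees, external positive.
#' @param hinge_level Hinge position as a fraction along the DTC-to-PTC
#'   segment (default 0.5, the mid-diaphyseal cut); immaterial for torsion
#'   since the rotation axis is the whole shaft line, kept for interface
#'   symmetry with [apply_frontal_angulation()].
#' @return The deformed landmark set.
#' @export
apply_torsion <- function(lms, theta_deg, hinge_level = 0.5) {
  stopifnot(inherits(lms, "tibia_landmarks"))
  .check_hinge(hinge_level)
  if (theta_deg == 0) return(lms)
  frame <- build_bone_frame(lms)
  angle <- .side_sign(lms$side) * theta_deg
  coords <- lms$landmarks
  for (nm in intersect(.DISTAL_LANDMARKS, rownames(coords))) {
    coords[nm, ] <- rotate_about_axis(coords[nm, ], frame$origin, frame$ez, angle)
  }
  .replace_landmarks(lms, coords)
}

#' Apply a frontal-plane (varus/valgus) angulation to a landmark set
#'
#' Rotates the distal landmarks about the craniocaudal axis (the
#' dorsal-plane normal) through the hinge point on the shaft line. Positive
#' `phi_deg` deviates the distal segment laterally (valgus) for the set's
#' side.
#'
#' @inheritParams apply_torsion
#' @param phi_deg Angulation in degrees, valgus (lateral) positive.
#' @param hinge_level Hinge position as a fraction along the DTC-to-PTC
#'   segment (default 0.5).
#' @return The deformed landmark set.
#' @export
apply_frontal_angulation <- function(lms, phi_deg, hinge_level = 0.5) {
  stopifnot(inherits(lms, "tibia_landmarks"))
  .check_hinge(hinge_level)
  if (phi_deg == 0) return(lms)
  frame <- build_bone_frame(lms)
  hinge <- frame$origin + hinge_level * (.lm(lms, "PTC") - frame$origin)
  coords <- lms$landmarks
  for (nm in intersect(.DISTAL_LANDMARKS, rownames(coords))) {
    coords[nm, ] <- rotate_about_axis(coords[nm, ], hinge, frame$ex, phi_deg)
  }
  .replace_landmarks(lms, coords)
}

#' Rigidly reposition a landmark set (scanner-pose simulation)
#'
#' Whole-set rigid motion emulating bone positioning on the scanner table:
#' rotation about the set centroid applied as x-tilt, then y-tilt, then
#' axial (z) spin, followed by a translation. The presets `"oblique15"` and
#' `"oblique45"` reproduce double-oblique poses deviating 15 or 45 degrees
#' towards both the x- and y-axes.
#'
#' @inheritParams apply_torsion
#' @param tilt_x_deg,tilt_y_deg,spin_deg Rotation angles in degrees.
#' @param translation Numeric length-3 translation, mm.
#' @param preset Optional `"oblique15"` or `"oblique45"`, overriding the
#'   tilt angles.
#' @return The repositioned landmark set.
#' @examples
#' posed <- apply_rigid_pose(tibia_template(), preset = "oblique45")
#' @export
apply_rigid_pose <- function(lms, tilt_x_deg = 0, tilt_y_deg = 0, spin_deg = 0,
                             translation = c(0, 0, 0), preset = NULL) {
  stopifnot(inherits(lms, "tibia_landmarks"))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("oblique15", "oblique45"))
    tilt <- if (preset == "oblique15") 15 else 45
    tilt_x_deg <- tilt
    tilt_y_deg <- tilt
    spin_deg <- 0
  }
  translation <- .check_vec3(translation, "translation")
  R <- .rotation_matrix(c(0, 0, 1), spin_deg) %*%
    .rotation_matrix(c(0, 1, 0), tilt_y_deg) %*%
    .rotation_matrix(c(1, 0, 0), tilt_x_deg)
  coords <- lms$landmarks
  pivot <- colMeans(coords)
  rotated <- sweep(coords, 2L, pivot) %*% t(R)
  rotated <- sweep(rotated, 2L, pivot + translation, `+`)
  dimnames(rotated) <- dimnames(coords)
  .replace_landmarks(lms, rotated)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add Gaussian landmark placement noise
#'
#' Displaces every landmark independently by an isotropic zero-mean Gaussian
#' offset with standard deviation `sigma_mm` per coordinate, emulating
#' observer variability in reference point placement.
#'
#' @inheritParams apply_torsion
#' @param sigma_mm Noise standard deviation per coordinate, mm (>= 0).
#' @param seed Optional integer seed; with a seed the result is
#'   deterministic and the caller's RNG state is left untouched.
#' @return The jittered landmark set.
#' @export
jitter_landmarks <- function(lms, sigma_mm, seed = NULL) {
  stopifnot(inherits(lms, "tibia_landmarks"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || !is.finite(sigma_mm) ||
      sigma_mm < 0) {
    .stop_validation("sigma_mm must be a single non-negative number")
  }
  if (sigma_mm == 0) return(lms)
  coords <- lms$landmarks
  noise <- .with_seed(seed, matrix(stats::rnorm(length(coords), 0, sigma_mm),
                                   nrow = nrow(coords)))
  .replace_landmarks(lms, coords + noise)
}

#' Simulate a torsion-deformity measurement study
#'
#' For each preset torsion angle and replicate, deforms the template with
#' [apply_torsion()], optionally jitters the landmarks, measures the torsion
#' angle, and collects the readouts in a long-format measurement table
#' together with a ground-truth manifest (true readout = 180 + preset).
#'
#' @param presets Numeric vector of preset torsion angles in degrees
#'   (external positive); the torsion-model design uses
#'   `c(0, -10, 10, ..., -50, 50, -90, 90)`.
#' @param sigma_mm Landmark noise standard deviation, mm (0 = noise-free).
#' @param replicates Replicate measurements per preset.
#' @param seed Optional integer seed controlling all noise draws.
#' @param template Baseline landmark set (default [tibia_template()]).
#' @param hinge_level Hinge position, see [apply_torsion()].
#' @return A `deformity_study` list: `measurements` (a
#'   [measurement_table()] with one TTA row per preset and replicate),
#'   `truth` (preset and true readout per condition), `sigma_mm` and `seed`.
#' @examples
#' sim <- simulate_deformity_study(c(0, 10, -10), sigma_mm = 0)
#' sim$measurements
#' @export
simulate_deformity_study <- function(presets, sigma_mm = 0, replicates = 1,
                                     seed = NULL, template = tibia_template(),
                                     hinge_level = 0.5) {
  if (!length(presets)) .stop_validation("presets must be nonempty")
  rows <- .with_seed(seed, {
    out <- vector("list", length(presets) * replicates)
    k <- 0L
    for (p in presets) {
      deformed <- apply_torsion(template, p, hinge_level)
      for (r in seq_len(replicates)) {
        lms <- jitter_landmarks(deformed, sigma_mm)
        k <- k + 1L
        out[[k]] <- data.frame(
          subject_id = template$bone_id,
          condition = sprintf("%g", p),
          observer = "sim",
          occasion = r,
          angle_type = "TTA",
          value = tibial_torsion_angle(lms)$readout,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
  structure(
    list(measurements = measurement_table(rows),
         truth = data.frame(condition = sprintf("%g", presets),
                            preset_deg = as.numeric(presets),
                            true_readout = 180 + as.numeric(presets),
                            stringsAsFactors = FALSE),
         sigma_mm = sigma_mm,
         seed = seed),
    class = "deformity_study"
  )
}

#' @export
print.deformity_study <- function(x, ...) {
  cat(sprintf("Simulated torsion study: %d presets x %d rows, sigma = %g mm%s\n",
              nrow(x$truth), nrow(x$measurements), x$sigma_mm,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}
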