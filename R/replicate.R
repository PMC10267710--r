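# Packaged validation data and one-command replication of the published
# quantitative results: torsion-model accuracy (Bland-Altman and
# Passing-Bablok against the goniometer reference), positioning independence
# (subtraction biases and within-subject CVs), and the synthetic analogue of
# the accuracy experiment on the landmark template.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "tibia3d", mustWork = FALSE)
  if (!nzchar(path)) .stop_parse(sprintf("packaged data file '%s' not found", file))
  path
}

#' Torsion-model accuracy data
#'
#' The 13 paired readouts of the physical torsion-deformity model: preset
#' hinge rotations of 0, +/-10, +/-20, +/-30, +/-40, +/-50 and +/-90 degrees
#' from the anatomical situation, each measured manually with a goniometer
#' and digitally from the CT scan, in the 180-neutral readout convention.
#'
#' @return Data frame with columns `preset_deg` (label), `goniometer` and
#'   `software` (degrees).
#' @export
torsion_model_data <- function() {
  utils::read.csv(.extdata("torsion_model_accuracy.csv"),
                  colClasses = c("character", "numeric", "numeric"))
}

#' Positioning-experiment measurement data
#'
#' Long-format readouts of the positioning experiment: 20 normal tibiae,
#' each CT-scanned parallel to the scanner z-axis and in 15- and 45-degree
#' double-oblique poses, with torsion and varus/valgus angles read three
#' times per scan (observer 1 at two occasions, observer 2 once) — 360
#' values. The data are kept verbatim, including one anomalous
#' varus/valgus value (132.2) that dominates the inter-observer CV of that
#' angle.
#'
#' @return A [measurement_table()] with 360 rows; `condition` is the pose
#'   (`"0"`, `"15"`, `"45"`).
#' @export
positioning_data <- function() {
  read_measurement_table(.extdata("positioning_measurements.csv"))
}

#' Replicate the torsion-model accuracy analysis
#'
#' Runs [bland_altman()] and [passing_bablok()] on the packaged
#' [torsion_model_data()] with the goniometer as reference (x) and the
#' CT-based software readout as test method (y). Agreement shows as a bias
#' whose magnitude rounds to 0.2 degrees and a regression slope angle that
#' rounds to 45 degrees.
#'
#' @return List with elements `bland_altman` and `passing_bablok`, plus
#'   `abs_bias` (|bias| at the 0.1-degree reporting resolution) and
#'   `slope_angle_deg`.
#' @examples
#' replicate_accuracy()
#' @export
replicate_accuracy <- function() {
  data <- torsion_model_data()
  ba <- bland_altman(data$goniometer, data$software)
  pb <- passing_bablok(data$goniometer, data$software)
  list(bland_altman = ba, passing_bablok = pb,
       abs_bias = round(abs(ba$bias), 1),
       slope_angle_deg = pb$slope_angle_deg)
}

#' Replicate the positioning-independence analysis
#'
#' From the packaged [positioning_data()]: the six subtraction biases
#' (per-bone three-reading means, all pairs of the three poses, both
#' angles) via [position_difference_table()], and the within-subject CVs
#' via [within_subject_cv()] — intra-observer (observer 1, occasions 1 vs 2)
#' and inter-observer (observer 1 occasion 1 vs observer 2) for each angle.
#'
#' @return List with `bias_table` (a `position_independence` data frame),
#'   `max_abs_bias`, and `cvs` (named list of `within_subject_cv` results:
#'   `tta_intra`, `tta_inter`, `tva_intra`, `tva_inter`).
#' @examples
#' rep <- replicate_position_independence()
#' rep$bias_table
#' @export
replicate_position_independence <- function() {
  table <- positioning_data()
  bias_table <- position_difference_table(table)
  cvs <- list(
    tta_intra = within_subject_cv(table, "TTA", "intra"),
    tta_inter = within_subject_cv(table, "TTA", "inter"),
    tva_intra = within_subject_cv(table, "TVA", "intra"),
    tva_inter = within_subject_cv(table, "TVA", "inter")
  )
  list(bias_table = bias_table, max_abs_bias = max(abs(bias_table$bias)),
       cvs = cvs)
}

#' Replicate the accuracy experiment on the synthetic template
#'
#' Transplants the torsion-model design onto the synthetic landmark
#' template: presets 0, +/-10, ..., +/-50, +/-90 degrees are applied with
#' the diaphyseal hinge and measured, first noise-free (exact recovery) and
#' then with Gaussian landmark noise, where recovered and true readouts are
#' compared by Passing-Bablok regression and Bland-Altman analysis.
#'
#' @param seed Integer seed for the noise draws.
#' @param sigma_mm Landmark noise standard deviation for the noisy arm, mm.
#' @param replicates Replicates per preset in the noisy arm.
#' @return List: `presets`, `noise_free` (data frame of preset, true and
#'   measured readouts plus `max_abs_error`), and `noisy`
#'   (`bland_altman`, `passing_bablok` of true vs recovered readouts).
#' @export
replicate_synthetic_accuracy <- function(seed = 1L, sigma_mm = 0.2,
                                         replicates = 2L) {
  presets <- c(0, rep(c(10, 20, 30, 40, 50, 90), each = 2) * c(1, -1))
  exact <- simulate_deformity_study(presets, sigma_mm = 0)
  exact_df <- merge(exact$measurements, exact$truth, by = "condition")
  noise_free <- data.frame(preset_deg = exact_df$preset_deg,
                           true_readout = exact_df$true_readout,
                           measured = exact_df$value)
  noise_free <- noise_free[order(noise_free$preset_deg), ]
  rownames(noise_free) <- NULL
  noisy <- simulate_deformity_study(presets, sigma_mm = sigma_mm,
                                    replicates = replicates, seed = seed)
  noisy_df <- merge(noisy$measurements, noisy$truth, by = "condition")
  list(
    presets = presets,
    noise_free = list(table = noise_free,
                      max_abs_error = max(abs(noise_free$measured -
                                                noise_free$true_readout))),
    noisy = list(bland_altman = bland_altman(noisy_df$true_readout, noisy_df$value),
                 passing_bablok = passing_bablok(noisy_df$true_readout,
                                                 noisy_df$value),
                 sigma_mm = sigma_mm, seed = seed)
  )
}
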