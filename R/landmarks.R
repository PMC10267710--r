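# Domain model for the ten named tibial reference points and file IO for
# landmark sets (native JSON, plain CSV, 3D-Slicer-style fiducial CSV) and
# long-format repeated-measurement tables.

.LANDMARKS_ALL <- c("TRCAx_med", "TRCAx_lat", "TACAx_med", "TACAx_lat",
                    "DTC", "PTC", "LTCC", "MTCC", "LTCGC", "MTCGC")
.LANDMARKS_TTA <- c("TRCAx_med", "TRCAx_lat", "TACAx_med", "TACAx_lat",
                    "DTC", "PTC")
.LANDMARKS_TVA_EXTRA <- c("LTCC", "MTCC", "LTCGC", "MTCGC")

.stop_validation <- function(message) {
  stop(.condition("tibia3d_validation_error", message))
}

.stop_parse <- function(message) {
  stop(.condition("tibia3d_parse_error", message))
}

#' Names of the tibial anatomical reference points
#'
#' The closed vocabulary of landmark names: the medial/lateral endpoints of
#' the proximal caudal retrocondylar axis (`TRCAx_med`, `TRCAx_lat`) and of
#' the distal cranial antecochlear axis (`TACAx_med`, `TACAx_lat`), the
#' distal and proximal tibial shaft centers (`DTC`, `PTC`), the lateral and
#' medial tibial condyle centers (`LTCC`, `MTCC`), and the lateral and
#' medial tibial cochlear groove centers (`LTCGC`, `MTCGC`).
#'
#' @param subset `"all"`, `"torsion"` (the six points needed for the tibial
#'   torsion angle) or `"varus"` (the four additional joint-surface points
#'   needed for the varus/valgus angle).
#' @return Character vector of landmark names.
#' @export
landmark_names <- function(subset = c("all", "torsion", "varus")) {
  switch(match.arg(subset),
         all = .LANDMARKS_ALL,
         torsion = .LANDMARKS_TTA,
         varus = .LANDMARKS_TVA_EXTRA)
}

#' Create a validated tibial landmark set
#'
#' A landmark set holds the named anatomical reference points of one tibia
#' as 3D coordinates in millimetres, together with the bone side and a
#' coordinate-frame label. The internal canonical frame is LPS (the DICOM
#' patient convention); coordinates declared as RAS are converted on input
#' by negating the first two components, a proper rotation that preserves
#' chirality and hence every downstream angle.
#'
#' @param landmarks Named list of numeric length-3 coordinates, or a numeric
#'   matrix with landmark names as row names and 3 columns (x, y, z), in mm.
#'   Names must come from [landmark_names()]; the six torsion landmarks are
#'   required, the four joint-surface landmarks optional.
#' @param side `"left"` or `"right"`.
#' @param bone_id Free-text bone identifier.
#' @param coordinate_frame Frame label; `"RAS"` triggers conversion to LPS,
#'   any other label is kept as metadata.
#' @return A `tibia_landmarks` object.
#' @examples
#' lms <- tibia_template()
#' lms
#' @export
tibia_landmarks <- function(landmarks, side = c("right", "left"),
                            bone_id = "bone", coordinate_frame = "LPS") {
  side <- match.arg(side)
  if (is.list(landmarks)) {
    nm <- names(landmarks)
    landmarks <- do.call(rbind, lapply(landmarks, function(v) .check_vec3(v, "landmark")))
    rownames(landmarks) <- nm
  }
  if (!is.matrix(landmarks) || ncol(landmarks) != 3L || is.null(rownames(landmarks))) {
    .stop_validation("landmarks must be a named list of length-3 coordinates or a named 3-column matrix")
  }
  storage.mode(landmarks) <- "double"
  colnames(landmarks) <- c("x", "y", "z")
  unknown <- setdiff(rownames(landmarks), .LANDMARKS_ALL)
  if (length(unknown)) {
    .stop_parse(sprintf("unknown landmark name(s): %s", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(rownames(landmarks))) {
    .stop_validation("duplicated landmark names")
  }
  if (!all(is.finite(landmarks))) {
    .stop_validation("landmark coordinates must be finite")
  }
  missing <- setdiff(.LANDMARKS_TTA, rownames(landmarks))
  if (length(missing)) {
    .stop_validation(sprintf("missing required landmark(s): %s", paste(missing, collapse = ", ")))
  }
  if (identical(toupper(coordinate_frame), "RAS")) {
    landmarks[, 1:2] <- -landmarks[, 1:2]
    coordinate_frame <- "LPS"
  }
  if (.norm3(landmarks["PTC", ] - landmarks["DTC", ]) <= 1) {
    .stop_validation("DTC and PTC must be more than 1 mm apart")
  }
  pairs <- list(c("TRCAx_med", "TRCAx_lat"), c("TACAx_med", "TACAx_lat"),
                c("MTCC", "LTCC"), c("MTCGC", "LTCGC"))
  for (pr in pairs) {
    if (all(pr %in% rownames(landmarks)) &&
        .norm3(landmarks[pr[2L], ] - landmarks[pr[1L], ]) <= 0.1) {
      .stop_validation(sprintf("medial/lateral pair %s-%s closer than 0.1 mm",
                               pr[1L], pr[2L]))
    }
  }
  structure(
    list(bone_id = as.character(bone_id), side = side,
         coordinate_frame = as.character(coordinate_frame),
         landmarks = landmarks[intersect(.LANDMARKS_ALL, rownames(landmarks)), ,
                               drop = FALSE]),
    class = "tibia_landmarks"
  )
}

#' @export
print.tibia_landmarks <- function(x, ...) {
  cat(sprintf("Tibia landmark set '%s' (%s side, frame %s): %d reference points\n",
              x$bone_id, x$side, x$coordinate_frame, nrow(x$landmarks)))
  print(round(x$landmarks, 3))
  invisible(x)
}

# Named coordinate accessor used throughout the measurement code.
.lm <- function(set, name) {
  if (!name %in% rownames(set$landmarks)) {
    .stop_validation(sprintf("missing required landmark(s): %s", name))
  }
  set$landmarks[name, ]
}

.require_landmarks <- function(set, names) {
  missing <- setdiff(names, rownames(set$landmarks))
  if (length(missing)) {
    .stop_validation(sprintf("missing required landmark(s): %s",
                             paste(missing, collapse = ", ")))
  }
}

.infer_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, json = "json", fcsv = "fcsv", csv = "csv",
         .stop_parse(sprintf("cannot infer landmark dialect from extension '.%s'", ext)))
}

.parse_num <- function(s, path, line) {
  v <- suppressWarnings(as.numeric(s))
  if (anyNA(v)) {
    .stop_parse(sprintf("%s: malformed numeric value on line %d", path, line))
  }
  v
}

#' Read a tibial landmark set from file
#'
#' Three dialects are supported: the native JSON schema
#' (`{bone_id, side, coordinate_frame, landmarks: {NAME: [x, y, z], ...}}`),
#' a plain CSV with a metadata comment line and `name,x,y,z` columns, and a
#' 3D-Slicer-style fiducial CSV (`.fcsv`) whose comment header declares the
#' coordinate system. Coordinates declared RAS are converted to LPS.
#'
#' @param path File path.
#' @param dialect `"json"`, `"csv"` or `"fcsv"`; inferred from the file
#'   extension when omitted.
#' @return A validated [tibia_landmarks()] object.
#' @seealso [write_landmarks()]
#' @export
read_landmarks <- function(path, dialect = NULL) {
  if (!file.exists(path)) .stop_parse(sprintf("file not found: %s", path))
  dialect <- if (is.null(dialect)) .infer_dialect(path) else
    match.arg(dialect, c("json", "csv", "fcsv"))
  switch(dialect,
         json = .read_landmarks_json(path),
         csv = .read_landmarks_csv(path),
         fcsv = .read_landmarks_fcsv(path))
}

.read_landmarks_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) .stop_parse(sprintf("%s: invalid JSON (%s)",
                                                          path, conditionMessage(e))))
  for (field in c("bone_id", "side", "coordinate_frame", "landmarks")) {
    if (is.null(obj[[field]])) .stop_parse(sprintf("%s: missing field '%s'", path, field))
  }
  lms <- lapply(obj$landmarks, as.numeric)
  tibia_landmarks(lms, side = obj$side, bone_id = obj$bone_id,
                  coordinate_frame = obj$coordinate_frame)
}

.read_landmarks_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#")) {
    .stop_parse(sprintf("%s: missing metadata header line ('# bone_id=... side=... frame=...')", path))
  }
  meta <- .parse_meta_line(lines[1L], path)
  df <- utils::read.csv(text = lines[-1L], stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(df))) {
    .stop_parse(sprintf("%s: expected columns name,x,y,z", path))
  }
  coords <- lapply(seq_len(nrow(df)), function(i) {
    .parse_num(unlist(df[i, c("x", "y", "z")]), path, i + 2L)
  })
  names(coords) <- df$name
  tibia_landmarks(coords, side = meta[["side"]], bone_id = meta[["bone_id"]],
                  coordinate_frame = meta[["frame"]])
}

.parse_meta_line <- function(line, path) {
  body <- sub("^#\\s*", "", line)
  kv <- regmatches(body, gregexpr("[A-Za-z_]+=[^ ,]+", body))[[1L]]
  if (!length(kv)) .stop_parse(sprintf("%s: unparseable metadata line", path))
  parts <- strsplit(kv, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  for (field in c("bone_id", "side", "frame")) {
    if (is.na(meta[field])) .stop_parse(sprintf("%s: metadata line lacks '%s'", path, field))
  }
  meta
}

.read_landmarks_fcsv <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
  frame <- "LPS"
  cs <- grep("CoordinateSystem", comments, value = TRUE)
  if (length(cs)) {
    val <- trimws(sub(".*=", "", cs[1L]))
    frame <- if (val %in% c("RAS", "0")) "RAS" else "LPS"
  }
  side <- "right"
  sd <- grep("^#\\s*side\\s*=", comments)
  if (length(sd)) side <- trimws(sub(".*=", "", comments[sd[1L]]))
  bone_id <- tools::file_path_sans_ext(basename(path))
  bi <- grep("^#\\s*bone_id\\s*=", comments)
  if (length(bi)) bone_id <- trimws(sub(".*=", "", comments[bi[1L]]))
  # column layout: id,x,y,z,...,label at position 12 (Slicer markups layout);
  # fall back to label,x,y,z when the file has only 4 columns
  coords <- list()
  for (i in seq_along(rows)) {
    fields <- strsplit(rows[i], ",", fixed = TRUE)[[1L]]
    if (length(fields) >= 12L) {
      label <- fields[12L]
      xyz <- .parse_num(fields[2:4], path, i)
    } else if (length(fields) >= 4L) {
      label <- fields[1L]
      xyz <- .parse_num(fields[2:4], path, i)
    } else {
      .stop_parse(sprintf("%s: malformed fiducial row on line %d", path, i))
    }
    coords[[label]] <- xyz
  }
  tibia_landmarks(coords, side = side, bone_id = bone_id, coordinate_frame = frame)
}

#' Write a tibial landmark set to file
#'
#' Inverse of [read_landmarks()]: a written file reads back to an identical
#' set (coordinates to 1e-6 mm; output uses 6 decimal places). All dialects
#' write the internal LPS coordinates and declare the frame.
#'
#' @inheritParams read_landmarks
#' @param set A [tibia_landmarks()] object.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(set, path, dialect = NULL) {
  stopifnot(inherits(set, "tibia_landmarks"))
  dialect <- if (is.null(dialect)) .infer_dialect(path) else
    match.arg(dialect, c("json", "csv", "fcsv"))
  fmt <- function(v) sprintf("%.6f", v)
  lmrows <- rownames(set$landmarks)
  switch(dialect,
    json = {
      obj <- list(bone_id = set$bone_id, side = set$side,
                  coordinate_frame = set$coordinate_frame,
                  landmarks = stats::setNames(
                    lapply(lmrows, function(n) round(set$landmarks[n, ], 6)), lmrows))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    },
    csv = {
      lines <- c(
        sprintf("# bone_id=%s side=%s frame=%s", set$bone_id, set$side,
                set$coordinate_frame),
        "name,x,y,z",
        vapply(lmrows, function(n) {
          paste(c(n, fmt(set$landmarks[n, ])), collapse = ",")
        }, "")
      )
      writeLines(lines, path)
    },
    fcsv = {
      lines <- c(
        "# Markups fiducial file version = 4.11",
        sprintf("# CoordinateSystem = %s", set$coordinate_frame),
        sprintf("# bone_id = %s", set$bone_id),
        sprintf("# side = %s", set$side),
        "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
        vapply(seq_along(lmrows), function(i) {
          n <- lmrows[i]
          paste(c(sprintf("vtkMRMLMarkupsFiducialNode_%d", i),
                  fmt(set$landmarks[n, ]), "0", "0", "0", "1", "1", "1", "0",
                  n, "", ""), collapse = ",")
        }, "")
      )
      writeLines(lines, path)
    }
  )
  invisible(path)
}

.MEASUREMENT_COLS <- c("subject_id", "condition", "observer", "occasion",
                       "angle_type", "value")

#' Validate a long-format measurement table
#'
#' A measurement table holds repeated angle readouts in long format with
#' columns `subject_id`, `condition` (e.g. scanner position or preset
#' torsion), `observer`, `occasion` (integer, 1-based), `angle_type`
#' (`"TTA"` or `"TVA"`) and `value` (degrees in the 180-neutral readout).
#' The (subject, condition, observer, occasion, angle type) key must be
#' unique and values must lie in (0, 360).
#'
#' @param table A data frame with the six columns above.
#' @return The validated table (classed `measurement_table`).
#' @export
measurement_table <- function(table) {
  missing <- setdiff(.MEASUREMENT_COLS, names(table))
  if (length(missing)) {
    .stop_validation(sprintf("measurement table lacks column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  table <- as.data.frame(table)[.MEASUREMENT_COLS]
  table$subject_id <- as.character(table$subject_id)
  table$condition <- as.character(table$condition)
  table$observer <- as.character(table$observer)
  table$occasion <- as.integer(table$occasion)
  table$angle_type <- as.character(table$angle_type)
  table$value <- as.numeric(table$value)
  if (nrow(table)) {
    if (any(!table$angle_type %in% c("TTA", "TVA"))) {
      .stop_validation("angle_type must be 'TTA' or 'TVA'")
    }
    if (any(is.na(table$occasion)) || any(table$occasion < 1L)) {
      .stop_validation("occasion must be an integer >= 1")
    }
    bad <- !is.finite(table$value) | table$value <= 0 | table$value >= 360
    if (any(bad)) {
      .stop_validation(sprintf("value out of (0, 360) in row(s) %s",
                               paste(which(bad), collapse = ", ")))
    }
    key <- do.call(paste, c(table[setdiff(.MEASUREMENT_COLS, "value")], sep = "|"))
    if (anyDuplicated(key)) {
      .stop_validation(sprintf("duplicate measurement key(s): %s",
                               paste(unique(key[duplicated(key)]), collapse = "; ")))
    }
  }
  class(table) <- c("measurement_table", "data.frame")
  table
}

#' Read / write a long-format measurement table (CSV)
#'
#' @param path CSV path with header
#'   `subject_id,condition,observer,occasion,angle_type,value`.
#' @return [read_measurement_table()] returns a validated
#'   [measurement_table()]; [write_measurement_table()] returns `path`
#'   invisibly. The pair round-trips losslessly.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) .stop_parse(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v) && nrow(df)) {
    .stop_parse(sprintf("%s: malformed numeric value on line %d", path,
                        which(is.na(v))[1L] + 1L))
  }
  df$value <- v
  measurement_table(df)
}

#' @rdname read_measurement_table
#' @param table A [measurement_table()] (or coercible data frame).
#' @export
write_measurement_table <- function(table, path) {
  table <- measurement_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
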