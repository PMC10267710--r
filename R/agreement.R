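# Method-comparison statistics: Bland-Altman agreement, Passing-Bablok
# regression (1983 procedure: shifted median of all pairwise slopes with
# rank-based confidence intervals), Bland's within-subject coefficient of
# variation for duplicate measurements, and the positioning subtraction
# analysis.

.as_pairs <- function(x, y = NULL) {
  if (is.null(y)) {
    if (!is.data.frame(x) || !all(c("x", "y") %in% names(x))) {
      .stop_validation("pairs must be a data frame with columns x and y (and optionally id)")
    }
    pairs <- data.frame(x = as.numeric(x$x), y = as.numeric(x$y))
  } else {
    if (length(x) != length(y)) .stop_validation("x and y must have equal length")
    pairs <- data.frame(x = as.numeric(x), y = as.numeric(y))
  }
  if (!all(is.finite(pairs$x)) || !all(is.finite(pairs$y))) {
    .stop_validation("paired values must be finite")
  }
  pairs
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `d = y - x` (second method minus reference);
#' the bias is their mean, and the limits of agreement are the bias plus or
#' minus 1.96 sample standard deviations.
#'
#' @param x Reference-method values, a numeric vector or a data frame with
#'   columns `x` and `y`.
#' @param y Second-method values when `x` is a vector.
#' @return A `bland_altman` object: `bias`, `sd_d`, `loa_low`, `loa_high`,
#'   `n`, and the per-pair `differences`.
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 3, 5))
#' @export
bland_altman <- function(x, y = NULL) {
  pairs <- .as_pairs(x, y)
  n <- nrow(pairs)
  if (n < 2L) .stop_validation("Bland-Altman requires at least 2 pairs")
  d <- pairs$y - pairs$x
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, sd_d = sd_d,
                 loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
                 n = n, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, SD %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$sd_d, x$loa_low, x$loa_high))
  invisible(x)
}

#' Passing-Bablok regression
#'
#' Non-parametric method-comparison regression: the slope is the shifted
#' median of all pairwise slopes (pairs with equal x contribute none, slopes
#' of exactly -1 are discarded, and the median index is offset by the number
#' of slopes below -1); the intercept is the median of `y - slope * x`.
#' Confidence intervals use the rank-based normal approximation with
#' half-width \eqn{z_{0.975} \sqrt{n(n-1)(2n+5)/18}} on the slope ranks.
#'
#' @inheritParams bland_altman
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A `passing_bablok` object: `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `slope_angle_deg` (= atan(slope) in degrees),
#'   `n_points`, `n_valid_slopes`.
#' @examples
#' passing_bablok(c(1, 2, 3, 4), c(3, 5, 7, 9))  # exact line y = 1 + 2x
#' @export
passing_bablok <- function(x, y = NULL, conf_level = 0.95) {
  pairs <- .as_pairs(x, y)
  n <- nrow(pairs)
  if (n < 3L) .stop_validation("Passing-Bablok requires at least 3 pairs")
  if (length(unique(pairs$x)) < 2L) {
    .stop_validation("Passing-Bablok requires at least two distinct x values")
  }
  dx <- outer(pairs$x, pairs$x, `-`)
  dy <- outer(pairs$y, pairs$y, `-`)
  lower <- lower.tri(dx)
  keep <- lower & dx != 0
  slopes <- dy[keep] / dx[keep]
  slopes <- slopes[slopes != -1]
  if (!length(slopes)) .stop_validation("no valid pairwise slopes")
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  b <- .offset_median(slopes, K)
  a <- stats::median(pairs$y - b * pairs$x)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((N - w) / 2)
  m2 <- N - m1 + 1
  b_lo <- slopes[max(1L, min(N, m1 + K))]
  b_hi <- slopes[max(1L, min(N, m2 + K))]
  structure(list(slope = b, intercept = a,
                 slope_ci = c(b_lo, b_hi),
                 intercept_ci = c(stats::median(pairs$y - b_hi * pairs$x),
                                  stats::median(pairs$y - b_lo * pairs$x)),
                 slope_angle_deg = atan(b) * 180 / pi,
                 n_points = n, n_valid_slopes = N,
                 conf_level = conf_level),
            class = "passing_bablok")
}

# Median of sorted slopes shifted by K (the count of slopes below -1), the
# 1983 estimator that makes the slope equivariant under axis swap.
.offset_median <- function(sorted_slopes, K) {
  N <- length(sorted_slopes)
  if (N %% 2L == 1L) {
    sorted_slopes[(N + 1L) %/% 2L + K]
  } else {
    mean(sorted_slopes[c(N %/% 2L + K, N %/% 2L + 1L + K)])
  }
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf("Passing-Bablok (n = %d, %d pairwise slopes)\n", x$n_points,
              x$n_valid_slopes))
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]  (angle %.2f deg)\n", x$slope,
              x$slope_ci[1], x$slope_ci[2], x$slope_angle_deg))
  cat(sprintf("  intercept %.4f  [%.4f, %.4f]\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Coefficient-of-variation grade
#'
#' Grades a within-subject CV on the conventional half-open bins:
#' below 3% excellent, 3-10% good, 10-15% moderate/fair, 15% and above poor.
#'
#' @param cv_percent Non-negative CV in percent.
#' @return One of `"excellent"`, `"good"`, `"moderate/fair"`, `"poor"`.
#' @export
classify_cv <- function(cv_percent) {
  if (!is.numeric(cv_percent) || length(cv_percent) != 1L ||
      !is.finite(cv_percent) || cv_percent < 0) {
    .stop_validation("cv_percent must be a single non-negative number")
  }
  if (cv_percent < 3) "excellent"
  else if (cv_percent < 10) "good"
  else if (cv_percent < 15) "moderate/fair"
  else "poor"
}

.extract_replicate <- function(table, angle_type, observer, occasion) {
  sub <- table[table$angle_type == angle_type & table$observer == observer &
                 table$occasion == occasion, ]
  stats::setNames(sub$value, paste(sub$subject_id, sub$condition, sep = "|"))
}

#' Within-subject coefficient of variation for duplicate measurements
#'
#' Bland's CV for repeated measurements: for each subject/condition key with
#' duplicate readings `(v1, v2)` the within-subject variance is
#' `s^2 = (v1 - v2)^2 / 2` and the subject mean is `m`; the CV is
#' `100 * sqrt(mean(s^2 / m^2))` (root mean square over subjects).
#'
#' @param table A [measurement_table()].
#' @param angle_type `"TTA"` or `"TVA"`.
#' @param pairing `"intra"` pairs two occasions of one observer;
#'   `"inter"` pairs one occasion of each of two observers.
#' @param observer Observer for `pairing = "intra"`.
#' @param occasions The two occasions paired for `pairing = "intra"`.
#' @param observers The two observers paired for `pairing = "inter"`.
#' @param inter_occasions Occasions used for each observer under
#'   `pairing = "inter"`; the default pairs the first observer's first
#'   occasion with the second observer's first occasion.
#' @return A `within_subject_cv` object: `cv_percent`, `overall_mean`,
#'   `n_subjects`, `grade` (see [classify_cv()]).
#' @export
within_subject_cv <- function(table, angle_type = c("TTA", "TVA"),
                              pairing = c("intra", "inter"),
                              observer = "O1", occasions = c(1L, 2L),
                              observers = c("O1", "O2"),
                              inter_occasions = c(1L, 1L)) {
  table <- measurement_table(table)
  angle_type <- match.arg(angle_type)
  pairing <- match.arg(pairing)
  if (pairing == "intra") {
    v1 <- .extract_replicate(table, angle_type, observer, occasions[1L])
    v2 <- .extract_replicate(table, angle_type, observer, occasions[2L])
  } else {
    v1 <- .extract_replicate(table, angle_type, observers[1L], inter_occasions[1L])
    v2 <- .extract_replicate(table, angle_type, observers[2L], inter_occasions[2L])
  }
  keys <- union(names(v1), names(v2))
  missing <- c(setdiff(keys, names(v1)), setdiff(keys, names(v2)))
  if (length(missing) || !length(keys)) {
    .stop_validation(sprintf("missing replicate for key(s): %s",
                             paste(unique(missing), collapse = "; ")))
  }
  v2 <- v2[names(v1)]
  m <- (v1 + v2) / 2
  s2 <- (v1 - v2)^2 / 2
  cv <- 100 * sqrt(mean(s2 / m^2))
  structure(list(cv_percent = cv, overall_mean = mean(c(v1, v2)),
                 n_subjects = length(v1), grade = classify_cv(cv),
                 angle_type = angle_type, pairing = pairing),
            class = "within_subject_cv")
}

#' @export
print.within_subject_cv <- function(x, ...) {
  cat(sprintf("%s %s-observer CV: %.2f%% (%s), overall mean %.2f, n = %d\n",
              x$angle_type, x$pairing, x$cv_percent, x$grade, x$overall_mean,
              x$n_subjects))
  invisible(x)
}

#' Positioning subtraction analysis
#'
#' Tests independence of the measurements from bone positioning: per bone
#' and position the mean over all readings is formed, and for every pair of
#' positions the per-bone differences of these means are summarized by their
#' mean (BIAS) and a two-sided one-sample t-test against zero. If the
#' measurements are position-independent the differences should tend to
#' zero.
#'
#' @param table A [measurement_table()] whose `condition` encodes the
#'   position.
#' @param conditions Positions to compare, in order; defaults to the three
#'   scanner poses `"0"`, `"15"`, `"45"` (degrees off the z-axis).
#' @return A `position_independence` data frame with one row per angle type
#'   and condition pair: `angle_type`, `condition_a`, `condition_b`, `bias`
#'   (mean of per-bone `a - b` differences), `p_value`, `n_bones`.
#' @export
position_difference_table <- function(table, conditions = c("0", "15", "45")) {
  table <- measurement_table(table)
  if (length(conditions) < 2L) .stop_validation("need at least two conditions")
  out <- list()
  for (ang in intersect(c("TTA", "TVA"), unique(table$angle_type))) {
    sub <- table[table$angle_type == ang & table$condition %in% conditions, ]
    means <- stats::aggregate(value ~ subject_id + condition, sub, mean)
    wide <- stats::reshape(means, idvar = "subject_id", timevar = "condition",
                           direction = "wide")
    cols <- paste0("value.", conditions)
    miss <- is.na(wide[cols])
    if (any(miss)) {
      cells <- paste(wide$subject_id[row(miss)[miss]],
                     conditions[col(miss)[miss]], sep = "/")
      .stop_validation(sprintf("incomplete design; missing cell(s): %s",
                               paste(cells, collapse = ", ")))
    }
    for (i in seq_along(conditions)[-length(conditions)]) {
      for (j in seq.int(i + 1L, length(conditions))) {
        d <- wide[[cols[i]]] - wide[[cols[j]]]
        out[[length(out) + 1L]] <- data.frame(
          angle_type = ang,
          condition_a = conditions[i], condition_b = conditions[j],
          bias = mean(d),
          p_value = stats::t.test(d, mu = 0)$p.value,
          n_bones = length(d),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("position_independence", "data.frame")
  res
}
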