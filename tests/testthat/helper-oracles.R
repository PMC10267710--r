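# Shared helpers: random rigid motions, mirrored landmark sets, and
# independent brute-force oracles kept deliberately separate from the
# package implementations they check.

# Uniform-ish random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_dec) %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply a rigid motion (rotation matrix + translation) to a landmark set.
transform_set <- function(lms, R, t = c(0, 0, 0)) {
  coords <- sweep(lms$landmarks %*% t(R), 2, t, `+`)
  tibia_landmarks(coords, side = lms$side, bone_id = lms$bone_id,
                  coordinate_frame = "LPS")
}

# Mirror a set across the x = 0 plane and flip the side label.
mirror_set <- function(lms) {
  coords <- lms$landmarks
  coords[, 1] <- -coords[, 1]
  tibia_landmarks(coords, side = if (lms$side == "right") "left" else "right",
                  bone_id = lms$bone_id, coordinate_frame = "LPS")
}

# Independent Passing-Bablok slope/intercept oracle: explicit double loop
# over all pairs, offset median by direct indexing of the sorted slopes.
pb_oracle <- function(x, y) {
  n <- length(x)
  S <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (x[i] != x[j]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) S <- c(S, s)
      }
    }
  }
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  b <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else (S[N / 2 + K] + S[N / 2 + 1 + K]) / 2
  c(slope = b, intercept = median(y - b * x))
}

# Closed-form within-subject CV for duplicate pairs.
cv_oracle <- function(v1, v2) {
  100 * sqrt(mean(((v1 - v2)^2 / 2) / ((v1 + v2) / 2)^2))
}
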