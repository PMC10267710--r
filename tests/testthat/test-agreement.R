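test_that("Bland-Altman bias and limits match the closed form", {
  ba <- bland_altman(c(1, 2, 3), c(2, 3, 5))
  expect_equal(ba$bias, 4 / 3, tolerance = 1e-9)
  expect_equal(ba$sd_d, sqrt(1 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd_d)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd_d)
  same <- bland_altman(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$bias, 0)
  expect_equal(same$sd_d, 0)
  # swapping the methods negates the bias exactly
  set.seed(31)
  x <- rnorm(10, 180, 5); y <- x + rnorm(10, 0.3, 1)
  expect_identical(bland_altman(y, x)$bias, -bland_altman(x, y)$bias)
  expect_error(bland_altman(1, 2), class = "tibia3d_validation_error")
})

test_that("Passing-Bablok recovers exact lines and the identity", {
  fit <- passing_bablok(c(1, 2, 3, 4), c(3, 5, 7, 9))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  id <- passing_bablok(c(2, 5, 9, 11, 14), c(2, 5, 9, 11, 14))
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0)
  expect_equal(id$slope_angle_deg, 45)
  expect_error(passing_bablok(c(1, 1, 1), c(1, 2, 3)),
               class = "tibia3d_validation_error")
})

test_that("Passing-Bablok matches the brute-force oracle and is equivariant", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n, 180, 20), 1)
    y <- round(1.05 * x - 8 + rnorm(n, 0, 3), 1)
    if (length(unique(x)) < 2) next
    fit <- passing_bablok(x, y)
    orc <- pb_oracle(x, y)
    expect_equal(fit$slope, unname(orc["slope"]), tolerance = 1e-12)
    expect_equal(fit$intercept, unname(orc["intercept"]), tolerance = 1e-12)
    expect_true(fit$slope_ci[1] <= fit$slope && fit$slope <= fit$slope_ci[2])
    expect_lte(fit$n_valid_slopes, n * (n - 1) / 2)
    # shifting y shifts the intercept and leaves the slope untouched
    sh <- passing_bablok(x, y + 11)
    expect_equal(sh$slope, fit$slope, tolerance = 1e-12)
    expect_equal(sh$intercept, fit$intercept + 11, tolerance = 1e-9)
  }
  # scale equivariance holds exactly on concordant data (all pairwise
  # slopes positive, so the -1 offset count stays zero under scaling)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- sort(sample(seq(1, 60, by = 0.5), n))
    y <- 5 + cumsum(runif(n, 0.1, 4))
    fit <- passing_bablok(x, y)
    sc <- passing_bablok(x, 2.5 * y)
    expect_equal(sc$slope, 2.5 * fit$slope, tolerance = 1e-9)
    expect_equal(sc$intercept, 2.5 * fit$intercept, tolerance = 1e-9)
  }
})

test_that("within-subject CV matches the duplicate closed form and its symmetries", {
  tab <- measurement_table(data.frame(
    subject_id = rep(c("s1", "s2"), each = 2),
    condition = "0", observer = "O1", occasion = rep(1:2, 2),
    angle_type = "TTA", value = c(100, 102, 200, 196)
  ))
  cv <- within_subject_cv(tab, "TTA", "intra")
  expect_equal(round(cv$cv_percent, 2), 1.41)
  expect_equal(cv$cv_percent, cv_oracle(c(100, 200), c(102, 196)), tolerance = 1e-12)
  expect_identical(cv$grade, "excellent")
  expect_equal(cv$n_subjects, 2L)
  # identical replicates give zero
  tab0 <- tab
  tab0$value <- rep(c(150, 170), each = 2)
  expect_equal(within_subject_cv(tab0, "TTA", "intra")$cv_percent, 0)
  # invariant to row order and to swapping the two replicates of a subject
  shuffled <- tab[c(3, 1, 4, 2), ]
  expect_equal(within_subject_cv(shuffled, "TTA", "intra")$cv_percent,
               cv$cv_percent)
  swapped <- tab
  swapped$value[1:2] <- swapped$value[2:1]
  expect_equal(within_subject_cv(swapped, "TTA", "intra")$cv_percent,
               cv$cv_percent)
  # a missing replicate names the offending key
  err <- expect_error(within_subject_cv(tab[-2, ], "TTA", "intra"),
                      class = "tibia3d_validation_error")
  expect_match(conditionMessage(err), "s1")
})

test_that("CV grading uses the half-open 3/10/15 percent bins", {
  expect_identical(classify_cv(2.9), "excellent")
  expect_identical(classify_cv(3), "good")
  expect_identical(classify_cv(9.99), "good")
  expect_identical(classify_cv(10), "moderate/fair")
  expect_identical(classify_cv(15), "poor")
  expect_error(classify_cv(-1), class = "tibia3d_validation_error")
})

test_that("position differences vanish for identical conditions and are antisymmetric", {
  base <- expand.grid(subject_id = paste0("b", 1:4), condition = c("0", "15", "45"),
                      observer = "O1", occasion = 1:2, angle_type = "TTA",
                      stringsAsFactors = FALSE)
  set.seed(33)
  per_bone <- rnorm(4, 175, 3)
  base$value <- per_bone[match(base$subject_id, paste0("b", 1:4))]
  res <- position_difference_table(measurement_table(base))
  expect_equal(res$bias, rep(0, 3))
  # reversing the condition order negates each pairwise bias
  noisy <- base
  noisy$value <- noisy$value + rnorm(nrow(noisy), 0, 0.5)
  fwd <- position_difference_table(measurement_table(noisy), c("0", "15"))
  rev <- position_difference_table(measurement_table(noisy), c("15", "0"))
  expect_equal(rev$bias, -fwd$bias, tolerance = 1e-12)
  # incomplete designs name the missing cell
  incomplete <- noisy[!(noisy$subject_id == "b2" & noisy$condition == "45"), ]
  err <- expect_error(position_difference_table(measurement_table(incomplete)),
                      class = "tibia3d_validation_error")
  expect_match(conditionMessage(err), "b2/45")
})
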