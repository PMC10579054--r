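make_suv <- function(values, spacing = c(4, 4, 4)) {
  pet_volume(values, spacing_mm = spacing, units = "SUV")
}

test_that("SUV conversion divides activity by dose per mass and is idempotent", {
  v <- pet_volume(array(7.5, c(3, 3, 3)), units = "kBq/ml",
                  injected_dose_kbq = 350000, body_mass_g = 70000)
  s <- to_suv(v)
  expect_equal(s$units, "SUV")
  expect_true(all(s$values == 1.5))
  expect_identical(to_suv(s), s)
  # identity: r == A0/M0 everywhere -> all ones
  v1 <- pet_volume(array(5, c(2, 2, 2)), units = "kBq/ml",
                   injected_dose_kbq = 350000, body_mass_g = 70000)
  expect_true(all(to_suv(v1)$values == 1))
  expect_error(pet_volume(array(1, c(2, 2, 2)), units = "kBq/ml",
                          injected_dose_kbq = -1, body_mass_g = 70000), "> 0")
})

test_that("SUV is invariant under joint rescaling of activity and dose", {
  set.seed(4)
  vals <- array(runif(4^3, 0, 20), c(4, 4, 4))
  for (k in c(0.1, 3, 17)) {
    a <- to_suv(pet_volume(vals, units = "kBq/ml",
                           injected_dose_kbq = 2e5, body_mass_g = 6e4))
    b <- to_suv(pet_volume(vals * k, units = "kBq/ml",
                           injected_dose_kbq = 2e5 * k, body_mass_g = 6e4))
    expect_equal(a$values, b$values, tolerance = 1e-12)
  }
})

test_that("region statistics match direct max/mean and reject empty masks", {
  vals <- array(0, c(4, 4, 4))
  vals[1, 1, 1] <- 2
  vals[2, 1, 1] <- 6
  mask <- array(FALSE, c(4, 4, 4))
  mask[1:2, 1, 1] <- TRUE
  st <- region_stats(make_suv(vals), mask)
  expect_equal(st$suv_max, 6)
  expect_equal(st$suv_mean, 4)
  expect_error(region_stats(make_suv(vals), array(FALSE, c(4, 4, 4))), "empty")
  # uniform region: max == mean == c
  u <- region_stats(make_suv(array(3.3, c(4, 4, 4))), mask)
  expect_equal(u$suv_max, 3.3)
  expect_equal(u$suv_mean, 3.3)
})

test_that("region statistics agree with a brute-force loop on random regions", {
  set.seed(11)
  for (i in 1:5) {
    vals <- array(rlnorm(10^3), c(10, 10, 10))
    mask <- array(runif(10^3) < 0.3, c(10, 10, 10))
    if (!any(mask)) next
    st <- region_stats(make_suv(vals), mask)
    mx <- -Inf; s <- 0; n <- 0
    for (j in seq_along(vals)) if (mask[j]) {
      if (vals[j] > mx) mx <- vals[j]
      s <- s + vals[j]; n <- n + 1
    }
    expect_equal(st$suv_max, mx)
    expect_equal(st$suv_mean, s / n)
  }
})

test_that("metabolic volume segments at 40% of SUVmax inclusively", {
  # uniform lesion: every voxel passes, full volume returned
  vals <- array(0.2, c(8, 8, 8))
  mask <- array(FALSE, c(8, 8, 8))
  mask[3:6, 3:6, 3:6] <- TRUE
  vals[mask] <- 5
  mv <- metabolic_volume(make_suv(vals), mask)
  expect_equal(mv$mask, mask)
  expect_equal(mv$volume_ml, 64 * 0.064)
  # single voxel at 4 mm spacing -> 0.064 ml
  m1 <- array(FALSE, c(8, 8, 8))
  m1[4, 4, 4] <- TRUE
  expect_equal(metabolic_volume(make_suv(vals), m1)$volume_ml, 0.064)
})

test_that("metabolic volume equals brute-force thresholding on Gaussian blobs", {
  ph <- small_phantom(peak = 10, noise = 0)
  suv <- ph$pet
  mask <- ph$truth$mask[[1]]
  mv <- metabolic_volume(suv, mask)
  expect_equal(mv$threshold, 0.4 * (10 + 0.5))
  expect_equal(sum(mv$mask), bf_threshold_count(suv$values, mask))
  # connected restriction is a no-op for a single blob
  expect_equal(metabolic_volume(suv, mask, connected = FALSE)$volume_ml, mv$volume_ml)
})

test_that("connected-component restriction drops satellite islands", {
  vals <- array(0, c(12, 12, 3))
  mask <- array(FALSE, c(12, 12, 3))
  mask[2:4, 2:4, 2] <- TRUE   # main blob holding the max
  mask[9:10, 9:10, 2] <- TRUE # disconnected satellite, also supra-threshold
  vals[2:4, 2:4, 2] <- 8
  vals[3, 3, 2] <- 10
  vals[9:10, 9:10, 2] <- 9
  with_cc <- metabolic_volume(make_suv(vals), mask, connected = TRUE)
  without <- metabolic_volume(make_suv(vals), mask, connected = FALSE)
  expect_equal(sum(with_cc$mask), 9)
  expect_equal(sum(without$mask), 13)
  expect_true(with_cc$mask[3, 3, 2])
})

test_that("threshold mask is idempotent, nested in the lesion, and above-threshold on average", {
  set.seed(21)
  for (i in 1:10) {
    ph <- small_phantom(peak = runif(1, 4, 15), noise = 0.3, seed = i)
    suv <- ph$pet
    mask <- ph$truth$mask[[1]]
    mv <- metabolic_volume(suv, mask)
    expect_true(all(mv$mask[!mask] == FALSE)) # subset of lesion mask
    expect_true(mv$mask[which.max(ifelse(mask, suv$values, -Inf))])
    again <- metabolic_volume(suv, mv$mask)
    expect_equal(again$mask, mv$mask) # idempotent
    st <- region_stats(suv, mv$mask)
    expect_gte(st$suv_mean, 0.4 * st$suv_max - 1e-12)
  }
})

test_that("exclusions are removed and excluding the max voxel is ill-posed", {
  ph <- small_phantom(peak = 10, noise = 0)
  mask <- ph$truth$mask[[1]]
  excl <- array(FALSE, dim(mask))
  excl[10, 10, 11] <- TRUE
  mv <- metabolic_volume(ph$pet, mask, exclusions = excl)
  expect_false(mv$mask[10, 10, 11])
  excl_max <- array(FALSE, dim(mask))
  excl_max[10, 10, 10] <- TRUE
  expect_error(metabolic_volume(ph$pet, mask, exclusions = excl_max), "ill-posed")
})

test_that("peak SUV averages a 1 ml sphere: uniform value preserved, hot spot diluted", {
  vals <- array(4.2, c(10, 10, 10))
  mask <- array(FALSE, c(10, 10, 10))
  mask[3:8, 3:8, 3:8] <- TRUE
  expect_equal(suv_peak(make_suv(vals), mask), 4.2)
  hot <- array(0, c(10, 10, 10))
  hot[5, 5, 5] <- 50
  m <- array(TRUE, c(10, 10, 10))
  expect_lt(suv_peak(make_suv(hot), m), 50)
  # against the naive sphere-mean oracle on a random blob
  ph <- small_phantom(peak = 9, noise = 0.2, seed = 5)
  got <- suv_peak(ph$pet, ph$truth$mask[[1]])
  r <- (3000 / (4 * pi))^(1 / 3)
  expect_equal(got, bf_sphere_mean(ph$pet$values, c(4, 4, 4), c(10, 10, 10), r),
               tolerance = 1e-12)
})
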