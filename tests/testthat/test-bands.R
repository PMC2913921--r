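# Decimal residuals, the band transformation, k-means classification and
# residual unwrapping.

test_that("decimal residual is the fractional part and rejects bad masses", {
  expect_equal(decimal_residual(203.126992), 0.126992, tolerance = 1e-9)
  expect_equal(decimal_residual(500.0), 0.0)
  expect_equal(decimal_residual(1500.9992), 0.9992, tolerance = 1e-9)
  expect_error(decimal_residual(0), "positive")
  expect_error(decimal_residual(-10), "positive")
  r <- decimal_residual(runif(100, 300, 6000))
  expect_true(all(r >= 0 & r < 1))
})

test_that("the transformation shifts masses by the constant times the residual", {
  expect_equal(transform_mass(2000.5, 0.5), 1100.5)
  expect_equal(transform_mass(300.0, 0.0), 300.0)
  # a band obeying D_R = 5.1357e-4 * P_M collapses to a narrow near-vertical
  # cluster: a 1,947 Da span of masses compresses to ~146 Da of transformed mass
  b <- 5.1357e-4
  m <- c(1000, 1900)
  tr <- transform_mass(m, (b * m) %% 1)
  expect_equal(tr[1], 1000 - 1800 * 0.51357, tolerance = 1e-6)
  expect_lt(abs(diff(tr)), 150)
  expect_error(transform_mass(100, 1.2), "\\[0, 1\\)")
})

test_that("classification assigns nearest-center bands and dummies rescue empty centers", {
  # transformed values {10, 12, 2005}: third preset center (4000) is empty
  # and must be rescued by its dummy point
  masses <- c(10.0, 12.0, 2005.0)  # residual 0 so transformed = mass
  cfg <- band_config(c(0, 2000, 4000), add_dummy_points = TRUE)
  expect_identical(classify_bands(masses, cfg), c(0L, 0L, 1L))
  # without dummies the empty center triggers a warned retry
  cfg_nodummy <- band_config(c(0, 2000, 4000), add_dummy_points = FALSE)
  expect_warning(bands <- classify_bands(masses, cfg_nodummy), "dummy")
  expect_identical(bands, c(0L, 0L, 1L))
  # a single mass classifies into band 0
  expect_identical(
    classify_bands(450.2, band_config(c(0, 2000, 4000),
                                      add_dummy_points = TRUE)),
    0L
  )
})

test_that("classification recovers true integer offsets on exact synthetic lines", {
  set.seed(51)
  for (b in c(5e-4, 5.5e-4, 6e-4, 6.5e-4)) {
    m <- runif(3000, 300, 5800)
    residual <- (b * m) %% 1
    truth <- round(b * m - residual)
    masses <- floor(m) + residual  # consistent mass/residual pair
    truth <- round(b * masses - decimal_residual(masses))
    cfg <- band_config(band_centers(b, max(masses)),
                       add_dummy_points = TRUE)
    assigned <- classify_bands(masses, cfg)
    expect_gte(mean(assigned == truth), 0.999)
  }
})

test_that("band boundaries fall where the residual wraps", {
  set.seed(52)
  b <- 5.1357e-4
  m <- sort(runif(3000, 300, 5800))
  masses <- floor(m) + (b * m) %% 1
  cfg <- band_config(c(0, 2000, 4000), add_dummy_points = TRUE)
  bands <- classify_bands(masses, cfg)
  # transitions occur near 1/b and 2/b (1947 and 3894 Da)
  expect_lt(abs(max(masses[bands == 0]) - 1 / b), 5)
  expect_lt(abs(max(masses[bands == 1]) - 2 / b), 5)
})

test_that("unwrapping adds the band index in Daltons", {
  expect_equal(unwrap_residuals(0.4, 0L), 0.4)
  expect_equal(unwrap_residuals(0.1, 2L), 2.1)
  expect_error(unwrap_residuals(c(0.1, 0.2), c(-1L, 0L)))
  # full pipeline: unwrapped minus raw residual is a non-negative integer
  set.seed(53)
  masses <- runif(500, 300, 5500)
  pts <- band_points(masses, band_config(add_dummy_points = TRUE))
  offs <- pts$residual_unwrapped - pts$residual
  expect_true(all(offs >= 0 & offs == floor(offs)))
  expect_identical(min(pts$band), 0L)
})

test_that("re-classification with a single center leaves residuals unchanged", {
  set.seed(54)
  masses <- runif(200, 300, 1800)
  pts <- band_points(masses, band_config(centers = 0))
  expect_equal(pts$residual_unwrapped, pts$residual)
  expect_true(all(pts$band == 0L))
})

test_that("dummy points do not move the fitted slope on well-spread data", {
  set.seed(55)
  b <- 5.2e-4
  m <- runif(500, 300, 5500)
  noise <- runif(500, -0.02, 0.02)
  masses <- floor(m) + ((b * m) %% 1 + noise) %% 1
  fit_for <- function(dummies) {
    pts <- band_points(masses, band_config(c(0, 2000, 4000),
                                           add_dummy_points = dummies))
    fit_slope_ols(pts$mass, pts$residual_unwrapped)$b
  }
  expect_equal(fit_for(TRUE), fit_for(FALSE), tolerance = 1e-7)
})

test_that("transformed-mass order matches mass order within a true band", {
  b <- 5.1357e-4
  m <- seq(400, 1900, by = 50)  # all in band 0 for this slope
  residual <- (b * m) %% 1
  tr <- transform_mass(m, residual)
  expect_identical(order(tr), order(m))
})

test_that("derived band centers reproduce the preset center sets", {
  light <- band_centers(5.1357e-4, 5800)
  heavy <- band_centers(6.3347e-4, 6100)
  expect_length(light, 3)
  expect_length(heavy, 4)
  expect_lt(max(abs(light - c(0, 2000, 4000))), 150)
  expect_lt(max(abs(heavy - c(0, 1600, 3200, 4800))), 250)
})
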